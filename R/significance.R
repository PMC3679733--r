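# Permutation machinery: genome-wide F thresholds from permuted datasets
# (residuals shuffled among individuals while the genotype indicators stay
# fixed) and a region-placement permutation test for pathway-gene overlap.

#' Genome-wide permutation threshold
#'
#' Residuals of the non-genetic model are shuffled among individuals while
#' the line-origin indicators stay fixed, preserving the fixed-effect
#' structure under the null. For each permutation the genome-wide maximum F
#' (over grid positions for a 1D scan, over admissible pairs for a 2D scan)
#' is recorded; the threshold at level `alpha` is the empirical (1 - alpha)
#' quantile of the maxima.
#'
#' @inheritParams scan_genome
#' @param n_perm number of permuted datasets (default 1000; >= 100 required).
#' @param alpha significance level(s) in (0, 1).
#' @param seed integer seed; the result is deterministic given the seed.
#' @param type `"1d"` (position scan) or `"2d"` (pair scan).
#' @param min_sep_steps same-group pair separation for `type = "2d"`.
#' @param batch permutations processed per block (memory control).
#' @return A `threshold_set`: named `thresholds` (one per alpha), the vector
#'   of permutation `maxima`, `n_perm`, `alpha`, `seed`, `type`.
#' @export
permutation_threshold <- function(nullspec, ind, n_perm = 1000,
                                  alpha = c(0.05, 0.01), seed = 1,
                                  type = c("1d", "2d"), min_sep_steps = 2,
                                  batch = 250) {
  type <- match.arg(type)
  if (n_perm < 100) stopf("parameter error: n_perm must be >= 100")
  if (any(alpha <= 0 | alpha >= 1)) stopf("parameter error: alpha must lie in (0, 1)")
  sp <- scan_inputs(nullspec, ind)
  base <- ols_qr(sp$X0, sp$y)
  resid <- sp$y - drop(sp$X0 %*% ifelse(is.na(base$coef), 0, base$coef))
  set.seed(seed)
  n <- length(resid)
  maxima <- numeric(n_perm)
  done <- 0
  while (done < n_perm) {
    nb <- min(batch, n_perm - done)
    Y <- vapply(seq_len(nb), function(i) resid[sample.int(n)], numeric(n))
    if (type == "1d") {
      Fm <- scan_F_multi(Y, ind, sp$rows_ind, sp$X0)
      maxima[done + seq_len(nb)] <- apply(Fm, 2, max, na.rm = TRUE)
    } else {
      maxima[done + seq_len(nb)] <- scan2d_maxF_multi(Y, ind, sp$rows_ind,
                                                      sp$X0, min_sep_steps)
    }
    done <- done + nb
  }
  thr <- stats::quantile(maxima, 1 - alpha, names = FALSE, type = 7)
  structure(list(thresholds = stats::setNames(thr, format(alpha)),
                 maxima = maxima, n_perm = n_perm, alpha = alpha,
                 seed = seed, type = type),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("Genome-wide %s permutation thresholds (%d permutations):\n",
              x$type, x$n_perm))
  for (a in names(x$thresholds)) {
    cat(sprintf("  alpha = %s: F = %.3f\n", a, x$thresholds[[a]]))
  }
  invisible(x)
}

# does region [s, e] on chromosome cc overlap any gene interval? (closed
# 1-based intervals; any shared base counts)
overlaps_gene <- function(cc, s, e, genes) {
  g <- genes[genes$chr == cc, , drop = FALSE]
  nrow(g) > 0 && any(g$start <= e & g$end >= s)
}

#' Count regions overlapping at least one gene
#'
#' @param regions data.frame with columns `chr`, `start`, `end` (1-based
#'   inclusive).
#' @param genes data.frame with columns `chr`, `start`, `end`.
#' @return Integer count of regions containing (overlapping) >= 1 gene.
#' @export
count_region_overlaps <- function(regions, genes) {
  sum(vapply(seq_len(nrow(regions)), function(k)
    overlaps_gene(regions$chr[k], regions$start[k], regions$end[k], genes), TRUE))
}

#' Region-placement permutation test for pathway enrichment
#'
#' Estimates how often the observed number of QTL regions containing pathway
#' genes would arise by chance. Per replicate: (1) each region is assigned a
#' chromosome uniformly with replacement from the supplied chromosomes;
#' (2) region sizes are drawn without replacement from the observed size
#' vector, with a validation step ensuring each chromosome is larger than the
#' summed sizes placed on it (the chromosome assignment is re-sampled on
#' failure); (3) start positions are uniform over valid bases, rejecting
#' placements that overrun the chromosome or overlap an already placed
#' region; then the number of regions overlapping >= 1 gene is scored.
#'
#' @param regions observed regions: data.frame `chr`, `start`, `end` (1-based
#'   inclusive, non-overlapping).
#' @param genes gene intervals: data.frame `chr`, `start`, `end`.
#' @param chrom_sizes data.frame `chr`, `size_bp` defining the chromosomes
#'   sampled from.
#' @param n_perm number of replicates (default 10000).
#' @param seed integer seed.
#' @param max_tries placement attempts before re-sampling a chromosome.
#' @return An `overlap_null`: `observed` count, `histogram` over counts
#'   0..n_regions, `p_ge` = Pr(count >= observed), `p_eq` = Pr(count ==
#'   observed), `n_perm`, `seed`.
#' @export
region_overlap_permutation <- function(regions, genes, chrom_sizes,
                                       n_perm = 10000, seed = 1,
                                       max_tries = 1000) {
  if (any(regions$end < regions$start)) stopf("region error: end < start")
  sizes <- regions$end - regions$start + 1
  csz <- stats::setNames(chrom_sizes$size_bp, as.character(chrom_sizes$chr))
  if (any(sizes > max(csz))) {
    stopf("infeasibility error: a region is larger than every chromosome")
  }
  chrs <- as.character(chrom_sizes$chr)
  nr <- length(sizes)
  observed <- count_region_overlaps(regions, genes)
  # pre-split genes by chromosome for speed
  gsplit <- split(genes[, c("start", "end")], as.character(genes$chr))
  set.seed(seed)
  counts <- integer(n_perm)
  for (rep in seq_len(n_perm)) {
    size_order <- sample.int(nr)           # sizes without replacement
    placed_s <- vector("list", length(chrs))
    names(placed_s) <- chrs
    placed_e <- placed_s
    used <- stats::setNames(numeric(length(chrs)), chrs)
    score <- 0L
    for (k in seq_len(nr)) {
      w <- sizes[size_order[k]]
      repeat {
        cc <- chrs[sample.int(length(chrs), 1)]   # with replacement
        if (used[cc] + w <= csz[cc]) break        # validation step
      }
      # uniform start over valid bases; reject overlaps and overruns
      tries <- 0
      repeat {
        tries <- tries + 1
        s <- sample.int(csz[cc] - w + 1, 1)
        e <- s + w - 1
        ps <- placed_s[[cc]]; pe <- placed_e[[cc]]
        if (is.null(ps) || !any(ps <= e & pe >= s)) break
        if (tries >= max_tries) {
          # pathological packing: re-sample the chromosome
          repeat {
            cc <- chrs[sample.int(length(chrs), 1)]
            if (used[cc] + w <= csz[cc]) break
          }
          tries <- 0
        }
      }
      placed_s[[cc]] <- c(placed_s[[cc]], s)
      placed_e[[cc]] <- c(placed_e[[cc]], e)
      used[cc] <- used[cc] + w
      g <- gsplit[[cc]]
      if (!is.null(g) && any(g$start <= e & g$end >= s)) score <- score + 1L
    }
    counts[rep] <- score
  }
  hist <- tabulate(counts + 1L, nbins = nr + 1L)
  names(hist) <- 0:nr
  structure(list(observed = observed, histogram = hist,
                 p_ge = mean(counts >= observed),
                 p_eq = mean(counts == observed),
                 counts = counts, n_perm = n_perm, seed = seed),
            class = "overlap_null")
}

#' @export
print.overlap_null <- function(x, ...) {
  cat(sprintf("Region-overlap permutation test (%d replicates)\n", x$n_perm))
  cat(sprintf("  observed regions with >= 1 pathway gene: %d\n", x$observed))
  cat(sprintf("  Pr(count >= observed) = %.4f; Pr(count == observed) = %.4f\n",
              x$p_ge, x$p_eq))
  invisible(x)
}

#' Convert between 1-based inclusive regions and 0-based half-open BED
#'
#' @param regions data.frame `chr`, `start`, `end` (1-based inclusive).
#' @return The same table in the other convention.
#' @export
regions_to_bed <- function(regions) {
  data.frame(chr = regions$chr, start = regions$start - 1, end = regions$end,
             stringsAsFactors = FALSE)
}

#' @rdname regions_to_bed
#' @param bed data.frame `chr`, `start`, `end` (0-based half-open).
#' @export
bed_to_regions <- function(bed) {
  data.frame(chr = bed$chr, start = bed$start + 1, end = bed$end,
             stringsAsFactors = FALSE)
}
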
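# Multipoint line-origin probabilities for F2 individuals.
#
# Hidden state at a locus = (maternal-gamete origin, paternal-gamete origin)
# in {A,B} x {A,B}, ordered AA, AB, BA, BB with the first letter the maternal
# gamete. Per-gamete transitions between adjacent loci are independent with
# switching probability equal to the Haldane recombination fraction for the
# cM gap; emissions are the probability of the observed biallelic call given
# the state and the founder-line allele frequencies; the prior at the start
# of each chromosome is (1/4, 1/4, 1/4, 1/4), the F2 expectation.

STATES <- c("AA", "AB", "BA", "BB")

#' Estimate founder-line allele frequencies
#'
#' Observed allele-1 proportions among the genotyped F0 of each line, with a
#' pseudocount per allele to keep frequencies off the 0/1 boundary (a single
#' miscalled founder would otherwise make an emission strictly impossible).
#'
#' @param genos a `cross_geno`.
#' @param pseudocount added to each allele's count (default 0.5).
#' @return data.frame of class `line_freqs`: marker, freq_a, freq_b (allele-1
#'   frequencies in lines A and B).
#' @export
estimate_line_frequencies <- function(genos, pseudocount = 0.5) {
  ped <- genos$ped
  out <- data.frame(marker = rownames(genos$calls), stringsAsFactors = FALSE)
  n_uninformative <- 0L
  for (ln in c("A", "B")) {
    ids <- ped$id[ped$generation == "F0" & !is.na(ped$line) & ped$line == ln]
    ids <- intersect(ids, colnames(genos$calls))
    if (length(ids) == 0) stopf("data error: no genotyped F0 founders in line %s", ln)
    g <- genos$calls[, ids, drop = FALSE]
    n_all <- 2 * rowSums(!is.na(g))
    n1 <- n_all - rowSums(g, na.rm = TRUE)     # allele-1 count
    freq <- (n1 + pseudocount) / (n_all + 2 * pseudocount)
    n_uninformative <- n_uninformative + sum(n_all == 0)
    out[[paste0("freq_", tolower(ln))]] <- freq
  }
  if (n_uninformative > 0) {
    warnf("%d marker/line combinations had no genotyped founders; frequency set to 0.5",
          n_uninformative)
  }
  class(out) <- c("line_freqs", "data.frame")
  out
}

# emission matrix (n_ind x 4) for one marker: probability of the observed
# call given each line-origin state; missing calls emit 1
emission_matrix <- function(g, pa, pb, epsilon = 0) {
  p1 <- c(pa, pa, pb, pb)   # maternal-gamete allele-1 frequency by state
  p2 <- c(pa, pb, pa, pb)   # paternal
  probs <- rbind(p1 * p2,                              # call 0 (two allele 1)
                 p1 * (1 - p2) + (1 - p1) * p2,        # call 1
                 (1 - p1) * (1 - p2))                  # call 2
  if (epsilon > 0) probs <- (1 - epsilon) * probs + epsilon / 3
  E <- matrix(1, length(g), 4)
  ok <- !is.na(g)
  E[ok, ] <- probs[g[ok] + 1L, , drop = FALSE]
  E
}

#' Compute line-origin probabilities on a cM grid
#'
#' Runs a 4-state forward-backward pass per F2 individual per chromosome,
#' evaluating posterior state probabilities at every grid position (grid
#' points that fall between markers are pseudo-loci with no emission). The
#' grid is anchored at the first marker of each group and ends at the last
#' marker, inclusive.
#'
#' @param genos a QC-passed `cross_geno`.
#' @param line_freqs a `line_freqs` table from [estimate_line_frequencies()]
#'   (markers must match `genos$map`).
#' @param grid_step grid spacing in cM (1 for one-dimensional scans, 5 is
#'   customary for two-dimensional scans).
#' @param epsilon per-call genotyping-error rate mixed into emissions
#'   (default 0).
#' @param individuals ids to compute for (default: all F2 in the pedigree).
#' @return A `lineorigin_grid`: list with `grid` (data.frame chr, pos),
#'   `prob` (array individuals x grid x 4, states AA, AB, BA, BB; maternal
#'   gamete first), and `ids`.
#' @export
compute_line_origin <- function(genos, line_freqs, grid_step = 1, epsilon = 0,
                                individuals = NULL) {
  map <- genos$map
  if (!identical(line_freqs$marker, map$marker)) {
    line_freqs <- line_freqs[match(map$marker, line_freqs$marker), , drop = FALSE]
    if (anyNA(line_freqs$freq_a)) stopf("data error: line frequencies missing for some markers")
  }
  if (grid_step <= 0) stopf("parameter error: grid_step must be positive")
  ids <- individuals %||% genos$ped$id[genos$ped$generation == "F2"]
  ids <- intersect(ids, colnames(genos$calls))
  n <- length(ids)
  if (n == 0) stopf("data error: no F2 individuals to compute for")

  chrs <- unique(map$chr)
  grid_list <- list(); prob_list <- list()
  for (cc in chrs) {
    mi <- which(map$chr == cc)
    mpos <- map$cM[mi]
    if (any(diff(mpos) < 0)) stopf("map error: negative cM gap on group %s", cc)
    gpos <- unique(c(seq(mpos[1], mpos[length(mpos)], by = grid_step),
                     mpos[length(mpos)]))
    # loci = union of markers and grid points, sorted; remember which is which
    loci <- sort(unique(c(mpos, gpos)))
    K <- length(loci)
    # emissions per locus (identity for pseudo-loci)
    E <- vector("list", K)
    for (k in seq_len(K)) {
      at <- mi[which(mpos == loci[k])]
      if (length(at) == 0) { E[[k]] <- NULL; next }
      Ek <- matrix(1, n, 4)
      for (m in at) {
        Ek <- Ek * emission_matrix(genos$calls[m, ids],
                                   line_freqs$freq_a[m], line_freqs$freq_b[m],
                                   epsilon)
      }
      E[[k]] <- Ek
    }
    r <- haldane(diff(loci))
    T4 <- lapply(r, function(rr) {
      t2 <- matrix(c(1 - rr, rr, rr, 1 - rr), 2, 2)
      t2 %x% t2
    })
    # forward
    f <- vector("list", K)
    cur <- matrix(0.25, n, 4)
    if (!is.null(E[[1]])) cur <- cur * E[[1]]
    cur <- cur / rowSums(cur)
    f[[1]] <- cur
    for (k in seq_len(K - 1)) {
      cur <- cur %*% T4[[k]]
      if (!is.null(E[[k + 1]])) cur <- cur * E[[k + 1]]
      cur <- cur / rowSums(cur)
      f[[k + 1]] <- cur
    }
    # backward
    post <- array(NA_real_, c(n, K, 4))
    cur <- matrix(1, n, 4)
    post[, K, ] <- f[[K]]
    for (k in rev(seq_len(K - 1))) {
      nxt <- cur
      if (!is.null(E[[k + 1]])) nxt <- nxt * E[[k + 1]]
      cur <- nxt %*% t(T4[[k]])
      cur <- cur / rowSums(cur)
      pk <- f[[k]] * cur
      post[, k, ] <- pk / rowSums(pk)
    }
    gi <- match(gpos, loci)
    grid_list[[cc]] <- data.frame(chr = cc, pos = gpos, stringsAsFactors = FALSE)
    prob_list[[cc]] <- post[, gi, , drop = FALSE]
  }
  grid <- do.call(rbind, grid_list)
  rownames(grid) <- NULL
  prob <- array(NA_real_, c(n, nrow(grid), 4),
                dimnames = list(ids, NULL, STATES))
  ofs <- 0
  for (cc in chrs) {
    np <- nrow(grid_list[[cc]])
    prob[, ofs + seq_len(np), ] <- prob_list[[cc]]
    ofs <- ofs + np
  }
  structure(list(grid = grid, prob = prob, ids = ids, step = grid_step),
            class = "lineorigin_grid")
}

#' @export
print.lineorigin_grid <- function(x, ...) {
  cat(sprintf("Line-origin grid: %d individuals, %d positions on %d group(s), step %g cM\n",
              length(x$ids), nrow(x$grid), length(unique(x$grid$chr)), x$step))
  invisible(x)
}

#' Regression indicators from line-origin probabilities
#'
#' A = Pr(AA) - Pr(BB) (in [-1, 1]; positive when the line-A origin is more
#' probable) and D = Pr(AB) + Pr(BA) (in [0, 1], the probability of
#' heterozygous line origin).
#'
#' @param grid a `lineorigin_grid`.
#' @return An `origin_indicators`: list with matrices `A` and `D`
#'   (individuals x grid positions), `grid` and `ids`.
#' @export
indicators <- function(grid) {
  d <- dim(grid$prob)[1:2]
  pick <- function(s) {
    m <- grid$prob[, , s, drop = FALSE]
    dim(m) <- d
    m
  }
  structure(list(A = pick(1) - pick(4), D = pick(2) + pick(3),
                 grid = grid$grid, ids = grid$ids, step = grid$step),
            class = "origin_indicators")
}
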
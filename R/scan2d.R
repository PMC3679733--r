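# Exhaustive two-locus epistasis scan. The null (marginal) model carries both
# loci's additive and dominance terms; the full model adds the four
# interaction indicators. F compares the two with 4 numerator df.

#' Interaction indicators for a locus pair
#'
#' Elementwise products of the marginal indicators:
#' I_A1A2 = A1*A2, I_A1D2 = A1*D2, I_D1A2 = D1*A2, I_D1D2 = D1*D2.
#'
#' @param A1,D1,A2,D2 aligned indicator vectors.
#' @return List with `I_A1A2`, `I_A1D2`, `I_D1A2`, `I_D1D2`.
#' @export
interaction_indicators <- function(A1, D1, A2, D2) {
  list(I_A1A2 = A1 * A2, I_A1D2 = A1 * D2, I_D1A2 = D1 * A2, I_D1D2 = D1 * D2)
}

# admissible pair list over the grid: all between-group pairs, plus
# within-group pairs separated by at least min_sep_steps grid steps
pair_list <- function(grid, step, min_sep_steps = 2) {
  np <- nrow(grid)
  ii <- rep(seq_len(np - 1), times = (np - 1):1)
  jj <- sequence((np - 1):1) + ii
  same <- grid$chr[ii] == grid$chr[jj]
  sep <- abs(grid$pos[jj] - grid$pos[ii])
  keep <- !same | sep >= min_sep_steps * step - 1e-9
  cbind(i = ii[keep], j = jj[keep])
}

#' Exhaustive two-dimensional epistasis scan
#'
#' For every admissible pair of grid positions, compares the full two-locus
#' model (marginal terms plus the four interaction indicators) against the
#' marginal-only model: F = ((RSS3 - RSS4)/4) / (RSS4/df4). Pairs on the same
#' linkage group must be at least `min_sep_steps` grid steps apart
#' (collinearity guard). Significant pairs exceed `threshold`; suggestive
#' pairs exceed `suggestive_F`. Adjacent significant grid pairs within
#' `merge_cM` on both axes are merged into peak regions, and each region is
#' reported at its maximum-F pair. Var% uses the marginal model as the
#' reduced model and the non-genetic model's mean square as denominator.
#'
#' @inheritParams scan_genome
#' @param ind an `origin_indicators`, typically on a 5 cM grid.
#' @param threshold genome-wide F threshold from [permutation_threshold()]
#'   with `type = "2d"`; when `NULL`, only the suggestive set is populated.
#' @param suggestive_F suggestive cut-off (default 8).
#' @param min_sep_steps minimum same-group separation in grid steps.
#' @param merge_cM merge radius for peak regions (default 20 cM).
#' @return An `epistasis_scan`: data.frame `pairs` (all pairs: chr1, pos1,
#'   chr2, pos2, F), `significant` and `suggestive` subsets reduced to peak
#'   regions with effect estimates (i1..i4 with SEs) and `var_pct`, and the
#'   fit bookkeeping.
#' @export
scan_pairs <- function(nullspec, ind, threshold = NULL, suggestive_F = 8,
                       min_sep_steps = 2, merge_cM = 20) {
  sp <- scan_inputs(nullspec, ind)
  y <- sp$y
  A <- ind$A[sp$rows_ind, , drop = FALSE]
  D <- ind$D[sp$rows_ind, , drop = FALSE]
  pl <- pair_list(ind$grid, ind$step, min_sep_steps)
  np <- nrow(pl)
  Fv <- numeric(np)
  rss3 <- numeric(np); rss4 <- numeric(np); df3 <- numeric(np); df4 <- numeric(np)
  n <- length(y)
  for (k in seq_len(np)) {
    i <- pl[k, 1]; j <- pl[k, 2]
    X3 <- cbind(sp$X0, A[, i], D[, i], A[, j], D[, j])
    X4 <- cbind(X3, A[, i] * A[, j], A[, i] * D[, j],
                D[, i] * A[, j], D[, i] * D[, j])
    f3 <- ols_qr(X3, y); f4 <- ols_qr(X4, y)
    rss3[k] <- f3$rss; rss4[k] <- f4$rss; df3[k] <- f3$df; df4[k] <- f4$df
    dfnum <- f4$rank - f3$rank
    Fv[k] <- if (dfnum > 0 && f4$df > 0 && f4$rss > 0)
      ((f3$rss - f4$rss) / dfnum) / (f4$rss / f4$df) else NA_real_
  }
  pairs <- data.frame(chr1 = ind$grid$chr[pl[, 1]], pos1 = ind$grid$pos[pl[, 1]],
                      chr2 = ind$grid$chr[pl[, 2]], pos2 = ind$grid$pos[pl[, 2]],
                      F = Fv, stringsAsFactors = FALSE)
  base <- ols_qr(sp$X0, y)
  ms_r <- base$rss / base$df
  sig <- if (!is.null(threshold)) which(Fv > threshold) else integer(0)
  sug <- which(Fv > suggestive_F)
  detail <- function(rows) {
    if (length(rows) == 0) return(empty_pairs())
    regions <- merge_pair_regions(pairs[rows, , drop = FALSE], merge_cM)
    out <- list()
    for (g in unique(regions)) {
      sub <- rows[regions == g]
      best <- sub[which.max(Fv[sub])]
      ft <- fit_pair(y, sp$X0, A, D, pl[best, 1], pl[best, 2])
      out[[length(out) + 1]] <- data.frame(
        chr1 = pairs$chr1[best], pos1 = pairs$pos1[best],
        chr2 = pairs$chr2[best], pos2 = pairs$pos2[best],
        F = Fv[best],
        i1 = ft$est[1], se_i1 = ft$se[1], i2 = ft$est[2], se_i2 = ft$se[2],
        i3 = ft$est[3], se_i3 = ft$se[3], i4 = ft$est[4], se_i4 = ft$se[4],
        var_pct = variance_explained(rss3[best] / df3[best],
                                     rss4[best] / df4[best], ms_r),
        n_grid_points = length(sub), stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }
  structure(list(pairs = pairs, significant = detail(sig),
                 suggestive = detail(setdiff(sug, sig)),
                 threshold = threshold, suggestive_F = suggestive_F,
                 ms_r = ms_r, n = n),
            class = "epistasis_scan")
}

empty_pairs <- function() {
  data.frame(chr1 = character(0), pos1 = numeric(0), chr2 = character(0),
             pos2 = numeric(0), F = numeric(0), i1 = numeric(0),
             se_i1 = numeric(0), i2 = numeric(0), se_i2 = numeric(0),
             i3 = numeric(0), se_i3 = numeric(0), i4 = numeric(0),
             se_i4 = numeric(0), var_pct = numeric(0),
             n_grid_points = integer(0))
}

# single-linkage merging of grid pairs into peak regions: two pairs belong to
# one region when both loci match in group and lie within merge_cM
merge_pair_regions <- function(pr, merge_cM) {
  m <- nrow(pr)
  grp <- seq_len(m)
  repeat {
    changed <- FALSE
    for (a in seq_len(m)) for (b in seq_len(m)) {
      if (grp[a] != grp[b] &&
          pr$chr1[a] == pr$chr1[b] && pr$chr2[a] == pr$chr2[b] &&
          abs(pr$pos1[a] - pr$pos1[b]) <= merge_cM &&
          abs(pr$pos2[a] - pr$pos2[b]) <= merge_cM) {
        grp[grp == grp[b]] <- grp[a]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  grp
}

# full two-locus fit returning interaction estimates, SEs and t statistics
fit_pair <- function(y, X0, A, D, i, j) {
  X4 <- cbind(X0, A[, i], D[, i], A[, j], D[, j],
              A[, i] * A[, j], A[, i] * D[, j], D[, i] * A[, j], D[, i] * D[, j])
  f <- ols_qr(X4, y)
  se <- ols_se(f)
  p <- ncol(X4)
  idx <- (p - 3):p
  est <- unname(f$coef[idx]); ses <- unname(se[idx])
  list(est = est, se = ses, t = est / ses, df = f$df, rss = f$rss)
}

#' @export
print.epistasis_scan <- function(x, ...) {
  cat(sprintf("Two-locus scan: %d pairs tested (n = %d)\n", nrow(x$pairs), x$n))
  cat(sprintf("  significant regions: %d (threshold %s)\n",
              nrow(x$significant),
              if (is.null(x$threshold)) "not supplied" else sprintf("F > %.2f", x$threshold)))
  cat(sprintf("  suggestive regions: %d (F > %g)\n", nrow(x$suggestive), x$suggestive_F))
  invisible(x)
}

#' Per-term significance of an epistatic pair
#'
#' t statistics for the four interaction effects from the full two-locus
#' model; the dominant term is the one with the largest |t|.
#'
#' @inheritParams scan_pairs
#' @param chr1,pos1,chr2,pos2 the pair to decompose.
#' @return data.frame with term, estimate, se, t, p and a `dominant` flag.
#' @export
decompose_epistasis <- function(nullspec, ind, chr1, pos1, chr2, pos2) {
  sp <- scan_inputs(nullspec, ind)
  A <- ind$A[sp$rows_ind, , drop = FALSE]
  D <- ind$D[sp$rows_ind, , drop = FALSE]
  i <- grid_index(ind, chr1, pos1); j <- grid_index(ind, chr2, pos2)
  ft <- fit_pair(sp$y, sp$X0, A, D, i, j)
  out <- data.frame(term = c("add_by_add", "add_by_dom", "dom_by_add", "dom_by_dom"),
                    estimate = ft$est, se = ft$se, t = ft$t,
                    p = 2 * stats::pt(-abs(ft$t), ft$df),
                    stringsAsFactors = FALSE)
  out$dominant <- FALSE
  out$dominant[which.max(abs(out$t))] <- TRUE
  out
}

# F profile over all admissible pairs for many response columns at once
# (permutation workhorse); returns max F per column
scan2d_maxF_multi <- function(Y, ind, rows_ind, X0, min_sep_steps = 2) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  A <- ind$A[rows_ind, , drop = FALSE]
  D <- ind$D[rows_ind, , drop = FALSE]
  pl <- pair_list(ind$grid, ind$step, min_sep_steps)
  mx <- rep(-Inf, ncol(Y))
  for (k in seq_len(nrow(pl))) {
    i <- pl[k, 1]; j <- pl[k, 2]
    X3 <- cbind(X0, A[, i], D[, i], A[, j], D[, j])
    X4 <- cbind(X3, A[, i] * A[, j], A[, i] * D[, j],
                D[, i] * A[, j], D[, i] * D[, j])
    Fv <- nested_F_multi(qr(X3), qr(X4), Y, n)
    mx <- pmax(mx, Fv, na.rm = TRUE)
  }
  mx
}

#' Discretised two-locus genotype-phenotype map
#'
#' Assigns each individual, at each of the two loci, the line-origin genotype
#' whose posterior probability exceeds `min_prob` (heterozygous classes AB
#' and BA pooled by summing before thresholding, unless `pool_het = FALSE`),
#' drops individuals without a confident call at either locus, and tabulates
#' counts and mean null-model residuals per two-locus genotype class.
#'
#' @param grid a `lineorigin_grid`.
#' @param chr1,pos1,chr2,pos2 the locus pair.
#' @param residuals named numeric vector of null-model residuals (names =
#'   individual ids), e.g. `nullspec$residuals`.
#' @param min_prob confidence threshold (default 0.8, strict).
#' @param pool_het pool AB/BA into one heterozygous class (default `TRUE`).
#' @return A `twolocus_map`: `count` and `mean` matrices (rows = locus-1
#'   classes, columns = locus-2 classes), plus `n_used` and `n_dropped`.
#' @export
genotype_phenotype_map <- function(grid, chr1, pos1, chr2, pos2, residuals,
                                   min_prob = 0.8, pool_het = TRUE) {
  al <- align_rows(names(residuals), grid$ids)
  fake_ind <- list(grid = grid$grid)   # reuse grid_index's lookup
  k1 <- grid_index(fake_ind, chr1, pos1)
  k2 <- grid_index(fake_ind, chr2, pos2)
  classify <- function(k) {
    P <- grid$prob[al$ind, k, , drop = TRUE]
    if (pool_het) {
      P3 <- cbind(AA = P[, 1], AB = P[, 2] + P[, 3], BB = P[, 4])
    } else {
      P3 <- P
      colnames(P3) <- STATES
    }
    best <- max.col(P3, ties.method = "first")
    conf <- P3[cbind(seq_len(nrow(P3)), best)] > min_prob
    ifelse(conf, colnames(P3)[best], NA_character_)
  }
  g1 <- classify(k1); g2 <- classify(k2)
  use <- !is.na(g1) & !is.na(g2)
  lev <- if (pool_het) c("AA", "AB", "BB") else STATES
  cnt <- matrix(0L, length(lev), length(lev), dimnames = list(lev, lev))
  mn <- matrix(NA_real_, length(lev), length(lev), dimnames = list(lev, lev))
  if (!any(use)) {
    warnf("no individuals with confident genotypes at both loci")
  } else {
    res <- as.numeric(residuals)[al$ph]
    tb <- table(factor(g1[use], lev), factor(g2[use], lev))
    cnt[] <- as.integer(tb)
    sums <- tapply(res[use], list(factor(g1[use], lev), factor(g2[use], lev)), mean)
    mn[!is.na(sums)] <- sums[!is.na(sums)]
  }
  structure(list(count = cnt, mean = mn, n_used = sum(use),
                 n_dropped = sum(!use)),
            class = "twolocus_map")
}

#' @export
print.twolocus_map <- function(x, ...) {
  cat(sprintf("Two-locus genotype-phenotype map (%d individuals, %d dropped)\n",
              x$n_used, x$n_dropped))
  cat("Counts:\n"); print(x$count)
  cat("Mean residual phenotype:\n"); print(round(x$mean, 3))
  invisible(x)
}
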
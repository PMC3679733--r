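# One-dimensional Haley-Knott genome scan: phenotype regressed on the
# expected additive (A) and dominance (D) line-origin indicators at each grid
# position, on top of the selected non-genetic model and any cofactors.

# stable OLS via QR with pivoting; returns coefficient table and fit summary
ols_qr <- function(X, y) {
  qx <- qr(X)
  r <- qx$rank
  cf <- qr.coef(qx, y)
  rss <- sum(qr.resid(qx, y)^2)
  df <- length(y) - r
  list(qr = qx, coef = cf, rss = rss, df = df, rank = r)
}

# standard errors for the coefficients of an ols_qr fit (NA where aliased)
ols_se <- function(fit) {
  p <- length(fit$coef)
  se <- rep(NA_real_, p)
  if (fit$df <= 0) return(se)
  R <- qr.R(fit$qr)[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE]
  xtxinv <- chol2inv(R)
  sigma2 <- fit$rss / fit$df
  piv <- fit$qr$pivot[seq_len(fit$rank)]
  se[piv] <- sqrt(pmax(sigma2 * diag(xtxinv), 0))
  names(se) <- names(fit$coef)
  se
}

# match phenotype rows (named y / null-model) to indicator rows
align_rows <- function(ids_pheno, ids_ind) {
  common <- intersect(ids_pheno, ids_ind)
  if (length(common) == 0) stopf("data error: no individuals shared between phenotype and indicators")
  list(ph = match(common, ids_pheno), ind = match(common, ids_ind), ids = common)
}

# index of the grid position for (chr, pos), nearest within the group
grid_index <- function(ind, chr, pos) {
  w <- which(ind$grid$chr == as.character(chr))
  if (length(w) == 0) stopf("position error: group '%s' not on grid", chr)
  w[which.min(abs(ind$grid$pos[w] - pos))]
}

#' Fit the single-position QTL model
#'
#' Least-squares fit of trait = non-genetic terms + cofactors + a*A + d*D,
#' versus the same model without (a, d). The F statistic has 2 numerator
#' degrees of freedom. A positive `a` means the line-A allele increases the
#' trait (A = Pr(AA) - Pr(BB)).
#'
#' @param y numeric response vector.
#' @param A,D indicator vectors at the tested position, aligned with `y`.
#' @param X0 design matrix of the non-genetic model (default: intercept).
#' @param cofactors optional matrix of frozen (A, D) columns of previously
#'   called QTL.
#' @return List of class `position_fit`: `a`, `d`, `se_a`, `se_d`, `F`,
#'   `rss_full`, `df_full`, `rss_red`, `df_red`, `degenerate` (`TRUE` when
#'   the full model fits perfectly, in which case `F` is `Inf` and the SEs
#'   are `NA`).
#' @export
fit_position <- function(y, A, D, X0 = NULL, cofactors = NULL) {
  n <- length(y)
  if (is.null(X0)) X0 <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  Xred <- if (is.null(cofactors)) X0 else cbind(X0, cofactors)
  Xfull <- cbind(Xred, A = A, D = D)
  if (n <= ncol(Xfull)) stopf("data error: more parameters than observations")
  red <- ols_qr(Xred, y)
  full <- ols_qr(Xfull, y)
  ia <- ncol(Xfull) - 1L; id <- ncol(Xfull)
  tol <- 1e-10 * max(red$rss, .Machine$double.eps)
  degenerate <- full$rss <= tol
  if (degenerate) {
    Fv <- Inf
    se <- c(NA_real_, NA_real_)
  } else {
    Fv <- ((red$rss - full$rss) / 2) / (full$rss / full$df)
    ses <- ols_se(full)
    se <- c(ses[ia], ses[id])
  }
  structure(list(a = unname(full$coef[ia]), d = unname(full$coef[id]),
                 se_a = unname(se[1]), se_d = unname(se[2]),
                 F = max(Fv, 0), rss_full = full$rss, df_full = full$df,
                 rss_red = red$rss, df_red = red$df,
                 degenerate = degenerate),
            class = "position_fit")
}

# F profile for many response columns at once (permutation workhorse):
# returns matrix n_positions x n_response
scan_F_multi <- function(Y, ind, rows_ind, X0, cofactors = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  Xred <- if (is.null(cofactors)) X0 else cbind(X0, cofactors)
  qr_red <- qr(Xred)
  np <- nrow(ind$grid)
  out <- matrix(NA_real_, np, ncol(Y))
  for (k in seq_len(np)) {
    Xfull <- cbind(Xred, ind$A[rows_ind, k], ind$D[rows_ind, k])
    out[k, ] <- nested_F_multi(qr_red, qr(Xfull), Y, n)
  }
  out
}

#' One-dimensional genome scan
#'
#' Fits [fit_position()] at every grid position. The peak is the position of
#' maximum F; ties are broken towards the smallest linkage-group number, then
#' the smallest cM.
#'
#' @param nullspec a [select_null_model()] result, or a named numeric vector
#'   of trait values (names = individual ids) for an intercept-only model.
#' @param ind an `origin_indicators` object.
#' @param cofactors optional matrix of cofactor columns (rows aligned with
#'   `ind$ids`), as built by [forward_scan()].
#' @param map optional [genetic_map()] for nearest-peak-marker reporting.
#' @return A `qtl_scan`: data.frame `result` (chr, pos, F, a, se_a, d, se_d),
#'   `peak` (row of the peak with nearest `marker` if a map was given), and
#'   the number of individuals used.
#' @export
scan_genome <- function(nullspec, ind, cofactors = NULL, map = NULL) {
  sp <- scan_inputs(nullspec, ind)
  cof <- if (is.null(cofactors)) NULL else cofactors[sp$rows_ind, , drop = FALSE]
  np <- nrow(ind$grid)
  res <- data.frame(chr = ind$grid$chr, pos = ind$grid$pos,
                    F = NA_real_, a = NA_real_, se_a = NA_real_,
                    d = NA_real_, se_d = NA_real_)
  for (k in seq_len(np)) {
    f <- fit_position(sp$y, ind$A[sp$rows_ind, k], ind$D[sp$rows_ind, k],
                      X0 = sp$X0, cofactors = cof)
    res$F[k] <- f$F; res$a[k] <- f$a; res$se_a[k] <- f$se_a
    res$d[k] <- f$d; res$se_d[k] <- f$se_d
  }
  ord <- order(-res$F, chr_rank(res$chr), res$pos)
  peak <- res[ord[1], , drop = FALSE]
  if (!is.null(map)) {
    mm <- map[map$chr == peak$chr, , drop = FALSE]
    peak$marker <- mm$marker[which.min(abs(mm$cM - peak$pos))]
  }
  structure(list(result = res, peak = peak, n = length(sp$y)),
            class = "qtl_scan")
}

#' @export
print.qtl_scan <- function(x, ...) {
  cat(sprintf("Genome scan over %d positions (n = %d); peak F = %.2f at %s:%g cM\n",
              nrow(x$result), x$n, x$peak$F, x$peak$chr, x$peak$pos))
  invisible(x)
}

# normalise the (nullspec | named y) polymorphism and align with indicators
scan_inputs <- function(nullspec, ind) {
  if (inherits(nullspec, "null_model")) {
    ids <- nullspec$ids
    y <- nullspec$fit$model[[1]]
    X0 <- nullspec$X
  } else {
    y <- nullspec
    ids <- names(y)
    if (is.null(ids)) {
      if (length(y) != length(ind$ids)) {
        stopf("data error: unnamed response of wrong length")
      }
      ids <- ind$ids
    }
    X0 <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  }
  al <- align_rows(ids, ind$ids)
  list(y = as.numeric(y)[al$ph], X0 = X0[al$ph, , drop = FALSE],
       rows_ind = al$ind, ids = al$ids)
}

#' Iterative forward cofactor scan
#'
#' Scans the genome, takes the most significant peak exceeding the 5%
#' genome-wide threshold, freezes its A and D indicators as cofactors, and
#' rescans, stopping when no peak exceeds the threshold. Thresholds are
#' computed once from the cofactor-free permutation null and reused across
#' rounds. Each call is classified at the 1% genome-wide level where its
#' round's peak F exceeds that threshold. Additive/dominance effects, their
#' SEs and the variance explained are reported from the final joint model
#' containing all called QTL.
#'
#' @inheritParams scan_genome
#' @param thresholds optional `threshold_set` from [permutation_threshold()];
#'   computed internally (with `n_perm`, `seed`) when `NULL`.
#' @param n_perm,seed permutation settings used when `thresholds` is `NULL`.
#' @param max_qtl safety cap on the number of rounds (default 10).
#' @param cross_tag prefix for QTL names (names are tag + linkage group +
#'   letter suffix in cM order, e.g. `"Q1a"`).
#' @return A `qtl_calls` object: data.frame `calls` (name, chr, pos, marker,
#'   F, a, se_a, d, se_d, var_pct, level), the `thresholds` used, and the
#'   final scan.
#' @export
forward_scan <- function(nullspec, ind, thresholds = NULL, n_perm = 1000,
                         seed = 1, max_qtl = 10, map = NULL, cross_tag = "Q") {
  sp <- scan_inputs(nullspec, ind)
  if (is.null(thresholds)) {
    thresholds <- permutation_threshold(nullspec, ind, n_perm = n_perm,
                                        alpha = c(0.05, 0.01), seed = seed)
  }
  thr5 <- thresholds$thresholds[["0.05"]]
  thr1 <- thresholds$thresholds[["0.01"]]
  calls <- list(); cof <- NULL; last_scan <- NULL
  for (round in seq_len(max_qtl)) {
    sc <- scan_genome(nullspec, ind, cofactors = cof, map = map)
    last_scan <- sc
    if (!is.finite(sc$peak$F) || sc$peak$F <= thr5) {
      if (is.infinite(sc$peak$F)) {
        # degenerate perfect fit: call it, but there is nothing left to scan
        calls[[round]] <- data.frame(chr = sc$peak$chr, pos = sc$peak$pos,
                                     F = Inf, level = "1%")
      }
      break
    }
    calls[[round]] <- data.frame(chr = sc$peak$chr, pos = sc$peak$pos,
                                 F = sc$peak$F,
                                 level = if (sc$peak$F > thr1) "1%" else "5%",
                                 stringsAsFactors = FALSE)
    k <- grid_index(ind, sc$peak$chr, sc$peak$pos)
    newcols <- cbind(ind$A[, k], ind$D[, k])
    colnames(newcols) <- paste0(c("A_", "D_"), sc$peak$chr, "_", sc$peak$pos)
    cof <- if (is.null(cof)) newcols else cbind(cof, newcols)
  }
  if (length(calls) == 0) {
    return(structure(list(calls = empty_calls(), thresholds = thresholds,
                          scan = last_scan), class = "qtl_calls"))
  }
  cl <- do.call(rbind, calls)
  # joint final model for effects, SEs and variance explained
  q <- nrow(cl)
  ks <- vapply(seq_len(q), function(i) grid_index(ind, cl$chr[i], cl$pos[i]), 0L)
  AD <- do.call(cbind, lapply(ks, function(k)
    cbind(ind$A[sp$rows_ind, k], ind$D[sp$rows_ind, k])))
  full <- ols_qr(cbind(sp$X0, AD), sp$y)
  ses <- ols_se(full)
  base <- ols_qr(sp$X0, sp$y)
  ms_r <- base$rss / base$df
  ms_f <- full$rss / full$df
  p0 <- ncol(sp$X0)
  cl$a <- cl$d <- cl$se_a <- cl$se_d <- cl$var_pct <- NA_real_
  for (i in seq_len(q)) {
    ia <- p0 + 2 * i - 1
    cl$a[i] <- unname(full$coef[ia]); cl$se_a[i] <- unname(ses[ia])
    cl$d[i] <- unname(full$coef[ia + 1]); cl$se_d[i] <- unname(ses[ia + 1])
    redX <- cbind(sp$X0, AD[, -c(2 * i - 1, 2 * i), drop = FALSE])
    red <- ols_qr(redX, sp$y)
    cl$var_pct[i] <- variance_explained(red$rss / red$df, ms_f, ms_r)
  }
  # nearest markers and names (letter suffix in cM order within group)
  cl$marker <- NA_character_
  if (!is.null(map)) {
    for (i in seq_len(q)) {
      mm <- map[map$chr == cl$chr[i], , drop = FALSE]
      cl$marker[i] <- mm$marker[which.min(abs(mm$cM - cl$pos[i]))]
    }
  }
  cl$name <- NA_character_
  for (cc in unique(cl$chr)) {
    w <- which(cl$chr == cc)
    w <- w[order(cl$pos[w])]
    suf <- if (length(w) > 1) letters[seq_along(w)] else ""
    cl$name[w] <- paste0(cross_tag, cc, suf)
  }
  cl <- cl[, c("name", "chr", "pos", "marker", "F", "a", "se_a", "d", "se_d",
               "var_pct", "level")]
  structure(list(calls = cl, thresholds = thresholds, scan = last_scan),
            class = "qtl_calls")
}

empty_calls <- function() {
  data.frame(name = character(0), chr = character(0), pos = numeric(0),
             marker = character(0), F = numeric(0), a = numeric(0),
             se_a = numeric(0), d = numeric(0), se_d = numeric(0),
             var_pct = numeric(0), level = character(0))
}

#' @export
print.qtl_calls <- function(x, ...) {
  if (nrow(x$calls) == 0) {
    cat("No QTL exceeded the genome-wide threshold\n")
  } else {
    cat(sprintf("%d QTL called (5%% threshold F = %.2f):\n", nrow(x$calls),
                x$thresholds$thresholds[["0.05"]]))
    print.data.frame(x$calls, digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' Joint test of two linked QTL
#'
#' Fits both positions' (A, D) pairs jointly with the non-genetic model and
#' computes each QTL's partial F (2 df) by dropping its own pair. The two
#' peaks are declared independent QTL only if both partial Fs exceed the
#' threshold.
#'
#' @inheritParams scan_genome
#' @param chr linkage group carrying both candidate peaks.
#' @param pos1,pos2 the two candidate positions (cM); must be at least one
#'   grid step apart.
#' @param threshold genome-wide F threshold to compare the partial Fs with.
#' @return List of class `linked_pair_test`: partial `F1`, `F2`, the joint
#'   fit RSS/df, and `independent` (logical verdict).
#' @export
test_linked_pair <- function(nullspec, ind, chr, pos1, pos2, threshold) {
  if (abs(pos1 - pos2) < ind$step) {
    stopf("collinearity error: positions are closer than one grid step")
  }
  sp <- scan_inputs(nullspec, ind)
  k1 <- grid_index(ind, chr, pos1); k2 <- grid_index(ind, chr, pos2)
  if (k1 == k2) stopf("collinearity error: positions resolve to the same grid point")
  X1 <- cbind(ind$A[sp$rows_ind, k1], ind$D[sp$rows_ind, k1])
  X2 <- cbind(ind$A[sp$rows_ind, k2], ind$D[sp$rows_ind, k2])
  full <- ols_qr(cbind(sp$X0, X1, X2), sp$y)
  red1 <- ols_qr(cbind(sp$X0, X2), sp$y)   # drop QTL 1
  red2 <- ols_qr(cbind(sp$X0, X1), sp$y)
  F1 <- ((red1$rss - full$rss) / 2) / (full$rss / full$df)
  F2 <- ((red2$rss - full$rss) / 2) / (full$rss / full$df)
  structure(list(F1 = F1, F2 = F2, rss_full = full$rss, df_full = full$df,
                 threshold = threshold,
                 independent = F1 > threshold && F2 > threshold),
            class = "linked_pair_test")
}

#' Variance explained by a QTL (or QTL pair)
#'
#' Var% = (MS'_R - MS_F) / MS_R x 100, where MS'_R is the residual mean
#' square of the reduced model (non-genetic terms plus any other QTL as
#' cofactors), MS_F that of the full model including the tested QTL, and
#' MS_R that of the non-genetic model alone.
#'
#' @param ms_r_prime,ms_f,ms_r residual mean squares as above (all >= 0,
#'   `ms_r` > 0).
#' @return Percentage of residual phenotypic variance explained.
#' @export
variance_explained <- function(ms_r_prime, ms_f, ms_r) {
  if (any(c(ms_r_prime, ms_f, ms_r) < 0)) stopf("parameter error: mean squares must be >= 0")
  if (ms_r == 0) stopf("degenerate error: null-model residual mean square is zero")
  (ms_r_prime - ms_f) / ms_r * 100
}
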
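# Phenotype cleaning, derived growth traits, correlations and selection of
# the non-genetic ("null") model whose residuals feed the QTL scans.

#' Flag boxplot outliers in one trait
#'
#' A value is flagged when it lies more than 1.5 interquartile ranges beyond
#' the lower or upper quartile. Quartiles use linear interpolation of order
#' statistics (R's default quantile type 7).
#'
#' @param values numeric vector (missing allowed; at least 4 non-missing).
#' @param k fence multiplier (default 1.5).
#' @return Character vector (same length): `"ok"`, `"low"`, `"high"`, or `NA`
#'   where the value is missing.
#' @export
flag_outliers <- function(values, k = 1.5) {
  obs <- values[!is.na(values)]
  if (length(obs) == 0) stopf("data error: trait has no observations")
  if (length(obs) < 4) stopf("data error: need >= 4 observations to form quartiles")
  q <- stats::quantile(obs, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - k * iqr
  hi <- q[2] + k * iqr
  out <- rep(NA_character_, length(values))
  ok <- !is.na(values)
  out[ok] <- ifelse(values[ok] < lo, "low",
                    ifelse(values[ok] > hi, "high", "ok"))
  out
}

#' Resolve flagged outliers across a longitudinal trait family
#'
#' A flagged value is retained (not excluded) when either: (a) the same
#' individual is flagged on the same side at two or more consecutive ages in
#' the family - the deviation is a consistent feature of the bird, not a
#' recording error; or (b) at least `K` individuals are flagged on the same
#' side at the same age - a clustered event such as a shared environmental
#' shock. All other flagged values are marked for exclusion.
#'
#' @param flags character matrix (individuals x ages, ordered by age) of
#'   `"ok"`/`"low"`/`"high"`/`NA` as returned by [flag_outliers()].
#' @param K cluster size for rule (b) (default 5).
#' @return Logical matrix of the same shape: `TRUE` where the value should be
#'   set missing.
#' @export
resolve_outliers <- function(flags, K = 5) {
  flags <- as.matrix(flags)
  flagged <- !is.na(flags) & flags != "ok"
  keep <- matrix(FALSE, nrow(flags), ncol(flags))
  for (side in c("low", "high")) {
    s <- !is.na(flags) & flags == side
    # (a) consecutive-age consistency
    if (ncol(s) > 1) {
      for (j in seq_len(ncol(s) - 1)) {
        both <- s[, j] & s[, j + 1]
        keep[both, j] <- TRUE
        keep[both, j + 1] <- TRUE
      }
    }
    # (b) same-side cluster at one age
    cl <- colSums(s) >= K
    keep[, cl] <- keep[, cl] | s[, cl, drop = FALSE]
  }
  flagged & !keep
}

#' Clean a phenotype table by the boxplot rule
#'
#' Applies [flag_outliers()] and [resolve_outliers()] to each longitudinal
#' trait family and sets excluded values missing.
#'
#' @param pheno a phenotype data.frame.
#' @param families named list; each element is a character vector of column
#'   names ordered by age (a family may have length 1, in which case only the
#'   cluster rule can retain a flagged value).
#' @param K cluster size for the retention rule.
#' @return List with `pheno` (cleaned) and `audit` (data.frame of removed
#'   values: id, trait, value, side).
#' @export
clean_phenotypes <- function(pheno, families, K = 5) {
  audit <- list()
  for (fam in names(families)) {
    cols <- families[[fam]]
    miss <- setdiff(cols, names(pheno))
    if (length(miss) > 0) stopf("data error: columns not in table: %s",
                                paste(miss, collapse = ", "))
    flags <- sapply(cols, function(cc) flag_outliers(pheno[[cc]]))
    excl <- resolve_outliers(flags, K = K)
    for (j in seq_along(cols)) {
      w <- which(excl[, j])
      if (length(w) > 0) {
        audit[[length(audit) + 1]] <- data.frame(
          id = if ("id" %in% names(pheno)) pheno$id[w] else w,
          trait = cols[j], value = pheno[[cols[j]]][w],
          side = flags[w, j], stringsAsFactors = FALSE)
        pheno[[cols[j]]][w] <- NA
      }
    }
  }
  list(pheno = pheno,
       audit = if (length(audit) > 0) do.call(rbind, audit)
               else data.frame(id = character(0), trait = character(0),
                               value = numeric(0), side = character(0)))
}

#' Derive growth rate and feed conversion ratio columns
#'
#' GR for a window is the body-weight gain between its endpoint weights; FCR
#' is feed intake over the window divided by the gain. A window with a
#' missing endpoint yields a missing derived value; an FCR window with zero
#' or negative gain is set missing with a warning (the ratio is undefined or
#' unstable).
#'
#' @param pheno phenotype data.frame.
#' @param gr_windows named list: derived column -> c(start BW column, end BW
#'   column). Default: GR0_4, GR4_8, GR8_12 from BW0..BW12.
#' @param fcr_windows named list: derived column -> c(intake column, start BW
#'   column, end BW column). Default: FCR6_8, FCR8_10, FCR10_12.
#' @return The table with derived columns appended (recomputed if present).
#' @export
derive_traits <- function(pheno,
                          gr_windows = list(GR0_4 = c("BW0", "BW4"),
                                            GR4_8 = c("BW4", "BW8"),
                                            GR8_12 = c("BW8", "BW12")),
                          fcr_windows = list(FCR6_8 = c("FI6_8", "BW6", "BW8"),
                                             FCR8_10 = c("FI8_10", "BW8", "BW10"),
                                             FCR10_12 = c("FI10_12", "BW10", "BW12"))) {
  for (nm in names(gr_windows)) {
    w <- gr_windows[[nm]]
    if (!all(w %in% names(pheno))) next
    pheno[[nm]] <- pheno[[w[2]]] - pheno[[w[1]]]
  }
  for (nm in names(fcr_windows)) {
    w <- fcr_windows[[nm]]
    if (!all(w %in% names(pheno))) next
    gain <- pheno[[w[3]]] - pheno[[w[2]]]
    bad <- !is.na(gain) & gain <= 0
    if (any(bad)) {
      warnf("%s: %d individuals with non-positive gain set missing", nm, sum(bad))
      gain[bad] <- NA
    }
    pheno[[nm]] <- pheno[[w[1]]] / gain
  }
  pheno
}

#' Pairwise Pearson correlations with p-values
#'
#' Pearson r on pairwise-complete observations, with two-sided p-values from
#' the t transform r * sqrt((n-2)/(1-r^2)). Pairs with fewer than 3 complete
#' observations or a zero-variance column are `NA`.
#'
#' @param pheno data.frame.
#' @param traits columns to correlate (default: all numeric columns).
#' @return List of class `trait_cor` with matrices `r`, `p` and `n`.
#' @export
trait_correlations <- function(pheno, traits = NULL) {
  if (is.null(traits)) {
    traits <- names(pheno)[vapply(pheno, is.numeric, TRUE)]
    traits <- setdiff(traits, c("batch", "family"))
  }
  X <- as.matrix(pheno[, traits, drop = FALSE])
  k <- ncol(X)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  for (i in seq_len(k)) for (j in i:k) {
    ok <- stats::complete.cases(X[, c(i, j)])
    nn <- sum(ok)
    n[i, j] <- n[j, i] <- nn
    if (nn < 3) next
    si <- stats::sd(X[ok, i]); sj <- stats::sd(X[ok, j])
    if (si == 0 || sj == 0) next
    rr <- stats::cor(X[ok, i], X[ok, j])
    r[i, j] <- r[j, i] <- rr
    if (i == j) { p[i, j] <- NA_real_; next }
    tt <- rr * sqrt((nn - 2) / max(1 - rr^2, .Machine$double.eps))
    p[i, j] <- p[j, i] <- 2 * stats::pt(-abs(tt), nn - 2)
  }
  structure(list(r = r, p = p, n = n), class = "trait_cor")
}

#' Select the non-genetic null model for a trait
#'
#' Backward elimination among candidate fixed-effect factors and covariates
#' by partial F-tests: starting from the model with all candidates, the least
#' significant term is dropped until every remaining term is significant at
#' `alpha`. The retained model supplies the residuals and residual mean
#' square used by the genome scans.
#'
#' @param pheno phenotype data.frame with an `id` column.
#' @param trait trait column name.
#' @param factors candidate fixed-effect factor columns (default sex, batch,
#'   family where present).
#' @param covariates candidate numeric covariate columns.
#' @param alpha retention level for the partial F-test (default 0.05).
#' @return Object of class `null_model`: trait, retained terms, fitted `lm`,
#'   `ids` of the rows used, named `residuals`, `ms_r` (residual mean
#'   square), `df_residual`, and the model design matrix `X`.
#' @export
select_null_model <- function(pheno, trait, factors = NULL, covariates = character(0),
                              alpha = 0.05) {
  if (is.null(factors)) factors <- intersect(c("sex", "batch", "family"), names(pheno))
  miss <- setdiff(c(trait, factors, covariates), names(pheno))
  if (length(miss) > 0) stopf("data error: columns not in table: %s",
                              paste(miss, collapse = ", "))
  dat <- pheno[, unique(c("id", trait, factors, covariates)), drop = FALSE]
  for (f in factors) dat[[f]] <- factor(dat[[f]])
  dat <- dat[stats::complete.cases(dat[, c(trait, factors, covariates), drop = FALSE]), ,
             drop = FALSE]
  # drop degenerate candidates (single level / zero variance)
  factors <- factors[vapply(factors, function(f) nlevels(dat[[f]]) > 1, TRUE)]
  covariates <- covariates[vapply(covariates, function(v) stats::sd(dat[[v]]) > 0, TRUE)]
  terms_now <- c(factors, covariates)
  repeat {
    fml <- stats::reformulate(if (length(terms_now) > 0) terms_now else "1",
                              response = trait)
    fit <- stats::lm(fml, data = dat)
    if (any(is.na(stats::coef(fit)))) {
      aliased <- names(which(is.na(stats::coef(fit))))
      warnf("rank-deficient design; aliased coefficients: %s",
            paste(aliased, collapse = ", "))
    }
    if (length(terms_now) == 0) break
    dr <- stats::drop1(fit, test = "F")
    pv <- dr[["Pr(>F)"]][-1]
    names(pv) <- rownames(dr)[-1]
    pv[is.na(pv)] <- 1      # aliased term explains nothing: drop it first
    worst <- which.max(pv)
    if (pv[worst] > alpha) {
      terms_now <- setdiff(terms_now, names(pv)[worst])
    } else break
  }
  res <- stats::residuals(fit)
  ids <- if ("id" %in% names(dat)) dat$id else rownames(dat)
  names(res) <- ids
  X <- stats::model.matrix(fit)
  structure(list(trait = trait,
                 factors = intersect(terms_now, factors),
                 covariates = intersect(terms_now, covariates),
                 fit = fit, ids = ids, residuals = res,
                 ms_r = sum(res^2) / fit$df.residual,
                 df_residual = fit$df.residual, X = X),
            class = "null_model")
}

#' @export
print.null_model <- function(x, ...) {
  cat(sprintf("Null model for %s: %s (n = %d, residual MS = %.4g, df = %d)\n",
              x$trait,
              if (length(c(x$factors, x$covariates)) > 0)
                paste(c(x$factors, x$covariates), collapse = " + ")
              else "intercept only",
              length(x$ids), x$ms_r, x$df_residual))
  invisible(x)
}
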
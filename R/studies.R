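# Reproducible simulation studies over the full pipeline: these are the
# package's parameter-recovery and calibration surfaces. Each runs the whole
# path (simulate cross -> QC -> line-origin inference -> scan) at a reduced
# but realistic scale: 5 linkage groups of 100 cM with markers every 5 cM and
# 500 F2 individuals, the phenotyped-population size of a typical divergent
# broiler intercross.

#' Default study map: 5 linkage groups of 100 cM, markers every 5 cM
#' @param n_chr,length_cM,spacing_cM map dimensions.
#' @return A [genetic_map()].
#' @export
study_map <- function(n_chr = 5, length_cM = 100, spacing_cM = 5) {
  sim_map(stats::setNames(rep(length_cM, n_chr), as.character(seq_len(n_chr))),
          spacing_cM = spacing_cM)
}

# simulate one cross and its line-origin indicators; internal study plumbing
study_cross <- function(map, n_f2, seed, grid_step, frac_diagnostic = 0.3,
                        missing_rate = 0.02) {
  set.seed(seed)
  fm <- sim_founder_freqs(nrow(map), frac_diagnostic)
  g <- simulate_cross(map, cross_design(n_f2 = n_f2, seed = seed), fm,
                      missing_rate = missing_rate)
  qc <- apply_qc(g)
  lf <- estimate_line_frequencies(qc$genos)
  lo <- compute_line_origin(qc$genos, lf, grid_step = grid_step)
  list(genos = g, qc = qc$genos, ind = indicators(lo), grid = lo)
}

#' Single-QTL parameter-recovery study
#'
#' Each replicate simulates a fresh cross and a trait with one additive QTL
#' at a random map position explaining `frac_var` of the phenotypic variance,
#' runs the one-dimensional scan, and records how far the peak lands from the
#' truth, the additive-effect estimate with its standard error, and the
#' variance explained at the peak.
#'
#' @param n_rep number of replicates (default 100).
#' @param n_f2 F2 individuals per replicate (default 500).
#' @param frac_var fraction of phenotypic variance explained by the QTL
#'   (default 0.15).
#' @param seed base seed; replicate r uses seed + r.
#' @param map study map (default [study_map()]).
#' @return data.frame, one row per replicate: true position, peak position,
#'   `loc_err` (cM; `Inf` when the peak is on the wrong group), `a_true`,
#'   `a_hat`, `se_a`, `var_pct`.
#' @export
study_recovery_1d <- function(n_rep = 100, n_f2 = 500, frac_var = 0.15,
                              seed = 1, map = study_map()) {
  a_true <- sqrt(2 * frac_var / (1 - frac_var))   # var(a*A) = a^2/2, sigma = 1
  chrs <- unique(map$chr)
  out <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    cr <- study_cross(map, n_f2, seed + r, grid_step = 1)
    tc <- sample(chrs, 1)
    tp <- round(runif(1, 0, max(map$cM[map$chr == tc])))
    tm <- trait_model(qtl = data.frame(chr = tc, pos = tp, a = a_true, d = 0),
                      residual_sd = 1)
    ph <- simulate_phenotypes(cr$genos, tm, seed = seed + r)
    y <- setNames(ph$y, ph$id)
    sc <- scan_genome(y, cr$ind)
    pk <- sc$peak
    k <- grid_index(cr$ind, pk$chr, pk$pos)
    al <- align_rows(names(y), cr$ind$ids)
    fp <- fit_position(as.numeric(y)[al$ph], cr$ind$A[al$ind, k],
                       cr$ind$D[al$ind, k])
    vp <- variance_explained(fp$rss_red / fp$df_red, fp$rss_full / fp$df_full,
                             fp$rss_red / fp$df_red)
    out[[r]] <- data.frame(true_chr = tc, true_pos = tp,
                           peak_chr = pk$chr, peak_pos = pk$pos,
                           loc_err = if (pk$chr == tc) abs(pk$pos - tp) else Inf,
                           F = pk$F, a_true = a_true, a_hat = fp$a,
                           se_a = fp$se_a, var_pct = vp,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Genome-wide threshold calibration study
#'
#' Simulates one cross, then scans `n_rep` independent null traits (pure
#' noise), comparing each trait's genome-wide maximum F against the 5%
#' threshold derived from its own `n_perm` permutations. Under a calibrated
#' procedure the rejection rate is close to `alpha`.
#'
#' @param n_rep null replicates (default 200).
#' @param n_perm permutations per replicate (default 200).
#' @param n_f2 F2 individuals (default 500).
#' @param alpha nominal level (default 0.05).
#' @param seed base seed.
#' @param map study map.
#' @param grid_step scan grid step in cM (default 1).
#' @return List: `reject` (logical per replicate), `rate`, `n_rep`.
#' @export
study_null_calibration <- function(n_rep = 200, n_perm = 200, n_f2 = 500,
                                   alpha = 0.05, seed = 1, map = study_map(),
                                   grid_step = 1) {
  cr <- study_cross(map, n_f2, seed, grid_step = grid_step)
  n <- length(cr$ind$ids)
  X0 <- matrix(1, n, 1)
  rows <- seq_len(n)
  set.seed(seed + 1)
  reject <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    y <- rnorm(n)
    yc <- y - mean(y)
    perms <- vapply(seq_len(n_perm), function(i) yc[sample.int(n)], numeric(n))
    Fm <- scan_F_multi(cbind(y, perms), cr$ind, rows, X0)
    mx <- apply(Fm, 2, max, na.rm = TRUE)
    thr <- quantile(mx[-1], 1 - alpha, names = FALSE, type = 7)
    reject[r] <- mx[1] > thr
  }
  list(reject = reject, rate = mean(reject), n_rep = n_rep)
}

#' Epistasis-recovery study
#'
#' Each replicate simulates a cross and a trait with a single
#' additive-by-additive pair (groups 1 and 2, 40 and 60 cM) explaining
#' `frac_var` of the phenotypic variance, scans all admissible 5 cM pairs
#' against a genome-wide permutation threshold (computed once from the first
#' replicate's null, and reused: the threshold reflects the scan's
#' multiplicity, which is identical across replicates), and records whether a
#' significant pair region matches the truth and whether the
#' additive-by-additive term is the dominant interaction component there.
#'
#' @param n_rep replicates (default 50).
#' @param n_f2 F2 individuals (default 500).
#' @param frac_var variance fraction of the pair (default 0.06).
#' @param n_perm permutations for the threshold (default 200).
#' @param match_cM match radius around the true positions (default 20 cM,
#'   the pair-region merge radius).
#' @param seed base seed.
#' @param map study map.
#' @return data.frame per replicate: `detected`, `matched` (a significant
#'   region at the true chromosome pair within `match_cM`), `aa_dominant`,
#'   `F_best`, `var_pct`; attribute `threshold` carries the F threshold used.
#' @export
study_epistasis_recovery <- function(n_rep = 50, n_f2 = 500, frac_var = 0.06,
                                     n_perm = 200, match_cM = 20, seed = 1,
                                     map = study_map()) {
  i1_true <- sqrt(frac_var / (1 - frac_var) / 0.25)  # var(I_A1A2) = 1/4
  true_pair <- list(chr1 = "1", pos1 = 40, chr2 = "2", pos2 = 60)
  cr0 <- study_cross(map, n_f2, seed, grid_step = 5)
  set.seed(seed)
  ynull <- setNames(rnorm(length(cr0$ind$ids)), cr0$ind$ids)
  thr <- permutation_threshold(ynull, cr0$ind, n_perm = n_perm, alpha = 0.05,
                               seed = seed, type = "2d")
  thr5 <- thr$thresholds[["0.05"]]
  out <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    cr <- if (r == 1) cr0 else study_cross(map, n_f2, seed + r, grid_step = 5)
    tm <- trait_model(epi = data.frame(chr1 = true_pair$chr1, pos1 = true_pair$pos1,
                                       chr2 = true_pair$chr2, pos2 = true_pair$pos2,
                                       i1 = i1_true, i2 = 0, i3 = 0, i4 = 0),
                      residual_sd = 1)
    ph <- simulate_phenotypes(cr$genos, tm, seed = seed + r)
    y <- setNames(ph$y, ph$id)
    es <- scan_pairs(y, cr$ind, threshold = thr5)
    sig <- es$significant
    matched <- FALSE; aa_dom <- FALSE; Fb <- NA_real_; vp <- NA_real_
    if (nrow(sig) > 0) {
      m <- which(sig$chr1 == true_pair$chr1 & sig$chr2 == true_pair$chr2 &
                   abs(sig$pos1 - true_pair$pos1) <= match_cM &
                   abs(sig$pos2 - true_pair$pos2) <= match_cM)
      if (length(m) > 0) {
        m <- m[which.max(sig$F[m])]
        matched <- TRUE
        Fb <- sig$F[m]; vp <- sig$var_pct[m]
        dc <- decompose_epistasis(y, cr$ind, sig$chr1[m], sig$pos1[m],
                                  sig$chr2[m], sig$pos2[m])
        aa_dom <- dc$term[dc$dominant] == "add_by_add"
      }
    }
    out[[r]] <- data.frame(detected = nrow(sig) > 0, matched = matched,
                           aa_dominant = matched && aa_dom,
                           F_best = Fb, var_pct = vp)
  }
  res <- do.call(rbind, out)
  attr(res, "threshold") <- thr5
  res
}
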
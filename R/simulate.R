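#' Describe an F2 reciprocal-cross design
#'
#' Defaults mirror a classic divergent broiler intercross: 4 cocks and 12 hens
#' per founder line, 56 F1 birds selected for inter-mating, and 500 phenotyped
#' F2 offspring produced by reciprocal matings (each F2 has an F1 sire and an
#' F1 dam of opposite cross types).
#'
#' @param n_f0_males_per_line,n_f0_females_per_line founder counts per line.
#' @param n_f1_selected number of F1 individuals retained for breeding (even;
#'   split equally between the A-sire and B-sire cross types when reciprocal).
#' @param n_f2 number of F2 offspring.
#' @param reciprocal if `TRUE` (default) F2 matings pair F1 parents of
#'   opposite cross types.
#' @param n_batches number of hatch batches F2 birds are assigned to.
#' @param seed integer seed controlling every random draw in
#'   [simulate_cross()].
#' @return A list of class `cross_design`.
#' @export
cross_design <- function(n_f0_males_per_line = 4, n_f0_females_per_line = 12,
                         n_f1_selected = 56, n_f2 = 500, reciprocal = TRUE,
                         n_batches = 6, seed = 1) {
  counts <- c(n_f0_males_per_line, n_f0_females_per_line, n_f1_selected, n_f2)
  if (any(counts < 1) || any(counts != round(counts))) {
    stopf("design error: all counts must be positive integers")
  }
  if (reciprocal && n_f1_selected %% 2 != 0) {
    stopf("design error: n_f1_selected must be even for a reciprocal design")
  }
  structure(list(n_f0_males_per_line = as.integer(n_f0_males_per_line),
                 n_f0_females_per_line = as.integer(n_f0_females_per_line),
                 n_f1_selected = as.integer(n_f1_selected),
                 n_f2 = as.integer(n_f2),
                 reciprocal = isTRUE(reciprocal),
                 n_batches = as.integer(n_batches),
                 seed = as.integer(seed)),
            class = "cross_design")
}

#' Founder-line allele frequencies
#'
#' Founder lines are outbred, so most SNPs are only partially informative
#' about line origin. A marker is fully diagnostic when one line is fixed for
#' allele 1 and the other for allele 2.
#'
#' @param freq_a,freq_b per-marker frequency of allele 1 in lines A and B.
#' @return List of class `founder_model` with the frequency vectors and the
#'   realised fraction of diagnostic markers.
#' @seealso [sim_founder_freqs()] to draw divergent frequencies at random.
#' @export
founder_model <- function(freq_a, freq_b) {
  if (length(freq_a) != length(freq_b)) {
    stopf("founder error: frequency vectors differ in length")
  }
  if (any(freq_a < 0 | freq_a > 1) || any(freq_b < 0 | freq_b > 1)) {
    stopf("founder error: frequencies must lie in [0, 1]")
  }
  structure(list(freq_a = as.numeric(freq_a), freq_b = as.numeric(freq_b),
                 frac_diagnostic = mean(abs(freq_a - freq_b) == 1)),
            class = "founder_model")
}

#' Draw divergent founder allele frequencies
#'
#' A fraction of markers is fully diagnostic (fixed 1 vs 0); the remainder are
#' divergent but segregating in both lines (allele-1 frequency uniform on
#' [0.6, 1] in line A and [0, 0.4] in line B), reflecting lines separated by
#' sustained directional selection.
#'
#' @param n_markers number of markers.
#' @param frac_diagnostic fraction of fully diagnostic markers (default 0.3).
#' @return A [founder_model()].
#' @export
sim_founder_freqs <- function(n_markers, frac_diagnostic = 0.3) {
  diag <- runif(n_markers) < frac_diagnostic
  fa <- ifelse(diag, 1, runif(n_markers, 0.6, 1))
  fb <- ifelse(diag, 0, runif(n_markers, 0, 0.4))
  founder_model(fa, fb)
}

# one meiosis on one chromosome under Haldane (Poisson crossovers, no
# interference): returns the transmitted haplotype index (1 = the parent's
# first/paternal haplotype) at the given positions plus the crossover record
meiosis_chr <- function(pos_cM, L) {
  k <- rpois(1, L / 100)
  breaks <- if (k > 0) sort(runif(k, 0, L)) else numeric(0)
  start <- sample.int(2L, 1L)
  seg <- findInterval(pos_cM, breaks)
  idx <- ifelse(seg %% 2L == 0L, start, 3L - start)
  list(idx = idx, start = start, breaks = breaks)
}

# haplotype index at arbitrary positions given a crossover record
gamete_index_at <- function(start, breaks, pos) {
  seg <- findInterval(pos, breaks)
  ifelse(seg %% 2L == 0L, start, 3L - start)
}

#' Simulate genotypes for a three-generation F2 intercross
#'
#' Generates founder (F0) haplotypes from line allele frequencies, produces F1
#' and F2 individuals by simulated meiosis with Poisson recombination
#' consistent with the map's cM distances under the Haldane map function, and
#' records, for every F2 gamete, the true founder-line origin along each
#' chromosome (as crossover breakpoints), so downstream line-origin inference
#' and QTL scans can be scored against the truth.
#'
#' @param map a [genetic_map()].
#' @param design a [cross_design()]; `design$seed` seeds all randomness.
#' @param founders a [founder_model()] with one frequency pair per map marker.
#' @param missing_rate fraction of genotype calls set missing at random
#'   (default 0.02), to exercise quality control.
#' @return A list of class `cross_geno` with elements `ped` (pedigree
#'   data.frame: id, sire, dam, generation, line, cross_type, family, sex,
#'   batch), `map`, `calls` (marker x individual integer matrix, 0/1/2 copies
#'   of allele 2, `NA` missing), and `truth` (per-chromosome crossover records
#'   and line labels for every F2 gamete).
#' @seealso [true_origin()], [true_indicators()], [simulate_phenotypes()]
#' @export
simulate_cross <- function(map, design, founders, missing_rate = 0.02) {
  if (!inherits(map, "genetic_map")) stopf("map error: not a genetic_map")
  if (!inherits(design, "cross_design")) stopf("design error: not a cross_design")
  if (!inherits(founders, "founder_model")) stopf("founder error: not a founder_model")
  if (length(founders$freq_a) != nrow(map)) {
    stopf("founder error: %d frequencies for %d markers",
          length(founders$freq_a), nrow(map))
  }
  set.seed(design$seed)

  chrs <- unique(map$chr)
  chr_idx <- lapply(chrs, function(cc) which(map$chr == cc))
  chr_pos <- lapply(chr_idx, function(ii) map$cM[ii])
  chr_len <- vapply(chr_pos, max, 0)
  nm <- nrow(map)

  # --- F0 ---------------------------------------------------------------
  n_m <- design$n_f0_males_per_line
  n_f <- design$n_f0_females_per_line
  f0 <- expand.grid(line = c("A", "B"), sex = c("M", "F"),
                    stringsAsFactors = FALSE)
  f0_ids <- character(0); f0_line <- character(0); f0_sex <- character(0)
  for (ln in c("A", "B")) {
    f0_ids <- c(f0_ids, sprintf("F0_%s_M%02d", ln, seq_len(n_m)),
                sprintf("F0_%s_F%02d", ln, seq_len(n_f)))
    f0_line <- c(f0_line, rep(ln, n_m + n_f))
    f0_sex <- c(f0_sex, rep("M", n_m), rep("F", n_f))
  }
  n_f0 <- length(f0_ids)

  # haplotypes stored as two (marker x individual) allele-2 indicator matrices
  draw_f0_hap <- function(line) {
    freq1 <- if (line == "A") founders$freq_a else founders$freq_b
    as.integer(runif(nm) >= freq1)   # 1 = allele 2
  }
  hap1 <- matrix(NA_integer_, nm, 0); hap2 <- matrix(NA_integer_, nm, 0)
  for (i in seq_len(n_f0)) {
    hap1 <- cbind(hap1, draw_f0_hap(f0_line[i]))
    hap2 <- cbind(hap2, draw_f0_hap(f0_line[i]))
  }

  meiose <- function(parent_col) {
    # returns list(allele = nm-vector, rec = per-chr crossover records)
    allele <- integer(nm); rec <- vector("list", length(chrs))
    for (ci in seq_along(chrs)) {
      ii <- chr_idx[[ci]]
      g <- meiosis_chr(chr_pos[[ci]], chr_len[ci])
      h <- ifelse(g$idx == 1L, hap1[ii, parent_col], hap2[ii, parent_col])
      allele[ii] <- h
      rec[[ci]] <- g[c("start", "breaks")]
    }
    list(allele = allele, rec = rec)
  }

  # --- F1 ---------------------------------------------------------------
  n_f1 <- design$n_f1_selected
  if (design$reciprocal) {
    type <- rep(c("AB", "BA"), each = n_f1 / 2)
  } else {
    type <- rep("AB", n_f1)
  }
  # a small number of F1 males, balanced across cross types; the rest are dams
  n_f1_m <- 2L * max(1L, as.integer(round(n_f1 / 14)))
  f1_sex <- rep("F", n_f1)
  if (design$reciprocal) {
    half <- n_f1_m %/% 2L
    f1_sex[seq_len(half)] <- "M"                     # first males of type AB
    f1_sex[n_f1 / 2 + seq_len(n_f1_m - half)] <- "M" # and of type BA
  } else {
    f1_sex[seq_len(n_f1_m)] <- "M"
  }
  f1_ids <- sprintf("F1_%03d", seq_len(n_f1))
  f1_sire <- character(n_f1); f1_dam <- character(n_f1)
  f0_m_of <- function(ln) which(f0_line == ln & f0_sex == "M")
  f0_f_of <- function(ln) which(f0_line == ln & f0_sex == "F")
  for (i in seq_len(n_f1)) {
    sl <- if (type[i] == "AB") "A" else "B"   # sire line
    dl <- if (type[i] == "AB") "B" else "A"
    si <- sample(f0_m_of(sl), 1L); di <- sample(f0_f_of(dl), 1L)
    f1_sire[i] <- f0_ids[si]; f1_dam[i] <- f0_ids[di]
    gs <- meiose(si); gd <- meiose(di)
    hap1 <- cbind(hap1, gs$allele)   # haplotype 1 = paternal (sire line)
    hap2 <- cbind(hap2, gd$allele)
  }

  # --- F2 families ------------------------------------------------------
  f1_all <- n_f0 + seq_len(n_f1)    # column indices of F1 in hap matrices
  males <- which(f1_sex == "M"); females <- which(f1_sex == "F")
  if (design$reciprocal) {
    # each dam mated to one sire of the opposite cross type (round-robin)
    fam_sire <- integer(0); fam_dam <- integer(0)
    for (tt in c("AB", "BA")) {
      dams <- females[type[females] == tt]
      sires <- males[type[males] != tt]
      if (length(sires) == 0L) stopf("design error: no F1 sires of type != %s", tt)
      fam_sire <- c(fam_sire, rep_len(sires, length(dams)))
      fam_dam <- c(fam_dam, dams)
    }
  } else {
    fam_sire <- rep_len(males, length(females)); fam_dam <- females
  }
  n_fam <- length(fam_dam)
  sizes <- rep(design$n_f2 %/% n_fam, n_fam)
  extra <- design$n_f2 - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  f2_fam <- rep(seq_len(n_fam), sizes)

  n_f2 <- design$n_f2
  f2_ids <- sprintf("F2_%04d", seq_len(n_f2))
  f2_sire <- f1_ids[fam_sire[f2_fam]]
  f2_dam <- f1_ids[fam_dam[f2_fam]]
  f2_sex <- sample(c("M", "F"), n_f2, replace = TRUE)
  f2_batch <- sample.int(design$n_batches, n_f2, replace = TRUE)

  # line labels of an F1 parent's two haplotypes (hap1 = from its sire)
  lab_of_type <- function(tt) if (tt == "AB") c("A", "B") else c("B", "A")

  truth <- lapply(seq_along(chrs), function(ci) {
    list(mat_start = integer(n_f2), mat_breaks = vector("list", n_f2),
         pat_start = integer(n_f2), pat_breaks = vector("list", n_f2))
  })
  names(truth) <- chrs
  pat_labels <- t(vapply(type[fam_sire[f2_fam]], lab_of_type, character(2)))
  mat_labels <- t(vapply(type[fam_dam[f2_fam]], lab_of_type, character(2)))

  f2_calls <- matrix(NA_integer_, nm, n_f2)
  for (i in seq_len(n_f2)) {
    gp <- meiose(f1_all[fam_sire[f2_fam[i]]])
    gm <- meiose(f1_all[fam_dam[f2_fam[i]]])
    f2_calls[, i] <- gp$allele + gm$allele
    for (ci in seq_along(chrs)) {
      truth[[ci]]$pat_start[i] <- gp$rec[[ci]]$start
      truth[[ci]]$pat_breaks[[i]] <- gp$rec[[ci]]$breaks
      truth[[ci]]$mat_start[i] <- gm$rec[[ci]]$start
      truth[[ci]]$mat_breaks[[i]] <- gm$rec[[ci]]$breaks
    }
  }

  ids <- c(f0_ids, f1_ids, f2_ids)
  calls <- cbind(hap1[, seq_len(n_f0), drop = FALSE] +
                   hap2[, seq_len(n_f0), drop = FALSE],
                 hap1[, f1_all, drop = FALSE] + hap2[, f1_all, drop = FALSE],
                 f2_calls)
  dimnames(calls) <- list(map$marker, ids)
  if (missing_rate > 0) {
    calls[runif(length(calls)) < missing_rate] <- NA_integer_
  }

  ped <- data.frame(
    id = ids,
    sire = c(rep(NA_character_, n_f0), f1_sire, f2_sire),
    dam = c(rep(NA_character_, n_f0), f1_dam, f2_dam),
    generation = rep(c("F0", "F1", "F2"), c(n_f0, n_f1, n_f2)),
    line = c(f0_line, rep(NA_character_, n_f1 + n_f2)),
    cross_type = c(rep(NA_character_, n_f0), type,
                   paste0(type[fam_sire[f2_fam]], "x", type[fam_dam[f2_fam]])),
    family = c(rep(NA_integer_, n_f0 + n_f1), f2_fam),
    sex = c(f0_sex, f1_sex, f2_sex),
    batch = c(rep(NA_integer_, n_f0 + n_f1), f2_batch),
    stringsAsFactors = FALSE)

  structure(list(ped = ped, map = map, calls = calls,
                 truth = list(chr = truth, f2_ids = f2_ids,
                              mat_labels = mat_labels, pat_labels = pat_labels),
                 design = design, founders = founders),
            class = "cross_geno")
}

#' @export
print.cross_geno <- function(x, ...) {
  tab <- table(x$ped$generation)
  cat(sprintf("F2 intercross: %s markers, %s\n", nrow(x$map),
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", ")))
  invisible(x)
}

#' True line origin of F2 gametes at arbitrary positions
#'
#' @param genos a `cross_geno` from [simulate_cross()] (truth retained).
#' @param chr linkage group.
#' @param positions cM positions on that group.
#' @return List with `mat` and `pat`: character matrices (F2 x position) of
#'   founder-line labels ("A"/"B").
#' @export
true_origin <- function(genos, chr, positions) {
  tr <- genos$truth$chr[[as.character(chr)]]
  if (is.null(tr)) stopf("position error: linkage group '%s' not simulated", chr)
  n <- length(tr$mat_start); np <- length(positions)
  mat <- pat <- matrix(NA_character_, n, np)
  for (i in seq_len(n)) {
    mi <- gamete_index_at(tr$mat_start[i], tr$mat_breaks[[i]], positions)
    pi <- gamete_index_at(tr$pat_start[i], tr$pat_breaks[[i]], positions)
    mat[i, ] <- genos$truth$mat_labels[i, ][mi]
    pat[i, ] <- genos$truth$pat_labels[i, ][pi]
  }
  list(mat = mat, pat = pat)
}

#' True additive/dominance indicators at a position
#'
#' From the true (not inferred) line origin: A = 1 for AA, -1 for BB, 0 for
#' heterozygous line origin; D = 1 for heterozygous, 0 otherwise.
#'
#' @inheritParams true_origin
#' @param pos single cM position.
#' @return List with numeric vectors `A` and `D` over F2 individuals.
#' @export
true_indicators <- function(genos, chr, pos) {
  o <- true_origin(genos, chr, pos)
  a <- (o$mat[, 1] == "A") + (o$pat[, 1] == "A") - 1L
  list(A = as.numeric(a), D = as.numeric(a == 0L))
}

#' Specify a generative trait model
#'
#' Phenotype = mean + fixed effects + covariates + QTL effects (from the true
#' line origin) + epistatic effects + Gaussian noise.
#'
#' @param name trait name (column name in the output).
#' @param mean trait mean (trait units).
#' @param qtl `NULL` or data.frame with columns `chr`, `pos`, `a`, `d`.
#' @param epi `NULL` or data.frame with columns `chr1`, `pos1`, `chr2`,
#'   `pos2`, `i1`, `i2`, `i3`, `i4` (additive-by-additive,
#'   additive-by-dominance, dominance-by-additive, dominance-by-dominance).
#' @param sex_effect additive shift for males (trait units).
#' @param batch_effects `NULL` or numeric vector of per-batch shifts.
#' @param covariate_slopes `NULL` or named numeric vector; standard-normal
#'   covariates with these names are generated and included.
#' @param residual_sd residual standard deviation (>= 0).
#' @return List of class `trait_model`.
#' @export
trait_model <- function(name = "y", mean = 0, qtl = NULL, epi = NULL,
                        sex_effect = 0, batch_effects = NULL,
                        covariate_slopes = NULL, residual_sd = 1) {
  if (residual_sd < 0) stopf("trait error: residual_sd must be >= 0")
  structure(list(name = name, mean = mean, qtl = qtl, epi = epi,
                 sex_effect = sex_effect, batch_effects = batch_effects,
                 covariate_slopes = covariate_slopes,
                 residual_sd = residual_sd),
            class = "trait_model")
}

check_on_map <- function(map, chr, pos) {
  for (k in seq_along(chr)) {
    ii <- map$chr == as.character(chr[k])
    if (!any(ii)) stopf("position error: group '%s' not on map", chr[k])
    if (pos[k] < min(map$cM[ii]) || pos[k] > max(map$cM[ii])) {
      stopf("position error: %s cM outside group '%s'", pos[k], chr[k])
    }
  }
  invisible(TRUE)
}

#' Simulate phenotypes from a trait model and true line origins
#'
#' @param genos a `cross_geno` with retained truth.
#' @param model a [trait_model()].
#' @param seed integer seed (phenotype noise is independent of the genotype
#'   simulation).
#' @param dropout fraction of F2 individuals whose trait value is set missing
#'   at random (default 0), emulating phenotyping attrition.
#' @return A data.frame of class `pheno_table`: one row per F2 with id, sex,
#'   batch, family, any covariates, and the trait column.
#' @export
simulate_phenotypes <- function(genos, model, seed = 1, dropout = 0) {
  if (!inherits(model, "trait_model")) stopf("trait error: not a trait_model")
  set.seed(seed)
  ped2 <- genos$ped[genos$ped$generation == "F2", ]
  n <- nrow(ped2)
  y <- rep(model$mean, n)
  if (!is.null(model$qtl) && nrow(model$qtl) > 0) {
    check_on_map(genos$map, model$qtl$chr, model$qtl$pos)
    for (k in seq_len(nrow(model$qtl))) {
      ind <- true_indicators(genos, model$qtl$chr[k], model$qtl$pos[k])
      y <- y + model$qtl$a[k] * ind$A + model$qtl$d[k] * ind$D
    }
  }
  if (!is.null(model$epi) && nrow(model$epi) > 0) {
    check_on_map(genos$map, c(model$epi$chr1, model$epi$chr2),
                 c(model$epi$pos1, model$epi$pos2))
    for (k in seq_len(nrow(model$epi))) {
      i1 <- true_indicators(genos, model$epi$chr1[k], model$epi$pos1[k])
      i2 <- true_indicators(genos, model$epi$chr2[k], model$epi$pos2[k])
      y <- y + model$epi$i1[k] * i1$A * i2$A + model$epi$i2[k] * i1$A * i2$D +
        model$epi$i3[k] * i1$D * i2$A + model$epi$i4[k] * i1$D * i2$D
    }
  }
  out <- data.frame(id = ped2$id, sex = ped2$sex, batch = ped2$batch,
                    family = ped2$family, stringsAsFactors = FALSE)
  y <- y + model$sex_effect * (ped2$sex == "M")
  if (!is.null(model$batch_effects)) {
    y <- y + model$batch_effects[((ped2$batch - 1) %% length(model$batch_effects)) + 1]
  }
  if (!is.null(model$covariate_slopes)) {
    for (nmv in names(model$covariate_slopes)) {
      v <- rnorm(n)
      out[[nmv]] <- v
      y <- y + model$covariate_slopes[[nmv]] * v
    }
  }
  y <- y + rnorm(n, 0, model$residual_sd)
  if (dropout > 0) y[runif(n) < dropout] <- NA_real_
  out[[model$name]] <- y
  class(out) <- c("pheno_table", "data.frame")
  out
}

#' Simulate a growth-trait study (body weights and feed intake)
#'
#' Generates a longitudinal body-weight series (hatch to 12 weeks, biweekly),
#' with an individual growth scale driven by the supplied QTL plus a
#' persistent environmental component, and per-window feed intake computed as
#' gain x (true feed conversion ratio + noise). Magnitudes follow typical
#' slow x fast broiler F2 data (mean hatch weight ~35 g rising to ~2 kg at 12
#' weeks; feed conversion worsening from ~2.9 to ~4.4 across windows).
#'
#' @param genos a `cross_geno`.
#' @param qtl `NULL` or data.frame (`chr`, `pos`, `a`, `d`) of growth QTL;
#'   effects in grams at 12 weeks of age.
#' @param seed integer seed.
#' @param fcr_sd SD of the per-window feed-conversion noise (default 0.15).
#' @return A `pheno_table` with columns BW0, BW2, ..., BW12 (g), FI6_8,
#'   FI8_10, FI10_12 (g), and design columns.
#' @export
simulate_growth_traits <- function(genos, qtl = NULL, seed = 1, fcr_sd = 0.15) {
  set.seed(seed)
  ped2 <- genos$ped[genos$ped$generation == "F2", ]
  n <- nrow(ped2)
  wk <- c(0, 2, 4, 6, 8, 10, 12)
  bw_mean <- c(35, 167, 443, 803, 1240, 1662, 2032)
  fcr_true <- c("6_8" = 2.9, "8_10" = 3.5, "10_12" = 4.4)
  g <- numeric(n)
  if (!is.null(qtl) && nrow(qtl) > 0) {
    check_on_map(genos$map, qtl$chr, qtl$pos)
    for (k in seq_len(nrow(qtl))) {
      ind <- true_indicators(genos, qtl$chr[k], qtl$pos[k])
      g <- g + qtl$a[k] * ind$A + qtl$d[k] * ind$D
    }
  }
  pe <- rnorm(n, 0, 240)                     # persistent environment, g at 12 wk
  sexef <- 180 * (ped2$sex == "M")           # sexual dimorphism, g at 12 wk
  out <- data.frame(id = ped2$id, sex = ped2$sex, batch = ped2$batch,
                    family = ped2$family, stringsAsFactors = FALSE)
  bw <- matrix(0, n, length(wk))
  for (t in seq_along(wk)) {
    scale_t <- bw_mean[t] / bw_mean[length(wk)]
    bw[, t] <- bw_mean[t] + scale_t * (g + pe + sexef) +
      rnorm(n, 0, 0.05 * bw_mean[t] + 1)
    out[[paste0("BW", wk[t])]] <- bw[, t]
  }
  for (w in names(fcr_true)) {
    ends <- as.numeric(strsplit(w, "_")[[1]])
    gain <- bw[, match(ends[2], wk)] - bw[, match(ends[1], wk)]
    out[[paste0("FI", w)]] <- gain * (fcr_true[w] + rnorm(n, 0, fcr_sd))
  }
  class(out) <- c("pheno_table", "data.frame")
  out
}
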
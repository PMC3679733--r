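test_that("founder allele frequencies follow the pseudocount formula", {
  map <- genetic_map(c(1, 1), c("m1", "m2"), c(0, 10))
  ids <- c(sprintf("a%02d", 1:10), sprintf("b%02d", 1:10))
  calls <- matrix(0L, 2, 20, dimnames = list(c("m1", "m2"), ids))
  calls["m1", 11:20] <- 2L          # line B homozygous-alt at m1
  calls["m2", 11:20] <- NA_integer_ # marker missing in all line-B founders
  ped <- founder_ped(ids, rep(c("A", "B"), each = 10))
  expect_warning(lf <- estimate_line_frequencies(manual_geno(calls, ped, map)),
                 "no genotyped founders")
  expect_equal(lf$freq_a[1], 20.5 / 21)
  expect_equal(lf$freq_b[1], 0.5 / 21)
  expect_equal(lf$freq_b[2], 0.5)   # uninformative prior
})

test_that("a line with no genotyped founders is a data error", {
  map <- genetic_map(1, "m1", 0)
  calls <- matrix(0L, 1, 2, dimnames = list("m1", c("a1", "a2")))
  ped <- founder_ped(c("a1", "a2"), c("A", "A"))
  expect_error(estimate_line_frequencies(manual_geno(calls, ped, map)),
               "data error.*line B")
})

test_that("estimated line divergence at diagnostic markers grows with founder count", {
  map <- sim_map(c("1" = 30), spacing_cM = 10)
  fm <- founder_model(rep(1, nrow(map)), rep(0, nrow(map)))
  div <- vapply(c(4, 20), function(nf) {
    g <- simulate_cross(map, cross_design(n_f0_males_per_line = nf,
                                          n_f0_females_per_line = nf,
                                          n_f2 = 10, seed = 42), fm,
                        missing_rate = 0)
    lf <- estimate_line_frequencies(g)
    mean(abs(lf$freq_a - lf$freq_b))
  }, 0)
  expect_gt(div[2], div[1])
  expect_gt(div[2], 0.95)
})

test_that("a diagnostic homozygote pins the posterior on the matching state", {
  map <- genetic_map(c(1, 1), c("m1", "m2"), c(0, 20))
  ids <- c("f2a")
  calls <- matrix(c(0L, NA), 2, 1, dimnames = list(c("m1", "m2"), ids))
  ped <- data.frame(id = ids, sire = NA_character_, dam = NA_character_,
                    generation = "F2", line = NA_character_, sex = "F",
                    stringsAsFactors = FALSE)
  lf <- data.frame(marker = c("m1", "m2"), freq_a = c(1, 1), freq_b = c(0, 0))
  lo <- compute_line_origin(manual_geno(calls, ped, map), lf, grid_step = 1)
  k <- which(lo$grid$pos == 0)
  expect_equal(unname(lo$prob[1, k, ]), c(1, 0, 0, 0))
})

test_that("uninformative chromosomes return the F2 prior everywhere", {
  map <- genetic_map(c(1, 1), c("m1", "m2"), c(0, 20))
  ids <- "f2a"
  calls <- matrix(c(1L, 1L), 2, 1, dimnames = list(c("m1", "m2"), ids))
  ped <- data.frame(id = ids, sire = NA_character_, dam = NA_character_,
                    generation = "F2", line = NA_character_, sex = "F",
                    stringsAsFactors = FALSE)
  lf <- data.frame(marker = c("m1", "m2"), freq_a = c(0.5, 0.5),
                   freq_b = c(0.5, 0.5))
  lo <- compute_line_origin(manual_geno(calls, ped, map), lf, grid_step = 5)
  expect_true(all(abs(lo$prob - 0.25) < 1e-12))
})

test_that("forward-backward equals exhaustive enumeration on small chromosomes", {
  # partially informative 3-marker chromosome, several genotype patterns,
  # posteriors checked at markers and at an off-marker pseudo-locus
  pos <- c(0, 7, 20)
  fa <- c(0.9, 1, 0.7); fb <- c(0.2, 0, 0.4)
  patterns <- list(c(0L, 1L, 2L), c(2L, NA, 0L), c(1L, 1L, 1L), c(0L, 0L, NA))
  map <- genetic_map(rep(1, 3), c("m1", "m2", "m3"), pos)
  lf <- data.frame(marker = map$marker, freq_a = fa, freq_b = fb)
  for (g in patterns) {
    calls <- matrix(g, 3, 1, dimnames = list(map$marker, "x"))
    ped <- data.frame(id = "x", sire = NA_character_, dam = NA_character_,
                      generation = "F2", line = NA_character_, sex = "F",
                      stringsAsFactors = FALSE)
    lo <- compute_line_origin(manual_geno(calls, ped, map), lf, grid_step = 1)
    # oracle over the union of markers and one pseudo-locus at 13 cM
    opos <- c(0, 7, 13, 20)
    ocalls <- c(g[1], g[2], NA, g[3])
    ofa <- c(fa[1], fa[2], 0.5, fa[3]); ofb <- c(fb[1], fb[2], 0.5, fb[3])
    post <- oracle_line_origin(ocalls, opos, ofa, ofb)
    for (q in seq_along(opos)) {
      k <- which(lo$grid$pos == opos[q])
      expect_lt(max(abs(lo$prob[1, k, ] - post[q, ])), 1e-10)
    }
  }
})

test_that("posterior quadruples are proper distributions and AB/BA are symmetric", {
  cr <- shared_cross()
  expect_true(all(abs(apply(cr$grid$prob, c(1, 2), sum) - 1) < 1e-9))
  expect_true(all(cr$grid$prob >= -1e-12))
  # emissions and transitions are orientation-symmetric, so the two
  # heterozygous states carry equal mass
  expect_lt(max(abs(cr$grid$prob[, , 2] - cr$grid$prob[, , 3])), 1e-9)
})

test_that("posterior probabilities are calibrated against the simulation truth", {
  cr <- shared_cross()
  ks <- which(cr$grid$grid$chr == "1")
  truth <- true_origin(cr$qc, "1", cr$grid$grid$pos[ks])
  p_aa <- as.vector(cr$grid$prob[, ks, 1])
  is_aa <- as.vector(truth$mat == "A" & truth$pat == "A")
  bins <- cut(p_aa, c(0, 0.2, 0.4, 0.6, 0.8, 1), include.lowest = TRUE)
  for (b in levels(bins)) {
    sel <- bins == b
    if (sum(sel) < 200) next
    centre <- mean(p_aa[sel])
    obs <- mean(is_aa[sel])
    # positions within an individual are correlated; allow a wide band
    expect_lt(abs(obs - centre), 0.08)
  }
})

test_that("indicator formulas and Mendelian averages hold", {
  grid <- structure(list(
    grid = data.frame(chr = "1", pos = c(0, 1, 2)),
    prob = array(c(1, 0.25, 0.1, 0, 0.25, 0.2, 0, 0.25, 0.3, 0, 0.25, 0.4),
                 c(1, 3, 4)),
    ids = "x", step = 1), class = "lineorigin_grid")
  ind <- indicators(grid)
  expect_equal(unname(ind$A[1, ]), c(1, 0, -0.3))
  expect_equal(unname(ind$D[1, ]), c(0, 0.5, 0.5))
  cr <- shared_cross()
  ci <- indicators(cr$grid)
  expect_lt(max(abs(colMeans(ci$A))), 0.15)
  expect_lt(max(abs(colMeans(ci$D) - 0.5)), 0.1)
})

test_that("negative cM gaps and bad grid steps are rejected", {
  cr <- shared_cross()
  expect_error(compute_line_origin(cr$qc, cr$freqs, grid_step = 0),
               "parameter error")
})
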
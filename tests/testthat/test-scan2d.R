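test_that("interaction indicators are elementwise products of the marginals", {
  ii <- interaction_indicators(1, 0, -1, 1)
  expect_equal(ii$I_A1A2, -1)
  ii2 <- interaction_indicators(0, 0.5, 0, 0.5)   # F2 prior at both loci
  expect_equal(unlist(ii2, use.names = FALSE), c(0, 0, 0, 0.25))
  ii3 <- interaction_indicators(0.6, 0.4, -0.5, 0.9)
  expect_equal(unlist(ii3, use.names = FALSE), c(-0.30, 0.54, -0.20, 0.36))
})

test_that("the pair list excludes identical and under-separated same-group points", {
  grid <- data.frame(chr = c("1", "1", "1", "2"), pos = c(0, 5, 10, 0))
  pl <- crossqtl:::pair_list(grid, step = 5, min_sep_steps = 2)
  pairs <- apply(pl, 1, paste, collapse = "-")
  expect_true("1-3" %in% pairs)        # 10 cM apart on one group: admissible
  expect_false("1-2" %in% pairs)       # 5 cM apart: excluded
  expect_false("2-3" %in% pairs)
  expect_true(all(c("1-4", "2-4", "3-4") %in% pairs))  # between groups
})

test_that("the marginal model nests in the full model and F is swap-invariant", {
  cr <- shared_cross()
  ind5 <- indicators(compute_line_origin(cr$qc, cr$freqs, grid_step = 5))
  set.seed(51)
  ph <- simulate_phenotypes(cr$genos,
                            trait_model(epi = data.frame(chr1 = "1", pos1 = 40,
                                                         chr2 = "2", pos2 = 60,
                                                         i1 = 0.5, i2 = 0,
                                                         i3 = 0, i4 = 0)),
                            seed = 51)
  y <- setNames(ph$y, ph$id)
  es <- scan_pairs(y, ind5, threshold = NULL)
  expect_true(all(es$pairs$F >= -1e-10, na.rm = TRUE))
  # direct swap check at one pair via the underlying fits
  sp <- crossqtl:::scan_inputs(y, ind5)
  A <- ind5$A[sp$rows_ind, ]; D <- ind5$D[sp$rows_ind, ]
  i <- crossqtl:::grid_index(ind5, "1", 40)
  j <- crossqtl:::grid_index(ind5, "2", 60)
  F_of <- function(i, j) {
    X3 <- cbind(sp$X0, A[, i], D[, i], A[, j], D[, j])
    X4 <- cbind(X3, A[, i] * A[, j], A[, i] * D[, j], D[, i] * A[, j],
                D[, i] * D[, j])
    f3 <- crossqtl:::ols_qr(X3, sp$y); f4 <- crossqtl:::ols_qr(X4, sp$y)
    ((f3$rss - f4$rss) / 4) / (f4$rss / f4$df)
  }
  expect_equal(F_of(i, j), F_of(j, i), tolerance = 1e-10)
})

test_that("an additive-by-additive pair is found with the right dominant term", {
  cr <- shared_cross()
  ind5 <- indicators(compute_line_origin(cr$qc, cr$freqs, grid_step = 5))
  ph <- simulate_phenotypes(cr$genos,
                            trait_model(epi = data.frame(chr1 = "1", pos1 = 40,
                                                         chr2 = "2", pos2 = 60,
                                                         i1 = 0.7, i2 = 0,
                                                         i3 = 0, i4 = 0)),
                            seed = 53)
  y <- setNames(ph$y, ph$id)
  es <- scan_pairs(y, ind5, threshold = 8)
  expect_gt(nrow(es$significant), 0)
  best <- es$significant[which.max(es$significant$F), ]
  expect_equal(best$chr1, "1"); expect_equal(best$chr2, "2")
  expect_lt(abs(best$pos1 - 40), 20); expect_lt(abs(best$pos2 - 60), 20)
  dc <- decompose_epistasis(y, ind5, best$chr1, best$pos1, best$chr2, best$pos2)
  expect_equal(dc$term[dc$dominant], "add_by_add")
  # a dominance-by-dominance pair decomposes the other way
  ph4 <- simulate_phenotypes(cr$genos,
                             trait_model(epi = data.frame(chr1 = "1", pos1 = 40,
                                                          chr2 = "2", pos2 = 60,
                                                          i1 = 0, i2 = 0, i3 = 0,
                                                          i4 = 1.4)),
                             seed = 54)
  y4 <- setNames(ph4$y, ph4$id)
  dc4 <- decompose_epistasis(y4, ind5, "1", 40, "2", 60)
  expect_equal(dc4$term[dc4$dominant], "dom_by_dom")
})

test_that("marginal-only traits yield interaction estimates centred on zero", {
  cr <- shared_cross()
  ind5 <- indicators(compute_line_origin(cr$qc, cr$freqs, grid_step = 5))
  ph <- simulate_phenotypes(cr$genos,
                            trait_model(qtl = data.frame(chr = "1", pos = 40,
                                                         a = 0.6, d = 0)),
                            seed = 55)
  y <- setNames(ph$y, ph$id)
  dc <- decompose_epistasis(y, ind5, "1", 40, "2", 60)
  expect_true(all(abs(dc$t) < 4))
})

test_that("two-locus genotype maps obey the confidence rule and match group means", {
  # hand-built grid for three individuals at two loci
  prob <- array(0, c(3, 2, 4))
  prob[1, 1, ] <- c(1, 0, 0, 0)          # confident AA
  prob[2, 1, ] <- c(0.79, 0.07, 0.07, 0.07)  # max pooled prob 0.79: dropped
  prob[3, 1, ] <- c(0, 0.5, 0.45, 0.05)  # pooled het 0.95: confident AB
  prob[1, 2, ] <- c(0, 0, 0, 1)
  prob[2, 2, ] <- c(1, 0, 0, 0)
  prob[3, 2, ] <- c(0, 0.41, 0.41, 0.18) # pooled het 0.82: confident AB
  grid <- structure(list(grid = data.frame(chr = c("1", "2"), pos = c(0, 0)),
                         prob = prob, ids = c("x", "y", "z"), step = 1),
                    class = "lineorigin_grid")
  res <- setNames(c(1.5, 99, 2.5), c("x", "y", "z"))
  m <- genotype_phenotype_map(grid, "1", 0, "2", 0, res)
  expect_equal(m$n_used, 2)
  expect_equal(m$n_dropped, 1)
  expect_equal(m$count["AA", "BB"], 1L)
  expect_equal(m$mean["AA", "BB"], 1.5)
  expect_equal(m$mean["AB", "AB"], 2.5)
  expect_true(is.na(m$mean["BB", "BB"]))
})

test_that("noise-free diagnostic simulations give fully assigned maps with exact class means", {
  map <- sim_map(c("1" = 40, "2" = 40), spacing_cM = 5)
  fm <- founder_model(rep(1, nrow(map)), rep(0, nrow(map)))
  g <- simulate_cross(map, cross_design(n_f2 = 120, seed = 61), fm,
                      missing_rate = 0)
  lf <- estimate_line_frequencies(g, pseudocount = 0)
  lo <- compute_line_origin(g, lf, grid_step = 5)
  tm <- trait_model(epi = data.frame(chr1 = "1", pos1 = 20, chr2 = "2",
                                     pos2 = 20, i1 = 1, i2 = 0, i3 = 0, i4 = 0),
                    residual_sd = 0)
  ph <- simulate_phenotypes(g, tm, seed = 61)
  res <- setNames(ph$y - mean(ph$y), ph$id)
  m <- genotype_phenotype_map(lo, "1", 20, "2", 20, res)
  expect_equal(m$n_dropped, 0)
  # naive group-by oracle from the truth
  t1 <- true_indicators(g, "1", 20); t2 <- true_indicators(g, "2", 20)
  cls <- function(ti) ifelse(ti$D == 1, "AB", ifelse(ti$A == 1, "AA", "BB"))
  oracle <- tapply(as.numeric(res), list(factor(cls(t1), c("AA", "AB", "BB")),
                                         factor(cls(t2), c("AA", "AB", "BB"))),
                   mean)
  expect_equal(unname(m$mean), unname(as.matrix(oracle)), tolerance = 1e-10)
})
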
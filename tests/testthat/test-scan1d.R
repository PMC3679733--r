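test_that("a perfect additive fit is flagged as degenerate with the exact effect", {
  cr <- shared_cross()
  ind <- cr$ind
  k <- crossqtl:::grid_index(ind, "1", 40)
  y <- 2 * ind$A[, k]
  f <- fit_position(y, ind$A[, k], ind$D[, k])
  expect_true(f$degenerate)
  expect_equal(f$F, Inf)
  expect_equal(f$a, 2, tolerance = 1e-10)
  expect_equal(f$d, 0, tolerance = 1e-10)
  expect_true(is.na(f$se_a))
})

test_that("position fits match the naive normal-equations oracle", {
  cr <- shared_cross()
  ind <- cr$ind
  set.seed(13)
  for (k in sample(ncol(ind$A), 5)) {
    n <- 150
    rows <- sample(nrow(ind$A), n)
    A <- ind$A[rows, k]; D <- ind$D[rows, k]
    X0 <- cbind(1, rnorm(n))          # intercept + a covariate
    y <- rnorm(n) + 0.5 * A
    f <- fit_position(y, A, D, X0 = X0)
    o <- naive_ols(cbind(X0, A, D), y)
    expect_equal(f$a, unname(o$coef[3]), tolerance = 1e-10)
    expect_equal(f$d, unname(o$coef[4]), tolerance = 1e-10)
    expect_equal(f$se_a, unname(o$se[3]), tolerance = 1e-10)
    expect_equal(f$rss_full, o$rss, tolerance = 1e-8)
    o_red <- naive_ols(X0, y)
    F_naive <- ((o_red$rss - o$rss) / 2) / (o$rss / o$df)
    expect_equal(f$F, F_naive, tolerance = 1e-10)
  }
})

test_that("the null F statistic has the expected mean", {
  cr <- shared_cross()
  ind <- cr$ind
  k <- crossqtl:::grid_index(ind, "2", 50)
  n <- nrow(ind$A)
  set.seed(17)
  Fs <- vapply(1:400, function(i) {
    fit_position(rnorm(n), ind$A[, k], ind$D[, k])$F
  }, 0)
  df <- n - 3
  expect_equal(mean(Fs), df / (df - 2), tolerance = 0.12)
})

test_that("scanning is deterministic and invariant to affine trait rescaling", {
  cr <- shared_cross()
  set.seed(31)
  ph <- simulate_phenotypes(cr$genos,
                            trait_model(qtl = data.frame(chr = "1", pos = 30,
                                                         a = 0.5, d = 0.2)),
                            seed = 31)
  y <- setNames(ph$y, ph$id)
  s1 <- scan_genome(y, cr$ind)
  s2 <- scan_genome(y, cr$ind)
  expect_identical(s1$result, s2$result)
  s3 <- scan_genome(3 * y + 7, cr$ind)
  expect_equal(s3$result$F, s1$result$F, tolerance = 1e-8)
  expect_equal(s3$result$a, 3 * s1$result$a, tolerance = 1e-8)
})

test_that("freezing a called QTL as cofactor removes its own signal", {
  cr <- shared_cross()
  ph <- simulate_phenotypes(cr$genos,
                            trait_model(qtl = data.frame(chr = "1", pos = 30,
                                                         a = 0.8, d = 0)),
                            seed = 33)
  y <- setNames(ph$y, ph$id)
  s1 <- scan_genome(y, cr$ind)
  k <- crossqtl:::grid_index(cr$ind, s1$peak$chr, s1$peak$pos)
  cof <- cbind(cr$ind$A[, k], cr$ind$D[, k])
  s2 <- scan_genome(y, cr$ind, cofactors = cof)
  k2 <- which(s2$result$chr == s1$peak$chr & s2$result$pos == s1$peak$pos)
  expect_lt(s2$result$F[k2], 1e-8)
})

test_that("forward selection recovers two unlinked QTL and stops", {
  cr <- shared_cross()
  tm <- trait_model(qtl = data.frame(chr = c("1", "2"), pos = c(30, 70),
                                     a = c(0.6, 0.6), d = c(0, 0)))
  ph <- simulate_phenotypes(cr$genos, tm, seed = 41)
  y <- setNames(ph$y, ph$id)
  fs <- forward_scan(y, cr$ind, n_perm = 150, seed = 41, map = cr$qc$map)
  expect_equal(nrow(fs$calls), 2)
  expect_setequal(fs$calls$chr, c("1", "2"))
  for (i in 1:2) {
    truth <- if (fs$calls$chr[i] == "1") 30 else 70
    expect_lt(abs(fs$calls$pos[i] - truth), 15)
  }
  # nearest-marker reporting: the named marker is on the call's chromosome
  expect_true(all(grepl("^c", fs$calls$marker)))
  expect_true(all(fs$calls$var_pct > 0))
})

test_that("linked-QTL testing separates real pairs from shoulders", {
  cr <- shared_cross()
  # two strong QTL 80 cM apart on one group
  tm <- trait_model(qtl = data.frame(chr = c("1", "1"), pos = c(10, 90),
                                     a = c(0.8, 0.8), d = c(0, 0)))
  ph <- simulate_phenotypes(cr$genos, tm, seed = 43)
  y <- setNames(ph$y, ph$id)
  tp <- test_linked_pair(y, cr$ind, "1", 10, 90, threshold = 6)
  expect_true(tp$independent)
  # a single QTL tested against its own shoulder 10 cM away
  tm1 <- trait_model(qtl = data.frame(chr = "1", pos = 50, a = 0.8, d = 0))
  ph1 <- simulate_phenotypes(cr$genos, tm1, seed = 44)
  y1 <- setNames(ph1$y, ph1$id)
  tp1 <- test_linked_pair(y1, cr$ind, "1", 50, 60, threshold = 6)
  expect_false(tp1$independent)
  expect_error(test_linked_pair(y1, cr$ind, "1", 50, 50.2, threshold = 6),
               "collinearity")
})

test_that("variance-explained arithmetic follows the mean-square formula", {
  expect_equal(variance_explained(110, 90, 120), (110 - 90) / 120 * 100)
  expect_equal(variance_explained(90, 90, 120), 0)
  expect_error(variance_explained(1, 1, 0), "degenerate")
  expect_error(variance_explained(-1, 1, 1), "parameter error")
})
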
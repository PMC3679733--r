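test_that("boxplot fences flag only points beyond 1.5 IQR from the quartiles", {
  # Q1 = 2, Q3 = 4 by linear interpolation; fences at -1 and 7
  f <- flag_outliers(c(1, 2, 3, 4, 100))
  expect_equal(f, c("ok", "ok", "ok", "ok", "high"))
  # symmetric data within the fences: nothing flagged
  expect_true(all(flag_outliers(c(-2, -1, 0, 1, 2)) == "ok"))
  # near-constant vector: zero-width fences, any deviant flagged
  f3 <- flag_outliers(c(rep(5, 10), 6, 4))
  expect_equal(f3[11], "high")
  expect_equal(f3[12], "low")
  expect_true(all(f3[1:10] == "ok"))
  expect_equal(flag_outliers(c(NA, 1, 2, 3, 4))[1], NA_character_)
  expect_error(flag_outliers(c(NA_real_, NA_real_)), "data error")
  expect_error(flag_outliers(c(1, 2, 3)), "data error")
})

test_that("outlier resolution retains consistent and clustered flags", {
  flags <- matrix("ok", 10, 3, dimnames = list(NULL, c("BW8", "BW10", "BW12")))
  flags[1, 1] <- "high"                      # isolated: removed
  flags[2, ] <- "high"                       # consistent across ages: kept
  flags[3, 2] <- "low"; flags[3, 3] <- "low" # consistent pair: kept
  excl <- resolve_outliers(flags, K = 5)
  expect_true(excl[1, 1])
  expect_false(any(excl[2, ]))
  expect_false(any(excl[3, 2:3]))
  # cluster rule: 6 birds flagged high at one age
  flags2 <- matrix("ok", 10, 2)
  flags2[1:6, 1] <- "high"
  excl2 <- resolve_outliers(flags2, K = 5)
  expect_false(any(excl2[1:6, 1]))
  # but 4 birds (below K) are removed
  flags3 <- matrix("ok", 10, 2)
  flags3[1:4, 1] <- "high"
  expect_true(all(resolve_outliers(flags3, K = 5)[1:4, 1]))
})

test_that("clean_phenotypes sets excluded values missing and audits them", {
  set.seed(1)
  ph <- data.frame(id = sprintf("i%02d", 1:30),
                   BW8 = rnorm(30, 100, 5), BW10 = rnorm(30, 120, 5))
  ph$BW8[1] <- 400
  out <- clean_phenotypes(ph, families = list(BW = c("BW8", "BW10")))
  expect_true(is.na(out$pheno$BW8[1]))
  expect_true("i01" %in% out$audit$id)
  expect_equal(out$audit$side[out$audit$id == "i01"], "high")
  expect_equal(out$audit$trait[out$audit$id == "i01"], "BW8")
})

test_that("growth rate and feed conversion derivations are exact and idempotent", {
  ph <- data.frame(BW0 = 35, BW4 = 443, BW6 = 800, BW8 = c(1240, NA, 800),
                   BW10 = 1600, BW12 = 2000,
                   FI6_8 = 2320, FI8_10 = 1200, FI10_12 = 1500)
  expect_warning(out <- derive_traits(ph), "non-positive gain")
  expect_equal(out$GR0_4, rep(408, 3))
  expect_equal(out$FCR6_8[1], 2320 / 440)
  # missing BW8 propagates to every window that uses it
  expect_true(is.na(out$GR4_8[2]) && is.na(out$GR8_12[2]) &&
                is.na(out$FCR6_8[2]) && is.na(out$FCR8_10[2]))
  # zero gain: FCR undefined
  expect_true(is.na(out$FCR6_8[3]))
  # magnitude check: 2320 g intake over an 800 g gain is FCR 2.9
  expect_equal(round(2320 / 800, 1), 2.9)
  expect_warning(out2 <- derive_traits(out), "non-positive gain")
  expect_equal(out2$GR0_4, out$GR0_4)
  expect_equal(out2$FCR8_10, out$FCR8_10)
})

test_that("trait correlations match a naive covariance oracle", {
  set.seed(3)
  tb <- data.frame(x = rnorm(10))
  tb$y <- 2 * tb$x + 3
  tb$z <- rnorm(10)
  tb$w <- rnorm(10); tb$w[c(2, 5)] <- NA
  tc <- trait_correlations(tb)
  expect_equal(tc$r["x", "x"], 1)
  expect_equal(tc$r["x", "y"], 1)       # affine invariance
  # naive pairwise oracle for x-w (with missing rows dropped)
  ok <- !is.na(tb$w)
  xm <- tb$x[ok] - mean(tb$x[ok]); wm <- tb$w[ok] - mean(tb$w[ok])
  r_naive <- sum(xm * wm) / sqrt(sum(xm^2) * sum(wm^2))
  expect_equal(tc$r["x", "w"], r_naive, tolerance = 1e-12)
  expect_equal(tc$n["x", "w"], 8)
  tt <- r_naive * sqrt(6 / (1 - r_naive^2))
  expect_equal(tc$p["x", "w"], 2 * pt(-abs(tt), 6), tolerance = 1e-12)
  # zero-variance column yields undefined correlations
  tb$c <- 1
  tc2 <- trait_correlations(tb)
  expect_true(is.na(tc2$r["c", "x"]))
})

test_that("null-model selection keeps strong effects and the intercept-only fallback works", {
  set.seed(9)
  n <- 500
  ph <- data.frame(id = sprintf("i%03d", 1:n),
                   sex = sample(c("M", "F"), n, TRUE),
                   batch = sample(1:6, n, TRUE))
  ph$y <- 2 * (ph$sex == "M") + rnorm(n)   # sex effect of 2 residual SD
  nm <- select_null_model(ph, "y")
  expect_true("sex" %in% nm$factors)
  expect_false("batch" %in% nm$factors)
  # no candidates: intercept-only, residuals are the centred trait
  nm0 <- select_null_model(ph, "y", factors = character(0))
  expect_equal(unname(nm0$residuals), ph$y - mean(ph$y), tolerance = 1e-12)
  expect_equal(nm0$df_residual, n - 1)
})

test_that("a pure-noise candidate factor is retained at about the nominal rate", {
  set.seed(21)
  n_rep <- 200
  kept <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    ph <- data.frame(id = 1:120, y = rnorm(120),
                     g = sample(c("u", "v"), 120, TRUE))
    nm <- select_null_model(ph, "y", factors = "g")
    kept[r] <- "g" %in% nm$factors
  }
  # binomial 99% band around 0.05 at 200 replicates
  expect_gt(mean(kept), 0.05 - 2.58 * sqrt(0.05 * 0.95 / n_rep))
  expect_lt(mean(kept), 0.05 + 2.58 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("the selected null model never fits worse than the intercept-only model", {
  set.seed(5)
  for (r in 1:20) {
    n <- 80
    ph <- data.frame(id = seq_len(n), y = rnorm(n),
                     sex = sample(c("M", "F"), n, TRUE),
                     batch = sample(1:4, n, TRUE), cv = rnorm(n))
    full <- select_null_model(ph, "y", covariates = "cv", alpha = 1)  # keep all
    none <- select_null_model(ph, "y", factors = character(0))
    rss_full <- sum(full$residuals^2)
    rss_none <- sum(none$residuals^2)
    expect_lte(rss_full, rss_none + 1e-10)
  }
})
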
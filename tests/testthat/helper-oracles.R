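# Independent oracles and fixture builders used across the test files.

# --- exhaustive line-origin posterior -----------------------------------
# Enumerates all 4^K hidden-state sequences for one individual on one
# chromosome (state = (maternal, paternal) gamete origin, order AA, AB, BA,
# BB) and computes posterior state probabilities at every locus by direct
# summation. `calls` may contain NA (emission 1); query positions without a
# call are pseudo-loci. Completely independent of the package's
# forward-backward implementation.
oracle_line_origin <- function(calls, pos, freq_a, freq_b) {
  K <- length(pos)
  stopifnot(length(calls) == K, K <= 6)
  hald <- function(d) (1 - exp(-2 * d / 100)) / 2
  # per-state allele-1 frequencies (maternal gamete first)
  emis <- function(g, pa, pb) {
    if (is.na(g)) return(rep(1, 4))
    p1 <- c(pa, pa, pb, pb); p2 <- c(pa, pb, pa, pb)
    switch(as.character(g),
           "0" = p1 * p2,
           "1" = p1 * (1 - p2) + (1 - p1) * p2,
           "2" = (1 - p1) * (1 - p2))
  }
  # gamete origin of each state: 1 = A for maternal/paternal
  mat_o <- c(1, 1, 2, 2); pat_o <- c(1, 2, 1, 2)
  seqs <- as.matrix(expand.grid(rep(list(1:4), K)))
  w <- numeric(nrow(seqs))
  for (s in seq_len(nrow(seqs))) {
    st <- seqs[s, ]
    p <- 0.25 * emis(calls[1], freq_a[1], freq_b[1])[st[1]]
    if (K > 1) for (k in 2:K) {
      r <- hald(pos[k] - pos[k - 1])
      pm <- if (mat_o[st[k]] == mat_o[st[k - 1]]) 1 - r else r
      pp <- if (pat_o[st[k]] == pat_o[st[k - 1]]) 1 - r else r
      p <- p * pm * pp * emis(calls[k], freq_a[k], freq_b[k])[st[k]]
    }
    w[s] <- p
  }
  post <- matrix(0, K, 4)
  for (k in seq_len(K)) {
    for (st in 1:4) post[k, st] <- sum(w[seqs[, k] == st])
  }
  post / rowSums(post)
}

# --- naive least squares ------------------------------------------------
# normal equations solved directly; coefficient SEs from (X'X)^-1
naive_ols <- function(X, y) {
  XtX <- t(X) %*% X
  b <- solve(XtX, t(X) %*% y)
  res <- y - X %*% b
  rss <- sum(res^2)
  df <- nrow(X) - ncol(X)
  se <- sqrt(diag(solve(XtX)) * rss / df)
  list(coef = drop(b), rss = rss, df = df, se = se)
}

# --- hand-built cross_geno objects --------------------------------------
# minimal cross_geno for QC / frequency tests: calls is marker x individual,
# ped needs id/sire/dam/generation/line columns
manual_geno <- function(calls, ped, map) {
  structure(list(ped = ped, map = map, calls = calls, truth = NULL),
            class = "cross_geno")
}

# small F0-only pedigree with na sires/dams
founder_ped <- function(ids, lines) {
  data.frame(id = ids, sire = NA_character_, dam = NA_character_,
             generation = "F0", line = lines, sex = "F",
             stringsAsFactors = FALSE)
}

# --- shared simulated cross (expensive; built once per test run) --------
.fixture_env <- new.env(parent = emptyenv())

shared_cross <- function() {
  if (is.null(.fixture_env$cross)) {
    map <- sim_map(c("1" = 100, "2" = 100), spacing_cM = 5)
    set.seed(2024)
    fm <- sim_founder_freqs(nrow(map), 0.3)
    g <- simulate_cross(map, cross_design(n_f2 = 300, seed = 2024), fm)
    qc <- apply_qc(g)
    lf <- estimate_line_frequencies(qc$genos)
    lo <- compute_line_origin(qc$genos, lf, grid_step = 1)
    .fixture_env$cross <- list(genos = g, qc = qc$genos, freqs = lf,
                               grid = lo, ind = indicators(lo))
  }
  .fixture_env$cross
}
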
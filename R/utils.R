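# internal helpers shared across modules

# round half away from zero at `digits` decimals (presentation rounding for
# map summaries; R's round() uses banker's rounding which differs at .5)
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# residual sums of squares of every column of Y regressed on X.
# X: n x p full-column-rank design (rank-deficiency tolerated via qr pivoting),
# Y: n x k response matrix. Returns k-vector of RSS.
rss_multi <- function(qrX, Y) {
  Y <- as.matrix(Y)
  qty <- qr.qty(qrX, Y)
  r <- qrX$rank
  colSums(Y^2) - colSums(qty[seq_len(r), , drop = FALSE]^2)
}

# F statistics comparing nested designs X_red inside X_full for each column
# of Y; df_extra is the number of added columns actually contributing rank.
nested_F_multi <- function(qr_red, qr_full, Y, n) {
  rss_red <- rss_multi(qr_red, Y)
  rss_full <- rss_multi(qr_full, Y)
  df_num <- qr_full$rank - qr_red$rank
  df_den <- n - qr_full$rank
  if (df_num <= 0 || df_den <= 0) {
    return(rep(NA_real_, ncol(as.matrix(Y))))
  }
  ((rss_red - rss_full) / df_num) / (rss_full / df_den)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
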
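#' Construct a genetic map
#'
#' A genetic map is an ordered table of SNP markers with sex-average genetic
#' positions (cM, group-local origin at 0) and optional physical positions
#' (bp, 1-based).
#'
#' @param chr linkage-group identifier per marker (character or integer).
#' @param marker unique marker names.
#' @param cM genetic position in centiMorgans within the linkage group.
#' @param bp optional physical position in base pairs (1-based).
#' @return A `data.frame` of class `genetic_map` with columns
#'   `chr`, `marker`, `cM` and (if given) `bp`, sorted by group and position.
#' @examples
#' gmap <- genetic_map(chr = rep(1, 3), marker = c("m1", "m2", "m3"),
#'                     cM = c(0, 10, 25))
#' @export
genetic_map <- function(chr, marker, cM, bp = NULL) {
  if (length(chr) == 0L) stopf("map error: map has no markers")
  if (anyDuplicated(marker)) stopf("map error: duplicated marker names")
  if (any(!is.finite(cM)) || any(cM < 0)) {
    stopf("map error: cM positions must be finite and non-negative")
  }
  m <- data.frame(chr = as.character(chr), marker = as.character(marker),
                  cM = as.numeric(cM), stringsAsFactors = FALSE)
  if (!is.null(bp)) m$bp <- as.numeric(bp)
  m <- m[order(chr_rank(m$chr), m$cM), , drop = FALSE]
  rownames(m) <- NULL
  class(m) <- c("genetic_map", "data.frame")
  m
}

# order linkage groups numerically where possible, otherwise lexically
chr_rank <- function(chr) {
  num <- suppressWarnings(as.numeric(chr))
  if (all(!is.na(num))) num else match(chr, unique(chr))
}

#' @export
print.genetic_map <- function(x, ...) {
  ng <- length(unique(x$chr))
  cat(sprintf("Genetic map: %d markers on %d linkage group(s), %.1f cM total\n",
              nrow(x), ng, sum(tapply(x$cM, x$chr, function(p) diff(range(p))))))
  invisible(x)
}

#' Build an evenly spaced marker map
#'
#' Convenience constructor for simulation studies: each linkage group gets
#' markers at a fixed spacing from 0 to its length.
#'
#' @param lengths_cM numeric vector of linkage-group lengths in cM; names (or
#'   seq_along) become group identifiers.
#' @param spacing_cM marker spacing in cM (default 5).
#' @return A [genetic_map()].
#' @export
sim_map <- function(lengths_cM, spacing_cM = 5) {
  if (any(lengths_cM <= 0)) stopf("map error: group lengths must be positive")
  chrs <- names(lengths_cM) %||% as.character(seq_along(lengths_cM))
  pieces <- lapply(seq_along(lengths_cM), function(i) {
    pos <- unique(c(seq(0, lengths_cM[i], by = spacing_cM), lengths_cM[i]))
    data.frame(chr = chrs[i], cM = pos, stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, pieces)
  genetic_map(chr = all$chr,
              marker = sprintf("c%s_m%03d", all$chr,
                               unlist(lapply(pieces, function(p) seq_len(nrow(p))))),
              cM = all$cM)
}

#' Haldane map function
#'
#' Converts a genetic distance to a recombination fraction assuming no
#' crossover interference: r = (1 - exp(-2d))/2 with d in Morgans.
#'
#' @param d_cM distance in centiMorgans.
#' @return Recombination fraction in [0, 0.5).
#' @export
haldane <- function(d_cM) {
  if (any(d_cM < 0)) stopf("map error: negative cM distance")
  (1 - exp(-2 * d_cM / 100)) / 2
}

#' Summarise a linkage map
#'
#' Produces the per-group summary table customary for F2 linkage maps: physical
#' size (Mb), marker count, sex-average genetic length (cM) and recombination
#' rate (cM/Mb, one decimal, rounded half-up), plus a totals row whose rate is
#' total cM over total Mb. Rates are not reported for groups physically
#' smaller than `min_mb` megabases, where a ratio of a long genetic length to
#' a tiny physical denominator is not meaningful.
#'
#' @param groups data.frame with columns `chr`, `size_mb`, `n_markers`,
#'   `length_cm` (one row per linkage group).
#' @param min_mb physical-size floor (Mb) below which the cM/Mb rate is
#'   reported as `NA` (default 3).
#' @return data.frame of class `map_summary`: the per-group rows followed by a
#'   `Total` row; column `rate_cm_mb` holds the rounded rate.
#' @export
summarize_map <- function(groups, min_mb = 3) {
  need <- c("chr", "size_mb", "n_markers", "length_cm")
  if (!all(need %in% names(groups))) {
    stopf("map error: groups must have columns %s", paste(need, collapse = ", "))
  }
  if (any(groups$size_mb < 0) || any(groups$length_cm < 0)) {
    stopf("map error: negative group sizes")
  }
  rate <- ifelse(groups$size_mb >= min_mb & groups$size_mb > 0,
                 round_half_up(groups$length_cm / groups$size_mb, 1),
                 NA_real_)
  # degenerate zero-length group: rate defined as 0 when size allows a rate
  rate[groups$size_mb >= min_mb & groups$length_cm == 0] <- 0
  tot_mb <- sum(groups$size_mb)
  tot_cm <- sum(groups$length_cm)
  out <- data.frame(chr = as.character(groups$chr),
                    size_mb = groups$size_mb,
                    n_markers = as.integer(groups$n_markers),
                    length_cm = groups$length_cm,
                    rate_cm_mb = rate,
                    stringsAsFactors = FALSE)
  total <- data.frame(chr = "Total",
                      size_mb = round_half_up(tot_mb, 1),
                      n_markers = sum(out$n_markers),
                      length_cm = round_half_up(tot_cm, 1),
                      rate_cm_mb = if (tot_mb > 0) round_half_up(tot_cm / tot_mb, 1) else NA_real_,
                      stringsAsFactors = FALSE)
  res <- rbind(out, total)
  rownames(res) <- NULL
  class(res) <- c("map_summary", "data.frame")
  res
}
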
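# Genotype quality control for a pedigreed SNP panel.
#
# Filters, in order: (1) individuals failing call rate or individual-level
# inheritance-error rate; (2) markers failing call frequency, minor allele
# frequency (computed among retained F2 by default) or marker-level
# inheritance-error rate. Individuals are filtered first because a single bad
# sample distorts the statistics of every marker, while a bad marker barely
# moves any individual's summary.

# transmissible allele-2 dosages per parent genotype (row 4 = missing parent)
.trans <- list(`0` = 0L, `1` = 0:1, `2` = 1L, miss = 0:1)

# 4 x 4 x 3 lookup: is child dosage (0/1/2) compatible with parent dosages
# (0/1/2/missing)?
.compat_table <- local({
  tb <- array(FALSE, c(4, 4, 3))
  for (p1 in 1:4) for (p2 in 1:4) {
    poss <- unique(outer(.trans[[p1]], .trans[[p2]], `+`))
    tb[p1, p2, ] <- (0:2) %in% poss
  }
  tb
})

# per-offspring inheritance-error count and comparison count over markers.
# A comparison is a marker where the child call and at least one parent call
# are non-missing; an error is a Mendelian impossibility at a biallelic locus.
inherit_errors <- function(calls, ped) {
  idx <- function(g) ifelse(is.na(g), 4L, g + 1L)
  n_mark <- nrow(calls)
  ids <- colnames(calls)
  err_i <- setNames(numeric(length(ids)), ids)
  cmp_i <- setNames(numeric(length(ids)), ids)
  err_m <- setNames(numeric(n_mark), rownames(calls))
  cmp_m <- setNames(numeric(n_mark), rownames(calls))
  off <- ped[!is.na(ped$sire) & !is.na(ped$dam) & ped$id %in% ids, , drop = FALSE]
  for (k in seq_len(nrow(off))) {
    cid <- off$id[k]
    s <- off$sire[k]; d <- off$dam[k]
    if (!(s %in% ids) && !(d %in% ids)) next
    child <- calls[, cid]
    p1 <- if (s %in% ids) calls[, s] else rep(NA_integer_, n_mark)
    p2 <- if (d %in% ids) calls[, d] else rep(NA_integer_, n_mark)
    use <- !is.na(child) & (!is.na(p1) | !is.na(p2))
    if (!any(use)) next
    ok <- .compat_table[cbind(idx(p1[use]), idx(p2[use]), child[use] + 1L)]
    err_i[cid] <- err_i[cid] + sum(!ok)
    cmp_i[cid] <- cmp_i[cid] + sum(use)
    werr <- which(use)[!ok]
    err_m[werr] <- err_m[werr] + 1
    cmp_m[use] <- cmp_m[use] + 1
  }
  list(err_ind = err_i, cmp_ind = cmp_i, err_mark = err_m, cmp_mark = cmp_m)
}

#' Apply genotype quality control
#'
#' Retention criteria (all strict inequalities): individual call rate > 0.9;
#' marker call frequency > 0.9; minor allele frequency > 0.05; inheritance
#' (parent-offspring incompatibility) error rate < 0.05 for both individuals
#' and markers. Individuals are filtered before markers; marker statistics are
#' then computed over the retained individuals. Inheritance-error rates use
#' the number of non-missing parent-offspring comparisons as denominator.
#'
#' @param genos a `cross_geno`.
#' @param min_ind_call_rate,min_marker_call_freq,min_maf,max_inherit_err
#'   thresholds in [0, 1].
#' @param maf_generation generation over which MAF is computed (default
#'   `"F2"`; the founder lines are divergent by design, so pooled MAF would
#'   count line divergence as polymorphism).
#' @return List with elements `genos` (the filtered `cross_geno`) and
#'   `report` (a `qc_report`: excluded individuals/markers with one primary
#'   reason each, and per-criterion counts).
#' @export
apply_qc <- function(genos, min_ind_call_rate = 0.9, min_marker_call_freq = 0.9,
                     min_maf = 0.05, max_inherit_err = 0.05,
                     maf_generation = "F2") {
  thr <- c(min_ind_call_rate, min_marker_call_freq, min_maf, max_inherit_err)
  if (any(thr < 0 | thr > 1)) stopf("parameter error: thresholds must lie in [0, 1]")
  calls <- genos$calls
  ped <- genos$ped

  # --- pass 1: individuals ---------------------------------------------
  call_rate <- colMeans(!is.na(calls))
  ie <- inherit_errors(calls, ped)
  ind_err_rate <- ifelse(ie$cmp_ind > 0, ie$err_ind / ie$cmp_ind, 0)
  fail_cr <- call_rate <= min_ind_call_rate
  fail_ie <- ind_err_rate >= max_inherit_err
  drop_ind <- fail_cr | fail_ie
  excl_ind <- data.frame(
    id = colnames(calls)[drop_ind],
    reason = ifelse(fail_cr[drop_ind], "call_rate", "inheritance_error"),
    stringsAsFactors = FALSE)

  keep_ids <- colnames(calls)[!drop_ind]
  calls2 <- calls[, keep_ids, drop = FALSE]
  ped2 <- ped[ped$id %in% keep_ids, , drop = FALSE]

  # --- pass 2: markers --------------------------------------------------
  call_freq <- rowMeans(!is.na(calls2))
  maf_ids <- ped2$id[ped2$generation %in% maf_generation]
  gm <- calls2[, maf_ids, drop = FALSE]
  n_alleles <- 2 * rowSums(!is.na(gm))
  f2_alt <- rowSums(gm, na.rm = TRUE)
  f <- ifelse(n_alleles > 0, f2_alt / n_alleles, NA_real_)
  maf <- pmin(f, 1 - f)
  ie2 <- inherit_errors(calls2, ped2)
  mark_err_rate <- ifelse(ie2$cmp_mark > 0, ie2$err_mark / ie2$cmp_mark, 0)
  fail_cf <- call_freq <= min_marker_call_freq
  fail_maf <- is.na(maf) | maf <= min_maf
  fail_me <- mark_err_rate >= max_inherit_err
  drop_mark <- fail_cf | fail_maf | fail_me
  reason_m <- ifelse(fail_cf[drop_mark], "call_freq",
                     ifelse(fail_maf[drop_mark], "maf", "inheritance_error"))
  excl_mark <- data.frame(marker = rownames(calls2)[drop_mark],
                          reason = reason_m, stringsAsFactors = FALSE)

  keep_mark <- rownames(calls2)[!drop_mark]
  out <- genos
  out$calls <- calls2[keep_mark, , drop = FALSE]
  out$ped <- ped2
  km <- genos$map[genos$map$marker %in% keep_mark, , drop = FALSE]
  class(km) <- class(genos$map)
  out$map <- km
  if (!is.null(out$truth)) {
    # truth is indexed by F2 position in the original pedigree; subset it
    f2_keep <- genos$truth$f2_ids %in% keep_ids
    out$truth$f2_ids <- genos$truth$f2_ids[f2_keep]
    out$truth$mat_labels <- genos$truth$mat_labels[f2_keep, , drop = FALSE]
    out$truth$pat_labels <- genos$truth$pat_labels[f2_keep, , drop = FALSE]
    out$truth$chr <- lapply(genos$truth$chr, function(tr) {
      list(mat_start = tr$mat_start[f2_keep],
           mat_breaks = tr$mat_breaks[f2_keep],
           pat_start = tr$pat_start[f2_keep],
           pat_breaks = tr$pat_breaks[f2_keep])
    })
  }

  report <- structure(list(
    excluded_individuals = excl_ind,
    excluded_markers = excl_mark,
    counts = list(
      individuals_call_rate = sum(fail_cr),
      individuals_inheritance = sum(!fail_cr & fail_ie),
      markers_call_freq = sum(fail_cf),
      markers_maf = sum(!fail_cf & fail_maf),
      markers_inheritance = sum(!fail_cf & !fail_maf & fail_me),
      individuals_total = nrow(excl_ind),
      markers_total = nrow(excl_mark)),
    params = list(min_ind_call_rate = min_ind_call_rate,
                  min_marker_call_freq = min_marker_call_freq,
                  min_maf = min_maf, max_inherit_err = max_inherit_err,
                  maf_generation = maf_generation),
    order = "individuals before markers, one pass each"),
    class = "qc_report")
  list(genos = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Genotype QC report (", x$order, ")\n", sep = "")
  cat(sprintf("  individuals excluded: %d (call rate %d, inheritance %d)\n",
              x$counts$individuals_total, x$counts$individuals_call_rate,
              x$counts$individuals_inheritance))
  cat(sprintf("  markers excluded: %d (call freq %d, MAF %d, inheritance %d)\n",
              x$counts$markers_total, x$counts$markers_call_freq,
              x$counts$markers_maf, x$counts$markers_inheritance))
  invisible(x)
}

#' Write a QC report as CSV files plus a log
#' @param report a `qc_report`.
#' @param dir output directory.
#' @export
write_qc_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$excluded_individuals,
                   file.path(dir, "qc_excluded_individuals.csv"), row.names = FALSE)
  utils::write.csv(report$excluded_markers,
                   file.path(dir, "qc_excluded_markers.csv"), row.names = FALSE)
  con <- file(file.path(dir, "qc_log.txt"), "w")
  sink(con); print(report); sink()
  close(con)
  invisible(dir)
}
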
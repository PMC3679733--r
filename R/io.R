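# Readers and writers for the pipeline's plain-text formats.
#
# Genotype matrix dialect: tab-delimited, rows = markers, columns =
# individuals, first column the marker name, header row of individual ids,
# cells are two-character allele calls (default alleles "A"/"B" per marker),
# missing code "--".

#' Write a genotype matrix
#'
#' @param genos a `cross_geno`.
#' @param file output path.
#' @param missing missing-call code (default `"--"`).
#' @param alleles length-2 character vector naming allele 1 and allele 2.
#' @export
write_genotypes <- function(genos, file, missing = "--", alleles = c("A", "B")) {
  g <- genos$calls
  txt <- matrix(missing, nrow(g), ncol(g))
  codes <- c(paste0(alleles[1], alleles[1]), paste0(alleles[1], alleles[2]),
             paste0(alleles[2], alleles[2]))
  for (v in 0:2) txt[which(g == v)] <- codes[v + 1]
  out <- data.frame(marker = rownames(g), txt, stringsAsFactors = FALSE,
                    check.names = FALSE)
  names(out) <- c("marker", colnames(g))
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a genotype matrix
#'
#' Calls are decoded against the per-marker alleles; any token that is neither
#' a valid call nor the missing code becomes a missing call, with a warning
#' reporting how many such tokens were seen.
#'
#' @param path genotype file (dialect of [write_genotypes()]).
#' @param map a [genetic_map()]; all file markers must be on it.
#' @param pedigree pedigree data.frame (columns id, sire, dam, generation,
#'   line, sex; see [read_pedigree()]).
#' @param missing missing-call code.
#' @param alleles length-2 character vector of allele names.
#' @return A `cross_geno` (without simulation truth).
#' @export
read_genotypes <- function(path, map, pedigree, missing = "--",
                           alleles = c("A", "B")) {
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character")
  if (nrow(raw) == 0 || ncol(raw) < 2) stopf("format error: empty genotype file")
  markers <- raw[[1]]
  bad <- setdiff(markers, map$marker)
  if (length(bad) > 0) {
    stopf("reconciliation error: markers not on map: %s",
          paste(utils::head(bad, 5), collapse = ", "))
  }
  ids <- names(raw)[-1]
  txt <- as.matrix(raw[, -1, drop = FALSE])
  short <- is.na(txt) | txt == ""
  if (any(short)) {
    stopf("format error: ragged genotype matrix (%d short cells); use the missing code '%s' for absent calls",
          sum(short), missing)
  }
  codes <- c(paste0(alleles[1], alleles[1]), paste0(alleles[1], alleles[2]),
             paste0(alleles[2], alleles[1]), paste0(alleles[2], alleles[2]))
  g <- matrix(NA_integer_, nrow(txt), ncol(txt))
  g[txt == codes[1]] <- 0L
  g[txt == codes[2] | txt == codes[3]] <- 1L
  g[txt == codes[4]] <- 2L
  unknown <- sum(!(txt %in% c(codes, missing)))
  if (unknown > 0) warnf("%d unrecognised genotype tokens set to missing", unknown)
  dimnames(g) <- list(markers, ids)
  # align to map order; markers on the map but absent from the file stay out
  keep_map <- map[map$marker %in% markers, , drop = FALSE]
  class(keep_map) <- class(map)
  g <- g[match(keep_map$marker, markers), , drop = FALSE]
  ped <- pedigree
  if (!all(c("id", "generation") %in% names(ped))) {
    stopf("format error: pedigree must have id and generation columns")
  }
  keep_ids <- intersect(ids, ped$id)
  structure(list(ped = ped[match(keep_ids, ped$id), , drop = FALSE],
                 map = keep_map,
                 calls = g[, keep_ids, drop = FALSE],
                 truth = NULL),
            class = "cross_geno")
}

#' Write / read a genetic map as TSV (group, marker, cM, bp)
#' @param map a [genetic_map()].
#' @param file path.
#' @export
write_map <- function(map, file) {
  utils::write.table(as.data.frame(map), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_map
#' @export
read_map <- function(file) {
  m <- utils::read.delim(file, header = TRUE, colClasses = NA)
  genetic_map(m$chr, m$marker, m$cM, bp = m$bp)
}

#' Write / read a pedigree as TSV (id, sire, dam, generation, line, sex, ...)
#' @param ped pedigree data.frame.
#' @param file path.
#' @export
write_pedigree <- function(ped, file) {
  utils::write.table(ped, file, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(file)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(file) {
  ped <- utils::read.delim(file, header = TRUE, colClasses = "character",
                           na.strings = "")
  for (cc in intersect(c("family", "batch"), names(ped))) {
    ped[[cc]] <- suppressWarnings(as.integer(ped[[cc]]))
  }
  ped
}

#' Write / read a phenotype table as CSV
#' @param pheno phenotype data.frame.
#' @param file path.
#' @export
write_phenotypes <- function(pheno, file) {
  utils::write.csv(pheno, file, row.names = FALSE, na = "")
  invisible(file)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(file) {
  ph <- utils::read.csv(file, header = TRUE, na.strings = c("", "NA"))
  class(ph) <- c("pheno_table", "data.frame")
  ph
}

#' Write a complete simulated cross to a directory
#'
#' Writes `geno.tsv`, `map.tsv` and `ped.tsv` in the package's standard
#' dialects.
#'
#' @param genos a `cross_geno`.
#' @param dir output directory (created if absent).
#' @export
write_cross <- function(genos, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(genos, file.path(dir, "geno.tsv"))
  write_map(genos$map, file.path(dir, "map.tsv"))
  write_pedigree(genos$ped, file.path(dir, "ped.tsv"))
  invisible(dir)
}

#' Write / read a line-origin grid as a wide TSV
#'
#' One row per individual x grid position: id, chr, cM, and the four state
#' probabilities (p_aa, p_ab, p_ba, p_bb; maternal gamete first).
#'
#' @param grid a `lineorigin_grid`.
#' @param file path.
#' @export
write_line_origin <- function(grid, file) {
  n <- length(grid$ids); np <- nrow(grid$grid)
  out <- data.frame(id = rep(grid$ids, np),
                    chr = rep(grid$grid$chr, each = n),
                    cM = rep(grid$grid$pos, each = n),
                    p_aa = as.vector(grid$prob[, , 1]),
                    p_ab = as.vector(grid$prob[, , 2]),
                    p_ba = as.vector(grid$prob[, , 3]),
                    p_bb = as.vector(grid$prob[, , 4]))
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_line_origin
#' @export
read_line_origin <- function(file) {
  d <- utils::read.delim(file, header = TRUE,
                         colClasses = c(id = "character", chr = "character"))
  ids <- unique(d$id)
  grid <- unique(d[, c("chr", "cM")])
  rownames(grid) <- NULL
  n <- length(ids); np <- nrow(grid)
  prob <- array(NA_real_, c(n, np, 4), dimnames = list(ids, NULL, STATES))
  prob[, , 1] <- matrix(d$p_aa, n, np)
  prob[, , 2] <- matrix(d$p_ab, n, np)
  prob[, , 3] <- matrix(d$p_ba, n, np)
  prob[, , 4] <- matrix(d$p_bb, n, np)
  step <- if (np > 1) min(diff(sort(unique(grid$cM)))) else 1
  structure(list(grid = data.frame(chr = grid$chr, pos = grid$cM,
                                   stringsAsFactors = FALSE),
                 prob = prob, ids = ids, step = step),
            class = "lineorigin_grid")
}
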
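#' Validate a genotype matrix
#'
#' A genotype matrix is an integer matrix of allele counts with lines in
#' rows and markers in columns. Calls count copies of the allele whose
#' nucleotide is first in alphabetical order, so 0 and 2 are the two
#' homozygotes and 1 the heterozygote; `NA` marks a missing call.
#'
#' @param G Matrix to validate.
#' @param allow_missing Permit `NA` calls (`TRUE` for raw input, `FALSE`
#'   after imputation).
#' @return `G`, invisibly, after passing all checks.
#' @export
validate_genotypes <- function(G, allow_missing = TRUE) {
  if (!is.matrix(G)) stop("genotypes must be a matrix (lines x markers)")
  if ((nrow(G) > 0L && is.null(rownames(G))) ||
      (ncol(G) > 0L && is.null(colnames(G)))) {
    stop("genotype matrix needs line ids as rownames and marker ids as colnames")
  }
  if (anyDuplicated(rownames(G))) {
    stop("duplicated line id(s): ",
         paste(unique(rownames(G)[duplicated(rownames(G))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(G))) {
    stop("duplicated marker id(s): ",
         paste(unique(colnames(G)[duplicated(colnames(G))]), collapse = ", "))
  }
  v <- G[!is.na(G)]
  if (length(v) && !all(v %in% c(0, 1, 2))) {
    stop("genotype calls must be 0, 1, 2 or missing")
  }
  if (!allow_missing && anyNA(G)) stop("genotype matrix contains missing calls")
  invisible(G)
}

#' Read a genotype matrix from CSV/TSV or VCF
#'
#' Delimited input has the line id in the first column and one column per
#' marker, cells in \{0, 1, 2\} with "NA", "" or "." accepted as missing.
#' VCF input (requires the VariantAnnotation package) converts diploid GT
#' fields to allele counts of the alphabetically first allele, so
#' chip-style tables and VCFs code identically.
#'
#' @param path Path to the file.
#' @param format One of "auto", "tsv", "csv", "vcf". "auto" uses the file
#'   extension.
#' @return Validated genotype matrix (see [validate_genotypes()]).
#' @export
load_genotypes <- function(path, format = c("auto", "tsv", "csv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", vcf = "vcf", "tsv")
  }
  if (format == "vcf") return(.load_genotypes_vcf(path))
  sep <- if (format == "csv") "," else "\t"
  tab <- read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                    colClasses = "character", na.strings = NULL)
  if (ncol(tab) < 2L) stop("genotype table needs a line-id column plus markers")
  line_ids <- tab[[1L]]
  marker_ids <- colnames(tab)[-1L]
  G <- matrix(NA_integer_, nrow(tab), length(marker_ids),
              dimnames = list(line_ids, marker_ids))
  for (j in seq_along(marker_ids)) {
    cell <- trimws(tab[[j + 1L]])
    miss <- cell %in% .MISSING_TOKENS
    bad <- !miss & !cell %in% c("0", "1", "2")
    if (any(bad)) {
      k <- which(bad)[1L]
      stop(sprintf("unparseable genotype call %s at line '%s', marker '%s'",
                   dQuote(cell[k]), line_ids[k], marker_ids[j]))
    }
    G[!miss, j] <- as.integer(cell[!miss])
  }
  validate_genotypes(G)
  G
}

.load_genotypes_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("VCF import requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT # markers x samples
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt_l <- VariantAnnotation::alt(vcf)
  alt <- vapply(seq_along(alt_l), function(i) {
    a <- as.character(alt_l[[i]])
    if (length(a)) a[1L] else ""
  }, character(1))
  # count the allele first in alphabetical order
  count_ref <- ref <= alt | alt == ""
  n_mark <- nrow(gt)
  G <- matrix(NA_integer_, ncol(gt), n_mark,
              dimnames = list(colnames(gt), rownames(gt)))
  for (i in seq_len(n_mark)) {
    g <- gt[i, ]
    g <- gsub("|", "/", g, fixed = TRUE)
    nref <- ifelse(g %in% c(".", "./.", ".|."), NA_integer_,
                   (g == "0/0") * 2L + (g %in% c("0/1", "1/0")) * 1L)
    G[, i] <- if (count_ref[i]) nref else 2L - nref
  }
  validate_genotypes(G)
  G
}

#' Write a genotype matrix as TSV
#'
#' Inverse of [load_genotypes()] for the delimited dialect; missing calls
#' are written as "NA". Round-trips exactly.
#'
#' @param G Genotype matrix.
#' @param path Output path.
#' @export
write_genotypes <- function(G, path) {
  validate_genotypes(G)
  tab <- data.frame(line_id = rownames(G), G, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a genetic map
#'
#' A genetic map is a data frame with columns `marker_id`, `chromosome`,
#' and `position_cM`. Markers must be unique and, within a chromosome,
#' stored in non-decreasing map order.
#'
#' @param map Data frame to validate.
#' @return `map`, invisibly.
#' @export
validate_genetic_map <- function(map) {
  need <- c("marker_id", "chromosome", "position_cM")
  if (!is.data.frame(map) || !all(need %in% names(map))) {
    stop("genetic map needs columns marker_id, chromosome, position_cM")
  }
  if (anyDuplicated(map$marker_id)) stop("duplicated marker id(s) in genetic map")
  if (any(!is.finite(map$position_cM)) || any(map$position_cM < 0)) {
    stop("map positions must be finite and non-negative (cM)")
  }
  for (ch in unique(map$chromosome)) {
    p <- map$position_cM[map$chromosome == ch]
    if (is.unsorted(p)) stop("positions not sorted within chromosome ", ch)
  }
  invisible(map)
}

#' Read a genetic map from TSV
#'
#' Expects columns `marker_id`, `chromosome`, `position_cM`. Rows are
#' sorted by chromosome then position before validation.
#'
#' @param path Path to the TSV.
#' @return Validated genetic map data frame.
#' @export
load_genetic_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  map <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  map <- map[order(map$chromosome, map$position_cM), , drop = FALSE]
  rownames(map) <- NULL
  validate_genetic_map(map)
  map
}

#' Harmonize a genotype matrix with a genetic map
#'
#' Restricts and reorders the marker columns of `G` to the map's marker
#' order. Markers missing from the map are dropped with a warning so that
#' training panels and simulated progeny stay on identical panels.
#'
#' @param G Genotype matrix.
#' @param map Genetic map.
#' @return List with elements `geno` (reordered matrix) and `map`
#'   (restricted to markers present in `G`).
#' @export
align_to_map <- function(G, map) {
  validate_genotypes(G)
  validate_genetic_map(map)
  keep <- colnames(G)[colnames(G) %in% map$marker_id]
  dropped <- setdiff(colnames(G), keep)
  if (length(dropped)) {
    warning(length(dropped), " marker(s) absent from the genetic map were dropped")
  }
  if (!length(keep)) stop("no genotyped marker is present in the genetic map")
  map <- map[map$marker_id %in% keep, , drop = FALSE]
  list(geno = G[, map$marker_id, drop = FALSE], map = map)
}

#' Read long-format phenotype records
#'
#' CSV with columns `line_id`, `year`, `location`, `rep`, `maturity_days`,
#' `yield`. Environment is defined downstream as year crossed with
#' location.
#'
#' @param path Path to the CSV.
#' @return Data frame of phenotype records.
#' @export
load_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  rec <- read.table(path, sep = ",", header = TRUE, stringsAsFactors = FALSE)
  need <- c("line_id", "year", "location", "rep", "maturity_days", "yield")
  if (!all(need %in% names(rec))) {
    stop("phenotype file needs columns: ", paste(need, collapse = ", "))
  }
  key <- paste(rec$line_id, rec$year, rec$location, rec$rep)
  if (anyDuplicated(key)) stop("duplicated (line, environment, rep) records")
  rec
}

#' Read a candidate cross list
#'
#' CSV with columns `parent1`, `parent2`; pairs are unordered and selfs
#' are rejected.
#'
#' @param path Path to the CSV.
#' @return Data frame with columns `parent1`, `parent2`.
#' @export
load_crosses <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cr <- read.table(path, sep = ",", header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("parent1", "parent2") %in% names(cr))) {
    stop("cross file needs columns parent1, parent2")
  }
  if (any(cr$parent1 == cr$parent2)) stop("self crosses are not allowed")
  cr[c("parent1", "parent2")]
}
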
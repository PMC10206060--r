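#' Per-marker minor allele frequency and missingness
#'
#' MAF is computed over observed (non-missing) calls only: with m lines
#' observed at a marker, the counted-allele frequency is sum(calls)/(2m)
#' and the MAF is the smaller of that frequency and its complement, which
#' makes the filter symmetric under allele relabelling (c -> 2 - c).
#'
#' @param G Genotype matrix.
#' @return Data frame with columns `marker_id`, `maf`, `missing_frac`.
#' @export
marker_stats <- function(G) {
  validate_genotypes(G)
  n_obs <- colSums(!is.na(G))
  p <- ifelse(n_obs > 0, colSums(G, na.rm = TRUE) / (2 * n_obs), NA_real_)
  data.frame(marker_id = colnames(G),
             maf = pmin(p, 1 - p),
             missing_frac = 1 - n_obs / nrow(G),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter markers on minor allele frequency and missingness
#'
#' Markers with MAF below `maf_min` or missing fraction above
#' `max_missing` are excluded (defaults follow standard SNP-chip QC for
#' inbred breeding panels: MAF < 0.06 or > 20% missing). A marker failing
#' both filters is booked under missingness, which is checked first, so
#' the report's removal counts are disjoint. The line set is never
#' changed. Removing every marker is allowed (with a warning), since the
#' empty panel is still a valid matrix.
#'
#' @param G Genotype matrix.
#' @param maf_min Minimum minor allele frequency to retain.
#' @param max_missing Maximum missing-call fraction to retain.
#' @return List with `geno` (filtered matrix) and `report`, a `qc_report`
#'   carrying counts and the per-marker statistics.
#' @export
filter_markers <- function(G, maf_min = 0.06, max_missing = 0.20) {
  stats <- marker_stats(G)
  fail_missing <- stats$missing_frac > max_missing
  fail_maf <- !fail_missing & (is.na(stats$maf) | stats$maf < maf_min)
  keep <- !fail_missing & !fail_maf
  if (!any(keep)) warning("all markers removed by QC filters")
  report <- structure(list(
    n_input_markers = ncol(G),
    n_removed_missing = sum(fail_missing),
    n_removed_maf = sum(fail_maf),
    n_retained = sum(keep),
    maf_min = maf_min,
    max_missing = max_missing,
    marker_stats = cbind(stats,
                         removed = ifelse(fail_missing, "missing",
                                          ifelse(fail_maf, "maf", "retained")))
  ), class = "qc_report")
  list(geno = G[, keep, drop = FALSE], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "Marker QC: %d input, %d removed (> %.0f%% missing), %d removed (MAF < %.3g), %d retained\n",
    x$n_input_markers, x$n_removed_missing, 100 * x$max_missing,
    x$n_removed_maf, x$maf_min, x$n_retained))
  invisible(x)
}

#' Write a QC report as TSV
#'
#' @param report A `qc_report` from [filter_markers()].
#' @param path Output path for the per-marker table.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  write.table(report$marker_stats, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Impute residual missing genotype calls
#'
#' A deliberately naive stand-in for haplotype-based imputation, adequate
#' for the low missingness left after QC. `mode` fills each missing call
#' with the most frequent observed call at that marker (ties broken
#' towards the lower call); `mean_round` fills with the observed mean call
#' rounded half away from zero. Both are deterministic; the `seed`
#' argument is reserved for future stochastic methods.
#'
#' @param G Genotype matrix after QC.
#' @param method "mode" or "mean_round".
#' @param seed Unused by the deterministic methods; kept in the interface.
#' @return Genotype matrix with no missing calls.
#' @export
impute_missing <- function(G, method = c("mode", "mean_round"), seed = NULL) {
  method <- match.arg(method)
  validate_genotypes(G)
  all_missing <- colSums(!is.na(G)) == 0L
  if (any(all_missing)) {
    stop("cannot impute marker(s) with all calls missing: ",
         paste(colnames(G)[all_missing], collapse = ", "))
  }
  for (j in which(colSums(is.na(G)) > 0L)) {
    obs <- G[!is.na(G[, j]), j]
    fill <- if (method == "mode") {
      counts <- tabulate(obs + 1L, nbins = 3L)
      which.max(counts) - 1L # which.max takes the first (lowest call) on ties
    } else {
      as.integer(floor(mean(obs) + 0.5))
    }
    G[is.na(G[, j]), j] <- fill
  }
  G
}
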
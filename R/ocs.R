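#' Canonical identifier for an unordered cross
#'
#' @param parent1,parent2 Parent line ids (vectorized).
#' @return Character id `"<min> x <max>"`, identical for (A,B) and (B,A).
#' @export
cross_id <- function(parent1, parent2) {
  paste(pmin(parent1, parent2), pmax(parent1, parent2), sep = " x ")
}

#' Enumerate all candidate crosses among a set of parents
#'
#' All unordered pairs without selfs, `n(n-1)/2` for n parents (e.g. 100
#' parents give 4,950 candidate crosses), in deterministic lexicographic
#' order.
#'
#' @param parent_ids Unique parent line ids (>= 2).
#' @return Data frame with columns `parent1`, `parent2`, `cross_id`.
#' @export
enumerate_crosses <- function(parent_ids) {
  if (anyDuplicated(parent_ids)) stop("duplicated parent id(s)")
  if (length(parent_ids) < 2L) stop("need at least 2 parents")
  ids <- sort(as.character(parent_ids))
  pairs <- combn(ids, 2L)
  data.frame(parent1 = pairs[1L, ], parent2 = pairs[2L, ],
             cross_id = cross_id(pairs[1L, ], pairs[2L, ]),
             stringsAsFactors = FALSE)
}

#' Usefulness criterion of a set of progeny GEBVs
#'
#' `UC = mu + i sigma_g`, operationalized as the mean of the top-i
#' fraction of predicted progeny GEBVs: with selection intensity `i = 0`
#' this is the plain progeny mean (MV); with `i > 0` it is the mean of
#' the top `k = max(1, round(i * n))` values (round half away from
#' zero). Ties at the cutoff are equivalent by value, so tie order is
#' irrelevant.
#'
#' @param gebvs Non-empty numeric vector of progeny GEBVs.
#' @param i Selection intensity in \[0, 1).
#' @return The usefulness criterion value.
#' @export
usefulness <- function(gebvs, i) {
  if (!length(gebvs)) stop("empty GEBV vector")
  stopifnot(is.numeric(i), length(i) == 1L, i >= 0, i < 1)
  if (i == 0) return(mean(gebvs))
  k <- max(1L, as.integer(floor(i * length(gebvs) + 0.5)))
  mean(sort(gebvs, decreasing = TRUE)[seq_len(k)])
}

#' Evaluate one candidate cross
#'
#' Simulates `n_progeny` F5-derived RIL progeny of the cross on the
#' genetic map, predicts their GEBVs under the supplied genomic
#' prediction fit, and summarizes the cross by the progeny GEBV mean, SD
#' and the usefulness criterion at each requested selection intensity.
#' Fully determined by `seed`.
#'
#' @param cross Either a `cross_id` string, a character vector
#'   `c(parent1, parent2)`, or a one-row data frame with `parent1`,
#'   `parent2`.
#' @param fit A `gp_fit` trained on the same marker panel.
#' @param geno Genotype matrix containing both parents (imputed).
#' @param map Genetic map aligned with `geno`.
#' @param n_progeny Progeny per cross (default 500).
#' @param intensities Selection intensities to report (default 0, 0.1,
#'   0.2 — MV, UC0.1, UC0.2).
#' @param seed Optional integer seed.
#' @param final_generation Filial generation of the simulated RILs.
#' @return Object of class `cross_value`: list with `cross_id`,
#'   `parents`, `mean`, `sd` (sample SD of progeny GEBVs), `uc` (named by
#'   intensity), `model_tag`, `n_progeny`, `seed`.
#' @export
evaluate_cross <- function(cross, fit, geno, map, n_progeny = 500,
                           intensities = c(0, 0.1, 0.2), seed = NULL,
                           final_generation = 5) {
  parents <- .cross_parents(cross)
  if (!all(parents %in% rownames(geno))) {
    stop("parent(s) not genotyped: ",
         paste(setdiff(parents, rownames(geno)), collapse = ", "))
  }
  cid <- cross_id(parents[1L], parents[2L])
  prog <- simulate_ril_progeny(geno[parents[1L], ], geno[parents[2L], ], map,
                               n = n_progeny,
                               final_generation = final_generation,
                               seed = seed, cross_id = cid)
  gebv <- predict_gebv(fit, prog$geno)
  uc <- vapply(intensities, function(i) usefulness(gebv, i), numeric(1))
  structure(list(cross_id = cid, parents = parents,
                 mean = mean(gebv), sd = sd(gebv),
                 uc = setNames(uc, as.character(intensities)),
                 model_tag = fit$model_tag, n_progeny = n_progeny,
                 seed = seed),
            class = "cross_value")
}

#' @export
print.cross_value <- function(x, ...) {
  cat(sprintf("%s [%s, n=%d]: mean %.4g, sd %.4g; UC: %s\n",
              x$cross_id, x$model_tag, x$n_progeny, x$mean, x$sd,
              paste(sprintf("i=%s -> %.4g", names(x$uc), x$uc),
                    collapse = ", ")))
  invisible(x)
}

.cross_parents <- function(cross) {
  if (is.data.frame(cross)) {
    stopifnot(nrow(cross) == 1L)
    return(c(cross$parent1[1L], cross$parent2[1L]))
  }
  if (is.character(cross) && length(cross) == 1L && grepl(" x ", cross, fixed = TRUE)) {
    return(strsplit(cross, " x ", fixed = TRUE)[[1L]])
  }
  stopifnot(is.character(cross), length(cross) == 2L)
  cross
}

#' Rank candidate crosses by a usefulness criterion
#'
#' Evaluates every cross (each with its own sub-seed derived from `seed`,
#' so one progeny set per cross is shared by all reported criteria) and
#' sorts descending by the criterion `uc[criterion]`, breaking ties by
#' lexicographic cross id.
#'
#' @param crosses Data frame with `parent1`, `parent2` (e.g. from
#'   [enumerate_crosses()]).
#' @param fit A `gp_fit`.
#' @param geno,map Genotypes and aligned genetic map.
#' @param criterion Selection intensity used for ranking (one of
#'   `intensities`).
#' @param n_progeny Progeny per cross.
#' @param intensities Intensities to report.
#' @param seed Master seed; per-cross seeds are derived deterministically.
#' @param final_generation Filial generation of the simulated RILs.
#' @return Data frame with columns `rank`, `parent1`, `parent2`, `mean`,
#'   `sd`, one `uc_<i>` column per intensity, `model`.
#' @export
rank_crosses <- function(crosses, fit, geno, map, criterion = 0.1,
                         n_progeny = 500, intensities = c(0, 0.1, 0.2),
                         seed = NULL, final_generation = 5) {
  stopifnot(is.data.frame(crosses), nrow(crosses) >= 1L)
  if (!criterion %in% intensities) intensities <- sort(c(criterion, intensities))
  vals <- lapply(seq_len(nrow(crosses)), function(k) {
    s <- if (is.null(seed)) NULL else derive_seed(seed, "evaluate_cross", k)
    evaluate_cross(crosses[k, , drop = FALSE], fit, geno, map,
                   n_progeny = n_progeny, intensities = intensities,
                   seed = s, final_generation = final_generation)
  })
  uc_tab <- do.call(rbind, lapply(vals, function(v) v$uc))
  colnames(uc_tab) <- paste0("uc_", colnames(uc_tab))
  out <- data.frame(parent1 = vapply(vals, function(v) v$parents[1L], ""),
                    parent2 = vapply(vals, function(v) v$parents[2L], ""),
                    mean = vapply(vals, function(v) v$mean, 0),
                    sd = vapply(vals, function(v) v$sd, 0),
                    uc_tab, model = fit$model_tag,
                    stringsAsFactors = FALSE, check.names = FALSE)
  crit_col <- paste0("uc_", as.character(criterion))
  ord <- order(-out[[crit_col]], cross_id(out$parent1, out$parent2))
  out <- out[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}
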
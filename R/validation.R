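#' Build a training-set composition
#'
#' Three compositions varying the genetic relatedness between the
#' training set and the predicted crosses:
#' * `FTS` (full training set): all lines retained.
#' * `WFS` (without full siblings): all lines whose recorded
#'   cross-of-origin is one of the predicted crosses are removed;
#'   parental lines are always retained.
#' * `RTS` (reduced training set): the same NUMBER of lines as WFS is
#'   removed, sampled uniformly among lines that are neither direct
#'   progeny of the predicted crosses nor parents — a size control that
#'   leaves relatedness essentially intact.
#'
#' @param all_lines Character vector of candidate training line ids.
#' @param predicted_crosses Data frame with `parent1`, `parent2`.
#' @param pedigree Data frame with `line_id`, `cross_id` recording each
#'   line's cross of origin (`cross_id` as in [cross_id()]); lines absent
#'   from the pedigree are treated as unrelated to any predicted cross.
#' @param tag One of "FTS", "WFS", "RTS".
#' @param seed Seed for RTS sampling.
#' @return Object of class `training_composition`: list with `tag`,
#'   `retained`, `removed`, `seed`.
#' @export
build_training_set <- function(all_lines, predicted_crosses, pedigree, tag,
                               seed = NULL) {
  tag <- match.arg(tag, c("FTS", "WFS", "RTS"))
  stopifnot(is.character(all_lines), !anyDuplicated(all_lines))
  parents <- unique(c(predicted_crosses$parent1, predicted_crosses$parent2))
  pred_ids <- cross_id(predicted_crosses$parent1, predicted_crosses$parent2)
  origin <- setNames(pedigree$cross_id, pedigree$line_id)
  progeny <- all_lines[!is.na(origin[all_lines]) &
                         origin[all_lines] %in% pred_ids]
  progeny <- setdiff(progeny, parents) # parents always retained
  removed <- switch(tag,
    FTS = character(0),
    WFS = progeny,
    RTS = {
      pool <- setdiff(all_lines, union(progeny, parents))
      if (length(pool) < length(progeny)) {
        stop("RTS infeasible: only ", length(pool),
             " non-progeny, non-parent lines available to remove ",
             length(progeny))
      }
      with_seed(seed, sample(pool, length(progeny)))
    })
  structure(list(tag = tag,
                 retained = setdiff(all_lines, removed),
                 removed = removed,
                 seed = if (tag == "RTS") seed else NULL),
            class = "training_composition")
}

#' @export
print.training_composition <- function(x, ...) {
  cat(sprintf("Training composition %s: %d retained, %d removed\n",
              x$tag, length(x$retained), length(x$removed)))
  invisible(x)
}

#' Observed value of a realized cross
#'
#' The arithmetic mean of the entry BLUPs of the cross's phenotyped
#' progeny.
#'
#' @param cross A cross id string, parent pair, or one-row data frame
#'   (see [evaluate_cross()]).
#' @param progeny_blups Named vector of entry BLUPs.
#' @param pedigree Data frame with `line_id`, `cross_id`.
#' @return The observed cross value.
#' @export
observed_cross_value <- function(cross, progeny_blups, pedigree) {
  parents <- .cross_parents(cross)
  cid <- cross_id(parents[1L], parents[2L])
  prog <- pedigree$line_id[pedigree$cross_id == cid]
  prog <- intersect(prog, names(progeny_blups))
  if (!length(prog)) stop("no phenotyped progeny recorded for cross ", cid)
  mean(progeny_blups[prog])
}

#' Spearman rank-correlation accuracy
#'
#' Rank correlation (average ranks for ties) between predicted and
#' observed cross values over a common cross set.
#'
#' @param predicted,observed Named numeric vectors over the same crosses
#'   (>= 3).
#' @return Spearman correlation in \[-1, 1\].
#' @export
spearman_accuracy <- function(predicted, observed) {
  stopifnot(!is.null(names(predicted)), !is.null(names(observed)))
  if (!setequal(names(predicted), names(observed))) {
    stop("predicted and observed must cover the same crosses")
  }
  if (length(predicted) < 3L) stop("need at least 3 crosses")
  observed <- observed[names(predicted)]
  if (var(predicted) == 0 || var(observed) == 0) {
    stop("rank correlation undefined for a constant vector")
  }
  cor(predicted, observed, method = "spearman")
}

# Fit one genomic prediction model by tag on a training subset.
.fit_model <- function(tag, y, D, seed = NULL, bayes_opts = list()) {
  switch(tag,
    RRBLUP = fit_rrblup(y, D),
    EGBLUP = {
      Dtr <- D[intersect(names(y), rownames(D)), , drop = FALSE]
      Gk <- additive_kernel(Dtr)
      fit_egblup(y, Gk, epistatic_kernel(Gk), Dtr)
    },
    GBLUP = {
      Dtr <- D[intersect(names(y), rownames(D)), , drop = FALSE]
      fit_gblup(y, additive_kernel(Dtr), Dtr)
    },
    BayesRR = do.call(fit_bayes, c(list(y = y, D = D, model = "BayesRR",
                                        seed = seed), bayes_opts)),
    BayesB = do.call(fit_bayes, c(list(y = y, D = D, model = "BayesB",
                                       seed = seed), bayes_opts)),
    stop("unknown model tag: ", tag))
}

#' Run the cross-prediction validation design
#'
#' Repeated validation tests of the optimal-cross-selection methods
#' against observed cross means: in each replicate a random sample of
#' `sample_size` crosses is drawn, each requested training-set
#' composition is built (progeny of ALL candidate crosses are removed
#' under WFS, mirroring a program that never repeats a cross), each
#' genomic prediction model is fitted on the composition, the sampled
#' crosses are scored under every selection intensity from one shared
#' simulated progeny set per cross, and the Spearman correlation with the
#' observed cross means is recorded per (model, criterion, composition).
#'
#' @param geno Imputed genotype matrix over all lines (training pool and
#'   any progeny used for observed values).
#' @param map Genetic map aligned with `geno`.
#' @param blups Named vector of entry BLUPs for all phenotyped lines.
#' @param crosses Data frame of candidate crosses (`parent1`, `parent2`),
#'   each with >= 1 phenotyped progeny in `pedigree`.
#' @param pedigree Data frame with `line_id`, `cross_id`.
#' @param config List overriding defaults: `models` (default all four),
#'   `criteria` (default c(0, 0.1, 0.2)), `ts_tags` (default FTS, WFS,
#'   RTS), `n_reps` (default 50), `sample_size` (default 40), `n_progeny`
#'   (default 500), `final_generation` (5), `seed`, `bayes_opts`, and
#'   `ts_lines` (candidate training pool; default all genotyped lines
#'   with a BLUP, i.e. the paper-style full set including phenotyped
#'   progeny). `keep_predictions = TRUE` additionally returns the
#'   per-cross predicted and observed values (for permutation nulls and
#'   diagnostics).
#' @return Object of class `validation_result`: `grid` (data frame rep x
#'   ts x model x criterion with accuracies), `summary` (mean/sd over
#'   replicates per method), `observed`, `config`.
#' @export
run_validation <- function(geno, map, blups, crosses, pedigree,
                           config = list()) {
  cfg <- modifyList(list(models = c("RRBLUP", "BayesRR", "BayesB", "EGBLUP"),
                         criteria = c(0, 0.1, 0.2),
                         ts_tags = c("FTS", "WFS", "RTS"),
                         n_reps = 50, sample_size = 40, n_progeny = 500,
                         final_generation = 5, seed = 1L,
                         bayes_opts = list(), ts_lines = NULL),
                    config)
  stopifnot(nrow(crosses) >= 3L, cfg$sample_size >= 3L)
  if (cfg$sample_size > nrow(crosses)) {
    stop("sample_size exceeds the number of candidate crosses")
  }
  cids <- cross_id(crosses$parent1, crosses$parent2)
  observed <- vapply(seq_len(nrow(crosses)), function(k) {
    observed_cross_value(crosses[k, , drop = FALSE], blups, pedigree)
  }, numeric(1))
  names(observed) <- cids
  pool <- intersect(rownames(geno), names(blups))
  if (!is.null(cfg$ts_lines)) pool <- intersect(pool, cfg$ts_lines)
  D_all <- build_design(geno)

  grid <- list()
  preds <- list()
  for (rep_i in seq_len(cfg$n_reps)) {
    rep_seed <- derive_seed(cfg$seed, "validation_rep", rep_i)
    sel <- with_seed(rep_seed, sample(seq_len(nrow(crosses)), cfg$sample_size))
    sampled <- crosses[sel, , drop = FALSE]
    sampled_ids <- cids[sel]
    # one progeny set per cross per replicate, shared by all models/criteria
    progeny_geno <- lapply(seq_len(nrow(sampled)), function(k) {
      s <- derive_seed(rep_seed, "progeny", k)
      simulate_ril_progeny(geno[sampled$parent1[k], ],
                           geno[sampled$parent2[k], ], map,
                           n = cfg$n_progeny,
                           final_generation = cfg$final_generation,
                           seed = s, cross_id = sampled_ids[k])$geno
    })
    for (tag in cfg$ts_tags) {
      ts <- build_training_set(pool, crosses, pedigree, tag,
                               seed = derive_seed(rep_seed, "rts"))
      y_ts <- blups[ts$retained]
      for (model in cfg$models) {
        fit <- .fit_model(model, y_ts, D_all,
                          seed = derive_seed(rep_seed, paste0("fit_", model)),
                          bayes_opts = cfg$bayes_opts)
        gebvs <- lapply(progeny_geno, function(pg) predict_gebv(fit, pg))
        for (crit in cfg$criteria) {
          pred <- vapply(gebvs, function(g) usefulness(g, crit), numeric(1))
          names(pred) <- sampled_ids
          acc <- spearman_accuracy(pred, observed[sampled_ids])
          grid[[length(grid) + 1L]] <- data.frame(
            rep = rep_i, ts = tag, model = model, criterion = crit,
            accuracy = acc, stringsAsFactors = FALSE)
          if (isTRUE(cfg$keep_predictions)) {
            preds[[length(preds) + 1L]] <- data.frame(
              rep = rep_i, ts = tag, model = model, criterion = crit,
              cross_id = sampled_ids, predicted = unname(pred),
              observed = unname(observed[sampled_ids]),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  grid <- do.call(rbind, grid)
  summ <- aggregate(accuracy ~ ts + model + criterion, grid,
                    function(a) c(mean = mean(a), sd = sd(a)))
  summ <- data.frame(summ[c("ts", "model", "criterion")],
                     mean_accuracy = summ$accuracy[, "mean"],
                     sd_accuracy = summ$accuracy[, "sd"])
  structure(list(grid = grid, summary = summ, observed = observed,
                 predictions = if (length(preds)) do.call(rbind, preds),
                 config = cfg),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("Cross-prediction validation: %d replicate(s), %d method combination(s)\n",
              max(x$grid$rep), nrow(x$summary)))
  print(x$summary, digits = 3)
  invisible(x)
}
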
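# Synthetic breeding scenarios: founders on a multi-chromosome map,
# additive + additive-by-additive QTL architectures with a target
# heritability, and realized, phenotyped validation crosses. Every
# pipeline stage can be exercised without any external data.

#' Configuration of a synthetic breeding scenario
#'
#' Defaults emulate a mid-size soybean breeding program: 20 chromosomes
#' of 125 cM, a few thousand polymorphic chip markers, ~700 inbred
#' training lines bred from a founder pool by two rounds of crossing plus
#' single seed descent, yield-like polygenic architecture (100 additive
#' QTL plus 30 additive-by-additive pairs), entry-mean heritability near
#' 0.5, and 42 validation crosses with 16 phenotyped RIL progeny each.
#'
#' @param ... Named overrides of the defaults.
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(...) {
  args <- list(...)
  if (length(args)) args <- args[!duplicated(names(args), fromLast = TRUE)]
  cfg <- modifyList(list(
    n_chromosomes = 20,
    chromosome_length_cM = 125,
    n_markers = 3762,
    n_founders = 40,
    n_training_lines = 702,
    n_qtl_additive = 100,
    n_qtl_epistatic_pairs = 30,
    h2_target = 0.51,
    n_validation_crosses = 42,
    progeny_per_cross = 16,
    final_generation = 5,
    mask_qtl = FALSE
  ), args)
  stopifnot(cfg$n_markers >= cfg$n_qtl_additive,
            cfg$h2_target >= 0, cfg$h2_target <= 1,
            cfg$n_founders >= 2, cfg$n_chromosomes >= 1)
  if (cfg$n_markers < cfg$n_chromosomes) {
    stop("need at least one marker per chromosome")
  }
  structure(cfg, class = c("scenario_config", "list"))
}

#' Simulate inbred founders and their genetic map
#'
#' Markers are placed uniformly at random along each chromosome (marker
#' counts split as evenly as possible across chromosomes). Founders are
#' fully homozygous; the counted-allele frequency of each marker is drawn
#' from U(0.1, 0.9), which keeps most markers polymorphic after QC.
#'
#' @param cfg A [scenario_config()].
#' @param seed Integer seed.
#' @return List with `geno` (founder genotype matrix of 0/2 calls) and
#'   `map` (genetic map).
#' @export
simulate_founders <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "scenario_config"))
  with_seed(seed, {
    per_chr <- diff(round(seq(0, cfg$n_markers, length.out = cfg$n_chromosomes + 1)))
    map <- do.call(rbind, lapply(seq_len(cfg$n_chromosomes), function(ch) {
      data.frame(chromosome = sprintf("chr%02d", ch),
                 position_cM = sort(runif(per_chr[ch], 0, cfg$chromosome_length_cM)))
    }))
    map <- data.frame(marker_id = sprintf("m%05d", seq_len(nrow(map))), map,
                      stringsAsFactors = FALSE)
    validate_genetic_map(map)
    freq <- runif(cfg$n_markers, 0.1, 0.9)
    G <- matrix(2L * (runif(cfg$n_founders * cfg$n_markers) <
                        rep(freq, each = cfg$n_founders)),
                cfg$n_founders, cfg$n_markers,
                dimnames = list(sprintf("F%03d", seq_len(cfg$n_founders)),
                                map$marker_id))
    storage.mode(G) <- "integer"
    list(geno = G, map = map)
  })
}

# Advance a population (rows = individuals) by `rounds` generations of
# selfing under single seed descent.
.ssd_bulk <- function(H1, H2, layout, rounds) {
  for (s in seq_len(rounds)) {
    N1 <- .gametes_bulk(H1, H2, layout)
    N2 <- .gametes_bulk(H1, H2, layout)
    H1 <- N1
    H2 <- N2
  }
  list(H1 = H1, H2 = H2)
}

# Random crosses among the rows of a haplotype pair, followed by SSD.
.random_cross_ssd <- function(H1, H2, layout, n_out, rounds) {
  n_in <- nrow(H1)
  i1 <- sample.int(n_in, n_out, replace = TRUE)
  i2 <- (i1 + sample.int(n_in - 1L, n_out, replace = TRUE) - 1L) %% n_in + 1L
  F1a <- .gametes_bulk(H1[i1, , drop = FALSE], H2[i1, , drop = FALSE], layout)
  F1b <- .gametes_bulk(H1[i2, , drop = FALSE], H2[i2, , drop = FALSE], layout)
  .ssd_bulk(F1a, F1b, layout, rounds)
}

#' Simulate a quantitative trait on a genotype panel
#'
#' Samples `n_qtl_additive` QTL among the markers with standard-normal
#' additive effects on the centered scores (call - 1), plus
#' `n_qtl_epistatic_pairs` additive-by-additive pairs drawn among the
#' additive QTL, each contributing `effect * score_i * score_j`.
#' Residual noise is scaled so the realized variance ratio
#' var(genetic)/var(phenotype) equals `h2_target` exactly on the sample;
#' with `h2_target = 1` the phenotype equals the true genetic value.
#'
#' @param geno Genotype matrix (no missing calls).
#' @param cfg A [scenario_config()].
#' @param seed Integer seed.
#' @return List with `phenotypes` (named vector, deviation scale),
#'   `true_values` (named vector of true genetic values), `qtl` (data
#'   frame of QTL effects), `epistasis` (data frame of epistatic pairs).
#' @export
simulate_trait <- function(geno, cfg, seed = NULL) {
  stopifnot(inherits(cfg, "scenario_config"))
  validate_genotypes(geno, allow_missing = FALSE)
  if (cfg$h2_target == 0) {
    stop("h2_target = 0 leaves the trait with no genetic signal; use a positive target")
  }
  with_seed(seed, {
    S <- geno - 1
    n_qtl <- min(cfg$n_qtl_additive, ncol(geno))
    qtl_idx <- sort(sample.int(ncol(geno), n_qtl))
    a <- rnorm(n_qtl)
    g <- drop(S[, qtl_idx, drop = FALSE] %*% a)
    n_pairs <- min(cfg$n_qtl_epistatic_pairs, floor(n_qtl / 2))
    epi <- data.frame(marker1 = character(0), marker2 = character(0),
                      effect = numeric(0))
    if (n_pairs > 0) {
      pairs <- matrix(sample(qtl_idx, 2L * n_pairs), ncol = 2L)
      w <- rnorm(n_pairs)
      for (k in seq_len(n_pairs)) {
        g <- g + w[k] * S[, pairs[k, 1L]] * S[, pairs[k, 2L]]
      }
      epi <- data.frame(marker1 = colnames(geno)[pairs[, 1L]],
                        marker2 = colnames(geno)[pairs[, 2L]],
                        effect = w, stringsAsFactors = FALSE)
    }
    vg <- var(g)
    if (cfg$h2_target == 1 || vg == 0) {
      pheno <- g
    } else {
      e <- rnorm(length(g))
      e <- e - mean(e)
      e <- e * sqrt(vg * (1 - cfg$h2_target) / (cfg$h2_target * var(e)))
      pheno <- g + e
    }
    names(pheno) <- names(g) <- rownames(geno)
    list(phenotypes = pheno, true_values = g,
         qtl = data.frame(marker_id = colnames(geno)[qtl_idx], effect = a,
                          stringsAsFactors = FALSE),
         epistasis = epi)
  })
}

#' True genetic value of arbitrary genotypes under a scenario's trait
#'
#' Recomputes additive + epistatic QTL sums for any genotype matrix on
#' the scenario's marker panel, e.g. for simulated progeny. Serves as the
#' oracle for parameter-recovery tests.
#'
#' @param geno Genotype matrix (no missing calls).
#' @param trait The trait object from [simulate_trait()] (or the `trait`
#'   element of a scenario bundle).
#' @return Named vector of true genetic values.
#' @export
true_genetic_values <- function(geno, trait) {
  S <- geno - 1
  g <- drop(S[, trait$qtl$marker_id, drop = FALSE] %*% trait$qtl$effect)
  if (nrow(trait$epistasis)) {
    for (k in seq_len(nrow(trait$epistasis))) {
      g <- g + trait$epistasis$effect[k] *
        S[, trait$epistasis$marker1[k]] * S[, trait$epistasis$marker2[k]]
    }
  }
  setNames(g, rownames(geno))
}

#' Generate a complete synthetic breeding scenario
#'
#' Builds founders and a map, derives the training population by two
#' rounds of random crossing each followed by single seed descent to the
#' configured filial generation, samples validation crosses among
#' training lines, realizes each cross with phenotyped RIL progeny, and
#' simulates one trait over all lines so that observed cross means,
#' training BLUP stand-ins and true genetic values are mutually
#' consistent.
#'
#' @param cfg A [scenario_config()].
#' @param seed Master integer seed; all stages derive sub-seeds from it.
#' @return List of class `breeding_scenario`: `geno` (all lines x
#'   markers), `map`, `phenotypes`, `true_values`, `trait` (QTL tables),
#'   `crosses` (validation crosses), `pedigree` (`line_id`, `cross_id`),
#'   `training_lines`, `parents`, `cfg`, `seed`.
#' @export
make_breeding_scenario <- function(cfg = scenario_config(), seed = 1L) {
  stopifnot(inherits(cfg, "scenario_config"))
  fo <- simulate_founders(cfg, seed = derive_seed(seed, "founders"))
  layout <- .map_layout(fo$map, colnames(fo$geno))
  rounds <- cfg$final_generation - 1L
  train <- with_seed(derive_seed(seed, "training_lines"), {
    Hf <- fo$geno / 2L # founders are homozygous: haplotype = call / 2
    storage.mode(Hf) <- "integer"
    g1 <- .random_cross_ssd(Hf, Hf, layout, cfg$n_training_lines, rounds)
    .random_cross_ssd(g1$H1, g1$H2, layout, cfg$n_training_lines, rounds)
  })
  train_geno <- train$H1 + train$H2
  colnames(train_geno) <- colnames(fo$geno)
  rownames(train_geno) <- sprintf("L%04d", seq_len(cfg$n_training_lines))

  # validation crosses among training lines
  crosses <- with_seed(derive_seed(seed, "crosses"), {
    k <- cfg$n_validation_crosses
    p1 <- sample(rownames(train_geno), k)
    rest <- setdiff(rownames(train_geno), p1)
    p2 <- sample(rest, k)
    data.frame(parent1 = pmin(p1, p2), parent2 = pmax(p1, p2),
               stringsAsFactors = FALSE)
  })
  crosses$cross_id <- cross_id(crosses$parent1, crosses$parent2)

  prog_list <- lapply(seq_len(nrow(crosses)), function(k) {
    simulate_ril_progeny(train_geno[crosses$parent1[k], ],
                         train_geno[crosses$parent2[k], ], fo$map,
                         n = cfg$progeny_per_cross,
                         final_generation = cfg$final_generation,
                         seed = derive_seed(seed, "realized_progeny", k),
                         cross_id = sprintf("C%02d", k))$geno
  })
  prog_geno <- do.call(rbind, prog_list)
  pedigree <- data.frame(
    line_id = rownames(prog_geno),
    cross_id = rep(crosses$cross_id, each = cfg$progeny_per_cross),
    stringsAsFactors = FALSE)

  geno_all <- rbind(train_geno, prog_geno)
  trait <- simulate_trait(geno_all, cfg, seed = derive_seed(seed, "trait"))
  if (cfg$mask_qtl) {
    keep <- setdiff(colnames(geno_all), trait$qtl$marker_id)
    geno_panel <- geno_all[, keep, drop = FALSE]
    map_panel <- fo$map[fo$map$marker_id %in% keep, , drop = FALSE]
  } else {
    geno_panel <- geno_all
    map_panel <- fo$map
  }
  structure(list(geno = geno_panel, map = map_panel,
                 phenotypes = trait$phenotypes,
                 true_values = trait$true_values, trait = trait,
                 crosses = crosses, pedigree = pedigree,
                 training_lines = rownames(train_geno),
                 parents = unique(c(crosses$parent1, crosses$parent2)),
                 cfg = cfg, seed = seed),
            class = "breeding_scenario")
}

#' @export
print.breeding_scenario <- function(x, ...) {
  cat(sprintf(
    "Synthetic breeding scenario: %d lines (%d training, %d progeny) x %d markers,\n  %d crosses x %d progeny, h2 target %.2f, seed %s\n",
    nrow(x$geno), length(x$training_lines),
    nrow(x$pedigree), ncol(x$geno), nrow(x$crosses),
    x$cfg$progeny_per_cross, x$cfg$h2_target, format(x$seed)))
  invisible(x)
}
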
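test_that("training-set compositions implement FTS, WFS and RTS", {
  # 10 candidate lines, 4 of them direct progeny of the two predicted
  # crosses; the parents themselves are older lines outside the pool
  all_lines <- sprintf("L%02d", 1:10)
  crosses <- data.frame(parent1 = c("P1", "P2"), parent2 = c("P3", "P4"))
  pedigree <- data.frame(
    line_id = c("L01", "L02", "L03", "L04", "L05"),
    cross_id = c(cross_id("P1", "P3"), cross_id("P1", "P3"),
                 cross_id("P2", "P4"), cross_id("P2", "P4"),
                 cross_id("P2", "L09")), # L05: progeny of a non-predicted cross
    stringsAsFactors = FALSE)

  fts <- build_training_set(all_lines, crosses, pedigree, "FTS")
  expect_identical(fts$retained, all_lines)
  expect_length(fts$removed, 0)

  wfs <- build_training_set(all_lines, crosses, pedigree, "WFS")
  expect_setequal(wfs$removed, c("L01", "L02", "L03", "L04"))
  expect_length(wfs$retained, 6)

  rts <- build_training_set(all_lines, crosses, pedigree, "RTS", seed = 1)
  expect_length(rts$removed, length(wfs$removed))
  # RTS keeps every direct progeny of the predicted crosses
  expect_true(all(c("L01", "L02", "L03", "L04") %in% rts$retained))
  rts2 <- build_training_set(all_lines, crosses, pedigree, "RTS", seed = 2)
  expect_length(rts2$removed, length(rts$removed))

  # parents in the pool are never removed by RTS
  pool_p <- c(all_lines, "P1", "P2", "P3", "P4")
  rts3 <- build_training_set(pool_p, crosses, pedigree, "RTS", seed = 3)
  expect_true(all(c("P1", "P2", "P3", "P4") %in% rts3$retained))

  # infeasible RTS: not enough unrelated lines to match the WFS removal count
  few <- c("L01", "L02", "L03", "L04", "L06", "L07")
  expect_error(build_training_set(few, crosses, pedigree, "RTS", seed = 1),
               "infeasible")
})

test_that("observed cross values average the progeny entry BLUPs", {
  ped <- data.frame(line_id = c("a", "b", "c"),
                    cross_id = rep(cross_id("P1", "P2"), 3),
                    stringsAsFactors = FALSE)
  blups <- c(a = 1, b = 3, c = 100)
  expect_equal(observed_cross_value(c("P1", "P2"), blups[c("a", "b")], ped), 2)
  expect_equal(observed_cross_value(c("P2", "P1"), blups[c("a", "b")], ped), 2)
  expect_equal(observed_cross_value(c("P1", "P2"), blups["a"], ped), 1)
  expect_error(observed_cross_value(c("P1", "P9"), blups, ped), "no phenotyped")
})

test_that("Spearman accuracy uses average ranks and flags degenerate input", {
  p <- setNames(c(1, 2, 3, 4), letters[1:4])
  expect_equal(spearman_accuracy(p, p), 1)
  expect_equal(spearman_accuracy(p, setNames(rev(p), letters[1:4])), -1)
  o <- setNames(c(1, 3, 2, 4), letters[1:4])
  expect_equal(spearman_accuracy(p, o), 0.8) # 1 - 6*2/(4*15)
  expect_error(spearman_accuracy(p, setNames(rep(1, 4), letters[1:4])),
               "constant")
  expect_error(spearman_accuracy(p[1:2], o[1:2]), "at least 3")
  expect_error(spearman_accuracy(p, o[c(1, 2, 3, 3)]), "same crosses")
})

test_that("a noiseless scenario is recovered almost perfectly under FTS", {
  cfg <- scenario_config(n_chromosomes = 3, chromosome_length_cM = 100,
                         n_markers = 120, n_founders = 12,
                         n_training_lines = 100, n_qtl_additive = 15,
                         n_qtl_epistatic_pairs = 0, h2_target = 1,
                         n_validation_crosses = 10, progeny_per_cross = 30)
  sc <- make_breeding_scenario(cfg, seed = 404)
  vcfg <- list(models = "RRBLUP", criteria = 0, ts_tags = "FTS", n_reps = 1,
               sample_size = 10, n_progeny = 300, seed = 7)
  res <- run_validation(sc$geno, sc$map, sc$phenotypes, sc$crosses,
                        sc$pedigree, config = vcfg)
  expect_gt(res$summary$mean_accuracy, 0.9)
  # accuracy grid has exactly n_reps x models x criteria x ts entries
  expect_equal(nrow(res$grid), 1)

  res2 <- run_validation(sc$geno, sc$map, sc$phenotypes, sc$crosses,
                         sc$pedigree, config = vcfg)
  expect_identical(res$grid, res2$grid)
})

test_that("validation configuration errors are raised before compute", {
  cfg <- scenario_config(n_chromosomes = 2, chromosome_length_cM = 80,
                         n_markers = 30, n_founders = 8,
                         n_training_lines = 20, n_qtl_additive = 5,
                         n_qtl_epistatic_pairs = 0, h2_target = 0.8,
                         n_validation_crosses = 4, progeny_per_cross = 4)
  sc <- make_breeding_scenario(cfg, seed = 2)
  expect_error(
    run_validation(sc$geno, sc$map, sc$phenotypes, sc$crosses, sc$pedigree,
                   config = list(sample_size = 99, n_reps = 1)),
    "sample_size")
})

test_that("validation grid covers the full method grid", {
  cfg <- scenario_config(n_chromosomes = 2, chromosome_length_cM = 90,
                         n_markers = 40, n_founders = 10,
                         n_training_lines = 40, n_qtl_additive = 10,
                         n_qtl_epistatic_pairs = 2, h2_target = 0.7,
                         n_validation_crosses = 5, progeny_per_cross = 6)
  sc <- make_breeding_scenario(cfg, seed = 31)
  res <- run_validation(sc$geno, sc$map, sc$phenotypes, sc$crosses,
                        sc$pedigree,
                        config = list(models = c("RRBLUP", "BayesRR"),
                                      criteria = c(0, 0.1), ts_tags = c("FTS", "WFS"),
                                      n_reps = 2, sample_size = 5,
                                      n_progeny = 40, seed = 3,
                                      bayes_opts = list(iterations = 300,
                                                        burn_in = 100)))
  expect_equal(nrow(res$grid), 2 * 2 * 2 * 2)
  expect_true(all(abs(res$grid$accuracy) <= 1))
  expect_equal(nrow(res$summary), 8)
})
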
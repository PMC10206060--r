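test_that("marker design is the centered-call bijection", {
  G <- rand_geno(4, 3, seed = 1)
  G[1, 1] <- 0L; G[2, 1] <- 1L; G[3, 1] <- 2L
  D <- build_design(G)
  expect_equal(unname(D[1:3, 1]), c(-1, 0, 1))
  expect_identical(matrix(as.integer(D + 1), 4, 3, dimnames = dimnames(G)), G)
  expect_true(all(build_design(matrix(2L, 2, 2,
    dimnames = list(c("a", "b"), c("x", "y")))) == 1))
  G[1, 1] <- NA
  expect_error(build_design(G), "missing")
})

test_that("additive and epistatic kernels match direct matrix arithmetic", {
  G <- rand_geno(4, 3, seed = 6)
  D <- build_design(G)
  Gk <- additive_kernel(D)
  Z <- sweep(D, 2, colMeans(D))
  ZZt <- tcrossprod(Z)
  expect_equal(unclass(Gk)[1:4, 1:4], ZZt / mean(diag(ZZt)),
               ignore_attr = TRUE)
  expect_equal(mean(diag(Gk)), 1)

  # identical lines have off-diagonal equal to their diagonals
  G2 <- rbind(G, G[1, , drop = FALSE])
  rownames(G2)[5] <- "dup"
  Gk2 <- additive_kernel(build_design(G2))
  expect_equal(Gk2["dup", rownames(G)[1]], Gk2["dup", "dup"])

  Hk <- epistatic_kernel(Gk)
  s <- mean(diag(Gk * Gk))
  expect_equal(unclass(Hk)[2, 3], Gk[2, 3]^2 / s)
  expect_equal(mean(diag(Hk)), 1)
  # Schur product theorem: H of a PSD G stays PSD
  ev <- eigen((Hk + t(Hk)) / 2, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)

  same <- matrix(1L, 3, 2, dimnames = list(letters[1:3], c("x", "y")))
  expect_warning(k1 <- additive_kernel(build_design(same)), "zero-variance")
  expect_true(all(k1 == 1))
})

test_that("RR-BLUP equals GBLUP at the matched variance ratio", {
  G <- rand_geno(50, 200, seed = 99)
  y <- withr::with_seed(99, setNames(rnorm(50), rownames(G)))
  D <- build_design(G)
  fit <- fit_rrblup(y, D)
  gebv <- predict_gebv(fit, G)
  Z <- sweep(D, 2, colMeans(D))
  lambda <- 1 / fit$varcomp$gamma
  K <- tcrossprod(Z)
  gebv_gblup <- fit$mu + drop(K %*% solve(K + diag(lambda, 50), y - fit$mu))
  expect_lt(max(abs(gebv - gebv_gblup)), 1e-6)
  # marker-permutation invariance
  perm <- withr::with_seed(1, sample(ncol(G)))
  fit_p <- fit_rrblup(y, D[, perm])
  expect_equal(predict_gebv(fit_p, G[, perm]), gebv, tolerance = 1e-8)
})

test_that("RR-BLUP degenerate inputs fall back to the intercept", {
  G <- rand_geno(10, 0, seed = 1)
  y <- setNames(rnorm(10), rownames(G))
  fit <- fit_rrblup(y, build_design(G))
  expect_equal(unname(predict_gebv(fit, G)), rep(mean(y), 10))

  G2 <- rand_geno(8, 12, seed = 2)
  y2 <- setNames(rep(3, 8), rownames(G2))
  expect_warning(fit2 <- fit_rrblup(y2, build_design(G2)), "constant")
  expect_true(all(fit2$effects == 0))
  expect_error(fit_rrblup(y[1], build_design(G[1, , drop = FALSE]))
               , "at least 2")
})

test_that("Bayesian samplers are seed-deterministic and shrink null signals", {
  G <- rand_geno(25, 40, seed = 3)
  D <- build_design(G)
  y <- withr::with_seed(3, setNames(rnorm(25) + D[, 5] * 0.8, rownames(G)))
  for (m in c("BayesRR", "BayesB")) {
    f1 <- fit_bayes(y, D, model = m, iterations = 600, burn_in = 200, seed = 9)
    f2 <- fit_bayes(y, D, model = m, iterations = 600, burn_in = 200, seed = 9)
    expect_identical(f1$effects, f2$effects)
    expect_identical(f1$mu, f2$mu)
  }
  # constant response: posterior-mean effects within noise of zero
  yc <- setNames(rep(2, 25), rownames(G))
  fc <- fit_bayes(yc, D, model = "BayesRR", iterations = 600, burn_in = 200,
                  seed = 4)
  expect_true(all(abs(fc$effects) < pmax(3 * fc$effect_sd, 1e-6)))
  expect_error(fit_bayes(y, D, iterations = 100, burn_in = 100), "exceed")
})

test_that("BayesRR with fixed variances matches the closed-form ridge posterior mean", {
  G <- rand_geno(30, 50, seed = 21)
  D <- build_design(G)
  y <- withr::with_seed(21, setNames(rnorm(30) + rowSums(D[, 1:4]) * 0.3,
                                     rownames(G)))
  vb <- 0.05; ve <- 0.5
  fit <- fit_bayes(y, D, model = "BayesRR", iterations = 6000, burn_in = 1000,
                   seed = 42, fix_sigma2_b = vb, fix_sigma2_e = ve)
  oracle <- ridge_effects(y, D, lambda = ve / vb)
  expect_lt(max(abs(fit$effects - oracle)), 0.02 * sd(y))
})

test_that("EGBLUP reduces to GBLUP without epistatic variance and predicts via the joint model", {
  G <- rand_geno(30, 60, seed = 31)
  D <- build_design(G)
  y <- withr::with_seed(31, setNames(rnorm(30) + rowSums(D[, 1:6]) * 0.4,
                                     rownames(G)))
  Gk <- additive_kernel(D)
  Hk <- epistatic_kernel(Gk)
  red <- fit_egblup(y, Gk, Hk, D, constrain_epistasis = TRUE)
  # closed-form single-kernel BLUP at the fitted variance ratio
  gam <- red$varcomp$sigma2_a / red$varcomp$sigma2_e
  V <- diag(30) + gam * unclass(Gk)
  oracle <- red$mu + gam * drop(unclass(Gk) %*% solve(V, y - red$mu))
  expect_lt(max(abs(predict_gebv(red, G) - oracle)), 1e-6)
  expect_identical(red$varcomp$sigma2_aa, 0)

  # constant y gives zero genetic solutions
  yc <- setNames(rep(1, 30), rownames(G))
  fc <- fit_egblup(yc, Gk, Hk, D)
  expect_true(all(abs(unlist(fc$kernel_fit$ghat)) < 1e-10))

  # projection formula equals the joint mixed-model solve on train + new lines
  G40 <- rand_geno(40, 60, seed = 32)
  tr <- rownames(G40)[1:30]; nw <- rownames(G40)[31:40]
  Dtr <- build_design(G40[tr, ])
  ytr <- withr::with_seed(32, setNames(rnorm(30) + rowSums(Dtr[, 1:6]) * 0.4, tr))
  Gk2 <- additive_kernel(Dtr)
  Hk2 <- epistatic_kernel(Gk2)
  fit <- fit_egblup(ytr, Gk2, Hk2, Dtr)
  pred <- predict_gebv(fit, G40[nw, ])
  Zall <- sweep(build_design(G40), 2, attr(Gk2, "center"))
  Gall <- tcrossprod(Zall) / attr(Gk2, "scale_c")
  Hall <- (Gall * Gall) / attr(Hk2, "scale_h")
  vc <- fit$varcomp
  V <- vc$sigma2_a * Gall[tr, tr] + vc$sigma2_aa * Hall[tr, tr] +
    diag(vc$sigma2_e, 30)
  Vir <- solve(V, ytr - fit$mu)
  joint <- fit$mu + drop(vc$sigma2_a * Gall[nw, tr] %*% Vir +
                           vc$sigma2_aa * Hall[nw, tr] %*% Vir)
  expect_lt(max(abs(pred - joint)), 1e-4)
})

test_that("EGBLUP attributes little variance to epistasis under a purely additive architecture", {
  ratios <- vapply(1:8, function(rep) {
    G <- rand_geno(40, 80, seed = 100 + rep)
    D <- build_design(G)
    y <- withr::with_seed(200 + rep, {
      setNames(drop(D %*% rnorm(80, 0, 0.3)) + rnorm(40, 0, 0.5), rownames(G))
    })
    Gk <- additive_kernel(D)
    fit <- fit_egblup(y, Gk, epistatic_kernel(Gk), D)
    fit$varcomp$sigma2_aa / (fit$varcomp$sigma2_a + fit$varcomp$sigma2_aa)
  }, numeric(1))
  expect_lt(median(ratios), 0.2)
})

test_that("predictions are self-consistent and shift-equivariant across all models", {
  G <- rand_geno(25, 30, seed = 55)
  D <- build_design(G)
  y <- withr::with_seed(55, setNames(rnorm(25) + rowSums(D[, 1:3]) * 0.5,
                                     rownames(G)))
  Gk <- additive_kernel(D)
  Hk <- epistatic_kernel(Gk)
  fits <- list(
    fit_rrblup(y, D),
    fit_bayes(y, D, model = "BayesRR", iterations = 400, burn_in = 100, seed = 1),
    fit_bayes(y, D, model = "BayesB", iterations = 400, burn_in = 100, seed = 1),
    fit_egblup(y, Gk, Hk, D))
  shifted <- list(
    fit_rrblup(y + 10, D),
    fit_bayes(y + 10, D, model = "BayesRR", iterations = 400, burn_in = 100, seed = 1),
    fit_bayes(y + 10, D, model = "BayesB", iterations = 400, burn_in = 100, seed = 1),
    fit_egblup(y + 10, Gk, Hk, D))
  dup <- G[c(1, 1), , drop = FALSE]
  rownames(dup) <- c("orig", "copy")
  for (k in seq_along(fits)) {
    gebv <- predict_gebv(fits[[k]], G)
    # a new line identical to a training line scores identically
    pd <- predict_gebv(fits[[k]], dup)
    expect_equal(unname(pd["copy"]), unname(pd["orig"]), tolerance = 1e-6)
    expect_equal(unname(pd["orig"]), unname(gebv[1]), tolerance = 1e-6)
    # adding a constant to y shifts GEBVs by that constant
    tol <- if (fits[[k]]$model_tag %in% c("RRBLUP", "EGBLUP")) 1e-6 else 0.15
    expect_equal(predict_gebv(shifted[[k]], G), gebv + 10, tolerance = tol)
  }
  bad <- G
  colnames(bad)[1] <- "other"
  expect_error(predict_gebv(fits[[1]], bad), "mismatch")
})

test_that("prediction accuracy grows with training size on additive data", {
  p <- 100
  mean_acc <- vapply(c(50, 200, 500), function(n) {
    accs <- vapply(1:10, function(rep) {
      set.seed(1000 + 17 * rep + n)
      G <- matrix(sample(0:2, (n + 50) * p, replace = TRUE), n + 50, p,
                  dimnames = list(sprintf("L%04d", seq_len(n + 50)),
                                  sprintf("m%03d", seq_len(p))))
      D <- build_design(G)
      beta <- rnorm(p, 0, 0.2)
      g <- drop(D %*% beta)
      y <- g + rnorm(n + 50, 0, sd(g)) # h2 = 0.5
      tr <- rownames(G)[seq_len(n)]
      te <- rownames(G)[(n + 1):(n + 50)]
      fit <- fit_rrblup(setNames(y[seq_len(n)], tr), D[tr, ])
      cor(predict_gebv(fit, G[te, ]), g[(n + 1):(n + 50)])
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  expect_true(all(diff(mean_acc) > 0))
})

test_that("gp_fit objects survive JSON round-trips", {
  G <- rand_geno(15, 12, seed = 77)
  D <- build_design(G)
  y <- withr::with_seed(77, setNames(rnorm(15), rownames(G)))
  path <- withr::local_tempfile(fileext = ".json")
  fit <- fit_rrblup(y, D)
  write_gp_fit(fit, path)
  expect_equal(predict_gebv(read_gp_fit(path), G), predict_gebv(fit, G),
               tolerance = 1e-12)
  Gk <- additive_kernel(D)
  fit2 <- fit_egblup(y, Gk, epistatic_kernel(Gk), D)
  write_gp_fit(fit2, path)
  expect_equal(predict_gebv(read_gp_fit(path), G), predict_gebv(fit2, G),
               tolerance = 1e-12)
})
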
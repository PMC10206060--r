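# Shared fixtures and independent oracles for the test suite.

# Small random genotype matrix (0/1/2 calls).
rand_geno <- function(n, p, seed = 1, prefix = "L") {
  withr_seed <- seed
  set.seed(withr_seed)
  matrix(sample(0:2, n * p, replace = TRUE), n, p,
         dimnames = list(sprintf("%s%03d", prefix, seq_len(n)),
                         sprintf("m%04d", seq_len(p))))
}

# Single-chromosome map with equally spaced markers.
simple_map <- function(marker_ids, spacing_cM = 10, chromosome = "chr1") {
  data.frame(marker_id = marker_ids, chromosome = chromosome,
             position_cM = (seq_along(marker_ids) - 1) * spacing_cM,
             stringsAsFactors = FALSE)
}

named_calls <- function(calls, ids = sprintf("m%d", seq_along(calls))) {
  setNames(as.integer(calls), ids)
}

haldane <- function(d_morgan) (1 - exp(-2 * d_morgan)) / 2

# Two-locus inbreeding oracle: 16 ordered haplotype-pair states, F1 = AB/ab,
# iterated over selfing generations; returns the 16-vector of state
# probabilities. Haplotypes indexed 1=AB, 2=Ab, 3=aB, 4=ab.
two_locus_oracle <- function(r, final_generation = 5) {
  haps <- list(c(1, 1), c(1, 0), c(0, 1), c(0, 0))
  hap_index <- function(g) which(vapply(haps, function(h) all(h == g), TRUE))
  gamete_dist <- function(a, b) {
    p <- numeric(4)
    p[hap_index(haps[[a]])] <- p[hap_index(haps[[a]])] + (1 - r) / 2
    p[hap_index(haps[[b]])] <- p[hap_index(haps[[b]])] + (1 - r) / 2
    r1 <- c(haps[[a]][1], haps[[b]][2])
    r2 <- c(haps[[b]][1], haps[[a]][2])
    p[hap_index(r1)] <- p[hap_index(r1)] + r / 2
    p[hap_index(r2)] <- p[hap_index(r2)] + r / 2
    p
  }
  st <- function(a, b) (a - 1) * 4 + b
  Tm <- matrix(0, 16, 16)
  for (a in 1:4) for (b in 1:4) {
    g <- gamete_dist(a, b)
    for (c1 in 1:4) for (c2 in 1:4) Tm[st(a, b), st(c1, c2)] <- g[c1] * g[c2]
  }
  v <- numeric(16)
  v[st(1, 4)] <- 1
  for (i in seq_len(final_generation - 1)) v <- drop(v %*% Tm)
  v
}
two_locus_state <- function(a, b) (a - 1) * 4 + b

# Balanced-ANOVA expected-mean-squares estimates of the variance
# components (method of moments) plus chi-square-based standard errors.
ems_varcomp <- function(records) {
  records$line <- factor(records$line_id)
  records$env <- factor(paste(records$year, records$location, sep = "_"))
  records$rf <- factor(records$rep)
  E <- nlevels(records$env)
  R <- nlevels(records$rf)
  a <- anova(stats::aov(yield ~ maturity_days + env + env:rf + line + env:line,
                        data = records))
  msG <- a["line", "Mean Sq"]
  msGE <- a["env:line", "Mean Sq"]
  msE <- a["Residuals", "Mean Sq"]
  dfG <- a["line", "Df"]; dfGE <- a["env:line", "Df"]; dfE <- a["Residuals", "Df"]
  list(est = c(G = (msG - msGE) / (E * R), GxE = (msGE - msE) / R, R = msE),
       se = c(G = sqrt(2 * msG^2 / dfG + 2 * msGE^2 / dfGE) / (E * R),
              GxE = sqrt(2 * msGE^2 / dfGE + 2 * msE^2 / dfE) / R,
              R = sqrt(2 * msE^2 / dfE)))
}

# Simulate a balanced multi-environment trial with known components.
balanced_trial <- function(n_lines, n_env, n_rep, s2G, s2GE, s2R, seed = 1) {
  set.seed(seed)
  lines <- sprintf("G%03d", seq_len(n_lines))
  envs <- sprintf("loc%d", seq_len(n_env))
  g <- rnorm(n_lines, 0, sqrt(s2G))
  ge <- matrix(rnorm(n_lines * n_env, 0, sqrt(s2GE)), n_lines, n_env)
  rec <- expand.grid(line_id = lines, year = 2020, location = envs,
                     rep = seq_len(n_rep), stringsAsFactors = FALSE)
  il <- match(rec$line_id, lines)
  ie <- match(rec$location, envs)
  rec$maturity_days <- rnorm(nrow(rec), 100, 2)
  rec$yield <- 50 + g[il] + ge[cbind(il, ie)] + rnorm(nrow(rec), 0, sqrt(s2R))
  rec
}

# Closed-form ridge solution on centered scores.
ridge_effects <- function(y, D, lambda) {
  Z <- sweep(D, 2, colMeans(D))
  drop(solve(crossprod(Z) + diag(lambda, ncol(Z)), crossprod(Z, y - mean(y))))
}
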
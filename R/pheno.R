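#' Fit the multi-environment phenotypic mixed model
#'
#' Fits `yield = mu + E + M + E(r) + G + E(G) + e` to long-format yield
#' records, where E (environment = year x location) and maturity M (days
#' from planting, a single linear covariate) and replicate-within-
#' environment E(r) are fixed, and the genotype G and its interaction with
#' environment E(G) are random. REML fitting is delegated to lme4, the
#' standard tool for this model class. Records with missing maturity are
#' dropped (count reported); one round of outlier removal drops records
#' with |standardized residual| above `max_std_resid` and refits.
#'
#' With a single environment the interaction is confounded with the
#' residual: it is dropped from the model, reported as 0 and flagged.
#'
#' @param records Data frame with columns `line_id`, `year`, `location`,
#'   `rep`, `maturity_days`, `yield` (see [load_phenotypes()]).
#' @param max_std_resid Outlier cutoff on standardized residuals.
#' @return List of class `pheno_fit` with elements `blups` (named vector
#'   of genotype BLUPs on the deviation scale), `varcomp` (list with
#'   `sigma2_G`, `sigma2_GxE`, `sigma2_R`, `gxe_confounded`), `n_env`,
#'   `n_rep`, `n_dropped_maturity`, `n_dropped_outlier`, and the lme4
#'   `fit` object.
#' @export
fit_pheno_model <- function(records, max_std_resid = 4) {
  need <- c("line_id", "year", "location", "rep", "maturity_days", "yield")
  stopifnot(is.data.frame(records), all(need %in% names(records)))
  n_drop_mat <- sum(is.na(records$maturity_days))
  if (n_drop_mat > 0L) {
    message(n_drop_mat, " record(s) without maturity dropped")
    records <- records[!is.na(records$maturity_days), , drop = FALSE]
  }
  if (anyNA(records$yield) || any(!is.finite(records$yield))) {
    stop("yield must be finite for all retained records")
  }
  records$line <- factor(records$line_id)
  records$env <- factor(paste(records$year, records$location, sep = "_"))
  records$rep_f <- factor(records$rep)
  if (nlevels(records$line) < 2L) stop("need at least 2 distinct lines")

  single_env <- nlevels(records$env) < 2L
  form <- if (single_env) {
    yield ~ maturity_days + rep_f + (1 | line)
  } else {
    yield ~ maturity_days + env + env:rep_f + (1 | line) + (1 | line:env)
  }
  ctrl <- lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.nRE = "ignore",
                            calc.derivs = FALSE)
  fit <- suppressMessages(lme4::lmer(form, data = records, REML = TRUE,
                                     control = ctrl))
  n_out <- 0L
  out <- abs(residuals(fit, scaled = TRUE)) > max_std_resid
  if (any(out)) {
    n_out <- sum(out)
    message(n_out, " outlier record(s) removed (|std resid| > ",
            max_std_resid, ")")
    records <- records[!out, , drop = FALSE]
    fit <- suppressMessages(lme4::lmer(form, data = records, REML = TRUE,
                                       control = ctrl))
  }

  vc <- as.data.frame(lme4::VarCorr(fit))
  pick <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v)) v[1L] else 0
  }
  varcomp <- list(sigma2_G = pick("line"),
                  sigma2_GxE = if (single_env) 0 else pick("line:env"),
                  sigma2_R = pick("Residual"),
                  gxe_confounded = single_env)

  re <- lme4::ranef(fit)$line
  blups <- setNames(re[["(Intercept)"]], rownames(re))

  structure(list(blups = blups, varcomp = varcomp,
                 n_env = nlevels(records$env), n_rep = nlevels(records$rep_f),
                 n_dropped_maturity = n_drop_mat, n_dropped_outlier = n_out,
                 fit = fit),
            class = "pheno_fit")
}

#' @export
print.pheno_fit <- function(x, ...) {
  cat(sprintf(
    "Phenotypic mixed model: %d lines, %d environments\n  sigma2_G = %.4g, sigma2_GxE = %.4g%s, sigma2_R = %.4g\n",
    length(x$blups), x$n_env, x$varcomp$sigma2_G, x$varcomp$sigma2_GxE,
    if (x$varcomp$gxe_confounded) " (confounded: single environment)" else "",
    x$varcomp$sigma2_R))
  invisible(x)
}

#' Broad-sense heritability on an entry-mean basis
#'
#' `H2 = sigma2_G / (sigma2_G + sigma2_GxE / e + sigma2_R / (e * r))` for
#' a trial with `e` environments and `r` replicates per environment.
#'
#' @param vc List with `sigma2_G`, `sigma2_GxE`, `sigma2_R` (all >= 0),
#'   e.g. the `varcomp` element of a [fit_pheno_model()] result.
#' @param e Number of environments (>= 1).
#' @param r Number of replicates per environment (>= 1).
#' @return Heritability in \[0, 1\].
#' @export
entry_mean_heritability <- function(vc, e, r) {
  stopifnot(e >= 1, r >= 1)
  comps <- c(vc$sigma2_G, vc$sigma2_GxE, vc$sigma2_R)
  if (any(!is.finite(comps)) || any(comps < 0)) {
    stop("variance components must be finite and non-negative")
  }
  denom <- vc$sigma2_G + vc$sigma2_GxE / e + vc$sigma2_R / (e * r)
  if (denom == 0) stop("heritability undefined: all variance components are zero")
  vc$sigma2_G / denom
}
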
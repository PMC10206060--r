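# Kernel-based REML machinery shared by RR-BLUP, GBLUP and EGBLUP.
#
# Model: y = 1*mu + sum_k g_k + e, g_k ~ N(0, sigma2_k K_k),
# e ~ N(0, sigma2_e I). Parametrized by variance ratios
# gamma_k = sigma2_k / sigma2_e; for fixed gammas the residual variance
# and the REML log-likelihood have closed forms, so fitting reduces to a
# 1- or 2-dimensional maximization over log(gamma).

# Profiled REML log-likelihood and GLS pieces at fixed gammas.
.reml_eval <- function(loggam, y, Ks) {
  n <- length(y)
  gam <- exp(loggam)
  V <- diag(n)
  for (k in seq_along(Ks)) V <- V + gam[k] * Ks[[k]]
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(list(ll = -Inf))
  Vi_y <- backsolve(R, forwardsolve(t(R), y))
  Vi_1 <- backsolve(R, forwardsolve(t(R), rep(1, n)))
  xvx <- sum(Vi_1)
  mu <- sum(Vi_y) / xvx
  r <- y - mu
  Vi_r <- Vi_y - mu * Vi_1
  s2e <- sum(r * Vi_r) / (n - 1)
  ll <- -0.5 * ((n - 1) * log(s2e) + 2 * sum(log(diag(R))) + log(xvx) +
                  (n - 1))
  list(ll = ll, mu = mu, s2e = s2e, Vi_r = Vi_r, gam = gam)
}

# Maximize REML over log(gamma); returns fitted pieces and BLUPs
# g_hat_k = gamma_k * K_k %*% Vi_r (on the V/sigma2_e scale).
.reml_kernels <- function(y, Ks, init_loggam = NULL, maxit = 400,
                          reltol = 1e-10) {
  stopifnot(length(y) >= 2L, length(Ks) >= 1L)
  if (var(y) == 0) {
    n <- length(y)
    return(list(mu = y[1L], s2e = 0, gammas = rep(0, length(Ks)),
                sigma2 = rep(0, length(Ks)),
                ghat = lapply(Ks, function(K) rep(0, n)),
                Vi_r = rep(0, n), constant_y = TRUE, convergence = 0L))
  }
  if (is.null(init_loggam)) init_loggam <- rep(0, length(Ks))
  if (length(Ks) == 1L) {
    opt <- optimize(function(lg) .reml_eval(lg, y, Ks)$ll,
                    interval = c(-12, 12), maximum = TRUE,
                    tol = .Machine$double.eps^0.5)
    sol <- .reml_eval(opt$maximum, y, Ks)
    conv <- 0L
  } else {
    obj <- function(lg) -.reml_eval(lg, y, Ks)$ll
    # box constraints keep V well-conditioned; the bounds correspond to
    # variance ratios between e^-15 and e^15, far beyond any data signal
    opt <- optim(pmin(pmax(init_loggam, -14), 14), obj, method = "L-BFGS-B",
                 lower = -15, upper = 15, control = list(maxit = maxit))
    if (opt$convergence != 0L && opt$convergence != 52L) {
      stop("REML did not converge (code ", opt$convergence,
           "); last log-ratios: ", paste(round(opt$par, 4), collapse = ", "))
    }
    sol <- .reml_eval(opt$par, y, Ks)
    conv <- opt$convergence
  }
  ghat <- lapply(seq_along(Ks), function(k) {
    drop(sol$gam[k] * (Ks[[k]] %*% sol$Vi_r))
  })
  list(mu = sol$mu, s2e = sol$s2e, gammas = sol$gam,
       sigma2 = sol$gam * sol$s2e, ghat = ghat, Vi_r = sol$Vi_r,
       constant_y = FALSE, convergence = conv)
}

#' Fit ridge-regression BLUP (RR-BLUP)
#'
#' Solves `y = 1 mu + Z u + e` with i.i.d. marker effects u sharing one
#' variance, by REML on the variance ratio through the equivalent kernel
#' model with `K = Z Z'` (the RR-BLUP/GBLUP equivalence). Marker effects
#' are recovered as `u = Z' (Z Z' + lambda I)^-1 (y - mu)`.
#'
#' @param y Named vector of training values (entry BLUPs), names = lines.
#' @param D Marker design from [build_design()] covering the training
#'   lines (rows matched by name).
#' @return Object of class `gp_fit` with the intercept, marker effects,
#'   variance components and the training centering means.
#' @export
fit_rrblup <- function(y, D) {
  fit <- .prep_training(y, D)
  y <- fit$y; D <- fit$D
  n <- length(y)
  if (n < 2L) stop("need at least 2 training lines")
  ctr <- colMeans(D)
  if (ncol(D) == 0L) {
    return(.gp_fit("RRBLUP", mu = mean(y), effects = numeric(0), center = ctr,
                   marker_ids = character(0),
                   varcomp = list(sigma2_u = 0, sigma2_e = var(y))))
  }
  Z <- sweep(D, 2L, ctr)
  if (var(y) == 0) {
    warning("constant training response: all marker effects are zero")
    return(.gp_fit("RRBLUP", mu = y[1L], effects = setNames(rep(0, ncol(D)),
                                                            colnames(D)),
                   center = ctr, marker_ids = colnames(D),
                   varcomp = list(sigma2_u = 0, sigma2_e = 0)))
  }
  K <- tcrossprod(Z)
  sol <- .reml_kernels(y, list(K))
  # u = sigma2_u Z' V^-1 r with V on the sigma2_e scale: u = gamma Z' Vi_r
  u <- drop(sol$gammas[1L] * crossprod(Z, sol$Vi_r))
  .gp_fit("RRBLUP", mu = sol$mu, effects = setNames(u, colnames(D)),
          center = ctr, marker_ids = colnames(D),
          varcomp = list(sigma2_u = sol$sigma2[1L], sigma2_e = sol$s2e,
                         gamma = sol$gammas[1L]))
}

#' Fit single-kernel genomic BLUP
#'
#' REML fit of `y = 1 mu + g + e`, `g ~ N(0, sigma2_g K)`, for an
#' arbitrary relationship kernel. Used directly and as the additive-only
#' special case of [fit_egblup()].
#'
#' @param y Named training values.
#' @param Gk Kernel over the training lines (e.g. [additive_kernel()]).
#' @param D Marker design of the training lines (stored for prediction).
#' @return Object of class `gp_fit` (kernel form).
#' @export
fit_gblup <- function(y, Gk, D) {
  fit <- .prep_training(y, D)
  y <- fit$y; D <- fit$D
  Gk <- Gk[names(y), names(y)]
  sol <- .reml_kernels(y, list(Gk))
  .gp_fit("GBLUP", mu = sol$mu, center = attr(Gk, "center"),
          marker_ids = colnames(D),
          varcomp = list(sigma2_a = sol$sigma2[1L], sigma2_e = sol$s2e),
          kernel_fit = list(Z_train = sweep(D, 2L, attr(Gk, "center")),
                            scale_c = attr(Gk, "scale_c"), scale_h = NULL,
                            ghat = list(additive = sol$ghat[[1L]]),
                            K_train = list(additive = Gk)))
}

#' Fit extended (epistatic) genomic BLUP
#'
#' REML fit of `y = 1 mu + g1 + g2 + e` with `g1 ~ N(0, sigma2_a G)` on
#' the additive kernel and `g2 ~ N(0, sigma2_aa H)` on its Hadamard
#' square, capturing additive-by-additive epistasis. The 2-parameter REML
#' surface is maximized directly (profiled residual variance,
#' Nelder-Mead on log variance ratios).
#'
#' @param y Named training values.
#' @param Gk Additive kernel over the training lines.
#' @param Hk Epistatic kernel from [epistatic_kernel()].
#' @param D Marker design of the training lines (stored for prediction).
#' @param constrain_epistasis If `TRUE`, fixes `sigma2_aa = 0`, reducing
#'   the model to single-kernel GBLUP (used for reduction checks).
#' @return Object of class `gp_fit` (kernel form) carrying both kernels'
#'   training solutions.
#' @export
fit_egblup <- function(y, Gk, Hk, D, constrain_epistasis = FALSE) {
  fit <- .prep_training(y, D)
  y <- fit$y; D <- fit$D
  Gk2 <- Gk[names(y), names(y)]
  Hk2 <- Hk[names(y), names(y)]
  .check_psd(Gk2)
  .check_psd(Hk2)
  if (constrain_epistasis) {
    sol <- .reml_kernels(y, list(Gk2))
    ghat <- list(additive = sol$ghat[[1L]], epistatic = rep(0, length(y)))
    sigma2 <- c(sol$sigma2[1L], 0)
  } else {
    sol <- .reml_kernels(y, list(Gk2, Hk2))
    ghat <- list(additive = sol$ghat[[1L]], epistatic = sol$ghat[[2L]])
    sigma2 <- sol$sigma2
  }
  .gp_fit("EGBLUP", mu = sol$mu, center = attr(Gk, "center"),
          marker_ids = colnames(D),
          varcomp = list(sigma2_a = sigma2[1L], sigma2_aa = sigma2[2L],
                         sigma2_e = sol$s2e),
          kernel_fit = list(Z_train = sweep(D, 2L, attr(Gk, "center")),
                            scale_c = attr(Gk, "scale_c"),
                            scale_h = attr(Hk, "scale_h"),
                            ghat = ghat,
                            K_train = list(additive = Gk2, epistatic = Hk2)))
}

# Align y and D by line names and drop lines lacking either piece.
.prep_training <- function(y, D) {
  stopifnot(is.numeric(y), !is.null(names(y)), is.matrix(D))
  keep <- intersect(names(y), rownames(D))
  if (length(keep) < 2L) stop("need at least 2 training lines with both phenotype and genotype")
  list(y = y[keep], D = D[keep, , drop = FALSE])
}

# Construct a gp_fit object.
.gp_fit <- function(model_tag, mu, center, marker_ids, varcomp,
                    effects = NULL, kernel_fit = NULL, settings = NULL) {
  structure(list(model_tag = model_tag, mu = unname(mu), effects = effects,
                 center = center, marker_ids = marker_ids, varcomp = varcomp,
                 kernel_fit = kernel_fit, settings = settings),
            class = "gp_fit")
}

#' @export
print.gp_fit <- function(x, ...) {
  cat(sprintf("Genomic prediction fit: %s (%d markers), intercept %.4g\n",
              x$model_tag, length(x$marker_ids), x$mu))
  vc <- unlist(x$varcomp)
  cat("  variance components:",
      paste(sprintf("%s = %.4g", names(vc), vc), collapse = ", "), "\n")
  invisible(x)
}
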
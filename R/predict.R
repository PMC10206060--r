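#' Predict genomic estimated breeding values for new genotypes
#'
#' Marker-effect models (RR-BLUP, BayesRR, BayesB) score each new line as
#' `mu + z u`, with the new scores centered by the TRAINING column means
#' recorded in the fit. Kernel models (GBLUP, EGBLUP) project the
#' training genetic values onto the new lines through the cross kernel:
#' `g_new = K_new,train (K_train,train + eps I)^-1 g_train` per kernel
#' (additive and, for EGBLUP, epistatic), summed and shifted by the
#' intercept. Cross kernels reuse the training centering and scaling, so
#' predictions are consistent with the training-set kernels.
#'
#' @param fit A `gp_fit` object.
#' @param newgeno Genotype matrix of the lines to predict, on the
#'   training marker panel, no missing calls.
#' @param training_geno Optional training genotype matrix; kernel fits
#'   already store their training design, so this is only needed when a
#'   fit has been deserialized without it.
#' @param eps Ridge jitter on the training-kernel inversion.
#' @return Named numeric vector of GEBVs (names = line ids).
#' @export
predict_gebv <- function(fit, newgeno, training_geno = NULL, eps = 1e-8) {
  stopifnot(inherits(fit, "gp_fit"))
  validate_genotypes(newgeno, allow_missing = FALSE)
  if (!identical(colnames(newgeno), fit$marker_ids)) {
    extra <- setdiff(colnames(newgeno), fit$marker_ids)
    miss <- setdiff(fit$marker_ids, colnames(newgeno))
    if (length(extra) || length(miss)) {
      stop("marker panel mismatch; missing from new genotypes: ",
           paste(utils::head(miss, 5L), collapse = ", "),
           "; unknown to fit: ", paste(utils::head(extra, 5L), collapse = ", "))
    }
    newgeno <- newgeno[, fit$marker_ids, drop = FALSE]
  }
  Zn <- sweep(newgeno - 1, 2L, fit$center)
  if (!is.null(fit$effects)) {
    if (length(fit$effects) == 0L) {
      return(setNames(rep(fit$mu, nrow(newgeno)), rownames(newgeno)))
    }
    return(setNames(drop(fit$mu + Zn %*% fit$effects), rownames(newgeno)))
  }
  kf <- fit$kernel_fit
  if (is.null(kf)) stop("fit carries neither marker effects nor kernel solutions")
  Zt <- kf$Z_train
  if (is.null(Zt)) {
    if (is.null(training_geno)) stop("kernel fit without stored training design: supply training_geno")
    Zt <- sweep(training_geno[, fit$marker_ids, drop = FALSE] - 1, 2L, fit$center)
  }
  G_nt <- tcrossprod(Zn, Zt) / kf$scale_c
  g <- rep(fit$mu, nrow(newgeno))
  for (kind in names(kf$ghat)) {
    ghat <- kf$ghat[[kind]]
    if (all(ghat == 0)) next
    K_nt <- if (kind == "epistatic") (G_nt * G_nt) / kf$scale_h else G_nt
    K_tt <- kf$K_train[[kind]]
    alpha <- solve(K_tt + diag(eps, nrow(K_tt)), ghat)
    g <- g + drop(K_nt %*% alpha)
  }
  setNames(g, rownames(newgeno))
}

#' @export
#' @rdname predict_gebv
#' @param object,... Standard predict-method arguments; `...` is passed
#'   to [predict_gebv()].
predict.gp_fit <- function(object, newgeno, ...) {
  predict_gebv(object, newgeno, ...)
}
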
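#' Build the marker design from a genotype matrix
#'
#' Recode calls to marker scores `call - 1`, giving \{-1, 0, +1\} for the
#' two homozygotes and the heterozygote. The transform is a bijection, so
#' the genotype matrix is recoverable as `D + 1`.
#'
#' @param G Genotype matrix with no missing calls.
#' @return Numeric score matrix with the same dimnames.
#' @export
build_design <- function(G) {
  validate_genotypes(G, allow_missing = FALSE)
  D <- G - 1
  storage.mode(D) <- "double"
  D
}

#' Additive genomic relationship kernel
#'
#' VanRaden-style relationship matrix `G = Z Z' / c` where Z is the score
#' matrix centered by its column means and c is the mean diagonal of
#' `Z Z'` before scaling, so that `mean(diag(G)) = 1` and variance
#' components are on a comparable scale across kernels. The centering
#' means and scale are attached as attributes so that the identical
#' transform can be applied to prediction genotypes.
#'
#' @param D Marker design from [build_design()].
#' @return Kernel matrix with attributes `kind = "additive"`, `center`
#'   (training column means) and `scale_c`.
#' @export
additive_kernel <- function(D) {
  stopifnot(is.matrix(D), ncol(D) >= 1L)
  ctr <- colMeans(D)
  Z <- sweep(D, 2L, ctr)
  K <- tcrossprod(Z)
  c0 <- mean(diag(K))
  if (c0 <= 0) {
    warning("zero-variance marker panel: all lines identical; returning kernel of ones")
    K <- matrix(1, nrow(D), nrow(D), dimnames = list(rownames(D), rownames(D)))
    c0 <- 1
  } else {
    K <- K / c0
  }
  attr(K, "kind") <- "additive"
  attr(K, "center") <- ctr
  attr(K, "scale_c") <- c0
  K
}

#' Additive-by-additive epistatic kernel (Hadamard square)
#'
#' `H = (G o G) / s` where `o` is the elementwise (Hadamard) product and s
#' rescales so `mean(diag(H)) = 1`. By the Schur product theorem H is
#' positive semi-definite whenever G is. This kernel captures
#' additive-by-additive epistatic relationships for the extended GBLUP
#' model.
#'
#' @param Gk Additive kernel from [additive_kernel()].
#' @return Epistatic kernel with attributes `kind = "epistatic"` and
#'   `scale_h` (in addition to the additive kernel's attributes).
#' @export
epistatic_kernel <- function(Gk) {
  stopifnot(is.matrix(Gk))
  if (!identical(attr(Gk, "kind"), "additive")) {
    stop("epistatic_kernel expects an additive kernel")
  }
  H <- Gk * Gk
  s <- mean(diag(H))
  H <- H / s
  attr(H, "kind") <- "epistatic"
  attr(H, "center") <- attr(Gk, "center")
  attr(H, "scale_c") <- attr(Gk, "scale_c")
  attr(H, "scale_h") <- s
  H
}

# Check numerical positive semi-definiteness of a kernel.
.check_psd <- function(K, tol = 1e-8) {
  ev <- eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(abs(ev), 1)) {
    stop("kernel is not positive semi-definite (min eigenvalue ",
         format(min(ev)), ")")
  }
  invisible(TRUE)
}
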
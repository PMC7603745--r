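# Imposing a target genetic correlation matrix on simulated genetic values
# via the Cholesky whitening/coloring transformation.

#' Impose a target correlation matrix on genetic values
#'
#' Transforms an individuals-by-traits matrix of genetic values so that the
#' sample correlation of its columns equals the target matrix exactly:
#'
#' 1. centre and scale each trait column;
#' 2. compute the sample correlation `Sigma` of the scaled columns;
#' 3. whiten with the inverse lower Cholesky factor of `Sigma`
#'    (`X = L^-1 Y`, `Sigma = L L^T`), making the columns exactly
#'    uncorrelated;
#' 4. colour with the lower Cholesky factor of the target
#'    (`Y' = L' X`, `Sigma' = L' L'^T`);
#' 5. restore each column's original mean and standard deviation.
#'
#' Because `Sigma` is the *sample* correlation of this very matrix, the
#' realized correlation after the transform equals the target to machine
#' precision — not merely in expectation. Each column keeps its original
#' sample mean and variance. With a single trait the transform is the
#' identity.
#'
#' @param Y numeric matrix, individuals in rows, traits in columns.
#' @param sigma_prime target correlation matrix (symmetric, unit diagonal,
#'   positive definite).
#' @return matrix of the same shape as `Y`.
#' @export
whiten_color <- function(Y, sigma_prime) {
  Y <- as.matrix(Y)
  t_n <- ncol(Y)
  if (t_n == 1) return(Y)
  if (!all(dim(sigma_prime) == t_n)) {
    pleio_stop("pleiosim_config_error",
               "target correlation matrix must be %d x %d", t_n, t_n)
  }
  check_correlation_matrix(sigma_prime, "target correlation matrix (cor)")
  mu <- colMeans(Y)
  sd0 <- apply(Y, 2, stats::sd)
  if (any(sd0 == 0)) {
    pleio_stop("pleiosim_validation_error",
               "trait %d has zero genetic variance; cannot impose a correlation",
               which(sd0 == 0)[1])
  }
  Ys <- sweep(sweep(Y, 2, mu, "-"), 2, sd0, "/")
  Sigma <- crossprod(Ys) / (nrow(Ys) - 1) # sample correlation (Ys is scaled)
  R <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(R)) {
    pleio_stop("pleiosim_validation_error",
               "sample correlation of the genetic values is not positive definite (collinear traits); whitening failed")
  }
  L <- t(R)
  X <- t(forwardsolve(L, t(Ys)))      # whiten: columns now uncorrelated
  Lp <- t(chol(sigma_prime))
  Yp <- X %*% t(Lp)                   # colour to the target correlation
  out <- sweep(sweep(Yp, 2, sd0, "*"), 2, mu, "+")
  dimnames(out) <- dimnames(Y)
  out
}
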
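# Residual-variance calibration from target heritabilities and simulation of
# (optionally correlated) normally distributed non-genetic error terms.

#' Residual variance implied by a target heritability
#'
#' Trait variance is dichotomized into the variance of the genetic values
#' and the variance of the random error terms, so
#' `var_e = var_g * (1 - h2) / h2` gives
#' `var_g / (var_g + var_e) = h2`. `var_g` should be the sample variance of
#' the replicate's genetic-value column, which makes the realized
#' heritability unbiased per replicate.
#'
#' @param var_g genetic variance (>= 0).
#' @param h2 target heritability in (0, 1].
#' @return residual variance (0 when `h2 = 1`).
#' @export
residual_variance <- function(var_g, h2) {
  if (any(h2 <= 0 | h2 > 1)) {
    pleio_stop("pleiosim_config_error",
               "heritability must lie in (0, 1] (got %s)",
               paste(h2[h2 <= 0 | h2 > 1], collapse = ", "))
  }
  if (any(var_g < 0)) {
    pleio_stop("pleiosim_config_error", "genetic variance must be >= 0")
  }
  var_g * (1 - h2) / h2
}

#' Draw non-genetic error terms
#'
#' Multivariate-normal errors with zero mean, per-trait marginal variances
#' `var_e` and cross-trait correlation `cor_res` (identity when `NULL`,
#' matching independent errors by default). Traits with `var_e = 0`
#' (heritability 1) receive exactly zero noise.
#'
#' @param n number of individuals.
#' @param var_e numeric vector of per-trait residual variances.
#' @param cor_res optional residual correlation matrix.
#' @param seed integer seed for this draw; recorded by the driver so noise
#'   is reproducible independently of any other option.
#' @return n x traits matrix of errors.
#' @export
simulate_errors <- function(n, var_e, cor_res = NULL, seed = 1) {
  t_n <- length(var_e)
  if (any(var_e < 0)) {
    pleio_stop("pleiosim_config_error", "residual variances must be >= 0")
  }
  E <- with_seed(seed, {
    Z <- matrix(stats::rnorm(n * t_n), n, t_n)
    if (!is.null(cor_res) && t_n > 1) {
      check_correlation_matrix(cor_res, "residual correlation matrix (cor_res)")
      Z <- Z %*% chol(cor_res) # upper factor: rows get correlation cor_res
    }
    Z
  })
  sweep(E, 2, sqrt(var_e), "*")
}

#' Combine genetic values and errors into phenotypes
#'
#' @param G individuals x traits matrix of genetic values.
#' @param E matching matrix of error terms.
#' @return list with `phenotypes` (`G + E`) and `realized_h2`, the per-trait
#'   sample heritability `var(G) / (var(G) + var(E))`.
#' @export
assemble_phenotypes <- function(G, E) {
  if (!all(dim(G) == dim(E))) {
    pleio_stop("pleiosim_validation_error",
               "genetic-value and error matrices have different shapes")
  }
  P <- G + E
  vg <- apply(G, 2, stats::var)
  ve <- apply(E, 2, stats::var)
  h2 <- ifelse(vg + ve > 0, vg / (vg + ve), NA_real_)
  list(phenotypes = P, realized_h2 = unname(h2))
}
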
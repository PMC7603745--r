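# Internal helpers: seed management and validation utilities.

#' Derive a child seed from a root seed
#'
#' All randomness in pleiosim flows from one root seed through this scheme:
#' each (replicate, stream, trait) combination gets its own deterministic
#' child seed, so partial reruns (e.g. regenerating only the noise of
#' replicate 7) reproduce exactly and toggling unrelated options never
#' perturbs a stream.
#'
#' Streams: 1 = QTN selection, 2 = non-genetic error draws, 3 = fixture
#' generation, 4 = effect assignment.
#'
#' @param root integer root seed.
#' @param rep replicate index (1-based; 0 for replicate-independent streams).
#' @param stream integer stream tag.
#' @param trait trait index (0 when the stream is not per-trait).
#' @return an integer seed in [0, 2^31 - 2].
#' @keywords internal
derive_seed <- function(root, rep = 0L, stream = 0L, trait = 0L) {
  m <- 2147483647 # 2^31 - 1, keeps seeds inside R's integer range
  s <- (as.numeric(root) %% m) + 1000003 * as.numeric(rep) +
    7919 * as.numeric(stream) + 101 * as.numeric(trait)
  as.integer(s %% m)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = genv)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = genv)), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# stop() with a condition class so callers/tests can discriminate error kinds.
pleio_stop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "pleiosim_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# sample() without the length-1 surprise: draws k elements from the vector x
sample_safe <- function(x, k = length(x)) x[sample.int(length(x), k)]

check_correlation_matrix <- function(m, name) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    pleio_stop("pleiosim_config_error", "%s must be a square matrix", name)
  }
  if (max(abs(m - t(m))) > 1e-8) {
    pleio_stop("pleiosim_config_error", "%s must be symmetric", name)
  }
  if (max(abs(diag(m) - 1)) > 1e-8) {
    pleio_stop("pleiosim_config_error", "%s must have a unit diagonal", name)
  }
  ch <- tryCatch(chol(m), error = function(e) NULL)
  if (is.null(ch)) {
    pleio_stop(
      "pleiosim_config_error",
      "%s is not positive definite (Cholesky decomposition failed)", name
    )
  }
  invisible(ch)
}
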
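# Internal numerical helpers shared across modules.

#' Log-density of a multivariate normal
#'
#' Evaluates the log-density of rows of `x` under N(mean, sigma) via a
#' Cholesky factorization, so downstream posterior arithmetic can stay in log
#' space throughout.
#'
#' @param x numeric matrix (rows = observations) or a single numeric vector.
#' @param mean numeric mean vector.
#' @param sigma positive-definite covariance matrix.
#' @return numeric vector of log-densities, one per row of `x`.
#' @keywords internal
#' @noRd
dmvnorm_log <- function(x, mean, sigma) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  d <- length(mean)
  if (ncol(x) != d) {
    abort(sprintf("dimension mismatch: x has %d columns, mean has length %d",
                  ncol(x), d))
  }
  ch <- tryCatch(chol(sigma), error = function(e) {
    abort("covariance matrix is not positive definite")
  })
  logdet <- 2 * sum(log(diag(ch)))
  centered <- sweep(x, 2, mean)
  # Mahalanobis distance via triangular solve: z = L^-T (x - mu)
  z <- backsolve(ch, t(centered), transpose = TRUE)
  maha <- colSums(z^2)
  -0.5 * (d * log(2 * pi) + logdet + maha)
}

#' Stable log(exp(a) + exp(b))
#' @keywords internal
#' @noRd
logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  m + log(exp(a - m) + exp(b - m))
}

#' Shannon entropy of a count/probability vector, in nats
#' @keywords internal
#' @noRd
entropy_nats <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0) return(0)
  p <- counts / sum(counts)
  -sum(p * log(p))
}

#' Derive reproducible per-stage seeds from one global seed
#'
#' All pipeline randomness flows from one integer seed; each named stage gets
#' its own derived stream so stages can be rerun in isolation. The caller's
#' random-number state is restored on exit.
#'
#' @param seed integer master seed.
#' @param stages character vector of stage names.
#' @return named integer vector of derived seeds, one per stage.
#' @examples
#' derive_seeds(1, c("simulate", "fit"))
#' @export
derive_seeds <- function(seed, stages) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  setNames(sample.int(.Machine$integer.max, length(stages)), stages)
}

#' Check that a probability vector sums to one
#' @keywords internal
#' @noRd
check_prob_vector <- function(p, name, tol = 1e-9) {
  if (any(p < 0)) abort(sprintf("'%s' has negative entries", name))
  if (abs(sum(p) - 1) > tol) {
    abort(sprintf("'%s' must sum to 1 (got %.12f)", name, sum(p)))
  }
  invisible(p)
}
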
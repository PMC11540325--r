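#' Legendre polynomial values by recurrence
#'
#' Evaluates the (unnormalized) Legendre polynomials P_0..P_k at `x` using
#' the Bonnet three-term recurrence.  The polynomials are orthogonal on
#' \[-1, 1\] with \eqn{\int P_k^2 = 2/(2k+1)}.
#'
#' @param x evaluation points (any real values; outside \[-1, 1\] the
#'   recurrence still defines the polynomial, used for mild extrapolation).
#' @param order highest polynomial degree k.
#' @return matrix `length(x)` by `order + 1`, column k+1 holding P_k(x).
#' @export
legendre_polynomials <- function(x, order) {
  stopifnot(order >= 0)
  P <- matrix(0, length(x), order + 1)
  P[, 1] <- 1
  if (order >= 1) P[, 2] <- x
  if (order >= 2) {
    for (k in 1:(order - 1)) {
      P[, k + 2] <- ((2 * k + 1) * x * P[, k + 1] - k * P[, k]) / (k + 1)
    }
  }
  P
}

#' Normalized Legendre basis on a standardized time axis
#'
#' Builds the basis used by the random-regression machinery: observed time
#' (cumulative GDD within a harvest cycle) is mapped affinely onto
#' \[-1, 1\] via `t* = 2 (t - t_min) / (t_max - t_min) - 1`, and the basis
#' functions are `phi_k(t*) = sqrt((2k+1)/2) P_k(t*)` so that
#' \eqn{\int_{-1}^{1} \phi_i \phi_j = \delta_{ij}}.  The orthonormal
#' scaling makes coefficient covariances comparable across orders; the
#' plain polynomials are available with `normalized = FALSE`.
#'
#' @param gdd numeric vector of observed time points (at least two
#'   distinct values), or `NULL` if `domain` is given directly.
#' @param order polynomial degree (default 3, i.e. four coefficients).
#' @param domain optional `c(min, max)` time domain overriding the range
#'   of `gdd`; used when a terminal yield record extends the support.
#' @param normalized use the orthonormal scaling.
#' @return object of class `legendre_basis`: list with `order`, `domain`,
#'   `normalized`, `standardize(t)` mapping time to t*, and `evaluate(t)`
#'   returning the basis matrix at raw times `t`.
#' @examples
#' b <- legendre_basis(c(100, 300, 500), order = 3)
#' b$evaluate(300)   # phi at t* = 0: c(sqrt(1/2), 0, -sqrt(5/2)/2, 0)
#' @export
legendre_basis <- function(gdd = NULL, order = 3, domain = NULL,
                           normalized = TRUE) {
  if (is.null(domain)) {
    if (is.null(gdd) || length(unique(gdd)) < 2) {
      stop("need at least two distinct time points (or an explicit domain)")
    }
    domain <- range(gdd)
  }
  if (diff(domain) <= 0) stop("degenerate time domain")
  scale_k <- if (normalized) sqrt((2 * seq(0, order) + 1) / 2) else
    rep(1, order + 1)
  standardize <- function(t) 2 * (t - domain[1]) / diff(domain) - 1
  evaluate <- function(t, standardized = FALSE) {
    ts <- if (standardized) t else standardize(t)
    if (any(abs(ts) > 1 + 1e-8)) {
      warning("evaluating Legendre basis outside the standardized domain",
              " (extrapolation)")
    }
    P <- legendre_polynomials(ts, order)
    sweep(P, 2, scale_k, `*`)
  }
  structure(list(order = order, domain = domain, normalized = normalized,
                 standardize = standardize, evaluate = evaluate),
            class = "legendre_basis")
}

#' @export
print.legendre_basis <- function(x, ...) {
  cat(sprintf("%segendre basis, degree %d, time domain [%g, %g]\n",
              if (x$normalized) "Orthonormal L" else "L",
              x$order, x$domain[1], x$domain[2]))
  invisible(x)
}

#' Covariance function implied by a coefficient covariance matrix
#'
#' For coefficient covariance `K` on basis `basis`, returns the continuous
#' covariance function `Cov(t, s) = phi(t)' K phi(s)` of the modeled
#' random effect over time, and its correlation version.
#'
#' @param K symmetric coefficient covariance, `(order+1)` square.
#' @param basis a [legendre_basis()].
#' @return list with `cov(t, s)`, `var(t)` and `cor(t, s)` evaluators
#'   (raw-time arguments; `standardized = TRUE` accepts t* directly).
#' @keywords internal
cov_function <- function(K, basis) {
  d <- basis$order + 1
  stopifnot(nrow(K) == d, ncol(K) == d)
  covf <- function(t, s, standardized = FALSE) {
    Pt <- basis$evaluate(t, standardized)
    Ps <- basis$evaluate(s, standardized)
    Pt %*% K %*% t(Ps)
  }
  varf <- function(t, standardized = FALSE) {
    P <- basis$evaluate(t, standardized)
    rowSums((P %*% K) * P)
  }
  corf <- function(t, s, standardized = FALSE) {
    v1 <- varf(t, standardized)
    v2 <- varf(s, standardized)
    out <- covf(t, s, standardized) / sqrt(outer(v1, v2))
    out[outer(v1, v2) <= 0] <- NA_real_
    out
  }
  list(cov = covf, var = varf, cor = corf, K = K, basis = basis)
}
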
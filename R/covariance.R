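#' Matern correlation function
#'
#' Isotropic stationary Matern correlation
#' \deqn{C(D) = \frac{1}{\Gamma(\nu) 2^{\nu-1}} (\kappa D)^\nu K_\nu(\kappa D)}
#' with smoothness \eqn{\nu} (fixed at 2 throughout the package) and scale
#' \eqn{\kappa}. The value at \eqn{D = 0} is the limit 1. Distances are
#' Euclidean on degrees; at the scales modeled here no great-circle correction
#' is applied.
#'
#' @param D non-negative distances (degrees).
#' @param kappa scale parameter (> 0); see [compute_kappa()].
#' @param nu smoothness (> 0), default 2.
#' @return correlations in (0, 1].
#' @export
matern_correlation <- function(D, kappa, nu = 2) {
  stopifnot(kappa > 0, nu > 0)
  if (any(D < 0)) stop("distances must be non-negative")
  out <- numeric(length(D))
  z <- kappa * D
  pos <- z > 0
  out[!pos] <- 1
  out[pos] <- (z[pos]^nu) * besselK(z[pos], nu) / (gamma(nu) * 2^(nu - 1))
  # guard against overflow-underflow at extreme arguments
  out[pos & !is.finite(out)] <- 0
  dim(out) <- dim(D)
  out
}

#' Matern scale from range
#'
#' \eqn{\kappa = \sqrt{8\nu} / \delta}, where the range \eqn{\delta} is the
#' approximate distance at which correlation drops to about 0.1.
#'
#' @param nu smoothness.
#' @param delta range parameter (> 0), degrees.
#' @return kappa.
#' @export
compute_kappa <- function(nu, delta) {
  if (delta <= 0) stop("delta must be > 0")
  sqrt(8 * nu) / delta
}

#' AR1 correlation matrix over a set of years
#'
#' @param n_years number of annual steps.
#' @param rho lag-1 correlation, |rho| < 1.
#' @return `n_years x n_years` correlation matrix \eqn{\rho^{|k-j|}}.
#' @export
ar1_correlation <- function(n_years, rho) {
  stopifnot(abs(rho) < 1)
  lag <- abs(outer(seq_len(n_years), seq_len(n_years), "-"))
  rho^lag
}

#' Gaussian-process hyperparameters
#'
#' Container for the covariance and random-effect parameters of the
#' space-time model: marginal GP variance `omega2` (logit^2 units), Matern
#' range `delta` (degrees), smoothness `nu` (fixed 2), temporal AR1
#' correlation `rho`, country random-effect variance `gamma2_country`, and
#' nugget variance `sigma2_nugget`. `kappa` is derived, never set.
#'
#' @param omega2,delta,rho,gamma2_country,sigma2_nugget see description.
#' @param nu smoothness, default 2.
#' @return object of class `gp_params`.
#' @export
gp_params <- function(omega2 = 0.5, delta = 3, rho = 0.8,
                      gamma2_country = 0.1, sigma2_nugget = 0.05, nu = 2) {
  stopifnot(omega2 >= 0, delta > 0, abs(rho) < 1,
            gamma2_country >= 0, sigma2_nugget >= 0, nu > 0)
  structure(list(omega2 = omega2, delta = delta, nu = nu,
                 kappa = compute_kappa(nu, delta), rho = rho,
                 gamma2_country = gamma2_country,
                 sigma2_nugget = sigma2_nugget),
            class = "gp_params")
}

#' @export
print.gp_params <- function(x, ...) {
  cat(sprintf(paste0("gp_params: omega2=%.3g delta=%.3g (kappa=%.3g, nu=%g) ",
                     "rho=%.3g gamma2=%.3g sigma2=%.3g\n"),
              x$omega2, x$delta, x$kappa, x$nu, x$rho,
              x$gamma2_country, x$sigma2_nugget))
  invisible(x)
}

#' Structured Matern x AR1 space-time covariance
#'
#' Builds the Kronecker-structured covariance
#' \eqn{\Sigma = \omega^2\, \Sigma^{space} \otimes \Sigma^{time}} over a set
#' of knots and years, exposing solve, log-determinant, quadratic-form and
#' sampling operations through eigen/Cholesky decompositions of the two
#' factors — the dense product is never materialized. Vectors are ordered
#' year-fast, knot-slow: entry `(k, t)` sits at `(k - 1) * n_years + t`,
#' matching `kronecker(S, T)`. See `st_index()`.
#'
#' @param knots data.frame with `lon`, `lat` (distinct rows).
#' @param years vector of years (only the length matters).
#' @param params a [gp_params()].
#' @param jitter small diagonal inflation of the spatial factor; the
#'   nu = 2 Matern is very smooth and its correlation matrix is otherwise
#'   numerically rank-deficient once the range exceeds the knot spacing.
#' @return object of class `spacetime_cov` with elements used by the
#'   `st_*` operations.
#' @export
build_spacetime_covariance <- function(knots, years, params, jitter = 1e-6) {
  D <- as.matrix(stats::dist(cbind(knots$lon, knots$lat)))
  if (any(D[upper.tri(D)] == 0)) stop("duplicate knots: spatial factor singular")
  S <- matern_correlation(D, params$kappa, params$nu) + jitter * diag(nrow(D))
  Tm <- ar1_correlation(length(years), params$rho)
  eS <- eigen(S, symmetric = TRUE)
  eT <- eigen(Tm, symmetric = TRUE)
  if (min(eS$values) <= 1e-12 * max(eS$values))
    stop("spatial covariance factor numerically non-positive-definite")
  structure(list(
    n_knots = nrow(knots), n_years = length(years),
    omega2 = params$omega2, S = S, Tm = Tm, eS = eS, eT = eT),
    class = "spacetime_cov")
}

# vec ordering: knot-major blocks of years -> index (k-1)*n_years + t
st_index <- function(cov, k, t) (k - 1L) * cov$n_years + t

#' @rdname build_spacetime_covariance
#' @param cov a `spacetime_cov`.
#' @export
st_logdet <- function(cov) {
  n <- cov$n_knots * cov$n_years
  n * log(cov$omega2) +
    cov$n_years * sum(log(cov$eS$values)) +
    cov$n_knots * sum(log(cov$eT$values))
}

#' @rdname build_spacetime_covariance
#' @param x vector (or matrix of columns) of length `n_knots * n_years`.
#' @export
st_solve <- function(cov, x) {
  # Sigma^{-1} x = omega^{-2} (Us (Ls^{-1} o Lt^{-1}) Us') x with U = Us o Ut
  one_col <- function(v) {
    M <- matrix(v, nrow = cov$n_years)               # t fast, k slow
    W <- crossprod(cov$eT$vectors, M %*% cov$eS$vectors)  # Ut' M Us
    W <- W / outer(cov$eT$values, cov$eS$values)
    as.vector(cov$eT$vectors %*% W %*% t(cov$eS$vectors)) / cov$omega2
  }
  if (is.matrix(x)) apply(x, 2, one_col) else one_col(x)
}

#' @rdname build_spacetime_covariance
#' @export
st_quadform <- function(cov, x) as.numeric(crossprod(x, st_solve(cov, x)))

#' @rdname build_spacetime_covariance
#' @param n number of samples.
#' @param seed optional integer seed.
#' @export
st_sample <- function(cov, n = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Ls <- cov$eS$vectors %*% (sqrt(pmax(cov$eS$values, 0)) * t(cov$eS$vectors))
  Lt <- cov$eT$vectors %*% (sqrt(pmax(cov$eT$values, 0)) * t(cov$eT$vectors))
  out <- matrix(0, cov$n_knots * cov$n_years, n)
  for (j in seq_len(n)) {
    Z <- matrix(stats::rnorm(cov$n_years * cov$n_knots), cov$n_years, cov$n_knots)
    out[, j] <- sqrt(cov$omega2) * as.vector(Lt %*% Z %*% t(Ls))
  }
  if (cov$omega2 == 0) out[] <- 0
  out
}

#' Precision matrix of the structured covariance (for the Laplace fit)
#'
#' Returns `Sigma^{-1}` as a dense matrix via the Kronecker identity
#' `(A o B)^{-1} = A^{-1} o B^{-1}` on the factor inverses. Used as the prior
#' precision block of the latent field; knot counts are small by design.
#'
#' @param cov a `spacetime_cov`.
#' @return dense precision matrix.
#' @keywords internal
st_precision <- function(cov) {
  Sinv <- cov$eS$vectors %*% ((1 / cov$eS$values) * t(cov$eS$vectors))
  Tinv <- cov$eT$vectors %*% ((1 / cov$eT$values) * t(cov$eT$vectors))
  kronecker(Sinv, Tinv) / cov$omega2
}

#' Dense-matrix oracle for the space-time covariance
#'
#' Materializes the full covariance \eqn{\omega^2 (S \otimes T)} with the
#' same vector ordering as the structured object. Quadratic in memory; used
#' in tests as the brute-force reference for [st_logdet()], [st_solve()] and
#' [st_quadform()].
#'
#' @inheritParams build_spacetime_covariance
#' @return dense covariance matrix.
#' @export
dense_spacetime_covariance <- function(knots, years, params, jitter = 1e-6) {
  D <- as.matrix(stats::dist(cbind(knots$lon, knots$lat)))
  S <- matern_correlation(D, params$kappa, params$nu) + jitter * diag(nrow(D))
  Tm <- ar1_correlation(length(years), params$rho)
  params$omega2 * kronecker(S, Tm)
}
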
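## Gauss-Legendre nodes/weights on [0,1], cached at load time.  Used for the
## correlation integral of the bivariate normal CDF.
.gl_cache <- new.env(parent = emptyenv())

.gauss_legendre01 <- function(n = 64L) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  g <- pracma::gaussLegendre(n, 0, 1)
  out <- list(x = g$x, w = g$w)
  .gl_cache[[key]] <- out
  out
}

#' Standard bivariate normal CDF
#'
#' \code{pbinorm(h, k, rho)} evaluates \eqn{P(X \le h, Y \le k)} for a
#' standard bivariate normal vector with correlation \code{rho}, using the
#' identity \eqn{\partial \Phi_2 / \partial \rho = \phi_2} so that
#' \eqn{\Phi_2(h,k;\rho) = \Phi(h)\Phi(k) + \int_0^\rho \phi_2(h,k;r)\,dr},
#' integrated by fixed Gauss-Legendre quadrature.  Vectorized over
#' \code{h} and \code{k}; \code{rho} is scalar.
#'
#' @param h,k upper integration limits (may be \code{Inf}/\code{-Inf}).
#' @param rho correlation in (-1, 1); values beyond ±0.9995 are clamped.
#' @return vector of probabilities.
#' @export
pbinorm <- function(h, k, rho) {
  stopifnot(length(rho) == 1L)
  rho <- max(min(rho, 0.9995), -0.9995)
  n <- max(length(h), length(k))
  h <- rep_len(h, n); k <- rep_len(k, n)
  ## finite proxies: at |x| >= 8.5 the univariate tail is < 1e-17
  hb <- pmax(pmin(h, 8.5), -8.5)
  kb <- pmax(pmin(k, 8.5), -8.5)
  base <- pnorm(hb) * pnorm(kb)
  if (rho == 0) return(base)
  gl <- .gauss_legendre01(64L)
  r <- rho * gl$x                       # nodes on [0, rho]
  w <- rho * gl$w
  acc <- numeric(n)
  hk <- hb * kb
  h2k2 <- hb^2 + kb^2
  for (i in seq_along(r)) {
    ri <- r[i]
    om <- 1 - ri^2
    acc <- acc + w[i] * exp(-(h2k2 - 2 * ri * hk) / (2 * om)) / (2 * pi * sqrt(om))
  }
  p <- base + acc
  pmin(pmax(p, 0), 1)
}

## density of the standard bivariate normal at (h, k) with correlation rho
.dbinorm <- function(h, k, rho) {
  om <- 1 - rho^2
  exp(-(h^2 - 2 * rho * h * k + k^2) / (2 * om)) / (2 * pi * sqrt(om))
}

## Gauss-Hermite rule transformed for N(0,1): nodes t, weights summing to 1.
gauss_hermite_normal <- function(n = 41L) {
  g <- pracma::gaussHermite(n)
  list(nodes = sqrt(2) * g$x, weights = g$w / sqrt(pi))
}

## Draw n multivariate normal rows with mean mu and covariance Sigma (chol).
rmvn <- function(n, mu, Sigma) {
  p <- length(mu)
  L <- chol(Sigma)
  z <- matrix(rnorm(n * p), n, p) %*% L
  sweep(z, 2L, mu, `+`)
}

## Symmetrize and clip eigenvalues so the matrix is positive definite.
nearest_pd <- function(S, eps = 1e-6) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) >= eps) return(list(mat = S, repaired = FALSE))
  v <- pmax(e$values, eps)
  M <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(M))
  M <- M / tcrossprod(d)                # restore unit diagonal (correlations)
  diag(M) <- 1
  list(mat = (M + t(M)) / 2, repaired = TRUE)
}

#' Round half away from zero
#'
#' Printed-table rounding convention (so -0.0248 renders as -0.025 at three
#' decimals and 0.5 rounds to 1), unlike base \code{round}'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded vector.
#' @export
round_half_away <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
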
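## Generative population for two-group ordinal SDQ responses.
##
## The latent-response model: for person in group g, eta ~ MVN(kappa_g, Phi_g);
## y*_i = Lambda_g[i,] eta + eps_i with Cov(eps) = Theta_g chosen so that
## Var(y*_i) = 1 within each group (standardized latent responses), and the
## observed ordinal category is #{k : y*_i > tau_g[i,k]}.  Girls (group 1) are
## the reference: kappa_1 = 0, Phi has unit diagonal.

.spec_factor_index <- function() {
  meta <- sdq_item_meta()
  match(meta$scale, sdq_scales())
}

## Build a 25 x 5 loading matrix from per-item primary loadings plus the
## tantrum -> emotion cross-loading.
.build_lambda <- function(primary, cross_loading) {
  meta <- sdq_item_meta()
  L <- matrix(0, 25L, 5L, dimnames = list(meta$item_id, sdq_scales()))
  L[cbind(seq_len(25L), .spec_factor_index())] <- primary
  L["tantrum", "emotion"] <- cross_loading
  L
}

## Residual covariance: diag = 1 - communality (per group), off-diagonal from
## standardized residual correlations r_jk: omega = r * sqrt(theta_j theta_k).
.build_theta <- function(L, Phi, residual_cor) {
  comm <- diag(L %*% Phi %*% t(L))
  th <- 1 - comm
  if (any(th <= 0))
    stop("implied residual variance non-positive for item(s): ",
         paste(rownames(L)[th <= 0], collapse = ", "))
  Th <- diag(th)
  dimnames(Th) <- list(rownames(L), rownames(L))
  if (nrow(residual_cor)) {
    for (r in seq_len(nrow(residual_cor))) {
      i <- residual_cor$item1[r]; j <- residual_cor$item2[r]
      Th[i, j] <- Th[j, i] <- residual_cor$value[r] * sqrt(th[i] * th[j])
    }
  }
  Th
}

.validate_spec <- function(spec) {
  for (g in 1:2) {
    tau <- spec$tau[[g]]
    if (any(tau[, 2] <= tau[, 1]))
      stop("thresholds must be strictly increasing per item (group ", g, ")")
    Phi <- spec$Phi[[g]]
    ev <- eigen((Phi + t(Phi)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-8)
      stop("factor covariance matrix is not positive definite (group ", g, ")")
    ## also checks residual variances are positive
    .build_theta(spec$Lambda[[g]], Phi, spec$residual_cor)
  }
  if (any(spec$kappa[[1]] != 0))
    stop("reference-group latent means must be zero")
  if (any(abs(diag(spec$Phi[[1]]) - 1) > 1e-12))
    stop("reference-group factor variances must be one")
  invisible(spec)
}

#' Construct a two-group generative population
#'
#' Presets encode the published SDQ parameter tables: \code{"table2_full"}
#' uses the girls' standardized loadings/thresholds for both groups except for
#' the eight DIF items, which take their published boys' values in group 2;
#' factor correlations are gender-specific, and boys' latent means are the
#' published DIF-accounting latent mean differences.  \code{"no_dif"} uses the
#' girls' parameters for both groups with zero latent mean differences and the
#' girls' factor correlations in both groups.  The tantrum-emotion
#' cross-loading (0.353) and the two residual correlations (restless-fidgety
#' .555, distractible-attends .332) are present in both groups under both
#' presets.
#'
#' @param preset \code{"table2_full"}, \code{"no_dif"} or \code{"custom"}
#'   (girls' parameters both groups, overrides required to differentiate).
#' @param overrides named list replacing spec slots (\code{Lambda}, \code{tau},
#'   \code{Phi}, \code{kappa}, \code{residual_cor}, \code{n}, \code{missing_rate},
#'   \code{cross_loading}); matrices/lists must match the slot shapes.
#' @param n integer vector of length 2, group sizes (girls, boys).
#' @param missing_rate MCAR missingness proportion per cell (default 0.015,
#'   matching "less than 2 percent" item missingness).
#' @return object of class \code{population_spec}.
#' @export
make_population_spec <- function(preset = c("table2_full", "no_dif", "custom"),
                                 overrides = list(),
                                 n = c(sdq_published_n()$n_girls,
                                       sdq_published_n()$n_boys),
                                 missing_rate = 0.015) {
  preset <- match.arg(preset)
  tab <- sdq_published_loadings()
  phi <- sdq_published_phi()
  mods <- sdq_published_modifications()
  cross <- mods$cross_loading_value
  if (!is.null(overrides$cross_loading)) cross <- overrides$cross_loading

  prim_g <- tab$loading_g
  tau_g <- cbind(tab$t1_g, tab$t2_g)
  rownames(tau_g) <- tab$item_id
  colnames(tau_g) <- c("t1", "t2")
  if (preset == "table2_full") {
    prim_b <- ifelse(tab$dif, tab$loading_b, tab$loading_g)
    tau_b <- cbind(ifelse(tab$dif, tab$t1_b, tab$t1_g),
                   ifelse(tab$dif, tab$t2_b, tab$t2_g))
    Phi2 <- phi$boys
    kappa2 <- sdq_published_latent_means()$kappa_dif
  } else {
    prim_b <- prim_g
    tau_b <- tau_g
    Phi2 <- if (preset == "no_dif") phi$girls else phi$girls
    kappa2 <- rep(0, 5)
  }
  dimnames(tau_b) <- dimnames(tau_g)

  spec <- list(
    preset = preset,
    Lambda = list(.build_lambda(prim_g, cross), .build_lambda(prim_b, cross)),
    tau = list(tau_g, tau_b),
    Phi = list(phi$girls, Phi2),
    kappa = list(rep(0, 5), kappa2),
    residual_cor = mods$residual_cor,
    n = as.integer(n),
    missing_rate = missing_rate,
    group_labels = c("girls", "boys")
  )
  names(spec$kappa[[1]]) <- names(spec$kappa[[2]]) <- sdq_scales()

  for (nm in setdiff(names(overrides), "cross_loading")) {
    if (!nm %in% names(spec)) stop("unknown override slot: ", nm)
    spec[[nm]] <- overrides[[nm]]
  }
  spec$n <- as.integer(spec$n)
  class(spec) <- "population_spec"
  .validate_spec(spec)
}

#' @export
print.population_spec <- function(x, ...) {
  cat("population_spec (preset ", x$preset, "): n = ",
      paste(x$n, collapse = "/"), ", missing rate ", x$missing_rate, "\n",
      sep = "")
  invisible(x)
}

#' Inject differential item functioning into group 2
#'
#' Shifts the group-2 primary loading and both thresholds of one item by
#' stated amounts, revalidating the spec.
#'
#' @param spec a \code{population_spec}.
#' @param item item id.
#' @param d_loading additive shift of the group-2 primary loading.
#' @param d_threshold additive shift applied to both group-2 thresholds.
#' @return modified \code{population_spec}.
#' @export
inject_dif <- function(spec, item, d_loading = 0, d_threshold = 0) {
  meta <- sdq_item_meta()
  if (!item %in% meta$item_id) stop("unknown item: ", item)
  f <- match(meta$scale[meta$item_id == item], sdq_scales())
  spec$Lambda[[2]][item, f] <- spec$Lambda[[2]][item, f] + d_loading
  spec$tau[[2]][item, ] <- spec$tau[[2]][item, ] + d_threshold
  .validate_spec(spec)
}

#' Model-implied latent-response correlation matrix of a population spec
#'
#' The correlation matrix of the latent responses for one group,
#' \eqn{\Lambda\Phi\Lambda' + \Theta} normalized to unit diagonal — the
#' generator's association structure and the engine's consistency oracle.
#'
#' @param spec a \code{population_spec}.
#' @param group 1 (reference) or 2.
#' @return 25 x 25 correlation matrix.
#' @export
spec_implied_corr <- function(spec, group = 1L) {
  L <- spec$Lambda[[group]]
  Phi <- spec$Phi[[group]]
  Th <- .build_theta(L, Phi, spec$residual_cor)
  S <- L %*% Phi %*% t(L) + Th
  ## unit variance holds by construction for unit factor variances; normalize
  ## so the function is exact for arbitrary Phi diagonals too
  stats::cov2cor(S)
}

#' Simulate ordinal item responses from a population spec
#'
#' Deterministic under (\code{spec}, \code{seed}).  Latent responses are
#' standardized within group; missingness is MCAR at \code{spec$missing_rate}.
#'
#' @param spec a \code{population_spec}.
#' @param seed integer seed.
#' @return an \code{\link{sdq_matrix}}.
#' @export
simulate_responses <- function(spec, seed = 1L) {
  set.seed(as.integer(seed))
  out <- vector("list", 2L)
  for (g in 1:2) {
    n <- spec$n[g]
    L <- spec$Lambda[[g]]
    Phi <- spec$Phi[[g]]
    Th <- .build_theta(L, Phi, spec$residual_cor)
    eta <- rmvn(n, spec$kappa[[g]], Phi)
    eps <- rmvn(n, rep(0, 25L), Th)
    ystar <- eta %*% t(L) + eps
    tau <- spec$tau[[g]]
    resp <- (ystar > matrix(tau[, 1], n, 25L, byrow = TRUE)) +
            (ystar > matrix(tau[, 2], n, 25L, byrow = TRUE))
    colnames(resp) <- rownames(L)
    ## the generative thresholds/loadings live on the reversed (problem-
    ## direction) scale; emit raw-wording responses so downstream scoring
    ## and modeling apply the reversal themselves
    resp <- reverse_items(resp)
    if (spec$missing_rate > 0) {
      miss <- matrix(runif(n * 25L) < spec$missing_rate, n, 25L)
      resp[miss] <- NA
    }
    out[[g]] <- resp
  }
  sdq_matrix(rbind(out[[1]], out[[2]]),
             rep(spec$group_labels, spec$n))
}
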
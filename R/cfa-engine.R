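## Ordinal CFA engine: diagonally weighted least squares on polychoric
## moments (thresholds + correlations) under the delta parameterization,
## with mean-and-variance adjusted (scaled-and-shifted) test statistics.
##
## Conventions (reference group = group 1):
##   group 1: latent-response variances 1, factor variances 1, latent means 0;
##   group 2 (constrained rungs): loadings/thresholds equated to group 1
##     except for explicitly freed (DIF) items; free latent means kappa_2,
##     free factor covariance matrix Phi_2, free scale factors delta_2
##     (fixed to 1 for freed items, as identification requires);
##   residual correlations are standardized residual correlations, free per
##     group, never equated by the invariance ladder.

#' Five-factor SDQ model specification
#'
#' @param cross_loading include the tantrum-emotion cross-loading.
#' @param residual_cors include the restless-fidgety and distractible-attends
#'   residual correlations.
#' @return object of class \code{sdq_model_spec}.
#' @export
sdq_model_spec <- function(cross_loading = TRUE, residual_cors = TRUE) {
  meta <- sdq_item_meta()
  cross <- if (cross_loading)
    data.frame(item = "tantrum", factor = "emotion", stringsAsFactors = FALSE)
  else data.frame(item = character(), factor = character())
  resid <- if (residual_cors)
    data.frame(item1 = c("restless", "distractible"),
               item2 = c("fidgety", "attends"), stringsAsFactors = FALSE)
  else data.frame(item1 = character(), item2 = character())
  structure(list(items = meta$item_id, factors = sdq_scales(),
                 primary = match(meta$scale, sdq_scales()),
                 cross = cross, resid = resid),
            class = "sdq_model_spec")
}

## ---------------------------------------------------------------------------
## parameter templates

.lam_positions <- function(mspec) {
  p <- length(mspec$items)
  rows <- seq_len(p); cols <- mspec$primary
  nm <- paste0("lam_", mspec$items)
  if (nrow(mspec$cross)) {
    rows <- c(rows, match(mspec$cross$item, mspec$items))
    cols <- c(cols, match(mspec$cross$factor, mspec$factors))
    nm <- c(nm, paste0("cross_", mspec$cross$item, "_", mspec$cross$factor))
  }
  list(rows = rows, cols = cols, names = nm)
}

.pairs_layout <- function(p) {
  ut <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  ut[order(ut[, 2], ut[, 1]), , drop = FALSE]
}

## template for a single standardized group (also one configural group)
.ctx_single <- function(mspec, tau_start) {
  p <- length(mspec$items); q <- length(mspec$factors)
  lp <- .lam_positions(mspec)
  nlam <- length(lp$names)
  phi_pairs <- .pairs_layout(q)
  nphi <- nrow(phi_pairs)
  nres <- nrow(mspec$resid)
  blocks <- list(
    lam = list(n = nlam, lower = -5, upper = 5,
               start = rep(0.5, nlam), names = lp$names),
    phi = list(n = nphi, lower = -0.95, upper = 0.95, start = rep(0, nphi),
               names = paste0("phi_", mspec$factors[phi_pairs[, 1]], "_",
                              mspec$factors[phi_pairs[, 2]])),
    res = list(n = nres, lower = -0.95, upper = 0.95, start = rep(0, nres),
               names = if (nres) paste0("rescor_", mspec$resid$item1, "_",
                                        mspec$resid$item2) else character())
  )
  ctx <- list(kind = "single", mspec = mspec, p = p, q = q, lp = lp,
              phi_pairs = phi_pairs, blocks = blocks, tau = tau_start)
  ctx$pair_idx <- .pairs_layout(p)
  ctx$pair_lin <- (ctx$pair_idx[, 2] - 1L) * p + ctx$pair_idx[, 1]
  ctx$resid_pair_pos <- if (nres) vapply(seq_len(nres), function(r) {
    i <- match(mspec$resid$item1[r], mspec$items)
    j <- match(mspec$resid$item2[r], mspec$items)
    which(ctx$pair_idx[, 1] == min(i, j) & ctx$pair_idx[, 2] == max(i, j))
  }, integer(1)) else integer()
  ctx$resid_items <- cbind(match(mspec$resid$item1, mspec$items),
                           match(mspec$resid$item2, mspec$items))
  ctx <- .finalize_ctx(ctx)
  ctx
}

.finalize_ctx <- function(ctx) {
  ns <- vapply(ctx$blocks, function(b) b$n, integer(1))
  off <- cumsum(c(0L, ns))
  ctx$index <- lapply(seq_along(ctx$blocks), function(i)
    if (ns[i]) (off[i] + 1L):(off[i] + ns[i]) else integer())
  names(ctx$index) <- names(ctx$blocks)
  ctx$npar <- sum(ns)
  ctx$lower <- unlist(lapply(ctx$blocks, function(b) rep(b$lower, b$n)))
  ctx$upper <- unlist(lapply(ctx$blocks, function(b) rep(b$upper, b$n)))
  ctx$start <- unlist(lapply(ctx$blocks, function(b) b$start))
  ctx$par_names <- unlist(lapply(ctx$blocks, function(b) b$names))
  names(ctx$start) <- ctx$par_names
  ctx
}

## implied correlation vector (canonical pair order) for one standardized
## group; returns list(sigma_corr, penalty, heywood, theta, v)
.implied_corr_std <- function(L, Phi, res_r, ctx) {
  A <- L %*% Phi %*% t(L)
  comm <- diag(A)
  theta <- 1 - comm
  pen <- 0; hey <- FALSE
  low <- theta < 1e-4
  if (any(low)) {
    pen <- pen + 1e3 * sum((1e-4 - theta[low])^2)
    theta[low] <- 1e-4
    hey <- TRUE
  }
  v <- comm + theta
  sv <- sqrt(v)
  sig <- A[ctx$pair_lin] / (sv[ctx$pair_idx[, 1]] * sv[ctx$pair_idx[, 2]])
  if (length(ctx$resid_pair_pos)) {
    ii <- ctx$resid_items[, 1]; jj <- ctx$resid_items[, 2]
    sig[ctx$resid_pair_pos] <- sig[ctx$resid_pair_pos] +
      res_r * sqrt(theta[ii] * theta[jj]) / (sv[ii] * sv[jj])
  }
  list(sigma = sig, penalty = pen, heywood = hey, theta = theta, v = v)
}

.phi_from_par <- function(phi_par, ctx) {
  Phi <- diag(ctx$q)
  Phi[ctx$phi_pairs] <- phi_par
  Phi[ctx$phi_pairs[, c(2, 1), drop = FALSE]] <- phi_par
  Phi
}

.pd_penalty <- function(Phi) {
  ev <- min(eigen((Phi + t(Phi)) / 2, symmetric = TRUE,
                  only.values = TRUE)$values)
  if (ev < 1e-4) 1e3 * (1e-4 - ev)^2 else 0
}

## sigma for a single standardized group: thresholds pass through
.sigma_single <- function(par, ctx) {
  L <- matrix(0, ctx$p, ctx$q)
  L[cbind(ctx$lp$rows, ctx$lp$cols)] <- par[ctx$index$lam]
  Phi <- .phi_from_par(par[ctx$index$phi], ctx)
  pen <- .pd_penalty(Phi)
  ic <- .implied_corr_std(L, Phi, par[ctx$index$res], ctx)
  list(sigma = c(as.vector(t(ctx$tau)), ic$sigma),
       penalty = pen + ic$penalty, heywood = ic$heywood)
}

## ---------------------------------------------------------------------------
## multigroup constrained template (strong / partial / structural rungs)

.ctx_multigroup <- function(mspec, tau_start, free_items = character(),
                            structural = FALSE,
                            free_cov = data.frame(f1 = character(),
                                                  f2 = character())) {
  p <- length(mspec$items); q <- length(mspec$factors)
  lp <- .lam_positions(mspec)
  nlam <- length(lp$names)
  phi_pairs <- .pairs_layout(q)
  nphi <- nrow(phi_pairs)
  nres <- nrow(mspec$resid)
  free_idx <- match(free_items, mspec$items)
  if (anyNA(free_idx)) stop("unknown freed item(s)")
  nfree <- length(free_idx)
  delta_items <- setdiff(seq_len(p), free_idx)

  cov_free_rows <- integer()
  if (structural && nrow(free_cov)) {
    cov_free_rows <- vapply(seq_len(nrow(free_cov)), function(r) {
      i <- match(free_cov$f1[r], mspec$factors)
      j <- match(free_cov$f2[r], mspec$factors)
      which(phi_pairs[, 1] == min(i, j) & phi_pairs[, 2] == max(i, j))
    }, integer(1))
  }
  ncov2 <- if (structural) length(cov_free_rows) else nphi

  blocks <- list(
    lam = list(n = nlam, lower = -5, upper = 5, start = rep(0.5, nlam),
               names = lp$names),
    lam2 = list(n = nfree, lower = -5, upper = 5, start = rep(0.5, nfree),
                names = if (nfree) paste0("lam2_", free_items) else character()),
    tau = list(n = 2L * p, lower = -8, upper = 8,
               start = as.vector(t(tau_start)),
               names = paste0(rep(mspec$items, each = 2), "|t", 1:2)),
    tau2 = list(n = 2L * nfree, lower = -8, upper = 8,
                start = if (nfree) as.vector(t(tau_start[free_idx, , drop = FALSE]))
                        else numeric(),
                names = if (nfree) paste0(rep(free_items, each = 2), "|t", 1:2, "_g2")
                        else character()),
    res1 = list(n = nres, lower = -0.95, upper = 0.95, start = rep(0, nres),
                names = if (nres) paste0("rescor1_", mspec$resid$item1) else character()),
    res2 = list(n = nres, lower = -0.95, upper = 0.95, start = rep(0, nres),
                names = if (nres) paste0("rescor2_", mspec$resid$item1) else character()),
    phi1 = list(n = nphi, lower = -0.95, upper = 0.95, start = rep(0, nphi),
                names = paste0("phi1_", phi_pairs[, 1], "_", phi_pairs[, 2])),
    logvar2 = list(n = q, lower = -2, upper = 2, start = rep(0, q),
                   names = paste0("logvar2_", mspec$factors)),
    cov2 = list(n = ncov2, lower = -3, upper = 3, start = rep(0, ncov2),
                names = if (ncov2) paste0("cov2_", seq_len(ncov2))
                        else character()),
    kappa2 = list(n = q, lower = -3, upper = 3, start = rep(0, q),
                  names = paste0("kappa2_", mspec$factors)),
    logdelta2 = list(n = length(delta_items), lower = -1.5, upper = 1.5,
                     start = rep(0, length(delta_items)),
                     names = paste0("logdelta2_", mspec$items[delta_items]))
  )
  ctx <- list(kind = "multigroup", mspec = mspec, p = p, q = q, lp = lp,
              phi_pairs = phi_pairs, blocks = blocks,
              free_idx = free_idx, free_items = free_items,
              delta_items = delta_items, structural = structural,
              cov_free_rows = cov_free_rows)
  ctx$pair_idx <- .pairs_layout(p)
  ctx$pair_lin <- (ctx$pair_idx[, 2] - 1L) * p + ctx$pair_idx[, 1]
  ctx$resid_pair_pos <- if (nres) vapply(seq_len(nres), function(r) {
    i <- match(mspec$resid$item1[r], mspec$items)
    j <- match(mspec$resid$item2[r], mspec$items)
    which(ctx$pair_idx[, 1] == min(i, j) & ctx$pair_idx[, 2] == max(i, j))
  }, integer(1)) else integer()
  ctx$resid_items <- cbind(match(mspec$resid$item1, mspec$items),
                           match(mspec$resid$item2, mspec$items))
  .finalize_ctx(ctx)
}

## implied stacked sigma (group1 thresholds, group1 corrs, group2 thresholds,
## group2 corrs) for the constrained multigroup template.
## `perturb` supports modification-index Jacobians: a list with either
## item = index, dlam, dtau (length 2) applied to the group-2 copy of a
## constrained item (its scale factor kept at the current estimate), or
## cov_row = row of phi_pairs, dcov applied to the group-2 covariance.
.sigma_multigroup <- function(par, ctx, perturb = NULL) {
  p <- ctx$p; q <- ctx$q
  ix <- ctx$index
  L1 <- matrix(0, p, q)
  L1[cbind(ctx$lp$rows, ctx$lp$cols)] <- par[ix$lam]
  Phi1 <- .phi_from_par(par[ix$phi1], ctx)
  pen <- .pd_penalty(Phi1)
  tau <- matrix(par[ix$tau], p, 2L, byrow = TRUE)

  ic1 <- .implied_corr_std(L1, Phi1, par[ix$res1], ctx)
  sig1 <- c(as.vector(t(tau)), ic1$sigma)

  ## group 2
  L2 <- L1
  tau2 <- tau
  if (length(ctx$free_idx)) {
    L2[cbind(ctx$free_idx, ctx$mspec$primary[ctx$free_idx])] <- par[ix$lam2]
    tau2[ctx$free_idx, ] <- matrix(par[ix$tau2], length(ctx$free_idx), 2L,
                                   byrow = TRUE)
  }
  if (!is.null(perturb) && !is.null(perturb$item)) {
    i <- perturb$item
    L2[i, ctx$mspec$primary[i]] <- L2[i, ctx$mspec$primary[i]] + perturb$dlam
    tau2[i, ] <- tau2[i, ] + perturb$dtau
  }
  var2 <- exp(par[ix$logvar2])
  Phi2 <- diag(var2)
  sdv <- sqrt(var2)
  if (ctx$structural) {
    cov2 <- par[ix$phi1]                      # equated covariances
    if (length(ctx$cov_free_rows)) cov2[ctx$cov_free_rows] <- par[ix$cov2]
  } else cov2 <- par[ix$cov2]
  if (!is.null(perturb) && !is.null(perturb$cov_row))
    cov2[perturb$cov_row] <- cov2[perturb$cov_row] + perturb$dcov
  Phi2[ctx$phi_pairs] <- cov2
  Phi2[ctx$phi_pairs[, c(2, 1), drop = FALSE]] <- cov2
  pen <- pen + .pd_penalty(stats::cov2cor(Phi2))

  A2 <- L2 %*% Phi2 %*% t(L2)
  comm2 <- diag(A2)
  v2 <- rep(1, p)
  v2[ctx$delta_items] <- exp(-2 * par[ix$logdelta2])
  theta2 <- v2 - comm2
  hey <- ic1$heywood
  low <- theta2 < 1e-4
  if (any(low)) {
    pen <- pen + 1e3 * sum((1e-4 - theta2[low])^2)
    theta2[low] <- 1e-4
    v2 <- comm2 + theta2
    hey <- TRUE
  }
  sv2 <- sqrt(v2)
  sig_corr2 <- A2[ctx$pair_lin] /
    (sv2[ctx$pair_idx[, 1]] * sv2[ctx$pair_idx[, 2]])
  if (length(ctx$resid_pair_pos)) {
    ii <- ctx$resid_items[, 1]; jj <- ctx$resid_items[, 2]
    sig_corr2[ctx$resid_pair_pos] <- sig_corr2[ctx$resid_pair_pos] +
      par[ix$res2] * sqrt(theta2[ii] * theta2[jj]) / (sv2[ii] * sv2[jj])
  }
  mu2 <- as.vector(L2 %*% par[ix$kappa2])
  tau2_std <- (tau2 - mu2) / sv2
  sig2 <- c(as.vector(t(tau2_std)), sig_corr2)

  list(sigma = c(sig1, sig2), penalty = pen, heywood = hey)
}

## ---------------------------------------------------------------------------
## DWLS core

## weights: inverse diagonal of Gamma (per-moment asymptotic variances of
## sqrt(n_g) * s_g); zero/negative guarded
.dwls_weights <- function(ps) {
  d <- diag(ps$Gamma)
  d[d < 1e-10] <- 1e-10
  1 / d
}

.fit_nlminb <- function(obj, start, lower, upper) {
  fit <- nlminb(start, obj, lower = lower, upper = upper,
                control = list(iter.max = 1000L, eval.max = 4000L,
                               rel.tol = 1e-12))
  g <- .num_grad(obj, fit$par)
  list(par = fit$par, objective = fit$objective,
       iterations = fit$iterations, convergence = fit$convergence,
       grad_norm = max(abs(g)))
}

.num_grad <- function(f, x, h = 1e-6) {
  f0 <- f(x)
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + h
    (f(xp) - f0) / h
  }, numeric(1))
}

## numeric forward-difference Jacobian of sigma(par)
.num_jacobian <- function(sig_fun, par, h = 1e-6) {
  s0 <- sig_fun(par)
  J <- matrix(0, length(s0), length(par))
  for (i in seq_along(par)) {
    pp <- par; pp[i] <- pp[i] + h
    J[, i] <- (sig_fun(pp) - s0) / h
  }
  J
}

## mean-and-variance adjusted (scaled-and-shifted) statistic for a stacked
## multigroup DWLS system.  s, sigma, w are stacked; Gamma_star and W_star are
## the stacked (block) matrices described below.
.robust_stat <- function(T_naive, df, J, W_star, Gamma_star) {
  WJ <- W_star * J                       # W diagonal: elementwise scaling
  A <- crossprod(J, WJ)                  # J' W J
  B <- crossprod(WJ, Gamma_star)         # J' W Gamma
  WG <- W_star * Gamma_star              # W Gamma (rowwise scaling)
  M <- WG - WJ %*% solve(A, B)
  trM <- sum(diag(M))
  trM2 <- sum(M * t(M))
  c1 <- sqrt(df / trM2)
  T_ms <- c1 * T_naive + (df - c1 * trM)
  list(T_ms = T_ms, trM = trM, trM2 = trM2, shift = df - c1 * trM, scale = c1)
}

## assemble stacked sample/weight/Gamma pieces from per-group summaries;
## corr_only drops the threshold moments (exact for models in which the
## thresholds are just-identified, where their statistic contribution is zero)
.stack_groups <- function(ps_list, corr_only = FALSE) {
  n <- sum(vapply(ps_list, function(x) x$n, numeric(1)))
  keep <- lapply(ps_list, function(ps)
    if (corr_only) which(ps$layout$type == "correlation")
    else seq_len(nrow(ps$layout)))
  s <- unlist(Map(function(ps, k) moment_vector(ps)[k], ps_list, keep))
  w_blocks <- Map(function(ps, k) .dwls_weights(ps)[k], ps_list, keep)
  frac <- vapply(ps_list, function(x) x$n, numeric(1)) / n
  ## F = sum_g (n_g/n) (s_g - sig_g)' W_g (s_g - sig_g)  =>  stacked diag
  w_star <- unlist(Map(function(w, f) w * f, w_blocks, frac))
  ## Gamma* = blockdiag(Gamma_g * n/n_g): cov of sqrt(n) * s_g
  nm <- vapply(keep, length, integer(1))
  Gs <- matrix(0, sum(nm), sum(nm))
  off <- cumsum(c(0L, nm))
  for (g in seq_along(ps_list))
    Gs[(off[g] + 1L):off[g + 1L], (off[g] + 1L):off[g + 1L]] <-
      ps_list[[g]]$Gamma[keep[[g]], keep[[g]]] / frac[g]
  list(n = n, s = s, w_star = w_star, Gamma_star = Gs, frac = frac)
}

.make_objective <- function(sig_fun_pen, s, w_star) {
  function(par) {
    sp <- sig_fun_pen(par)
    r <- s - sp$sigma
    sum(w_star * r * r) + sp$penalty
  }
}

## shared post-fit computation
.finish_fit <- function(opt, sig_fun_pen, stack, ctx, df, mspec, ps_list,
                        label) {
  sp <- sig_fun_pen(opt$par)
  r <- stack$s - sp$sigma
  F_val <- sum(stack$w_star * r * r)
  T_naive <- stack$n * F_val
  sig_only <- function(par) sig_fun_pen(par)$sigma
  J <- .num_jacobian(sig_only, opt$par)
  rs <- .robust_stat(T_naive, df, J, stack$w_star, stack$Gamma_star)
  ## sandwich covariance of parameter estimates:
  ## acov = (J'WJ)^{-1} J'W Gamma* W J (J'WJ)^{-1} / n
  WJ <- stack$w_star * J
  A <- crossprod(J, WJ)
  Bm <- crossprod(WJ, stack$Gamma_star) %*% WJ
  Ainv <- solve(A)
  vc <- Ainv %*% Bm %*% Ainv / stack$n
  dimnames(vc) <- list(ctx$par_names, ctx$par_names)
  par <- setNames(opt$par, ctx$par_names)
  structure(list(label = label, par = par, se = sqrt(pmax(diag(vc), 0)),
                 vcov = vc, sigma = sp$sigma, resid = r,
                 discrepancy = F_val, T_naive = T_naive, T_ms = rs$T_ms,
                 df = df, trM = rs$trM, trM2 = rs$trM2,
                 n = stack$n, n_groups = length(ps_list),
                 converged = opt$convergence == 0L || opt$grad_norm < 1e-4,
                 iterations = opt$iterations, grad_norm = opt$grad_norm,
                 heywood = sp$heywood, ctx = ctx, stack = stack,
                 J = J, mspec = mspec, ps_list = ps_list),
            class = "sdq_fit")
}

#' @export
print.sdq_fit <- function(x, ...) {
  cat("ordinal CFA fit (", x$label, "): ", x$n_groups, " group(s), n = ",
      x$n, "\n", sep = "")
  cat(sprintf("  WLSMV T = %.2f, df = %d; discrepancy = %.6f; %s\n",
              x$T_ms, x$df, x$discrepancy,
              if (x$converged) "converged" else "NOT CONVERGED"))
  if (x$heywood) cat("  note: residual variance hit the 1e-4 soft bound\n")
  invisible(x)
}

#' Fit the ordinal factor model to one group by DWLS
#'
#' Thresholds are just-identified in a single standardized group, so the fit
#' is driven by the polychoric correlations; the threshold moments are carried
#' through for the test-statistic bookkeeping.
#'
#' @param ps a \code{\link{polychoric_matrix}} summary with \code{acov="full"}.
#' @param mspec an \code{\link{sdq_model_spec}}.
#' @param start optional named start vector.
#' @return an \code{sdq_fit}.
#' @export
fit_dwls <- function(ps, mspec = sdq_model_spec(), start = NULL) {
  if (is.null(ps$Gamma)) stop("polychoric summary must carry acov='full'")
  ctx <- .ctx_single(mspec, ps$thresholds)
  ## thresholds are just-identified here: fit and test on correlations only
  ## (equivalent to the full system in which the threshold block of the
  ## residual-weighting operator vanishes exactly)
  stack <- .stack_groups(list(ps), corr_only = TRUE)
  sig_fun <- function(par) {
    sp <- .sigma_single(par, ctx)
    sp$sigma <- sp$sigma[-seq_len(2L * ctx$p)]
    sp
  }
  obj <- .make_objective(sig_fun, stack$s, stack$w_star)
  s0 <- ctx$start
  if (!is.null(start)) s0[names(start)] <- start
  opt <- .fit_nlminb(obj, s0, ctx$lower, ctx$upper)
  ## df bookkeeping on the full moment set: thresholds are free parameters
  nmom <- length(stack$s) + 2L * ctx$p
  npar_eff <- ctx$npar + 2L * ctx$p
  df <- as.integer(nmom - npar_eff)
  .finish_fit(opt, sig_fun, stack, ctx, df, mspec, list(ps), "single-group")
}

#' Baseline (independence) model statistic
#'
#' Zero correlations, free thresholds, per group; the reference model for
#' incremental fit indices.
#'
#' @param ps_list list of polychoric summaries (one per group).
#' @return list with \code{T_ms}, \code{df}, \code{T_naive}.
#' @export
fit_baseline <- function(ps_list) {
  if (inherits(ps_list, "polychoric_summary")) ps_list <- list(ps_list)
  n <- sum(vapply(ps_list, function(x) x$n, numeric(1)))
  T_naive <- 0; trM <- 0; trM2 <- 0; df <- 0L
  for (ps in ps_list) {
    idx <- which(ps$layout$type == "correlation")
    s <- moment_vector(ps)[idx]
    w <- .dwls_weights(ps)[idx]
    frac <- ps$n / n
    T_naive <- T_naive + n * frac * sum(w * s * s)
    ## no free parameters touch the correlations: U = W on the corr block
    M <- (w * frac) * ps$Gamma[idx, idx] / frac
    trM <- trM + sum(diag(M))
    trM2 <- trM2 + sum(M * t(M))
    df <- df + length(idx)
  }
  c1 <- sqrt(df / trM2)
  list(T_ms = c1 * T_naive + (df - c1 * trM), df = df, T_naive = T_naive)
}

#' Robust fit indices
#'
#' CFI, TLI, RMSEA (with 90\% CI by noncentrality root finding) from the
#' mean-and-variance adjusted statistics of a fitted and a baseline model.
#' For multigroup fits the RMSEA uses the sqrt(G) convention.
#'
#' @param fit an \code{sdq_fit} (or list with \code{T_ms}, \code{df},
#'   \code{n}, \code{n_groups}).
#' @param baseline result of \code{\link{fit_baseline}} on the same sample.
#' @return data.frame row: \code{chi2}, \code{df}, \code{cfi}, \code{tli},
#'   \code{rmsea}, \code{rmsea_lo}, \code{rmsea_hi}.
#' @export
fit_indices <- function(fit, baseline) {
  Tm <- fit$T_ms; dfm <- fit$df
  T0 <- baseline$T_ms; df0 <- baseline$df
  N <- fit$n
  G <- if (!is.null(fit$n_groups)) fit$n_groups else 1L
  num <- max(Tm - dfm, 0)
  den <- max(T0 - df0, Tm - dfm, 0)
  cfi <- if (den > 0) 1 - num / den else 1
  tli <- if (df0 > 0 && dfm > 0 && (T0 / df0 - 1) != 0)
    ((T0 / df0) - (Tm / dfm)) / ((T0 / df0) - 1) else NA_real_
  if (dfm > 0) {
    rmsea <- sqrt(G) * sqrt(max(Tm - dfm, 0) / (dfm * (N - 1)))
    ci <- .rmsea_ci(Tm, dfm, N, G)
  } else {
    rmsea <- 0; ci <- c(0, 0)
  }
  data.frame(chi2 = Tm, df = dfm, cfi = cfi, tli = tli,
             rmsea = rmsea, rmsea_lo = ci[1], rmsea_hi = ci[2])
}

.rmsea_ci <- function(Tm, dfm, N, G, level = 0.90) {
  a <- (1 - level) / 2
  f_lo <- function(ncp) pchisq(Tm, dfm, ncp) - (1 - a)
  f_hi <- function(ncp) pchisq(Tm, dfm, ncp) - a
  lo <- if (f_lo(0) < 0) 0 else uniroot(f_lo, c(0, max(Tm, 1)),
                                        extendInt = "downX")$root
  hi <- if (f_hi(0) < 0) 0 else uniroot(f_hi, c(0, max(Tm * 2, 1)),
                                        extendInt = "downX")$root
  sqrt(G) * sqrt(c(lo, hi) / (dfm * (N - 1)))
}

#' Model-implied moments of the five-factor model
#'
#' Returns the implied latent-response correlation matrix under the delta
#' parameterization (\eqn{\Sigma = D(\Lambda\Phi\Lambda' + \Theta)D} with unit
#' diagonal) plus pass-through thresholds for one standardized group.
#'
#' @param params list with \code{Lambda} (25 x 5 matrix; or \code{primary}
#'   25-vector plus \code{cross} scalar), \code{Phi} (5 x 5),
#'   \code{residual_cor} (values for the model's residual pairs, standardized),
#'   \code{tau} (25 x 2).
#' @param mspec an \code{\link{sdq_model_spec}}.
#' @return list: \code{corr} (25 x 25), \code{thresholds} (25 x 2).
#' @export
implied_moments <- function(params, mspec = sdq_model_spec()) {
  p <- length(mspec$items)
  if (!is.null(params$Lambda)) L <- params$Lambda
  else {
    L <- matrix(0, p, length(mspec$factors))
    L[cbind(seq_len(p), mspec$primary)] <- params$primary
    if (nrow(mspec$cross))
      L[cbind(match(mspec$cross$item, mspec$items),
              match(mspec$cross$factor, mspec$factors))] <- params$cross
  }
  ctx <- .ctx_single(mspec, params$tau)
  res_r <- if (nrow(mspec$resid)) params$residual_cor else numeric()
  ic <- .implied_corr_std(L, params$Phi, res_r, ctx)
  S <- diag(p)
  S[ctx$pair_lin] <- ic$sigma
  S[lower.tri(S)] <- t(S)[lower.tri(S)]
  dimnames(S) <- list(mspec$items, mspec$items)
  list(corr = S, thresholds = params$tau)
}
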
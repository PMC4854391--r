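## Gender measurement-invariance ladder:
## configural -> strong (loadings + thresholds equated) -> partial-invariance
## search by tandem modification-index freeing -> structural equivalence of
## latent covariances -> latent means.
## Invariance decisions use the drop in CFI relative to the configural model
## (delta-CFI rule, cutoff 0.002 by default).

.ps_per_group <- function(data, acov = "full") {
  lapply(levels(data$group), function(g)
    polychoric_matrix(data, group = g, acov = acov))
}

#' Configural multigroup fit
#'
#' Same factor structure in both groups, all parameters free: equivalent to
#' independent single-group DWLS fits, with a joint mean-and-variance adjusted
#' statistic.
#'
#' @param data an \code{\link{sdq_matrix}} (first group level = reference), or
#'   \code{NULL} if \code{ps_list} is supplied.
#' @param mspec an \code{\link{sdq_model_spec}}.
#' @param ps_list optional precomputed list of per-group polychoric summaries.
#' @return object of class \code{sdq_mg_fit}: per-group \code{sdq_fit}s plus
#'   joint statistic, df and fit indices.
#' @export
fit_configural <- function(data = NULL, mspec = sdq_model_spec(),
                           ps_list = NULL) {
  if (is.null(ps_list)) ps_list <- .ps_per_group(data)
  if (length(ps_list) != 2L) stop("two groups required")
  fits <- lapply(ps_list, fit_dwls, mspec = mspec)
  T_naive <- sum(vapply(fits, function(f) f$T_naive, numeric(1)))
  trM <- sum(vapply(fits, function(f) f$trM, numeric(1)))
  trM2 <- sum(vapply(fits, function(f) f$trM2, numeric(1)))
  df <- as.integer(sum(vapply(fits, function(f) f$df, numeric(1))))
  c1 <- sqrt(df / trM2)
  T_ms <- c1 * T_naive + (df - c1 * trM)
  n <- sum(vapply(ps_list, function(x) x$n, numeric(1)))
  baseline <- fit_baseline(ps_list)
  out <- structure(list(label = "configural", groups = fits,
                        ps_list = ps_list, mspec = mspec,
                        T_naive = T_naive, T_ms = T_ms, df = df,
                        trM = trM, trM2 = trM2, n = n, n_groups = 2L,
                        baseline = baseline,
                        converged = all(vapply(fits, function(f) f$converged,
                                               logical(1)))),
                   class = c("sdq_mg_fit"))
  out$indices <- fit_indices(out, baseline)
  out
}

#' @export
print.sdq_mg_fit <- function(x, ...) {
  cat("multigroup ordinal CFA (", x$label, "): n = ", x$n, "\n", sep = "")
  cat(sprintf("  WLSMV T = %.2f, df = %d, CFI = %.4f, RMSEA = %.4f\n",
              x$T_ms, x$df, x$indices$cfi, x$indices$rmsea))
  invisible(x)
}

#' Constrained multigroup fit
#'
#' Joint two-group DWLS fit with loadings and thresholds equated across
#' groups except for \code{free_items}; group-2 latent means, factor
#' covariances and scale factors free (scale factors of freed items fixed to
#' 1).  With \code{structural = TRUE} the factor covariances are additionally
#' equated except for the pairs in \code{free_cov}.
#'
#' @param ps_list list of two per-group polychoric summaries (reference
#'   first) from \code{\link{polychoric_matrix}} with \code{acov = "full"}.
#' @param mspec an \code{\link{sdq_model_spec}}.
#' @param free_items item ids exempted from the equality constraints.
#' @param structural equate factor covariances across groups.
#' @param free_cov data.frame (\code{f1}, \code{f2}) of factor pairs whose
#'   covariance stays group-specific under \code{structural = TRUE}.
#' @param start optional named start vector (warm start).
#' @param label label stored on the fit.
#' @return an \code{sdq_fit}.
#' @export
fit_multigroup <- function(ps_list, mspec = sdq_model_spec(),
                           free_items = character(), structural = FALSE,
                           free_cov = data.frame(f1 = character(),
                                                 f2 = character()),
                           start = NULL, label = "strong") {
  tau_start <- (ps_list[[1]]$thresholds + ps_list[[2]]$thresholds) / 2
  ctx <- .ctx_multigroup(mspec, tau_start, free_items = free_items,
                         structural = structural, free_cov = free_cov)
  stack <- .stack_groups(ps_list)
  sig_fun <- function(par) .sigma_multigroup(par, ctx)
  obj <- .make_objective(sig_fun, stack$s, stack$w_star)
  s0 <- ctx$start
  if (!is.null(start)) {
    common <- intersect(names(start), ctx$par_names)
    s0[common] <- start[common]
  }
  ## freed structural covariances start from the equated (group-1) values
  if (structural && length(ctx$cov_free_rows))
    s0[ctx$index$cov2] <- s0[ctx$index$phi1][ctx$cov_free_rows]
  opt <- .fit_nlminb(obj, s0, ctx$lower, ctx$upper)
  df <- as.integer(length(stack$s) - ctx$npar)
  fit <- .finish_fit(opt, sig_fun, stack, ctx, df, mspec, ps_list, label)
  fit$free_items <- free_items
  fit$structural <- structural
  fit$free_cov <- free_cov
  fit$baseline <- fit_baseline(ps_list)
  fit$indices <- fit_indices(fit, fit$baseline)
  fit
}

#' Strong (scalar) invariance fit
#'
#' Loadings and thresholds equated across groups; group-2 latent means,
#' factor covariance matrix and scale factors freed (delta parameterization).
#' Residual correlations remain free per group.
#'
#' @param configural an \code{sdq_mg_fit} from \code{\link{fit_configural}}.
#' @param free_items items exempted from the equality constraints (partial
#'   invariance); their group-2 scale factors are fixed to 1.
#' @param cutoff delta-CFI cutoff for the invariance verdict.
#' @return an \code{sdq_fit} with \code{$decision} (delta-CFI, cutoff,
#'   verdict, freed items).
#' @export
constrain_strong <- function(configural, free_items = character(),
                             cutoff = 0.002, start = NULL) {
  fit <- fit_multigroup(configural$ps_list, configural$mspec,
                        free_items = free_items, start = start,
                        label = if (length(free_items)) "partial" else "strong")
  dcfi <- configural$indices$cfi - fit$indices$cfi
  fit$decision <- list(delta_cfi = dcfi, cutoff = cutoff,
                       verdict = if (dcfi <= cutoff) "invariant"
                                 else "non-invariant",
                       freed_items = free_items)
  fit
}

#' Modification indices for constrained item parameters
#'
#' For each candidate item still constrained across groups, the expected
#' improvement in the (n-scaled) discrepancy from freeing its group-2 primary
#' loading and both thresholds in tandem, from the univariate
#' Lagrange-multiplier quadratic approximation at the constrained solution.
#' The optional refit mode frees the candidate, refits, and measures the CFI
#' gain directly (slow; used as the approximation's oracle in tests).
#'
#' @param fit constrained \code{sdq_fit} from \code{\link{constrain_strong}}.
#' @param candidates item ids (default: all constrained items whose factor
#'   keeps at least one other constrained anchor item).
#' @param method \code{"lm"} (quadratic approximation) or \code{"refit"}.
#' @param configural needed for \code{method = "refit"} (delta-CFI gain).
#' @return data.frame sorted by decreasing \code{mi}: \code{item}, \code{mi}.
#' @export
modification_indices <- function(fit, candidates = NULL, method = c("lm", "refit"),
                                 configural = NULL) {
  method <- match.arg(method)
  ctx <- fit$ctx
  if (ctx$kind != "multigroup") stop("need a constrained multigroup fit")
  mspec <- fit$mspec
  constrained <- setdiff(mspec$items, ctx$free_items)
  if (is.null(candidates)) {
    ## anchor guard: never offer the last constrained item of a factor
    keep <- vapply(constrained, function(it) {
      f <- mspec$primary[match(it, mspec$items)]
      others <- constrained[mspec$primary[match(constrained, mspec$items)] == f]
      length(others) > 1L
    }, logical(1))
    candidates <- constrained[keep]
  }
  if (!length(candidates)) return(data.frame(item = character(), mi = numeric()))

  if (method == "refit") {
    if (is.null(configural)) stop("refit mode needs the configural fit")
    mi <- vapply(candidates, function(it) {
      f2 <- fit_multigroup(fit$ps_list, mspec,
                           free_items = c(ctx$free_items, it),
                           structural = ctx$structural,
                           free_cov = fit$free_cov, start = fit$par)
      f2$indices$cfi - fit$indices$cfi
    }, numeric(1))
  } else {
    ## local Lagrange-multiplier approximation: quadratic expansion in the
    ## candidate's group-2 deviations holding the fitted parameters fixed.
    ## (The full Schur-complement version is degenerate here: threshold
    ## shifts proportional to the loadings are exactly absorbable by the
    ## free latent means, so the coupled information is near-singular.)
    r <- fit$resid
    w <- fit$stack$w_star
    s0 <- fit$sigma
    h <- 1e-5
    mi <- vapply(candidates, function(it) {
      i <- match(it, mspec$items)
      Ju <- matrix(0, length(s0), 3L)
      pert <- list(list(item = i, dlam = h, dtau = c(0, 0)),
                   list(item = i, dlam = 0, dtau = c(h, 0)),
                   list(item = i, dlam = 0, dtau = c(0, h)))
      for (k in 1:3)
        Ju[, k] <- (.sigma_multigroup(fit$par, ctx, pert[[k]])$sigma - s0) / h
      g <- -2 * crossprod(Ju, w * r)
      H <- 2 * crossprod(Ju, w * Ju)
      drop(fit$n * 0.5 * t(g) %*% solve(H + diag(1e-10, 3L), g))
    }, numeric(1))
  }
  out <- data.frame(item = candidates, mi = mi, stringsAsFactors = FALSE)
  ## ties broken toward the lower item index (stable order)
  out[order(-out$mi, match(out$item, mspec$items)), , drop = FALSE]
}

#' Partial-invariance search by tandem freeing
#'
#' Fits the strong model; while the CFI drop relative to the configural model
#' exceeds the cutoff, frees the loading and thresholds of the item with the
#' largest modification index and refits.
#'
#' @param data an \code{\link{sdq_matrix}} (or \code{NULL} with
#'   \code{ps_list}).
#' @param mspec an \code{\link{sdq_model_spec}}.
#' @param cutoff delta-CFI cutoff (default 0.002).
#' @param ps_list,configural optional precomputed pieces.
#' @param max_free safety cap on freed items.
#' @param refine_top number of top-MI candidates refitted per iteration; the
#'   one with the largest measured CFI gain is freed.  \code{refine_top = 1}
#'   frees the top-MI item directly.
#' @return list: \code{fit} (final \code{sdq_fit}), \code{decision},
#'   \code{configural}, \code{log} (per-iteration data.frame).
#' @export
partial_invariance_search <- function(data = NULL, mspec = sdq_model_spec(),
                                      cutoff = 0.002, ps_list = NULL,
                                      configural = NULL, max_free = 25L,
                                      refine_top = 4L) {
  if (is.null(configural))
    configural <- fit_configural(data, mspec, ps_list = ps_list)
  freed <- character()
  log <- list()
  fit <- constrain_strong(configural, freed, cutoff)
  repeat {
    log[[length(log) + 1L]] <- data.frame(
      step = length(log) + 1L, n_free = length(freed),
      freed = paste(freed, collapse = ";"),
      cfi = fit$indices$cfi, delta_cfi = fit$decision$delta_cfi,
      stringsAsFactors = FALSE)
    if (fit$decision$delta_cfi <= cutoff || length(freed) >= max_free) break
    mi <- modification_indices(fit)
    if (!nrow(mi)) break
    top <- mi$item[seq_len(min(refine_top, nrow(mi)))]
    if (length(top) == 1L) {
      freed <- c(freed, top)
      fit <- constrain_strong(configural, freed, cutoff, start = fit$par)
    } else {
      ## free the shortlisted item with the largest measured improvement
      trials <- lapply(top, function(it)
        constrain_strong(configural, c(freed, it), cutoff, start = fit$par))
      best <- which.max(vapply(trials, function(f) f$indices$cfi, numeric(1)))
      freed <- c(freed, top[best])
      fit <- trials[[best]]
    }
  }
  fit$decision$freed_items <- freed
  fit$decision$verdict <- if (length(freed) == 0L &&
                              fit$decision$delta_cfi <= cutoff) "invariant"
                          else if (fit$decision$delta_cfi <= cutoff)
                            "partial-invariant" else "non-invariant"
  list(fit = fit, decision = fit$decision, configural = configural,
       log = do.call(rbind, log))
}

## modification indices for the equated factor covariances
.cov_modification_indices <- function(fit) {
  ctx <- fit$ctx
  constrained_rows <- setdiff(seq_len(nrow(ctx$phi_pairs)), ctx$cov_free_rows)
  if (!length(constrained_rows))
    return(data.frame(row = integer(), f1 = character(), f2 = character(),
                      mi = numeric()))
  r <- fit$resid; w <- fit$stack$w_star; s0 <- fit$sigma
  h <- 1e-5
  mi <- vapply(constrained_rows, function(rr) {
    Ju <- (.sigma_multigroup(fit$par, ctx,
                             list(cov_row = rr, dcov = h))$sigma - s0) / h
    g <- -2 * sum(Ju * w * r)
    H <- 2 * sum(Ju * w * Ju)
    fit$n * 0.5 * g^2 / (H + 1e-10)
  }, numeric(1))
  fs <- fit$mspec$factors
  out <- data.frame(row = constrained_rows,
                    f1 = fs[ctx$phi_pairs[constrained_rows, 1]],
                    f2 = fs[ctx$phi_pairs[constrained_rows, 2]],
                    mi = mi, stringsAsFactors = FALSE)
  out[order(-out$mi, out$row), , drop = FALSE]
}

#' Structural equivalence of the latent covariances
#'
#' Starting from the (partial-)invariance measurement model, equates the
#' latent factor covariances across groups (group-2 factor variances stay
#' free) and iteratively frees the covariance with the largest modification
#' index until the CFI drop relative to the configural model is within the
#' cutoff.
#'
#' @param search result of \code{\link{partial_invariance_search}} (or a list
#'   with \code{fit} and \code{configural}).
#' @param cutoff delta-CFI cutoff.
#' @param refine_top number of top-MI covariance candidates refitted per
#'   iteration (the largest measured CFI gain is kept).
#' @return list: \code{fit} (final structural \code{sdq_fit}),
#'   \code{freed_cov} (data.frame of freed factor pairs), \code{log}.
#' @export
structural_equivalence <- function(search, cutoff = 0.002, refine_top = 3L) {
  configural <- search$configural
  meas <- search$fit
  refit <- function(fc, start) fit_multigroup(
    meas$ps_list, meas$mspec, free_items = meas$free_items,
    structural = TRUE, free_cov = fc, start = start, label = "structural")
  free_cov <- data.frame(f1 = character(), f2 = character(),
                         stringsAsFactors = FALSE)
  fit <- refit(free_cov, meas$par)
  log <- list()
  repeat {
    dcfi <- configural$indices$cfi - fit$indices$cfi
    log[[length(log) + 1L]] <- data.frame(
      step = length(log) + 1L,
      freed = paste(paste(free_cov$f1, free_cov$f2, sep = "~"), collapse = ";"),
      cfi = fit$indices$cfi, delta_cfi = dcfi, stringsAsFactors = FALSE)
    if (dcfi <= cutoff || nrow(free_cov) >= nrow(fit$ctx$phi_pairs)) break
    mi <- .cov_modification_indices(fit)
    if (!nrow(mi)) break
    top <- mi[seq_len(min(refine_top, nrow(mi))), , drop = FALSE]
    trials <- lapply(seq_len(nrow(top)), function(k)
      refit(rbind(free_cov, data.frame(f1 = top$f1[k], f2 = top$f2[k],
                                       stringsAsFactors = FALSE)),
            fit$par))
    best <- which.max(vapply(trials, function(f) f$indices$cfi, numeric(1)))
    free_cov <- rbind(free_cov, data.frame(f1 = top$f1[best], f2 = top$f2[best],
                                           stringsAsFactors = FALSE))
    fit <- trials[[best]]
  }
  fit$decision <- list(delta_cfi = dcfi, cutoff = cutoff,
                       verdict = if (dcfi <= cutoff) "equivalent"
                                 else "non-equivalent",
                       freed_cov = free_cov)
  list(fit = fit, freed_cov = free_cov, log = do.call(rbind, log))
}

#' Latent mean differences
#'
#' Group-2 latent means (reference group fixed at zero) with both groups'
#' factor variances, from a strong or partial-invariance fit.
#'
#' @param fit constrained \code{sdq_fit} with identified means.
#' @return data.frame: \code{factor}, \code{kappa2}, \code{se},
#'   \code{phi1}, \code{phi2}.
#' @export
latent_mean_differences <- function(fit) {
  ctx <- fit$ctx
  if (is.null(ctx) || ctx$kind != "multigroup")
    stop("latent means are identified only under threshold/loading constraints")
  ix <- ctx$index
  data.frame(factor = fit$mspec$factors,
             kappa2 = unname(fit$par[ix$kappa2]),
             se = unname(fit$se[ix$kappa2]),
             phi1 = 1,
             phi2 = unname(exp(fit$par[ix$logvar2])),
             stringsAsFactors = FALSE)
}

#' Standardized solution
#'
#' Loadings and thresholds on unit-variance latent-response and unit-variance
#' factor scales per group (thresholds are divided by the latent-response SD
#' without subtracting the latent-mean shift, the usual reporting convention
#' for ordinal multigroup models).
#'
#' @param fit an \code{sdq_fit}.
#' @return data.frame: \code{item_id}, \code{group} (1 = reference),
#'   \code{loading} (primary), \code{cross} (cross-loading or NA), \code{t1},
#'   \code{t2}, plus \code{rescor} rows are reported via attributes
#'   \code{phi} (per-group factor correlations) and \code{residual_cor}.
#' @export
standardize <- function(fit) {
  ctx <- fit$ctx
  mspec <- fit$mspec
  p <- ctx$p; q <- ctx$q
  ix <- ctx$index
  one_group <- function(L, Phi, tau, res_r) {
    A <- L %*% Phi %*% t(L)
    comm <- diag(A)
    theta <- pmax(1 - comm, 1e-4)
    v <- comm + theta
    dimnames(Phi) <- list(mspec$factors, mspec$factors)
    list(L = L, v = v, Phi = Phi, tau = tau, res = res_r)
  }
  if (ctx$kind == "single") {
    L <- matrix(0, p, q)
    L[cbind(ctx$lp$rows, ctx$lp$cols)] <- fit$par[ix$lam]
    gs <- list(one_group(L, .phi_from_par(fit$par[ix$phi], ctx), ctx$tau,
                         fit$par[ix$res]))
  } else {
    L1 <- matrix(0, p, q)
    L1[cbind(ctx$lp$rows, ctx$lp$cols)] <- fit$par[ix$lam]
    Phi1 <- .phi_from_par(fit$par[ix$phi1], ctx)
    tau <- matrix(fit$par[ix$tau], p, 2L, byrow = TRUE)
    L2 <- L1; tau2 <- tau
    if (length(ctx$free_idx)) {
      L2[cbind(ctx$free_idx, mspec$primary[ctx$free_idx])] <- fit$par[ix$lam2]
      tau2[ctx$free_idx, ] <- matrix(fit$par[ix$tau2],
                                     length(ctx$free_idx), 2L, byrow = TRUE)
    }
    var2 <- exp(fit$par[ix$logvar2])
    Phi2 <- diag(var2)
    if (ctx$structural) {
      cov2 <- fit$par[ix$phi1]
      if (length(ctx$cov_free_rows)) cov2[ctx$cov_free_rows] <- fit$par[ix$cov2]
    } else cov2 <- fit$par[ix$cov2]
    Phi2[ctx$phi_pairs] <- cov2
    Phi2[ctx$phi_pairs[, c(2, 1), drop = FALSE]] <- cov2
    gs <- list(one_group(L1, Phi1, tau, fit$par[ix$res1]),
               one_group(L2, Phi2, tau2, fit$par[ix$res2]))
    ## group-2 total variance honours the free scale factors
    v2 <- rep(1, p)
    v2[ctx$delta_items] <- exp(-2 * fit$par[ix$logdelta2])
    gs[[2]]$v <- v2
  }
  rows <- lapply(seq_along(gs), function(g) {
    z <- gs[[g]]
    sv <- sqrt(z$v)
    fsd <- sqrt(diag(z$Phi))
    Lstd <- sweep(sweep(z$L, 1L, sv, `/`), 2L, fsd, `*`)
    prim <- Lstd[cbind(seq_len(p), mspec$primary)]
    cross <- rep(NA_real_, p)
    if (nrow(mspec$cross)) {
      ci <- match(mspec$cross$item, mspec$items)
      cross[ci] <- Lstd[cbind(ci, match(mspec$cross$factor, mspec$factors))]
    }
    data.frame(item_id = mspec$items, group = g, loading = prim,
               cross = cross, t1 = z$tau[, 1] / sv, t2 = z$tau[, 2] / sv,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "phi") <- lapply(gs, function(z) stats::cov2cor(z$Phi))
  attr(out, "residual_cor") <- lapply(gs, function(z) z$res)
  out
}
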
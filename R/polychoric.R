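## Two-step polychoric correlation machinery.
##
## Step 1: per-item probit thresholds from cumulative margins.
## Step 2: per-pair correlation maximizing the bivariate-normal likelihood of
## the contingency table given the thresholds.  Asymptotic (co)variances come
## from the stacked M-estimator influence functions, which also account for
## pairwise deletion under MCAR; the full moment covariance feeds the WLSMV
## test statistics.

#' Probit thresholds from category counts
#'
#' \eqn{\hat\tau_k = \Phi^{-1}} of the cumulative proportion through category
#' \eqn{k-1}.  Cumulative proportions are clamped to
#' \eqn{[1/(2n), 1 - 1/(2n)]} so boundary categories yield finite thresholds.
#'
#' @param counts non-negative counts per ordered category (length >= 2).
#' @return numeric vector of length \code{length(counts) - 1}.
#' @export
estimate_thresholds <- function(counts) {
  n <- sum(counts)
  if (n <= 0) stop("empty category counts")
  p <- cumsum(counts)[-length(counts)] / n
  p <- pmin(pmax(p, 1 / (2 * n)), 1 - 1 / (2 * n))
  qnorm(p)
}

## cell probabilities of an RxC ordinal table given thresholds (with +-Inf
## boundaries appended) and correlation rho
.cellprobs <- function(tau_r, tau_c, rho) {
  a <- c(-Inf, tau_r, Inf)
  b <- c(-Inf, tau_c, Inf)
  g <- expand.grid(a = a, b = b)
  P <- matrix(pbinorm(g$a, g$b, rho), length(a), length(b))
  pr <- P[-1, -1, drop = FALSE] - P[-nrow(P), -1, drop = FALSE] -
        P[-1, -ncol(P), drop = FALSE] + P[-nrow(P), -ncol(P), drop = FALSE]
  pmax(pr, 1e-12)
}

## d(cell probability)/d(rho): Plackett's identity at the four cell corners
.cellprobs_drho <- function(tau_r, tau_c, rho) {
  a <- c(-Inf, tau_r, Inf)
  b <- c(-Inf, tau_c, Inf)
  D <- outer(a, b, function(h, k) ifelse(is.finite(h) & is.finite(k),
                                         .dbinorm(ifelse(is.finite(h), h, 0),
                                                  ifelse(is.finite(k), k, 0),
                                                  rho), 0))
  D[-1, -1, drop = FALSE] - D[-nrow(D), -1, drop = FALSE] -
    D[-1, -ncol(D), drop = FALSE] + D[-nrow(D), -ncol(D), drop = FALSE]
}

.polychoric_loglik <- function(rho, tab, tau_r, tau_c) {
  sum(tab * log(.cellprobs(tau_r, tau_c, rho)))
}

#' Polychoric correlation of one contingency table
#'
#' Two-step estimate: thresholds from the table margins, then the correlation
#' maximizing the bivariate-normal likelihood over the cells.  The variance is
#' the inverse negative second derivative of the profile log-likelihood at the
#' maximum.
#'
#' @param tab matrix of counts (rows = item 1 categories, cols = item 2).
#' @return list: \code{rho}, \code{var}, \code{tau_r}, \code{tau_c}, \code{n}.
#' @export
polychoric_corr <- function(tab) {
  tab <- as.matrix(tab)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]  # collapse
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("degenerate table: need at least two non-empty rows and columns")
  n <- sum(tab)
  tau_r <- estimate_thresholds(rowSums(tab))
  tau_c <- estimate_thresholds(colSums(tab))
  opt <- optimize(.polychoric_loglik, c(-0.999, 0.999), tab = tab,
                  tau_r = tau_r, tau_c = tau_c, maximum = TRUE,
                  tol = 1e-8)
  rho <- opt$maximum
  h <- 1e-4
  d2 <- (.polychoric_loglik(min(rho + h, 0.999), tab, tau_r, tau_c) -
         2 * opt$objective +
         .polychoric_loglik(max(rho - h, -0.999), tab, tau_r, tau_c)) / h^2
  list(rho = rho, var = if (d2 < 0) -1 / d2 else NA_real_,
       tau_r = tau_r, tau_c = tau_c, n = n)
}

## canonical ordering of the moment vector for p items:
## thresholds item-major (item1 t1, item1 t2, ...), then correlations for
## pairs (i, j), i < j, in column-major upper-triangle order
moment_layout <- function(items, n_thresh = 2L) {
  p <- length(items)
  thr <- data.frame(
    type = "threshold",
    item1 = rep(items, each = n_thresh),
    item2 = NA_character_,
    k = rep(seq_len(n_thresh), p),
    stringsAsFactors = FALSE
  )
  ut <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  ut <- ut[order(ut[, 2], ut[, 1]), , drop = FALSE]
  cor <- data.frame(
    type = "correlation",
    item1 = items[ut[, 1]],
    item2 = items[ut[, 2]],
    k = NA_integer_,
    stringsAsFactors = FALSE
  )
  out <- rbind(thr, cor)
  out$name <- ifelse(out$type == "threshold",
                     paste0(out$item1, "|t", out$k),
                     paste0(out$item1, "~~", out$item2))
  out
}

#' Polychoric correlation matrix of an item-response matrix
#'
#' All item pairs are estimated on pairwise-complete observations.  The full
#' asymptotic covariance matrix of the stacked (thresholds, correlations)
#' moment vector is assembled from per-observation influence functions of the
#' two-step estimator, including the propagation of threshold uncertainty into
#' the correlations.  A nearest-positive-definite repair (eigenvalue clipping)
#' is applied to the correlation matrix only when it is indefinite, and logged.
#'
#' @param m an \code{\link{sdq_matrix}} (reverse-scored items are flipped to
#'   the problem-direction scale before estimation), or a plain integer matrix
#'   with values in {0,1,2}/NA and item-id column names (used as-is).
#' @param group \code{NULL} for the pooled sample or one group label.
#' @param items optional subset of item ids (default: all columns).
#' @param acov \code{"full"} (influence-function moment covariance, needed for
#'   WLSMV fitting) or \code{"diag"} (profile-likelihood variances only).
#' @return object of class \code{polychoric_summary}: thresholds, correlation
#'   matrix \code{rho}, per-entry variances, pairwise n, moment layout, and
#'   (if requested) the moment covariance \code{Gamma} of \eqn{\sqrt n} times
#'   the moment vector.
#' @export
polychoric_matrix <- function(m, group = NULL, items = NULL,
                              acov = c("full", "diag")) {
  acov <- match.arg(acov)
  if (inherits(m, "sdq_matrix")) {
    ## model on the problem-direction scale: reverse-scored items flipped
    X <- reverse_items(m$responses)
    if (!is.null(group)) X <- X[m$group == group, , drop = FALSE]
  } else X <- as.matrix(m)
  if (!is.null(items)) X <- X[, items, drop = FALSE]
  items <- colnames(X)
  p <- length(items)
  if (p < 2L) stop("need at least two items")
  n <- nrow(X)

  ## exclude single-category items
  n_cat <- apply(X, 2L, function(x) length(unique(x[!is.na(x)])))
  excluded <- items[n_cat < 2L]
  if (length(excluded)) {
    warning("excluding single-category item(s): ",
            paste(excluded, collapse = ", "))
    X <- X[, n_cat >= 2L, drop = FALSE]
    items <- colnames(X)
    p <- length(items)
  }

  layout <- moment_layout(items)
  nm <- nrow(layout)
  tau <- matrix(NA_real_, p, 2L, dimnames = list(items, c("t1", "t2")))
  n_item <- integer(p)
  IF <- if (acov == "full") matrix(0, n, nm) else NULL

  for (j in seq_len(p)) {
    x <- X[, j]
    obs <- !is.na(x)
    n_item[j] <- sum(obs)
    cnt <- tabulate(x[obs] + 1L, nbins = 3L)
    tau[j, ] <- estimate_thresholds(cnt)
    if (acov == "full") {
      for (k in 1:2) {
        col <- (j - 1L) * 2L + k
        ind <- as.numeric(x[obs] <= (k - 1L))
        IF[obs, col] <- (ind - pnorm(tau[j, k])) / dnorm(tau[j, k]) *
          (n / n_item[j])
      }
    }
  }

  R <- diag(p)
  dimnames(R) <- list(items, items)
  Rvar <- matrix(NA_real_, p, p, dimnames = dimnames(R))
  Npair <- matrix(NA_real_, p, p, dimnames = dimnames(R))
  pair_rows <- which(layout$type == "correlation")

  for (r in pair_rows) {
    i <- match(layout$item1[r], items)
    j <- match(layout$item2[r], items)
    ok <- !is.na(X[, i]) & !is.na(X[, j])
    n_p <- sum(ok)
    Npair[i, j] <- Npair[j, i] <- n_p
    tab <- matrix(0, 3L, 3L)
    tt <- table(factor(X[ok, i], 0:2), factor(X[ok, j], 0:2))
    tab[as.integer(rownames(tt)) + 1L, as.integer(colnames(tt)) + 1L] <- tt
    ti <- tau[i, ]; tj <- tau[j, ]
    nz_r <- rowSums(tab) > 0; nz_c <- colSums(tab) > 0
    opt <- optimize(function(rho)
      sum(tab[nz_r, nz_c, drop = FALSE] *
            log(.cellprobs(ti, tj, rho)[nz_r, nz_c, drop = FALSE])),
      c(-0.999, 0.999), maximum = TRUE, tol = 1e-8)
    rho <- opt$maximum
    R[i, j] <- R[j, i] <- rho

    ## per-cell score s = (dpi/drho)/pi and its derivatives
    pi0 <- .cellprobs(ti, tj, rho)
    s0 <- .cellprobs_drho(ti, tj, rho) / pi0
    phat <- tab / n_p
    h <- 1e-4
    sc <- function(ti2, tj2, rho2)
      .cellprobs_drho(ti2, tj2, rho2) / .cellprobs(ti2, tj2, rho2)
    ds_drho <- (sc(ti, tj, rho + h) - sc(ti, tj, rho - h)) / (2 * h)
    B_rho <- (n_p / n) * sum(phat * ds_drho)
    if (!is.finite(B_rho) || B_rho >= 0) {
      ## near-boundary or flat profile: fall back to score variance
      B_rho <- -(n_p / n) * sum(phat * s0^2)
    }
    Rvar[i, j] <- Rvar[j, i] <- 1 / (n_p * sum(phat * s0^2))

    if (acov == "full") {
      m_i <- numeric(n)
      ## s0 is 3x3 indexed [cat_i+1, cat_j+1]; column-major linear index
      cell <- X[, i] + 3L * X[, j] + 1L
      m_i[ok] <- as.vector(s0)[cell[ok]]
      corr_col <- -m_i / B_rho
      for (l in 1:4) {
        it <- if (l <= 2) i else j
        kk <- if (l <= 2) l else l - 2L
        tpert_i <- ti; tpert_j <- tj
        if (l <= 2) tpert_i[kk] <- tpert_i[kk] + h else tpert_j[kk] <- tpert_j[kk] + h
        s_plus <- sc(tpert_i, tpert_j, rho)
        if (l <= 2) tpert_i[kk] <- tpert_i[kk] - 2 * h else tpert_j[kk] <- tpert_j[kk] - 2 * h
        s_minus <- sc(tpert_i, tpert_j, rho)
        B_tau <- (n_p / n) * sum(phat * (s_plus - s_minus) / (2 * h))
        tcol <- (it - 1L) * 2L + kk
        corr_col <- corr_col - (B_tau / B_rho) * IF[, tcol]
      }
      IF[, r] <- corr_col
    }
  }

  repaired <- FALSE
  pd <- nearest_pd(R)
  if (pd$repaired) {
    repaired <- TRUE
    R <- pd$mat
    dimnames(R) <- list(items, items)
  }

  Gamma <- NULL
  if (acov == "full") Gamma <- crossprod(IF) / n

  structure(list(items = items, thresholds = tau, rho = R, rho_var = Rvar,
                 n_pair = Npair, n_item = n_item, n = n, layout = layout,
                 Gamma = Gamma, repaired = repaired, excluded = excluded),
            class = "polychoric_summary")
}

#' @export
print.polychoric_summary <- function(x, ...) {
  cat("polychoric summary:", length(x$items), "items, n =", x$n,
      if (x$repaired) "(PD-repaired)" else "", "\n")
  invisible(x)
}

## sample moment vector in canonical layout
moment_vector <- function(ps) {
  thr <- as.vector(t(ps$thresholds))
  idx <- which(ps$layout$type == "correlation")
  cors <- vapply(idx, function(r)
    ps$rho[ps$layout$item1[r], ps$layout$item2[r]], numeric(1))
  setNames(c(thr, cors), ps$layout$name)
}

#' Cronbach's and ordinal alpha per subscale
#'
#' Cronbach's alpha is computed from pairwise-complete Pearson covariances of
#' the (reversed) item scores.  Ordinal alpha applies the standardized-alpha
#' formula to the polychoric correlation matrix:
#' \eqn{\alpha = k\bar r / (1 + (k-1)\bar r)} with \eqn{\bar r} the mean
#' off-diagonal polychoric correlation, equivalently
#' \eqn{(k/(k-1)) (1 - k/(k + \sum_{i \ne j} \hat r_{ij}))}.
#'
#' @param m an \code{\link{sdq_matrix}}.
#' @return data.frame: scale (five subscales and \code{total}), \code{k},
#'   \code{cronbach_alpha}, \code{ordinal_alpha}.
#' @export
reliability <- function(m) {
  meta <- sdq_item_meta()
  resp <- reverse_items(m$responses, meta)
  sets <- c(lapply(sdq_scales(), function(sc) meta$item_id[meta$scale == sc]),
            list(meta$item_id[meta$scale != "prosocial"]))
  names(sets) <- c(sdq_scales(), "total")
  out <- lapply(names(sets), function(nm) {
    cols <- sets[[nm]]
    Xs <- resp[, cols, drop = FALSE]
    v <- apply(Xs, 2L, stats::var, na.rm = TRUE)
    if (any(v == 0, na.rm = TRUE)) {
      warning("dropping zero-variance item(s) in scale ", nm, ": ",
              paste(cols[v == 0], collapse = ", "))
      cols <- cols[v > 0]
      Xs <- Xs[, cols, drop = FALSE]
    }
    k <- length(cols)
    C <- stats::cov(Xs, use = "pairwise.complete.obs")
    cronbach <- (k / (k - 1)) * (1 - sum(diag(C)) / sum(C))
    Rp <- polychoric_matrix(Xs, acov = "diag")$rho
    rbar <- mean(Rp[upper.tri(Rp)])
    ordinal <- k * rbar / (1 + (k - 1) * rbar)
    data.frame(scale = nm, k = k, cronbach_alpha = cronbach,
               ordinal_alpha = ordinal, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Standardized alpha from a correlation matrix
#'
#' @param R correlation matrix.
#' @return scalar alpha.
#' @export
alpha_from_corr <- function(R) {
  k <- nrow(R)
  rbar <- mean(R[upper.tri(R)])
  k * rbar / (1 + (k - 1) * rbar)
}
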
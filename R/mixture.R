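# Weighted Gaussian mixture EM on log-Ks, with sequential parametric-bootstrap
# likelihood-ratio selection of the component count (the boot.comp-style test).

# One EM fit for fixed k. x: log-Ks values; w: observation weights.
# Initialisation: component means at weighted quantile splits, jittered across
# restarts. Log-likelihood is asserted non-decreasing at every iteration.
em_fit <- function(x, w, k, restarts = 10L, max_iter = 500L, tol = 1e-8) {
  n <- length(x)
  sw <- sum(w)
  if (k == 1L) { # closed form: weighted moments
    mu <- sum(w * x) / sw
    sdv <- sqrt(sum(w * (x - mu)^2) / sw)
    ll <- sum(w * dnorm(x, mu, sdv, log = TRUE))
    return(list(
      k = 1L, weight = 1, meanlog = mu, sdlog = sdv, loglik = ll,
      n_iter = 0L, converged = TRUE,
      resp = matrix(1, n, 1L)
    ))
  }
  ord <- order(x)
  cum <- cumsum(w[ord]) / sw
  wquant <- function(p) {
    idx <- pmin(pmax(findInterval(p, cum) + 1L, 1L), n)
    x[ord][idx]
  }
  sd0 <- sqrt(sum(w * (x - sum(w * x) / sw)^2) / sw)
  best <- NULL
  for (r in seq_len(restarts)) {
    p0 <- (seq_len(k) - 0.5) / k
    if (r > 1L) p0 <- pmin(0.99, pmax(0.01, p0 + runif(k, -0.5 / k, 0.5 / k)))
    mu <- sort(wquant(p0))
    sdv <- rep(max(sd0 / k, 0.05), k)
    pi_k <- rep(1 / k, k)
    ll_prev <- -Inf
    converged <- FALSE
    iter <- 0L
    resp <- NULL
    while (iter < max_iter) {
      iter <- iter + 1L
      lg <- vapply(seq_len(k), function(j) {
        dnorm(x, mu[j], sdv[j], log = TRUE) + log(pi_k[j])
      }, numeric(n))
      mx <- lg[cbind(seq_len(n), max.col(lg))]
      p <- exp(lg - mx)
      rs <- rowSums(p)
      ll <- sum(w * (mx + log(rs)))
      if (ll < ll_prev - 1e-6 * (1 + abs(ll_prev))) {
        abort("internal error: EM log-likelihood decreased")
      }
      resp <- p / rs
      wk <- resp * w
      Wk <- colSums(wk)
      Wk <- pmax(Wk, 1e-12)
      pi_k <- Wk / sw
      mu <- colSums(wk * x) / Wk
      sdv <- sqrt(colSums(wk * (x - rep(mu, each = n))^2) / Wk)
      sdv <- pmax(sdv, 1e-4)
      if (is.finite(ll_prev) && (ll - ll_prev) < tol * (1 + abs(ll))) {
        converged <- TRUE
        ll_prev <- ll
        break
      }
      ll_prev <- ll
    }
    cand <- list(k = k, weight = pi_k, meanlog = mu, sdlog = sdv,
                 loglik = ll_prev, n_iter = iter, converged = converged,
                 resp = resp)
    if (is.null(best) || cand$loglik > best$loglik) best <- cand
  }
  best
}

# Draw n unweighted values from a fitted log-normal mixture (on the Ks scale).
sample_mixture <- function(fit, n) {
  comp <- sample.int(fit$k, n, replace = TRUE, prob = fit$weight)
  exp(rnorm(n, fit$meanlog[comp], fit$sdlog[comp]))
}

# Parametric-bootstrap LRT of k vs k+1 components with early stopping once
# the accept/reject decision is settled. The observed statistic is computed
# with exactly the same reduced-effort EM as the bootstrap replicates, so the
# test is calibrated; only the reported parameter fit uses the full effort.
boot_lrt <- function(x, w, fit_k, n_boot, alpha,
                     boot_restarts = 1L, boot_iter = 150L, boot_tol = 1e-5) {
  quick <- function(xx, ww, k) {
    em_fit(xx, ww, k, restarts = boot_restarts, max_iter = boot_iter,
           tol = boot_tol)
  }
  q0 <- quick(x, w, fit_k$k)
  q1 <- quick(x, w, fit_k$k + 1L)
  stat_obs <- max(0, 2 * (q1$loglik - q0$loglik))
  n <- length(x)
  exceed <- 0L
  i <- 0L
  # once exceed reaches this, p >= alpha whatever the remaining replicates do
  stop_at <- ceiling(alpha * (1 + n_boot)) - 1L + 1L
  while (i < n_boot) {
    i <- i + 1L
    xb <- log(sample_mixture(fit_k, n))
    wb <- rep(1, n)
    f0 <- quick(xb, wb, fit_k$k)
    f1 <- quick(xb, wb, fit_k$k + 1L)
    if (max(0, 2 * (f1$loglik - f0$loglik)) >= stat_obs) exceed <- exceed + 1L
    if (exceed >= stop_at) break
    if ((1 + exceed + (n_boot - i)) < alpha * (1 + n_boot)) break
  }
  list(stat = stat_obs, p = (1 + exceed) / (1 + i), n_boot_used = i)
}

#' Fit a log-normal mixture to a Ks distribution and select the peak count
#'
#' Fits weighted Gaussian mixtures to `log(Ks)` by EM and chooses the number
#' of components by a sequential parametric-bootstrap likelihood-ratio test
#' (k vs k+1), stopping at the first non-significant test or at `k_max`. The
#' median Ks of a component is `exp(meanlog)` (log-normal median identity).
#'
#' @param dist A `ks_distribution` (see [node_weighted_distribution()]), or
#'   any data frame with `ks` and optional `weight` columns.
#' @param k_max Maximum number of components to consider.
#' @param n_boot Parametric-bootstrap replicates per test.
#' @param alpha Significance level of each bootstrap LRT.
#' @param seed Optional integer seed.
#' @param restarts,max_iter,tol EM settings for fits to the observed data.
#' @return An object of class `ks_mixture`: component table (weights,
#'   log-scale means/sds, Ks-scale medians with asymptotic 95% intervals),
#'   log-likelihood, convergence info and the selection trace.
#' @export
fit_ks_mixture <- function(dist, k_max = 4L, n_boot = 200L, alpha = 0.05,
                           seed = NULL, restarts = 10L, max_iter = 500L,
                           tol = 1e-8) {
  stopifnot(is.data.frame(dist), "ks" %in% names(dist))
  w <- if ("weight" %in% names(dist)) dist$weight else rep(1, nrow(dist))
  keep <- dist$ks > 0
  x <- log(dist$ks[keep])
  w <- w[keep]
  if (sum(w) < 50) abort("need at least 50 effective observations")
  run <- function() {
    fits <- list(em_fit(x, w, 1L))
    trace <- list()
    k <- 1L
    while (k < k_max) {
      tst <- boot_lrt(x, w, fits[[k]], n_boot, alpha)
      trace[[k]] <- tibble(k_null = k, k_alt = k + 1L, stat = tst$stat,
                           p_value = tst$p, n_boot_used = tst$n_boot_used)
      if (tst$p >= alpha) break
      k <- k + 1L
      fits[[k]] <- em_fit(x, w, k, restarts = restarts,
                          max_iter = max_iter, tol = tol)
    }
    final <- fits[[k]]
    ord <- order(final$meanlog)
    wgt <- final$weight[ord]
    mlog <- final$meanlog[ord]
    slog <- final$sdlog[ord]
    n_eff <- colSums(final$resp * w)[ord]
    se <- slog / sqrt(pmax(n_eff, 1))
    comps <- tibble(
      component = seq_len(k),
      weight = wgt, meanlog = mlog, sdlog = slog,
      median = exp(mlog),
      median_lo = exp(mlog - 1.96 * se),
      median_hi = exp(mlog + 1.96 * se)
    )
    structure(list(
      k = k, components = comps, loglik = final$loglik,
      n_iter = final$n_iter, converged = final$converged,
      selection = bind_rows(trace), alpha = alpha, n_boot = n_boot,
      window = attr(dist, "window"), n_obs = length(x),
      data = tibble(ks = exp(x), weight = w)
    ), class = "ks_mixture")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.ks_mixture <- function(x, ...) {
  cat(sprintf("Log-normal Ks mixture: k = %d (n = %d, loglik = %.2f%s)\n",
              x$k, x$n_obs, x$loglik,
              if (x$converged) "" else ", EM not converged"))
  print(x$components)
  if (nrow(x$selection) > 0) {
    cat("Component selection (parametric-bootstrap LRT):\n")
    print(x$selection)
  }
  invisible(x)
}

#' @rdname fit_ks_mixture
#' @param x A `ks_mixture` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.ks_mixture <- function(x, ...) x$components

#' @rdname fit_ks_mixture
#' @exportS3Method generics::glance
glance.ks_mixture <- function(x, ...) {
  tibble(k = x$k, loglik = x$loglik, n_obs = x$n_obs,
         converged = x$converged, n_iter = x$n_iter)
}
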
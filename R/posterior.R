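# Posterior summaries and convergence diagnostics.
#
# Rhat is the rank-normalized split potential scale reduction factor and ESS
# the matching bulk effective sample size (Geyer initial monotone sequence).
# Implemented here rather than imported so the package has no MCMC-framework
# dependency and the diagnostics are testable against closed forms.

.as_chain_matrix <- function(draws) {
  if (is.list(draws) && !is.data.frame(draws)) {
    len <- unique(lengths(draws))
    if (length(len) != 1L)
      stop("draws: chains must have equal length", call. = FALSE)
    draws <- do.call(cbind, draws)
  }
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1L)
  storage.mode(draws) <- "double"
  draws
}

.split_chains <- function(mat) {
  n <- nrow(mat)
  half <- n %/% 2L
  cbind(mat[seq_len(half), , drop = FALSE],
        mat[(n - half + 1L):n, , drop = FALSE])
}

.rank_normalize <- function(mat) {
  z <- stats::qnorm((rank(mat) - 3 / 8) / (length(mat) + 1 / 4))
  matrix(z, nrow = nrow(mat))
}

.rhat_basic <- function(mat) {
  n <- nrow(mat)
  m <- ncol(mat)
  if (n < 2L || m < 2L) return(NA_real_)
  chain_means <- colMeans(mat)
  chain_vars <- apply(mat, 2L, stats::var)
  w <- mean(chain_vars)
  b <- n * stats::var(chain_means)
  if (!is.finite(w) || w <= .Machine$double.eps) return(NA_real_)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Split-chain rank-normalized Rhat
#' @param draws Numeric vector (one chain), matrix (iterations x chains), or
#'   list of equal-length chains.
#' @return Rhat, or `NA` when fewer than 2 chains or degenerate draws.
#' @export
rhat <- function(draws) {
  mat <- .split_chains(.as_chain_matrix(draws))
  if (ncol(mat) < 4L) return(NA_real_)        # < 2 original chains
  if (stats::var(as.vector(mat)) <= .Machine$double.eps) return(NA_real_)
  bulk <- .rhat_basic(.rank_normalize(mat))
  folded <- .rhat_basic(.rank_normalize(abs(mat - stats::median(mat))))
  max(bulk, folded, na.rm = TRUE)
}

#' Bulk effective sample size
#' @inheritParams rhat
#' @return ESS estimate (capped at the total draw count), or `NA` when
#'   degenerate.
#' @export
ess_bulk <- function(draws) {
  mat <- .split_chains(.as_chain_matrix(draws))
  if (stats::var(as.vector(mat)) <= .Machine$double.eps) return(NA_real_)
  mat <- .rank_normalize(mat)
  n <- nrow(mat)
  m <- ncol(mat)
  if (n < 4L) return(NA_real_)
  chain_vars <- apply(mat, 2L, stats::var)
  w <- mean(chain_vars)
  var_plus <- (n - 1) / n * w + n * stats::var(colMeans(mat)) / n
  lag_max <- min(n - 2L, 1000L)
  acov <- sapply(seq_len(m), function(j)
    stats::acf(mat[, j], lag.max = lag_max, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1L, 1L])
  rho <- 1 - (w - rowMeans(acov)) / var_plus   # rho[1] is lag 0
  # Geyer: sum consecutive pairs while positive, enforce monotonicity
  tau <- 0
  prev_pair <- Inf
  t <- 1L
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (pair < 0) break
    pair <- min(pair, prev_pair)
    tau <- tau + pair
    prev_pair <- pair
    t <- t + 2L
  }
  tau <- max(2 * tau - 1, 1 / log10(n * m + 10))
  min(n * m / tau, n * m)
}

#' Summarize posterior draws
#'
#' Mean, median and equal-tailed 95% credible interval (2.5th and 97.5th
#' percentiles), with rank-normalized split-Rhat and bulk ESS. With a single
#' chain Rhat is reported as `NA` (unavailable), never fabricated. Draws
#' from multiple chains are pooled for the point and interval summaries.
#'
#' @inheritParams rhat
#' @param rhat_threshold Warn when Rhat exceeds this (default 1.01).
#' @return Object of class `posterior_summary` with fields `mean`, `median`,
#'   `cri_low`, `cri_high`, `rhat`, `ess`, `n_draws`, `n_chains` and a
#'   `converged` flag (`NA` when Rhat is unavailable).
#' @export
summarize_posterior <- function(draws, rhat_threshold = 1.01) {
  mat <- .as_chain_matrix(draws)
  if (!all(is.finite(mat)))
    stop("summarize_posterior: draws must be finite", call. = FALSE)
  x <- as.vector(mat)
  if (length(x) == 0L)
    stop("summarize_posterior: no draws", call. = FALSE)
  q <- unname(stats::quantile(x, c(0.025, 0.5, 0.975), type = 7))
  r <- rhat(mat)
  conv <- if (is.na(r)) NA else r <= rhat_threshold
  if (isFALSE(conv))
    warning(sprintf("summarize_posterior: Rhat = %.3f exceeds %.2f; chains may not have converged",
                    r, rhat_threshold), call. = FALSE)
  structure(
    list(mean = mean(x), median = q[2L], cri_low = q[1L], cri_high = q[3L],
         rhat = r, ess = ess_bulk(mat), n_draws = length(x),
         n_chains = ncol(mat), converged = conv),
    class = "posterior_summary"
  )
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("mean %.4f  median %.4f  95%% CrI [%.4f, %.4f]  Rhat %s  ESS %s\n",
              x$mean, x$median, x$cri_low, x$cri_high,
              ifelse(is.na(x$rhat), "NA", sprintf("%.3f", x$rhat)),
              ifelse(is.na(x$ess), "NA", sprintf("%.0f", x$ess))))
  invisible(x)
}

#' Render a prevalence summary in percent with its 95% interval
#'
#' Formats a proportion-scale posterior summary the way the field reports
#' prevalences, e.g. `"21% [95% CI 7-34]"` (whole percent).
#'
#' @param x A `posterior_summary` (or list with `mean`, `cri_low`,
#'   `cri_high`) on the proportion scale.
#' @return Character string.
#' @export
format_prevalence <- function(x) {
  sprintf("%.0f%% [95%% CI %.0f–%.0f]",
          100 * x$mean, 100 * x$cri_low, 100 * x$cri_high)
}

#' Contrast two sets of posterior draws
#'
#' Summarizes the difference `A - B` and the posterior probability that A
#' exceeds B. With `paired = TRUE` (default) draws are matched by iteration,
#' which is exact when both cells were estimated within one MCMC run; with
#' `paired = FALSE` the shorter vector is resampled-free compared by
#' recycling-truncation to the common length, declared as an independent
#' comparison.
#'
#' @param draws_a,draws_b Numeric vectors of posterior draws (proportion or
#'   any common scale).
#' @param paired Logical; pair draws by iteration (requires equal lengths).
#' @return List with `summary` (a `posterior_summary` of A - B),
#'   `p_greater`, and `differs` (TRUE when the 95% interval of A - B
#'   excludes 0).
#' @export
contrast_strata <- function(draws_a, draws_b, paired = TRUE) {
  draws_a <- as.numeric(draws_a)
  draws_b <- as.numeric(draws_b)
  if (length(draws_a) == 0L || length(draws_b) == 0L)
    stop("contrast_strata: empty draws", call. = FALSE)
  if (paired) {
    if (length(draws_a) != length(draws_b))
      stop("contrast_strata: paired contrast requires equal draw counts",
           call. = FALSE)
  } else {
    n <- min(length(draws_a), length(draws_b))
    draws_a <- draws_a[seq_len(n)]
    draws_b <- draws_b[seq_len(n)]
  }
  d <- draws_a - draws_b
  qs <- unname(stats::quantile(d, c(0.025, 0.5, 0.975), type = 7))
  summ <- structure(
    list(mean = mean(d), median = qs[2L], cri_low = qs[1L], cri_high = qs[3L],
         rhat = NA_real_, ess = NA_real_, n_draws = length(d),
         n_chains = 1L, converged = NA),
    class = "posterior_summary"
  )
  list(summary = summ,
       p_greater = mean(draws_a > draws_b),
       differs = qs[1L] > 0 || qs[3L] < 0)
}
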
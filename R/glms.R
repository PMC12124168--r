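# Visit-frequency and household-structure models: NB2 negative binomial
# regression (incidence rate ratios) and logistic regression (odds ratios),
# both with Wald 95% intervals.

#' Household dependency measures
#'
#' Two distinct measures computed from the same raw counts, never from each
#' other: the dependency ratio (members under 18 divided by working members
#' 18 or older; missing when there are no working adults) and a binary flag
#' for households with more minors than adults in total.
#'
#' @param n_minors,n_working_adults,n_adults_total Non-negative integer
#'   vectors (recycled to a common length).
#' @return Data frame with columns `ratio` (`NA` when the household has no
#'   working adults, with a warning) and `exceeds_flag` (1 when minors
#'   outnumber all adults).
#' @export
dependency_measures <- function(n_minors, n_working_adults, n_adults_total) {
  n <- max(length(n_minors), length(n_working_adults), length(n_adults_total))
  n_minors <- rep_len(n_minors, n)
  n_working_adults <- rep_len(n_working_adults, n)
  n_adults_total <- rep_len(n_adults_total, n)
  counts <- c(n_minors, n_working_adults, n_adults_total)
  if (any(is.na(counts)) || any(counts < 0) ||
      any(counts != as.integer(counts)))
    stop("dependency_measures: counts must be non-negative integers",
         call. = FALSE)
  ratio <- ifelse(n_working_adults > 0, n_minors / n_working_adults, NA_real_)
  if (anyNA(ratio))
    warning(sprintf("dependency_measures: %d household(s) with no working adults; ratio set to NA",
                    sum(is.na(ratio))), call. = FALSE)
  data.frame(ratio = ratio,
             exceeds_flag = as.integer(n_minors > n_adults_total))
}

.wald_table <- function(coefs, ses, n, effect_label, dispersion = NA_real_) {
  z <- stats::qnorm(0.975)
  data.frame(
    term = names(coefs),
    estimate = unname(coefs),
    std_error = unname(ses),
    effect = exp(unname(coefs)),
    ci_low = exp(unname(coefs) - z * ses),
    ci_high = exp(unname(coefs) + z * ses),
    effect_type = effect_label,
    dispersion = dispersion,
    n = n,
    stringsAsFactors = FALSE
  )
}

#' Negative binomial regression for visit counts
#'
#' NB2 maximum-likelihood fit (quadratic mean-variance) with estimated
#' dispersion; exponentiated coefficients are incidence rate ratios with
#' Wald 95% intervals.
#'
#' @param counts Non-negative integer response vector.
#' @param X Numeric design matrix (no intercept column; one is added).
#' @return Object of class `glm_result`: a data frame of per-term rows
#'   (coefficient, SE, IRR, Wald bounds) with the NB dispersion `theta`
#'   attached.
#' @export
fit_negbin_visits <- function(counts, X) {
  X <- as.matrix(X)
  if (any(counts < 0) || any(counts != as.integer(counts)))
    stop("fit_negbin_visits: counts must be non-negative integers",
         call. = FALSE)
  if (qr(cbind(1, X))$rank < ncol(X) + 1L)
    stop("fit_negbin_visits: design matrix is rank deficient", call. = FALSE)
  dat <- data.frame(.y = counts, X, check.names = FALSE)
  fit <- tryCatch(
    withCallingHandlers(
      MASS::glm.nb(.y ~ ., data = dat),
      warning = function(w) {
        if (grepl("iteration limit", conditionMessage(w)))
          invokeRestart("muffleWarning")
      }),
    error = function(e) stop("fit_negbin_visits: did not converge: ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!fit$converged)
    stop("fit_negbin_visits: IWLS did not converge after ",
         fit$iter, " iterations", call. = FALSE)
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  if (any(se > 50))
    warning("fit_negbin_visits: very large standard error; possible ",
            "separation-like degeneracy in ",
            paste(names(co)[se > 50], collapse = ", "), call. = FALSE)
  res <- .wald_table(co, se, length(counts), "IRR", dispersion = fit$theta)
  class(res) <- c("glm_result", class(res))
  res
}

#' Logistic regression for household structure
#'
#' Maximum-likelihood logistic fit; exponentiated coefficients are odds
#' ratios with Wald 95% intervals. Complete separation is an error naming
#' the covariate rather than a silently divergent estimate.
#'
#' @param outcome Binary response vector.
#' @param X Numeric design matrix (intercept added).
#' @return Object of class `glm_result` (see [fit_negbin_visits()]).
#' @export
fit_logistic_structure <- function(outcome, X) {
  X <- as.matrix(X)
  if (!all(outcome %in% c(0L, 1L)))
    stop("fit_logistic_structure: outcome must be binary", call. = FALSE)
  if (qr(cbind(1, X))$rank < ncol(X) + 1L)
    stop("fit_logistic_structure: design matrix is rank deficient",
         call. = FALSE)
  dat <- data.frame(.y = outcome, X, check.names = FALSE)
  fit <- suppressWarnings(stats::glm(.y ~ ., data = dat, family = stats::binomial()))
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  sep <- abs(co) > 15 | se > 50
  if (any(sep))
    stop("fit_logistic_structure: complete or quasi-complete separation in ",
         paste(names(co)[sep], collapse = ", "), call. = FALSE)
  res <- .wald_table(co, se, length(outcome), "OR")
  class(res) <- c("glm_result", class(res))
  res
}

#' Render a GLM effect row in report style
#' @param x A `glm_result` row (or data frame).
#' @return Character vector like `"IRR 3.02, 95% CI 2.42-3.77"`.
#' @export
format_glm_effect <- function(x) {
  sprintf("%s %.2f, 95%% CI %.2f–%.2f",
          x$effect_type, x$effect, x$ci_low, x$ci_high)
}
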
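#' Domino randomizer design
#'
#' The masking device of the unrelated-question randomized-response design.
#' A respondent draws one domino from a bag of `n_total`; `n_sensitive` of
#' them route the respondent to the sensitive question, the rest to an
#' innocuous unrelated question. The interviewer never sees the draw, so an
#' individual answer carries no direct evidence of illegal behaviour; only
#' the aggregate mixture is informative. The default bag holds 6 dominoes,
#' 4 of which select the sensitive question, so `p_s = 4/6 = 2/3`.
#'
#' @param n_total Total number of dominoes in the bag (integer >= 1).
#' @param n_sensitive Number of dominoes that select the sensitive question
#'   (integer, `0 <= n_sensitive <= n_total`).
#' @return An object of class `randomizer_design`: a list with `n_total`,
#'   `n_sensitive` and `p_s = n_sensitive / n_total`.
#' @examples
#' rd <- randomizer_design()
#' rd$p_s  # 2/3
#' @export
randomizer_design <- function(n_total = 6L, n_sensitive = 4L) {
  if (length(n_total) != 1L || is.na(n_total) || n_total < 1 ||
      n_total != as.integer(n_total)) {
    stop("randomizer_design: 'n_total' must be a single integer >= 1", call. = FALSE)
  }
  if (length(n_sensitive) != 1L || is.na(n_sensitive) ||
      n_sensitive != as.integer(n_sensitive) ||
      n_sensitive < 0 || n_sensitive > n_total) {
    stop("randomizer_design: 'n_sensitive' must be an integer in [0, n_total]",
         call. = FALSE)
  }
  structure(
    list(n_total = as.integer(n_total),
         n_sensitive = as.integer(n_sensitive),
         p_s = as.integer(n_sensitive) / as.integer(n_total)),
    class = "randomizer_design"
  )
}

#' @export
print.randomizer_design <- function(x, ...) {
  cat(sprintf("Randomizer: %d/%d dominoes sensitive (p_s = %.4f)\n",
              x$n_sensitive, x$n_total, x$p_s))
  invisible(x)
}

#' Draw question assignments from a randomizer
#'
#' Simulates the domino draw for `n` respondents: each is routed to the
#' sensitive question with probability exactly `p_s`.
#'
#' @param design A [randomizer_design()].
#' @param n Number of draws.
#' @return Character vector of `"sensitive"` / `"nonsensitive"`.
#' @export
draw_randomizer <- function(design, n = 1L) {
  stopifnot(inherits(design, "randomizer_design"))
  z <- stats::rbinom(n, 1L, design$p_s)
  c("nonsensitive", "sensitive")[z + 1L]
}
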
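#' Bayes post-test probability of disease
#'
#' Updates a pre-test probability (prevalence) with a screening result via
#' Bayes' theorem. Computation runs in odds space — pre-test odds times the
#' likelihood ratio of the observed result, `LR+ = sens / (1 - spec)` or
#' `LR- = (1 - sens) / spec` — which is numerically stable at the very low
#' prevalences relevant to population screening (~1e-4).
#'
#' @param prevalence pre-test disease probability, strictly inside (0, 1).
#'   Accepts a number or a fraction string such as `"1/220"`.
#' @param sensitivity,specificity operating characteristics in \[0, 1\].
#' @param result `"positive"` or `"negative"` test result.
#' @return posterior probability of disease.
#' @examples
#' # risk of a woman under 40 (prevalence 1 in 220) after a positive test
#' # at the balanced cut-off (sens 82.96%, spec 83.47%): about 2.24%
#' posterior_probability("1/220", 0.8296, 0.8347, "positive")
#' @export
posterior_probability <- function(prevalence, sensitivity, specificity,
                                  result = c("positive", "negative")) {
  result <- match.arg(result)
  p <- parse_prevalence(prevalence)
  if (p <= 0 || p >= 1)
    stop("prevalence must lie strictly inside (0, 1)", call. = FALSE)
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  pre_odds <- p / (1 - p)
  lr <- if (result == "positive") {
    if (specificity == 1) Inf else sensitivity / (1 - specificity)
  } else {
    if (specificity == 0) Inf else (1 - sensitivity) / specificity
  }
  post_odds <- pre_odds * lr
  if (is.infinite(post_odds)) return(1)
  if (is.nan(post_odds)) return(0)  # 0 * Inf cannot occur; 0 odds -> 0
  post_odds / (1 + post_odds)
}

parse_prevalence <- function(x) {
  if (is.character(x)) {
    parts <- strsplit(x, "/", fixed = TRUE)[[1]]
    if (length(parts) == 2) {
      return(as.numeric(parts[1]) / as.numeric(parts[2]))
    }
    return(as.numeric(x))
  }
  x
}

#' Post-test probability table over prevalences
#'
#' Tabulates the posterior for both positive and negative results of one
#' cut-off's operating characteristics across a list of prevalences (e.g.
#' the under-40 rate of 1 in 220 and the over-40 rate of 4 in 165).
#'
#' @param sensitivity,specificity operating characteristics, or pass a
#'   metrics list from [screening_metrics()] as `sensitivity` and leave
#'   `specificity` missing.
#' @param prevalences numeric (or fraction-string) vector of pre-test
#'   probabilities; nonempty.
#' @return `data.frame`: `prevalence`, `pretest_pct`,
#'   `posterior_positive_pct`, `posterior_negative_pct`. Rows are in input
#'   order; the positive-result posterior is nondecreasing in prevalence.
#' @export
risk_table <- function(sensitivity, specificity = NULL, prevalences) {
  if (is.list(sensitivity) && is.null(specificity)) {
    specificity <- sensitivity$specificity
    sensitivity <- sensitivity$sensitivity
  }
  if (length(prevalences) == 0) stop("prevalences must be nonempty", call. = FALSE)
  prev <- vapply(prevalences, parse_prevalence, numeric(1))
  pos <- vapply(prev, function(p)
    posterior_probability(p, sensitivity, specificity, "positive"), numeric(1))
  neg <- vapply(prev, function(p)
    posterior_probability(p, sensitivity, specificity, "negative"), numeric(1))
  data.frame(prevalence = prev,
             pretest_pct = 100 * prev,
             posterior_positive_pct = 100 * pos,
             posterior_negative_pct = 100 * neg)
}
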
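#' Univariate least-squares fit with a tidy report
#'
#' Ordinary least squares with an intercept, reporting per-term slope,
#' standard error, t statistic, residual degrees of freedom, and two-sided
#' p-value, plus the model R-squared. A thin wrapper around [stats::lm()]
#' that returns one row per non-intercept term.
#'
#' @param formula Model formula.
#' @param data Data frame containing the variables.
#' @param label Model label carried into the report (defaults to the
#'   deparsed formula).
#'
#' @return Data frame with columns `model`, `term`, `b`, `se`, `t`, `df`,
#'   `p`, `r_squared`, `n`.
#' @examples
#' d <- data.frame(x = 1:10, y = 3 + 2 * (1:10))
#' ols_fit(y ~ x, d)
#' @export
ols_fit <- function(formula, data, label = NULL) {
  if (is.null(label)) label <- deparse(formula)
  data <- stats::na.omit(data[, all.vars(formula), drop = FALSE])
  fit <- stats::lm(formula, data = data)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("collinear design; aliased term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  co <- sm$coefficients
  keep <- rownames(co) != "(Intercept)"
  data.frame(
    model = label,
    term = rownames(co)[keep],
    b = co[keep, "Estimate"],
    se = co[keep, "Std. Error"],
    t = co[keep, "t value"],
    df = fit$df.residual,
    p = co[keep, "Pr(>|t|)"],
    r_squared = sm$r.squared,
    n = nrow(data),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Univariate follow-up regressions for choice inflexibility
#'
#' Three models decomposing the headline multivariate association: choice
#' inflexibility on age alone, on amygdala binding potential alone, and on
#' both jointly (the age-adjusted amygdala slope). Both the simple and
#' age-adjusted amygdala effects are reported, clearly labeled, since either
#' can be meant by an effect "controlling for age". Participants with flagged
#' (missing) metrics are excluded with a message.
#'
#' @param features Participant-level metric table (from [profile_cohort()]),
#'   with `id` and `choice_inflexibility`.
#' @param cohort Participant table with `id`, `age`, and `amygdala` columns.
#'
#' @return Data frame of stacked [ols_fit()] reports (3 models).
#' @export
followup_suite <- function(features, cohort) {
  d <- merge(cohort[, c("id", "age", "amygdala")], features, by = "id")
  complete <- stats::complete.cases(
    d[, c("age", "amygdala", "choice_inflexibility")])
  if (any(!complete))
    message("followup_suite: excluding ", sum(!complete),
            " participant(s) with flagged metrics")
  d <- d[complete, ]
  rbind(
    ols_fit(choice_inflexibility ~ age, d, "inflexibility ~ age"),
    ols_fit(choice_inflexibility ~ amygdala, d, "inflexibility ~ amygdala"),
    ols_fit(choice_inflexibility ~ amygdala + age, d,
            "inflexibility ~ amygdala + age")
  )
}
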
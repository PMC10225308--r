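#' Objectively optimal asset at a given belief
#'
#' Compares the stock's expected dividend at the pre-choice belief with the
#' certain bond payoff in the trial's frame. Returns `"tie"` when the two
#' expected values are equal (within `tol`), which happens on every block's
#' first trial because the expected values tie exactly at the prior.
#'
#' @param posterior_pre Belief(s) that the stock is good, in `[0, 1]`.
#' @param framing `"gain"`/`"loss"`, scalar or vector.
#' @param cfg A [task_config()].
#' @param tol Absolute tolerance for declaring a tie.
#'
#' @return Character vector in `{"stock", "bond", "tie"}`.
#' @examples
#' optimal_asset(c(0.3, 0.5, 0.7), "gain", task_config())
#' @export
optimal_asset <- function(posterior_pre, framing, cfg, tol = 1e-9) {
  ev <- asset_expected_values(posterior_pre, framing, cfg)
  d <- ev$ev_stock - ev$ev_bond
  out <- ifelse(d > tol, "stock", ifelse(d < -tol, "bond", "tie"))
  out
}

# first-trial choice of each trial's block, aligned with the trial rows;
# assumes one participant's trials (or a key that already includes id)
block_first_choice <- function(trials, key = trials$block_index) {
  first <- trials$trial_index == 0L
  if (!any(first))
    stop("every block must contain a trial with trial_index == 0",
         call. = FALSE)
  trials$choice[first][match(key, key[first])]
}

#' Choice inflexibility
#'
#' Proportion of eligible trials on which a participant persisted in choosing
#' the asset chosen on the block's first trial although that asset was
#' objectively the less optimal choice at the time. Eligible trials are
#' non-first trials where the first-trial asset is strictly suboptimal at the
#' trial's pre-choice posterior; tie trials are excluded. By default the
#' proportion pools eligible trials across blocks; `per_block = TRUE` averages
#' per-block proportions instead.
#'
#' @param trials One participant's trial records
#'   (see [simulate_cohort_sessions()]).
#' @param cfg A [task_config()].
#' @param per_block Average per-block ratios instead of pooling trials.
#'
#' @return A proportion in `[0, 1]`, or `NA` (flagged missing) when no trial
#'   is eligible.
#' @export
choice_inflexibility <- function(trials, cfg, per_block = FALSE) {
  fc <- block_first_choice(trials)
  opt <- optimal_asset(trials$posterior_pre, trials$framing, cfg)
  eligible <- trials$trial_index > 0L & opt != "tie" & opt != fc
  if (!any(eligible)) return(NA_real_)
  persisted <- trials$choice == fc
  if (!per_block) return(mean(persisted[eligible]))
  ratios <- tapply(persisted[eligible], trials$block_index[eligible], mean)
  mean(ratios)
}

#' First stock choice (risk-taking propensity)
#'
#' Proportion of blocks on which the stock (rather than the bond) was chosen
#' on the first trial.
#'
#' @inheritParams choice_inflexibility
#' @return A proportion in `[0, 1]`.
#' @export
first_stock_choice <- function(trials) {
  first <- trials$trial_index == 0L
  if (!any(first))
    stop("no first trials present", call. = FALSE)
  mean(trials$choice[first] == "stock")
}

#' Suboptimal investment
#'
#' Proportion of trials on which the participant chose the asset with the
#' lower objective expected value at the pre-choice posterior. Tie trials
#' (notably every block's first trial) carry no objective signal and are
#' excluded from the denominator.
#'
#' @inheritParams choice_inflexibility
#' @return A proportion in `[0, 1]`, or `NA` when every trial is a tie.
#' @export
suboptimal_investment <- function(trials, cfg) {
  opt <- optimal_asset(trials$posterior_pre, trials$framing, cfg)
  eligible <- opt != "tie"
  if (!any(eligible)) return(NA_real_)
  mean(trials$choice[eligible] != opt[eligible])
}

#' Belief estimation errors: optimism and absolute error
#'
#' The per-trial signed error is the reported probability minus 100 times the
#' objective posterior (after the trial's dividend). Optimism is the mean
#' signed error; absolute error is the mean of the per-trial absolute errors
#' (not the absolute value of the mean), so a reporter who is alternately too
#' high and too low has zero optimism but positive absolute error.
#'
#' @inheritParams choice_inflexibility
#' @return Named numeric vector `c(optimism, absolute_error)` in percentage
#'   points.
#' @export
belief_errors <- function(trials) {
  e <- trials$belief_report - 100 * trials$posterior_post
  c(optimism = mean(e), absolute_error = mean(abs(e)))
}

#' Incentive-compatible task payment
#'
#' One tenth of the cumulative realized payoff, plus 0.10 currency units for
#' each trial whose probability estimate is within 5 percentage points of the
#' objective Bayesian posterior.
#'
#' @inheritParams choice_inflexibility
#' @return Payment in currency units.
#' @export
task_payment <- function(trials) {
  e <- trials$belief_report - 100 * trials$posterior_post
  sum(trials$realized_payoff) / 10 + 0.10 * sum(abs(e) <= 5)
}

#' Behavioral profile of one participant
#'
#' Assembles the five criterion measures: choice inflexibility, first stock
#' choice, suboptimal investment, absolute estimation error, and optimism.
#' Metrics with an empty denominator are `NA` (flagged missing) and are
#' excluded downstream with a warning.
#'
#' @inheritParams choice_inflexibility
#' @return One-row data frame with the five metric columns.
#' @export
profile_participant <- function(trials, cfg, per_block = FALSE) {
  be <- belief_errors(trials)
  data.frame(
    choice_inflexibility = choice_inflexibility(trials, cfg, per_block),
    first_stock_choice = first_stock_choice(trials),
    suboptimal_investment = suboptimal_investment(trials, cfg),
    absolute_error = unname(be["absolute_error"]),
    optimism = unname(be["optimism"])
  )
}

#' Behavioral profiles for a whole cohort
#'
#' Vectorized equivalent of applying [profile_participant()] to each
#' participant's trials; identical results, computed with grouped sums for
#' speed on large simulated cohorts.
#'
#' @param trials Trial records for many participants (column `id` present).
#' @param cfg A [task_config()].
#'
#' @return Data frame with `id` and the five metric columns, one row per
#'   participant (ordered by first appearance of `id`).
#' @export
profile_cohort <- function(trials, cfg) {
  id <- trials$id
  ids <- unique(id)
  g <- match(id, ids)

  key <- paste(id, trials$block_index)
  fc <- block_first_choice(trials, key = key)
  opt <- optimal_asset(trials$posterior_pre, trials$framing, cfg)

  elig_inflex <- trials$trial_index > 0L & opt != "tie" & opt != fc
  persisted <- trials$choice == fc
  num <- group_sum(persisted & elig_inflex, g, length(ids))
  den <- group_sum(elig_inflex, g, length(ids))
  inflex <- ifelse(den > 0, num / den, NA_real_)

  first <- trials$trial_index == 0L
  fsc <- group_sum(first & trials$choice == "stock", g, length(ids)) /
    group_sum(first, g, length(ids))

  elig_sub <- opt != "tie"
  wrong <- trials$choice != opt
  nsub <- group_sum(elig_sub, g, length(ids))
  sub <- ifelse(nsub > 0,
                group_sum(elig_sub & wrong, g, length(ids)) / nsub, NA_real_)

  e <- trials$belief_report - 100 * trials$posterior_post
  ntr <- group_sum(rep(1, length(g)), g, length(ids))
  optm <- group_sum(e, g, length(ids)) / ntr
  abse <- group_sum(abs(e), g, length(ids)) / ntr

  data.frame(id = ids, choice_inflexibility = inflex,
             first_stock_choice = fsc, suboptimal_investment = sub,
             absolute_error = abse, optimism = optm)
}

group_sum <- function(x, g, n_groups) {
  out <- numeric(n_groups)
  s <- rowsum(as.numeric(x), g, reorder = FALSE)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}
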
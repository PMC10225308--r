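#' Generative agent parameters
#'
#' Interpretable parameters of the simulated decision-maker. Choices follow a
#' softmax on expected-value differences with a risk-propensity bonus and a
#' stickiness bonus toward the block's anchor choice; belief reports distort
#' the objective posterior on the log-odds scale and add report noise.
#'
#' @param stickiness kappa >= 0, value bonus toward repeating the block's
#'   anchor (by default first-trial) choice, in payoff units.
#' @param risk_propensity rho, additive bonus to the stock's value on every
#'   trial; governs the first-trial stock choice, in payoff units.
#' @param inv_temperature beta > 0, softmax inverse temperature (choice
#'   determinism), per payoff unit.
#' @param belief_slope lambda > 0, multiplicative distortion of the objective
#'   posterior's log-odds.
#' @param belief_bias delta, additive shift of the log-odds (positive values
#'   produce optimistic reports).
#' @param report_noise sigma_r >= 0, SD of Gaussian noise added to the
#'   reported probability, in percentage points.
#'
#' @return An object of class `agent_params` (a validated named list).
#' @examples
#' agent_params(stickiness = 2)
#' @export
agent_params <- function(stickiness = 1,
                         risk_propensity = 0.85,
                         inv_temperature = 1,
                         belief_slope = 1,
                         belief_bias = 0,
                         report_noise = 15) {
  par <- list(
    stickiness = as.numeric(stickiness),
    risk_propensity = as.numeric(risk_propensity),
    inv_temperature = as.numeric(inv_temperature),
    belief_slope = as.numeric(belief_slope),
    belief_bias = as.numeric(belief_bias),
    report_noise = as.numeric(report_noise)
  )
  validate_agent_params(par)
  class(par) <- "agent_params"
  par
}

#' @rdname agent_params
#' @format NULL
#' @export
agent_param_names <- c("stickiness", "risk_propensity", "inv_temperature",
                       "belief_slope", "belief_bias", "report_noise")

validate_agent_params <- function(par) {
  bad <- !vapply(par[agent_param_names], function(x) all(is.finite(x)),
                 logical(1))
  if (any(bad))
    stop("agent parameters must be finite: ",
         paste(agent_param_names[bad], collapse = ", "), call. = FALSE)
  if (any(par$inv_temperature <= 0))
    stop("inv_temperature must be > 0", call. = FALSE)
  if (any(par$stickiness < 0))
    stop("stickiness must be >= 0", call. = FALSE)
  if (any(par$report_noise < 0))
    stop("report_noise must be >= 0", call. = FALSE)
  if (any(par$belief_slope <= 0))
    stop("belief_slope must be > 0", call. = FALSE)
  invisible(par)
}

# softmax logit for choosing the stock; anchor_sign is +1 when the anchor
# choice was the stock, -1 when the bond, 0 on the anchor trial itself.
# All params may be vectors (recycled column-wise against matrix beliefs).
choice_logit <- function(posterior_pre, framing, anchor_sign, params, cfg) {
  ev <- asset_expected_values(posterior_pre, framing, cfg)
  params$inv_temperature *
    (ev$ev_stock - ev$ev_bond + params$risk_propensity +
       params$stickiness * anchor_sign)
}

#' Sample one asset choice
#'
#' Stochastic choice between stock and bond: the probability of choosing the
#' stock is a logistic function of the expected-value difference at the
#' current belief, plus the risk-propensity bonus and (after the first trial)
#' the stickiness bonus toward the block's anchor choice. On the first trial
#' the expected values tie at the prior, so P(stock) = logistic(beta * rho).
#'
#' @param posterior_pre Belief that the stock is good before this trial's
#'   dividend.
#' @param framing `"gain"` or `"loss"`.
#' @param trial_index 0-based trial index within the block.
#' @param anchor_choice The block's anchor choice (`"stock"`/`"bond"`; by
#'   default the first-trial choice). Ignored on trial 0.
#' @param params An [agent_params()].
#' @param cfg A [task_config()].
#'
#' @return `"stock"` or `"bond"`, sampled with the current RNG state.
#' @export
choose_asset <- function(posterior_pre, framing, trial_index, anchor_choice,
                         params, cfg) {
  anchor_sign <- if (trial_index == 0L) 0 else
    ifelse(anchor_choice == "stock", 1, -1)
  lgt <- choice_logit(posterior_pre, framing, anchor_sign, params, cfg)
  ifelse(stats::runif(length(lgt)) < stats::plogis(lgt), "stock", "bond")
}

#' Generate a belief report from the objective posterior
#'
#' The subjective log-odds are `lambda * logit(posterior) + delta`; the report
#' is 100 times the corresponding probability plus Gaussian noise, clipped to
#' `[0, 100]`. With `lambda = 1`, `delta = 0`, `sigma_r = 0` the report equals
#' the objective posterior in percentage points.
#'
#' @param posterior_post Objective posterior after this trial's dividend,
#'   strictly inside (0, 1); vectorized.
#' @param params An [agent_params()] (fields may be vectors).
#'
#' @return Reported probability in percentage points, 0-100.
#' @export
report_belief <- function(posterior_post, params) {
  if (any(posterior_post <= 0 | posterior_post >= 1))
    stop("'posterior_post' must lie strictly inside (0, 1)", call. = FALSE)
  subj <- params$belief_slope * stats::qlogis(posterior_post) +
    params$belief_bias
  report <- 100 * stats::plogis(subj) +
    stats::rnorm(length(posterior_post), 0, params$report_noise)
  pmin(pmax(report, 0), 100)
}

#' Simulate full task sessions for a cohort of agents
#'
#' Plays every agent through the shared session. Dividends are drawn per
#' agent and block from the block's payoff distribution; the objective
#' posterior is updated from the dividends alone (learning is independent of
#' choice, since the stock payoff is shown regardless of the choice made).
#' Choices and belief reports follow the agent model in [agent_params()].
#'
#' @param session Data frame from [build_session()].
#' @param params Either an [agent_params()] (one agent) or a data frame with
#'   an `id` column plus the six parameter columns named as in
#'   `agent_param_names` (one row per agent).
#' @param cfg A [task_config()].
#' @param seed Integer seed; identical seed, session, and parameters give
#'   identical trial records.
#' @param stick_anchor `"first"` (default) anchors stickiness to the block's
#'   first-trial choice; `"previous"` anchors to the immediately preceding
#'   trial's choice.
#'
#' @return A data frame of trial records: `id`, `block_index`, `trial_index`,
#'   `framing`, `stock_type`, `choice`, `dividend`, `is_high_dividend`,
#'   `n_high_so_far`, `t_so_far`, `posterior_pre`, `posterior_post`,
#'   `belief_report` (0-100), `realized_payoff`.
#' @examples
#' cfg <- task_config()
#' ses <- build_session(cfg, seed = 1)
#' tr <- simulate_cohort_sessions(ses, agent_params(), cfg, seed = 2)
#' nrow(tr)  # 60
#' @export
simulate_cohort_sessions <- function(session, params, cfg, seed = 1L,
                                     stick_anchor = c("first", "previous")) {
  validate_task_config(cfg)
  stick_anchor <- match.arg(stick_anchor)
  if (is.null(session) || nrow(session) == 0L)
    stop("'session' must contain at least one block", call. = FALSE)
  if (inherits(params, "agent_params"))
    params <- data.frame(id = 1L, as.list(unclass(params)))
  missing_cols <- setdiff(c("id", agent_param_names), names(params))
  if (length(missing_cols))
    stop("'params' lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  n_ag <- nrow(params)
  tpb <- cfg$trials_per_block
  set.seed(as.integer(seed))

  pvec <- lapply(params[agent_param_names], as.numeric)
  out <- vector("list", nrow(session))
  for (b in seq_len(nrow(session))) {
    blk <- session[b, ]
    pay <- frame_payoffs(blk$framing, cfg)
    p_high <- if (blk$stock_type == "good") cfg$q_high else 1 - cfg$q_high

    is_high <- matrix(stats::runif(n_ag * tpb) < p_high, n_ag, tpb)
    cum <- is_high %*% upper.tri(diag(tpb), diag = TRUE)  # row cumsums
    tmat <- matrix(seq_len(tpb), n_ag, tpb, byrow = TRUE)
    post <- bayes_posterior(cfg$prior_good, cfg$q_high, cum, tmat)
    pre <- cbind(rep(cfg$prior_good, n_ag), post[, -tpb, drop = FALSE])

    choice <- matrix(NA_character_, n_ag, tpb)
    lgt0 <- choice_logit(pre[, 1L], blk$framing, 0, pvec, cfg)
    choice[, 1L] <- ifelse(stats::runif(n_ag) < stats::plogis(lgt0),
                           "stock", "bond")
    if (stick_anchor == "first") {
      anchor_sign <- ifelse(choice[, 1L] == "stock", 1, -1)
      lgt <- choice_logit(pre[, -1L, drop = FALSE], blk$framing,
                          anchor_sign, pvec, cfg)
      u <- matrix(stats::runif(n_ag * (tpb - 1L)), n_ag, tpb - 1L)
      choice[, -1L] <- ifelse(u < stats::plogis(lgt), "stock", "bond")
    } else {
      for (j in 2:tpb) {
        anchor_sign <- ifelse(choice[, j - 1L] == "stock", 1, -1)
        lgt <- choice_logit(pre[, j], blk$framing, anchor_sign, pvec, cfg)
        choice[, j] <- ifelse(stats::runif(n_ag) < stats::plogis(lgt),
                              "stock", "bond")
      }
    }

    subj <- pvec$belief_slope * stats::qlogis(post) + pvec$belief_bias
    noise <- matrix(stats::rnorm(n_ag * tpb), n_ag, tpb) * pvec$report_noise
    report <- pmin(pmax(100 * stats::plogis(subj) + noise, 0), 100)

    dividend <- ifelse(is_high, pay$high, pay$low)
    realized <- ifelse(choice == "stock", dividend, pay$bond)

    out[[b]] <- data.frame(
      id = rep(params$id, tpb),
      block_index = blk$block_index,
      trial_index = rep(seq_len(tpb) - 1L, each = n_ag),
      framing = blk$framing,
      stock_type = blk$stock_type,
      choice = as.vector(choice),
      dividend = as.vector(dividend),
      is_high_dividend = as.vector(is_high),
      n_high_so_far = as.vector(cum),
      t_so_far = as.vector(tmat),
      posterior_pre = as.vector(pre),
      posterior_post = as.vector(post),
      belief_report = as.vector(report),
      realized_payoff = as.vector(realized),
      stringsAsFactors = FALSE
    )
  }
  trials <- do.call(rbind, out)
  trials <- trials[order(trials$id, trials$block_index, trials$trial_index), ]
  rownames(trials) <- NULL
  trials
}

#' Simulate one agent's session
#'
#' Convenience wrapper around [simulate_cohort_sessions()] for a single agent.
#'
#' @inheritParams simulate_cohort_sessions
#' @param params An [agent_params()].
#' @return A data frame of trial records (see [simulate_cohort_sessions()]).
#' @export
simulate_agent_session <- function(session, params, cfg, seed = 1L,
                                   stick_anchor = c("first", "previous")) {
  stopifnot(inherits(params, "agent_params"))
  simulate_cohort_sessions(session, params, cfg, seed = seed,
                           stick_anchor = match.arg(stick_anchor))
}
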
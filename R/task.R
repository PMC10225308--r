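#' Configure the risky investment task
#'
#' Builds the configuration for the stock-versus-bond learning task: a
#' 2 (framing: gain or loss) x 2 (stock payoff distribution: good or bad)
#' design played in fixed-length blocks. Within a block the stock pays from a
#' single distribution; a good stock pays its high dividend with probability
#' `q_high`, a bad stock with probability `1 - q_high`. The bond pays a
#' certain amount with the same sign as the frame.
#'
#' @param n_blocks Number of blocks per session.
#' @param trials_per_block Trials within each block (at least 2).
#' @param gain_stock_payoffs Length-2 numeric, `c(low, high)` stock dividends
#'   in the gain frame.
#' @param loss_stock_payoffs Length-2 numeric, `c(low, high)` stock dividends
#'   in the loss frame. "High" is the better (less negative) outcome.
#' @param gain_bond,loss_bond Certain bond payoff in each frame.
#' @param q_high Probability that a good stock pays the high dividend on a
#'   trial; a bad stock pays it with probability `1 - q_high`.
#' @param prior_good Prior probability that a block's stock is good.
#' @param n_gain_blocks Number of gain-framed blocks (the rest are loss).
#'
#' @return An object of class `task_config` (a validated list).
#' @examples
#' cfg <- task_config()
#' cfg$q_high
#' @export
task_config <- function(n_blocks = 10,
                        trials_per_block = 6,
                        gain_stock_payoffs = c(2, 10),
                        loss_stock_payoffs = c(-10, -2),
                        gain_bond = 6,
                        loss_bond = -6,
                        q_high = 0.7,
                        prior_good = 0.5,
                        n_gain_blocks = 5) {
  cfg <- list(
    n_blocks = as.integer(n_blocks),
    trials_per_block = as.integer(trials_per_block),
    gain_stock_payoffs = as.numeric(gain_stock_payoffs),
    loss_stock_payoffs = as.numeric(loss_stock_payoffs),
    gain_bond = as.numeric(gain_bond),
    loss_bond = as.numeric(loss_bond),
    q_high = as.numeric(q_high),
    prior_good = as.numeric(prior_good),
    n_gain_blocks = as.integer(n_gain_blocks)
  )
  validate_task_config(cfg)
  class(cfg) <- "task_config"
  cfg
}

validate_task_config <- function(cfg) {
  stop_cfg <- function(field, msg) {
    stop(sprintf("invalid task configuration: field '%s' %s", field, msg),
         call. = FALSE)
  }
  if (is.na(cfg$n_blocks) || cfg$n_blocks < 1L)
    stop_cfg("n_blocks", "must be a positive count")
  if (is.na(cfg$trials_per_block) || cfg$trials_per_block < 2L)
    stop_cfg("trials_per_block", "must be at least 2")
  if (length(cfg$gain_stock_payoffs) != 2L ||
      cfg$gain_stock_payoffs[2L] <= cfg$gain_stock_payoffs[1L])
    stop_cfg("gain_stock_payoffs", "must be c(low, high) with high > low")
  if (length(cfg$loss_stock_payoffs) != 2L ||
      cfg$loss_stock_payoffs[2L] <= cfg$loss_stock_payoffs[1L])
    stop_cfg("loss_stock_payoffs", "must be c(low, high) with high > low")
  if (!is.finite(cfg$q_high) || cfg$q_high <= 0 || cfg$q_high >= 1)
    stop_cfg("q_high", "must lie strictly between 0 and 1")
  if (!is.finite(cfg$prior_good) || cfg$prior_good <= 0 || cfg$prior_good >= 1)
    stop_cfg("prior_good", "must lie strictly between 0 and 1")
  if (is.na(cfg$n_gain_blocks) || cfg$n_gain_blocks < 0L ||
      cfg$n_gain_blocks > cfg$n_blocks)
    stop_cfg("n_gain_blocks", "must be between 0 and n_blocks")
  invisible(cfg)
}

# payoff constants for one frame: c(low, high, bond)
frame_payoffs <- function(framing, cfg) {
  gain <- framing == "gain"
  list(
    low  = ifelse(gain, cfg$gain_stock_payoffs[1L], cfg$loss_stock_payoffs[1L]),
    high = ifelse(gain, cfg$gain_stock_payoffs[2L], cfg$loss_stock_payoffs[2L]),
    bond = ifelse(gain, cfg$gain_bond, cfg$loss_bond)
  )
}

#' Build the shared session (block order and stock types)
#'
#' Draws a pseudorandom block order with exactly `n_gain_blocks` gain-framed
#' blocks, and assigns each block a good or bad stock with probability
#' `prior_good`. The session is shared across all simulated participants, so
#' the objective prior is correct for every block.
#'
#' @param cfg A [task_config()].
#' @param seed Integer seed; identical seeds give identical sessions.
#'
#' @return A data frame with one row per block: `block_index` (0-based),
#'   `framing` (`"gain"`/`"loss"`), and `stock_type` (`"good"`/`"bad"`).
#' @examples
#' build_session(task_config(), seed = 1)
#' @export
build_session <- function(cfg, seed = 1L) {
  validate_task_config(cfg)
  set.seed(as.integer(seed))
  framing <- sample(rep(c("gain", "loss"),
                        c(cfg$n_gain_blocks, cfg$n_blocks - cfg$n_gain_blocks)))
  stock_type <- ifelse(stats::runif(cfg$n_blocks) < cfg$prior_good,
                       "good", "bad")
  data.frame(
    block_index = seq_len(cfg$n_blocks) - 1L,
    framing = framing,
    stock_type = stock_type,
    stringsAsFactors = FALSE
  )
}

#' Draw stock dividends for a block
#'
#' Samples dividends from the block's payoff distribution using the current
#' RNG state: a good stock pays the high (better) dividend with probability
#' `q_high`, a bad stock with probability `1 - q_high`. In the loss frame the
#' "high" dividend is the less negative payoff.
#'
#' @param block One row of a [build_session()] data frame (or any list with
#'   `framing` and `stock_type`).
#' @param cfg A [task_config()].
#' @param n Number of draws.
#'
#' @return A data frame with columns `dividend` and `is_high`.
#' @export
draw_dividend <- function(block, cfg, n = 1L) {
  validate_task_config(cfg)
  pay <- frame_payoffs(block$framing, cfg)
  p_high <- if (block$stock_type == "good") cfg$q_high else 1 - cfg$q_high
  is_high <- stats::runif(n) < p_high
  data.frame(dividend = ifelse(is_high, pay$high, pay$low), is_high = is_high)
}

#' Objective posterior probability that the stock is good
#'
#' Closed-form Bayesian posterior that a block's stock pays from the good
#' distribution after observing `n` high dividends in `t` trials, starting
#' from prior `p`, when a good stock pays high with probability `q` (and a bad
#' stock with `1 - q`):
#' \deqn{P(good \mid n, t) = \frac{1}{1 + \frac{1-p}{p}
#'   \left(\frac{q}{1-q}\right)^{t-2n}}}
#' Equivalently, the prior odds are multiplied by the likelihood ratio
#' \eqn{(q/(1-q))^{2n-t}}. With no evidence (`t = 0`) the prior is returned;
#' the posterior is strictly increasing in `n` at fixed `t` (for `q > 1/2`)
#' and decreasing in `t` at fixed `n`.
#'
#' @param p Prior probability the stock is good, in (0, 1).
#' @param q Probability a good stock pays the high dividend, in (0, 1).
#' @param n Number of high dividends observed (vectorized).
#' @param t Number of trials observed (vectorized, `n <= t`).
#'
#' @return Posterior probabilities, same shape as `n`/`t`.
#' @examples
#' bayes_posterior(0.5, 0.7, 1, 1)  # 0.7
#' bayes_posterior(0.5, 0.7, 0, 1)  # 0.3
#' @export
bayes_posterior <- function(p, q, n, t) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("prior 'p' must lie strictly between 0 and 1", call. = FALSE)
  if (any(!is.finite(q)) || any(q <= 0) || any(q >= 1))
    stop("'q' must lie strictly between 0 and 1", call. = FALSE)
  if (any(n < 0) || any(n > t))
    stop("counts must satisfy 0 <= n <= t", call. = FALSE)
  1 / (1 + ((1 - p) / p) * (q / (1 - q))^(t - 2 * n))
}

#' Expected values of the two assets at a given belief
#'
#' Expected dividend of the stock under the current belief that it is good,
#' and the certain bond payoff, in the given frame. At belief equal to the
#' prior 0.5 the two expected values tie exactly (payoff symmetry), which is
#' why every block's first trial carries no objective choice signal.
#'
#' @param belief Probability the stock is good, in `[0, 1]`; may be a vector
#'   or matrix.
#' @param framing `"gain"` or `"loss"`; scalar or vector matching `belief`.
#' @param cfg A [task_config()].
#'
#' @return A list with `ev_stock` and `ev_bond` (shapes follow `belief`).
#' @examples
#' asset_expected_values(1, "gain", task_config())  # stock 7.6 vs bond 6
#' @export
asset_expected_values <- function(belief, framing, cfg) {
  if (any(belief < 0 | belief > 1, na.rm = TRUE))
    stop("'belief' must lie in [0, 1]", call. = FALSE)
  pay <- frame_payoffs(framing, cfg)
  q <- cfg$q_high
  ev_good <- q * pay$high + (1 - q) * pay$low
  ev_bad <- (1 - q) * pay$high + q * pay$low
  list(ev_stock = belief * ev_good + (1 - belief) * ev_bad,
       ev_bond = pay$bond + 0 * belief)
}
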
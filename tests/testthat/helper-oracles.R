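# Independent oracles and fixture builders used across test files.

# Brute-force Bayes: enumerate P(n high in t | stock type) for both types and
# apply Bayes' rule directly. Independent of the closed-form implementation.
brute_bayes <- function(p, q, n, t) {
  like_good <- choose(t, n) * q^n * (1 - q)^(t - n)
  like_bad <- choose(t, n) * (1 - q)^n * q^(t - n)
  like_good * p / (like_good * p + like_bad * (1 - p))
}

# Grid-search oracle for the first canonical correlation of a 2x2 problem:
# unit-norm weights parameterized by angle, exhaustive correlation scan.
grid_cca_r1 <- function(x, y, step = 0.002) {
  theta <- seq(0, pi, by = step)
  A <- rbind(cos(theta), sin(theta))
  sx <- scale(as.matrix(x) %*% A)
  sy <- scale(as.matrix(y) %*% A)
  max(abs(crossprod(sx, sy) / (nrow(x) - 1)))
}

# Hand-built single-block trial table (one participant) for metric tests.
# Dividend high/low flags are given; posteriors are filled in from the
# closed form the rest of the package also uses (checked against
# brute_bayes elsewhere).
make_block <- function(cfg, framing, stock_type, is_high, choice,
                       block_index = 0L, belief_report = NULL) {
  tpb <- length(is_high)
  pay <- if (framing == "gain")
    list(low = cfg$gain_stock_payoffs[1], high = cfg$gain_stock_payoffs[2],
         bond = cfg$gain_bond)
  else
    list(low = cfg$loss_stock_payoffs[1], high = cfg$loss_stock_payoffs[2],
         bond = cfg$loss_bond)
  nh <- cumsum(is_high)
  post <- bayes_posterior(cfg$prior_good, cfg$q_high, nh, seq_len(tpb))
  pre <- c(cfg$prior_good, post[-tpb])
  dividend <- ifelse(is_high, pay$high, pay$low)
  if (is.null(belief_report)) belief_report <- 100 * post
  data.frame(
    id = 1L, block_index = block_index, trial_index = seq_len(tpb) - 1L,
    framing = framing, stock_type = stock_type, choice = choice,
    dividend = dividend, is_high_dividend = is_high,
    n_high_so_far = nh, t_so_far = seq_len(tpb),
    posterior_pre = pre, posterior_post = post,
    belief_report = belief_report,
    realized_payoff = ifelse(choice == "stock", dividend, pay$bond),
    stringsAsFactors = FALSE
  )
}

# Simulate a linked cohort end to end and return features + cohort.
simulate_linked_cohort <- function(n, seed, ccfg = cohort_config(),
                                   tcfg = task_config()) {
  ccfg$n_participants <- as.integer(n)
  ch <- sample_cohort(ccfg, seed = seed)
  ch <- link_agent_params(ch, ccfg, seed = seed + 101L)
  ses <- build_session(tcfg, seed = seed + 202L)
  tr <- simulate_cohort_sessions(ses, ch, tcfg, seed = seed + 303L)
  list(cohort = ch, trials = tr, features = profile_cohort(tr, tcfg),
       session = ses)
}

null_cohort_config <- function(n = 35) {
  cfg <- cohort_config(n_participants = n)
  cfg$linkage[] <- 0
  cfg
}

metric_cols <- c("choice_inflexibility", "first_stock_choice",
                 "suboptimal_investment", "absolute_error", "optimism")
predictor_cols <- c("age", "midbrain", "amygdala", "insula",
                    "anterior_cingulate")
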
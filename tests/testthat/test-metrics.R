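cfg <- task_config()

test_that("optimal asset follows expected value, with first-trial ties", {
  expect_identical(optimal_asset(0.5, "gain", cfg), "tie")
  expect_identical(optimal_asset(0.5, "loss", cfg), "tie")
  expect_identical(optimal_asset(0.3, "gain", cfg), "bond")  # EV 5.36 < 6
  expect_identical(optimal_asset(0.7, "loss", cfg), "stock") # -5.36 > -6
  expect_identical(optimal_asset(0.7, "gain", cfg), "stock")
})

test_that("choice inflexibility on a hand-built persistently-wrong block", {
  # bad/gain block, first choice stock, all low dividends: posteriors
  # 0.3, 0.155, ... make the bond optimal on trials 1-5
  blk <- make_block(cfg, "gain", "bad", is_high = rep(FALSE, 6),
                    choice = rep("stock", 6))
  expect_true(all(optimal_asset(blk$posterior_pre[-1], "gain", cfg) == "bond"))
  expect_equal(choice_inflexibility(blk, cfg), 1)           # 5/5 persisted
  expect_equal(suboptimal_investment(blk, cfg), 1)          # 5/5 wrong

  switcher <- blk
  switcher$choice <- c("stock", rep("bond", 5))
  expect_equal(choice_inflexibility(switcher, cfg), 0)      # 0/5
  expect_equal(suboptimal_investment(switcher, cfg), 0)
})

test_that("inflexibility is flagged missing when no trial is eligible", {
  # good/gain block, all high dividends, stock chosen throughout: the first
  # choice is optimal on every non-tie trial, so nothing is eligible
  blk <- make_block(cfg, "gain", "good", is_high = rep(TRUE, 6),
                    choice = rep("stock", 6))
  expect_true(is.na(choice_inflexibility(blk, cfg)))
  expect_equal(suboptimal_investment(blk, cfg), 0)
})

test_that("per-block averaging option changes the aggregation, not the logic", {
  b1 <- make_block(cfg, "gain", "bad", rep(FALSE, 6),
                   c("stock", "stock", rep("bond", 4)), block_index = 0L)
  b2 <- make_block(cfg, "gain", "bad", rep(FALSE, 6),
                   rep("stock", 6), block_index = 1L)
  tr <- rbind(b1, b2)
  expect_equal(choice_inflexibility(tr, cfg), 6 / 10)            # pooled
  expect_equal(choice_inflexibility(tr, cfg, per_block = TRUE),
               mean(c(1 / 5, 1)))                                # averaged
})

test_that("first stock choice counts blocks", {
  blocks <- lapply(0:9, function(b)
    make_block(cfg, "gain", "good", rep(TRUE, 6),
               c(if (b < 7) "stock" else "bond", rep("bond", 5)),
               block_index = b))
  tr <- do.call(rbind, blocks)
  expect_equal(first_stock_choice(tr), 0.7)
  tr_all <- do.call(rbind, lapply(blocks, function(b) {
    b$choice[1] <- "stock"; b
  }))
  expect_equal(first_stock_choice(tr_all), 1.0)
})

test_that("risk-neutral agents choose the stock first about half the time", {
  ses <- build_session(task_config(n_blocks = 100, n_gain_blocks = 50),
                       seed = 1)
  par <- agent_params(risk_propensity = 0)
  tcfg <- task_config(n_blocks = 100, n_gain_blocks = 50)
  tr <- do.call(rbind, lapply(1:100, function(s) {
    t1 <- simulate_agent_session(ses, par, tcfg, seed = s); t1$id <- s; t1
  }))
  fsc <- profile_cohort(tr, tcfg)$first_stock_choice
  expect_lt(abs(mean(fsc) - 0.5), 3 * sqrt(0.25 / 1e4))
})

test_that("belief errors separate signed bias from absolute error", {
  blk <- make_block(cfg, "gain", "good", rep(TRUE, 6), rep("stock", 6))
  expect_equal(belief_errors(blk), c(optimism = 0, absolute_error = 0))
  # low posteriors (bad block, all low dividends) keep +10 inside [0, 100]
  low <- make_block(cfg, "gain", "bad", rep(FALSE, 6), rep("stock", 6))
  high <- low
  high$belief_report <- 100 * low$posterior_post + 10
  expect_equal(belief_errors(high),
               c(optimism = 10, absolute_error = 10))
  alt <- low
  alt$belief_report <- 100 * low$posterior_post + c(10, -10, 10, -10, 10, -10)
  expect_equal(belief_errors(alt), c(optimism = 0, absolute_error = 10))
})

test_that("task payment combines payoff share and accuracy bonus", {
  blk <- make_block(cfg, "gain", "good", rep(TRUE, 6), rep("stock", 6))
  # perfectly calibrated: bonus on all trials
  expect_equal(task_payment(blk), sum(blk$realized_payoff) / 10 + 0.6)
  off <- blk
  off$belief_report <- pmax(100 * blk$posterior_post - 20, 0)
  expect_equal(task_payment(off), sum(blk$realized_payoff) / 10)
  # constructed ledger: cumulative 500 with 20 accurate estimates -> 52;
  # bad blocks with all-low dividends keep posteriors low so no report clips
  many <- do.call(rbind, lapply(0:9, function(b)
    make_block(cfg, "gain", "bad", rep(FALSE, 6), rep("stock", 6),
               block_index = b)))
  many$realized_payoff <- rep(500 / 60, 60)
  many$belief_report <- 100 * many$posterior_post +
    rep(c(4, 50), c(20, 40))  # 20 within 5 points
  expect_equal(task_payment(many), 500 / 10 + 0.10 * 20)
})

test_that("profiles are invariant to row order and match per-participant ops", {
  sim <- simulate_linked_cohort(30, seed = 77)
  prof <- profile_cohort(sim$trials, task_config())
  set.seed(1)
  shuffled <- sim$trials[sample(nrow(sim$trials)), ]
  prof_sh <- profile_cohort(shuffled, task_config())
  prof_sh <- prof_sh[match(prof$id, prof_sh$id), ]
  rownames(prof_sh) <- NULL
  expect_equal(prof, prof_sh)
  # vectorized cohort profiling agrees with the per-participant operations
  for (i in c(1, 7, 30)) {
    one <- sim$trials[sim$trials$id == i, ]
    expect_equal(as.numeric(profile_participant(one, task_config())),
                 as.numeric(prof[prof$id == i, -1]))
  }
})

test_that("absolute error dominates |optimism| and errors correlate (Jensen)", {
  sim <- simulate_linked_cohort(300, seed = 13)
  prof <- sim$features
  expect_true(all(prof$absolute_error >= abs(prof$optimism) - 1e-12))
  expect_true(all(prof$choice_inflexibility >= 0 &
                    prof$choice_inflexibility <= 1, na.rm = TRUE))
  expect_true(all(prof$suboptimal_investment >= 0 &
                    prof$suboptimal_investment <= 1))
  # inflexible choices on eligible trials are wrong by construction
  expect_gt(cor(prof$choice_inflexibility, prof$suboptimal_investment,
                use = "complete.obs"), 0)
})
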
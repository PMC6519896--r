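test_that("runs are reproducible and traces well formed", {
  cfg <- abm_config(population_preset("diverse", "abm"), truth_tm2(),
                    "SC", strategy_mode("soft", 0.1), iterations = 400,
                    burn_in = 100, seed = 301)
  r1 <- abm_run(cfg)
  r2 <- abm_run(cfg)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$metrics, r2$metrics)
  expect_equal(nrow(r1$records), 400)
  # a winning proposal becomes the consensus, a losing one never does
  with(r1$records[!r1$records$is_replication, ], {
    expect_true(all(global_after[proposed_won] == proposed[proposed_won]))
    expect_true(all(global_after[!proposed_won] ==
                      global_before[!proposed_won]))
  })
  # replication flags only carry a reproduced verdict
  expect_true(all(is.na(r1$records$reproduced[!r1$records$is_replication])))
  expect_false(anyNA(r1$records$reproduced[r1$records$is_replication]))
})

test_that("the replicator re-runs her predecessor's exact contest pair", {
  cfg <- abm_config(population(rey = 1, tess = 0.0001), truth_tm2(),
                    "AIC", strategy_mode("soft", 0.1), iterations = 10,
                    burn_in = 0)
  d1 <- dataset_with_seed(cfg$truth, 311)
  d2 <- dataset_with_seed(cfg$truth, 312)
  state <- list(global = parse_model("1+2"), prev = NULL)

  set.seed(313)
  s1 <- abm_step(state, cfg, data = d1, scientist = "tess")
  r1 <- s1$record
  s2 <- abm_step(s1$state, cfg, data = d2, scientist = "rey")
  r2 <- s2$record
  # the pair is the predecessor's, even when the consensus moved on
  expect_identical(r2$proposed, r1$proposed)
  expect_identical(r2$global_before, r1$global_before)
  if (r1$proposed_won) expect_false(r2$global_before == r1$global_after)
  # her verdict matches iff the outcomes agree, and her winner is installed
  ct <- contest(parse_model(r2$proposed), parse_model(r2$global_before),
                d2, "AIC")
  expect_equal(r2$reproduced, ct$proposed_won == r1$proposed_won)
  expect_equal(r2$global_after,
               model_label(if (ct$proposed_won) parse_model(r2$proposed)
                           else parse_model(r2$global_before)))

  # a replication of a replication re-runs the same pair again
  d3 <- dataset_with_seed(cfg$truth, 314)
  s3 <- abm_step(s2$state, cfg, data = d3, scientist = "rey")
  expect_identical(s3$record$proposed, r1$proposed)
  expect_identical(s3$record$global_before, r1$global_before)
})

test_that("identical replication data always reproduces the original", {
  cfg <- abm_config(population(rey = 0.5, bo = 0.5), truth_tm2(),
                    "SC", strategy_mode("hard"), iterations = 10,
                    burn_in = 0)
  d <- dataset_with_seed(cfg$truth, 321)
  state <- list(global = parse_model("1+2+3"), prev = NULL)
  set.seed(322)
  s1 <- abm_step(state, cfg, data = d, scientist = "bo")
  s2 <- abm_step(s1$state, cfg, data = d, scientist = "rey")
  expect_true(s2$record$reproduced)
})

test_that("a replicator drawn first is replaced by a proposer", {
  cfg <- abm_config(population(rey = 1), truth_tm2(), "AIC",
                    iterations = 5, burn_in = 0)
  set.seed(331)
  s1 <- abm_step(list(global = parse_model("1"), prev = NULL), cfg)
  expect_false(s1$record$is_replication)
  expect_true(s1$record$scientist %in% c("tess", "mave", "bo"))
})

test_that("run metrics implement the documented conventions", {
  truth_lab <- "1+2+3+12"
  recs <- data.frame(
    scientist = c("tess", "rey", "bo", "rey", "rey"),
    proposed = c("1+2+3+12", "1+2+3+12", "1", "1", "1"),
    global_before = c("1", "1", truth_lab, truth_lab, truth_lab),
    global_after = c(truth_lab, truth_lab, truth_lab, truth_lab, "1"),
    proposed_won = c(TRUE, TRUE, FALSE, FALSE, TRUE),
    is_replication = c(FALSE, TRUE, FALSE, TRUE, TRUE),
    reproduced = c(NA, TRUE, NA, TRUE, FALSE),
    stringsAsFactors = FALSE)
  m <- run_metrics(recs, init = "1", truth_label = truth_lab, burn_in = 0)
  expect_equal(m$first_passage, 1L)   # reached after the first experiment
  expect_false(m$censored)
  expect_equal(m$time_at_truth, 4 / 5)
  # states: 1, TM, TM, TM, TM, 1 -> from TM, stays 3 times out of 4
  expect_equal(m$stickiness, 3 / 4)
  expect_equal(m$repro_overall, 2 / 3)
  expect_equal(m$repro_at_truth, 1 / 2)
  expect_equal(m$repro_elsewhere, 1)
  # starting at the truth means first passage zero by convention
  m0 <- run_metrics(recs, init = truth_lab, truth_label = truth_lab)
  expect_equal(m0$first_passage, 0L)
  # no replication experiments: undefined rates
  m1 <- run_metrics(recs[1, ], init = "1", truth_label = truth_lab)
  expect_true(is.na(m1$repro_overall))
})

test_that("censoring is flagged when the truth is never reached", {
  recs <- data.frame(scientist = "tess", proposed = "1+2",
                     global_before = "1", global_after = "1+2",
                     proposed_won = TRUE, is_replication = FALSE,
                     reproduced = NA, stringsAsFactors = FALSE)
  m <- run_metrics(recs, init = "1", truth_label = "1+2+3+12")
  expect_true(m$censored)
  expect_true(is.na(m$first_passage))
})

test_that("zero noise makes truth absorbing and replications certain", {
  # with sigma^2 = 0 every model containing the truth fits perfectly and
  # contests involving the truth are decided deterministically (fit, then
  # parameter count), so once found the truth never falls and replications
  # of contests against it always reproduce
  cfg0 <- true_model_config(parse_model("1+2+3+12"), noise_ratio = 0)
  cfgA <- abm_config(population(tess = 0.4, mave = 0.2, bo = 0.2,
                                rey = 0.2),
                     cfg0, "SC", strategy_mode("soft", 0.1),
                     iterations = 5000, burn_in = 2000, seed = 341)
  run <- abm_run(cfgA)
  m <- run$metrics
  expect_false(m$censored)
  expect_gt(m$time_at_truth, 0.99)
  expect_gt(m$stickiness, 0.99)
  expect_equal(m$repro_at_truth, 1)
  expect_gt(m$repro_overall, 0.95)
})

test_that("the reference engine matches the chain's stationary law", {
  cfg <- truth_tm2(noise_ratio = "1:4")
  pop <- population_preset("mave", "markov")
  popA <- population(tess = pop[["tess"]], mave = pop[["mave"]],
                     bo = pop[["bo"]])
  cfgA <- abm_config(popA, cfg, "SC", strategy_mode("soft", 0.1),
                     iterations = 3000, burn_in = 500, seed = 351)
  run <- abm_run(cfgA, engine = "r")
  set.seed(352)
  wt <- win_table(cfg, reps = 4000)
  ch <- transition_matrix(pop, wt, "SC")
  pi_tm <- stationary_distribution(ch)[["1+2+3+12"]]
  post <- run$records$global_after[-(1:500)]
  freq <- mean(post == "1+2+3+12")
  # batch-means standard error over 25 batches of 100
  bm <- tapply(post == "1+2+3+12", rep(1:25, each = 100), mean)
  se <- sd(bm) / sqrt(25)
  expect_lt(abs(freq - pi_tm), 4 * se + 0.03)
})

test_that("stopping at the first passage truncates the trace", {
  cfg <- abm_config(population_preset("mave", "abm"), truth_tm2(),
                    "SC", strategy_mode("soft", 0.1), iterations = 5000,
                    burn_in = 0, seed = 361, stop_at_truth = TRUE)
  run <- abm_run(cfg)
  expect_false(run$metrics$censored)
  expect_equal(nrow(run$records), run$metrics$first_passage)
  expect_equal(run$records$global_after[nrow(run$records)], "1+2+3+12")
})
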
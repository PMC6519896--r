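test_that("two-state chains match their closed forms", {
  p <- 0.3; q <- 0.7
  Tm <- matrix(c(1 - p, p, q, 1 - q), 2, 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("a", "b")))
  pi_ <- stationary_distribution(Tm)
  expect_equal(unname(pi_), c(q / (p + q), p / (p + q)), tolerance = 1e-12)
  sym <- matrix(c(0.8, 0.2, 0.2, 0.8), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(unname(stationary_distribution(sym)), c(0.5, 0.5))
  # geometric first passage: MFPT(a -> b) = 1/p
  m <- mean_first_passage(Tm, "b")
  expect_equal(unname(m), c(1 / p, 0), tolerance = 1e-12)
  # jump chain: with self-loops removed each state reaches the other in one
  mj <- mean_first_passage(Tm, "b", time = "updates")
  expect_equal(unname(mj), c(1, 0), tolerance = 1e-12)
})

test_that("three-state MFPT agrees with the truncated-propagation oracle", {
  Tm <- toy3()
  for (target in 1:3) {
    m <- mean_first_passage(Tm, rownames(Tm)[target])
    for (from in setdiff(1:3, target)) {
      oracle <- mfpt_by_truncation(Tm, target, from)
      expect_equal(unname(m[from]), oracle, tolerance = 1e-8)
    }
    expect_equal(unname(m[target]), 0)
  }
})

test_that("stationary distributions satisfy pi T = pi to 1e-10", {
  Tm <- toy3()
  pi_ <- stationary_distribution(Tm)
  expect_equal(sum(pi_), 1, tolerance = 1e-12)
  expect_lt(max(abs(drop(pi_ %*% Tm) - pi_)), 1e-10)
})

test_that("reducible chains are reported, not silently solved", {
  Tm <- diag(2)
  dimnames(Tm) <- list(c("a", "b"), c("a", "b"))
  err <- tryCatch(stationary_distribution(Tm), error = identity)
  expect_s3_class(err, "mc_reducible_chain")
  expect_length(err$classes, 2)
  # unreachable target in first passage
  expect_error(mean_first_passage(Tm, "b"),
               class = "mc_unreachable_target")
})

test_that("transition matrices from win tables are proper and composable", {
  cfg <- truth_tm2(noise_ratio = "1:4")
  set.seed(201)
  wt <- win_table(cfg, reps = 800)
  for (pn in c("tess", "mave", "bo", "diverse")) {
    ch <- transition_matrix(population_preset(pn, "markov"), wt, "AIC")
    expect_equal(unname(rowSums(ch$T)), rep(1, 14), tolerance = 1e-12)
    expect_true(all(ch$T >= 0 & ch$T <= 1))
  }
  # pure-Mave population: off-diagonals are exactly p_win / 14
  mave_only <- population(mave = 1)
  ch <- transition_matrix(mave_only, wt, "SC", strategy_mode("hard"))
  W <- wt$sc
  off <- ch$T; diag(off) <- 0
  expect_equal(off, t(W) / 14, tolerance = 1e-12,
               ignore_attr = TRUE)
  # stickiness is the diagonal complement of the truth row
  tm_lab <- "1+2+3+12"
  expect_equal(stickiness(ch),
               1 - sum(W[setdiff(rownames(W), tm_lab), tm_lab]) / 14,
               tolerance = 1e-12)
})

test_that("a hand-set two-state win table reproduces the arithmetic", {
  # single type (Mave on a 2-model toy is not available; use matrix math on
  # a constructed chain): T[g, m] = q(m|g) p_win(m, g)
  p_win <- matrix(c(0, 0.6, 0.2, 0), 2, 2,   # p_win[proposed, global]
                  dimnames = list(c("g1", "g2"), c("g1", "g2")))
  q <- matrix(0.5, 2, 2)
  Tm <- q * t(p_win)
  diag(Tm) <- 0
  diag(Tm) <- 1 - rowSums(Tm)
  expect_equal(Tm["g1", "g2"], 0.5 * 0.6)
  expect_equal(Tm["g1", "g1"], 1 - 0.3)
  expect_equal(unname(rowSums(Tm)), c(1, 1))
})

test_that("an absorbing truth has stickiness one and is the stationary mass", {
  cfg <- truth_tm2()
  set.seed(202)
  wt <- win_table(cfg, reps = 400)
  # force the truth to never lose: zero win probability against it
  tm_lab <- "1+2+3+12"
  for (s in c("aic", "sc")) wt[[s]][, tm_lab] <- 0
  ch <- transition_matrix(population_preset("diverse", "markov"), wt, "AIC")
  expect_equal(stickiness(ch), 1)
  pi_ <- stationary_distribution(ch)
  expect_equal(unname(pi_[tm_lab]), 1, tolerance = 1e-9)
})

test_that("boosting the truth's win probabilities cannot hurt its long run", {
  # numerical monotonicity check on a toy instance
  base <- toy3()
  target <- "b"
  pi0 <- stationary_distribution(base)[target]
  up <- base
  up[, "b"] <- up[, "b"] + c(0.1, 0, 0.1)   # more mass into b from a and c
  up <- up / rowSums(up)
  pi1 <- stationary_distribution(up)[target]
  expect_gte(pi1, pi0)
})

test_that("chain metrics bundle the per-truth properties consistently", {
  cfg <- truth_tm2()
  set.seed(203)
  wt <- win_table(cfg, reps = 800)
  ch <- transition_matrix(population_preset("mave", "markov"), wt, "SC")
  cm <- chain_metrics(ch)
  expect_equal(cm$time_at_truth, unname(cm$stationary["1+2+3+12"]))
  expect_equal(cm$stickiness, unname(ch$T["1+2+3+12", "1+2+3+12"]))
  keep <- setdiff(names(cm$mfpt), "1+2+3+12")
  expect_equal(cm$mfpt_mean, mean(cm$mfpt[keep]))
  expect_true(cm$mfpt_updates_mean < cm$mfpt_mean)  # self-loops dominate
})
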
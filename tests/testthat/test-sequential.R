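mk_trials <- function(offers, choices, rewards, block_type = "win",
                      id = "p1", block = 1L, rt = NA_integer_) {
  T <- nrow(offers)
  payoff <- if (block_type == "win") rewards else rewards - 1L
  payoff[is.na(choices)] <- NA_integer_
  data.frame(participant_id = id, block = block, block_type = block_type,
             trial = seq_len(T), offer_a = offers[, 1],
             offer_b = offers[, 2], choice = choices,
             payoff = payoff, reward01 = rewards, rt_ms = rep_len(rt, T))
}

test_that("exclusion rules drop trials and participants as stated", {
  # p_slow: 12% of trials outside the RT window -> participant dropped
  # p_noresp: 6% no-response -> dropped; p_ok: kept, bad trials removed
  mk_p <- function(id, rts, choices) {
    off <- matrix(rep(c(0L, 1L), each = 50), ncol = 2)
    mk_trials(off, choices, as.integer(!is.na(choices)), id = id, rt = rts)
  }
  rts_ok <- rep(800L, 50); rts_ok[1] <- 150L         # 2% excluded
  rts_slow <- rep(800L, 50); rts_slow[1:6] <- 150L    # 12% excluded
  ch <- rep(0L, 50)
  ch_nr <- ch; ch_nr[1:3] <- NA_integer_              # 6% no response
  trials <- rbind(mk_p("p_ok", rts_ok, ch),
                  mk_p("p_slow", rts_slow, ch),
                  mk_p("p_noresp", rep(800L, 50), ch_nr))
  res <- apply_exclusions(cohort(trials), exclusion_config())
  expect_setequal(res$report$participant_id[res$report$dropped],
                  c("p_slow", "p_noresp"))
  kept <- res$cohort$trials
  expect_equal(unique(kept$participant_id), "p_ok")
  expect_equal(nrow(kept), 49)  # the 150 ms trial is gone

  # simulated data without RTs must be pointed at the rt-free mode
  coh <- small_cohort(n = 2, seed = 110)
  expect_error(apply_exclusions(coh, exclusion_config()), "rt-free|use_rt")
  ok <- apply_exclusions(coh, exclusion_config(use_rt = FALSE))
  expect_equal(nrow(ok$cohort$trials), nrow(coh$trials))
})

test_that("the lagged filter emits exactly the qualifying trial pairs", {
  # case 1: unchosen B reoffered with a fresh card -> row
  t1 <- mk_trials(rbind(c(0L, 1L), c(1L, 2L)), c(0L, 1L), c(1L, 0L))
  r1 <- build_lagged_dataset(cohort(t1), lag = 1L)
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$prev_outcome, 1L)
  expect_equal(r1$chose_prev_unchosen, 1L)  # picked previously unchosen B

  # case 2: the previously chosen card is reoffered -> no row
  t2 <- mk_trials(rbind(c(0L, 1L), c(0L, 1L)), c(0L, 1L), c(1L, 0L))
  expect_equal(nrow(build_lagged_dataset(cohort(t2), lag = 1L)), 0L)

  # case 3: the unchosen card is not reoffered -> no row
  t3 <- mk_trials(rbind(c(0L, 1L), c(2L, 3L)), c(0L, 2L), c(1L, 0L))
  expect_equal(nrow(build_lagged_dataset(cohort(t3), lag = 1L)), 0L)

  # case 4: chose the third card instead -> row with outcome 0
  t4 <- mk_trials(rbind(c(0L, 1L), c(1L, 3L)), c(0L, 3L), c(0L, 1L))
  r4 <- build_lagged_dataset(cohort(t4), lag = 1L)
  expect_equal(r4$chose_prev_unchosen, 0L)
  expect_equal(r4$prev_outcome, 0L)

  # no-response at either end suppresses the row
  t5 <- mk_trials(rbind(c(0L, 1L), c(1L, 2L)), c(0L, NA), c(1L, NA))
  expect_equal(nrow(build_lagged_dataset(cohort(t5), lag = 1L)), 0L)

  # lag 2: same clauses relative to n and n+2
  t6 <- mk_trials(rbind(c(0L, 1L), c(0L, 1L), c(1L, 2L)),
                  c(0L, 0L, 1L), c(1L, 1L, 0L))
  r6 <- build_lagged_dataset(cohort(t6), lag = 2L)
  expect_equal(nrow(r6), 1L)
  expect_equal(r6$lag, 2L)
  expect_equal(r6$trial, 3L)
})

test_that("the filter is invariant to arm relabeling and offer order", {
  coh <- small_cohort("select_reject", n = 3, seed = 111)
  rows <- build_lagged_dataset(coh, lag = 1L)
  perm <- c(3L, 0L, 2L, 1L)
  tr <- coh$trials
  tr$offer_a <- perm[coh$trials$offer_a + 1L]
  tr$offer_b <- perm[coh$trials$offer_b + 1L]
  tr$choice <- perm[coh$trials$choice + 1L]
  # also swap the offer columns on odd trials
  swap <- seq_len(nrow(tr)) %% 2 == 1
  tmp <- tr$offer_a[swap]
  tr$offer_a[swap] <- tr$offer_b[swap]
  tr$offer_b[swap] <- tmp
  rows2 <- build_lagged_dataset(cohort(tr), lag = 1L)
  keycols <- c("participant_id", "block", "trial", "prev_outcome",
               "chose_prev_unchosen")
  expect_equal(rows[keycols], rows2[keycols], ignore_attr = TRUE)
})

test_that("lag-1 and lag-2 rows never double-count a trial pair", {
  coh <- small_cohort("baseline", n = 3, seed = 112)
  r1 <- build_lagged_dataset(coh, lag = 1L)
  r2 <- build_lagged_dataset(coh, lag = 2L)
  k1 <- paste(r1$participant_id, r1$block, r1$trial - r1$lag, r1$trial)
  k2 <- paste(r2$participant_id, r2$block, r2$trial - r2$lag, r2$trial)
  expect_length(intersect(k1, k2), 0L)
})

test_that("raw rates handle pooled, split and degenerate cells", {
  t1 <- mk_trials(rbind(c(0L, 1L), c(1L, 2L), c(2L, 0L), c(0L, 3L)),
                  c(0L, 1L, 2L, 0L), c(1L, 1L, 1L, 1L))
  rows <- build_lagged_dataset(cohort(t1), lag = 1L)
  rr <- raw_rates(rows)
  expect_true(all(rr$overall$rate >= 0 & rr$overall$rate <= 1, na.rm = TRUE))
  # all rows share prev_outcome = 1 here: the unrewarded cell is NA, not 0
  expect_true(is.na(rr$overall$rate[rr$overall$prev_outcome == 0]))
  all_one <- rows
  all_one$chose_prev_unchosen <- 1L
  expect_equal(raw_rates(all_one)$overall$rate[
    raw_rates(all_one)$overall$prev_outcome == 1], 1)
  expect_error(raw_rates(rows[0, ]), "no lagged rows")
})

test_that("the hierarchical logistic regression recovers a known effect", {
  set.seed(113)
  n_sub <- 25; n_rows <- 60
  u <- stats::rnorm(n_sub, 0, 0.3)
  rows <- do.call(rbind, lapply(seq_len(n_sub), function(i) {
    prev <- stats::rbinom(n_rows, 1, 0.5)
    eta <- 0.2 - 0.3 * prev + u[i]
    data.frame(participant_id = sprintf("s%02d", i),
               block_type = sample(c("win", "loss"), n_rows, TRUE),
               prev_outcome = prev,
               chose_prev_unchosen = stats::rbinom(n_rows, 1,
                                                   stats::plogis(eta)),
               prev_rt = NA_integer_,
               prev_difficulty = stats::runif(n_rows),
               curr_difficulty = stats::runif(n_rows))
  }))
  reg <- fit_lagged_regression(rows, chains = 2, warmup = 300, draws = 200,
                               seed = 114)
  est <- reg$summary[reg$summary$coefficient == "prev_outcome", ]
  expect_lt(abs(est$median - (-0.3)), 0.25)
  expect_lt(est$hdi_low, -0.3 + 0.35)
  expect_equal(rownames(reg$participant_effects),
               sprintf("s%02d", seq_len(n_sub)))

  # moderator with zero variance is refused by name
  rows_const <- rows
  rows_const$block_type <- "win"
  expect_error(fit_lagged_regression(rows_const, moderators = "block_type",
                                     chains = 2, warmup = 50, draws = 50),
               "block_type")
  expect_error(fit_lagged_regression(rows, moderators = "typo"), "unknown")
  expect_error(fit_lagged_regression(rows, moderators = "prev_rt"),
               "missing")
})

test_that("accuracy scores oracle and noise agents correctly", {
  coh <- small_cohort("baseline", n = 1, seed = 115)
  tr <- coh$trials
  sched <- coh$schedules[[tr$participant_id[1]]]
  pa <- sched[cbind(tr$block, tr$trial, tr$offer_a + 1L)]
  pb <- sched[cbind(tr$block, tr$trial, tr$offer_b + 1L)]
  tr$choice <- ifelse(pa >= pb, tr$offer_a, tr$offer_b)
  tr$reward01 <- 0L
  tr$payoff <- lvbandit:::payoff_from_reward(0L, tr$block_type)
  oracle <- cohort(tr, schedules = coh$schedules, config = coh$config)
  expect_equal(unname(accuracy_score(oracle)), 1)

  noise_params <- sample_cohort_params(
    "baseline", list(location = c(alpha_chosen = 0.3, beta = 1e-9),
                     scale = c(alpha_chosen = 0, beta = 0)), 5, seed = 116)
  noise <- simulate_cohort("baseline", noise_params, seed = 117)
  expect_lt(abs(mean(accuracy_score(noise)) - 0.5), 0.06)
  expect_error(accuracy_score(cohort(tr)), "schedules")
})

test_that("correlations report exact and null cases with a posterior", {
  x <- stats::rnorm(30)
  lin <- individual_correlations(x, 2 * x + 1)
  expect_equal(lin$r, 1, tolerance = 1e-12)
  anti <- individual_correlations(x, -x)
  expect_equal(anti$r, -1, tolerance = 1e-12)
  set.seed(118)
  nullr <- individual_correlations(stats::rnorm(10000), stats::rnorm(10000))
  expect_lt(abs(nullr$r), 0.03)
  expect_lt(nullr$pd, 0.995)
  expect_true(nullr$hdi_low < nullr$r & nullr$r < nullr$hdi_high)
  expect_error(individual_correlations(x, rep(1, 30)), "zero variance")
  expect_error(individual_correlations(x, x[1:10]), "lengths")
})
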
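test_that("states initialize at 0.5 with the right shape", {
  st <- init_state("baseline", 4)
  expect_equal(st$q, rep(0.5, 4))
  sr <- init_state("select_reject", 4)
  expect_equal(c(sr$q_select, sr$q_reject), rep(0.5, 8))
  expect_error(init_state("baseline", 0), "n_arms")
})

test_that("model_params enforces each model's parameter set and ranges", {
  expect_error(model_params("baseline", alpha_chosen = 0.3), "exactly")
  expect_error(model_params("baseline", alpha_chosen = 1.2, beta = 4),
               "\\[0, 1\\]")
  expect_error(model_params("select_reject", alpha = 0.3, omega = 0.7,
                            beta = -1), "beta")
  p <- model_params("double_one_pe", alpha_chosen = 0.3,
                    alpha_unchosen = 0.1, beta = 4)
  expect_s3_class(p, "lvb_params")
})

test_that("choice probabilities follow the softmax and the net-value rule", {
  st <- init_state("baseline")
  p <- choice_prob("baseline", st, c(0, 1),
                   list(alpha_chosen = 0.3, beta = 7))
  expect_equal(unname(p), c(0.5, 0.5))  # equal values -> symmetric

  st$q[1:2] <- c(0.6, 0.4)
  expect_equal(unname(choice_prob("baseline", st, c(0, 1),
                                  list(alpha_chosen = 0.3, beta = 0))),
               c(0.5, 0.5))  # beta = 0 ignores values
  p4 <- choice_prob("baseline", st, c(0, 1), list(alpha_chosen = 0.3, beta = 4))
  expect_equal(unname(p4[1]), 1 / (1 + exp(-0.8)), tolerance = 1e-10)

  # select-reject pairs each offer's select value with the other's reject
  sr <- init_state("select_reject")
  sr$q_select[1] <- 0.6; sr$q_reject[2] <- 0.4
  sr$q_select[2] <- 0.5; sr$q_reject[1] <- 0.5
  pr <- choice_prob("select_reject", sr, c(0, 1),
                    list(alpha = 0.3, omega = 0.7, beta = 1))
  qnet1 <- 0.7 * 0.6 + 0.3 * 0.4  # = 0.54
  qnet2 <- 0.7 * 0.5 + 0.3 * 0.5
  expect_equal(unname(pr[1]), stats::plogis(qnet1 - qnet2), tolerance = 1e-12)
  expect_equal(sum(pr), 1)
})

test_that("update rules match the arithmetic of each learning mechanism", {
  # baseline: chosen moves toward reward by alpha * delta
  st <- init_state("baseline")
  up <- update_state("baseline", st, c(0, 1), 0, 1,
                     list(alpha_chosen = 0.3, beta = 4))
  expect_equal(up$pe$delta_chosen, 0.5)
  expect_equal(up$state$q, c(0.65, 0.5, 0.5, 0.5))

  # double, two PEs: unchosen moves toward the inverted outcome
  st <- init_state("double_two_pe")
  up <- update_state("double_two_pe", st, c(0, 1), 0, 1,
                     list(alpha_chosen = 0.3, alpha_unchosen = 0.1, beta = 4))
  expect_equal(up$pe$delta_unchosen, -0.5)
  expect_equal(up$state$q[2], 0.45)

  # double, one PE: unchosen receives the sign-flipped chosen PE
  st <- init_state("double_one_pe")
  st$q <- c(0.5, 0.8, 0.5, 0.5)
  up <- update_state("double_one_pe", st, c(0, 1), 0, 1,
                     list(alpha_chosen = 0.3, alpha_unchosen = 0.1, beta = 4))
  expect_equal(up$state$q[2], 0.8 - 0.1 * 0.5)

  # select-reject: the unchosen arm's REJECT value moves toward the observed
  # reward itself, not its inverse
  st <- init_state("select_reject")
  up <- update_state("select_reject", st, c(0, 1), 0, 1,
                     list(alpha = 0.3, omega = 0.7, beta = 4))
  expect_equal(up$pe$delta_unchosen, 0.5)
  expect_equal(up$state$q_reject[2], 0.65)
  expect_equal(up$state$q_select[1], 0.65)
  # the chosen arm's reject value and unoffered arms are untouched
  expect_equal(up$state$q_reject[1], 0.5)
  expect_equal(up$state$q_select[3:4], c(0.5, 0.5))

  expect_error(update_state("baseline", init_state("baseline"), c(0, 1), 0,
                            -1, list(alpha_chosen = 0.3, beta = 4)),
               "recode")
  expect_error(update_state("baseline", init_state("baseline"), c(0, 1), 2,
                            1, list(alpha_chosen = 0.3, beta = 4)),
               "offered")
})

test_that("truncation clamps values into [0, 1]", {
  st <- init_state("baseline")
  st$q <- c(1.08, -0.03, 0.5, 1)
  expect_equal(truncate_q(st)$q, c(1, 0, 0.5, 1))
})

test_that("sequence log-likelihood handles symmetric and noise policies", {
  blk <- random_block(T = 1, seed = 10)
  ll <- sequence_loglik("baseline", list(alpha_chosen = 0.3, beta = 4), blk)
  expect_equal(ll$total, log(0.5), tolerance = 1e-12)

  blk20 <- random_block(T = 20, seed = 11)
  ll0 <- sequence_loglik("select_reject",
                         list(alpha = 0.3, omega = 0.7, beta = 0), blk20)
  expect_equal(ll0$total, 20 * log(0.5), tolerance = 1e-12)

  # no-response trials contribute neither likelihood nor updates
  blknr <- random_block(T = 30, seed = 12, p_noresp = 0.2)
  llnr <- sequence_loglik("baseline", list(alpha_chosen = 0.4, beta = 3),
                          blknr)
  expect_equal(sum(is.na(llnr$pointwise)), sum(is.na(blknr$choice)))
  expect_equal(llnr$pointwise[!is.na(blknr$choice)],
               oracle_block_loglik("baseline",
                                   list(alpha_chosen = 0.4, beta = 3),
                                   blknr)[!is.na(blknr$choice)],
               tolerance = 1e-12)
  expect_error(sequence_loglik("baseline", list(alpha_chosen = 0.3, beta = 4),
                               blk20[c(3, 1, 2), ]), "sorted")
})

test_that("exact reductions: select_reject(omega=1) and double_one_pe(a_un=0) equal baseline", {
  for (s in 1:5) {
    blk <- random_block(T = 50, seed = 20 + s, p_noresp = 0.05)
    a <- stats::runif(1, 0.1, 0.8)
    b <- stats::runif(1, 0.5, 8)
    base <- sequence_loglik("baseline",
                            list(alpha_chosen = a, beta = b), blk)$pointwise
    sr <- sequence_loglik("select_reject",
                          list(alpha = a, omega = 1, beta = b),
                          blk)$pointwise
    d1 <- sequence_loglik("double_one_pe",
                          list(alpha_chosen = a, alpha_unchosen = 0,
                               beta = b), blk)$pointwise
    expect_equal(sr, base, tolerance = 1e-10)
    expect_equal(d1, base, tolerance = 1e-10)
  }
})

test_that("vectorized likelihoods match the straight-line transcription", {
  for (model in lvb_models()) for (s in 1:4) {
    blk <- random_block(T = 50, seed = 30 + s, p_noresp = 0.1)
    pars <- random_params(model, seed = 40 + s)
    fast <- sequence_loglik(model, pars, blk)$pointwise
    slow <- oracle_block_loglik(model, pars, blk)
    expect_equal(fast, slow, tolerance = 1e-10)
  }
})

test_that("offered-arm probabilities are a proper, monotone distribution", {
  for (model in lvb_models()) {
    pars <- random_params(model, seed = 50)
    st <- init_state(model)
    if (model == "select_reject") {
      st$q_select <- stats::runif(4); st$q_reject <- stats::runif(4)
    } else st$q <- stats::runif(4)
    p <- choice_prob(model, st, c(1, 3), pars)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p > 0))
    # raising an arm's (select) value never lowers its choice probability
    st2 <- st
    if (model == "select_reject") st2$q_select[2] <- st$q_select[2] + 0.2
    else st2$q[2] <- st$q[2] + 0.2
    expect_gte(choice_prob(model, st2, c(1, 3), pars)[1], p[1])
  }
})

test_that("prediction errors and Q values stay in range under random play", {
  for (model in lvb_models()) {
    pars <- random_params(model, seed = 60)
    st <- init_state(model)
    set.seed(61)
    for (i in 1:200) {
      off <- sort(sample(0:3, 2))
      ch <- sample(off, 1)
      up <- update_state(model, st, off, ch, sample(0:1, 1), pars)
      st <- up$state
      vals <- unlist(st[intersect(names(st), c("q", "q_select", "q_reject"))])
      expect_true(all(vals >= 0 & vals <= 1))
      expect_true(abs(up$pe$delta_chosen) <= 1)
      if (!is.na(up$pe$delta_unchosen))
        expect_true(abs(up$pe$delta_unchosen) <= 1)
    }
  }
})

test_that("simulation is reproducible and respects the policy limits", {
  cfg <- task_config()
  sched <- generate_reward_schedule(cfg, seed = 70)
  offers <- generate_offers(cfg, seed = 71)
  a1 <- simulate_agent("select_reject",
                       list(alpha = 0.3, omega = 0.7, beta = 4),
                       sched, offers, cfg, seed = 72)
  a2 <- simulate_agent("select_reject",
                       list(alpha = 0.3, omega = 0.7, beta = 4),
                       sched, offers, cfg, seed = 72)
  expect_identical(a1, a2)

  # alpha_unchosen = 0 makes double_one_pe trajectories identical to baseline
  b1 <- simulate_agent("baseline", list(alpha_chosen = 0.4, beta = 3),
                       sched, offers, cfg, seed = 73)
  b2 <- simulate_agent("double_one_pe",
                       list(alpha_chosen = 0.4, alpha_unchosen = 0, beta = 3),
                       sched, offers, cfg, seed = 73)
  expect_identical(b1$choice, b2$choice)

  # beta = 0: both offered arms chosen equally often in the long run
  lcfg <- task_config(n_blocks = 1L, trials_per_block = 4000L)
  lsched <- generate_reward_schedule(lcfg, seed = 74)
  loff <- generate_offers(lcfg, seed = 75)
  noise <- simulate_agent("baseline", list(alpha_chosen = 0.3, beta = 0),
                          lsched, loff, lcfg, seed = 76)
  expect_lt(abs(mean(noise$choice == noise$offer_a) - 0.5), 0.03)

  # near-greedy agent on a frozen, well-separated schedule converges to the
  # higher-value arm
  gcfg <- task_config(n_blocks = 1L, trials_per_block = 300L, drift_sd = 0)
  gsched <- generate_reward_schedule(gcfg, seed = 77)
  gsched[1, , ] <- rep(c(0.9, 0.1, 0.85, 0.15), each = 300)
  goff <- generate_offers(gcfg, seed = 78)
  greedy <- simulate_agent("baseline", list(alpha_chosen = 0.5, beta = 30),
                           gsched, goff, gcfg, seed = 79)
  late <- greedy[greedy$trial > 100, ]
  better <- ifelse(gsched[1, 1, late$offer_a + 1] >
                     gsched[1, 1, late$offer_b + 1],
                   late$offer_a, late$offer_b)
  expect_gt(mean(late$choice == better), 0.85)
})
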
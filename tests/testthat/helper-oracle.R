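# Straight-line, loop-based transcriptions of the four learning rules and of
# the pointwise predictive density. Deliberately independent of the package's
# C++ kernels: plain R, no vectorization, no shared helpers.

oracle_block_loglik <- function(model, pars, blk, n_arms = 4) {
  q <- rep(0.5, n_arms)
  qs <- rep(0.5, n_arms)
  qr <- rep(0.5, n_arms)
  out <- rep(NA_real_, nrow(blk))
  for (t in seq_len(nrow(blk))) {
    a <- blk$offer_a[t] + 1
    b <- blk$offer_b[t] + 1
    if (is.na(blk$choice[t])) next
    ch <- blk$choice[t] + 1
    un <- if (ch == a) b else a
    r <- blk$reward01[t]
    beta <- pars$beta
    if (model == "select_reject") {
      w <- pars$omega
      vch <- w * qs[ch] + (1 - w) * qr[un]
      vun <- w * qs[un] + (1 - w) * qr[ch]
    } else {
      vch <- q[ch]
      vun <- q[un]
    }
    out[t] <- log(exp(beta * vch) / (exp(beta * vch) + exp(beta * vun)))
    if (model == "baseline") {
      d <- r - q[ch]
      q[ch] <- q[ch] + pars$alpha_chosen * d
    } else if (model == "double_two_pe") {
      d <- r - q[ch]
      q[ch] <- q[ch] + pars$alpha_chosen * d
      du <- (1 - r) - q[un]
      q[un] <- q[un] + pars$alpha_unchosen * du
    } else if (model == "double_one_pe") {
      d <- r - q[ch]
      q[ch] <- q[ch] + pars$alpha_chosen * d
      q[un] <- q[un] + pars$alpha_unchosen * (-d)
    } else if (model == "select_reject") {
      d <- r - qs[ch]
      qs[ch] <- qs[ch] + pars$alpha * d
      du <- r - qr[un]
      qr[un] <- qr[un] + pars$alpha * du
    }
    for (i in seq_len(n_arms)) {
      if (q[i] < 0) q[i] <- 0
      if (q[i] > 1) q[i] <- 1
      if (qs[i] < 0) qs[i] <- 0
      if (qs[i] > 1) qs[i] <- 1
      if (qr[i] < 0) qr[i] <- 0
      if (qr[i] > 1) qr[i] <- 1
    }
  }
  out
}

# brute-force pointwise elpd: loop draws x trials, average the probability
oracle_block_elpd <- function(model, draws_df, blk, n_arms = 4) {
  S <- nrow(draws_df)
  acc <- rep(0, nrow(blk))
  for (s in seq_len(S)) {
    lp <- oracle_block_loglik(model, as.list(draws_df[s, , drop = FALSE]),
                              blk, n_arms)
    acc <- acc + exp(lp)
  }
  log(acc / S)
}

# a random single participant-block with valid structure
random_block <- function(T = 50, n_arms = 4, seed = 1, p_noresp = 0) {
  set.seed(seed)
  offs <- t(replicate(T, sort(sample.int(n_arms, 2L) - 1L)))
  choice <- ifelse(stats::runif(T) < 0.5, offs[, 1L], offs[, 2L])
  nr <- stats::runif(T) < p_noresp
  choice[nr] <- NA_integer_
  reward <- as.integer(stats::runif(T) < 0.5)
  reward[nr] <- NA_integer_
  data.frame(participant_id = "p1", block = 1L, block_type = "win",
             trial = seq_len(T), offer_a = offs[, 1L], offer_b = offs[, 2L],
             choice = choice,
             payoff = ifelse(nr, 0L, reward), reward01 = reward,
             rt_ms = NA_integer_)
}

random_params <- function(model, seed = 1) {
  set.seed(seed)
  vals <- switch(model,
                 baseline = list(alpha_chosen = stats::runif(1, 0.05, 0.9),
                                 beta = stats::runif(1, 0.5, 8)),
                 double_two_pe = ,
                 double_one_pe = list(alpha_chosen = stats::runif(1, 0.05, 0.9),
                                      alpha_unchosen = stats::runif(1, 0.02, 0.6),
                                      beta = stats::runif(1, 0.5, 8)),
                 select_reject = list(alpha = stats::runif(1, 0.05, 0.9),
                                      omega = stats::runif(1, 0.05, 0.95),
                                      beta = stats::runif(1, 0.5, 8)))
  do.call(model_params, c(list(model = model), vals))
}

# quick simulated cohort for structural tests
small_cohort <- function(model = "baseline", n = 4, seed = 1,
                         config = task_config()) {
  truths <- recovery_truths(model)
  params <- sample_cohort_params(model, truths, n, seed = seed)
  simulate_cohort(model, params, config, seed = seed + 1L)
}

# hand-built minimal lvb_fit (all draws equal to the given natural params)
fake_fit <- function(model, params_list, participants, S = 10) {
  nm <- param_names(model)
  k <- length(nm)
  n <- length(participants)
  z <- array(NA_real_, c(S, n, k))
  for (i in seq_len(n)) {
    zi <- to_unconstrained(model, unlist(params_list[[i]])[nm])
    for (j in seq_len(k)) z[, i, j] <- zi[j]
  }
  structure(list(model = model, param_names = nm,
                 participants = participants, n_arms = 4L,
                 mu = matrix(0, S, k), sigma = matrix(1, S, k),
                 z = z, chain = rep(1L, S)),
            class = "lvb_fit")
}
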
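#' Exclusion rules for empirical-format data
#'
#' Trials with response times under `rt_min` or over `rt_max` are dropped;
#' participants with more than `max_excluded_fraction` of trials dropped, or
#' with a no-response rate above `max_no_response_fraction`, are excluded
#' altogether.
#'
#' @param rt_min,rt_max Response-time window in milliseconds (200, 4000).
#' @param max_excluded_fraction Participant-level cap on the fraction of
#'   RT-excluded trials (0.10).
#' @param max_no_response_fraction Participant-level cap on the no-response
#'   rate (0.05).
#' @param use_rt Apply the RT rules? Set `FALSE` for simulated data without
#'   response times.
#' @return List of class `lvb_exclusion_config`.
#' @export
exclusion_config <- function(rt_min = 200, rt_max = 4000,
                             max_excluded_fraction = 0.10,
                             max_no_response_fraction = 0.05,
                             use_rt = TRUE) {
  stopifnot(rt_min < rt_max,
            max_excluded_fraction > 0, max_excluded_fraction < 1,
            max_no_response_fraction > 0, max_no_response_fraction < 1)
  structure(list(rt_min = rt_min, rt_max = rt_max,
                 max_excluded_fraction = max_excluded_fraction,
                 max_no_response_fraction = max_no_response_fraction,
                 use_rt = use_rt),
            class = "lvb_exclusion_config")
}

#' Apply trial- and participant-level exclusions
#'
#' @param data An `lvb_cohort`.
#' @param cfg An [exclusion_config()].
#' @return List with the filtered `cohort` and a `report` (data frame of
#'   per-participant excluded-trial and no-response fractions plus a
#'   `dropped` flag).
#' @export
apply_exclusions <- function(data, cfg = exclusion_config()) {
  stopifnot(inherits(data, "lvb_cohort"),
            inherits(cfg, "lvb_exclusion_config"))
  trials <- data$trials
  if (cfg$use_rt && all(is.na(trials$rt_ms)))
    stop("no response times in the data; for simulated cohorts use ",
         "`exclusion_config(use_rt = FALSE)`", call. = FALSE)
  rt_bad <- if (cfg$use_rt)
    !is.na(trials$rt_ms) & (trials$rt_ms < cfg$rt_min |
                              trials$rt_ms > cfg$rt_max)
  else rep(FALSE, nrow(trials))
  per <- split(seq_len(nrow(trials)), trials$participant_id)
  report <- do.call(rbind, lapply(names(per), function(id) {
    idx <- per[[id]]
    data.frame(participant_id = id,
               n_trials = length(idx),
               excluded_fraction = mean(rt_bad[idx]),
               no_response_fraction = mean(is.na(trials$choice[idx])))
  }))
  report$dropped <- report$excluded_fraction > cfg$max_excluded_fraction |
    report$no_response_fraction > cfg$max_no_response_fraction
  keep_ids <- report$participant_id[!report$dropped]
  kept <- trials[!rt_bad & trials$participant_id %in% keep_ids, ,
                 drop = FALSE]
  sched <- data$schedules
  if (!is.null(sched)) sched <- sched[intersect(names(sched), keep_ids)]
  list(cohort = cohort(kept, schedules = sched, config = data$config,
                       provenance = c(data$provenance,
                                      list(exclusions = "applied"))),
       report = report)
}

#' Build the lagged-trial dataset
#'
#' Implements the selection filter behind the model-independent analysis:
#' for a trial `n` with an observed choice, write `C` for the chosen and `U`
#' for the unchosen offered card. A row is emitted for trial `n + lag`
#' (within the same block) iff `U` is offered again, `C` is not offered, and
#' the card offered alongside `U` was not offered at trial `n`. The row
#' records whether the participant now picked `U` (`chose_prev_unchosen`)
#' and the outcome of trial `n` (`prev_outcome`), together with moderator
#' covariates: the previous response time and, when true reward
#' probabilities are available, the previous and current difficulty (the
#' absolute difference in true expected value between the two offers).
#'
#' @param data An `lvb_cohort`.
#' @param lag 1 or 2 trials back.
#' @return Data frame of `SequentialRow`s: `participant_id, block,
#'   block_type, trial, lag, prev_outcome, chose_prev_unchosen, prev_rt,
#'   prev_difficulty, curr_difficulty`.
#' @export
build_lagged_dataset <- function(data, lag = 1L) {
  stopifnot(inherits(data, "lvb_cohort"), lag %in% c(1L, 2L))
  trials <- data$trials
  out <- vector("list", 0L)
  for (id in unique(trials$participant_id)) {
    sched <- data$schedules[[id]]
    pt <- trials[trials$participant_id == id, , drop = FALSE]
    for (b in unique(pt$block)) {
      blk <- pt[pt$block == b, , drop = FALSE]
      blk <- blk[order(blk$trial), , drop = FALSE]
      m_idx <- match(blk$trial + lag, blk$trial)
      for (i in which(!is.na(m_idx))) {
        j <- m_idx[i]
        if (is.na(blk$choice[i]) || is.na(blk$choice[j])) next
        C <- blk$choice[i]
        U <- if (blk$offer_a[i] == C) blk$offer_b[i] else blk$offer_a[i]
        off_m <- c(blk$offer_a[j], blk$offer_b[j])
        if (!(U %in% off_m)) next
        if (C %in% off_m) next
        third <- off_m[off_m != U]
        if (third %in% c(blk$offer_a[i], blk$offer_b[i])) next
        diff_at <- function(row) {
          if (is.null(sched)) return(NA_real_)
          abs(sched[b, blk$trial[row], blk$offer_a[row] + 1L] -
                sched[b, blk$trial[row], blk$offer_b[row] + 1L])
        }
        out[[length(out) + 1L]] <- data.frame(
          participant_id = id, block = b,
          block_type = blk$block_type[i], trial = blk$trial[j],
          lag = lag,
          prev_outcome = blk$reward01[i],
          chose_prev_unchosen = as.integer(blk$choice[j] == U),
          prev_rt = blk$rt_ms[i],
          prev_difficulty = diff_at(i),
          curr_difficulty = diff_at(j))
      }
    }
  }
  if (!length(out))
    return(data.frame(participant_id = character(), block = integer(),
                      block_type = character(), trial = integer(),
                      lag = integer(), prev_outcome = integer(),
                      chose_prev_unchosen = integer(), prev_rt = integer(),
                      prev_difficulty = double(), curr_difficulty = double()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Raw choice rates of the previously unchosen card
#'
#' Pooled and per-participant probabilities of picking the previously
#' unchosen card, split by the previous trial's outcome, overall and per
#' block type.
#'
#' @param rows Output of [build_lagged_dataset()].
#' @return List with `overall` (data frame `prev_outcome, rate, n`),
#'   `by_block_type`, and `per_participant` (participant means per outcome;
#'   empty cells are `NA`, never 0).
#' @export
raw_rates <- function(rows) {
  if (!nrow(rows)) stop("no lagged rows", call. = FALSE)
  cell <- function(d) {
    do.call(rbind, lapply(c(0L, 1L), function(o) {
      sel <- d$prev_outcome == o
      data.frame(prev_outcome = o,
                 rate = if (any(sel)) mean(d$chose_prev_unchosen[sel])
                        else NA_real_,
                 n = sum(sel))
    }))
  }
  by_bt <- do.call(rbind, lapply(split(rows, rows$block_type), function(d)
    cbind(block_type = d$block_type[1L], cell(d))))
  rownames(by_bt) <- NULL
  per <- stats::aggregate(chose_prev_unchosen ~ participant_id + prev_outcome,
                          rows, mean)
  list(overall = cell(rows), by_block_type = by_bt, per_participant = per)
}

# ---- hierarchical Bayesian logistic regression -----------------------------

# log Bernoulli-logit likelihood per row
.bern_ll <- function(y, eta) {
  ifelse(y == 1L, stats::plogis(eta, log.p = TRUE),
         stats::plogis(-eta, log.p = TRUE))
}

#' Hierarchical logistic regression of lagged choices
#'
#' Fits, by adaptive MCMC, the hierarchical Bayesian logistic regression of
#' `chose_prev_unchosen` on the previous trial's outcome and optional
#' moderators, the analysis that detects latent value updating of unchosen
#' actions. Population ("fixed") coefficients carry Normal(0, 2) priors;
#' the per-participant random intercept and random slopes (for
#' `prev_outcome` and every interaction) are Normal around the population
#' coefficient with half-Normal(0, 1) scale priors. Moderator main effects
#' are population-level only. Continuous moderators are standardized within
#' participant; `block_type` is coded win = +1/2, loss = -1/2.
#'
#' @param rows Output of [build_lagged_dataset()].
#' @param moderators Subset of `c("block_type", "prev_rt",
#'   "prev_difficulty", "curr_difficulty")`; each adds a main effect and a
#'   `prev_outcome` interaction.
#' @param center_outcome Code `prev_outcome` as -1/2, +1/2 instead of 0/1.
#' @param chains,warmup,draws MCMC settings.
#' @param seed Integer seed.
#' @return Object of class `lvb_regression`: `summary` (posterior median,
#'   HDI95 and pd per coefficient, log-odds scale), `draws` (population
#'   coefficient draws), `participant_effects` (per-participant posterior
#'   median coefficients for the random terms), `rhat`.
#' @export
fit_lagged_regression <- function(rows, moderators = character(0),
                                  center_outcome = FALSE,
                                  chains = 4L, warmup = 600L, draws = 400L,
                                  seed = 1L) {
  if (!nrow(rows)) stop("no lagged rows to fit", call. = FALSE)
  allowed <- c("block_type", "prev_rt", "prev_difficulty", "curr_difficulty")
  bad <- setdiff(moderators, allowed)
  if (length(bad))
    stop("unknown moderators: ", paste(bad, collapse = ", "), call. = FALSE)

  ids <- unique(rows$participant_id)
  pid <- match(rows$participant_id, ids)
  y <- as.integer(rows$chose_prev_unchosen)
  X <- cbind("(Intercept)" = rep(1, nrow(rows)),
             prev_outcome = rows$prev_outcome - if (center_outcome) 0.5 else 0)
  for (m in moderators) {
    v <- if (m == "block_type") {
      ifelse(rows$block_type == "win", 0.5, -0.5)
    } else {
      raw <- rows[[m]]
      if (anyNA(raw))
        stop("moderator `", m, "` has missing values", call. = FALSE)
      stats::ave(raw, pid, FUN = function(u) {
        s <- stats::sd(u)
        if (is.na(s) || s == 0) rep(0, length(u)) else (u - mean(u)) / s
      })
    }
    if (stats::sd(v) == 0)
      stop("moderator `", m, "` has zero variance", call. = FALSE)
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- m
    X <- cbind(X, v * X[, "prev_outcome"])
    colnames(X)[ncol(X)] <- paste0("prev_outcome:", m)
  }
  rand <- c("(Intercept)", "prev_outcome",
            grep("^prev_outcome:", colnames(X), value = TRUE))
  fixed <- setdiff(colnames(X), rand)
  Xr <- X[, rand, drop = FALSE]
  Xf <- X[, fixed, drop = FALSE]
  n <- length(ids); kr <- length(rand); kf <- length(fixed)

  total <- chains * draws
  b_d <- matrix(NA_real_, total, kr + kf,
                dimnames = list(NULL, c(rand, fixed)))
  s_d <- matrix(NA_real_, total, kr, dimnames = list(NULL, rand))
  c_d <- array(NA_real_, c(total, n, kr))
  chain_id <- rep(seq_len(chains), each = draws)
  row0 <- 0L

  for (chn in seq_len(chains)) {
    set.seed(seed + chn - 1L)
    b_r <- rep(0, kr); s_r <- rep(0.5, kr); b_f <- rep(0, kf)
    cf <- matrix(rep(b_r, each = n), n, kr) +
      matrix(stats::rnorm(n * kr, 0, 0.1), n, kr)
    eta_fix <- if (kf) drop(Xf %*% b_f) else rep(0, nrow(X))
    eta_rand <- rowSums(Xr * cf[pid, , drop = FALSE])
    ll_i <- rowsum(.bern_ll(y, eta_fix + eta_rand), pid)[, 1L]
    log_eps <- rep(log(0.3), n)
    log_step_f <- log(0.2)
    log_step_s <- rep(log(0.4), kr)

    for (t in seq_len(warmup + draws)) {
      # participant random effects, block MH vectorized over participants
      cp <- cf + exp(log_eps) * matrix(stats::rnorm(n * kr), n, kr)
      eta_p <- eta_fix + rowSums(Xr * cp[pid, , drop = FALSE])
      llp_i <- rowsum(.bern_ll(y, eta_p), pid)[, 1L]
      pr_cur <- rowSums(stats::dnorm(cf, rep(b_r, each = n),
                                     rep(s_r, each = n), log = TRUE))
      pr_prop <- rowSums(stats::dnorm(cp, rep(b_r, each = n),
                                      rep(s_r, each = n), log = TRUE))
      acc <- log(stats::runif(n)) < (llp_i + pr_prop - ll_i - pr_cur)
      cf[acc, ] <- cp[acc, , drop = FALSE]
      ll_i[acc] <- llp_i[acc]
      eta_rand <- rowSums(Xr * cf[pid, , drop = FALSE])

      # population means of random coefficients: conjugate Normal
      prec <- n / s_r^2 + 1 / 4
      b_r <- stats::rnorm(kr, (colSums(cf) / s_r^2) / prec, 1 / sqrt(prec))

      # random-effect scales: log-scale MH, half-Normal(0,1) prior
      for (j in seq_len(kr)) {
        lsp <- log(s_r[j]) + stats::rnorm(1L, 0, exp(log_step_s[j]))
        sp <- exp(lsp)
        logr <- sum(stats::dnorm(cf[, j], b_r[j], sp, log = TRUE)) -
          sum(stats::dnorm(cf[, j], b_r[j], s_r[j], log = TRUE)) +
          stats::dnorm(sp, 0, 1, log = TRUE) -
          stats::dnorm(s_r[j], 0, 1, log = TRUE) +
          lsp - log(s_r[j])
        acc_s <- log(stats::runif(1L)) < logr
        if (acc_s) s_r[j] <- sp
        if (t <= warmup)
          log_step_s[j] <- log_step_s[j] +
            min(0.5, 3 / sqrt(t)) * ((acc_s) - 0.44)
      }

      # fixed-only coefficients: joint MH over the full likelihood
      if (kf) {
        bp <- b_f + exp(log_step_f) * stats::rnorm(kf)
        eta_fp <- drop(Xf %*% bp)
        logr <- sum(.bern_ll(y, eta_fp + eta_rand)) -
          sum(.bern_ll(y, eta_fix + eta_rand)) +
          sum(stats::dnorm(bp, 0, 2, log = TRUE)) -
          sum(stats::dnorm(b_f, 0, 2, log = TRUE))
        acc_f <- log(stats::runif(1L)) < logr
        if (acc_f) {
          b_f <- bp; eta_fix <- eta_fp
          ll_i <- rowsum(.bern_ll(y, eta_fix + eta_rand), pid)[, 1L]
        }
        if (t <= warmup)
          log_step_f <- log_step_f + min(0.5, 3 / sqrt(t)) * ((acc_f) - 0.30)
      }

      if (t <= warmup) {
        log_eps <- log_eps + min(0.5, 3 / sqrt(t)) * (acc - 0.30)
      } else {
        r <- row0 + (t - warmup)
        b_d[r, ] <- c(b_r, b_f)
        s_d[r, ] <- s_r
        c_d[r, , ] <- cf
      }
    }
    row0 <- row0 + draws
  }

  coefs <- c(rand, fixed)
  summ <- do.call(rbind, lapply(coefs, function(cl)
    cbind(data.frame(coefficient = cl), posterior_summary(b_d[, cl]))))
  rownames(summ) <- NULL
  pe <- matrix(NA_real_, n, kr, dimnames = list(ids, rand))
  for (j in seq_len(kr)) pe[, j] <- apply(c_d[, , j, drop = FALSE], 2L,
                                          stats::median)
  rhat <- vapply(coefs, function(cl) split_rhat(b_d[, cl], chain_id), 0)
  structure(list(summary = summ, draws = b_d, scale_draws = s_d,
                 participant_effects = pe, chain = chain_id, rhat = rhat,
                 moderators = moderators, n_rows = nrow(rows),
                 converged = all(rhat <= 1.05)),
            class = "lvb_regression")
}

#' @export
print.lvb_regression <- function(x, ...) {
  cat("Hierarchical logistic regression on", x$n_rows, "lagged rows",
      "(log-odds scale)\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Per-participant accuracy against the true latent values
#'
#' A choice is accurate when the chosen card's true reward probability is
#' strictly higher than the alternative's; exact ties score 0.5. Only
#' answered trials count.
#'
#' @param data An `lvb_cohort` carrying true schedules.
#' @return Named numeric vector of per-participant mean accuracies.
#' @export
accuracy_score <- function(data) {
  stopifnot(inherits(data, "lvb_cohort"))
  if (is.null(data$schedules))
    stop("accuracy needs the true reward schedules", call. = FALSE)
  trials <- data$trials[!is.na(data$trials$choice), , drop = FALSE]
  ids <- unique(trials$participant_id)
  out <- stats::setNames(numeric(length(ids)), ids)
  for (id in ids) {
    sched <- data$schedules[[id]]
    if (is.null(sched)) stop("no schedule for participant ", id,
                             call. = FALSE)
    pt <- trials[trials$participant_id == id, , drop = FALSE]
    p_ch <- sched[cbind(pt$block, pt$trial, pt$choice + 1L)]
    other <- ifelse(pt$choice == pt$offer_a, pt$offer_b, pt$offer_a)
    p_ot <- sched[cbind(pt$block, pt$trial, other + 1L)]
    out[id] <- mean(ifelse(p_ch > p_ot, 1, ifelse(p_ch == p_ot, 0.5, 0)))
  }
  out
}

#' Correlation between per-participant quantities
#'
#' Pearson correlation with a large-sample posterior on the Fisher-z scale
#' (`atanh(r)` with standard error `1/sqrt(n - 3)`), giving an HDI and a
#' probability of direction without any sampling.
#'
#' @param x,y Numeric vectors of equal length (>= 4, so that the z-scale
#'   standard error exists).
#' @param prob Interval mass.
#' @return List with `r`, `n`, `hdi_low`, `hdi_high`, `pd`.
#' @export
individual_correlations <- function(x, y, prob = 0.95) {
  if (length(x) != length(y)) stop("lengths differ", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in `x` or `y`", call. = FALSE)
  r <- stats::cor(x, y)
  se <- 1 / sqrt(n - 3)
  z <- atanh(min(max(r, -1 + 1e-12), 1 - 1e-12))
  q <- stats::qnorm(c((1 - prob) / 2, 1 - (1 - prob) / 2), z, se)
  pd <- max(stats::pnorm(0, z, se), 1 - stats::pnorm(0, z, se))
  list(r = r, n = n, hdi_low = tanh(q[1L]), hdi_high = tanh(q[2L]), pd = pd)
}
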
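#' Task configuration for the four-armed restless bandit
#'
#' Describes the study design: four cards of which two are offered per trial,
#' four interleaved win/loss blocks of 50 trials, and per-arm reward
#' probabilities that drift as independent bounded Gaussian random walks.
#'
#' In a win block the possible payoffs are +1 (rewarded) and 0 (unrewarded);
#' in a loss block they are 0 (rewarded, i.e. loss avoided) and -1
#' (unrewarded). All learning models consume the recoded binary reward
#' (`reward01`), so the two block types are computationally identical.
#'
#' @param n_arms Number of cards (arms). Default 4.
#' @param n_blocks Number of blocks. Default 4.
#' @param trials_per_block Trials per block. Default 50.
#' @param drift_sd Standard deviation of the per-trial Gaussian increment of
#'   each arm's reward probability. Default 0.03.
#' @param first_block_type `"win"` or `"loss"`; block types alternate from
#'   this one.
#' @return An object of class `lvb_task_config`.
#' @examples
#' cfg <- task_config()
#' cfg$block_types
#' @export
task_config <- function(n_arms = 4L, n_blocks = 4L, trials_per_block = 50L,
                        drift_sd = 0.03, first_block_type = c("win", "loss")) {
  first_block_type <- match.arg(first_block_type)
  n_arms <- as.integer(n_arms)
  n_blocks <- as.integer(n_blocks)
  trials_per_block <- as.integer(trials_per_block)
  if (is.na(n_arms) || n_arms < 2L)
    stop("`n_arms` must be at least 2", call. = FALSE)
  if (is.na(n_blocks) || n_blocks < 1L)
    stop("`n_blocks` must be positive", call. = FALSE)
  if (is.na(trials_per_block) || trials_per_block < 1L)
    stop("`trials_per_block` must be positive", call. = FALSE)
  if (!is.numeric(drift_sd) || drift_sd < 0)
    stop("`drift_sd` must be non-negative", call. = FALSE)
  types <- c("win", "loss")
  if (first_block_type == "loss") types <- rev(types)
  structure(
    list(n_arms = n_arms, n_blocks = n_blocks,
         trials_per_block = trials_per_block, drift_sd = drift_sd,
         block_types = rep_len(types, n_blocks)),
    class = "lvb_task_config")
}

#' @export
print.lvb_task_config <- function(x, ...) {
  cat("Bandit task:", x$n_arms, "arms,", x$n_blocks, "blocks x",
      x$trials_per_block, "trials, drift SD", x$drift_sd, "\n")
  cat("Block types:", paste(x$block_types, collapse = ", "), "\n")
  invisible(x)
}

# Reflect a value into [0, 1], preserving overshoot magnitude.
reflect01 <- function(x) {
  # two reflections are enough for any realistic increment, but iterate to
  # be safe for large drift_sd
  while (any(x < 0 | x > 1)) {
    x <- ifelse(x < 0, -x, x)
    x <- ifelse(x > 1, 2 - x, x)
  }
  x
}

#' Generate drifting reward probabilities
#'
#' Each arm's reward probability starts at an independent Uniform(0.25, 0.75)
#' draw and evolves as a Gaussian random walk with increment SD `drift_sd`,
#' reflected at 0 and 1. Arms and blocks are independent (each block gets a
#' fresh schedule).
#'
#' @param config A [task_config()].
#' @param seed Optional integer seed. If `NULL`, the current RNG stream is
#'   used (so that callers can manage seeding themselves).
#' @return Array `[block, trial, arm]` of reward probabilities,
#'   class `lvb_schedule`.
#' @examples
#' sched <- generate_reward_schedule(task_config(), seed = 1)
#' range(sched)
#' @export
generate_reward_schedule <- function(config, seed = NULL) {
  stopifnot(inherits(config, "lvb_task_config"))
  if (!is.null(seed)) set.seed(seed)
  p <- array(NA_real_,
             dim = c(config$n_blocks, config$trials_per_block, config$n_arms))
  for (b in seq_len(config$n_blocks)) {
    cur <- stats::runif(config$n_arms, 0.25, 0.75)
    p[b, 1L, ] <- cur
    for (t in seq_len(config$trials_per_block - 1L)) {
      cur <- reflect01(cur + stats::rnorm(config$n_arms, 0, config$drift_sd))
      p[b, t + 1L, ] <- cur
    }
  }
  class(p) <- c("lvb_schedule", class(p))
  p
}

#' Generate random offers
#'
#' On every trial the computer offers two distinct cards, drawn uniformly
#' from the `choose(n_arms, 2)` unordered pairs, independently across trials.
#'
#' @param config A [task_config()].
#' @param seed Optional integer seed (see [generate_reward_schedule()]).
#' @return Integer matrix `[total trials, 2]` of 0-based arm indices with
#'   columns `offer_a`, `offer_b`; trials are ordered block by block.
#' @export
generate_offers <- function(config, seed = NULL) {
  stopifnot(inherits(config, "lvb_task_config"))
  if (!is.null(seed)) set.seed(seed)
  pairs <- t(utils::combn(config$n_arms, 2L)) - 1L
  total <- config$n_blocks * config$trials_per_block
  idx <- sample.int(nrow(pairs), total, replace = TRUE)
  out <- pairs[idx, , drop = FALSE]
  colnames(out) <- c("offer_a", "offer_b")
  out
}

#' Sample a single trial outcome
#'
#' Draws a Bernoulli reward and maps it to the block's payoff currency:
#' win blocks pay +1/0, loss blocks pay 0/-1 for rewarded/unrewarded.
#'
#' @param p_reward Reward probability in `[0, 1]`.
#' @param block_type `"win"` or `"loss"`.
#' @return List with `reward01` (0/1) and `payoff` (-1/0/+1).
#' @export
sample_outcome <- function(p_reward, block_type = c("win", "loss")) {
  block_type <- match.arg(block_type)
  if (!is.numeric(p_reward) || is.na(p_reward) || p_reward < 0 || p_reward > 1)
    stop("`p_reward` must be a probability in [0, 1]", call. = FALSE)
  r <- as.integer(stats::runif(1L) < p_reward)
  list(reward01 = r, payoff = payoff_from_reward(r, block_type))
}

# reward01 <-> payoff recoding (bijective within each block type)
payoff_from_reward <- function(reward01, block_type) {
  n <- max(length(reward01), length(block_type))
  ifelse(rep_len(block_type, n) == "win", rep_len(reward01, n),
         rep_len(reward01, n) - 1L)
}

reward_from_payoff <- function(payoff, block_type) {
  n <- max(length(payoff), length(block_type))
  ifelse(rep_len(block_type, n) == "win", rep_len(payoff, n),
         rep_len(payoff, n) + 1L)
}

trial_columns <- c("participant_id", "block", "block_type", "trial",
                   "offer_a", "offer_b", "choice", "payoff", "reward01",
                   "rt_ms")

#' Assemble a cohort dataset
#'
#' A cohort bundles per-trial records with (optionally) the true reward
#' schedules that generated them and a provenance tag.
#'
#' @param trials Data frame with the columns described in [read_trials()].
#' @param schedules Named list (by participant id) of `lvb_schedule` arrays,
#'   or `NULL` when true probabilities are unknown (e.g. empirical data).
#' @param config The [task_config()] used, or `NULL`.
#' @param provenance Free-form list tag (generating model, seed, or
#'   `"empirical"`).
#' @return Object of class `lvb_cohort`.
#' @export
cohort <- function(trials, schedules = NULL, config = NULL,
                   provenance = list(source = "unknown")) {
  validate_trials(trials)
  if (!is.null(schedules)) {
    miss <- setdiff(unique(trials$participant_id), names(schedules))
    if (length(miss))
      stop("schedules missing for participants: ",
           paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  }
  structure(list(trials = trials, schedules = schedules, config = config,
                 provenance = provenance),
            class = "lvb_cohort")
}

#' @export
print.lvb_cohort <- function(x, ...) {
  cat("Cohort:", length(unique(x$trials$participant_id)), "participants,",
      nrow(x$trials), "trials",
      if (is.null(x$schedules)) "(no true schedules)" else "", "\n")
  if (!is.null(x$provenance$source))
    cat("Provenance:", x$provenance$source, "\n")
  invisible(x)
}

validate_trials <- function(trials) {
  miss <- setdiff(setdiff(trial_columns, "rt_ms"), names(trials))
  if (length(miss))
    stop("trial data lacks required columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- which(!trials$block_type %in% c("win", "loss"))
  if (length(bad))
    stop("unknown block_type at row ", bad[1L], call. = FALSE)
  bad <- which(trials$offer_a == trials$offer_b)
  if (length(bad))
    stop("offer_a equals offer_b at row ", bad[1L], call. = FALSE)
  bad <- which(!is.na(trials$choice) &
                 trials$choice != trials$offer_a &
                 trials$choice != trials$offer_b)
  if (length(bad))
    stop("choice outside the offered pair at row ", bad[1L], call. = FALSE)
  answered <- !is.na(trials$choice)
  expected <- reward_from_payoff(trials$payoff[answered],
                                 trials$block_type[answered])
  if (any(trials$reward01[answered] != expected))
    stop("reward01 inconsistent with payoff at row ",
         which(answered)[which(trials$reward01[answered] != expected)[1L]],
         call. = FALSE)
  invisible(TRUE)
}

#' Write / read per-trial choice data
#'
#' The on-disk format is a UTF-8 CSV with header
#' `participant_id, block, block_type, trial, offer_a, offer_b, choice,
#' payoff, reward01, rt_ms`. Arms are 0-based; `choice`, `reward01` and
#' `rt_ms` may be empty (no-response trials / missing response times). The
#' round trip is lossless. `write_trials()` also writes the true reward
#' probabilities to `<path>_schedule.csv` (columns `participant_id, block,
#' trial, p_arm0..`) when the cohort carries them; `read_trials()` picks that
#' companion file up automatically when present.
#'
#' @param x An `lvb_cohort` (or plain trials data frame).
#' @param path CSV path.
#' @return `read_trials()` returns an `lvb_cohort`.
#' @export
write_trials <- function(x, path) {
  trials <- if (inherits(x, "lvb_cohort")) x$trials else x
  validate_trials(trials)
  if (!"rt_ms" %in% names(trials)) trials$rt_ms <- NA_integer_
  utils::write.csv(trials[trial_columns], path, row.names = FALSE, na = "")
  if (inherits(x, "lvb_cohort") && !is.null(x$schedules)) {
    sp <- schedule_path(path)
    rows <- lapply(names(x$schedules), function(id) {
      s <- x$schedules[[id]]
      d <- dim(s)
      grid <- expand.grid(trial = seq_len(d[2L]), block = seq_len(d[1L]))
      pm <- t(apply(grid, 1L, function(g) s[g["block"], g["trial"], ]))
      colnames(pm) <- paste0("p_arm", seq_len(d[3L]) - 1L)
      cbind(data.frame(participant_id = id, block = grid$block,
                       trial = grid$trial), pm)
    })
    utils::write.csv(do.call(rbind, rows), sp, row.names = FALSE)
  }
  invisible(path)
}

schedule_path <- function(path) {
  sub("\\.csv$", "_schedule.csv", path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  trials <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"rt_ms" %in% names(trials)) trials$rt_ms <- NA_integer_
  trials$participant_id <- as.character(trials$participant_id)
  for (col in c("block", "trial", "offer_a", "offer_b", "choice",
                "payoff", "reward01", "rt_ms")) {
    if (!is.numeric(trials[[col]]) && !all(is.na(trials[[col]])))
      stop("non-numeric values in column `", col, "`", call. = FALSE)
    trials[[col]] <- suppressWarnings(as.integer(trials[[col]]))
  }
  validate_trials(trials)
  schedules <- NULL
  sp <- schedule_path(path)
  if (file.exists(sp)) {
    sc <- utils::read.csv(sp, stringsAsFactors = FALSE)
    sc$participant_id <- as.character(sc$participant_id)
    parms <- grep("^p_arm", names(sc), value = TRUE)
    schedules <- lapply(split(sc, sc$participant_id), function(d) {
      nb <- max(d$block); nt <- max(d$trial)
      arr <- array(NA_real_, dim = c(nb, nt, length(parms)))
      for (i in seq_len(nrow(d)))
        arr[d$block[i], d$trial[i], ] <- as.numeric(d[i, parms])
      class(arr) <- c("lvb_schedule", class(arr))
      arr
    })
  }
  cohort(trials, schedules = schedules,
         provenance = list(source = "file", path = path))
}
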
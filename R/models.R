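#' The four Q-learning observers
#'
#' @description
#' `lvb_models()` returns the closed set of model identifiers:
#'
#' * `baseline` — Rescorla-Wagner learner: only the chosen card's value moves
#'   toward the observed reward; softmax choice with inverse noise `beta`.
#' * `double_two_pe` — double updating with two prediction errors: the
#'   unchosen card additionally moves toward the *inverted* outcome
#'   `1 - reward` with its own learning rate `alpha_unchosen`.
#' * `double_one_pe` — double updating with one prediction error: the
#'   unchosen card receives `-alpha_unchosen * delta_chosen`, a sign-flipped
#'   share of the chosen card's prediction error.
#' * `select_reject` — separate value ledgers for selecting a card
#'   (`Q_select`) and for rejecting it (`Q_reject`); both the chosen card's
#'   select value and the unchosen card's reject value move toward the same
#'   observed reward with a shared `alpha`. Choice integrates the two ledgers
#'   with weight `omega`: `Q_net(x) = omega * Q_select(x) +
#'   (1 - omega) * Q_reject(other)`. With `omega = 1` the model reduces
#'   exactly to the baseline.
#'
#' @return Character vector of model ids.
#' @export
lvb_models <- function() {
  c("baseline", "double_two_pe", "double_one_pe", "select_reject")
}

.model_code <- function(model) {
  match(match.arg(model, lvb_models()), lvb_models()) - 1L
}

#' Names of a model's free parameters
#'
#' @param model A model id from [lvb_models()].
#' @return Character vector of natural-scale parameter names.
#' @export
param_names <- function(model) {
  switch(match.arg(model, lvb_models()),
         baseline = c("alpha_chosen", "beta"),
         double_two_pe = c("alpha_chosen", "alpha_unchosen", "beta"),
         double_one_pe = c("alpha_chosen", "alpha_unchosen", "beta"),
         select_reject = c("alpha", "omega", "beta"))
}

# Map a named natural-scale parameter list/vector to the uniform 3-slot
# layout used by the C++ kernels: (alpha_chosen, alpha_unchosen|omega, beta).
.par_slots <- function(model, params) {
  nm <- param_names(model)
  p <- vapply(nm, function(x) {
    v <- params[[x]]
    if (is.null(v) || !is.numeric(v)) NA_real_ else as.double(v)
  }, 0)
  if (anyNA(p))
    stop("missing parameter(s): ", paste(nm[is.na(p)], collapse = ", "),
         call. = FALSE)
  if (model == "baseline") c(p[["alpha_chosen"]], 0, p[["beta"]])
  else if (model == "select_reject") c(p[["alpha"]], p[["omega"]], p[["beta"]])
  else c(p[["alpha_chosen"]], p[["alpha_unchosen"]], p[["beta"]])
}

#' Construct model parameters
#'
#' Builds a validated natural-scale parameter set for one model. Learning
#' rates and `omega` live in `[0, 1]`; the softmax inverse noise `beta` is
#' non-negative.
#'
#' @param model Model id.
#' @param ... Named parameter values; exactly the names in
#'   [param_names()] for that model.
#' @return List of class `lvb_params`.
#' @examples
#' model_params("select_reject", alpha = 0.3, omega = 0.7, beta = 4)
#' @export
model_params <- function(model, ...) {
  model <- match.arg(model, lvb_models())
  vals <- list(...)
  nm <- param_names(model)
  if (!setequal(names(vals), nm))
    stop("`", model, "` takes exactly the parameters: ",
         paste(nm, collapse = ", "), call. = FALSE)
  vals <- vals[nm]
  for (p in setdiff(nm, "beta"))
    if (vals[[p]] < 0 || vals[[p]] > 1)
      stop("`", p, "` must lie in [0, 1]", call. = FALSE)
  if (vals$beta < 0) stop("`beta` must be non-negative", call. = FALSE)
  structure(c(list(model = model), vals), class = "lvb_params")
}

#' Initialize Q values
#'
#' All values start at 0.5, the midpoint of the recoded binary outcome.
#' The select-reject model carries two ledgers (2 x `n_arms` values).
#'
#' @param model Model id.
#' @param n_arms Number of arms (>= 2).
#' @return List of class `lvb_state` with `q`, or `q_select`/`q_reject`.
#' @export
init_state <- function(model, n_arms = 4L) {
  model <- match.arg(model, lvb_models())
  n_arms <- as.integer(n_arms)
  if (is.na(n_arms) || n_arms < 2L)
    stop("`n_arms` must be at least 2", call. = FALSE)
  st <- if (model == "select_reject")
    list(model = model, q_select = rep(0.5, n_arms),
         q_reject = rep(0.5, n_arms))
  else list(model = model, q = rep(0.5, n_arms))
  structure(st, class = "lvb_state")
}

#' Clamp Q values into [0, 1]
#'
#' Values can leave the unit interval only under `double_one_pe` (the
#' sign-flipped update); in that rare event they are truncated.
#'
#' @param state An `lvb_state`.
#' @return The state with every value clamped into `[0, 1]`.
#' @export
truncate_q <- function(state) {
  for (f in intersect(names(state), c("q", "q_select", "q_reject")))
    state[[f]] <- pmin(1, pmax(0, state[[f]]))
  state
}

#' Choice probabilities for an offered pair
#'
#' Softmax over the two offered arms' values. For the select-reject model
#' the decision values are the integrated
#' `Q_net(x) = omega * Q_select(x) + (1 - omega) * Q_reject(other)`.
#'
#' @param model Model id.
#' @param state An `lvb_state`.
#' @param offer Integer pair of distinct 0-based arm indices.
#' @param params An `lvb_params` (or named list) for the model.
#' @return Named numeric of length 2: probability of each offered arm
#'   (sums to 1).
#' @export
choice_prob <- function(model, state, offer, params) {
  model <- match.arg(model, lvb_models())
  if (length(offer) != 2L || offer[1L] == offer[2L])
    stop("`offer` must be two distinct arms", call. = FALSE)
  p <- .par_slots(model, params)
  a <- offer[1L] + 1L; b <- offer[2L] + 1L
  if (model == "select_reject") {
    w <- p[2L]
    va <- w * state$q_select[a] + (1 - w) * state$q_reject[b]
    vb <- w * state$q_select[b] + (1 - w) * state$q_reject[a]
  } else {
    va <- state$q[a]; vb <- state$q[b]
  }
  pa <- 1 / (1 + exp(-p[3L] * (va - vb)))
  stats::setNames(c(pa, 1 - pa), paste0("arm", offer))
}

#' Apply one trial's value update
#'
#' Updates the state from an observed (choice, reward) pair according to the
#' model's learning rule, then truncates values into `[0, 1]`. Arms outside
#' the offered pair never change.
#'
#' @inheritParams choice_prob
#' @param choice 0-based index of the chosen arm (must be in `offer`).
#' @param reward01 Recoded binary reward (0 or 1). Raw payoffs must be
#'   recoded first.
#' @return List with the new `state` and `pe`, the prediction errors
#'   (`delta_chosen`, and `delta_unchosen` where the model defines one).
#' @export
update_state <- function(model, state, offer, choice, reward01, params) {
  model <- match.arg(model, lvb_models())
  if (!choice %in% offer)
    stop("`choice` must be one of the offered arms", call. = FALSE)
  if (!reward01 %in% c(0, 1))
    stop("`reward01` must be 0 or 1 (recode payoffs first)", call. = FALSE)
  p <- .par_slots(model, params)
  ch <- choice + 1L
  un <- offer[offer != choice] + 1L
  pe <- list(delta_chosen = NA_real_, delta_unchosen = NA_real_)
  if (model == "select_reject") {
    pe$delta_chosen <- reward01 - state$q_select[ch]
    state$q_select[ch] <- state$q_select[ch] + p[1L] * pe$delta_chosen
    pe$delta_unchosen <- reward01 - state$q_reject[un]
    state$q_reject[un] <- state$q_reject[un] + p[1L] * pe$delta_unchosen
  } else {
    pe$delta_chosen <- reward01 - state$q[ch]
    state$q[ch] <- state$q[ch] + p[1L] * pe$delta_chosen
    if (model == "double_two_pe") {
      pe$delta_unchosen <- (1 - reward01) - state$q[un]
      state$q[un] <- state$q[un] + p[2L] * pe$delta_unchosen
    } else if (model == "double_one_pe") {
      state$q[un] <- state$q[un] + p[2L] * (-pe$delta_chosen)
    }
  }
  list(state = truncate_q(state), pe = pe)
}

#' Sequence log-likelihood of one participant-block
#'
#' Runs the model trial-by-trial through a single block (state initialized at
#' the block start, updated after every observed outcome) and accumulates the
#' log-probability of each observed choice. No-response trials contribute no
#' likelihood and trigger no update.
#'
#' @param model Model id.
#' @param params An `lvb_params` (or named list) on the natural scale.
#' @param block_trials Data frame of one participant's trials in one block,
#'   sorted by `trial` (columns `offer_a`, `offer_b`, `choice`, `reward01`).
#' @param n_arms Number of arms.
#' @return List with `total` (sum over answered trials) and `pointwise`
#'   (per-trial log-probabilities; `NA` for no-response trials).
#' @export
sequence_loglik <- function(model, params, block_trials, n_arms = 4L) {
  model <- match.arg(model, lvb_models())
  if ("block" %in% names(block_trials) &&
      length(unique(block_trials$block)) > 1L)
    stop("`block_trials` mixes blocks; pass a single participant-block",
         call. = FALSE)
  if ("trial" %in% names(block_trials) && is.unsorted(block_trials$trial))
    stop("`block_trials` must be sorted by trial", call. = FALSE)
  ch <- block_trials$choice
  ch[is.na(ch)] <- -1L
  pw <- cpp_block_loglik(.model_code(model), .par_slots(model, params),
                         as.integer(block_trials$offer_a),
                         as.integer(block_trials$offer_b),
                         as.integer(ch),
                         as.integer(ifelse(is.na(block_trials$reward01), 0L,
                                           block_trials$reward01)),
                         as.integer(n_arms))
  list(total = sum(pw, na.rm = TRUE), pointwise = pw)
}

#' Simulate one agent on a given task
#'
#' Choices are sampled from the model's softmax policy, outcomes from the
#' true drifting reward probabilities; the value state is reset at every
#' block start. Fully reproducible given a seed.
#'
#' @param model Model id.
#' @param params Natural-scale parameters for the agent.
#' @param schedule An `lvb_schedule` array `[block, trial, arm]`.
#' @param offers Integer matrix of offers as from [generate_offers()].
#' @param config The [task_config()].
#' @param seed Optional integer seed (`NULL` = use current RNG stream).
#' @param participant_id Identifier stored in the records.
#' @return Data frame of trial records (see [read_trials()] for columns).
#' @export
simulate_agent <- function(model, params, schedule, offers, config,
                           seed = NULL, participant_id = "agent1") {
  model <- match.arg(model, lvb_models())
  stopifnot(inherits(config, "lvb_task_config"))
  if (!is.null(seed)) set.seed(seed)
  tpb <- config$trials_per_block
  if (nrow(offers) != config$n_blocks * tpb)
    stop("`offers` does not span the configured blocks and trials",
         call. = FALSE)
  par <- .par_slots(model, params)
  out <- vector("list", config$n_blocks)
  for (b in seq_len(config$n_blocks)) {
    rows <- (b - 1L) * tpb + seq_len(tpb)
    pmat <- matrix(schedule[b, , ], nrow = tpb)
    sim <- cpp_simulate_block(.model_code(model), par, pmat,
                              as.integer(offers[rows, 1L]),
                              as.integer(offers[rows, 2L]))
    bt <- config$block_types[b]
    out[[b]] <- data.frame(
      participant_id = participant_id, block = b, block_type = bt,
      trial = seq_len(tpb),
      offer_a = offers[rows, 1L], offer_b = offers[rows, 2L],
      choice = sim$choice, payoff = payoff_from_reward(sim$reward01, bt),
      reward01 = sim$reward01, rt_ms = NA_integer_)
  }
  do.call(rbind, out)
}

#' Simulate a cohort of agents
#'
#' Draws a fresh reward schedule and offer sequence per agent and simulates
#' each agent with its own parameters.
#'
#' @param model Model id.
#' @param params_df Data frame with one row per agent holding the
#'   natural-scale parameters named as in [param_names()] (e.g. from
#'   [sample_cohort_params()]).
#' @param config The [task_config()].
#' @param seed Integer seed governing schedules, offers and choices.
#' @return An [cohort()] with per-participant true schedules and a
#'   provenance tag naming the generating model and seed.
#' @export
simulate_cohort <- function(model, params_df, config = task_config(),
                            seed = 1L) {
  model <- match.arg(model, lvb_models())
  set.seed(seed)
  n <- nrow(params_df)
  ids <- sprintf("sim%03d", seq_len(n))
  trials <- vector("list", n)
  schedules <- vector("list", n)
  for (i in seq_len(n)) {
    sched <- generate_reward_schedule(config)
    offers <- generate_offers(config)
    trials[[i]] <- simulate_agent(model, as.list(params_df[i, , drop = FALSE]),
                                  sched, offers, config,
                                  participant_id = ids[i])
    schedules[[i]] <- sched
  }
  names(schedules) <- ids
  cohort(do.call(rbind, trials), schedules = schedules, config = config,
         provenance = list(source = "simulated", model = model, seed = seed))
}

# ---- internal: pack a cohort for the C++ likelihood kernels ----------------

# Returns sorted trial vectors plus participant index and block-start flags.
pack_cohort <- function(trials, participants = NULL) {
  if (is.null(participants)) participants <- unique(trials$participant_id)
  trials <- trials[trials$participant_id %in% participants, , drop = FALSE]
  ord <- order(match(trials$participant_id, participants),
               trials$block, trials$trial)
  trials <- trials[ord, , drop = FALSE]
  pid <- match(trials$participant_id, participants) - 1L
  key <- paste(trials$participant_id, trials$block)
  new_block <- as.integer(!duplicated(key))
  ch <- trials$choice
  ch[is.na(ch)] <- -1L
  list(participants = participants,
       offer_a = as.integer(trials$offer_a),
       offer_b = as.integer(trials$offer_b),
       choice = as.integer(ch),
       reward = as.integer(ifelse(is.na(trials$reward01), 0L,
                                  trials$reward01)),
       pid = pid, new_block = new_block,
       trials = trials)
}

# Per-participant summed log-likelihood; theta is an n x 3 natural-scale
# matrix in .par_slots layout.
cohort_loglik <- function(model, theta, packed, n_arms = 4L) {
  cpp_cohort_loglik(.model_code(model), theta,
                    packed$offer_a, packed$offer_b, packed$choice,
                    packed$reward, packed$pid, packed$new_block,
                    as.integer(n_arms))
}
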
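#' Posterior summary of a vector of draws
#'
#' Reports the posterior median, the 95% highest-density interval and the
#' probability of direction `pd = max(P(x > 0), P(x < 0))`.
#'
#' @param x Numeric vector of posterior draws (at least 100).
#' @param prob Interval mass (default 0.95).
#' @param method `"hdi"` (highest-density, default) or `"eti"`
#'   (equal-tailed).
#' @return Data frame with columns `median`, `hdi_low`, `hdi_high`, `pd`.
#' @export
posterior_summary <- function(x, prob = 0.95, method = c("hdi", "eti")) {
  method <- match.arg(method)
  x <- x[is.finite(x)]
  if (length(x) < 100L)
    stop("need at least 100 draws to summarize a posterior", call. = FALSE)
  if (method == "hdi") {
    iv <- hdi_interval(x, prob)
  } else {
    iv <- unname(stats::quantile(x, c((1 - prob) / 2, 1 - (1 - prob) / 2)))
  }
  data.frame(median = stats::median(x), hdi_low = iv[1L], hdi_high = iv[2L],
             pd = max(mean(x > 0), mean(x < 0)))
}

hdi_interval <- function(x, prob = 0.95) {
  s <- sort(x)
  n <- length(s)
  m <- max(1L, floor(prob * n))
  if (m >= n) return(c(s[1L], s[n]))
  widths <- s[(m + 1L):n] - s[1L:(n - m)]
  i <- which.min(widths)
  c(s[i], s[i + m])
}

# split R-hat (Gelman et al.): x vector of draws, chain id per draw
split_rhat <- function(x, chain) {
  halves <- unlist(lapply(split(x, chain), function(v) {
    h <- length(v) %/% 2L
    list(v[seq_len(h)], v[(h + 1L):(2L * h)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- min(lengths(halves))
  halves <- lapply(halves, utils::head, n)
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Hierarchical log posterior (non-centered parameterization)
#'
#' The density targeted by [fit_hier()]: population locations `mu_j ~
#' Normal(0, 2)`, population scales `sigma_j ~ half-Cauchy(0, 2)`, individual
#' unit offsets `~ Normal(0, 1)` with individual unconstrained parameters
#' `z_ij = mu_j + sigma_j * offset_ij`, and the trial-sequential choice
#' likelihood on the natural scale. Exposed mainly for testing and for
#' writing alternative samplers.
#'
#' @param model Model id.
#' @param data An `lvb_cohort` (may be empty of trials, in which case the
#'   prior alone is returned).
#' @param mu,sigma Numeric vectors, one entry per model parameter.
#' @param offsets Matrix (participants x parameters) of unit-scale offsets.
#' @param n_arms Number of arms.
#' @return Scalar log posterior density (unnormalized).
#' @export
log_posterior <- function(model, data, mu, sigma, offsets, n_arms = 4L) {
  model <- match.arg(model, lvb_models())
  k <- length(param_names(model))
  offsets <- rbind(offsets)
  stopifnot(length(mu) == k, length(sigma) == k, ncol(offsets) == k)
  if (any(!is.finite(mu)) || any(!is.finite(sigma)) ||
      any(!is.finite(offsets)))
    stop("non-finite parameter values", call. = FALSE)
  if (any(sigma <= 0)) return(-Inf)
  lp <- sum(stats::dnorm(mu, 0, 2, log = TRUE)) +
    sum(stats::dcauchy(sigma, 0, 2, log = TRUE) + log(2)) +
    sum(stats::dnorm(offsets, 0, 1, log = TRUE))
  trials <- if (inherits(data, "lvb_cohort")) data$trials else data
  if (!is.null(trials) && nrow(trials) > 0L) {
    packed <- pack_cohort(trials)
    if (length(packed$participants) != nrow(offsets))
      stop("offsets rows must match the number of participants",
           call. = FALSE)
    z <- sweep(sweep(offsets, 2L, sigma, `*`), 2L, mu, `+`)
    lp <- lp + sum(cohort_loglik(model, z_to_slots(model, z), packed,
                                 n_arms))
  }
  lp
}

#' Sampler presets
#'
#' `"desk"` (4 chains x 500 warm-up x 250 draws) keeps recovery experiments
#' in CI-scale minutes; `"production"` (4 x 1000 x 500) is the default for
#' real fits; `"paper"` mirrors the recovery runs of the original study
#' (20 chains x 1000 warm-up x 50 draws = 1000 posterior samples).
#'
#' @param preset Preset name.
#' @param ... Overrides for `chains`, `warmup`, `draws`.
#' @return List with `chains`, `warmup`, `draws`.
#' @export
sampler_config <- function(preset = c("production", "desk", "paper"), ...) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
                production = list(chains = 4L, warmup = 1000L, draws = 500L),
                desk = list(chains = 4L, warmup = 500L, draws = 250L),
                paper = list(chains = 20L, warmup = 1000L, draws = 50L))
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Fit a model hierarchically to a cohort
#'
#' Samples the posterior of [log_posterior()] with an adaptive
#' Metropolis-within-Gibbs scheme on the centered parameterization:
#' per-participant joint random-walk proposals for the individual
#' unconstrained parameters (the only step touching the choice likelihood,
#' evaluated in C++ for the whole cohort at once), a conjugate Normal draw
#' for each population location, and a log-scale random-walk step for each
#' population scale. Proposal step sizes adapt during warm-up
#' (Robbins-Monro, targets 0.30 / 0.44) and are frozen afterwards.
#'
#' @param model Model id.
#' @param data An `lvb_cohort` or trials data frame.
#' @param chains Number of chains (>= 2 for R-hat).
#' @param warmup,draws Warm-up sweeps and retained draws per chain.
#' @param seed Integer seed; chain `c` uses `seed + c - 1`.
#' @param n_arms Number of arms.
#' @return Object of class `lvb_fit` holding population draws (`mu`,
#'   `sigma`, unconstrained scale), individual draws (`z`), chain labels and
#'   convergence diagnostics (split R-hat per population parameter; the fit
#'   is flagged `converged = FALSE` when any R-hat exceeds 1.01, but still
#'   returned).
#' @export
fit_hier <- function(model, data, chains = 4L, warmup = 1000L, draws = 500L,
                     seed = 1L, n_arms = 4L) {
  model <- match.arg(model, lvb_models())
  if (chains < 2L) stop("need at least 2 chains for R-hat", call. = FALSE)
  trials <- if (inherits(data, "lvb_cohort")) data$trials else data
  packed <- pack_cohort(trials)
  n <- length(packed$participants)
  k <- length(param_names(model))
  beta_j <- which(param_names(model) == "beta")

  total <- chains * draws
  mu_d <- matrix(NA_real_, total, k)
  sig_d <- matrix(NA_real_, total, k)
  z_d <- array(NA_real_, c(total, n, k))
  chain_id <- rep(seq_len(chains), each = draws)
  row0 <- 0L

  for (ch in seq_len(chains)) {
    set.seed(seed + ch - 1L)
    mu <- rep(0, k); mu[beta_j] <- 1.5
    sigma <- rep(0.5, k)
    z <- matrix(rep(mu, each = n), n, k) + matrix(stats::rnorm(n * k, 0, 0.3), n, k)
    ll <- cohort_loglik(model, z_to_slots(model, z), packed, n_arms)
    log_eps <- matrix(log(0.5), n, k) # per-participant/-parameter step
    log_step <- rep(log(0.4), k)      # per-parameter sigma proposal scale

    for (t in seq_len(warmup + draws)) {
      # -- individual parameters: one vectorized MH step per dimension ----
      gam <- min(0.5, 3 / sqrt(t))
      for (j in seq_len(k)) {
        zp <- z
        zp[, j] <- z[, j] + exp(log_eps[, j]) * stats::rnorm(n)
        llp <- cohort_loglik(model, z_to_slots(model, zp), packed, n_arms)
        acc <- log(stats::runif(n)) <
          (llp - ll +
             stats::dnorm(zp[, j], mu[j], sigma[j], log = TRUE) -
             stats::dnorm(z[, j], mu[j], sigma[j], log = TRUE))
        z[acc, j] <- zp[acc, j]
        ll[acc] <- llp[acc]
        if (t <= warmup)
          log_eps[, j] <- log_eps[, j] + gam * (acc - 0.44)
      }

      # -- population locations: conjugate Normal given z, sigma ----------
      prec <- n / sigma^2 + 1 / 4
      mean_post <- (colSums(z) / sigma^2) / prec
      mu <- stats::rnorm(k, mean_post, 1 / sqrt(prec))

      # -- population scales: log-scale MH with half-Cauchy prior --------
      for (j in seq_len(k)) {
        ls_prop <- log(sigma[j]) + stats::rnorm(1L, 0, exp(log_step[j]))
        sp <- exp(ls_prop)
        logr <- sum(stats::dnorm(z[, j], mu[j], sp, log = TRUE)) -
          sum(stats::dnorm(z[, j], mu[j], sigma[j], log = TRUE)) +
          stats::dcauchy(sp, 0, 2, log = TRUE) -
          stats::dcauchy(sigma[j], 0, 2, log = TRUE) +
          ls_prop - log(sigma[j])  # Jacobian of the log transform
        acc_s <- log(stats::runif(1L)) < logr
        if (acc_s) sigma[j] <- sp
        if (t <= warmup)
          log_step[j] <- log_step[j] + gam * ((acc_s) - 0.44)
      }

      if (t > warmup) {
        r <- row0 + (t - warmup)
        mu_d[r, ] <- mu
        sig_d[r, ] <- sigma
        z_d[r, , ] <- z
      }
    }
    row0 <- row0 + draws
  }

  nm <- param_names(model)
  colnames(mu_d) <- colnames(sig_d) <- nm
  rhat <- c(
    stats::setNames(vapply(seq_len(k), function(j)
      split_rhat(mu_d[, j], chain_id), 0), paste0("mu_", nm)),
    stats::setNames(vapply(seq_len(k), function(j)
      split_rhat(sig_d[, j], chain_id), 0), paste0("sigma_", nm)))
  structure(
    list(model = model, param_names = nm,
         participants = packed$participants, n_arms = n_arms,
         mu = mu_d, sigma = sig_d, z = z_d, chain = chain_id,
         chains = chains, warmup = warmup, draws_per_chain = draws,
         seed = seed,
         diagnostics = list(rhat = rhat,
                            converged = all(rhat <= 1.01, na.rm = TRUE))),
    class = "lvb_fit")
}

#' @export
print.lvb_fit <- function(x, ...) {
  cat("Hierarchical fit of `", x$model, "`: ",
      length(x$participants), " participants, ",
      x$chains, " chains x ", x$draws_per_chain, " draws\n", sep = "")
  print(population_summary(x), row.names = FALSE)
  if (!x$diagnostics$converged)
    cat("WARNING: non-converged (max R-hat ",
        round(max(x$diagnostics$rhat), 3), ")\n", sep = "")
  invisible(x)
}

#' Population-level posterior summaries
#'
#' Summarizes the population location of every parameter. With
#' `natural = TRUE` (default) the location draws are pushed through the
#' parameter transform first, so e.g. the `omega` row is the posterior of
#' the natural-scale population decision weight.
#'
#' @param fit An `lvb_fit`.
#' @param natural Report on the natural scale?
#' @param method Interval type, see [posterior_summary()].
#' @return Data frame, one row per parameter.
#' @export
population_summary <- function(fit, natural = TRUE, method = "hdi") {
  tr <- param_transforms(fit$model)
  out <- do.call(rbind, lapply(seq_along(fit$param_names), function(j) {
    d <- fit$mu[, j]
    if (natural)
      d <- if (tr[j] == "softplus") softplus(d) else inv_logit(d)
    posterior_summary(d, method = method)
  }))
  cbind(data.frame(parameter = fit$param_names,
                   scale = if (natural) "natural" else "unconstrained"),
        out)
}

#' Posterior medians of individual natural-scale parameters
#'
#' @param fit An `lvb_fit`.
#' @return Matrix (participants x parameters) of posterior medians on the
#'   natural scale; rownames are participant ids.
#' @export
individual_medians <- function(fit) {
  k <- length(fit$param_names)
  n <- length(fit$participants)
  out <- matrix(NA_real_, n, k,
                dimnames = list(fit$participants, fit$param_names))
  tr <- param_transforms(fit$model)
  for (j in seq_len(k)) {
    d <- fit$z[, , j, drop = FALSE]
    d <- if (tr[j] == "softplus") softplus(d) else inv_logit(d)
    out[, j] <- apply(d[, , 1L, drop = FALSE], 2L, stats::median)
  }
  out
}

# 3-slot natural-scale draws for one participant (S x 3), for elpd scoring
participant_theta_draws <- function(fit, i) {
  z_i <- fit$z[, i, , drop = TRUE]
  z_i <- matrix(z_i, ncol = length(fit$param_names))
  natural_to_slots(fit$model, to_natural(fit$model, z_i))
}

#' Stated population values of the recovery experiments
#'
#' Natural-scale population locations and unconstrained-scale individual
#' SDs used by the simulation studies: learning rates 0.3 (chosen) and 0.1
#' (unchosen), decision weight 0.7, inverse noise 4; individual SDs 1 for
#' rates/weights and 1.5 for the inverse noise.
#'
#' @param model Model id.
#' @return List with named `location` (natural scale) and `scale`
#'   (unconstrained SDs).
#' @export
recovery_truths <- function(model) {
  model <- match.arg(model, lvb_models())
  switch(model,
         baseline = list(
           location = c(alpha_chosen = 0.3, beta = 4),
           scale = c(alpha_chosen = 1, beta = 1.5)),
         double_two_pe = ,
         double_one_pe = list(
           location = c(alpha_chosen = 0.3, alpha_unchosen = 0.1, beta = 4),
           scale = c(alpha_chosen = 1, alpha_unchosen = 1, beta = 1.5)),
         select_reject = list(
           location = c(alpha = 0.3, omega = 0.7, beta = 4),
           scale = c(alpha = 1, omega = 1, beta = 1.5)))
}

#' Draw per-agent parameters from a population
#'
#' Individual unconstrained parameters are Normal around the population
#' location with the population SD, then mapped to the natural scale. The
#' population can be a fixed specification (as from [recovery_truths()]) or
#' a fitted posterior, in which case each agent first draws a retained
#' posterior sample of `(mu, sigma)` — i.e. agents come from the population
#' marginal posterior.
#'
#' @param model Model id.
#' @param population Either `list(location=, scale=)` with natural-scale
#'   locations and unconstrained SDs, or an `lvb_fit`.
#' @param n_agents Number of agents.
#' @param seed Optional integer seed.
#' @return Data frame (agents x parameters) of natural-scale parameters;
#'   the unconstrained draws are attached as attribute `"unconstrained"`.
#' @export
sample_cohort_params <- function(model, population, n_agents, seed = NULL) {
  model <- match.arg(model, lvb_models())
  if (!is.null(seed)) set.seed(seed)
  if (n_agents < 1L) stop("`n_agents` must be >= 1", call. = FALSE)
  nm <- param_names(model)
  k <- length(nm)
  if (inherits(population, "lvb_fit")) {
    stopifnot(population$model == model)
    idx <- sample.int(nrow(population$mu), n_agents, replace = TRUE)
    loc <- population$mu[idx, , drop = FALSE]
    sc <- population$sigma[idx, , drop = FALSE]
  } else {
    loc_nat <- population$location[nm]
    if (anyNA(loc_nat)) stop("population location missing parameters",
                             call. = FALSE)
    loc <- matrix(to_unconstrained(model, loc_nat), n_agents, k, byrow = TRUE)
    sc <- matrix(population$scale[nm], n_agents, k, byrow = TRUE)
  }
  z <- loc + sc * matrix(stats::rnorm(n_agents * k), n_agents, k)
  nat <- to_natural(model, z)
  out <- as.data.frame(rbind(nat))
  names(out) <- nm
  attr(out, "unconstrained") <- z
  out
}
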
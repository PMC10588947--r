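#' Parameter-recovery experiment
#'
#' Simulates a cohort hierarchically from one model at stated population
#' truths, refits the model, and reports (a) whether each natural-scale
#' population truth falls inside the HDI95 of its posterior and (b) the
#' individual-level Pearson correlation between true and posterior-median
#' parameters.
#'
#' @param model Model id (the recovery battery targets the three
#'   3-parameter models, but `baseline` is allowed).
#' @param n_agents Number of simulated agents (paper scale: 175; desk scale
#'   defaults to 40).
#' @param truths Population specification, see [recovery_truths()].
#' @param config Task design, see [task_config()].
#' @param chains,warmup,draws Sampler settings.
#' @param seed Master seed for the experiment.
#' @return Object of class `lvb_recovery`: `population` (truth, posterior
#'   median, HDI, `covered`), `individual` (Pearson r per parameter; `NA`
#'   and flagged when an individual SD of 0 makes it undefined), the `fit`,
#'   and `converged`.
#' @export
run_parameter_recovery <- function(model, n_agents = 40L,
                                   truths = recovery_truths(model),
                                   config = task_config(),
                                   chains = 4L, warmup = 500L, draws = 250L,
                                   seed = 1L) {
  model <- match.arg(model, lvb_models())
  params <- sample_cohort_params(model, truths, n_agents, seed = seed)
  coh <- simulate_cohort(model, params, config, seed = seed + 1L)
  fit <- fit_hier(model, coh, chains = chains, warmup = warmup,
                  draws = draws, seed = seed + 2L)
  pop <- population_summary(fit, natural = TRUE)
  pop$truth <- unname(truths$location[pop$parameter])
  pop$covered <- pop$truth >= pop$hdi_low & pop$truth <= pop$hdi_high
  med <- individual_medians(fit)
  indiv <- do.call(rbind, lapply(fit$param_names, function(p) {
    truth_i <- params[[p]]
    degenerate <- stats::sd(truth_i) == 0
    data.frame(parameter = p,
               pearson_r = if (degenerate) NA_real_
                           else stats::cor(truth_i, med[, p]),
               degenerate = degenerate)
  }))
  structure(list(model = model, n_agents = n_agents,
                 population = pop[, c("parameter", "truth", "median",
                                      "hdi_low", "hdi_high", "covered")],
                 individual = indiv, fit = fit,
                 converged = fit$diagnostics$converged, seed = seed),
            class = "lvb_recovery")
}

#' @export
print.lvb_recovery <- function(x, ...) {
  cat("Parameter recovery for `", x$model, "` (", x$n_agents, " agents)\n",
      sep = "")
  print(x$population, row.names = FALSE)
  print(x$individual, row.names = FALSE)
  if (!x$converged) cat("WARNING: fit flagged non-converged\n")
  invisible(x)
}

#' Model-recovery experiment
#'
#' For every generating model: simulate one cohort at the stated truths,
#' compute the leave-one-block-out elpd of every candidate model on that
#' cohort, and tabulate the elpd difference of each alternative relative to
#' the data-generating model (negative = worse than the generator), with
#' the standard error of the pointwise difference. Successful recovery means
#' the generating model tops every column and beats the baseline by more
#' than twice the SE.
#'
#' @param generating Models to generate from (default: the three
#'   3-parameter models).
#' @param fitted Candidate models to fit (default: all four).
#' @param n_agents Agents per generated cohort.
#' @param config Task design.
#' @param chains,warmup,draws Sampler settings per cross-validation fold.
#' @param seed Master seed.
#' @return Object of class `lvb_model_recovery`: `delta` and `se` matrices
#'   (fitted x generating), `comparisons` (per generating model, the
#'   [compare_elpd()] table), `top_model` per column.
#' @export
run_model_recovery <- function(generating = c("select_reject",
                                              "double_one_pe",
                                              "double_two_pe"),
                               fitted = lvb_models(),
                               n_agents = 40L, config = task_config(),
                               chains = 2L, warmup = 400L, draws = 200L,
                               seed = 1L) {
  delta <- se <- matrix(NA_real_, length(fitted), length(generating),
                        dimnames = list(fitted, generating))
  comparisons <- list()
  top <- character(length(generating))
  names(top) <- generating
  for (gi in seq_along(generating)) {
    g <- generating[gi]
    params <- sample_cohort_params(g, recovery_truths(g), n_agents,
                                   seed = seed + 10L * gi)
    coh <- simulate_cohort(g, params, config, seed = seed + 10L * gi + 1L)
    elpds <- lapply(fitted, function(m)
      leave_one_block_out(m, coh, chains = chains, warmup = warmup,
                          draws = draws, seed = seed + 10L * gi + 2L))
    names(elpds) <- fitted
    comparisons[[g]] <- compare_elpd(elpds)
    pw_g <- elpds[[g]]$elpd
    for (m in fitted) {
      d <- elpds[[m]]$elpd - pw_g
      ok <- !is.na(d)
      delta[m, g] <- sum(d[ok])
      se[m, g] <- if (m == g) 0 else sqrt(sum(ok)) * stats::sd(d[ok])
    }
    top[g] <- fitted[which.max(vapply(elpds, attr, 0, "total"))]
  }
  structure(list(delta = delta, se = se, comparisons = comparisons,
                 top_model = top, n_agents = n_agents, seed = seed),
            class = "lvb_model_recovery")
}

#' @export
print.lvb_model_recovery <- function(x, ...) {
  cat("Model recovery (", x$n_agents, " agents): delta elpd vs generating",
      "model (SE)\n", sep = "")
  tab <- matrix(sprintf("%.1f (%.1f)", x$delta, x$se),
                nrow(x$delta), ncol(x$delta), dimnames = dimnames(x$delta))
  print(tab, quote = FALSE)
  cat("Top model per column:",
      paste(names(x$top_model), "->", x$top_model, collapse = "; "), "\n")
  invisible(x)
}

#' Signature-reproduction experiment
#'
#' Simulates a cohort from one model (at fixed truths or from a fitted
#' population posterior), builds the lagged-trial dataset and fits the
#' hierarchical logistic regression, reporting whether the simulated agents
#' reproduce the behavioural signature of latent value updating: a negative
#' previous-outcome coefficient. The baseline model is expected to produce a
#' null effect (HDI covering zero), the three updating models a negative
#' one.
#'
#' @param model Model id.
#' @param population Fixed `list(location=, scale=)` or an `lvb_fit`; agents
#'   are drawn from the population marginal posterior in the latter case.
#' @param n_agents Number of simulated agents.
#' @param lag Trials back (1 or 2).
#' @param moderators Moderators for the regression (simulated data has no
#'   response times, so the default moderation check uses previous
#'   difficulty).
#' @param config Task design.
#' @param seed Master seed.
#' @param ... Passed to [fit_lagged_regression()].
#' @return Object of class `lvb_signature`: `rates`, `regression`, and
#'   `prev_outcome` (its posterior summary row plus the sign).
#' @export
run_signature_reproduction <- function(model,
                                       population = recovery_truths(model),
                                       n_agents = 40L, lag = 1L,
                                       moderators = "prev_difficulty",
                                       config = task_config(), seed = 1L,
                                       ...) {
  model <- match.arg(model, lvb_models())
  params <- sample_cohort_params(model, population, n_agents, seed = seed)
  coh <- simulate_cohort(model, params, config, seed = seed + 1L)
  rows <- build_lagged_dataset(coh, lag = lag)
  reg <- fit_lagged_regression(rows, moderators = moderators,
                               seed = seed + 2L, ...)
  po <- reg$summary[reg$summary$coefficient == "prev_outcome", ]
  structure(list(model = model, n_agents = n_agents, lag = lag,
                 rates = raw_rates(rows), regression = reg,
                 prev_outcome = cbind(po,
                                      sign = sign(po$median),
                                      null_covered = po$hdi_low <= 0 &
                                        po$hdi_high >= 0),
                 seed = seed),
            class = "lvb_signature")
}

#' @export
print.lvb_signature <- function(x, ...) {
  cat("Signature reproduction for `", x$model, "` (", x$n_agents,
      " agents, lag ", x$lag, ")\n", sep = "")
  print(x$rates$overall, row.names = FALSE)
  print(x$prev_outcome, row.names = FALSE)
  invisible(x)
}

#' Run the full validation battery
#'
#' Executes parameter recovery for the three 3-parameter models, model
#' recovery, and signature reproduction for all four models, under one
#' master seed, optionally writing all artifacts plus a JSON manifest to a
#' directory. A failing stage is recorded in the manifest and does not
#' abort later independent stages.
#'
#' @param n_agents Agents per experiment.
#' @param scale_factor Multiplies `n_agents` and the sampler draws (e.g.
#'   `0.5` halves both) for quick desk runs.
#' @param config Task design.
#' @param seed Master seed.
#' @param out_dir Output directory for CSV/JSON artifacts, or `NULL`.
#' @return List with `parameter_recovery`, `model_recovery`, `signatures`,
#'   and `manifest`.
#' @export
run_full_study <- function(n_agents = 40L, scale_factor = 1,
                           config = task_config(), seed = 1L,
                           out_dir = NULL) {
  n_agents <- max(2L, as.integer(round(n_agents * scale_factor)))
  sc <- function(x) max(50L, as.integer(round(x * scale_factor)))
  manifest <- list(seed = seed, n_agents = n_agents,
                   scale_factor = scale_factor, stages = list())
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    manifest$stages[[name]] <<- if (inherits(res, "error"))
      list(status = "failed", message = conditionMessage(res))
    else list(status = "ok")
    if (inherits(res, "error")) NULL else res
  }
  pr <- lapply(c("double_two_pe", "double_one_pe", "select_reject"),
               function(m) run_stage(paste0("parameter_recovery_", m),
                 run_parameter_recovery(m, n_agents = n_agents,
                                        config = config,
                                        warmup = sc(500L), draws = sc(250L),
                                        seed = seed)))
  names(pr) <- c("double_two_pe", "double_one_pe", "select_reject")
  mr <- run_stage("model_recovery",
                  run_model_recovery(n_agents = n_agents, config = config,
                                     warmup = sc(400L), draws = sc(200L),
                                     seed = seed + 1L))
  sig <- lapply(lvb_models(), function(m)
    run_stage(paste0("signature_", m),
              run_signature_reproduction(m, n_agents = n_agents,
                                         config = config, seed = seed + 2L)))
  names(sig) <- lvb_models()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (m in names(pr)) if (!is.null(pr[[m]])) {
      utils::write.csv(pr[[m]]$population,
                       file.path(out_dir, paste0("recovery_", m, ".csv")),
                       row.names = FALSE)
    }
    if (!is.null(mr))
      utils::write.csv(as.data.frame(mr$delta),
                       file.path(out_dir, "model_recovery_delta.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(parameter_recovery = pr, model_recovery = mr, signatures = sig,
       manifest = manifest)
}
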
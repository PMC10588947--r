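#' Pointwise held-out log predictive density
#'
#' For every answered trial `i` of the held-out records,
#' `elpd_i = log( mean_s p(choice_i | theta_s) )` over the retained posterior
#' draws, with the predicted probability obtained by running the model
#' teacher-forced through the held-out block: the value state is
#' re-initialized at the block start and updated within the block using the
#' *observed* choices and outcomes, scoring one-step-ahead choice
#' probabilities.
#'
#' @param fit An `lvb_fit` whose training data excluded the held-out block.
#' @param heldout Trials data frame (or `lvb_cohort`) of the held-out
#'   records; every participant must appear in the fit.
#' @return Data frame `participant_id, block, trial, elpd` (`NA` elpd for
#'   no-response trials), class `lvb_elpd` with attributes `total` and
#'   `se_total`.
#' @export
pointwise_elpd <- function(fit, heldout) {
  trials <- if (inherits(heldout, "lvb_cohort")) heldout$trials else heldout
  if (!is.null(attr(fit, "heldout_guard"))) {
    tb <- attr(fit, "heldout_guard")
    if (any(paste(trials$participant_id, trials$block) %in% tb))
      stop("fit was trained on data containing the held-out block",
           call. = FALSE)
  }
  miss <- setdiff(unique(trials$participant_id), fit$participants)
  if (length(miss))
    stop("participants absent from the fit: ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  code <- .model_code(fit$model)
  out <- vector("list", 0L)
  for (id in unique(trials$participant_id)) {
    i <- match(id, fit$participants)
    draws <- participant_theta_draws(fit, i)
    pt <- trials[trials$participant_id == id, , drop = FALSE]
    for (b in unique(pt$block)) {
      blk <- pt[pt$block == b, , drop = FALSE]
      blk <- blk[order(blk$trial), , drop = FALSE]
      chv <- blk$choice
      chv[is.na(chv)] <- -1L
      e <- cpp_block_elpd(code, draws,
                          as.integer(blk$offer_a), as.integer(blk$offer_b),
                          as.integer(chv),
                          as.integer(ifelse(is.na(blk$reward01), 0L,
                                            blk$reward01)),
                          fit$n_arms)
      out[[length(out) + 1L]] <- data.frame(
        participant_id = id, block = b, trial = blk$trial, elpd = e)
    }
  }
  res <- do.call(rbind, out)
  ok <- !is.na(res$elpd)
  structure(res, class = c("lvb_elpd", class(res)),
            model = fit$model,
            total = sum(res$elpd[ok]),
            se_total = sqrt(sum(ok)) * stats::sd(res$elpd[ok]))
}

#' Leave-one-block-out cross-validated elpd
#'
#' For each block `b`: fit the model hierarchically on all other blocks,
#' then score block `b` pointwise with [pointwise_elpd()]. Every trial is
#' scored exactly once; participants appear in every training fold (the
#' fold holds out a block, not a participant).
#'
#' @param model Model id.
#' @param data An `lvb_cohort`.
#' @param chains,warmup,draws Sampler settings per fold, see [fit_hier()].
#' @param seed Integer seed; fold `b` uses `seed + 100 * b`.
#' @return `lvb_elpd` data frame covering all blocks, with attributes
#'   `total`, `se_total`, and `fits` (the per-fold fits, invisibly heavy).
#' @export
leave_one_block_out <- function(model, data, chains = 4L, warmup = 500L,
                                draws = 250L, seed = 1L) {
  stopifnot(inherits(data, "lvb_cohort"))
  blocks <- sort(unique(data$trials$block))
  if (length(blocks) < 2L)
    stop("leave-one-block-out needs at least 2 blocks", call. = FALSE)
  parts <- vector("list", length(blocks))
  for (bi in seq_along(blocks)) {
    b <- blocks[bi]
    train <- data$trials[data$trials$block != b, , drop = FALSE]
    test <- data$trials[data$trials$block == b, , drop = FALSE]
    fit <- fit_hier(model, train, chains = chains, warmup = warmup,
                    draws = draws, seed = seed + 100L * bi,
                    n_arms = data$config$n_arms %||% 4L)
    attr(fit, "heldout_guard") <- unique(paste(train$participant_id,
                                               train$block))
    parts[[bi]] <- pointwise_elpd(fit, test)
  }
  res <- do.call(rbind, lapply(parts, as.data.frame))
  res <- res[order(res$participant_id, res$block, res$trial), , drop = FALSE]
  rownames(res) <- NULL
  ok <- !is.na(res$elpd)
  structure(res, class = c("lvb_elpd", "data.frame"),
            model = model,
            total = sum(res$elpd[ok]),
            se_total = sqrt(sum(ok)) * stats::sd(res$elpd[ok]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pairwise elpd model comparison
#'
#' Ranks models by total held-out elpd and reports, for every model, the
#' difference to the best model together with its standard error
#' `se = sqrt(N) * sd(pointwise differences)`. A difference larger (in
#' magnitude) than twice its SE is flagged `substantial`.
#'
#' @param elpds Named list of `lvb_elpd` objects computed on identical trial
#'   sets (names = model ids; unnamed lists use the stored model attribute).
#' @return Data frame `model, elpd, se_elpd, delta_vs_best, se_delta,
#'   substantial`, best model first, class `lvb_elpd_comparison`.
#' @export
compare_elpd <- function(elpds) {
  if (is.null(names(elpds)) || any(!nzchar(names(elpds))))
    names(elpds) <- vapply(elpds, function(e) attr(e, "model"), "")
  key <- function(e) paste(e$participant_id, e$block, e$trial)
  k0 <- key(elpds[[1L]])
  for (nm in names(elpds)[-1L]) {
    ki <- key(elpds[[nm]])
    if (length(ki) != length(k0) || any(ki != k0))
      stop("pointwise trial sets differ between `", names(elpds)[1L],
           "` and `", nm, "`", call. = FALSE)
  }
  totals <- vapply(elpds, attr, 0, "total")
  best <- names(which.max(totals))
  pw_best <- elpds[[best]]$elpd
  rows <- lapply(names(elpds), function(nm) {
    d <- elpds[[nm]]$elpd - pw_best
    ok <- !is.na(d)
    delta <- sum(d[ok])
    se_d <- if (nm == best) 0 else sqrt(sum(ok)) * stats::sd(d[ok])
    data.frame(model = nm, elpd = totals[[nm]],
               se_elpd = attr(elpds[[nm]], "se_total"),
               delta_vs_best = delta, se_delta = se_d,
               substantial = nm != best & abs(delta) > 2 * se_d)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$elpd), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("lvb_elpd_comparison", "data.frame"), best = best)
}
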
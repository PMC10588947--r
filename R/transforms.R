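#' Parameter transforms between natural and unconstrained scales
#'
#' Hierarchical sampling and the population Normal hierarchy live on an
#' unconstrained scale: learning rates and `omega` are logit-transformed,
#' `beta` goes through the inverse softplus (an inverse noise below zero is
#' meaningless). Both maps are monotone bijections, so natural-scale medians
#' are preserved by transforming unconstrained medians.
#'
#' @param x Value(s) to transform.
#' @name transforms
NULL

#' @rdname transforms
#' @export
logit <- function(x) {
  if (any(x <= 0 | x >= 1))
    stop("logit is defined on (0, 1) only", call. = FALSE)
  stats::qlogis(x)
}

#' @rdname transforms
#' @export
inv_logit <- function(x) stats::plogis(x)

#' @rdname transforms
#' @export
softplus <- function(x) {
  ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))
}

#' @rdname transforms
#' @export
inv_softplus <- function(x) {
  if (any(x <= 0))
    stop("inverse softplus is defined on (0, Inf) only", call. = FALSE)
  ifelse(x > 30, x, log(expm1(x)))
}

# transform type per natural parameter of a model
param_transforms <- function(model) {
  nm <- param_names(model)
  ifelse(nm == "beta", "softplus", "logit")
}

#' Map unconstrained parameters to the natural scale (and back)
#'
#' @param model Model id.
#' @param z Numeric vector (length = number of parameters) or matrix
#'   (individuals x parameters) on the unconstrained scale.
#' @return Same shape on the natural scale, named by [param_names()].
#' @export
to_natural <- function(model, z) {
  tr <- param_transforms(model)
  z <- rbind(z)
  out <- z
  for (j in seq_along(tr))
    out[, j] <- if (tr[j] == "softplus") softplus(z[, j]) else inv_logit(z[, j])
  colnames(out) <- param_names(model)
  if (nrow(out) == 1L) out[1L, ] else out
}

#' @rdname to_natural
#' @param x Natural-scale vector or matrix.
#' @export
to_unconstrained <- function(model, x) {
  tr <- param_transforms(model)
  x <- rbind(x)
  out <- x
  for (j in seq_along(tr))
    out[, j] <- if (tr[j] == "softplus") inv_softplus(x[, j]) else logit(x[, j])
  colnames(out) <- param_names(model)
  if (nrow(out) == 1L) out[1L, ] else out
}

# natural-parameter matrix (n x k) -> uniform 3-slot layout for C++
natural_to_slots <- function(model, nat) {
  nat <- rbind(nat)
  if (model == "baseline") cbind(nat[, 1L], 0, nat[, 2L])
  else cbind(nat[, 1L], nat[, 2L], nat[, 3L])
}

# unconstrained matrix (n x k) -> 3-slot natural matrix
z_to_slots <- function(model, z) {
  natural_to_slots(model, to_natural(model, z))
}
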
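#' Fit the redirection-threshold model to kick data
#'
#' Sequential grid-Bayesian fit of the psychometric observer model to a set
#' of kicks. Each row of `data` is one kick with columns `trial_type`
#' (`"redirect"`/`"no_redirect"`), `tau_actual_ms` (realized dive lead time),
#' `anticipated` and `success` (logical). Starting from the prior, the
#' posterior over (threshold, slope, lapse, anticipation) is updated kick by
#' kick with the full likelihood case table, so the threshold estimate is
#' corrected for both anticipation behaviour and the global lapse rate.
#'
#' @param data Data frame of kicks (see Details).
#' @param grid A [param_grid].
#' @param prior,... Prior specification passed to [init_posterior].
#' @param forget Forgetting factor in (0, 1] applied at every update
#'   (see [update_posterior]); 1 fits a static ability.
#' @return An object of class `redirection_fit` with components `posterior`,
#'   `estimate` (from [threshold_estimate]), `n_trials`, `data`, `call`.
#' @seealso [coef.redirection_fit], [predict.redirection_fit],
#'   [plot.redirection_fit]
#' @examples
#' set.seed(1)
#' pl <- psychometric_params(429, 0.02, 0.1, 0.1)
#' taus <- seq(300, 550, by = 25)
#' kicks <- do.call(rbind, lapply(taus, function(tau) {
#'   out <- simulate_kick(pl, trial_type = "redirect", tau_ms = tau, n = 4)
#'   cbind(trial_type = "redirect", tau_actual_ms = tau, out)
#' }))
#' fit <- fit_threshold(kicks, grid = param_grid(theta_ms = seq(200, 650, 25)))
#' coef(fit)
#' @export
fit_threshold <- function(data, grid = param_grid(),
                          prior = c("uniform", "normal"), forget = 1, ...) {
  required <- c("trial_type", "tau_actual_ms", "anticipated", "success")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols))
    stop("'data' is missing column(s): ", paste(missing_cols, collapse = ", "))
  post <- init_posterior(grid, prior = match.arg(prior), ...)
  for (i in seq_len(nrow(data))) {
    ev <- trial_evidence(data$trial_type[i], data$tau_actual_ms[i],
                         data$anticipated[i], data$success[i])
    post <- update_posterior(post, ev, forget = forget)
  }
  structure(list(posterior = post, estimate = threshold_estimate(post),
                 n_trials = nrow(data), data = data,
                 call = match.call()),
            class = "redirection_fit")
}

#' @export
print.redirection_fit <- function(x, ...) {
  cat("Redirection-threshold fit (grid Bayes)\n")
  cat(sprintf("  kicks: %d (%d redirect)\n", x$n_trials,
              sum(x$data$trial_type == "redirect")))
  cat(sprintf("  50%% redirection threshold: %.1f ms (95%% CI %.1f-%.1f ms)\n",
              x$estimate$estimate_ms, x$estimate$ci_ms[1],
              x$estimate$ci_ms[2]))
  invisible(x)
}

#' Posterior-mean parameters of a redirection fit
#'
#' @param object A `redirection_fit`.
#' @param ... Unused.
#' @return Named vector with `threshold_ms`, `slope`, `lapse_rate`,
#'   `anticipation_rate` (posterior means).
#' @export
coef.redirection_fit <- function(object, ...) {
  g <- object$posterior$grid
  mass <- object$posterior$mass
  theta_vec <- rep.int(g$theta_ms, length(mass) / g$dim[1])
  slope_vec <- g$slope[(g$idx_ts - 1L) %/% g$dim[1] + 1L]
  c(threshold_ms = sum(mass * theta_vec),
    slope = sum(mass * slope_vec),
    lapse_rate = sum(mass * g$lapse_vec),
    anticipation_rate = sum(mass * g$antic_vec))
}

#' @export
summary.redirection_fit <- function(object, ...) {
  out <- list(coef = coef(object), estimate = object$estimate,
              n_trials = object$n_trials,
              n_redirect = sum(object$data$trial_type == "redirect"),
              n_anticipated = sum(object$data$anticipated))
  class(out) <- "summary.redirection_fit"
  out
}

#' @export
print.summary.redirection_fit <- function(x, ...) {
  cat("Redirection-threshold fit\n")
  cat(sprintf("  kicks: %d (%d redirect, %d anticipated)\n", x$n_trials,
              x$n_redirect, x$n_anticipated))
  cat(sprintf("  threshold: %.1f ms (95%% CI %.1f-%.1f ms)\n",
              x$estimate$estimate_ms, x$estimate$ci_ms[1],
              x$estimate$ci_ms[2]))
  cat(sprintf("  slope: %.4f /ms   lapse: %.3f   anticipation: %.3f\n",
              x$coef["slope"], x$coef["lapse_rate"],
              x$coef["anticipation_rate"]))
  invisible(x)
}

#' Predicted redirection success probability at given lead times
#'
#' Posterior-expected probability of a successful redirection kick at each
#' lead time, i.e. the fitted success curve evaluated at `tau_ms`.
#'
#' @param object A `redirection_fit`.
#' @param tau_ms Lead times in ms.
#' @param conditioning `"raw"` (observable success rate, includes lapse and
#'   anticipation) or `"redirection_component"` (the logistic component F
#'   alone).
#' @param ... Unused.
#' @return Probabilities, same length as `tau_ms`.
#' @export
predict.redirection_fit <- function(object, tau_ms,
                                    conditioning = c("raw",
                                                     "redirection_component"),
                                    ...) {
  curve <- success_curve(object$posterior, tau_ms,
                         conditioning = match.arg(conditioning))
  curve$p_success
}

#' Plot the posterior threshold marginal of a fit
#'
#' @param x A `redirection_fit`.
#' @param ... Passed to [graphics::plot].
#' @export
plot.redirection_fit <- function(x, ...) {
  marg <- theta_marginal(x$posterior)
  graphics::plot(marg$theta_ms, marg$mass, type = "h",
                 xlab = "redirection threshold (ms)",
                 ylab = "posterior mass", ...)
  graphics::abline(v = x$estimate$estimate_ms, lty = 2)
  invisible(x)
}
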
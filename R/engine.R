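#' Discretized grid over psychometric parameters
#'
#' The engine represents a player-side's ability as a probability mass
#' function over a four-dimensional grid: threshold (ms), slope (1/ms,
#' log-spaced), lapse rate and anticipation rate. Defaults cover thresholds
#' 150-700 ms in 5 ms steps, 15 log-spaced slopes in 0.005-0.1 /ms, and 7
#' equispaced values in 0-0.3 for lapse and anticipation.
#'
#' @param theta_ms Strictly increasing threshold axis in ms.
#' @param slope Strictly increasing slope axis in 1/ms.
#' @param lapse Strictly increasing lapse axis in `[0, 1)`.
#' @param anticipation Strictly increasing anticipation axis in `[0, 1)`.
#' @return An object of class `param_grid`.
#' @export
param_grid <- function(theta_ms = seq(150, 700, by = 5),
                       slope = exp(seq(log(0.005), log(0.1),
                                       length.out = 15)),
                       lapse = seq(0, 0.3, length.out = 7),
                       anticipation = seq(0, 0.3, length.out = 7)) {
  axes <- list(theta_ms = theta_ms, slope = slope, lapse = lapse,
               anticipation = anticipation)
  for (nm in names(axes)) {
    ax <- axes[[nm]]
    if (length(ax) < 1 || is.unsorted(ax, strictly = TRUE))
      stop(sprintf("axis '%s' must be strictly increasing", nm))
  }
  if (any(theta_ms <= 0)) stop("threshold axis must be positive")
  if (any(slope <= 0)) stop("slope axis must be positive")
  if (any(lapse < 0 | lapse >= 1)) stop("lapse axis must lie in [0, 1)")
  if (any(anticipation < 0 | anticipation >= 1))
    stop("anticipation axis must lie in [0, 1)")
  nt <- length(theta_ms); ns <- length(slope)
  nl <- length(lapse); na <- length(anticipation)
  n <- nt * ns * nl * na
  # node order: theta fastest, then slope, lapse, anticipation
  # cached full-length parameter vectors make per-trial likelihoods pure
  # vector arithmetic
  g <- structure(list(
    theta_ms = theta_ms, slope = slope, lapse = lapse,
    anticipation = anticipation,
    n_nodes = n, dim = c(nt, ns, nl, na),
    idx_ts = rep.int(seq_len(nt * ns), nl * na),
    lapse_vec = rep(rep(lapse, each = nt * ns), times = na),
    antic_vec = rep(anticipation, each = nt * ns * nl)),
    class = "param_grid")
  # cached products used by every likelihood evaluation
  g$noant_vec <- 1 - g$antic_vec
  g$exec_vec <- g$noant_vec * (1 - g$lapse_vec)
  g
}

#' @export
print.param_grid <- function(x, ...) {
  cat(sprintf(
    "Parameter grid: %d theta x %d slope x %d lapse x %d anticipation = %d nodes\n",
    x$dim[1], x$dim[2], x$dim[3], x$dim[4], x$n_nodes))
  invisible(x)
}

# F(tau) on the theta x slope sub-grid, as an nt x ns matrix.
grid_F <- function(grid, tau_ms) {
  stats::plogis(outer(tau_ms - grid$theta_ms, grid$slope))
}

#' Initialize a grid posterior
#'
#' Returns a normalized prior mass over the grid. The threshold axis is flat
#' (`prior = "uniform"`) or normal (`prior = "normal"`); the default normal
#' parameters are the published elite-player baseline threshold distribution
#' (mean 429.02 ms, SD 53.46 ms), an empirical-Bayes choice. The nuisance
#' axes are flat unless given densities: a log-normal prior over slope
#' (`slope_meanlog`/`slope_sdlog`) and Beta priors over lapse and
#' anticipation rates, which encode that elite players rarely lapse or
#' anticipate and sharpen the threshold marginal considerably at the 20-40
#' kicks available per player-side.
#'
#' @param grid A [param_grid].
#' @param prior `"uniform"` or `"normal"` (over threshold).
#' @param theta_mean,theta_sd Mean and SD (ms) of the normal threshold prior.
#' @param slope_meanlog,slope_sdlog Log-normal prior over slope (flat if
#'   `slope_meanlog` is `NULL`).
#' @param lapse_shape,anticipation_shape Beta shape pairs for the lapse and
#'   anticipation priors (flat if `NULL`).
#' @return An object of class `kick_posterior`: the grid plus a mass vector
#'   summing to 1.
#' @export
init_posterior <- function(grid, prior = c("uniform", "normal"),
                           theta_mean = 429.02, theta_sd = 53.46,
                           slope_meanlog = NULL, slope_sdlog = 0.5,
                           lapse_shape = NULL, anticipation_shape = NULL) {
  stopifnot(inherits(grid, "param_grid"))
  prior <- match.arg(prior)
  nt <- grid$dim[1]; ns <- grid$dim[2]
  nl <- grid$dim[3]; na <- grid$dim[4]
  p_theta <- if (prior == "uniform") rep(1, nt)
             else stats::dnorm(grid$theta_ms, theta_mean, theta_sd)
  p_slope <- if (is.null(slope_meanlog)) rep(1, ns)
             else stats::dlnorm(grid$slope, slope_meanlog, slope_sdlog)
  p_lapse <- if (is.null(lapse_shape)) rep(1, nl)
             else stats::dbeta(grid$lapse, lapse_shape[1], lapse_shape[2])
  p_antic <- if (is.null(anticipation_shape)) rep(1, na)
             else stats::dbeta(grid$anticipation, anticipation_shape[1],
                               anticipation_shape[2])
  mass <- rep.int(rep(p_theta, times = ns), nl * na) *
    rep.int(rep(p_slope, each = nt), nl * na) *
    rep(rep(p_lapse, each = nt * ns), times = na) *
    rep(p_antic, each = nt * ns * nl)
  z <- sum(mass)
  if (!is.finite(z) || z <= 0) stop("prior evaluates to zero everywhere")
  structure(list(grid = grid, mass = mass / z), class = "kick_posterior")
}

#' @export
print.kick_posterior <- function(x, ...) {
  est <- threshold_estimate(x)
  cat(sprintf(
    "Grid posterior over %d nodes; threshold %.1f ms (95%% CI %.1f-%.1f ms)\n",
    x$grid$n_nodes, est$estimate_ms, est$ci_ms[1], est$ci_ms[2]))
  invisible(x)
}

#' Construct one trial's evidence
#'
#' The quadruple the engine consumes after a kick: the trial type, the
#' *realized* dive lead time (as measured, not as commanded), whether the
#' player anticipated, and whether the kick was successful.
#'
#' @param trial_type `"redirect"` or `"no_redirect"`.
#' @param tau_actual_ms Realized dive lead time in ms (>= 0).
#' @param anticipated Logical.
#' @param success Logical. An anticipated kick cannot be successful.
#' @return An object of class `trial_evidence`.
#' @export
trial_evidence <- function(trial_type = c("redirect", "no_redirect"),
                           tau_actual_ms, anticipated, success) {
  trial_type <- match.arg(trial_type)
  stopifnot(is.numeric(tau_actual_ms), tau_actual_ms >= 0,
            is.logical(anticipated), is.logical(success))
  if (anticipated && success)
    stop("an anticipated kick cannot be successful")
  structure(list(trial_type = trial_type, tau_actual_ms = tau_actual_ms,
                 anticipated = anticipated, success = success),
            class = "trial_evidence")
}

#' Likelihood of one trial's evidence at a parameter node
#'
#' The observation model, the exact mirror of the generative simulator in
#' [simulate_kick]. With alpha the anticipation rate, lambda the lapse rate
#' and F the logistic redirection component at the realized lead time:
#' redirection trial — anticipated: alpha; success: (1-alpha)(1-lambda)F;
#' failure without anticipation: (1-alpha)(1 - (1-lambda)F). No-redirection
#' trial — anticipated: alpha; success: (1-alpha)(1-lambda); failure:
#' (1-alpha)lambda. Taking the lapse and anticipation behaviour into account
#' in the likelihood is what keeps the threshold estimate free of
#' anticipation-related bias.
#'
#' @param params A [psychometric_params] node.
#' @param evidence A [trial_evidence].
#' @return A probability.
#' @export
evidence_likelihood <- function(params, evidence) {
  stopifnot(inherits(params, "psychometric_params"),
            inherits(evidence, "trial_evidence"))
  a <- params$anticipation_rate; l <- params$lapse_rate
  if (evidence$anticipated) return(a)
  if (evidence$trial_type == "redirect") {
    f <- logistic_component(evidence$tau_actual_ms, params$threshold_ms,
                            params$slope)
    if (evidence$success) (1 - a) * (1 - l) * f
    else (1 - a) * (1 - (1 - l) * f)
  } else {
    if (evidence$success) (1 - a) * (1 - l) else (1 - a) * l
  }
}

#' Bayesian update of a grid posterior with one trial
#'
#' Multiplies the posterior mass node-wise by the trial likelihood and
#' renormalizes; the input posterior is not modified. Renormalizing after
#' every trial keeps the mass on the unit scale, so long campaigns cannot
#' underflow. An optional forgetting factor `forget` in (0, 1] tempers the
#' current posterior (`mass^forget`, renormalized) before the update —
#' exponential discounting of old evidence, used during training where the
#' player's threshold is drifting; `forget = 1` is the standard static
#' update.
#'
#' @param posterior A `kick_posterior`.
#' @param evidence A [trial_evidence].
#' @param forget Forgetting factor in (0, 1].
#' @return The updated `kick_posterior`.
#' @export
update_posterior <- function(posterior, evidence, forget = 1) {
  stopifnot(inherits(posterior, "kick_posterior"),
            inherits(evidence, "trial_evidence"),
            forget > 0, forget <= 1)
  mass <- posterior$mass
  if (forget < 1) {
    mass <- mass^forget
    mass <- mass / sum(mass)
  }
  g <- posterior$grid
  Fts <- if (evidence$trial_type == "redirect" && !evidence$anticipated)
    as.numeric(grid_F(g, evidence$tau_actual_ms)) else numeric(1)
  res <- .grid_update_cpp(
    mass, Fts, g$idx_ts, g$exec_vec, g$noant_vec, g$antic_vec,
    if (evidence$trial_type == "redirect") 0L else 1L,
    if (evidence$anticipated) 0L else if (evidence$success) 1L else 2L,
    g$dim[1])
  # the kernel accumulates the threshold marginal in the same pass; keep it
  # as a cache (invalidated by anything that replaces the mass vector)
  posterior$theta_marg <- attr(res, "theta_marg")
  attr(res, "theta_marg") <- NULL
  posterior$mass <- res
  posterior
}

#' Marginal posterior over the threshold axis
#'
#' Sums the posterior mass over the slope, lapse and anticipation axes.
#'
#' @param posterior A `kick_posterior`.
#' @return Object of class `theta_marginal`: list with `theta_ms` axis and
#'   `mass` summing to 1.
#' @export
theta_marginal <- function(posterior) {
  stopifnot(inherits(posterior, "kick_posterior"))
  m <- posterior$theta_marg
  if (is.null(m)) {
    nt <- posterior$grid$dim[1]
    m <- .rowSums(posterior$mass, nt, length(posterior$mass) / nt)
  }
  structure(list(theta_ms = posterior$grid$theta_ms, mass = m),
            class = "theta_marginal")
}

# Quantile of a discrete marginal. The grid nodes are atoms, so the inverse
# CDF is a step function: the quantile is the first node whose cumulative
# mass reaches q (a point-mass marginal thus has zero-width intervals). When
# q falls exactly on a boundary between two nodes the midpoint is
# interpolated.
marginal_quantile <- function(theta, cum, q) {
  i <- which(cum >= q - 1e-12)[1]
  if (is.na(i)) return(theta[length(theta)])
  if (i < length(theta) && abs(cum[i] - q) < 1e-12)
    return((theta[i] + theta[i + 1L]) / 2)
  theta[i]
}

#' Point estimate and credible interval of the redirection threshold
#'
#' Point estimate is the mean of the threshold marginal; the interval is the
#' central `level` credible interval obtained by inverting the marginal's
#' cumulative mass (grid nodes are atoms, so a point-mass marginal yields a
#' zero-width interval).
#'
#' @param posterior A `kick_posterior` or a `theta_marginal`.
#' @param level Credible level (default 0.95).
#' @return List with `estimate_ms`, `ci_ms` (length 2) and `level`.
#' @export
threshold_estimate <- function(posterior, level = 0.95) {
  marg <- if (inherits(posterior, "theta_marginal")) posterior
          else theta_marginal(posterior)
  stopifnot(level > 0, level < 1)
  cum <- cumsum(marg$mass)
  a <- (1 - level) / 2
  list(estimate_ms = sum(marg$theta_ms * marg$mass),
       ci_ms = c(marginal_quantile(marg$theta_ms, cum, a),
                 marginal_quantile(marg$theta_ms, cum, 1 - a)),
       level = level)
}

# Expected post-update entropy of the threshold marginal for each candidate
# lead time, assuming a redirection trial. Uses the factorization of the
# likelihood over (theta, slope) x lapse x anticipation so each candidate
# costs only O(n_theta * n_slope).
expected_theta_entropy <- function(posterior, candidates) {
  g <- posterior$grid
  .expected_entropy_cpp(posterior$mass, g$theta_ms, g$slope, g$exec_vec,
                        g$noant_vec, g$antic_vec, as.numeric(candidates))
}

#' Select the next commanded dive lead time
#'
#' Adaptive stimulus placement over a candidate grid of lead times. The
#' `"entropy"` policy (estimation) picks the candidate minimizing the
#' expected post-update Shannon entropy of the threshold marginal, the
#' expectation running over the posterior-predictive outcome probabilities
#' (anticipated / success / failure) of a redirection trial at that lead
#' time. The `"challenge"` policy (training) picks the candidate closest to
#' the current threshold-marginal median — about 50% conditional success, the
#' optimal challenge zone — with a uniform jitter of plus/minus one candidate
#' step to avoid lock-in. Ties break toward the smaller (harder) lead time.
#'
#' @param posterior A `kick_posterior`.
#' @param candidates Increasing vector of candidate lead times in ms
#'   (default 150-650 ms in 10 ms steps).
#' @param policy `"entropy"` or `"challenge"`.
#' @param jitter Logical; apply the one-step jitter of the challenge policy.
#' @return The selected lead time in ms.
#' @export
select_next_tau <- function(posterior, candidates = seq(150, 650, by = 10),
                            policy = c("entropy", "challenge"),
                            jitter = TRUE) {
  stopifnot(inherits(posterior, "kick_posterior"))
  policy <- match.arg(policy)
  if (!length(candidates)) stop("'candidates' must be non-empty")
  if (is.unsorted(candidates, strictly = TRUE))
    stop("'candidates' must be strictly increasing")
  th <- posterior$grid$theta_ms
  if (candidates[1] < th[1] || candidates[length(candidates)] > th[length(th)])
    stop("'candidates' must lie within the threshold axis range")
  if (policy == "entropy") {
    eh <- expected_theta_entropy(posterior, candidates)
    return(candidates[which.min(eh)])   # first minimum = smallest tau
  }
  challenge_tau(theta_marginal(posterior), candidates, jitter)
}

# Challenge-policy selection from a precomputed threshold marginal.
challenge_tau <- function(marg, candidates, jitter) {
  med <- marginal_quantile(marg$theta_ms, cumsum(marg$mass), 0.5)
  i <- which.min(abs(candidates - med))
  if (jitter) i <- i + sample.int(3L, 1L) - 2L
  candidates[min(max(i, 1L), length(candidates))]
}

#' Serialize a posterior summary to JSON
#'
#' Writes the threshold axis, threshold marginal, point estimate and 95%
#' credible interval of a grid posterior as JSON; `read_posterior_summary`
#' restores the summary as a list.
#'
#' @param posterior A `kick_posterior`.
#' @param path File path.
#' @return `write_posterior_summary` returns `path` invisibly;
#'   `read_posterior_summary` the summary list.
#' @export
write_posterior_summary <- function(posterior, path) {
  stopifnot(inherits(posterior, "kick_posterior"))
  marg <- theta_marginal(posterior)
  est <- threshold_estimate(marg)
  payload <- list(schema = "redirkick-posterior/1",
                  theta_axis_ms = marg$theta_ms,
                  theta_marginal = marg$mass,
                  estimate_ms = est$estimate_ms,
                  ci_ms = est$ci_ms, level = est$level)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_posterior_summary
#' @export
read_posterior_summary <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(payload$schema) || payload$schema != "redirkick-posterior/1")
    stop("not a recognized posterior summary file")
  payload
}
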
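#' Psychometric parameters of a penalty taker on one redirection side
#'
#' Bundles the latent ability of a (player, redirection side) pair. The
#' redirection-specific success component is a logistic function of the
#' goalkeeper-dive lead time tau (ms before foot-ball contact),
#' \deqn{F(\tau) = 1 / (1 + \exp(-slope \cdot (\tau - \theta))),}
#' so `threshold_ms` is the 50% redirection threshold: the lead time at which
#' the player redirects successfully half the time, once lapses and
#' anticipation are factored out. `lapse_rate` is the probability of failing a
#' kick for reasons unrelated to redirection timing (e.g. missing the target);
#' `anticipation_rate` is the probability of committing to a side before the
#' dive, which always voids the kick.
#'
#' @param threshold_ms 50% redirection threshold in ms (> 0).
#' @param slope Steepness of the psychometric function in 1/ms (> 0).
#' @param lapse_rate Lapse probability in `[0, 1)`.
#' @param anticipation_rate Anticipation probability in `[0, 1)`.
#' @return An object of class `psychometric_params`.
#' @examples
#' p <- psychometric_params(429, 0.02, 0.1, 0.1)
#' success_probability(p, 429)
#' @export
psychometric_params <- function(threshold_ms, slope, lapse_rate = 0,
                                anticipation_rate = 0) {
  stopifnot(is.numeric(threshold_ms), length(threshold_ms) == 1L,
            is.numeric(slope), length(slope) == 1L)
  if (threshold_ms <= 0) stop("'threshold_ms' must be positive")
  if (slope <= 0) stop("'slope' must be positive")
  if (lapse_rate < 0 || lapse_rate >= 1)
    stop("'lapse_rate' must lie in [0, 1)")
  if (anticipation_rate < 0 || anticipation_rate >= 1)
    stop("'anticipation_rate' must lie in [0, 1)")
  if (lapse_rate + anticipation_rate >= 1)
    stop("'lapse_rate' + 'anticipation_rate' must be < 1")
  structure(list(threshold_ms = threshold_ms, slope = slope,
                 lapse_rate = lapse_rate,
                 anticipation_rate = anticipation_rate),
            class = "psychometric_params")
}

#' @export
print.psychometric_params <- function(x, ...) {
  cat(sprintf(
    "Psychometric parameters: threshold %.1f ms, slope %.4f /ms, lapse %.3f, anticipation %.3f\n",
    x$threshold_ms, x$slope, x$lapse_rate, x$anticipation_rate))
  invisible(x)
}

# Logistic redirection component F(tau); vectorized over any argument.
logistic_component <- function(tau_ms, threshold_ms, slope) {
  stats::plogis(slope * (tau_ms - threshold_ms))
}

#' Probability of a successful redirection kick
#'
#' Probability that a redirection trial succeeds at dive lead time `tau_ms`:
#' the player must not anticipate, not lapse, and beat the redirection time
#' constraint, giving
#' `(1 - anticipation_rate) * (1 - lapse_rate) * F(tau_ms)`.
#' Strictly increasing in `tau_ms` and bounded above by
#' `(1 - anticipation_rate) * (1 - lapse_rate)`.
#'
#' @param params A [psychometric_params] object.
#' @param tau_ms Dive lead time(s) in ms before foot-ball contact (>= 0).
#' @return Success probabilities, same length as `tau_ms`.
#' @export
success_probability <- function(params, tau_ms) {
  stopifnot(inherits(params, "psychometric_params"), is.numeric(tau_ms))
  if (any(tau_ms < 0)) stop("'tau_ms' must be non-negative")
  (1 - params$anticipation_rate) * (1 - params$lapse_rate) *
    logistic_component(tau_ms, params$threshold_ms, params$slope)
}

#' Simulate kick outcomes
#'
#' Draws one or more kick outcomes from the generative observer model. The
#' player first anticipates with probability `anticipation_rate`; an
#' anticipated kick is never successful (on a no-redirection trial the player
#' pre-committed to a side and is ruled to have anticipated). A
#' non-anticipated redirection kick succeeds with probability
#' `(1 - lapse_rate) * F(tau_ms)`; a non-anticipated no-redirection kick
#' succeeds with probability `1 - lapse_rate`.
#'
#' @param player A [synthetic_player] (with `side`) or a
#'   [psychometric_params] object (then `side` is ignored).
#' @param side Redirection side, `"left"` or `"right"` (only used when
#'   `player` is a `synthetic_player`).
#' @param trial_type `"redirect"` or `"no_redirect"`.
#' @param tau_ms Realized dive lead time in ms (>= 0).
#' @param n Number of independent outcomes to draw.
#' @return A data frame with logical columns `anticipated` and `success`,
#'   `n` rows. Deterministic given the R random-number stream.
#' @export
simulate_kick <- function(player, side = NULL,
                          trial_type = c("redirect", "no_redirect"),
                          tau_ms, n = 1L) {
  trial_type <- match.arg(trial_type)
  params <- if (inherits(player, "psychometric_params")) player
            else player_side_params(player, side)
  stopifnot(is.numeric(tau_ms), length(tau_ms) == 1L, tau_ms >= 0, n >= 1L)
  anticipated <- stats::runif(n) < params$anticipation_rate
  p_exec <- if (trial_type == "redirect") {
    (1 - params$lapse_rate) *
      logistic_component(tau_ms, params$threshold_ms, params$slope)
  } else {
    1 - params$lapse_rate
  }
  success <- !anticipated & (stats::runif(n) < p_exec)
  data.frame(anticipated = anticipated, success = success)
}

#' Exponential learning curve for the redirection threshold
#'
#' Training is modelled as an exponential approach of the threshold from
#' `theta_initial_ms` towards `theta_asymptote_ms` with time constant
#' `rate_kicks`, counted in training kicks:
#' `theta(k) = asymptote + (initial - asymptote) * exp(-k / rate)`.
#'
#' @param theta_initial_ms Baseline threshold in ms.
#' @param theta_asymptote_ms Asymptotic threshold in ms (> 0, <= initial).
#' @param rate_kicks Exponential time constant in kicks (> 0; `Inf` means no
#'   learning).
#' @return An object of class `learning_curve`.
#' @export
learning_curve <- function(theta_initial_ms, theta_asymptote_ms, rate_kicks) {
  if (theta_asymptote_ms <= 0) stop("'theta_asymptote_ms' must be positive")
  if (theta_initial_ms < theta_asymptote_ms)
    stop("'theta_initial_ms' must be >= 'theta_asymptote_ms'")
  if (rate_kicks <= 0) stop("'rate_kicks' must be positive")
  structure(list(theta_initial_ms = theta_initial_ms,
                 theta_asymptote_ms = theta_asymptote_ms,
                 rate_kicks = rate_kicks),
            class = "learning_curve")
}

# Threshold implied by a learning curve after k training kicks.
learning_theta_at <- function(curve, kicks) {
  with(curve, theta_asymptote_ms +
         (theta_initial_ms - theta_asymptote_ms) * exp(-kicks / rate_kicks))
}

#' Solve the learning-curve rate for a target post-training threshold
#'
#' Closed-form inversion of the exponential learning curve: returns the rate
#' (in kicks) such that starting from `theta_initial` the threshold equals
#' `theta_target_after` after `n_training_kicks` kicks, given the asymptote.
#'
#' @param theta_initial Baseline threshold in ms.
#' @param theta_target_after Desired threshold after training, in ms.
#' @param n_training_kicks Number of training kicks (> 0).
#' @param theta_asymptote Asymptotic threshold in ms.
#' @return The rate in kicks.
#' @examples
#' calibrate_learning(429, 309, 200, 300)  # ~75.2 kicks
#' @export
calibrate_learning <- function(theta_initial, theta_target_after,
                               n_training_kicks, theta_asymptote) {
  if (!(theta_asymptote < theta_target_after &&
        theta_target_after < theta_initial))
    stop("need theta_asymptote < theta_target_after < theta_initial")
  stopifnot(n_training_kicks > 0)
  n_training_kicks / log((theta_initial - theta_asymptote) /
                           (theta_target_after - theta_asymptote))
}

#' Construct a synthetic player
#'
#' A synthetic player carries one set of psychometric parameters and one
#' learning curve per redirection side (left/right; with right-footed players
#' a leftward redirection is "crossed", a rightward one "reverse-crossed"),
#' plus a counter of training kicks experienced.
#'
#' @param player_id Label.
#' @param params_per_side Named list (`left`, `right`) of
#'   [psychometric_params].
#' @param learning Named list (`left`, `right`) of [learning_curve].
#' @param footedness `"right"` (default) or `"left"`.
#' @param kicks_trained Non-negative count of training kicks already taken.
#' @return An object of class `synthetic_player`.
#' @export
synthetic_player <- function(player_id, params_per_side, learning,
                             footedness = "right", kicks_trained = 0L) {
  stopifnot(all(c("left", "right") %in% names(params_per_side)),
            all(c("left", "right") %in% names(learning)),
            kicks_trained >= 0)
  for (s in c("left", "right")) {
    stopifnot(inherits(params_per_side[[s]], "psychometric_params"),
              inherits(learning[[s]], "learning_curve"))
  }
  footedness <- match.arg(footedness, c("right", "left"))
  structure(list(player_id = player_id, params_per_side = params_per_side,
                 learning = learning, footedness = footedness,
                 kicks_trained = as.integer(kicks_trained)),
            class = "synthetic_player")
}

player_side_params <- function(player, side) {
  stopifnot(inherits(player, "synthetic_player"))
  side <- match.arg(side, c("left", "right"))
  player$params_per_side[[side]]
}

#' Crossed / reverse-crossed label of a redirection side
#'
#' Redirecting toward the side opposite the kicking foot is "crossed";
#' toward the kicking-foot side is "reverse_crossed".
#'
#' @param side Redirection side, `"left"` or `"right"`.
#' @param footedness `"right"` or `"left"`.
#' @return `"crossed"` or `"reverse_crossed"`.
#' @export
redirection_type <- function(side, footedness = "right") {
  side <- match.arg(side, c("left", "right"))
  footedness <- match.arg(footedness, c("right", "left"))
  if (side == footedness) "reverse_crossed" else "crossed"
}

#' Advance a player's learning state
#'
#' Adds `n_kicks` training kicks and moves each side's threshold along its
#' exponential learning curve. Thresholds never increase; all other
#' psychometric parameters are left unchanged.
#'
#' @param player A [synthetic_player].
#' @param n_kicks Number of additional training kicks (>= 0).
#' @return The updated `synthetic_player`.
#' @export
advance_learning <- function(player, n_kicks) {
  stopifnot(inherits(player, "synthetic_player"), n_kicks >= 0)
  k <- player$kicks_trained + n_kicks
  for (s in c("left", "right")) {
    player$params_per_side[[s]]$threshold_ms <-
      learning_theta_at(player$learning[[s]], k)
  }
  player$kicks_trained <- as.integer(k)
  player
}

# Truncated-normal draws by inverse CDF.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  p_lo <- stats::pnorm(lower, mean, sd)
  p_hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(p_lo + stats::runif(n) * (p_hi - p_lo), mean, sd)
}

#' Default cohort distribution settings
#'
#' Distributional settings used by [sample_cohort]. Baseline 50% thresholds
#' follow a normal distribution with mean 429.02 ms and SD 53.46 ms truncated
#' to \[319, 536\] ms, the group statistics of the elite-player study cohort.
#' Side thresholds scatter around the player mean with SD `side_sd_ms`
#' (default 20 ms; no systematic side difference). Lapse and anticipation
#' rates are Beta-distributed with small means. Learning is calibrated per
#' side so the expected post-training group mean is `target_post_mean_ms`
#' after `n_training_kicks_ref` kicks: each side's target reduction is
#' `baseline_mean_ms - target_post_mean_ms` and its asymptote sits
#' `max_drop_ms` below the side's baseline.
#'
#' @param baseline_mean_ms,baseline_sd_ms,baseline_range_ms Truncated-normal
#'   parameters of the baseline threshold (ms).
#' @param side_sd_ms Between-side SD around the player mean (ms).
#' @param slope_meanlog,slope_sdlog Log-normal parameters of the psychometric
#'   slope (1/ms).
#' @param lapse_shape,anticipation_shape Beta shape pairs for lapse and
#'   anticipation rates.
#' @param target_post_mean_ms Expected group-mean threshold after training.
#' @param n_training_kicks_ref Training kicks over which the target is
#'   reached (10 sessions x 20 kicks).
#' @param max_drop_ms Distance from baseline to the learning asymptote (ms).
#' @param footedness Footedness assigned to every synthetic player.
#' @return A list of settings for [sample_cohort].
#' @export
cohort_config <- function(baseline_mean_ms = 429.02, baseline_sd_ms = 53.46,
                          baseline_range_ms = c(319, 536), side_sd_ms = 20,
                          slope_meanlog = log(0.02), slope_sdlog = 0.25,
                          lapse_shape = c(2, 18),
                          anticipation_shape = c(2, 18),
                          target_post_mean_ms = 309.08,
                          n_training_kicks_ref = 200, max_drop_ms = 129,
                          footedness = "right") {
  stopifnot(baseline_sd_ms > 0, length(baseline_range_ms) == 2L,
            baseline_range_ms[1] < baseline_range_ms[2],
            side_sd_ms >= 0, all(lapse_shape > 0),
            all(anticipation_shape > 0),
            target_post_mean_ms < baseline_mean_ms,
            max_drop_ms > baseline_mean_ms - target_post_mean_ms)
  as.list(environment())
}

#' Sample a synthetic cohort of penalty takers
#'
#' Draws `n_players` players with per-side psychometric parameters and
#' calibrated learning curves from the distributions in `config`
#' (see [cohort_config]). Per-side baseline thresholds are clamped to the
#' truncation range so every baseline threshold lies within it.
#'
#' @param n_players Number of players (>= 1).
#' @param config Settings from [cohort_config].
#' @param seed Optional integer seed for reproducibility.
#' @return A list of [synthetic_player] objects.
#' @export
sample_cohort <- function(n_players, config = cohort_config(), seed = NULL) {
  stopifnot(n_players >= 1)
  if (!is.null(seed)) set.seed(seed)
  lo <- config$baseline_range_ms[1]; hi <- config$baseline_range_ms[2]
  player_mean <- rtruncnorm(n_players, config$baseline_mean_ms,
                            config$baseline_sd_ms, lo, hi)
  reduction <- config$baseline_mean_ms - config$target_post_mean_ms
  lapply(seq_len(n_players), function(i) {
    params <- list(); learn <- list()
    for (s in c("left", "right")) {
      th <- player_mean[i] + stats::rnorm(1, 0, config$side_sd_ms)
      th <- min(max(th, lo), hi)
      params[[s]] <- psychometric_params(
        threshold_ms = th,
        slope = stats::rlnorm(1, config$slope_meanlog, config$slope_sdlog),
        lapse_rate = stats::rbeta(1, config$lapse_shape[1],
                                  config$lapse_shape[2]),
        anticipation_rate = stats::rbeta(1, config$anticipation_shape[1],
                                         config$anticipation_shape[2]))
      rate <- calibrate_learning(th, th - reduction,
                                 config$n_training_kicks_ref,
                                 th - config$max_drop_ms)
      learn[[s]] <- learning_curve(th, th - config$max_drop_ms, rate)
    }
    synthetic_player(player_id = sprintf("P%02d", i),
                     params_per_side = params, learning = learn,
                     footedness = config$footedness)
  })
}
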
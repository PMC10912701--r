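#' Campaign configuration
#'
#' Assembles the full configuration of a simulated training campaign,
#' mirroring the study design: 2 baseline sessions to estimate baseline
#' performance, then 10 training sessions, each of 20 kicks of which 12
#' randomly placed kicks require redirection, with the initial target side
#' fixed within a session and alternating across sessions.
#'
#' @param n_players Number of players (default 13).
#' @param n_baseline_sessions,n_training_sessions Session counts (2 and 10).
#' @param kicks_per_session Kicks per session (20).
#' @param n_redirect_per_session Redirection kicks per session (12).
#' @param seed Integer seed driving the whole campaign.
#' @param cohort Cohort settings, see [cohort_config].
#' @param kinematics List: `sampling_hz`, `nominal_speed_mps`, `accel_mps2`,
#'   `speed_cv`, `position_noise_sd_m`, `start_radius_range_m`,
#'   `bin_width_m`, `window_traces` (sliding window of run-ups the
#'   time/radius map is refit from).
#' @param engine List: `grid` (a [param_grid]); prior specification
#'   (`prior`, `theta_mean`, `theta_sd`, `slope_meanlog`, `slope_sdlog`,
#'   `lapse_shape`, `anticipation_shape`, see [init_posterior] — the default
#'   is the empirical-Bayes prior built from the published cohort
#'   statistics); `candidate_tau_ms`,
#'   `baseline_policy`, `training_policy`, `jitter`, `session_forget`
#'   (tempering exponent applied to the session side's posterior at the
#'   start of each training session; the default 0.36, i.e. 0.95 per kick
#'   compounded over a 20-kick session, gives the posterior a roughly
#'   two-session effective memory so it can track the improving threshold
#'   instead of averaging over the whole learning transient; 1 disables
#'   forgetting).
#' @return An object of class `campaign_config`.
#' @export
campaign_config <- function(n_players = 13, n_baseline_sessions = 2,
                            n_training_sessions = 10, kicks_per_session = 20,
                            n_redirect_per_session = 12, seed = 1,
                            cohort = cohort_config(),
                            kinematics = list(), engine = list()) {
  stopifnot(n_players >= 1, n_baseline_sessions >= 1,
            n_training_sessions >= 0, kicks_per_session >= 1,
            n_redirect_per_session >= 0,
            n_redirect_per_session <= kicks_per_session,
            is.numeric(seed), length(seed) == 1L)
  kin_def <- list(sampling_hz = 60, nominal_speed_mps = 4, accel_mps2 = 4,
                  speed_cv = 0.05, position_noise_sd_m = 0.02,
                  start_radius_range_m = c(2.2, 2.8), bin_width_m = 0.05,
                  window_traces = 10)
  eng_def <- list(grid = param_grid(), prior = "normal",
                  theta_mean = 429.02, theta_sd = 53.46,
                  slope_meanlog = log(0.02), slope_sdlog = 0.5,
                  lapse_shape = c(2, 18), anticipation_shape = c(2, 18),
                  candidate_tau_ms = seq(150, 650, by = 10),
                  baseline_policy = "entropy", training_policy = "challenge",
                  jitter = TRUE, session_forget = 0.36)
  kin_def[names(kinematics)] <- kinematics
  eng_def[names(engine)] <- engine
  structure(list(n_players = n_players,
                 n_baseline_sessions = n_baseline_sessions,
                 n_training_sessions = n_training_sessions,
                 kicks_per_session = kicks_per_session,
                 n_redirect_per_session = n_redirect_per_session,
                 seed = as.integer(seed), cohort = cohort,
                 kinematics = kin_def, engine = eng_def),
            class = "campaign_config")
}

#' Read a campaign configuration from JSON or YAML
#'
#' Reads a (possibly partial) configuration file and merges it over the
#' defaults of [campaign_config]. Recognized top-level keys are the arguments
#' of [campaign_config]; `cohort`, `kinematics` and `engine` blocks may be
#' partial. The engine grid may be given as axis vectors under
#' `engine$grid` (`theta_ms`, `slope`, `lapse`, `anticipation`).
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A `campaign_config`.
#' @export
read_campaign_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  args <- raw[intersect(names(raw),
                        setdiff(names(formals(campaign_config)),
                                c("cohort", "kinematics", "engine")))]
  if (!is.null(raw$cohort))
    args$cohort <- do.call(cohort_config, as.list(raw$cohort))
  for (blk in c("kinematics", "engine"))
    if (!is.null(raw[[blk]])) args[[blk]] <- as.list(raw[[blk]])
  if (!is.null(args$engine$grid) && !inherits(args$engine$grid, "param_grid"))
    args$engine$grid <- do.call(param_grid, as.list(args$engine$grid))
  do.call(campaign_config, args)
}

#' Plan one session's trial sequence
#'
#' A session is `kicks_per_session` kicks at one fixed target side;
#' `n_redirect_per_session` of them (a uniformly random subset) require
#' redirection. The phase (baseline/training) is derived from the session
#' index.
#'
#' @param config A [campaign_config].
#' @param session_index 1-based session index.
#' @param target_side `"left"` or `"right"`.
#' @return Object of class `session_plan`: `session_index`, `phase`,
#'   `target_side`, `trial_sequence` (character vector of
#'   `"redirect"`/`"no_redirect"`).
#' @export
plan_session <- function(config, session_index, target_side) {
  stopifnot(inherits(config, "campaign_config"), session_index >= 1)
  target_side <- match.arg(target_side, c("left", "right"))
  n <- config$kicks_per_session
  seq_types <- c(rep("redirect", config$n_redirect_per_session),
                 rep("no_redirect", n - config$n_redirect_per_session))
  structure(list(
    session_index = as.integer(session_index),
    phase = if (session_index <= config$n_baseline_sessions) "baseline"
            else "training",
    target_side = target_side,
    trial_sequence = sample(seq_types)),
    class = "session_plan")
}

#' Assign target sides to sessions
#'
#' Default scheme: strict alternation starting from a random side, so the two
#' redirection sides receive equal numbers of sessions and each side is
#' covered during baseline.
#'
#' @param n_sessions Number of sessions (>= 1).
#' @return Character vector of `"left"`/`"right"` target sides.
#' @export
assign_sides <- function(n_sessions) {
  stopifnot(n_sessions >= 1)
  first <- sample(c("left", "right"), 1)
  sides <- rep(c(first, setdiff(c("left", "right"), first)),
               length.out = n_sessions)
  sides
}

opposite_side <- function(side) ifelse(side == "left", "right", "left")

#' Run a full simulated training campaign
#'
#' For every player and session, runs the full per-trial loop: the engine
#' selects the commanded dive lead time (entropy policy during baseline,
#' challenge policy during training), a run-up is generated, the goalkeeper
#' dive is triggered through the current time/radius map (cold-started from
#' the nominal run-up speed and refit after every trial from a sliding
#' window of recent run-ups), the kick outcome is simulated from the
#' player's current latent parameters at the *realized* lead time, the side's
#' posterior is updated with that realized evidence, and — during training —
#' the player's learning advances by one kick. All kicks of a session update
#' the posterior of that session's redirection side (the side opposite the
#' target). At the start of each training session the session side's
#' posterior is tempered by `engine$session_forget` — exponential
#' forgetting that lets the estimate track the improving threshold instead
#' of averaging over the whole learning transient.
#' Posterior snapshots are stored per player-side at the end of
#' baseline and at the end of training. The whole campaign is reproducible
#' from `config$seed`.
#'
#' @param cohort List of [synthetic_player]s, or `NULL` to sample one from
#'   `config$cohort`.
#' @param config A [campaign_config].
#' @return Object of class `campaign_result`: `log` (one row per kick, see
#'   [write_log] for columns), `snapshots` (per player, per side, `baseline`
#'   and `post` threshold marginals with estimates), `cohort`, `config`.
#' @export
run_campaign <- function(cohort = NULL, config = campaign_config()) {
  stopifnot(inherits(config, "campaign_config"))
  set.seed(config$seed)
  if (is.null(cohort)) cohort <- sample_cohort(config$n_players, config$cohort)
  n_sessions <- config$n_baseline_sessions + config$n_training_sessions
  kin <- config$kinematics
  eng <- config$engine
  n_rows <- length(cohort) * n_sessions * config$kicks_per_session
  L <- list(
    player_id = character(n_rows), session_index = integer(n_rows),
    trial_index = integer(n_rows), phase = character(n_rows),
    target_side = character(n_rows), redirection_side = character(n_rows),
    redirection_type = character(n_rows), trial_type = character(n_rows),
    tau_commanded_ms = numeric(n_rows), tau_actual_ms = numeric(n_rows),
    anticipated = logical(n_rows), success = logical(n_rows),
    posterior_theta_mean_after = numeric(n_rows))
  snapshots <- list()
  row <- 0L
  prior0 <- init_posterior(
    eng$grid, prior = eng$prior, theta_mean = eng$theta_mean,
    theta_sd = eng$theta_sd, slope_meanlog = eng$slope_meanlog,
    slope_sdlog = eng$slope_sdlog, lapse_shape = eng$lapse_shape,
    anticipation_shape = eng$anticipation_shape)
  marg0 <- theta_marginal(prior0)
  for (player in cohort) {
    posteriors <- list(left = prior0, right = prior0)
    margs <- list(left = marg0, right = marg0)
    traces <- list()
    map <- linear_radius_time_map(
      kin$nominal_speed_mps, max_radius_m = kin$start_radius_range_m[2],
      bin_width_m = kin$bin_width_m)
    sides <- assign_sides(n_sessions)
    snap <- list(left = list(), right = list())
    for (s in seq_len(n_sessions)) {
      plan <- plan_session(config, s, sides[s])
      redir_side <- opposite_side(plan$target_side)
      training <- plan$phase == "training"
      policy <- if (training) eng$training_policy else eng$baseline_policy
      if (training && eng$session_forget < 1) {
        tempered <- posteriors[[redir_side]]$mass^eng$session_forget
        posteriors[[redir_side]]$mass <- tempered / sum(tempered)
        margs[[redir_side]] <- theta_marginal(posteriors[[redir_side]])
      }
      for (k in seq_along(plan$trial_sequence)) {
        type <- plan$trial_sequence[k]
        tau_cmd <- if (policy == "challenge") {
          challenge_tau(margs[[redir_side]], eng$candidate_tau_ms,
                        eng$jitter)
        } else {
          select_next_tau(posteriors[[redir_side]],
                          candidates = eng$candidate_tau_ms,
                          policy = policy, jitter = eng$jitter)
        }
        trace <- generate_runup(
          start_radius_m = stats::runif(1, kin$start_radius_range_m[1],
                                        kin$start_radius_range_m[2]),
          speed_mps = kin$nominal_speed_mps, accel_mps2 = kin$accel_mps2,
          speed_cv = kin$speed_cv, noise_sd_m = kin$position_noise_sd_m,
          sampling_hz = kin$sampling_hz)
        trig <- simulate_dive_trigger(trace, map,
                                      clamp_tau_to_map(map, tau_cmd))
        tau_act <- if (trig$triggered) trig$tau_actual_ms else 0
        out <- simulate_kick(player, redir_side, type, tau_act)
        ev <- trial_evidence(type, tau_act, out$anticipated, out$success)
        posteriors[[redir_side]] <-
          update_posterior(posteriors[[redir_side]], ev)
        margs[[redir_side]] <- theta_marginal(posteriors[[redir_side]])
        if (training) player <- advance_learning(player, 1)
        traces <- c(traces, list(trace))
        if (length(traces) > kin$window_traces)
          traces <- traces[-1]
        map <- fit_radius_time_map(traces, bin_width_m = kin$bin_width_m)
        row <- row + 1L
        L$player_id[row] <- player$player_id
        L$session_index[row] <- s
        L$trial_index[row] <- k
        L$phase[row] <- plan$phase
        L$target_side[row] <- plan$target_side
        L$redirection_side[row] <- redir_side
        L$redirection_type[row] <- redirection_type(redir_side,
                                                    player$footedness)
        L$trial_type[row] <- type
        L$tau_commanded_ms[row] <- tau_cmd
        L$tau_actual_ms[row] <- tau_act
        L$anticipated[row] <- out$anticipated
        L$success[row] <- out$success
        L$posterior_theta_mean_after[row] <-
          sum(margs[[redir_side]]$theta_ms * margs[[redir_side]]$mass)
      }
      if (s == config$n_baseline_sessions) {
        for (sd_ in c("left", "right"))
          snap[[sd_]]$baseline <- snapshot_of(posteriors[[sd_]])
      }
      if (s == n_sessions) {
        for (sd_ in c("left", "right"))
          snap[[sd_]]$post <- snapshot_of(posteriors[[sd_]])
      }
    }
    snap$footedness <- player$footedness
    snapshots[[player$player_id]] <- snap
  }
  log <- as.data.frame(L, stringsAsFactors = FALSE)
  structure(list(log = log, snapshots = snapshots, cohort = cohort,
                 config = config),
            class = "campaign_result")
}

snapshot_of <- function(posterior) {
  marg <- theta_marginal(posterior)
  list(marginal = marg, estimate = threshold_estimate(marg),
       posterior = posterior)
}

#' @export
print.campaign_result <- function(x, ...) {
  cat(sprintf("Simulated campaign: %d players, %d kicks logged\n",
              length(x$cohort), nrow(x$log)))
  invisible(x)
}

log_columns <- c("player_id", "session_index", "trial_index", "phase",
                 "target_side", "redirection_side", "redirection_type",
                 "trial_type", "tau_commanded_ms", "tau_actual_ms",
                 "anticipated", "success", "posterior_theta_mean_after")

#' Write / read a campaign trial log
#'
#' Tidy CSV with a fixed column order (`player_id`, `session_index`,
#' `trial_index`, `phase`, `target_side`, `redirection_side`,
#' `redirection_type`, `trial_type`, `tau_commanded_ms`, `tau_actual_ms`,
#' `anticipated`, `success`, `posterior_theta_mean_after`). Floats are
#' serialized at full (17 significant digits) precision so
#' `read_log(write_log(x))` is the identity.
#'
#' @param records Data frame of trial records (a `campaign_result$log`).
#' @param path File path.
#' @return `write_log` returns `path` invisibly; `read_log` returns the
#'   records.
#' @export
write_log <- function(records, path) {
  missing_cols <- setdiff(log_columns, names(records))
  if (length(missing_cols))
    stop("records are missing column(s): ",
         paste(missing_cols, collapse = ", "))
  out <- records[, log_columns, drop = FALSE]
  for (nm in c("tau_commanded_ms", "tau_actual_ms",
               "posterior_theta_mean_after"))
    out[[nm]] <- sprintf("%.17g", out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_log
#' @export
read_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(log_columns, names(df))
  if (length(missing_cols))
    stop("log file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- df[, log_columns, drop = FALSE]
  for (nm in c("anticipated", "success"))
    df[[nm]] <- as.logical(df[[nm]])
  num_cols <- c("session_index", "trial_index", "tau_commanded_ms",
                "tau_actual_ms", "posterior_theta_mean_after")
  for (nm in num_cols) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    bad <- which(is.na(v) & !is.na(df[[nm]]))
    if (length(bad))
      stop(sprintf("malformed value in column '%s' at line %d", nm,
                   bad[1] + 1L))   # +1 for the header line
    df[[nm]] <- v
  }
  bad <- which(is.na(df$anticipated) | is.na(df$success))
  if (length(bad))
    stop(sprintf("malformed logical value at line %d", bad[1] + 1L))
  df$session_index <- as.integer(df$session_index)
  df$trial_index <- as.integer(df$trial_index)
  df
}
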
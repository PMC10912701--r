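#' Posterior distribution of the threshold improvement
#'
#' Distribution of the threshold difference Delta = theta_baseline -
#' theta_post from two threshold marginals on the same axis, computed by
#' discrete cross-correlation under independence of the two posteriors (they
#' come from disjoint trial sets). `prob_improvement` is the total mass
#' strictly above 0 ("lower after training"); `prob_improvement_gt_sd` is the
#' mass above one standard deviation of the Delta distribution itself.
#'
#' @param marg_baseline,marg_post `theta_marginal` objects (see
#'   [theta_marginal]) on identical axes.
#' @param sd_reference `"delta"` (default: SD of the Delta distribution) or
#'   `"baseline"` (SD of the baseline marginal) as the "one standard
#'   deviation" reference.
#' @return Object of class `improvement_distribution`: `delta_axis_ms`,
#'   `mass`, `prob_improvement`, `prob_improvement_gt_sd`, `mean_ms`,
#'   `sd_ms`.
#' @export
improvement_distribution <- function(marg_baseline, marg_post,
                                     sd_reference = c("delta", "baseline")) {
  stopifnot(inherits(marg_baseline, "theta_marginal"),
            inherits(marg_post, "theta_marginal"))
  sd_reference <- match.arg(sd_reference)
  th <- marg_baseline$theta_ms
  if (length(th) != length(marg_post$theta_ms) ||
      any(abs(th - marg_post$theta_ms) > 1e-9))
    stop("the two marginals must share one threshold axis")
  # joint over (baseline node i, post node j); Delta = theta_i - theta_j
  joint <- outer(marg_baseline$mass, marg_post$mass)
  d <- round(outer(th, th, "-"), 9)
  grp <- factor(as.numeric(d))
  mass <- as.numeric(tapply(as.numeric(joint), grp, sum))
  delta <- as.numeric(levels(grp))
  mean_ms <- sum(delta * mass)
  sd_ms <- sqrt(max(0, sum(delta^2 * mass) - mean_ms^2))
  sd_ref <- if (sd_reference == "delta") sd_ms else {
    mb <- sum(th * marg_baseline$mass)
    sqrt(max(0, sum(th^2 * marg_baseline$mass) - mb^2))
  }
  structure(list(delta_axis_ms = delta, mass = mass,
                 prob_improvement = sum(mass[delta > 0]),
                 prob_improvement_gt_sd = sum(mass[delta > sd_ref]),
                 mean_ms = mean_ms, sd_ms = sd_ms),
            class = "improvement_distribution")
}

#' @export
print.improvement_distribution <- function(x, ...) {
  cat(sprintf(
    "Threshold improvement: mean %.1f ms (SD %.1f); P(improvement) = %.3f, P(> 1 SD) = %.3f\n",
    x$mean_ms, x$sd_ms, x$prob_improvement, x$prob_improvement_gt_sd))
  invisible(x)
}

#' Plot an improvement distribution
#'
#' Threshold-difference density with the positive (improvement) area shaded.
#'
#' @param x An `improvement_distribution`.
#' @param ... Passed to [graphics::plot].
#' @export
plot.improvement_distribution <- function(x, ...) {
  graphics::plot(x$delta_axis_ms, x$mass, type = "l",
                 xlab = "threshold reduction (ms)",
                 ylab = "probability mass", ...)
  pos <- x$delta_axis_ms > 0
  if (any(pos))
    graphics::polygon(c(x$delta_axis_ms[pos], rev(x$delta_axis_ms[pos])),
                      c(x$mass[pos], rep(0, sum(pos))),
                      col = grDevices::adjustcolor("forestgreen", 0.4),
                      border = NA)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

#' Posterior-expected success curve
#'
#' Estimated probability of successfully redirecting the kick as a function
#' of the goalkeeper-dive lead time, averaged over the posterior. `"raw"`
#' (default) gives the observable success rate
#' `(1 - alpha)(1 - lambda) F(tau)`; `"redirection_component"` gives the
#' lapse/anticipation-corrected component `F(tau)` alone.
#'
#' @param posterior A `kick_posterior`.
#' @param tau_axis_ms Lead times in ms at which to evaluate the curve.
#' @param conditioning `"raw"` or `"redirection_component"`.
#' @return Object of class `success_curve`: `tau_axis_ms`, `p_success`.
#' @export
success_curve <- function(posterior, tau_axis_ms,
                          conditioning = c("raw", "redirection_component")) {
  stopifnot(inherits(posterior, "kick_posterior"),
            is.numeric(tau_axis_ms), all(tau_axis_ms >= 0))
  conditioning <- match.arg(conditioning)
  g <- posterior$grid
  nt <- g$dim[1]; ns <- g$dim[2]
  nts <- nt * ns
  w <- if (conditioning == "raw") {
    posterior$mass * (1 - g$lapse_vec) * (1 - g$antic_vec)
  } else {
    posterior$mass
  }
  Wts <- matrix(.rowSums(w, nts, length(w) / nts), nt, ns)
  p <- vapply(tau_axis_ms, function(tau) sum(grid_F(g, tau) * Wts),
              numeric(1))
  structure(list(tau_axis_ms = tau_axis_ms, p_success = p,
                 conditioning = conditioning),
            class = "success_curve")
}

#' Plot before/after success curves
#'
#' @param x A `success_curve` (baseline).
#' @param after Optional second `success_curve` (post-training).
#' @param ... Passed to [graphics::plot].
#' @export
plot.success_curve <- function(x, after = NULL, ...) {
  graphics::plot(x$tau_axis_ms, x$p_success, type = "l", ylim = c(0, 1),
                 xlab = "dive lead time before contact (ms)",
                 ylab = "P(successful redirection)", ...)
  if (!is.null(after))
    graphics::lines(after$tau_axis_ms, after$p_success, col = "forestgreen")
  invisible(x)
}

#' Success-rate change at a reference lead time
#'
#' Interpolates two success curves at a reference dive lead time (e.g. the
#' group baseline threshold) and reports the before/after success
#' probabilities and their difference in percentage points.
#'
#' @param curve_baseline,curve_post `success_curve` objects.
#' @param tau_ref_ms Reference lead time in ms, within both curves' axes.
#' @return List with `p_before`, `p_after`, `difference_pp`.
#' @export
success_improvement_at <- function(curve_baseline, curve_post, tau_ref_ms) {
  stopifnot(inherits(curve_baseline, "success_curve"),
            inherits(curve_post, "success_curve"))
  interp <- function(curve) {
    rng <- range(curve$tau_axis_ms)
    if (tau_ref_ms < rng[1] || tau_ref_ms > rng[2])
      stop(sprintf("tau_ref %.1f ms outside the curve's axis [%g, %g]",
                   tau_ref_ms, rng[1], rng[2]))
    stats::approx(curve$tau_axis_ms, curve$p_success, xout = tau_ref_ms,
                  ties = "ordered")$y
  }
  p_before <- interp(curve_baseline)
  p_after <- interp(curve_post)
  list(p_before = p_before, p_after = p_after,
       difference_pp = 100 * (p_after - p_before))
}

#' Exact two-tailed binomial test
#'
#' Exact binomial p-value by summation of the binomial probability mass:
#' `min(1, 2 * min(P(X <= k), P(X >= k)))` with `X ~ Binomial(n, p0)`
#' (method `"double"`, the default). Method `"minlike"` instead sums the
#' probabilities of all outcomes no more likely than `k`.
#'
#' @param k Number of successes (0..n).
#' @param n Number of trials.
#' @param p0 Null success probability in (0, 1).
#' @param method `"double"` or `"minlike"`.
#' @return The p-value.
#' @examples
#' binomial_two_tailed(24, 26, 0.5)  # about 1e-5
#' @export
binomial_two_tailed <- function(k, n, p0 = 0.5,
                                method = c("double", "minlike")) {
  stopifnot(k >= 0, k <= n, n >= 1, p0 > 0, p0 < 1)
  method <- match.arg(method)
  if (method == "double") {
    lower <- stats::pbinom(k, n, p0)
    upper <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
    return(min(1, 2 * min(lower, upper)))
  }
  d <- stats::dbinom(0:n, n, p0)
  sum(d[d <= d[k + 1] * (1 + 1e-7)])
}

#' Full campaign analytics report
#'
#' Computes, from a campaign's posterior snapshots, the study's derived
#' quantities. Per player-side: baseline and post-training threshold
#' estimates with credible intervals, the threshold-improvement distribution
#' (mean, SD, probability of improvement, probability of improvement larger
#' than one SD), and success-rate changes at the reference lead times 429 ms
#' (group baseline threshold) and 309 ms (group post-training threshold).
#' Group level: mean thresholds, mean reduction in ms and percent, the count
#' of player-sides with probability of improvement above 0.5, and the exact
#' two-tailed binomial test of that count against chance.
#'
#' @param campaign A `campaign_result` from [run_campaign].
#' @param tau_ref_ms Reference lead times for success-rate changes.
#' @param conditioning Passed to [success_curve].
#' @return Object of class `campaign_report`: list with `per_side` (data
#'   frame) and `group` (list), plus `tau_ref_ms`.
#' @export
campaign_report <- function(campaign, tau_ref_ms = c(429, 309),
                            conditioning = "raw") {
  stopifnot(inherits(campaign, "campaign_result"))
  snaps <- campaign$snapshots
  if (!length(snaps)) stop("campaign has no posterior snapshots")
  tau_axis <- campaign$config$engine$grid$theta_ms
  rows <- list()
  for (pid in names(snaps)) {
    for (side in c("left", "right")) {
      sn <- snaps[[pid]][[side]]
      if (is.null(sn$baseline) || is.null(sn$post))
        stop(sprintf("missing snapshot for player %s side %s", pid, side))
      imp <- improvement_distribution(sn$baseline$marginal,
                                      sn$post$marginal)
      cb <- success_curve(sn$baseline$posterior, tau_axis, conditioning)
      cp <- success_curve(sn$post$posterior, tau_axis, conditioning)
      succ <- lapply(tau_ref_ms, function(tr)
        success_improvement_at(cb, cp, tr))
      row <- data.frame(
        player_id = pid, side = side,
        redirection_type = redirection_type(side, snaps[[pid]]$footedness),
        baseline_ms = sn$baseline$estimate$estimate_ms,
        baseline_ci_lo = sn$baseline$estimate$ci_ms[1],
        baseline_ci_hi = sn$baseline$estimate$ci_ms[2],
        post_ms = sn$post$estimate$estimate_ms,
        post_ci_lo = sn$post$estimate$ci_ms[1],
        post_ci_hi = sn$post$estimate$ci_ms[2],
        delta_mean_ms = imp$mean_ms, delta_sd_ms = imp$sd_ms,
        prob_improvement = imp$prob_improvement,
        prob_improvement_gt_sd = imp$prob_improvement_gt_sd,
        stringsAsFactors = FALSE)
      for (j in seq_along(tau_ref_ms)) {
        row[[sprintf("p_before_at_%d", round(tau_ref_ms[j]))]] <-
          succ[[j]]$p_before
        row[[sprintf("p_after_at_%d", round(tau_ref_ms[j]))]] <-
          succ[[j]]$p_after
        row[[sprintf("improvement_pp_at_%d", round(tau_ref_ms[j]))]] <-
          succ[[j]]$difference_pp
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  per_side <- do.call(rbind, rows)
  n_sides <- nrow(per_side)
  n_improved <- sum(per_side$prob_improvement > 0.5)
  mean_base <- mean(per_side$baseline_ms)
  mean_post <- mean(per_side$post_ms)
  group <- list(
    n_player_sides = n_sides,
    mean_baseline_ms = mean_base,
    mean_post_ms = mean_post,
    mean_reduction_ms = mean_base - mean_post,
    mean_reduction_pct = 100 * (mean_base - mean_post) / mean_base,
    mean_prob_improvement = mean(per_side$prob_improvement),
    n_improved = n_improved,
    binomial_p = binomial_two_tailed(n_improved, n_sides, 0.5))
  structure(list(per_side = per_side, group = group,
                 tau_ref_ms = tau_ref_ms),
            class = "campaign_report")
}

#' @export
print.campaign_report <- function(x, ...) {
  g <- x$group
  cat("Campaign report\n")
  cat(sprintf("  player-sides: %d\n", g$n_player_sides))
  cat(sprintf("  mean threshold: %.1f ms (baseline) -> %.1f ms (post)\n",
              g$mean_baseline_ms, g$mean_post_ms))
  cat(sprintf("  mean reduction: %.1f ms (%.1f%%)\n", g$mean_reduction_ms,
              g$mean_reduction_pct))
  cat(sprintf("  P(improvement) mean: %.2f; improved sides: %d/%d (binomial p = %.3g)\n",
              g$mean_prob_improvement, g$n_improved, g$n_player_sides,
              g$binomial_p))
  invisible(x)
}

#' Write / read a campaign report as JSON
#'
#' Versioned JSON serialization of a [campaign_report]; `read_report`
#' restores the same structure (as plain lists/data frame).
#'
#' @param report A `campaign_report`.
#' @param path File path.
#' @return `write_report` returns `path` invisibly; `read_report` the
#'   report.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "campaign_report"))
  payload <- list(schema = "redirkick-report/1",
                  tau_ref_ms = report$tau_ref_ms,
                  group = report$group, per_side = report$per_side)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(payload$schema) || payload$schema != "redirkick-report/1")
    stop("not a recognized campaign report file")
  structure(list(per_side = payload$per_side, group = payload$group,
                 tau_ref_ms = payload$tau_ref_ms),
            class = "campaign_report")
}
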
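make_marginal <- function(theta, mass) {
  structure(list(theta_ms = theta, mass = mass / sum(mass)),
            class = "theta_marginal")
}

test_that("improvement distribution handles point and symmetric cases", {
  th <- seq(200, 600, by = 1)
  pm <- function(at) make_marginal(th, as.numeric(th == at))
  imp <- improvement_distribution(pm(429), pm(309))
  expect_equal(imp$mean_ms, 120)
  expect_equal(imp$prob_improvement, 1)
  expect_equal(sum(imp$mass), 1, tolerance = 1e-12)

  # identical symmetric marginals: P(improvement) = (1 - P(0)) / 2
  m <- make_marginal(seq(300, 500, 50), c(1, 2, 4, 2, 1))
  imp2 <- improvement_distribution(m, m)
  p0 <- imp2$mass[imp2$delta_axis_ms == 0]
  expect_equal(imp2$prob_improvement, (1 - p0) / 2, tolerance = 1e-12)
  expect_error(improvement_distribution(m, pm(429)), "axis")
})

test_that("improvement distribution equals exhaustive pair enumeration", {
  th <- c(300, 350, 400, 450, 500)
  set.seed(44)
  a <- make_marginal(th, runif(5)); b <- make_marginal(th, runif(5))
  imp <- improvement_distribution(a, b)
  # brute force over all 25 pairs
  deltas <- as.numeric(outer(th, th, "-"))
  probs <- as.numeric(outer(a$mass, b$mass))
  expect_equal(sum(imp$mass), 1, tolerance = 1e-12)
  for (d in unique(deltas)) {
    expect_equal(imp$mass[abs(imp$delta_axis_ms - d) < 1e-9],
                 sum(probs[deltas == d]), tolerance = 1e-12)
  }
  expect_equal(imp$prob_improvement, sum(probs[deltas > 0]),
               tolerance = 1e-12)
  expect_equal(imp$mean_ms, sum(probs * deltas), tolerance = 1e-12)

  # shift invariance of the improvement probability
  a2 <- make_marginal(th + 70, a$mass); b2 <- make_marginal(th + 70, b$mass)
  imp2 <- improvement_distribution(a2, b2)
  expect_equal(imp2$prob_improvement, imp$prob_improvement,
               tolerance = 1e-12)
})

test_that("success curves are monotone posterior mixtures of the logistic", {
  g <- param_grid(theta_ms = c(350, 450), slope = c(0.02), lapse = c(0),
                  anticipation = c(0))
  tau_ax <- seq(200, 600, by = 20)
  point <- function(at) {
    post <- init_posterior(g)
    post$mass <- as.numeric(g$theta_ms == at)
    post
  }
  # point-mass posterior with no lapse/anticipation equals the logistic
  c350 <- success_curve(point(350), tau_ax)
  expect_equal(c350$p_success, plogis(0.02 * (tau_ax - 350)),
               tolerance = 1e-12)
  # mixture linearity
  post_mix <- init_posterior(g)
  post_mix$mass <- as.numeric(g$theta_ms == 350) * 0.3 +
    as.numeric(g$theta_ms == 450) * 0.7
  cm <- success_curve(post_mix, tau_ax)
  c450 <- success_curve(point(450), tau_ax)
  expect_equal(cm$p_success, 0.3 * c350$p_success + 0.7 * c450$p_success,
               tolerance = 1e-12)
  expect_true(all(diff(cm$p_success) >= 0))

  # raw vs redirection-component conditioning
  g2 <- param_grid(theta_ms = 429, slope = 0.02, lapse = 0.1,
                   anticipation = 0.1)
  post2 <- init_posterior(g2)
  raw <- success_curve(post2, 429, "raw")
  comp <- success_curve(post2, 429, "redirection_component")
  expect_equal(raw$p_success, 0.5 * 0.81, tolerance = 1e-12)
  expect_equal(comp$p_success, 0.5, tolerance = 1e-12)
})

test_that("success improvements interpolate the curves", {
  g <- param_grid(theta_ms = c(309, 429), slope = 0.02, lapse = 0,
                  anticipation = 0)
  point <- function(at) {
    post <- init_posterior(g)
    post$mass <- as.numeric(g$theta_ms == at)
    post
  }
  tau_ax <- seq(209, 649, by = 10)   # contains both reference lead times
  cb <- success_curve(point(429), tau_ax)
  cp <- success_curve(point(309), tau_ax)
  res <- success_improvement_at(cb, cp, 429)
  expect_equal(res$p_before, 0.5, tolerance = 1e-12)
  expect_equal(res$p_after, plogis(0.02 * 120), tolerance = 1e-12)
  expect_gt(res$difference_pp, 0)
  # identical curves: zero difference
  expect_equal(success_improvement_at(cb, cb, 400)$difference_pp, 0)
  # on-grid reference equals direct evaluation
  res2 <- success_improvement_at(cb, cp, 349)
  expect_equal(res2$p_before, cb$p_success[cb$tau_axis_ms == 349])
  expect_error(success_improvement_at(cb, cp, 1000), "outside")
})

test_that("exact binomial test matches closed forms and is symmetric", {
  # closed form for 24 of 26 at chance level
  p_exact <- 2 * (choose(26, 24) + choose(26, 25) + choose(26, 26)) / 2^26
  expect_equal(binomial_two_tailed(24, 26, 0.5), p_exact, tolerance = 1e-12)
  expect_equal(binomial_two_tailed(13, 26, 0.5), 1)
  expect_equal(binomial_two_tailed(26, 26, 0.5), 2^-25, tolerance = 1e-9)
  # symmetry at p0 = 1/2
  for (k in 0:10)
    expect_equal(binomial_two_tailed(k, 26, 0.5),
                 binomial_two_tailed(26 - k, 26, 0.5), tolerance = 1e-12)
  # minlike variant agrees with the symmetric doubling here
  expect_equal(binomial_two_tailed(24, 26, 0.5, method = "minlike"),
               p_exact, tolerance = 1e-12)
  expect_error(binomial_two_tailed(30, 26, 0.5), "k")
})

test_that("campaign report aggregates per-side analytics and round-trips", {
  camp <- run_campaign(config = small_campaign_config(seed = 21))
  rep <- campaign_report(camp, tau_ref_ms = c(429, 309))
  expect_equal(nrow(rep$per_side), 4)
  expect_true(all(rep$per_side$prob_improvement >= 0 &
                    rep$per_side$prob_improvement <= 1))
  expect_equal(rep$group$mean_reduction_ms,
               mean(rep$per_side$baseline_ms) - mean(rep$per_side$post_ms),
               tolerance = 1e-9)
  expect_equal(rep$group$binomial_p,
               binomial_two_tailed(rep$group$n_improved, 4, 0.5))

  path <- tempfile(fileext = ".json")
  write_report(rep, path)
  back <- read_report(path)
  expect_equal(back$group$mean_reduction_ms, rep$group$mean_reduction_ms,
               tolerance = 1e-9)
  expect_equal(back$per_side$prob_improvement,
               rep$per_side$prob_improvement, tolerance = 1e-9)
  expect_error(read_report({
    p <- tempfile(fileext = ".json")
    jsonlite::write_json(list(a = 1), p); p
  }), "not a recognized")
})

test_that("plot methods render without error", {
  camp <- run_campaign(config = small_campaign_config(seed = 2))
  sn <- camp$snapshots[[1]]$left
  imp <- improvement_distribution(sn$baseline$marginal, sn$post$marginal)
  curve <- success_curve(sn$post$posterior, seq(250, 600, 25))
  pdf(NULL)
  on.exit(dev.off())
  expect_no_error(plot(imp))
  expect_no_error(plot(curve, after = curve))
})
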
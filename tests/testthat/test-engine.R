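test_that("priors initialize to normalized mass with the right structure", {
  g <- tiny_grid()
  post <- init_posterior(g)
  expect_equal(sum(post$mass), 1, tolerance = 1e-12)
  expect_true(all(post$mass == post$mass[1]))       # uniform

  postn <- init_posterior(g, prior = "normal", theta_mean = 400,
                          theta_sd = 60)
  marg <- theta_marginal(postn)
  ref <- dnorm(g$theta_ms, 400, 60)
  expect_equal(marg$mass, ref / sum(ref), tolerance = 1e-12)
  expect_equal(sum(postn$mass), 1, tolerance = 1e-12)
})

test_that("likelihood case table is coherent and mirrors the simulator", {
  p <- psychometric_params(429, 0.02, 0.12, 0.1)
  # anticipated evidence has likelihood alpha regardless of tau
  for (tt in c("redirect", "no_redirect"))
    expect_equal(evidence_likelihood(
      p, trial_evidence(tt, 500, TRUE, FALSE)), 0.1)
  # the three outcomes partition probability 1 for each trial type
  for (tt in c("redirect", "no_redirect")) {
    tot <- evidence_likelihood(p, trial_evidence(tt, 380, TRUE, FALSE)) +
      evidence_likelihood(p, trial_evidence(tt, 380, FALSE, TRUE)) +
      evidence_likelihood(p, trial_evidence(tt, 380, FALSE, FALSE))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
  # at threshold with no lapse/anticipation the success likelihood is 1/2
  p0 <- psychometric_params(429, 0.02, 0, 0)
  expect_equal(evidence_likelihood(
    p0, trial_evidence("redirect", 429, FALSE, TRUE)), 0.5)

  # Monte-Carlo agreement with simulate_kick on every outcome cell
  set.seed(71)
  n <- 1e5
  for (tt in c("redirect", "no_redirect")) {
    out <- simulate_kick(p, trial_type = tt, tau_ms = 380, n = n)
    cells <- list(c(TRUE, FALSE), c(FALSE, TRUE), c(FALSE, FALSE))
    for (cell in cells) {
      freq <- mean(out$anticipated == cell[1] & out$success == cell[2])
      prob <- evidence_likelihood(p, trial_evidence(tt, 380, cell[1],
                                                    cell[2]))
      expect_lt(abs(freq - prob), 4 * sqrt(prob * (1 - prob) / n))
    }
  }
})

test_that("posterior updates follow Bayes rule", {
  g <- tiny_grid()
  post <- init_posterior(g)
  # constant likelihood leaves the posterior unchanged
  post2 <- update_posterior(post, trial_evidence("redirect", 400, TRUE,
                                                 FALSE))
  # likelihood alpha varies only along the anticipation axis: theta marginal
  # must stay uniform
  marg <- theta_marginal(post2)
  expect_equal(marg$mass, rep(1 / length(marg$mass), length(marg$mass)),
               tolerance = 1e-12)

  # hand-computed two-node example via a grid collapsed to two thetas
  g2 <- param_grid(theta_ms = c(300, 500), slope = 0.02, lapse = 0,
                   anticipation = 0)
  p2 <- init_posterior(g2)
  ev <- trial_evidence("redirect", 400, FALSE, TRUE)
  l <- c(plogis(0.02 * 100), plogis(-0.02 * 100))
  p2u <- update_posterior(p2, ev)
  expect_equal(p2u$mass, l / sum(l), tolerance = 1e-12)
  expect_equal(sum(p2u$mass), 1, tolerance = 1e-12)
  # input posterior is not modified
  expect_equal(p2$mass, rep(0.5, 2))
})

test_that("sequential updates equal brute-force joint normalization", {
  g <- coarse_grid()
  set.seed(13)
  evs <- lapply(1:20, function(i) {
    tt <- sample(c("redirect", "no_redirect"), 1)
    ant <- runif(1) < 0.15
    trial_evidence(tt, runif(1, 250, 550), ant,
                   if (ant) FALSE else runif(1) < 0.5)
  })
  post <- init_posterior(g)
  for (ev in evs) post <- update_posterior(post, ev)

  # independent brute force: loop over every node, multiply scalar
  # likelihoods, normalize once
  nodes <- expand.grid(ti = seq_along(g$theta_ms), si = seq_along(g$slope),
                       li = seq_along(g$lapse),
                       ai = seq_along(g$anticipation))
  joint <- vapply(seq_len(nrow(nodes)), function(i) {
    pp <- psychometric_params(g$theta_ms[nodes$ti[i]], g$slope[nodes$si[i]],
                              g$lapse[nodes$li[i]],
                              g$anticipation[nodes$ai[i]])
    prod(vapply(evs, function(ev) evidence_likelihood(pp, ev), numeric(1)))
  }, numeric(1))
  joint <- joint / sum(joint)
  # node order of the grid: theta fastest, then slope, lapse, anticipation
  ord <- order(nodes$ai, nodes$li, nodes$si, nodes$ti)
  expect_lt(max(abs(post$mass - joint[ord])), 1e-12)
})

test_that("theta marginal sums correctly and matches direct expectations", {
  g <- tiny_grid()
  post <- init_posterior(g)
  set.seed(29)
  for (i in 1:10) {
    out <- runif(1) < 0.6
    post <- update_posterior(post, trial_evidence("redirect",
                                                  runif(1, 300, 550),
                                                  FALSE, out))
  }
  marg <- theta_marginal(post)
  expect_equal(sum(marg$mass), 1, tolerance = 1e-9)
  theta_full <- rep(g$theta_ms, times = g$n_nodes / g$dim[1])
  expect_equal(sum(marg$theta_ms * marg$mass), sum(theta_full * post$mass),
               tolerance = 1e-12)
})

test_that("threshold estimate handles point masses and symmetric marginals", {
  g2 <- param_grid(theta_ms = c(300, 429, 500), slope = 0.02, lapse = 0,
                   anticipation = 0)
  post <- init_posterior(g2)
  post$mass <- c(0, 1, 0)
  est <- threshold_estimate(post)
  expect_equal(est$estimate_ms, 429)
  expect_equal(diff(est$ci_ms), 0)

  g3 <- param_grid(theta_ms = c(300, 500), slope = 0.02, lapse = 0,
                   anticipation = 0)
  post <- init_posterior(g3)
  expect_equal(threshold_estimate(post)$estimate_ms, 400)
})

test_that("entropy policy matches brute-force expected entropy", {
  g2 <- param_grid(theta_ms = c(350, 450), slope = 0.02, lapse = c(0, 0.1),
                   anticipation = c(0, 0.1))
  post <- init_posterior(g2)
  post <- update_posterior(post, trial_evidence("redirect", 420, FALSE,
                                                TRUE))
  cands <- seq(360, 440, by = 20)

  brute <- vapply(cands, function(tau) {
    total <- 0
    for (cell in list(c(TRUE, FALSE), c(FALSE, TRUE), c(FALSE, FALSE))) {
      lik <- vapply(seq_along(post$mass), function(i) {
        ti <- (i - 1) %% 2 + 1
        si <- 1
        li <- ((i - 1) %/% 2) %% 2 + 1
        ai <- (i - 1) %/% 4 + 1
        evidence_likelihood(
          psychometric_params(g2$theta_ms[ti], g2$slope[si], g2$lapse[li],
                              g2$anticipation[ai]),
          trial_evidence("redirect", tau, cell[1], cell[2]))
      }, numeric(1))
      w <- post$mass * lik
      p_out <- sum(w)
      marg <- c(sum(w[c(1, 3, 5, 7)]), sum(w[c(2, 4, 6, 8)])) / p_out
      marg <- marg[marg > 0]
      total <- total + p_out * (-sum(marg * log(marg)))
    }
    total
  }, numeric(1))

  eh <- redirkick:::expected_theta_entropy(post, cands)
  expect_equal(eh, brute, tolerance = 1e-12)
  expect_equal(select_next_tau(post, cands, policy = "entropy"),
               cands[which.min(brute)])
})

test_that("challenge policy targets the threshold-marginal median", {
  g <- param_grid(theta_ms = seq(300, 500, by = 25), slope = 0.02,
                  lapse = 0, anticipation = 0)
  post <- init_posterior(g)
  post$mass <- as.numeric(g$theta_ms == 425)
  cands <- seq(310, 490, by = 20)
  expect_equal(select_next_tau(post, cands, policy = "challenge",
                               jitter = FALSE), 430)
  # jitter stays within one candidate step
  set.seed(2)
  picks <- replicate(60, select_next_tau(post, cands, policy = "challenge"))
  expect_true(all(picks %in% c(410, 430, 450)))
  expect_error(select_next_tau(post, numeric(0)), "non-empty")
  expect_error(select_next_tau(post, c(100, 200)), "axis range")
})

test_that("selected lead times stay inside a narrow posterior's support", {
  set.seed(51)
  g <- param_grid()
  hits <- vapply(1:100, function(i) {
    post <- init_posterior(g, prior = "normal",
                           theta_mean = runif(1, 350, 500), theta_sd = 18)
    est <- threshold_estimate(post)
    tau <- select_next_tau(post, policy = "challenge")
    tau >= est$ci_ms[1] - 10 && tau <= est$ci_ms[2] + 10
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("fit_threshold recovers a simulated player and exposes methods", {
  set.seed(123)
  truth <- psychometric_params(420, 0.025, 0.08, 0.08)
  taus <- rep(seq(300, 550, by = 25), each = 6)
  rows <- lapply(taus, function(tau) {
    out <- simulate_kick(truth, trial_type = "redirect", tau_ms = tau)
    data.frame(trial_type = "redirect", tau_actual_ms = tau,
               anticipated = out$anticipated, success = out$success)
  })
  extra <- lapply(1:30, function(i) {
    out <- simulate_kick(truth, trial_type = "no_redirect", tau_ms = 0)
    data.frame(trial_type = "no_redirect", tau_actual_ms = 0,
               anticipated = out$anticipated, success = out$success)
  })
  dat <- do.call(rbind, c(rows, extra))
  fit <- fit_threshold(dat, prior = "normal", slope_meanlog = log(0.02),
                       lapse_shape = c(2, 18),
                       anticipation_shape = c(2, 18))
  expect_s3_class(fit, "redirection_fit")
  expect_lt(abs(coef(fit)["threshold_ms"] - 420), 40)
  expect_lt(abs(coef(fit)["lapse_rate"] - 0.08), 0.1)
  expect_output(print(fit), "threshold")
  expect_output(print(summary(fit)), "kicks")
  # predicted success curve is increasing and matches success_curve
  tau_ax <- seq(250, 600, by = 50)
  pr <- predict(fit, tau_ax)
  expect_true(all(diff(pr) >= 0))
  expect_equal(pr, success_curve(fit$posterior, tau_ax)$p_success)
  expect_error(fit_threshold(dat[, -1]), "missing column")
})

test_that("posterior summaries round-trip through JSON", {
  post <- init_posterior(tiny_grid(), prior = "normal", theta_mean = 420,
                         theta_sd = 40)
  path <- tempfile(fileext = ".json")
  write_posterior_summary(post, path)
  back <- read_posterior_summary(path)
  marg <- theta_marginal(post)
  expect_equal(back$theta_marginal, marg$mass, tolerance = 1e-12)
  expect_equal(back$estimate_ms, threshold_estimate(post)$estimate_ms,
               tolerance = 1e-12)
  expect_error(read_posterior_summary({
    p <- tempfile(); jsonlite::write_json(list(x = 1), p); p
  }), "not a recognized")
})
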
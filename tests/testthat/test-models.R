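test_that("utility functions evaluate their printed forms", {
  expect_equal(utility(0.5, model_spec("EV", m0 = 0.5)), 1)
  expect_equal(utility(0.25, model_spec("EU_power", a = 2, m0 = 0.5)), 0.25)
  expect_equal(utility(0.5, model_spec("EU_sshape", a = 0.7, b = 1.3,
                                       m0 = 0.5)), 1)
  expect_equal(utility(0, model_spec("EU_sshape", a = 0.7, b = 1.3)), 0)
  expect_equal(utility(0, model_spec("EU_power", a = 0.4)), 0)
  expect_warning(utility(0.6, model_spec("EU_sshape", a = 0.7, b = 1,
                                         m0 = 0.5)), "above m0")
})

test_that("Prelec weighting has its fixed endpoints and identity case", {
  expect_equal(prelec_weight(1), 1)
  expect_equal(prelec_weight(0, 0.5, 2), 0)
  p <- seq(0.05, 1, by = 0.05)
  expect_equal(prelec_weight(p, 1, 1), p)
  expect_equal(prelec_weight(exp(-1), 0.5, 1), exp(-1))
})

test_that("gamble values follow each family's definition", {
  g <- gamble(c(0.5, 0), c(0.5, 0.5))
  expect_equal(gamble_value(g, model_spec("EV", m0 = 0.5)), 0.5)
  expect_equal(gamble_value(g, model_spec("mean_variance", beta = 0)),
               expected_value(g))
  expect_equal(gamble_value(g, model_spec("mean_variance", beta = -2)),
               expected_value(g) - 2 * risk_variance(g))
  # PW with identity weighting reduces to EU on one-non-zero gambles
  for (pp in c(0.2, 0.5, 0.9)) {
    g1 <- gamble(c(0.3, 0), c(pp, 1 - pp))
    expect_equal(gamble_value(g1, model_spec("PW", a = 0.7)),
                 gamble_value(g1, model_spec("EU_power", a = 0.7)))
  }
  # EV kind is EU with linear utility: V = EV / m0 for arbitrary gambles
  set.seed(5)
  for (i in 1:10) {
    k <- sample(1:3, 1)
    g2 <- gamble(runif(k, 0, 0.9) + seq_len(k), { q <- runif(k); q / sum(q) })
    expect_equal(gamble_value(g2, model_spec("EV", m0 = 0.5)),
                 expected_value(g2) / 0.5)
  }
  expect_error(gamble_value(gamble(c(0.1, 0.3), c(0.5, 0.5)),
                            model_spec("PW")), "non-zero outcome")
})

test_that("choice probabilities follow the logistic rule", {
  sp <- model_spec("EV", tau = 0.2, m0 = 0.5)
  g <- degenerate(0.3)
  expect_equal(choice_probability(g, g, sp), 0.5)
  expect_equal(choice_probability(degenerate(0.4), degenerate(0.3), sp),
               1 / (1 + exp(-(0.8 - 0.6) / 0.2)))
  expect_equal(choice_probability(degenerate(0.4), degenerate(0.3), sp) +
                 choice_probability(degenerate(0.3), degenerate(0.4), sp), 1)
})

test_that("negative log-likelihood is the Bernoulli sum with clipping", {
  g <- degenerate(0.3)
  n <- 40L
  tt <- data.frame(session = 1, trial = 1:n,
                   gamble_left = format_gamble(g),
                   gamble_right = format_gamble(g),
                   chosen_side = rep(c("L", "R"), n / 2),
                   reward_delivered = 0.3)
  sp <- model_spec("EV", tau = 0.1)
  expect_equal(negative_log_likelihood(tt, sp), n * log(2))

  t1 <- data.frame(session = 1, trial = 1,
                   gamble_left = format_gamble(degenerate(0.4)),
                   gamble_right = format_gamble(degenerate(0.3)),
                   chosen_side = "L", reward_delivered = 0.4)
  sp2 <- model_spec("EV", tau = 0.2, m0 = 0.5)
  expect_equal(negative_log_likelihood(t1, sp2),
               -log(1 / (1 + exp(-1))), tolerance = 1e-12)
  expect_equal(negative_log_likelihood(rbind(t1, t1), sp2),
               2 * negative_log_likelihood(t1, sp2))
})

test_that("predicted indifference points match the closed power form", {
  for (a in c(0.5, 1, 2)) {
    sp <- model_spec("EU_power", a = a, m0 = 0.5)
    got <- predict_indifference_point(degenerate(0.25), 0.5, sp)
    expect_equal(got, (0.25 / 0.5)^a, tolerance = 1.0001e-3)
  }
  sp <- model_spec("EU_power", a = 1)
  expect_equal(predict_indifference_point(degenerate(0.25), 0.25, sp), 1)
  expect_warning(
    ip <- predict_indifference_point(degenerate(0.25), 0.1, sp),
    "cannot reach")
  expect_true(is.na(ip))
})

test_that("indifference maps are monotone and EV curves follow p = mB/m", {
  sp <- model_spec("EV", m0 = 0.5)
  map <- build_indifference_map(sp, c(0.15, 0.3), m_step = 0.01)
  for (bb in unique(map$b)) {
    d <- map[map$b == bb, ]
    mB <- parse_gamble(bb)$m
    expect_true(all(abs(d$probability - mB / d$magnitude) <= 1.0001e-3))
    expect_true(all(diff(d$probability) < 1e-12))  # strictly decreasing
  }
  # equal-valued B gambles predict identical indifference points
  spp <- model_spec("EU_power", a = 2, m0 = 0.5)
  b_risky <- gamble(c(0.5, 0), c(0.25, 0.75))  # value 0.25 = U(0.25)
  for (probe in c(0.3, 0.4, 0.5)) {
    expect_equal(predict_indifference_point(degenerate(0.25), probe, spp),
                 predict_indifference_point(b_risky, probe, spp))
  }
})

test_that("utility curvature warps the map around the EV curves", {
  ip_at <- function(a) predict_indifference_point(
    degenerate(0.25), 0.5, model_spec("EU_power", a = a, m0 = 0.5))
  # concave utility (risk averse): IP above the EV curve's 0.5
  expect_gt(ip_at(0.5), 0.5)
  # convex utility (risk seeking): below
  expect_lt(ip_at(2), 0.5)
  # warping is graded in the exponent
  expect_gt(ip_at(0.25), ip_at(0.5))
})

test_that("profile likelihood is lowest near the generating parameters", {
  ag <- agent_spec(model_spec("EU_power", a = 0.6, tau = 0.1))
  tr <- simulate_experiment(ag, mixed_design(repeats = 40L), seed = 21)
  nll <- function(a, tau) negative_log_likelihood(
    tr, model_spec("EU_power", a = a, tau = tau))
  at_truth <- nll(0.6, 0.1)
  expect_lt(at_truth, nll(0.6 * 1.2, 0.1))
  expect_lt(at_truth, nll(0.6 * 0.8, 0.1))
  expect_lt(at_truth, nll(0.6, 0.1 * 1.2))
  expect_lt(at_truth, nll(0.6, 0.1 * 0.8))
})

test_that("choice probabilities depend only on value differences", {
  # mean-variance values shift by a constant when all magnitudes shift the
  # EV equally; the logistic rule must be invariant to common shifts
  sp <- model_spec("EV", tau = 0.1, m0 = 1)
  g1 <- degenerate(0.2)
  g2 <- degenerate(0.35)
  d <- 0.3
  expect_equal(choice_probability(g1, g2, sp),
               choice_probability(degenerate(0.2 + d),
                                  degenerate(0.35 + d), sp))
})

test_that("model fits recover nested and misspecified structure", {
  ag <- ev_agent(tau = 0.1)
  tr <- simulate_experiment(ag, mixed_design(repeats = 8L), seed = 31)
  f <- fit_model_mle(tr, "EU_power", seed = 1)
  ci <- f$estimates[f$estimates$parameter == "a", ]
  expect_true(ci$ci_low <= 1 && 1 <= ci$ci_high)
  expect_error(fit_model_mle(tr[0, ], "EV"), "no trials")
  expect_warning(fit_model_mle(tr[1:15, ], "EU_power", n_starts = 1L),
                 "fewer than 10 trials per free parameter")
})

test_that("model comparison computes rmse/var metrics and guards inputs", {
  ag <- eu_agent(a = 0.6, tau = 0.05)
  tr <- simulate_continuity(ag, repeats = 60L, seed = 41)
  ct <- test_continuity(tr, fx_A, fx_B, fx_C)
  fits <- list(fit_model_mle(tr, "EV", seed = 1),
               fit_model_mle(tr, "EU_power", seed = 1))
  cmp <- compare_models(fits, list(ct))
  expect_equal(nrow(cmp), 2L)
  # misspecification gap: power-generated data fit worse by EV
  expect_lt(cmp$rmse_ip[cmp$model == "EU_power"],
            cmp$rmse_ip[cmp$model == "EV"])
  expect_true(all(is.finite(cmp$var_pref)))
  expect_error(compare_models(fits[1]), "at least two")
  f_short <- fit_model_mle(tr[1:100, ], "EV", seed = 1)
  expect_error(compare_models(list(fits[[1]], f_short)), "different trial")
  # identical specs give identical metrics
  cmp2 <- compare_models(list(fits[[2]], fits[[2]]), list(ct))
  expect_equal(cmp2$bic[1], cmp2$bic[2])
  expect_equal(cmp2$rmse_ip[1], cmp2$rmse_ip[2])
})

test_that("IP cross-correlation separates shared drift from noise", {
  set.seed(9)
  n_sess <- 40
  common <- cumsum(rnorm(n_sess, 0, 0.05))
  driven <- sapply(1:4, function(i) 0.5 + common + rnorm(n_sess, 0, 0.01))
  res <- ip_cross_correlation(driven, ic = c(1, 1, 2, 2))
  expect_gt(res$within_ic$mean_rho, 0.5)
  expect_lt(res$within_ic$p_value, 0.05)
  expect_lt(res$across_ic$p_value, 0.05)

  indep <- sapply(1:4, function(i) 0.5 + rnorm(n_sess, 0, 0.02))
  res2 <- ip_cross_correlation(indep, ic = c(1, 1, 2, 2))
  expect_gt(res2$across_ic$p_value, 0.05)

  # perfectly common drift, no noise: all correlations are 1
  perfect <- sapply(1:3, function(i) 0.5 + common)
  res3 <- ip_cross_correlation(perfect)
  expect_equal(res3$pairs$rho, rep(1, 3))
  expect_error(ip_cross_correlation(driven[1:2, ]), "three sessions")
})
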
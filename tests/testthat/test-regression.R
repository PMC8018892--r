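sim_regression_table <- function(agent, repeats = 8L, n_sessions = 1L,
                                 seed = 1L) {
  simulate_experiment(agent,
                      mixed_design(repeats = repeats,
                                   n_sessions = n_sessions),
                      seed = seed)
}

test_that("choice regression recovers the sign structure of value-driven choice", {
  ag <- ev_agent(tau = 0.1)
  tr <- sim_regression_table(ag, repeats = 32L, seed = 50)
  fit <- fit_choice_logistic(tr)
  b <- fit$coefficients
  expect_lt(b[["m_L"]], 0)
  expect_lt(b[["p_L"]], 0)
  expect_gt(b[["m_R"]], 0)
  expect_gt(b[["p_R"]], 0)
  expect_lt(abs(fit$standardized[["prev"]]), 0.1)
  expect_false(fit$separation)
})

test_that("side bias appears in the intercept", {
  # degenerate-only pairs keep the value difference linear in the
  # magnitude regressors, so the intercept isolates the side bias
  mags <- seq(0.1, 0.5, by = 0.1)
  pairs <- list()
  for (i in seq_along(mags)) for (j in seq_along(mags))
    if (i != j) pairs <- c(pairs, list(list(a = degenerate(mags[i]),
                                            b = degenerate(mags[j]))))
  ag <- agent_spec(model_spec("EV", tau = 0.4), side_bias = 1)
  tr <- simulate_experiment(ag, pair_design(pairs, repeats = 150L),
                            seed = 51)
  fit <- suppressWarnings(fit_choice_logistic(tr))
  expect_equal(fit$coefficients[["intercept"]], 1, tolerance = 0.3)

  ag0 <- agent_spec(model_spec("EV", tau = 0.4), side_bias = 0)
  tr0 <- simulate_experiment(ag0, pair_design(pairs, repeats = 150L),
                             seed = 51)
  fit0 <- suppressWarnings(fit_choice_logistic(tr0))
  expect_lt(abs(fit0$coefficients[["intercept"]]), 0.3)
})

test_that("a win-stay strategy loads on the previous-trial regressor", {
  # construct win-stay choices directly: repeat the last side if rewarded
  set.seed(60)
  g1 <- gamble(c(0.4, 0), c(0.5, 0.5))
  g2 <- gamble(c(0.3, 0), c(0.6, 0.4))
  n <- 600L
  side <- character(n)
  rew <- numeric(n)
  side[1] <- "L"
  rew[1] <- 0.4
  for (i in 2:n) {
    side[i] <- if (rew[i - 1] > 0) side[i - 1] else sample(c("L", "R"), 1)
    g <- if ((side[i] == "L") == (i %% 2 == 0)) g1 else g2
    rew[i] <- g$m[sample.int(2, 1, prob = g$p)]
  }
  tr <- data.frame(session = 1, trial = 1:n,
                   gamble_left = ifelse(1:n %% 2 == 0, format_gamble(g1),
                                        format_gamble(g2)),
                   gamble_right = ifelse(1:n %% 2 == 0, format_gamble(g2),
                                         format_gamble(g1)),
                   chosen_side = side, reward_delivered = rew,
                   prev_choice = c(0, ifelse(side == "L", -1, 1)[-n]),
                   prev_reward = c(0, rew[-n]))
  # alternating fixed pairs make the value regressors collinear; only the
  # history regressor matters here
  fit <- suppressWarnings(fit_choice_logistic(tr))
  expect_gt(fit$coefficients[["prev"]], 1)
})

test_that("standardization follows the SD-ratio formula and its flags", {
  ag <- ev_agent(tau = 0.1)
  tr <- sim_regression_table(ag, repeats = 8L, seed = 52)
  fit <- fit_choice_logistic(tr)
  # hand recomputation for one coefficient
  gl <- parse_gamble(tr$gamble_left)
  mL <- vapply(gl, function(g) max(g$m), 0)
  y <- as.integer(tr$chosen_side == "R")
  expect_equal(fit$standardized[["m_L"]],
               fit$coefficients[["m_L"]] * sd(mL) / sd(y))
  expect_true(is.na(fit$standardized[["intercept"]]))

  # scale invariance: ml -> microliters leaves standardized betas unchanged
  scale_g <- function(s) vapply(parse_gamble(s), function(g)
    format_gamble(gamble(g$m * 1000, g$p)), "")
  tr2 <- tr
  tr2$gamble_left <- scale_g(tr$gamble_left)
  tr2$gamble_right <- scale_g(tr$gamble_right)
  fit2 <- fit_choice_logistic(tr2)
  expect_equal(fit2$standardized[c("m_L", "m_R", "p_L", "p_R")],
               fit$standardized[c("m_L", "m_R", "p_L", "p_R")],
               tolerance = 1e-6)

  # zero-variance regressor: degenerate-only options make p constant
  pairs <- list(list(a = degenerate(0.4), b = degenerate(0.3)),
                list(a = degenerate(0.5), b = degenerate(0.2)))
  tr3 <- simulate_experiment(ev_agent(tau = 0.2),
                             pair_design(pairs, repeats = 40L), seed = 5)
  fit3 <- suppressWarnings(fit_choice_logistic(tr3))
  expect_true(is.na(fit3$standardized[["p_L"]]))
})

test_that("mirroring all trials mirrors the coefficients", {
  ag <- agent_spec(model_spec("EV", tau = 0.1), side_bias = 0.5)
  tr <- sim_regression_table(ag, repeats = 16L, seed = 53)
  fit <- fit_choice_logistic(tr)
  mir <- tr
  mir$gamble_left <- tr$gamble_right
  mir$gamble_right <- tr$gamble_left
  mir$chosen_side <- ifelse(tr$chosen_side == "L", "R", "L")
  mir$prev_choice <- -tr$prev_choice
  fit_m <- fit_choice_logistic(mir)
  # flipping y negates the linear predictor, so the mirrored fit carries
  # the left/right-swapped coefficients with opposite sign
  expect_equal(fit_m$coefficients[["intercept"]],
               -fit$coefficients[["intercept"]], tolerance = 1e-6)
  expect_equal(fit_m$coefficients[["m_L"]], -fit$coefficients[["m_R"]],
               tolerance = 1e-6)
  expect_equal(fit_m$coefficients[["p_L"]], -fit$coefficients[["p_R"]],
               tolerance = 1e-6)
  expect_equal(fit_m$coefficients[["m_R"]], -fit$coefficients[["m_L"]],
               tolerance = 1e-6)
  expect_equal(fit_m$coefficients[["prev"]], fit$coefficients[["prev"]],
               tolerance = 1e-6)
})

test_that("population tests flag value coefficients but not history", {
  ag <- ev_agent(tau = 0.1)
  tr <- sim_regression_table(ag, repeats = 2L, n_sessions = 20L, seed = 54)
  fits <- lapply(unique(tr$session), function(s)
    suppressWarnings(fit_choice_logistic(tr[tr$session == s, ])))
  pop <- population_beta_tests(fits)
  sig <- setNames(pop$significant, pop$coefficient)
  expect_true(all(sig[c("m_L", "p_L", "m_R", "p_R")]))
  expect_false(sig[["prev"]])
  expect_equal(sign(pop$mean[pop$coefficient == "m_R"]), 1)
  expect_error(population_beta_tests(fits[1:2]), "at least 3")
})
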
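# brute-force oracles, independent of the implementation path
binom_two_sided_oracle <- function(k, n) {
  pmf <- choose(n, 0:n) / 2^n
  sum(pmf[pmf <= pmf[k + 1L] + 1e-12])
}

bh_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  below <- which(ps <= (seq_len(m) / m) * q)
  reject <- logical(m)
  if (length(below)) reject[o[seq_len(max(below))]] <- TRUE
  reject
}

test_that("binomial preference matches the exact tail probabilities", {
  r <- binomial_preference(9, 10)
  expect_equal(r$p_value, 2 * sum(choose(10, 9:10)) / 2^10)
  expect_equal(r$direction, "preferred")

  r2 <- binomial_preference(5, 10)
  expect_equal(r2$p_value, 1)
  expect_equal(r2$direction, "indifferent")

  r3 <- binomial_preference(0, 20)
  expect_equal(r3$p_value, 2 * 2^-20)
  expect_equal(r3$direction, "dispreferred")

  expect_error(binomial_preference(1, 0), "n must be")
  expect_error(binomial_preference(5, 4), "k must lie")

  # exact agreement with pmf enumeration for all k, n <= 12 (the full
  # n <= 25 sweep runs in the acceptance checks)
  for (n in 1:12) for (k in 0:n) {
    expect_equal(binomial_preference(k, n)$p_value,
                 min(1, binom_two_sided_oracle(k, n)),
                 tolerance = 1e-12)
  }
})

test_that("Clopper-Pearson interval bounds are honored", {
  r <- binomial_preference(18, 20)
  expect_true(r$ci_low > 0.5)      # clearly preferred
  expect_true(r$ci_high <= 1)
  r2 <- binomial_preference(10, 20)
  expect_true(r2$ci_low < 0.5 && r2$ci_high > 0.5)
})

test_that("BH FDR matches the step-up oracle", {
  r <- bh_fdr(c(0.01, 0.02, 0.04), q = 0.05)
  expect_true(all(r$reject))
  expect_false(any(bh_fdr(rep(1, 6))$reject))
  expect_true(bh_fdr(0.04, q = 0.05)$reject)

  set.seed(123)
  for (i in 1:100) {
    m <- sample(1:20, 1)
    p <- runif(m)^sample(1:3, 1)
    q <- runif(1, 0.01, 0.2)
    r <- bh_fdr(p, q)
    expect_identical(r$reject, bh_oracle(p, q))
    expect_true(all(diff(sort(r$p_adjusted)) >= 0))
  }
})

test_that("FSD battery pools dominance tests correctly", {
  ag <- ev_agent(tau = 0.05)
  mk <- function(p) gamble(c(0.3, 0), c(p, 1 - p))
  pairs <- lapply(seq(0.3, 0.9, by = 0.15), function(p)
    list(a = mk(p), b = mk(p - 0.25)))
  tr <- simulate_experiment(ag, pair_design(pairs, repeats = 30L), seed = 3)
  res <- test_fsd(tr)
  expect_true(res$compliant)
  expect_equal(nrow(res$per_pair), length(pairs))
  expect_true(all(res$per_pair$proportion > 0.5))

  # coin-flip agent: pooled CI straddles 0.5
  coin <- agent_spec(model_spec("EV", tau = 1e6))
  tr2 <- simulate_experiment(coin, pair_design(pairs, repeats = 30L),
                             seed = 3)
  expect_false(test_fsd(tr2)$compliant)

  # no dominance relation: domain error
  nd <- pair_design(list(list(a = gamble(c(0.5, 0), c(0.5, 0.5)),
                              b = degenerate(0.25))), repeats = 4L)
  tr3 <- simulate_experiment(ag, nd, seed = 1)
  expect_error(test_fsd(tr3), "no first-order stochastic dominance")
})

test_that("weak and strong stochastic transitivity follow their definitions", {
  r <- test_transitivity(80, 100, 70, 100, 90, 100)
  expect_true(r$wst)
  expect_true(r$sst)

  r2 <- test_transitivity(80, 100, 70, 100, 75, 100)
  expect_true(r2$wst)
  expect_false(r2$sst)   # 0.75 < max(0.80, 0.70)

  r3 <- test_transitivity(55, 100, 70, 100, 90, 100)
  expect_false(r3$wst)   # A over B not significant

  tr <- simulate_experiment(
    ev_agent(tau = 0.05),
    pair_design(list(list(a = degenerate(0.45), b = degenerate(0.30)),
                     list(a = degenerate(0.30), b = degenerate(0.15)),
                     list(a = degenerate(0.45), b = degenerate(0.15))),
                repeats = 40L), seed = 10)
  rt <- transitivity_from_trials(tr, degenerate(0.45), degenerate(0.30),
                                 degenerate(0.15))
  expect_true(rt$wst)
  expect_error(
    transitivity_from_trials(tr, degenerate(0.45), degenerate(0.30),
                             degenerate(0.10)),
    "missing")
})

test_that("continuity test is sensitive for an EU agent", {
  tr <- simulate_continuity(eu_agent(a = 0.8, tau = 0.05), seed = 15)
  ct <- test_continuity(tr, fx_A, fx_B, fx_C)
  expect_true(ct$compliant)
  expect_true(ct$has_dispreferred_level && ct$has_preferred_level)
  expect_true(ct$monotone)
  a_true <- alpha_eu_power(0.25, 0.5, 0.8)
  expect_lt(abs(ct$ip$alpha - a_true), 0.06)
  expect_gt(ct$ip$alpha, 0)
  expect_lt(ct$ip$alpha, 1)
})

test_that("continuity test rejects lexicographic and null agents", {
  tr <- simulate_continuity(lex_agent(0.02), seed = 16)
  ct <- test_continuity(tr, fx_A, fx_B, fx_C, fit_ip = FALSE)
  expect_false(ct$compliant)
  expect_false(ct$has_dispreferred_level)  # AC preferred at every pA > 0
  expect_true(ct$has_preferred_level)

  # indifferent agent on an interior grid (precheck unavailable)
  null_ag <- agent_spec(model_spec("EV", tau = 1e6))
  tr2 <- simulate_continuity(null_ag, levels = seq(0.1, 0.9, 0.1),
                             seed = 17)
  expect_warning(
    ct2 <- test_continuity(tr2, fx_A, fx_B, fx_C,
                           levels = seq(0.1, 0.9, 0.1), fit_ip = FALSE),
    "precheck incomplete")
  expect_false(ct2$compliant)
})

test_that("continuity test refuses an unranked premise", {
  # reversed roles: 'A' is the worst gamble, so the precheck A > B fails
  trr <- simulate_experiment(
    eu_agent(),
    continuity_design(fx_C, fx_B, fx_A, levels = seq(0, 1, 0.1),
                      repeats = 30L), seed = 18)
  expect_error(test_continuity(trr, fx_C, fx_B, fx_A),
               "ranked-gambles")
})

test_that("expected per-level preference is nondecreasing in pA for value agents", {
  sp <- model_spec("EU_sshape", a = 1.4, b = 0.9, tau = 0.08)
  probs <- vapply(seq(0, 1, 0.1), function(q)
    choice_probability(mix_gambles(fx_A, fx_C, q), fx_B, sp), 0)
  expect_true(all(diff(probs) >= -1e-12))
})
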
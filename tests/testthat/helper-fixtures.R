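# shared fixtures: the canonical continuity test of the degenerate-gamble
# task (A = 0.5 ml, B = 0.25 ml, C = 0 ml) and small agent builders

fx_A <- degenerate(0.5)
fx_B <- degenerate(0.25)
fx_C <- degenerate(0)

eu_agent <- function(a = 0.8, tau = 0.05, ...) {
  agent_spec(model_spec("EU_power", a = a, tau = tau), ...)
}

ev_agent <- function(tau = 0.05, m0 = 0.5, ...) {
  agent_spec(model_spec("EV", tau = tau, m0 = m0), ...)
}

lex_agent <- function(lapse = 0.02) {
  agent_spec(kind = "lexicographic", lapse = lapse)
}

# trial table for one continuity test
simulate_continuity <- function(agent, levels = seq(0, 1, by = 0.1),
                                repeats = 30L, n_sessions = 1L, seed = 1L,
                                A = fx_A, B = fx_B, C = fx_C) {
  simulate_experiment(agent,
                      continuity_design(A, B, C, levels = levels,
                                        repeats = repeats,
                                        n_sessions = n_sessions),
                      seed = seed)
}

# closed-form EU indifference point for degenerate A, B and C = 0:
# pA * U(mA) = U(mB)  =>  alpha = (mB / mA)^a
alpha_eu_power <- function(mB, mA, a) (mB / mA)^a
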
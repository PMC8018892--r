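#' Specify a synthetic choice agent
#'
#' Agents generate trial tables with the statistical structure the analysis
#' pipeline assumes: logistic (softmax) choice noise around a value model, a
#' constant side bias, gradual across-session drift of one model parameter
#' (random walk), and a within-session decline of the indifference point
#' emulating satiation. A `"lexicographic"` agent implements the
#' attribute-at-a-time heuristic that violates the continuity axiom: it
#' always picks the option with the higher maximum magnitude (ties broken
#' by the probability of that magnitude), softened by a lapse rate.
#'
#' @param model a [model_spec()] for value-based agents, or `NULL` for
#'   lexicographic agents.
#' @param kind `"value"` or `"lexicographic"`.
#' @param side_bias logit offset in favor of the right side (unitless).
#' @param drift_param name of the model parameter performing an
#'   across-session random walk (e.g. `"a"`), or `NULL`.
#' @param across_session_sd random-walk SD per session on `drift_param`
#'   (>= 0).
#' @param within_session_decline target change of the indifference point
#'   from the first to the second half of a session (probability units;
#'   negative = declining preference for the risky mixture). Requires
#'   `drift_param` and a `reference` continuity test so the parameter path
#'   can be calibrated.
#' @param reference list with gambles `A`, `B`, `C` defining the continuity
#'   test used to calibrate drift in IP units; defaults to the first test of
#'   the simulated design.
#' @param lapse lapse rate for lexicographic agents (probability of picking
#'   the lexicographically worse option), default 0.02 so that choice
#'   proportions stay estimable.
#' @return An object of class `"agent_spec"`.
#' @examples
#' ag <- agent_spec(model_spec("EU_power", a = 0.8, tau = 0.05))
#' @export
agent_spec <- function(model = NULL, kind = c("value", "lexicographic"),
                       side_bias = 0, drift_param = NULL,
                       across_session_sd = 0, within_session_decline = 0,
                       reference = NULL, lapse = 0.02) {
  kind <- match.arg(kind)
  if (kind == "value" && !inherits(model, "model_spec"))
    stop("value agents require a model_spec")
  if (across_session_sd < 0) stop("across_session_sd must be >= 0")
  if (lapse < 0 || lapse >= 0.5) stop("lapse must be in [0, 0.5)")
  if ((across_session_sd > 0 || within_session_decline != 0) &&
      is.null(drift_param))
    stop("drifting agents must name a drift_param")
  structure(list(model = model, kind = kind, side_bias = side_bias,
                 drift_param = drift_param,
                 across_session_sd = across_session_sd,
                 within_session_decline = within_session_decline,
                 reference = reference, lapse = lapse),
            class = "agent_spec")
}

# model spec with the drifting parameter set to `value`
drifted_spec <- function(agent, value = NULL) {
  sp <- agent$model
  if (!is.null(value) && !is.null(agent$drift_param))
    sp[[agent$drift_param]] <- value
  sp
}

# lexicographic comparison: +1 if gA better, -1 if gB better, 0 tie
lex_compare <- function(gA, gB) {
  mA <- max(gA$m); mB <- max(gB$m)
  if (abs(mA - mB) > 1e-9) return(sign(mA - mB))
  pA <- sum(gA$p[abs(gA$m - mA) <= 1e-9])
  pB <- sum(gB$p[abs(gB$m - mB) <= 1e-9])
  if (abs(pA - pB) > 1e-12) sign(pA - pB) else 0
}

#' Choice probability of an agent for a gamble pair
#'
#' For value agents, the logistic of the subjective-value difference at the
#' agent's (possibly drifted) parameters; side bias is a property of screen
#' sides, not of the options, and is therefore applied in
#' [simulate_experiment()], not here. For lexicographic agents, the
#' deterministic attribute rule softened by the lapse rate.
#'
#' @param agent an [agent_spec()].
#' @param gA,gB gambles.
#' @param drift_value optional current value of the drifting parameter.
#' @return Probability of choosing `gA`.
#' @export
choice_probability_of_agent <- function(agent, gA, gB, drift_value = NULL) {
  if (agent$kind == "lexicographic") {
    cmpv <- lex_compare(gA, gB)
    if (cmpv == 0) return(0.5)
    if (cmpv > 0) 1 - agent$lapse else agent$lapse
  } else {
    choice_probability(gA, gB, drifted_spec(agent, drift_value))
  }
}

# indifference mixture probability of the agent's model for a reference
# test, as a function of the drifting parameter value
ip_of_param <- function(agent, value, reference) {
  sp <- drifted_spec(agent, value)
  model_ip(sp, reference$A, reference$B, reference$C, p_step = 1e-4)
}

#' Per-trial drift schedule for an agent
#'
#' Builds the drifting-parameter path: an across-session Gaussian random
#' walk (SD `across_session_sd`) around the base parameter value, plus a
#' within-session linear ramp calibrated (by monotone interpolation of the
#' parameter-to-IP mapping for the agent's reference continuity test) so
#' that the model-implied indifference point shifts by approximately
#' `within_session_decline` between the first and second half of each
#' session; the ramp therefore spans twice the decline over the full
#' session.
#'
#' @param agent an [agent_spec()].
#' @param n_sessions number of sessions (>= 1).
#' @param trials_per_session trials per session.
#' @param reference continuity test (list of gambles `A`, `B`, `C`)
#'   overriding `agent$reference`.
#' @return List of numeric vectors (one per session) of parameter values,
#'   or `NULL` when the agent has no drifting parameter.
#' @export
make_drift_schedule <- function(agent, n_sessions, trials_per_session,
                                reference = NULL) {
  if (n_sessions < 1L) stop("n_sessions must be >= 1")
  if (is.null(agent$drift_param)) return(NULL)
  base <- agent$model[[agent$drift_param]]
  walk <- base + cumsum(c(0, stats::rnorm(n_sessions - 1L, 0,
                                          agent$across_session_sd)))
  walk <- pmax(walk, base * 0.05)

  decline <- agent$within_session_decline
  if (decline == 0)
    return(lapply(walk, function(v) rep(v, trials_per_session)))

  ref <- if (!is.null(reference)) reference else agent$reference
  if (is.null(ref))
    stop("within-session decline requires a reference continuity test")
  lapply(walk, function(v) {
    # parameter -> IP mapping on a log-spaced grid around the session value
    grid <- v * exp(seq(log(0.25), log(4), length.out = 31L))
    ips <- vapply(grid, function(g) ip_of_param(agent, g, ref), 0)
    if (any(diff(ips) == 0)) ips <- ips + seq_along(ips) * 1e-9
    f <- (seq_len(trials_per_session) - 0.5) / trials_per_session
    target <- ip_of_param(agent, v, ref) + 2 * decline * (f - 0.5)
    target <- pmin(pmax(target, min(ips)), max(ips))
    stats::approx(ips, grid, xout = target, rule = 2)$y
  })
}

#' Design helpers for simulated experiments
#'
#' `continuity_design()` lays out one continuity-axiom test: choices between
#' the middle gamble B and the mixture `pA * A + (1 - pA) * C` at every `pA`
#' grid level, repeated `repeats` times per level in each of `n_sessions`
#' sessions. `pair_design()` lays out arbitrary gamble pairs, and
#' `mixed_design()` produces a magnitude/probability-crossed set of
#' safe-versus-risky pairs suitable for value-model estimation.
#'
#' @param A,B,C gambles of the continuity test (A preferred, C least
#'   preferred).
#' @param levels pA grid (default 0 to 1 in 0.1 steps).
#' @param repeats trials per pair per session.
#' @param n_sessions number of sessions.
#' @return A design: list with `sessions` (list of pair lists, each pair a
#'   list with gambles `a`, `b` and `repeats`).
#' @export
continuity_design <- function(A, B, C, levels = seq(0, 1, by = 0.1),
                              repeats = 30L, n_sessions = 1L) {
  pairs <- lapply(levels, function(q)
    list(a = mix_gambles(A, C, q), b = B, repeats = repeats))
  structure(list(sessions = rep(list(pairs), n_sessions)),
            class = "choice_design")
}

#' @rdname continuity_design
#' @param pairs list of `list(a = , b = )` gamble pairs.
#' @export
pair_design <- function(pairs, repeats = 30L, n_sessions = 1L) {
  pairs <- lapply(pairs, function(pr) {
    pr$repeats <- if (is.null(pr$repeats)) repeats else pr$repeats
    pr
  })
  structure(list(sessions = rep(list(pairs), n_sessions)),
            class = "choice_design")
}

#' @rdname continuity_design
#' @param safe_magnitudes,risky_magnitudes,risky_probabilities grids (ml /
#'   probability) crossed into safe-versus-risky pairs.
#' @export
mixed_design <- function(safe_magnitudes = seq(0.05, 0.45, by = 0.1),
                         risky_magnitudes = seq(0.15, 0.5, by = 0.05),
                         risky_probabilities = seq(0.125, 0.875, by = 0.25),
                         repeats = 5L, n_sessions = 1L) {
  grid <- expand.grid(ms = safe_magnitudes, mr = risky_magnitudes,
                      pr = risky_probabilities)
  pairs <- lapply(seq_len(nrow(grid)), function(i)
    list(a = gamble(c(grid$mr[i], 0), c(grid$pr[i], 1 - grid$pr[i])),
         b = degenerate(grid$ms[i]), repeats = repeats))
  structure(list(sessions = rep(list(pairs), n_sessions)),
            class = "choice_design")
}

# left-choice probabilities for one session, vectorized where possible
session_left_probs <- function(agent, ga, gb, a_left, drift) {
  n <- length(ga)
  if (agent$kind == "lexicographic") {
    pa <- vapply(seq_len(n), function(i) {
      cmpv <- lex_compare(ga[[i]], gb[[i]])
      if (cmpv == 0) 0.5 else if (cmpv > 0) 1 - agent$lapse else agent$lapse
    }, 0)
    p_left <- ifelse(a_left, pa, 1 - pa)
    # lexicographic rule has no value scale; apply side bias on the logit
    if (agent$side_bias != 0) {
      eps <- pmin(pmax(p_left, 1e-9), 1 - 1e-9)
      p_left <- stats::plogis(stats::qlogis(eps) - agent$side_bias)
    }
    return(p_left)
  }
  va <- numeric(n); vb <- numeric(n)
  if (is.null(drift) || length(unique(drift)) == 1L) {
    sp <- drifted_spec(agent, if (is.null(drift)) NULL else drift[1L])
    memo_value <- function(gs) {
      key <- vapply(gs, format_gamble, "")
      u <- unique(key)
      vu <- vapply(seq_along(u), function(j)
        gamble_value(gs[[match(u[j], key)]], sp), 0)
      vu[match(key, u)]
    }
    va <- memo_value(ga)
    vb <- memo_value(gb)
  } else {
    for (i in seq_len(n)) {
      sp <- drifted_spec(agent, drift[i])
      va[i] <- gamble_value(ga[[i]], sp)
      vb[i] <- gamble_value(gb[[i]], sp)
    }
  }
  tau <- agent$model$tau
  vl <- ifelse(a_left, va, vb)
  vr <- ifelse(a_left, vb, va)
  stats::plogis((vl - vr) / tau - agent$side_bias)
}

#' Simulate a choice experiment
#'
#' Draws a full trial table from an agent and a design. Each pair appears
#' equally often with each left/right layout (exactly for even repeat
#' counts); trial order is shuffled within session; rewards are realized by
#' sampling the chosen gamble; `prev_choice` (-1 left / +1 right, 0 on the
#' first trial of a session) and `prev_reward` (ml, 0 on the first trial)
#' are filled in. A single seed drives per-session substreams, so
#' generation is reproducible.
#'
#' @param agent an [agent_spec()].
#' @param design a design from [continuity_design()], [pair_design()] or
#'   [mixed_design()].
#' @param seed integer seed.
#' @return A `data.frame` trial table with columns `session`, `trial`,
#'   `gamble_left`, `gamble_right` (serialized, see [format_gamble()]),
#'   `chosen_side` (`"L"`/`"R"`), `reward_delivered`, `prev_choice`,
#'   `prev_reward`.
#' @export
simulate_experiment <- function(agent, design, seed = 1L) {
  if (!inherits(design, "choice_design") || !length(design$sessions))
    stop("empty or invalid design")
  set.seed(seed)
  n_sessions <- length(design$sessions)
  session_seeds <- sample.int(.Machine$integer.max - 1L, n_sessions)
  trials_per_session <- vapply(design$sessions, function(prs)
    sum(vapply(prs, function(pr) as.numeric(pr$repeats), 0)), 0)

  sched <- NULL
  if (!is.null(agent$drift_param)) {
    ref <- agent$reference
    if (is.null(ref)) {
      pr1 <- design$sessions[[1L]][[1L]]
      ref <- list(A = pr1$a, B = pr1$b, C = degenerate(0))
    }
    sched <- make_drift_schedule(agent, n_sessions,
                                 max(trials_per_session), reference = ref)
  }

  out <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    set.seed(session_seeds[s])
    prs <- design$sessions[[s]]
    ga <- list(); gb <- list(); a_left <- logical(0)
    for (pr in prs) {
      r <- pr$repeats
      if (r < 1L) stop("repeats must be >= 1")
      nl <- r %/% 2L + (r %% 2L) * stats::rbinom(1L, 1L, 0.5)
      ga <- c(ga, rep(list(pr$a), r))
      gb <- c(gb, rep(list(pr$b), r))
      a_left <- c(a_left, sample(rep(c(TRUE, FALSE), c(nl, r - nl))))
    }
    n <- length(ga)
    ord <- sample.int(n)
    ga <- ga[ord]; gb <- gb[ord]; a_left <- a_left[ord]
    drift <- if (is.null(sched)) NULL else sched[[s]][seq_len(n)]

    p_left <- session_left_probs(agent, ga, gb, a_left, drift)
    choose_left <- stats::runif(n) < p_left
    chosen <- ifelse(choose_left,
                     ifelse(a_left, "a", "b"),
                     ifelse(a_left, "b", "a"))
    reward <- vapply(seq_len(n), function(i) {
      g <- if (chosen[i] == "a") ga[[i]] else gb[[i]]
      g$m[sample.int(length(g$m), 1L, prob = g$p)]
    }, 0)
    ch_side <- ifelse(choose_left, "L", "R")
    out[[s]] <- data.frame(
      session = s,
      trial = seq_len(n),
      gamble_left = vapply(seq_len(n), function(i)
        format_gamble(if (a_left[i]) ga[[i]] else gb[[i]]), ""),
      gamble_right = vapply(seq_len(n), function(i)
        format_gamble(if (a_left[i]) gb[[i]] else ga[[i]]), ""),
      chosen_side = ch_side,
      reward_delivered = reward,
      prev_choice = c(0, ifelse(ch_side == "L", -1, 1)[-n]),
      prev_reward = c(0, reward[-n]),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
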
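#' Specify an economic value model
#'
#' The package implements six value-model families for binary risky choice.
#' Every family maps a gamble to a scalar subjective value `V`, and choices
#' are generated / scored by the logistic discrete-choice rule
#' `P(A | {A, B}) = 1 / (1 + exp(-(V_A - V_B) / tau))`.
#'
#' Families (utility normalized so U(m0) = 1, with `m0` the maximum reward
#' magnitude, default 0.5 ml):
#' \describe{
#'   \item{`EV`}{expected value, `V = sum (m_i/m0) p_i` (linear utility).}
#'   \item{`EU_power`}{expected utility with power utility
#'     `U(m) = (m/m0)^a`.}
#'   \item{`EU_sshape`}{expected utility with the two-parameter Prelec form
#'     used as an S-shaped utility, `U(m) = exp(-b (-log(m/m0))^a)`.}
#'   \item{`PW`}{prospect-theory style value `V = U(m) * w(p)` with power
#'     utility and the two-parameter Prelec probability-weighting function
#'     `w(p) = exp(-b_w (-log p)^a_w)`; defined for gambles with at most one
#'     non-zero outcome.}
#'   \item{`additive`}{`V = w_m * U(m) + w_p * p`, magnitude and probability
#'     weighted and summed rather than multiplied; same one-non-zero-outcome
#'     domain as `PW`.}
#'   \item{`mean_variance`}{`V = EV + beta * Risk`, with Risk the outcome
#'     variance ([risk_variance()]); no utility function involved.}
#' }
#'
#' @param kind one of `"EV"`, `"EU_power"`, `"EU_sshape"`, `"PW"`,
#'   `"additive"`, `"mean_variance"`.
#' @param a,b utility parameters (power exponent; Prelec a, b), where
#'   applicable; must be > 0.
#' @param a_w,b_w Prelec probability-weighting parameters (`PW` only), > 0.
#' @param w_m,w_p magnitude and probability weights (`additive` only), > 0.
#' @param beta risk coefficient (`mean_variance` only); unconstrained sign
#'   (positive = risk seeking, negative = risk averse).
#' @param tau softmax temperature, > 0 (lower = more deterministic choice).
#' @param m0 normalizing magnitude in ml, > 0.
#' @return An object of class `"model_spec"`.
#' @examples
#' spec <- model_spec("EU_power", a = 0.8, tau = 0.05)
#' gamble_value(degenerate(0.25), spec)
#' @export
model_spec <- function(kind = c("EV", "EU_power", "EU_sshape", "PW",
                                "additive", "mean_variance"),
                       a = 1, b = 1, a_w = 1, b_w = 1,
                       w_m = 1, w_p = 1, beta = 0,
                       tau = 0.1, m0 = 0.5) {
  kind <- match.arg(kind)
  if (!is.numeric(tau) || tau <= 0) stop("tau must be > 0")
  if (m0 <= 0) stop("m0 must be > 0")
  if (a <= 0 || b <= 0 || a_w <= 0 || b_w <= 0)
    stop("utility / weighting parameters must be > 0")
  if (w_m <= 0 || w_p <= 0) stop("additive weights must be > 0")
  structure(list(kind = kind, a = a, b = b, a_w = a_w, b_w = b_w,
                 w_m = w_m, w_p = w_p, beta = beta, tau = tau, m0 = m0),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  pars <- model_params(x$kind)
  cat(sprintf("<model_spec> %s: %s\n", x$kind,
              paste(sprintf("%s = %g", pars, unlist(x[pars])),
                    collapse = ", ")))
  invisible(x)
}

# free-parameter names per family (order used by the MLE)
model_params <- function(kind) {
  switch(kind,
         EV            = "tau",
         EU_power      = c("a", "tau"),
         EU_sshape     = c("a", "b", "tau"),
         PW            = c("a", "a_w", "b_w", "tau"),
         additive      = c("a", "w_m", "w_p", "tau"),
         mean_variance = c("beta", "tau"),
         stop("unknown model kind: ", kind))
}

#' Utility of a reward magnitude
#'
#' Evaluates the model's utility function, normalized so that U(m0) = 1 and
#' U(0) = 0 (by continuity for the power and S-shaped forms). `EV` and
#' `mean_variance` specs use linear utility here. For the S-shaped form,
#' magnitudes above `m0` fall outside the log domain; a warning is issued
#' and the utility is capped at 1 (monotone extension).
#'
#' @param m numeric vector of magnitudes (ml, >= 0).
#' @param spec a [model_spec()].
#' @return Numeric vector of utilities.
#' @export
utility <- function(m, spec) {
  if (any(m < 0)) stop("magnitudes must be non-negative")
  x <- m / spec$m0
  switch(spec$kind,
         EV = ,
         mean_variance = ,
         additive_linear = x,
         EU_power = ,
         PW = ,
         additive = x^spec$a,
         EU_sshape = {
           u <- numeric(length(x))
           over <- x > 1 + 1e-12
           if (any(over)) {
             warning("S-shaped utility evaluated above m0; capped at 1")
             u[over] <- 1
           }
           ok <- x > 0 & !over
           u[ok] <- exp(-spec$b * (-log(x[ok]))^spec$a)
           u
         },
         stop("unknown model kind"))
}

#' Two-parameter Prelec probability-weighting function
#'
#' `w(p) = exp(-b_w * (-log p)^a_w)`, with `w(0) = 0` by continuity and
#' `w(1) = 1`. Reduces to the identity for `a_w = b_w = 1`.
#'
#' @param p probabilities in \[0, 1\].
#' @param a_w,b_w Prelec parameters, > 0.
#' @return Numeric vector of weighted probabilities.
#' @export
prelec_weight <- function(p, a_w = 1, b_w = 1) {
  if (any(p < -1e-12 | p > 1 + 1e-12)) stop("p must be in [0, 1]")
  if (a_w <= 0 || b_w <= 0) stop("Prelec parameters must be > 0")
  w <- numeric(length(p))
  pos <- p > 0
  w[pos] <- exp(-b_w * (-log(pmin(p[pos], 1)))^a_w)
  w
}

# the single non-zero outcome of a gamble, for PW / additive models;
# errors when the gamble has >= 2 distinct non-zero outcomes
single_nonzero_outcome <- function(g) {
  nz <- g$m > 1e-12
  if (sum(nz) > 1L)
    stop("PW and additive models are defined only for gambles with at ",
         "most one non-zero outcome")
  if (!any(nz)) list(m = 0, p = 0)
  else list(m = g$m[nz], p = g$p[nz])
}

#' Subjective value of a gamble under a model
#'
#' Dispatches on the model family (see [model_spec()]). `EV`, `EU_power`,
#' `EU_sshape` and `mean_variance` accept any gamble; `PW` and `additive`
#' are defined (as in prospect theory) only for gambles with at most one
#' non-zero outcome and raise an error otherwise.
#'
#' @param g a [gamble()].
#' @param spec a [model_spec()].
#' @return Numeric scalar value.
#' @export
gamble_value <- function(g, spec) {
  stopifnot_gamble(g)
  switch(spec$kind,
         EV = ,
         EU_power = ,
         EU_sshape = sum(utility(g$m, spec) * g$p),
         mean_variance = expected_value(g) + spec$beta * risk_variance(g),
         PW = {
           o <- single_nonzero_outcome(g)
           (o$m / spec$m0)^spec$a * prelec_weight(o$p, spec$a_w, spec$b_w)
         },
         additive = {
           o <- single_nonzero_outcome(g)
           spec$w_m * (o$m / spec$m0)^spec$a + spec$w_p * o$p
         })
}

# vectorized value of the two-outcome gamble {(m, p), (0, 1-p)}; used by
# the numerical indifference-map construction. m, p may be vectors.
value_mp <- function(m, p, spec) {
  x <- m / spec$m0
  switch(spec$kind,
         EV = x * p,
         EU_power = x^spec$a * p,
         EU_sshape = {
           u <- ifelse(x > 0, exp(-spec$b * (-log(pmin(x, 1)))^spec$a), 0)
           u[x > 1 + 1e-12] <- 1
           u * p
         },
         PW = x^spec$a * prelec_weight(p, spec$a_w, spec$b_w),
         additive = spec$w_m * x^spec$a + spec$w_p * p,
         mean_variance = m * p + spec$beta * m^2 * p * (1 - p))
}

#' Logistic choice probability between two gambles
#'
#' The discrete-choice rule `P(A | {A, B}) = 1/(1 + exp(-(V_A - V_B)/tau))`,
#' with subjective values from [gamble_value()].
#'
#' @param gA,gB gambles.
#' @param spec a [model_spec()].
#' @return Probability of choosing `gA`, in (0, 1).
#' @export
choice_probability <- function(gA, gB, spec) {
  stats::plogis((gamble_value(gA, spec) - gamble_value(gB, spec)) / spec$tau)
}

# ---- trial arrays: padded outcome matrices for fast likelihoods ----------

# trials: data.frame with gamble_left / gamble_right strings and chosen_side
trial_arrays <- function(trials, m0 = 0.5) {
  pad <- function(gs) {
    n <- length(gs)
    k <- max(vapply(gs, function(g) length(g$m), 0L))
    M <- matrix(0, n, k)
    P <- matrix(0, n, k)
    for (i in seq_len(n)) {
      li <- length(gs[[i]]$m)
      M[i, seq_len(li)] <- gs[[i]]$m
      P[i, seq_len(li)] <- gs[[i]]$p
    }
    list(M = M, P = P)
  }
  gl <- parse_gamble(trials$gamble_left)
  gr <- parse_gamble(trials$gamble_right)
  if (is_gamble(gl)) gl <- list(gl)
  if (is_gamble(gr)) gr <- list(gr)
  L <- pad(gl)
  R <- pad(gr)
  n_nonzero <- function(A) rowSums(A$M > 1e-12 & A$P > 0)
  list(left = precompute_side(L$M, L$P, m0),
       right = precompute_side(R$M, R$P, m0),
       sign = ifelse(trials$chosen_side == "L", 1, -1),
       multi_nonzero = pmax(n_nonzero(L), n_nonzero(R)) > 1L)
}

# per-side quantities precomputed once per trial table, so likelihood
# evaluations inside the optimizer are pure vector arithmetic; padded
# zero-magnitude cells carry log(m/m0) = -Inf, which the IEEE limits of
# exp()/powers map to the intended U(0) = 0, w(0) = 0 endpoints
precompute_side <- function(M, P, m0) {
  LX <- log(M / m0)
  LXc <- pmin(LX, 0)                   # S-shaped form: U(m > m0) capped at 1
  nz <- M > 1e-12
  mstar <- M[, 1L]
  if (ncol(M) > 1L)
    for (j in 2L:ncol(M)) mstar <- pmax(mstar, M[, j])
  ev <- rowSums(M * P)
  list(P = P, LX = LX, LXc = LXc, ev = ev / m0, ev_raw = ev,
       m2_raw = rowSums(M^2 * P),
       lmstar = log(mstar / m0), pstar = rowSums(P * nz))
}

side_values <- function(s, spec) {
  switch(spec$kind,
         EV = s$ev,
         EU_power = rowSums(exp(spec$a * s$LX) * s$P),
         EU_sshape = rowSums(exp(-spec$b * (-s$LXc)^spec$a) * s$P),
         mean_variance = s$ev_raw + spec$beta * (s$m2_raw - s$ev_raw^2),
         PW = exp(spec$a * s$lmstar) *
           exp(-spec$b_w * (-log(s$pstar))^spec$a_w),
         additive = spec$w_m * exp(spec$a * s$lmstar) +
           spec$w_p * s$pstar)
}

nll_arrays <- function(arr, spec) {
  if (spec$kind %in% c("PW", "additive") && any(arr$multi_nonzero))
    stop("trial ", which(arr$multi_nonzero)[1L], ": PW/additive models ",
         "cannot score gambles with >= 2 distinct non-zero outcomes")
  dv <- side_values(arr$left, spec) - side_values(arr$right, spec)
  p_chosen <- stats::plogis(arr$sign * dv / spec$tau)
  -sum(log(pmax(p_chosen, 1e-12)))
}

#' Negative log-likelihood of a trial table under a model
#'
#' Sums the per-trial Bernoulli log-likelihoods of the observed choices
#' under the logistic discrete-choice rule, with probabilities clipped to
#' `[1e-12, 1 - 1e-12]` so the result is always finite.
#'
#' @param trials a trial table (see [simulate_experiment()] /
#'   [read_trials()]).
#' @param spec a [model_spec()].
#' @return The negative log-likelihood (scalar).
#' @export
negative_log_likelihood <- function(trials, spec) {
  if (nrow(trials) == 0L) stop("no trials to score")
  nll_arrays(trial_arrays(trials, spec$m0), spec)
}

# parameter <-> optimizer-scale transforms (log for positive parameters)
par_pack <- function(spec) {
  nm <- model_params(spec$kind)
  v <- unlist(spec[nm])
  ifelse(nm == "beta", v, log(v))
}

par_unpack <- function(theta, kind, m0) {
  nm <- model_params(kind)
  v <- ifelse(nm == "beta", theta, exp(theta))
  args <- as.list(v)
  names(args) <- nm
  do.call(model_spec, c(list(kind = kind, m0 = m0), args))
}

#' Fit a value model to single-trial choices by maximum likelihood
#'
#' Minimizes the negative log-likelihood with the Nelder-Mead simplex from
#' multiple seeded starting points (positive parameters are optimized on the
#' log scale; the mean-variance risk coefficient is unconstrained). One-
#' parameter families use Brent's method. Standard errors come from the
#' numerical Hessian at the optimum; Wald 95% confidence intervals are
#' reported on the natural scale.
#'
#' @param trials a trial table.
#' @param kind model family (see [model_spec()]).
#' @param n_starts number of optimizer starts (>= 1); the first is a
#'   canonical initialization, the rest are seeded log-normal jitters.
#' @param seed integer seed for the jittered starts.
#' @param m0 normalizing magnitude (ml).
#' @param init optional [model_spec()] overriding the canonical start.
#' @return An object of class `"model_fit"`: list with `spec` (fitted),
#'   `log_likelihood`, `n_trials`, `n_params`, `bic`, `aic`, `estimates`
#'   (data.frame with `estimate`, `se`, `ci_low`, `ci_high` per parameter),
#'   and `convergence`.
#' @export
fit_model_mle <- function(trials, kind, n_starts = 5L, seed = 1L,
                          m0 = 0.5, init = NULL) {
  n <- nrow(trials)
  if (is.null(n) || n == 0L) stop("no trials to fit")
  nm <- model_params(kind)
  k <- length(nm)
  if (n < 10L * k)
    warning("fewer than 10 trials per free parameter; estimates may be ",
            "unstable")
  arr <- trial_arrays(trials, m0)
  if (kind %in% c("PW", "additive") && any(arr$multi_nonzero))
    stop("trial ", which(arr$multi_nonzero)[1L], ": PW/additive models ",
         "cannot score gambles with >= 2 distinct non-zero outcomes")
  obj <- function(theta) {
    val <- tryCatch(nll_arrays(arr, par_unpack(theta, kind, m0)),
                    error = function(e) NA_real_)
    if (!is.finite(val)) 1e10 else val
  }

  if (is.null(init)) init <- model_spec(kind, tau = 0.2, m0 = m0)
  theta0 <- par_pack(init)
  starts <- list(theta0)
  if (n_starts > 1L) {
    rs <- local({
      set.seed(seed)
      lapply(seq_len(n_starts - 1L),
             function(i) theta0 + stats::rnorm(k, 0, 0.7))
    })
    starts <- c(starts, rs)
  }

  best <- NULL
  conv <- integer(0)
  for (th in starts) {
    fit <- if (k == 1L) {
      stats::optim(th, obj, method = "Brent", lower = th - 8, upper = th + 8)
    } else {
      stats::optim(th, obj, method = "Nelder-Mead",
                   control = list(maxit = 1000L, reltol = 1e-9))
    }
    conv <- c(conv, fit$convergence)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || best$value >= 1e10)
    stop("model fit failed to converge for kind ", kind,
         " (all ", length(starts), " starts degenerate)")

  theta_hat <- best$par
  spec_hat <- par_unpack(theta_hat, kind, m0)
  ll <- -best$value

  se_nat <- rep(NA_real_, k)
  H <- tryCatch(stats::optimHess(theta_hat, obj), error = function(e) NULL)
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V)) {
      se_theta <- sqrt(pmax(diag(as.matrix(V)), 0))
      est_nat <- unlist(spec_hat[nm])
      # delta method: d exp(theta)/d theta = exp(theta)
      se_nat <- ifelse(nm == "beta", se_theta, est_nat * se_theta)
    }
  }
  est <- unlist(spec_hat[nm])
  z <- stats::qnorm(0.975)
  ests <- data.frame(parameter = nm, estimate = est, se = se_nat,
                     ci_low = ifelse(nm == "beta", est - z * se_nat,
                                     est * exp(-z * se_nat / pmax(est, 1e-12))),
                     ci_high = ifelse(nm == "beta", est + z * se_nat,
                                      est * exp(z * se_nat / pmax(est, 1e-12))),
                     row.names = NULL)

  structure(list(spec = spec_hat, log_likelihood = ll, n_trials = n,
                 n_params = k,
                 bic = k * log(n) - 2 * ll,
                 aic = 2 * k - 2 * ll,
                 estimates = ests,
                 convergence = conv),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> %s: LL = %.2f, BIC = %.2f, AIC = %.2f (n = %d)\n",
              x$spec$kind, x$log_likelihood, x$bic, x$aic, x$n_trials))
  print(x$estimates)
  invisible(x)
}

#' Model-predicted indifference point for a probe magnitude
#'
#' Numerically inverts the value model: for the reference gamble B, finds
#' the probability `p` at which the two-outcome gamble `{(probe, p),
#' (0, 1 - p)}` matches B's subjective value, by grid search over
#' `p = p_step, 2 p_step, ..., 1` (ties broken toward the smaller `p`).
#'
#' @param b_gamble the reference gamble B.
#' @param probe_magnitude probe magnitude in ml (>= B's magnitude for a
#'   well-defined IP under increasing utility).
#' @param spec a [model_spec()].
#' @param p_step probability grid step (default 0.001).
#' @return The indifference probability, or `NA` (with a warning) when even
#'   the sure probe (`p = 1`) falls short of B's value.
#' @export
predict_indifference_point <- function(b_gamble, probe_magnitude, spec,
                                       p_step = 0.001) {
  vB <- gamble_value(b_gamble, spec)
  p <- seq(p_step, 1, by = p_step)
  v <- value_mp(probe_magnitude, p, spec)
  if (vB > max(v) + 1e-12) {
    warning("probe magnitude ", probe_magnitude,
            " cannot reach the reference value; IP undefined")
    return(NA_real_)
  }
  p[which.min(abs(v - vB))]
}

#' Model-predicted indifference map
#'
#' Builds one model-predicted indifference curve per reference gamble B by
#' sweeping probe magnitudes (default step 0.001 ml, as in the numerical
#' IP-construction procedure) and recording the indifference probability at
#' each probe ([predict_indifference_point()]).
#'
#' @param spec a [model_spec()].
#' @param b_gambles list of reference gambles (or numeric magnitudes, taken
#'   as degenerate gambles).
#' @param magnitude_max largest probe magnitude (default `spec$m0`).
#' @param m_step,p_step grid steps in ml and probability.
#' @return A data.frame of class `"indifference_map"` with columns `b`
#'   (label), `magnitude`, `probability`.
#' @export
build_indifference_map <- function(spec, b_gambles,
                                   magnitude_max = spec$m0,
                                   m_step = 0.001, p_step = 0.001) {
  if (is.numeric(b_gambles)) b_gambles <- lapply(b_gambles, degenerate)
  p <- seq(p_step, 1, by = p_step)
  out <- lapply(seq_along(b_gambles), function(i) {
    B <- b_gambles[[i]]
    vB <- gamble_value(B, spec)
    m_start <- max(B$m)
    probes <- seq(m_start, magnitude_max, by = m_step)
    V <- outer(probes, p, function(mm, pp) value_mp(mm, pp, spec))
    ip <- p[apply(abs(V - vB), 1L, which.min)]
    ip[vB > apply(V, 1L, max) + 1e-12] <- NA_real_
    data.frame(b = format_gamble(B), magnitude = probes, probability = ip)
  })
  res <- do.call(rbind, out)
  class(res) <- c("indifference_map", "data.frame")
  attr(res, "spec") <- spec
  res
}

#' @export
plot.indifference_map <- function(x, ...) {
  bs <- unique(x$b)
  cols <- grDevices::hcl.colors(max(length(bs), 2L), "Dark 2")
  plot(NULL, xlim = range(x$probability, na.rm = TRUE),
       ylim = range(x$magnitude), xlab = "reward probability",
       ylab = "reward magnitude (ml)", main = "Indifference map", ...)
  for (i in seq_along(bs)) {
    d <- x[x$b == bs[i], ]
    graphics::lines(d$probability, d$magnitude, col = cols[i], lwd = 2)
  }
  invisible(x)
}

# model-implied indifference mixture probability for a continuity test:
# the p minimizing |V(mix(A, C, p)) - V(B)| on a probability grid
model_ip <- function(spec, A, B, C, p_step = 0.001) {
  vB <- gamble_value(B, spec)
  p <- seq(0, 1, by = p_step)
  deg0 <- function(g) length(g$m) == 1L && g$m <= 1e-12
  v <- if (length(A$m) == 1L && deg0(C)) {
    value_mp(A$m, p, spec)
  } else {
    vapply(p, function(q) gamble_value(mix_gambles(A, C, q), spec), 0)
  }
  p[which.min(abs(v - vB))]
}

#' Compare fitted value models on shared data
#'
#' Computes the four model-comparison metrics (lower is better for all):
#' BIC and AIC from the fits; `rmse_ip`, the root mean squared distance in
#' probability units between model-implied and measured indifference points
#' across the supplied continuity tests; and `var_pref`, the variance of the
#' differences between model-predicted and observed AC-choice proportions
#' across all (test, pA-level) conditions.
#'
#' @param fits list of [fit_model_mle()] results on the same trial set.
#' @param continuity_tests list of [test_continuity()] results supplying the
#'   measured indifference points and per-level choice proportions.
#' @return A data.frame of class `"model_comparison"` with one row per
#'   model and attribute `"best_bic"` naming the BIC-best family.
#' @export
compare_models <- function(fits, continuity_tests = NULL) {
  if (length(fits) < 2L) stop("need at least two fits to compare")
  ns <- vapply(fits, function(f) f$n_trials, 0)
  if (length(unique(ns)) != 1L)
    stop("fits were obtained on different trial sets; metrics not comparable")

  one <- function(f) {
    rmse <- NA_real_
    vp <- NA_real_
    if (length(continuity_tests)) {
      errs <- vapply(continuity_tests, function(ct) {
        pred <- model_ip(f$spec, ct$gambles$A, ct$gambles$B, ct$gambles$C)
        pred - ct$ip$alpha
      }, 0)
      rmse <- sqrt(mean(errs^2))
      diffs <- unlist(lapply(continuity_tests, function(ct) {
        ok <- ct$n > 0L
        pred <- vapply(ct$levels[ok], function(q)
          choice_probability(mix_gambles(ct$gambles$A, ct$gambles$C, q),
                             ct$gambles$B, f$spec), 0)
        pred - ct$k[ok] / ct$n[ok]
      }))
      vp <- stats::var(diffs)
    }
    data.frame(model = f$spec$kind, n_params = f$n_params,
               log_likelihood = f$log_likelihood, bic = f$bic, aic = f$aic,
               rmse_ip = rmse, var_pref = vp)
  }
  res <- do.call(rbind, lapply(fits, one))
  class(res) <- c("model_comparison", "data.frame")
  attr(res, "best_bic") <- res$model[which.min(res$bic)]
  res
}

#' Cross-correlation of indifference points across sessions
#'
#' Tests whether indifference points co-vary across sessions (as expected
#' when a single drifting utility function generates the whole indifference
#' map). Computes the Pearson correlation for every pair of IP series over
#' sessions (pairwise-complete, requiring >= 3 shared sessions), groups
#' pairs into within-IC (same reference gamble B) and across-IC, and runs a
#' one-sample t test of the mean correlation against zero in each group.
#'
#' @param ip_matrix numeric matrix, sessions x IPs (NA allowed).
#' @param ic vector of IC labels (one per column); columns sharing a label
#'   belong to the same indifference curve. Default: all distinct.
#' @return List with `pairs` (data.frame of pairwise correlations), and per
#'   group the mean correlation, t statistic and p value.
#' @export
ip_cross_correlation <- function(ip_matrix, ic = seq_len(ncol(ip_matrix))) {
  ip_matrix <- as.matrix(ip_matrix)
  if (ncol(ip_matrix) < 2L) stop("need at least two IP series")
  if (nrow(ip_matrix) < 3L) stop("need at least three sessions")
  if (length(ic) != ncol(ip_matrix))
    stop("ic labels must match the IP columns")
  cmb <- utils::combn(ncol(ip_matrix), 2L)
  rows <- lapply(seq_len(ncol(cmb)), function(j) {
    i1 <- cmb[1L, j]; i2 <- cmb[2L, j]
    ok <- stats::complete.cases(ip_matrix[, c(i1, i2)])
    if (sum(ok) < 3L) {
      message("skipping IP pair (", i1, ", ", i2, "): fewer than 3 ",
              "overlapping sessions")
      return(NULL)
    }
    data.frame(ip1 = i1, ip2 = i2, n = sum(ok),
               rho = stats::cor(ip_matrix[ok, i1], ip_matrix[ok, i2]),
               within_ic = ic[i1] == ic[i2])
  })
  pairs <- do.call(rbind, rows)
  if (is.null(pairs)) stop("no IP pair had enough overlapping sessions")
  grp <- function(w) {
    r <- pairs$rho[pairs$within_ic == w]
    if (length(r) < 2L || stats::sd(r) < 1e-12)
      return(list(mean_rho = mean(r), t = NA_real_, p_value = NA_real_,
                  n_pairs = length(r)))
    tt <- stats::t.test(r, mu = 0)
    list(mean_rho = mean(r), t = unname(tt$statistic),
         p_value = tt$p.value, n_pairs = length(r))
  }
  list(pairs = pairs, within_ic = grp(TRUE), across_ic = grp(FALSE),
       mean_rho = mean(pairs$rho))
}
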
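#' Estimate an indifference point by softmax fit
#'
#' Fits the psychometric softmax
#' `P(AC)(pA) = 1 / (1 + exp(-(pA - alpha) / tau))` to per-level choice
#' proportions by least squares weighted by the per-level trial counts (so
#' unequal repeats are handled). `alpha` is the indifference point: the
#' fitted curve crosses 0.5 exactly at `alpha` by construction. `tau` is
#' the softmax temperature (steepness; optimized on the log scale within
#' `[1e-4, 10]`). The confidence interval on `alpha` comes from a seeded
#' nonparametric bootstrap over trials (resampling choices within each
#' level).
#'
#' When every proportion lies on one side of 0.5 the curve has no crossing
#' inside the data; the fit is still returned but `alpha` is extrapolated
#' and flagged (`extrapolated = TRUE`, with a warning).
#'
#' @param levels pA grid (>= 3 levels).
#' @param k choices of the AC option per level.
#' @param n trials per level (>= 1 each).
#' @param init_alpha optional starting value for `alpha` (e.g. an
#'   EV-predicted indifference point); default: the interpolated 0.5
#'   crossing of the observed proportions.
#' @param boot bootstrap resamples for the CI (default 1000; 0 skips).
#' @param seed seed for the bootstrap.
#' @param conf confidence level.
#' @return An object of class `"indifference_point"`: list with `alpha`,
#'   `tau`, `ci_low`, `ci_high`, `n_trials`, `sse` (weighted), and
#'   `extrapolated`.
#' @export
fit_softmax_ip <- function(levels, k, n, init_alpha = NULL, boot = 1000L,
                           seed = 1L, conf = 0.95) {
  if (length(levels) < 3L) stop("need at least 3 levels")
  if (length(k) != length(levels) || length(n) != length(levels))
    stop("levels, k, n must have equal length")
  if (any(n < 1L)) stop("each level needs at least one trial")
  if (any(k < 0 | k > n)) stop("k must lie in [0, n] per level")
  o <- order(levels)
  levels <- levels[o]; k <- k[o]; n <- n[o]
  prop <- k / n

  crossing_init <- function(pr) {
    above <- pr > 0.5
    if (all(above) || all(!above)) return(NA_real_)
    i <- which(diff(above) != 0)[1L]
    x1 <- levels[i]; x2 <- levels[i + 1L]
    y1 <- pr[i]; y2 <- pr[i + 1L]
    if (abs(y2 - y1) < 1e-12) (x1 + x2) / 2
    else x1 + (0.5 - y1) * (x2 - x1) / (y2 - y1)
  }

  fit_once <- function(kk) {
    pr <- kk / n
    a0 <- if (!is.null(init_alpha)) init_alpha else crossing_init(pr)
    if (is.na(a0)) a0 <- stats::weighted.mean(levels, n)
    obj <- function(par) {
      alpha <- par[1L]
      tau <- exp(par[2L])
      sum(n * (pr - stats::plogis((levels - alpha) / tau))^2)
    }
    sp <- diff(range(levels))
    opt <- stats::optim(c(a0, log(0.1)), obj, method = "L-BFGS-B",
                        lower = c(min(levels) - sp, log(1e-4)),
                        upper = c(max(levels) + sp, log(10)))
    c(alpha = opt$par[1L], tau = exp(opt$par[2L]), sse = opt$value)
  }

  est <- fit_once(k)
  extrapolated <- all(prop > 0.5) || all(prop < 0.5)
  if (extrapolated)
    warning("choice proportions never cross 0.5; indifference point is ",
            "extrapolated")

  ci <- c(NA_real_, NA_real_)
  if (boot > 0L) {
    set.seed(seed)
    ab <- vapply(seq_len(boot), function(b) {
      kk <- stats::rbinom(length(n), n, prop)
      fit_once(kk)[["alpha"]]
    }, 0)
    ci <- stats::quantile(ab, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          names = FALSE)
  }
  structure(list(alpha = unname(est[["alpha"]]), tau = unname(est[["tau"]]),
                 ci_low = ci[1L], ci_high = ci[2L], n_trials = sum(n),
                 sse = unname(est[["sse"]]), extrapolated = extrapolated,
                 levels = levels, k = k, n = n),
            class = "indifference_point")
}

#' @export
print.indifference_point <- function(x, ...) {
  cat(sprintf("<indifference_point> alpha = %.4f, tau = %.4f (n = %d%s)",
              x$alpha, x$tau, x$n_trials,
              if (x$extrapolated) ", extrapolated" else ""))
  if (!is.na(x$ci_low))
    cat(sprintf(", 95%% CI [%.4f, %.4f]", x$ci_low, x$ci_high))
  cat("\n")
  invisible(x)
}

ic_forms <- c("linear", "power", "hyperbolic")

ic_predict <- function(params, form, x) {
  switch(form,
         linear = params[["a"]] * x + params[["b"]],
         power = params[["a"]] * (x - params[["c"]])^params[["b"]],
         hyperbolic = params[["a"]] + params[["b"]] / (x - params[["c"]]))
}

#' Fit an indifference curve to a set of indifference points
#'
#' Fits reward probability as a function of reward magnitude over a set of
#' indifference points, by least squares in the probability domain, using
#' one of three forms: linear `a x + b`, power `a (x - c)^b`, or hyperbolic
#' `a + b / (x - c)`. The power/hyperbolic fits use bounded
#' Levenberg-Marquardt (`minpack.lm::nlsLM`) with the shift `c` constrained
#' to `[0, min(x))` so the power base stays positive.
#'
#' @param magnitudes,probabilities coordinates of the indifference points
#'   (or pass a list of [fit_softmax_ip()] objects via `ips` together with
#'   `magnitudes`).
#' @param form one of `"linear"`, `"power"`, `"hyperbolic"`.
#' @return An object of class `"indifference_curve"`: list with `form`,
#'   `params` (named), `mse` (probability^2 units), `fitted`, and a
#'   `predict` closure.
#' @export
fit_indifference_curve <- function(magnitudes, probabilities,
                                   form = c("linear", "power",
                                            "hyperbolic")) {
  form <- match.arg(form)
  x <- as.numeric(magnitudes)
  y <- as.numeric(probabilities)
  if (length(x) != length(y)) stop("coordinate lengths differ")
  n_par <- if (form == "linear") 2L else 3L
  if (length(x) < n_par)
    stop("need at least ", n_par, " indifference points for the ",
         form, " form")
  if (length(unique(x)) < 2L)
    stop("indifference-curve fit is degenerate: all magnitudes equal")

  # bounded least squares used when the Levenberg-Marquardt path fails
  # (e.g. a singular gradient at an already-perfect start)
  optim_fallback <- function(start, lower, upper, fn) {
    opt <- stats::optim(start, fn, method = "L-BFGS-B", lower = lower,
                        upper = upper)
    opt$par
  }

  if (form == "linear") {
    fit <- stats::lm(y ~ x)
    params <- c(a = unname(stats::coef(fit)[2L]),
                b = unname(stats::coef(fit)[1L]))
  } else {
    d <- data.frame(x = x, y = y)
    xmin <- min(x)
    if (form == "power") {
      # log-log slope as starting exponent (guarded for non-positive y)
      pos <- y > 0
      b0 <- if (sum(pos) >= 2L)
        unname(stats::coef(stats::lm(log(y[pos]) ~ log(x[pos])))[2L])
      else -1
      a0 <- exp(mean(log(pmax(y[pos], 1e-6)) - b0 * log(x[pos])))
      fit <- tryCatch(
        minpack.lm::nlsLM(y ~ a * (x - c)^b, data = d,
                          start = list(a = a0, b = b0, c = 0),
                          lower = c(1e-8, -10, 0),
                          upper = c(Inf, 10, xmin - 1e-6),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      params <- if (!is.null(fit)) stats::coef(fit)
      else stats::setNames(optim_fallback(
        c(a0, b0, 0), c(1e-8, -10, 0), c(Inf, 10, xmin - 1e-6),
        function(pp) sum((y - pp[1L] * (x - pp[3L])^pp[2L])^2)),
        c("a", "b", "c"))
    } else {
      lf <- stats::lm(y ~ I(1 / x))
      st <- c(unname(stats::coef(lf)[1L]), unname(stats::coef(lf)[2L]), 0)
      fit <- tryCatch(
        minpack.lm::nlsLM(y ~ a + b / (x - c), data = d,
                          start = list(a = st[1L], b = st[2L], c = st[3L]),
                          lower = c(-Inf, -Inf, -Inf),
                          upper = c(Inf, Inf, xmin - 1e-6),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      params <- if (!is.null(fit)) stats::coef(fit)
      else stats::setNames(optim_fallback(
        st, c(-Inf, -Inf, -Inf), c(Inf, Inf, xmin - 1e-6),
        function(pp) sum((y - pp[1L] - pp[2L] / (x - pp[3L]))^2)),
        c("a", "b", "c"))
    }
    if (!all(is.finite(params)))
      stop(form, " indifference-curve fit failed (non-finite parameters)")
  }
  fitted <- ic_predict(params, form, x)
  structure(list(form = form, params = params,
                 mse = mean((y - fitted)^2),
                 magnitudes = x, probabilities = y, fitted = fitted),
            class = "indifference_curve")
}

#' @export
print.indifference_curve <- function(x, ...) {
  cat(sprintf("<indifference_curve> %s: %s | MSE = %.3g\n", x$form,
              paste(sprintf("%s = %.4g", names(x$params), x$params),
                    collapse = ", "), x$mse))
  invisible(x)
}

#' @export
predict.indifference_curve <- function(object, newdata, ...) {
  x <- if (is.list(newdata)) newdata$magnitude else newdata
  ic_predict(object$params, object$form, x)
}

#' Leave-one-out coverage of an indifference-curve fit
#'
#' For each indifference point, refits the curve without it, builds a
#' bootstrap confidence band at the left-out magnitude (pairs bootstrap of
#' the remaining points, percentile interval of the predicted probability),
#' and records whether the left-out probability falls inside the band.
#'
#' @param magnitudes,probabilities the indifference points (>= 4).
#' @param form curve form, see [fit_indifference_curve()].
#' @param boot bootstrap resamples per left-out point.
#' @param conf band confidence level.
#' @param seed bootstrap seed.
#' @return List with `coverage` (fraction covered), `covered` (logical per
#'   point) and the band bounds.
#' @export
loo_coverage <- function(magnitudes, probabilities,
                         form = c("linear", "power", "hyperbolic"),
                         boot = 200L, conf = 0.95, seed = 1L) {
  form <- match.arg(form)
  x <- as.numeric(magnitudes)
  y <- as.numeric(probabilities)
  if (length(x) < 4L) stop("leave-one-out coverage needs at least 4 points")
  set.seed(seed)
  lo <- numeric(length(x))
  hi <- numeric(length(x))
  for (i in seq_along(x)) {
    xr <- x[-i]; yr <- y[-i]
    preds <- vapply(seq_len(boot), function(b) {
      idx <- sample.int(length(xr), replace = TRUE)
      fit <- tryCatch(fit_indifference_curve(xr[idx], yr[idx], form),
                      error = function(e) NULL)
      if (is.null(fit)) NA_real_ else ic_predict(fit$params, form, x[i])
    }, 0)
    preds <- preds[is.finite(preds)]
    if (length(preds) < boot / 4)
      stop("too many bootstrap refits failed for point ", i)
    qs <- stats::quantile(preds, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          names = FALSE)
    lo[i] <- qs[1L]; hi[i] <- qs[2L]
  }
  covered <- y >= lo & y <= hi
  list(coverage = mean(covered), covered = covered, lower = lo, upper = hi)
}

#' Within-session change of the indifference point
#'
#' Splits each session's continuity-test trials at the midpoint of the
#' trial order (the middle trial of an odd count goes to the first half),
#' estimates the indifference point separately in each half, and tests the
#' per-session differences `alpha(second half) - alpha(first half)` against
#' zero with a one-sample t test. Sessions in which either half cannot be
#' fitted are excluded with a message.
#'
#' @param trials trial table covering one continuity test across sessions.
#' @param A,B,C the test gambles.
#' @param levels pA grid of the test.
#' @return List with `delta` (per-session IP changes), `sessions`,
#'   `mean_delta`, `t`, `p_value`, `df`.
#' @export
within_session_ip_change <- function(trials, A, B, C,
                                     levels = seq(0, 1, by = 0.1)) {
  sess <- sort(unique(trials$session))
  half_ip <- function(tt) {
    ct <- test_continuity(tt, A, B, C, levels = levels, fit_ip = TRUE,
                          boot = 0L)
    if (is.null(ct$ip)) stop("IP fit failed")
    ct$ip$alpha
  }
  deltas <- numeric(0)
  used <- integer(0)
  for (s in sess) {
    tt <- trials[trials$session == s, ]
    tt <- tt[order(tt$trial), ]
    nh <- ceiling(nrow(tt) / 2)
    d <- tryCatch({
      a1 <- suppressWarnings(half_ip(tt[seq_len(nh), ]))
      a2 <- suppressWarnings(half_ip(tt[(nh + 1L):nrow(tt), ]))
      a2 - a1
    }, error = function(e) {
      message("session ", s, " excluded from IP-change analysis: ",
              conditionMessage(e))
      NA_real_
    })
    if (!is.na(d)) {
      deltas <- c(deltas, d)
      used <- c(used, s)
    }
  }
  if (length(deltas) < 2L)
    stop("need at least two sessions with estimable IP halves")
  if (length(deltas) == 2L)
    warning("only two sessions available; t test has 1 degree of freedom")
  tt <- stats::t.test(deltas, mu = 0)
  list(delta = deltas, sessions = used, mean_delta = mean(deltas),
       t = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter))
}

#' Moving average of an indifference-point series
#'
#' Centered moving average across sessions (default 5-session window), with
#' windows shortened symmetrically at the edges so the output has the same
#' length as the input.
#'
#' @param ips numeric vector of per-session indifference points.
#' @param window odd window width (default 5).
#' @return Numeric vector of smoothed values.
#' @export
ip_session_series <- function(ips, window = 5L) {
  if (window < 1L || window %% 2L == 0L) stop("window must be odd and >= 1")
  n <- length(ips)
  h <- window %/% 2L
  vapply(seq_len(n), function(i) {
    mean(ips[max(1L, i - h):min(n, i + h)], na.rm = TRUE)
  }, 0)
}
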
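# scalar (m, p) encoding of a gamble for the choice regression:
# degenerate -> (m, 1); two-outcome with a zero outcome -> the non-zero
# outcome's (m, p); anything else -> (EV, 1), flagged
encode_side <- function(g) {
  nz <- g$m > 1e-12
  if (length(g$m) == 1L)
    return(c(m = g$m, p = 1, complex = 0))
  if (length(g$m) == 2L && sum(nz) == 1L)
    return(c(m = g$m[nz], p = g$p[nz], complex = 0))
  c(m = expected_value(g), p = 1, complex = 1)
}

regression_frame <- function(trials) {
  enc <- function(col) {
    gs <- parse_gamble(trials[[col]])
    if (is_gamble(gs)) gs <- list(gs)
    t(vapply(gs, encode_side, c(m = 0, p = 0, complex = 0)))
  }
  L <- enc("gamble_left")
  R <- enc("gamble_right")
  data.frame(y = as.integer(trials$chosen_side == "R"),
             m_L = L[, "m"], p_L = L[, "p"],
             m_R = R[, "m"], p_R = R[, "p"],
             prev = trials$prev_choice * trials$prev_reward,
             complex = L[, "complex"] + R[, "complex"] > 0)
}

#' Single-trial logistic regression of choice
#'
#' Fits the choice-consistency regression
#' `logit P(right) = b0 + b1 m_L + b2 p_L + b3 m_R + b4 p_R +
#' b5 prevCh * prevRew` by maximum likelihood (`glm`, binomial). `m` and
#' `p` are the scalar magnitude/probability encoding of each side's gamble
#' (degenerate: its magnitude and 1; two-outcome with a zero outcome: the
#' non-zero outcome's magnitude and probability; other gambles enter
#' through their expected value with p = 1 and the result is flagged).
#' `prevCh` is -1/+1 for a previous left/right choice (0 on the first trial
#' of a session) and `prevRew` the previously delivered reward in ml.
#'
#' When complete separation is detected the fit is repeated with a small
#' ridge penalty on the coefficients and flagged.
#'
#' @param trials a trial table.
#' @return An object of class `"choice_regression"`: `coefficients` (raw),
#'   `standardized` (see [standardize_coefficients()]), `n_trials`,
#'   `separation`, `complex_gambles` flag, and the underlying `glm` fit
#'   (absent after a penalized refit).
#' @export
fit_choice_logistic <- function(trials) {
  if (nrow(trials) < 50L)
    warning("fewer than 50 trials; regression estimates will be unstable")
  df <- regression_frame(trials)
  X <- as.matrix(df[c("m_L", "p_L", "m_R", "p_R", "prev")])
  if (qr(cbind(1, X))$rank < ncol(X) + 1L)
    warning("design matrix is rank deficient; some coefficients are ",
            "not identifiable")

  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ m_L + p_L + m_R + p_R + prev, data = df,
               family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  beta <- stats::coef(fit)

  if (separation) {
    # ridge-penalized refit keeps coefficients finite under separation
    pen_nll <- function(b) {
      eta <- b[1L] + X %*% b[-1L]
      p <- stats::plogis(eta)
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      -sum(df$y * log(p) + (1 - df$y) * log(1 - p)) + 0.5 * sum(b[-1L]^2)
    }
    b0 <- ifelse(is.finite(beta) & abs(beta) < 10, beta, 0)
    opt <- stats::optim(b0, pen_nll, method = "BFGS",
                        control = list(maxit = 500L))
    beta <- opt$par
    fit <- NULL
  }
  names(beta) <- c("intercept", "m_L", "p_L", "m_R", "p_R", "prev")

  res <- structure(list(coefficients = beta, n_trials = nrow(trials),
                        separation = separation,
                        complex_gambles = any(df$complex),
                        glm = fit),
                   class = "choice_regression")
  res$standardized <- standardize_coefficients(res, trials)
  res
}

#' Standardize regression coefficients
#'
#' Multiplies each raw coefficient by the ratio of its regressor's SD to
#' the SD of the 0/1 right-choice indicator, so that coefficients are
#' comparable across regressors and sessions. The intercept has no
#' regressor and is excluded (`NA`); zero-variance regressors are also
#' flagged `NA`.
#'
#' @param result a [fit_choice_logistic()] result.
#' @param trials the trial table it was fitted on.
#' @return Named numeric vector of standardized coefficients.
#' @export
standardize_coefficients <- function(result, trials) {
  df <- regression_frame(trials)
  sdy <- stats::sd(df$y)
  nm <- c("m_L", "p_L", "m_R", "p_R", "prev")
  std <- c(intercept = NA_real_,
           vapply(nm, function(v) {
             sdx <- stats::sd(df[[v]])
             if (sdx == 0 || sdy == 0) NA_real_
             else unname(result$coefficients[v]) * sdx / sdy
           }, 0))
  std
}

#' @export
print.choice_regression <- function(x, ...) {
  cat(sprintf("<choice_regression> n = %d%s\n", x$n_trials,
              if (x$separation) " (separation; ridge-penalized)" else ""))
  print(round(rbind(raw = x$coefficients, standardized = x$standardized),
              4L))
  invisible(x)
}

#' Population-level tests of the regression coefficients
#'
#' Given per-session regression results, tests each coefficient against
#' zero across sessions: one-sample t tests on the standardized
#' coefficients (raw intercept, which has no standardized form), BH-FDR
#' corrected across the six coefficients, with 95% confidence intervals.
#'
#' @param results list of [fit_choice_logistic()] results (>= 3 sessions).
#' @param q FDR level.
#' @return data.frame with one row per coefficient: `mean`, `t`,
#'   `p_value`, `p_adjusted`, `significant`, `ci_low`, `ci_high`,
#'   `n_sessions`.
#' @export
population_beta_tests <- function(results, q = 0.05) {
  if (length(results) < 3L) stop("need results from at least 3 sessions")
  nm <- c("intercept", "m_L", "p_L", "m_R", "p_R", "prev")
  mat <- t(vapply(results, function(r) {
    v <- r$standardized
    v["intercept"] <- r$coefficients[["intercept"]]
    v[nm]
  }, stats::setNames(numeric(6L), nm)))
  rows <- lapply(nm, function(v) {
    x <- mat[, v]
    x <- x[is.finite(x)]
    if (length(x) < 3L)
      return(data.frame(coefficient = v, mean = mean(x), t = NA_real_,
                        p_value = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, n_sessions = length(x)))
    tt <- stats::t.test(x, mu = 0)
    data.frame(coefficient = v, mean = mean(x), t = unname(tt$statistic),
               p_value = tt$p.value, ci_low = tt$conf.int[1L],
               ci_high = tt$conf.int[2L], n_sessions = length(x))
  })
  res <- do.call(rbind, rows)
  fdr <- bh_fdr(res$p_value, q = q)
  res$p_adjusted <- fdr$p_adjusted
  res$significant <- fdr$reject
  res
}
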
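#' Exact binomial preference test
#'
#' Stochastic interpretation of a deterministic preference: option 1 is
#' preferred to option 2 when the proportion of option-1 choices exceeds
#' 0.5 by an exact two-sided binomial test. The direction is assigned from
#' the point estimate only when the test is significant; otherwise the pair
#' is classed as indifferent. The 95% confidence interval is Clopper-
#' Pearson.
#'
#' @param k number of choices for option 1.
#' @param n total trials (>= 1).
#' @param alpha significance threshold (default 0.05).
#' @param conf confidence level for the interval.
#' @return An object of class `"preference_result"`: list with `k`, `n`,
#'   `proportion`, `ci_low`, `ci_high`, `p_value`, `direction` (one of
#'   `"preferred"`, `"dispreferred"`, `"indifferent"`).
#' @export
binomial_preference <- function(k, n, alpha = 0.05, conf = 0.95) {
  if (length(n) != 1L || is.na(n) || n < 1L) stop("n must be >= 1")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  bt <- stats::binom.test(k, n, p = 0.5, conf.level = conf)
  direction <- if (bt$p.value < alpha) {
    if (k / n > 0.5) "preferred" else "dispreferred"
  } else "indifferent"
  structure(list(k = k, n = n, proportion = k / n,
                 ci_low = bt$conf.int[1L], ci_high = bt$conf.int[2L],
                 p_value = bt$p.value, direction = direction),
            class = "preference_result")
}

#' @export
print.preference_result <- function(x, ...) {
  cat(sprintf("<preference> %d/%d = %.3f [%.3f, %.3f], p = %.4g -> %s\n",
              x$k, x$n, x$proportion, x$ci_low, x$ci_high, x$p_value,
              x$direction))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up FDR correction over a family of p values; a thin wrapper around
#' `stats::p.adjust(method = "BH")` that also returns the rejection flags
#' at level `q`.
#'
#' @param p_values numeric vector of p values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return List with `p_adjusted` (monotone BH-adjusted p values) and
#'   `reject` (logical flags, `p_adjusted <= q`).
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]")
  adj <- stats::p.adjust(p_values, method = "BH")
  list(p_adjusted = adj, reject = !is.na(adj) & adj <= q)
}

# group a trial table by unordered gamble pair; returns per-pair counts of
# choices for the pair's first gamble
pair_counts <- function(trials) {
  key1 <- pmin(trials$gamble_left, trials$gamble_right)
  key2 <- pmax(trials$gamble_left, trials$gamble_right)
  key <- paste(key1, key2, sep = "|")
  chose_first <- ifelse(trials$gamble_left == key1,
                        trials$chosen_side == "L",
                        trials$chosen_side == "R")
  agg <- stats::aggregate(chose_first,
                          by = list(key = key, g1 = key1, g2 = key2),
                          FUN = function(v) c(sum(v), length(v)))
  data.frame(g1 = agg$g1, g2 = agg$g2,
             k = agg$x[, 1L], n = agg$x[, 2L], stringsAsFactors = FALSE)
}

#' First-order stochastic dominance test battery
#'
#' Groups a trial table by gamble pair, requires one gamble of each pair to
#' first-order stochastically dominate the other, and tests whether the
#' dominant option was preferred: per-pair exact binomial tests plus a
#' pooled compliance flag (Clopper-Pearson 95% CI of the pooled proportion
#' entirely above 0.5).
#'
#' @param trials a trial table in which every pair has an FSD relation.
#' @param alpha per-pair significance threshold.
#' @return List of class `"fsd_test"`: `per_pair` data.frame (`k`, `n`,
#'   `proportion`, `p_value`, `significant`), pooled `k`, `n`, `ci_low`,
#'   and `compliant` (pooled CI above 0.5).
#' @export
test_fsd <- function(trials, alpha = 0.05) {
  pc <- pair_counts(trials)
  rows <- lapply(seq_len(nrow(pc)), function(i) {
    g1 <- parse_gamble(pc$g1[i])
    g2 <- parse_gamble(pc$g2[i])
    if (fsd_dominates(g1, g2)) {
      k <- pc$k[i]
    } else if (fsd_dominates(g2, g1)) {
      k <- pc$n[i] - pc$k[i]
    } else {
      stop("pair (", pc$g1[i], ") vs (", pc$g2[i],
           ") has no first-order stochastic dominance relation")
    }
    pr <- binomial_preference(k, pc$n[i], alpha = alpha)
    data.frame(dominant_k = k, n = pc$n[i], proportion = pr$proportion,
               p_value = pr$p_value,
               significant = pr$direction == "preferred")
  })
  per_pair <- do.call(rbind, rows)
  pooled <- binomial_preference(sum(per_pair$dominant_k), sum(per_pair$n),
                                alpha = alpha)
  structure(list(per_pair = per_pair, pooled_k = pooled$k,
                 pooled_n = pooled$n, pooled_ci_low = pooled$ci_low,
                 compliant = pooled$ci_low > 0.5),
            class = "fsd_test")
}

#' Weak and strong stochastic transitivity
#'
#' For a triplet A, B, C with pairwise choice counts, weak stochastic
#' transitivity (WST) holds when all three proportions P(A over B),
#' P(B over C), P(A over C) significantly exceed 0.5
#' ([binomial_preference()]); strong stochastic transitivity (SST)
#' additionally requires the point estimate of P(A over C) to be at least
#' the larger of the other two.
#'
#' @param k_ab,n_ab choices of A and trials in the A-vs-B pairing.
#' @param k_bc,n_bc choices of B and trials in the B-vs-C pairing.
#' @param k_ac,n_ac choices of A and trials in the A-vs-C pairing.
#' @param alpha significance threshold.
#' @return List of class `"transitivity_test"` with `wst`, `sst`,
#'   `proportions` (named vector) and the three `preference` results.
#' @export
test_transitivity <- function(k_ab, n_ab, k_bc, n_bc, k_ac, n_ac,
                              alpha = 0.05) {
  pr_ab <- binomial_preference(k_ab, n_ab, alpha = alpha)
  pr_bc <- binomial_preference(k_bc, n_bc, alpha = alpha)
  pr_ac <- binomial_preference(k_ac, n_ac, alpha = alpha)
  props <- c(ab = pr_ab$proportion, bc = pr_bc$proportion,
             ac = pr_ac$proportion)
  wst <- pr_ab$direction == "preferred" && pr_bc$direction == "preferred" &&
    pr_ac$direction == "preferred"
  sst <- wst && props["ac"] >= max(props["ab"], props["bc"])
  structure(list(wst = wst, sst = unname(sst), proportions = props,
                 preferences = list(ab = pr_ab, bc = pr_bc, ac = pr_ac)),
            class = "transitivity_test")
}

#' @rdname test_transitivity
#' @param trials a trial table containing the three pairings.
#' @param A,B,C the triplet gambles (A assumed most preferred).
#' @export
transitivity_from_trials <- function(trials, A, B, C, alpha = 0.05) {
  pc <- pair_counts(trials)
  get <- function(g1, g2) {
    s1 <- format_gamble(g1); s2 <- format_gamble(g2)
    lo <- min(s1, s2); hi <- max(s1, s2)
    i <- which(pc$g1 == lo & pc$g2 == hi)
    if (length(i) != 1L)
      stop("pairing (", s1, ") vs (", s2, ") missing from the trial table")
    k_first <- pc$k[i]
    if (lo == s1) c(k_first, pc$n[i]) else c(pc$n[i] - k_first, pc$n[i])
  }
  ab <- get(A, B); bc <- get(B, C); ac <- get(A, C)
  test_transitivity(ab[1L], ab[2L], bc[1L], bc[2L], ac[1L], ac[2L],
                    alpha = alpha)
}

#' Stochastic test of the continuity axiom
#'
#' Implements the continuity-axiom test for ranked gambles A > B > C. The
#' trial table must contain choices between the middle gamble B and the
#' mixtures `pA * A + (1 - pA) * C` at every grid level. The test has three
#' ingredients:
#' \enumerate{
#'   \item Ranking precheck: A must be preferred to B and B to C
#'     ([binomial_preference()]); the endpoint levels `pA = 1` (AC = A) and
#'     `pA = 0` (AC = C) supply these counts when present. A failed
#'     precheck aborts with an error since the axiom's premise is not met;
#'     a missing precheck produces a warning.
#'   \item Archimedean criterion: among the interior levels
#'     (`0 < pA < 1`), at least one must be significantly dispreferred and
#'     one significantly preferred (exact binomial tests, BH-FDR corrected
#'     across the interior levels of this test). Endpoints are excluded
#'     because the axiom's Archimedean property quantifies over mixture
#'     probabilities strictly inside (0, 1); including them would let any
#'     agent that merely ranks A > B > C (e.g. a lexicographic one) pass.
#'   \item Monotonicity criterion: a significant positive trial-level
#'     Spearman rank correlation between `pA` and the AC choice across the
#'     interior levels.
#' }
#' Compliance requires both criteria. The indifference point is then
#' estimated by [fit_softmax_ip()] on all levels.
#'
#' @param trials trial table with the B-versus-mixture choices (other
#'   trials are ignored).
#' @param A,B,C the test gambles.
#' @param levels pA grid (>= 3 levels).
#' @param alpha significance threshold for the binomial and rank tests.
#' @param q FDR level across the interior levels.
#' @param fit_ip estimate the indifference point (logical).
#' @param boot bootstrap resamples for the IP confidence interval (0 to
#'   skip).
#' @param seed seed for the IP bootstrap.
#' @return An object of class `"continuity_result"`: the per-level counts
#'   (`levels`, `k`, `n`), per-level `preference` results and FDR-adjusted
#'   p values, `rank_corr_rho` / `rank_corr_p`, the criterion flags
#'   (`has_dispreferred_level`, `has_preferred_level`, `monotone`),
#'   `compliant`, the fitted `ip`, and the test `gambles`.
#' @export
test_continuity <- function(trials, A, B, C, levels = seq(0, 1, by = 0.1),
                            alpha = 0.05, q = 0.05, fit_ip = TRUE,
                            boot = 0L, seed = 1L) {
  if (length(levels) < 3L) stop("need at least 3 pA grid levels")
  levels <- sort(levels)
  sB <- format_gamble(B)
  mix_keys <- vapply(levels, function(qq)
    format_gamble(mix_gambles(A, C, qq)), "")

  k <- integer(length(levels))
  n <- integer(length(levels))
  pa_trial <- numeric(0)
  choice_trial <- integer(0)
  for (i in seq_along(levels)) {
    sel_l <- trials$gamble_left == mix_keys[i] & trials$gamble_right == sB
    sel_r <- trials$gamble_right == mix_keys[i] & trials$gamble_left == sB
    chose_ac <- c(trials$chosen_side[sel_l] == "L",
                  trials$chosen_side[sel_r] == "R")
    k[i] <- sum(chose_ac)
    n[i] <- length(chose_ac)
    pa_trial <- c(pa_trial, rep(levels[i], n[i]))
    choice_trial <- c(choice_trial, as.integer(chose_ac))
  }
  if (all(n == 0L)) stop("no B-versus-mixture trials found for this test")

  interior <- levels > 1e-9 & levels < 1 - 1e-9
  if (sum(interior & n > 0L) < 3L)
    stop("need at least 3 interior pA levels with trials")

  # ranking precheck from endpoint levels when present
  precheck <- list(ab = NULL, bc = NULL)
  i1 <- which(abs(levels - 1) <= 1e-9)
  i0 <- which(abs(levels) <= 1e-9)
  if (length(i1) && n[i1] > 0L)
    precheck$ab <- binomial_preference(k[i1], n[i1], alpha = alpha)
  if (length(i0) && n[i0] > 0L)
    precheck$bc <- binomial_preference(n[i0] - k[i0], n[i0], alpha = alpha)
  if (is.null(precheck$ab) || is.null(precheck$bc)) {
    warning("ranking precheck incomplete (endpoint levels missing); ",
            "assuming A > B > C")
  } else if (precheck$ab$direction != "preferred" ||
             precheck$bc$direction != "preferred") {
    stop("ranked-gambles error: precheck does not establish A > B > C; ",
         "the continuity test premise is not met")
  }

  prefs <- vector("list", length(levels))
  pvals <- rep(NA_real_, length(levels))
  for (i in seq_along(levels)) {
    if (n[i] > 0L) {
      prefs[[i]] <- binomial_preference(k[i], n[i], alpha = alpha)
      pvals[i] <- prefs[[i]]$p_value
    }
  }
  fdr <- bh_fdr(pvals[interior], q = q)
  sig <- rep(FALSE, length(levels))
  sig[interior] <- fdr$reject
  p_adj <- rep(NA_real_, length(levels))
  p_adj[interior] <- fdr$p_adjusted

  has_disp <- any(sig & interior & (k / pmax(n, 1L)) < 0.5, na.rm = TRUE)
  has_pref <- any(sig & interior & (k / pmax(n, 1L)) > 0.5, na.rm = TRUE)

  int_trial <- pa_trial > 1e-9 & pa_trial < 1 - 1e-9
  ct <- suppressWarnings(
    stats::cor.test(pa_trial[int_trial], choice_trial[int_trial],
                    method = "spearman", exact = FALSE))
  monotone <- is.finite(ct$estimate) && ct$estimate > 0 &&
    ct$p.value < alpha

  ip <- NULL
  if (fit_ip)
    ip <- tryCatch(
      fit_softmax_ip(levels[n > 0L], k[n > 0L], n[n > 0L], boot = boot,
                     seed = seed),
      error = function(e) NULL)

  structure(list(levels = levels, k = k, n = n, preference = prefs,
                 p_adjusted = p_adj, significant = sig,
                 rank_corr_rho = unname(ct$estimate),
                 rank_corr_p = ct$p.value,
                 has_dispreferred_level = has_disp,
                 has_preferred_level = has_pref,
                 monotone = monotone,
                 compliant = has_disp && has_pref && monotone,
                 precheck = precheck, ip = ip,
                 gambles = list(A = A, B = B, C = C)),
            class = "continuity_result")
}

#' @export
print.continuity_result <- function(x, ...) {
  cat("<continuity_result>\n")
  cat(sprintf("  levels: %s\n",
              paste(sprintf("%.2g", x$levels), collapse = " ")))
  cat(sprintf("  P(AC):  %s\n",
              paste(sprintf("%.2f", x$k / pmax(x$n, 1L)), collapse = " ")))
  cat(sprintf("  Archimedean: dispreferred=%s preferred=%s | rank rho = %.3f (p = %.3g)\n",
              x$has_dispreferred_level, x$has_preferred_level,
              x$rank_corr_rho, x$rank_corr_p))
  cat(sprintf("  compliant: %s", x$compliant))
  if (!is.null(x$ip)) cat(sprintf(" | IP alpha = %.3f (tau = %.3f)",
                                  x$ip$alpha, x$ip$tau))
  cat("\n")
  invisible(x)
}

#' @export
plot.continuity_result <- function(x, ...) {
  prop <- x$k / pmax(x$n, 1L)
  plot(x$levels, prop, pch = 19, ylim = c(0, 1),
       xlab = expression(p[A]), ylab = "P(choose AC)",
       main = "Continuity axiom test", ...)
  graphics::abline(h = 0.5, lty = 2, col = "gray")
  if (!is.null(x$ip)) {
    pg <- seq(0, 1, length.out = 200L)
    graphics::lines(pg, stats::plogis((pg - x$ip$alpha) / x$ip$tau),
                    col = "red")
    graphics::abline(v = x$ip$alpha, col = "red", lty = 3)
  }
  invisible(x)
}
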
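#' Construct a gamble
#'
#' A gamble is a finite probability distribution over non-negative liquid
#' reward magnitudes (ml). It is the universal choice object of the package:
#' sure rewards are degenerate gambles (a single outcome with probability 1),
#' risky options carry two or three outcomes, and probabilistic mixtures of
#' gambles (see [mix_gambles()]) are themselves gambles.
#'
#' Gambles are stored in canonical form: outcomes sorted by increasing
#' magnitude, outcomes whose magnitudes coincide within 1e-9 ml merged by
#' summing their probabilities, and zero-probability outcomes dropped.
#' Probabilities must sum to 1 within 1e-9 and are renormalized exactly, so
#' that gambles survive text-file round trips.
#'
#' @param magnitudes numeric vector of reward magnitudes in ml (>= 0).
#' @param probabilities numeric vector of outcome probabilities, same length
#'   as `magnitudes`, summing to 1 within 1e-9.
#' @return An object of class `"gamble"`: a list with numeric fields `m`
#'   (magnitudes, ascending) and `p` (probabilities).
#' @examples
#' g <- gamble(c(0.5, 0), c(0.5, 0.5))
#' expected_value(g)
#' @export
gamble <- function(magnitudes, probabilities) {
  if (!is.numeric(magnitudes) || !is.numeric(probabilities))
    stop("magnitudes and probabilities must be numeric")
  if (length(magnitudes) != length(probabilities))
    stop("magnitudes and probabilities must have the same length")
  if (length(magnitudes) == 0L) stop("a gamble needs at least one outcome")
  if (any(!is.finite(magnitudes)) || any(!is.finite(probabilities)))
    stop("magnitudes and probabilities must be finite")
  if (any(magnitudes < 0)) stop("reward magnitudes must be non-negative")
  if (any(probabilities < -1e-9)) stop("probabilities must be non-negative")
  s <- sum(probabilities)
  if (abs(s - 1) > 1e-9)
    stop("outcome probabilities must sum to 1 (got ", format(s), ")")
  p <- pmax(probabilities, 0) / sum(pmax(probabilities, 0))

  o <- order(magnitudes)
  m <- magnitudes[o]
  p <- p[o]
  # merge outcomes whose magnitudes coincide within 1e-9 ml
  grp <- cumsum(c(TRUE, diff(m) > 1e-9))
  m <- as.numeric(tapply(m, grp, function(x) x[1L]))
  p <- as.numeric(tapply(p, grp, sum))
  keep <- p > 1e-12
  if (!any(keep)) stop("gamble has no outcome with positive probability")
  m <- m[keep]
  p <- p[keep] / sum(p[keep])
  structure(list(m = m, p = p), class = "gamble")
}

#' Degenerate (sure-reward) gamble
#'
#' @param magnitude reward magnitude in ml.
#' @return A one-outcome [gamble()] with probability 1.
#' @export
degenerate <- function(magnitude) gamble(magnitude, 1)

#' @export
print.gamble <- function(x, ...) {
  cat("<gamble> ", paste(sprintf("%g ml @ %g", x$m, x$p), collapse = "; "),
      "\n", sep = "")
  invisible(x)
}

is_gamble <- function(x) inherits(x, "gamble")

stopifnot_gamble <- function(g) {
  if (!is_gamble(g)) stop("expected a gamble object")
  invisible(g)
}

#' Serialize a gamble to its compact string form
#'
#' The trial-table format stores gambles as `"m1:p1;m2:p2;..."` with
#' magnitudes in ml. [parse_gamble()] is the exact inverse.
#'
#' @param g a [gamble()].
#' @return A single character string.
#' @export
format_gamble <- function(g) {
  stopifnot_gamble(g)
  paste(sprintf("%.12g:%.12g", g$m, g$p), collapse = ";")
}

#' Parse a gamble from its compact string form
#'
#' @param s a character string `"m1:p1;m2:p2;..."` (or vector of them).
#' @return A [gamble()] for a single string, otherwise a list of gambles.
#' @export
parse_gamble <- function(s) {
  parse1 <- function(x) {
    parts <- strsplit(x, ";", fixed = TRUE)[[1L]]
    mp <- vapply(strsplit(parts, ":", fixed = TRUE), function(v) {
      if (length(v) != 2L) stop("malformed gamble string: ", x)
      as.numeric(v)
    }, numeric(2L))
    if (any(!is.finite(mp))) stop("malformed gamble string: ", x)
    gamble(mp[1L, ], mp[2L, ])
  }
  if (length(s) == 1L) parse1(s) else lapply(s, parse1)
}

#' Expected value of a gamble
#'
#' The objective expected value EV = sum(m_i * p_i), in ml.
#'
#' @param g a [gamble()].
#' @return Numeric scalar (ml).
#' @export
expected_value <- function(g) {
  stopifnot_gamble(g)
  sum(g$m * g$p)
}

#' Outcome variance (risk) of a gamble
#'
#' Risk = sum(p_i * (m_i - EV)^2), the expected squared deviation of the
#' outcome from the gamble's mean, in ml^2. This is the risk term of the
#' mean-variance value model.
#'
#' @param g a [gamble()].
#' @return Numeric scalar (ml^2).
#' @export
risk_variance <- function(g) {
  stopifnot_gamble(g)
  ev <- sum(g$m * g$p)
  sum(g$p * (g$m - ev)^2)
}

#' Probabilistic mixture of two gambles
#'
#' `mix_gambles(A, C, pA)` is the compound gamble that yields gamble `A` with
#' probability `pA` and gamble `C` with probability `1 - pA`; its outcome set
#' is the union of the two outcome sets, canonicalized (shared magnitudes
#' merged). This is the AC combination of a continuity-axiom test.
#'
#' @param gA,gC gambles.
#' @param pA probability of obtaining `gA`, in \[0, 1\].
#' @return A [gamble()].
#' @export
mix_gambles <- function(gA, gC, pA) {
  stopifnot_gamble(gA)
  stopifnot_gamble(gC)
  if (!is.numeric(pA) || length(pA) != 1L || is.na(pA) || pA < 0 || pA > 1)
    stop("pA must be a probability in [0, 1]")
  gamble(c(gA$m, gC$m), c(pA * gA$p, (1 - pA) * gC$p))
}

#' First-order stochastic dominance
#'
#' `fsd_dominates(g1, g2)` is `TRUE` iff the CDF of `g1` lies weakly below
#' the CDF of `g2` everywhere and strictly below somewhere, i.e. `g1`
#' first-order stochastically dominates `g2` ("more is better" in
#' probabilistic form). Any expected-utility maximizer with strictly
#' increasing utility prefers the dominant gamble.
#'
#' @param g1,g2 gambles.
#' @return Logical scalar.
#' @export
fsd_dominates <- function(g1, g2) {
  stopifnot_gamble(g1)
  stopifnot_gamble(g2)
  xs <- sort(unique(c(g1$m, g2$m)))
  cdf <- function(g, x) vapply(x, function(v) sum(g$p[g$m <= v + 1e-12]), 0)
  F1 <- cdf(g1, xs)
  F2 <- cdf(g2, xs)
  all(F1 <= F2 + 1e-12) && any(F1 < F2 - 1e-12)
}

#' Marschak-Machina triangle coordinates
#'
#' Maps a gamble whose outcomes all lie on three fixed magnitude levels onto
#' the Marschak-Machina triangle: `p1` is the probability of the lowest
#' level, `p3` of the highest (the middle level has `p2 = 1 - p1 - p3`).
#'
#' @param g a [gamble()] whose outcome magnitudes are all among `levels`.
#' @param levels the three fixed magnitudes (ml), in any order.
#' @return An object of class `"mm_point"`: list with `p1`, `p3`, `levels`
#'   (sorted ascending).
#' @seealso [mm_gamble()] for the inverse construction.
#' @export
mm_coordinates <- function(g, levels = c(0, 0.25, 0.5)) {
  stopifnot_gamble(g)
  if (length(levels) != 3L) stop("exactly three magnitude levels required")
  levels <- sort(levels)
  idx <- vapply(g$m, function(m) {
    j <- which(abs(levels - m) <= 1e-9)
    if (length(j) != 1L)
      stop("outcome magnitude ", m, " is not one of the triangle levels")
    j
  }, 0L)
  p <- c(0, 0, 0)
  for (k in seq_along(idx)) p[idx[k]] <- p[idx[k]] + g$p[k]
  structure(list(p1 = p[1L], p3 = p[3L], levels = levels),
            class = "mm_point")
}

#' Gamble from Marschak-Machina coordinates
#'
#' @param p1 probability of the lowest level.
#' @param p3 probability of the highest level (`p1 + p3 <= 1`).
#' @param levels the three fixed magnitudes (ml).
#' @return A [gamble()].
#' @export
mm_gamble <- function(p1, p3, levels = c(0, 0.25, 0.5)) {
  if (p1 < -1e-12 || p3 < -1e-12 || p1 + p3 > 1 + 1e-9)
    stop("require p1 >= 0, p3 >= 0, p1 + p3 <= 1")
  levels <- sort(levels)
  gamble(levels, c(p1, 1 - p1 - p3, p3))
}

#' @export
print.mm_point <- function(x, ...) {
  cat(sprintf("<mm_point> p1 = %g, p3 = %g on levels {%s} ml\n",
              x$p1, x$p3, paste(x$levels, collapse = ", ")))
  invisible(x)
}
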
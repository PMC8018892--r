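trial_columns <- c("session", "trial", "gamble_left", "gamble_right",
                   "chosen_side", "reward_delivered")

#' Read a trial table from a delimited text file
#'
#' The canonical trial format is tab-delimited text with a header and one
#' row per trial: `session`, `trial`, `gamble_left`, `gamble_right`
#' (serialized gambles, see [format_gamble()]), `chosen_side` (`L`/`R`),
#' `reward_delivered` (ml). Gamble strings are validated row by row;
#' `prev_choice` and `prev_reward` are (re)derived from the within-session
#' trial order.
#'
#' @param path file path.
#' @return A validated trial table (`data.frame`).
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tt <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(trial_columns, names(tt))
  if (length(missing_cols))
    stop("trial table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (nrow(tt) == 0L) {
    warning("trial table is empty")
    tt$prev_choice <- numeric(0)
    tt$prev_reward <- numeric(0)
    return(tt)
  }
  for (col in c("gamble_left", "gamble_right")) {
    for (i in seq_len(nrow(tt))) {
      ok <- tryCatch({
        parse_gamble(tt[[col]][i])
        TRUE
      }, error = function(e) FALSE)
      if (!ok)
        stop("row ", i, ": malformed gamble string in ", col, ": ",
             tt[[col]][i])
    }
  }
  bad <- !tt$chosen_side %in% c("L", "R")
  if (any(bad))
    stop("row ", which(bad)[1L], ": chosen_side must be 'L' or 'R'")
  tt <- tt[order(tt$session, tt$trial), ]
  rownames(tt) <- NULL
  prev_ch <- numeric(nrow(tt))
  prev_rw <- numeric(nrow(tt))
  for (s in unique(tt$session)) {
    idx <- which(tt$session == s)
    ch <- ifelse(tt$chosen_side[idx] == "L", -1, 1)
    prev_ch[idx] <- c(0, ch[-length(idx)])
    prev_rw[idx] <- c(0, tt$reward_delivered[idx][-length(idx)])
  }
  tt$prev_choice <- prev_ch
  tt$prev_reward <- prev_rw
  tt
}

#' Write a trial table to a delimited text file
#'
#' @param trials a trial table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  utils::write.table(trials[intersect(c(trial_columns, "prev_choice",
                                        "prev_reward"), names(trials))],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

config_gamble <- function(x) {
  if (is_gamble(x)) x
  else if (is.character(x)) parse_gamble(x)
  else if (is.numeric(x) && length(x) == 1L) degenerate(x)
  else if (is.list(x)) gamble(unlist(x$m), unlist(x$p))
  else stop("cannot interpret gamble specification")
}

config_agent <- function(cfg) {
  if (identical(cfg$kind, "lexicographic"))
    return(agent_spec(kind = "lexicographic",
                      lapse = if (is.null(cfg$lapse)) 0.02 else cfg$lapse,
                      side_bias = if (is.null(cfg$side_bias)) 0
                                  else cfg$side_bias))
  margs <- cfg[intersect(names(cfg),
                         c("a", "b", "a_w", "b_w", "w_m", "w_p", "beta",
                           "tau", "m0"))]
  model <- do.call(model_spec, c(list(kind = cfg$model), margs))
  agent_spec(model,
             side_bias = if (is.null(cfg$side_bias)) 0 else cfg$side_bias,
             drift_param = cfg$drift_param,
             across_session_sd = if (is.null(cfg$across_session_sd)) 0
                                 else cfg$across_session_sd,
             within_session_decline =
               if (is.null(cfg$within_session_decline)) 0
               else cfg$within_session_decline)
}

#' Run the analysis pipeline from a configuration
#'
#' Orchestrates simulate -> continuity test -> IP fit -> model fits ->
#' model comparison -> choice regression, as configured, and writes a
#' report bundle ([write_report()]). The configuration is a named list (or
#' the path of a YAML file with the same structure):
#' \describe{
#'   \item{`seed`}{integer; drives every stochastic step.}
#'   \item{`trials`}{path of an existing trial table, *or*}
#'   \item{`simulate`}{list with `agent` (e.g. `list(model = "EU_power",
#'     a = 0.8, tau = 0.05)` or `list(kind = "lexicographic")`) and
#'     `design` (`list(type = "continuity", A = , B = , C = , levels = ,
#'     repeats = , sessions = )`).}
#'   \item{`continuity`}{list of tests, each `list(A = , B = , C = ,
#'     levels = )` (gambles as magnitudes, strings or `list(m =, p =)`).}
#'   \item{`models`}{character vector of model families to fit and
#'     compare.}
#'   \item{`regression`}{logical; per-session logistic regressions plus
#'     population tests.}
#' }
#'
#' @param config named list or YAML file path.
#' @param out_dir output directory for the report bundle (created).
#' @return The result bundle (named list), invisibly if `out_dir` is
#'   given.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config must set a seed")
  if (!is.null(config$models) && length(config$models) == 0L)
    stop("config lists an empty model set")
  seed <- as.integer(config$seed)

  if (!is.null(config$trials)) {
    trials <- read_trials(config$trials)
  } else if (!is.null(config$simulate)) {
    sim <- config$simulate
    agent <- config_agent(sim$agent)
    dz <- sim$design
    design <- switch(dz$type,
      continuity = continuity_design(
        config_gamble(dz$A), config_gamble(dz$B), config_gamble(dz$C),
        levels = if (is.null(dz$levels)) seq(0, 1, by = 0.1)
                 else unlist(dz$levels),
        repeats = if (is.null(dz$repeats)) 30L else dz$repeats,
        n_sessions = if (is.null(dz$sessions)) 1L else dz$sessions),
      mixed = mixed_design(
        repeats = if (is.null(dz$repeats)) 5L else dz$repeats,
        n_sessions = if (is.null(dz$sessions)) 1L else dz$sessions),
      stop("unknown design type: ", dz$type))
    trials <- simulate_experiment(agent, design, seed = seed)
  } else stop("config must provide either 'trials' or 'simulate'")

  results <- list(seed = seed, trials = trials)

  if (!is.null(config$continuity)) {
    results$continuity <- lapply(config$continuity, function(tc)
      test_continuity(trials,
                      config_gamble(tc$A), config_gamble(tc$B),
                      config_gamble(tc$C),
                      levels = if (is.null(tc$levels)) seq(0, 1, by = 0.1)
                               else unlist(tc$levels),
                      boot = if (is.null(tc$boot)) 0L else tc$boot,
                      seed = seed))
  }

  if (!is.null(config$models)) {
    results$fits <- lapply(config$models, function(kind)
      fit_model_mle(trials, kind, seed = seed))
    names(results$fits) <- config$models
    if (length(results$fits) >= 2L)
      results$comparison <- compare_models(results$fits,
                                           results$continuity)
  }

  if (isTRUE(config$regression)) {
    sessions <- unique(trials$session)
    fits <- lapply(sessions, function(s)
      suppressWarnings(fit_choice_logistic(trials[trials$session == s, ])))
    results$regression <- list(per_session = fits)
    if (length(fits) >= 3L)
      results$regression$population <- population_beta_tests(fits)
  }

  if (!is.null(out_dir)) {
    write_report(results, out_dir)
    return(invisible(results))
  }
  results
}

#' Export a subjective-value surface
#'
#' Evaluates a model's value `V(m, p)` for two-outcome gambles
#' `{(m, p), (0, 1 - p)}` on a magnitude-by-probability grid and writes it
#' as a tab-delimited matrix (rows = magnitudes, columns = probabilities),
#' the three-dimensional utility surface used to relate models to neuronal
#' activity.
#'
#' @param spec a [model_spec()].
#' @param path output file path (`NULL` returns the matrix only).
#' @param m_step,p_step grid steps (ml / probability).
#' @return The value matrix, invisibly when written to `path`.
#' @export
export_value_surface <- function(spec, path = NULL, m_step = 0.01,
                                 p_step = 0.01) {
  m <- seq(0, spec$m0, by = m_step)
  p <- seq(0, 1, by = p_step)
  V <- outer(m, p, function(mm, pp) value_mp(mm, pp, spec))
  dimnames(V) <- list(magnitude = sprintf("%g", m),
                      probability = sprintf("%g", p))
  if (is.null(path)) return(V)
  utils::write.table(V, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(V)
}

#' Write a report bundle
#'
#' Writes the pipeline results as delimited text tables plus a
#' machine-readable JSON summary stamped with the seed and package
#' version.
#'
#' @param results a [run_pipeline()] result bundle (or any subset with the
#'   same names).
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(seed = results$seed,
                  package_version =
                    as.character(utils::packageVersion("riskaxioms")))

  if (!is.null(results$trials))
    write_trials(results$trials, file.path(out_dir, "trials.tsv"))

  if (!is.null(results$continuity)) {
    tab <- do.call(rbind, lapply(seq_along(results$continuity),
                                 function(i) {
      ct <- results$continuity[[i]]
      data.frame(test = i,
                 A = format_gamble(ct$gambles$A),
                 B = format_gamble(ct$gambles$B),
                 C = format_gamble(ct$gambles$C),
                 compliant = ct$compliant,
                 rank_corr_rho = ct$rank_corr_rho,
                 rank_corr_p = ct$rank_corr_p,
                 alpha = if (is.null(ct$ip)) NA_real_ else ct$ip$alpha,
                 tau = if (is.null(ct$ip)) NA_real_ else ct$ip$tau,
                 alpha_ci_low = if (is.null(ct$ip)) NA_real_
                                else ct$ip$ci_low,
                 alpha_ci_high = if (is.null(ct$ip)) NA_real_
                                 else ct$ip$ci_high)
    }))
    utils::write.table(tab, file.path(out_dir, "continuity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$continuity <- tab
  }

  if (!is.null(results$comparison)) {
    utils::write.table(results$comparison,
                       file.path(out_dir, "model_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$model_comparison <- as.data.frame(results$comparison)
    summary$best_model_bic <- attr(results$comparison, "best_bic")
  } else if (!is.null(results$fits)) {
    summary$fits <- lapply(results$fits, function(f)
      list(kind = f$spec$kind, log_likelihood = f$log_likelihood,
           bic = f$bic, aic = f$aic))
  }

  if (!is.null(results$regression$population)) {
    utils::write.table(results$regression$population,
                       file.path(out_dir, "regression_population.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$regression <- results$regression$population
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(out_dir)
}
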
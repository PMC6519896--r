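# Forward-in-time agent-based simulation of the discovery process with
# replication experiments (Rey) and reproducibility accounting.

#' Configure an agent-based simulation run
#'
#' @param pop an [population()]; any composition of Tess, Mave, Bo, Rey.
#' @param truth an \code{mc_truth} data-generating configuration.
#' @param stat \code{"AIC"} or \code{"SC"}.
#' @param mode an [strategy_mode()] (hard or soft proposals).
#' @param iterations experiments to simulate (default 11000).
#' @param burn_in initial steps discarded when computing long-run
#'   proportions (default 1000). First passage times are computed on the
#'   full trace, never burned in.
#' @param init initial global model: \code{"random_nontrue"} (default; drawn
#'   uniformly from the 13 models other than the truth) or a model label.
#' @param seed optional integer seed applied at the start of the run.
#' @param stop_at_truth if \code{TRUE} the run ends as soon as the global
#'   model first equals the truth (first-passage-only analyses).
#' @return list of class \code{mc_abm_config}.
#' @export
abm_config <- function(pop, truth, stat = c("AIC", "SC"),
                       mode = strategy_mode(), iterations = 11000L,
                       burn_in = 1000L, init = "random_nontrue",
                       seed = NULL, stop_at_truth = FALSE) {
  stat <- .match_stat(stat)
  stopifnot(inherits(pop, "mc_population"), inherits(truth, "mc_truth"))
  iterations <- as.integer(iterations)
  burn_in <- as.integer(burn_in)
  if (!(iterations > burn_in && burn_in >= 0L))
    stop("need iterations > burn_in >= 0", call. = FALSE)
  structure(list(pop = pop, truth = truth, stat = stat, mode = mode,
                 iterations = iterations, burn_in = burn_in, init = init,
                 seed = seed, stop_at_truth = isTRUE(stop_at_truth)),
            class = "mc_abm_config")
}

.resolve_init <- function(config) {
  space <- config$truth$space
  truth_lab <- model_label(config$truth$model)
  if (identical(config$init, "random_nontrue")) {
    sample(setdiff(space$labels, truth_lab), 1L)
  } else {
    stopifnot(config$init %in% space$labels)
    config$init
  }
}

#' One step of the agent-based discovery process
#'
#' Reference (pure R) implementation of a single experiment: draw a
#' scientist, obtain her proposal, generate fresh data, decide the contest,
#' and update the global model. A drawn replicator re-runs her
#' predecessor's exact (proposed, global) pair on the fresh data and scores
#' it against her predecessor's outcome; the winner of her own contest
#' becomes the global model. A replicator drawn at the first step (no
#' predecessor) is replaced by a redraw among the proposer types.
#'
#' @param state list with \code{global} (current global \code{mc_model}) and
#'   \code{prev} (\code{NULL} or list \code{proposed}, \code{global_before},
#'   \code{won} describing the predecessor experiment).
#' @param config an [abm_config()].
#' @param data optionally, a fixed \code{mc_dataset} to use instead of
#'   generating one (used to force outcomes in structural tests).
#' @param scientist optionally force the scientist type (\code{"tess"},
#'   \code{"mave"}, \code{"bo"}, \code{"rey"}).
#' @return list with \code{state} (updated) and \code{record} (one-row
#'   data.frame matching the trace format of [abm_run()]).
#' @export
abm_step <- function(state, config, data = NULL, scientist = NULL) {
  space <- config$truth$space
  if (is.null(scientist)) {
    scientist <- sample(.SCIENTIST_TYPES, 1L, prob = unclass(config$pop))
  }
  if (scientist == "rey" && is.null(state$prev)) {
    w <- unclass(config$pop)[c("tess", "mave", "bo")]
    if (sum(w) <= 0) w <- rep(1, 3)
    scientist <- sample(c("tess", "mave", "bo"), 1L, prob = w)
  }
  if (is.null(data)) data <- generate_dataset(config$truth)

  if (scientist == "rey") {
    proposed <- state$prev$proposed
    global_before <- state$prev$global_before
  } else {
    q <- proposal_distribution(scientist, state$global, space, config$mode)
    proposed <- space$models[[sample.int(length(q), 1L, prob = q)]]
    global_before <- state$global
  }
  ct <- contest(proposed, global_before, data, config$stat, space)
  is_rep <- scientist == "rey"
  reproduced <- if (is_rep) ct$proposed_won == state$prev$won else NA
  new_global <- if (is_rep) ct$winner else (if (ct$proposed_won) proposed
                                            else state$global)
  record <- data.frame(
    scientist = scientist,
    proposed = model_label(proposed),
    global_before = model_label(global_before),
    global_after = model_label(new_global),
    proposed_won = ct$proposed_won,
    is_replication = is_rep,
    reproduced = reproduced,
    score_proposed = ct$score_proposed,
    score_global = ct$score_global,
    stringsAsFactors = FALSE)
  list(state = list(global = new_global,
                    prev = list(proposed = proposed,
                                global_before = global_before,
                                won = ct$proposed_won)),
       record = record)
}

#' Run the agent-based discovery simulation
#'
#' Iterates [abm_step()] for the configured number of experiments and
#' derives the run-level properties of the process. The default engine is a
#' compiled kernel; \code{engine = "r"} runs the pure-R reference
#' implementation (same process, slower; the two engines draw random numbers
#' in different orders, so trajectories match in distribution, not
#' step-for-step).
#'
#' @param config an [abm_config()].
#' @param engine \code{"cpp"} (default) or \code{"r"}.
#' @return list of class \code{mc_run}: \code{records} (the per-experiment
#'   trace as a data.frame), \code{init}, \code{truth_label}, and
#'   \code{metrics}, a list with \code{first_passage} (steps until the
#'   global model first equals the truth; 0 if started there),
#'   \code{censored} (\code{TRUE} when the truth was never reached),
#'   \code{time_at_truth} (post-burn-in proportion), \code{stickiness}
#'   (empirical one-step stay probability at the truth), and the three
#'   reproducibility rates of [reproducibility_rates()].
#' @export
abm_run <- function(config, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(config, "mc_abm_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  space <- config$truth$space
  truth_lab <- model_label(config$truth$model)
  init_lab <- .resolve_init(config)

  if (engine == "cpp") {
    Q <- lapply(c(tess = "tess", mave = "mave", bo = "bo"),
                function(ty) proposal_matrix(ty, space, config$mode))
    truth_cols <- space$model_cols[[match(truth_lab, space$labels)]]
    res <- cpp_abm_run(
      config$truth$sample_size, config$iterations,
      lapply(space$model_cols, as.integer), as.integer(truth_cols),
      as.numeric(config$truth$coefficients),
      sqrt(calibrate_sigma2(config$truth)),
      as.numeric(config$truth$predictor_mean),
      as.numeric(config$truth$predictor_sd),
      space$n_factors,
      vapply(space$design_terms, function(t) sum(2^(t - 1L)), numeric(1)),
      if (identical(config$truth$predictor_law, "uniform")) 1L else 0L,
      Q$tess, Q$mave, Q$bo, as.numeric(unclass(config$pop)),
      if (config$stat == "AIC") 0L else 1L,
      match(init_lab, space$labels), match(truth_lab, space$labels),
      config$stop_at_truth)
    records <- data.frame(
      scientist = .SCIENTIST_TYPES[res$scientist],
      proposed = space$labels[res$proposed],
      global_before = space$labels[res$global_before],
      global_after = space$labels[res$global_after],
      proposed_won = res$won == 1L,
      is_replication = res$is_replication == 1L,
      reproduced = ifelse(is.na(res$reproduced), NA, res$reproduced == 1L),
      score_proposed = res$score_proposed,
      score_global = res$score_global,
      stringsAsFactors = FALSE)
  } else {
    state <- list(global = space$models[[match(init_lab, space$labels)]],
                  prev = NULL)
    recs <- vector("list", config$iterations)
    for (t in seq_len(config$iterations)) {
      out <- abm_step(state, config)
      state <- out$state
      recs[[t]] <- out$record
      if (config$stop_at_truth &&
          out$record$global_after == truth_lab) {
        recs <- recs[seq_len(t)]
        break
      }
    }
    records <- do.call(rbind, recs)
  }

  structure(list(records = records, init = init_lab,
                 truth_label = truth_lab, config = config,
                 metrics = run_metrics(records, init_lab, truth_lab,
                                       config$burn_in)),
            class = "mc_run")
}

#' Run-level metrics from an ABM trace
#'
#' @param records a trace data.frame as produced by [abm_run()].
#' @param init label of the initial global model.
#' @param truth_label label of the true model.
#' @param burn_in steps discarded for the long-run proportions (the first
#'   passage time always uses the full trace).
#' @return list of metrics; see [abm_run()].
#' @export
run_metrics <- function(records, init, truth_label, burn_in = 0L) {
  states <- c(init, records$global_after)   # states[t+1] = global after step t
  hit <- which(states == truth_label) - 1L
  censored <- length(hit) == 0L
  first_passage <- if (censored) NA_integer_ else hit[1]
  post <- records$global_after[seq_len(nrow(records)) > burn_in]
  time_at_truth <- mean(post == truth_label)
  at_truth <- states[-length(states)] == truth_label
  stick <- if (any(at_truth))
    mean(states[-1][at_truth] == truth_label) else NA_real_
  c(list(first_passage = first_passage, censored = censored,
         time_at_truth = time_at_truth, stickiness = stick),
    reproducibility_rates(records, truth_label))
}

#' Reproducibility rates from a trace
#'
#' The rate of reproducibility is the proportion of replication experiments
#' whose outcome (consensus updated or retained) matches their original
#' experiment's, reported overall and stratified by whether the global model
#' of the replicated contest was the true model.
#'
#' @param records a trace data.frame with columns \code{is_replication},
#'   \code{reproduced}, \code{global_before}.
#' @param truth_label label of the true model.
#' @return list with \code{repro_overall}, \code{repro_at_truth},
#'   \code{repro_elsewhere}; a stratum with no replication experiments
#'   yields \code{NA} (undefined rate).
#' @export
reproducibility_rates <- function(records, truth_label) {
  reps <- records[records$is_replication, , drop = FALSE]
  rate <- function(x) if (length(x) == 0L) NA_real_ else mean(x)
  list(repro_overall = rate(reps$reproduced),
       repro_at_truth = rate(reps$reproduced[reps$global_before ==
                                               truth_label]),
       repro_elsewhere = rate(reps$reproduced[reps$global_before !=
                                                truth_label]))
}

#' @export
print.mc_run <- function(x, ...) {
  m <- x$metrics
  cat("<abm run> ", nrow(x$records), " experiments, true model ",
      x$truth_label, ", init ", x$init, "\n",
      "  first passage: ",
      if (m$censored) "censored (never reached)" else m$first_passage, "\n",
      "  time at truth: ", sprintf("%.4f", m$time_at_truth),
      "   stickiness: ", sprintf("%.4f", m$stickiness), "\n",
      "  reproducibility: overall ", sprintf("%.4f", m$repro_overall),
      ", at truth ", sprintf("%.4f", m$repro_at_truth),
      ", elsewhere ", sprintf("%.4f", m$repro_elsewhere), "\n", sep = "")
  invisible(x)
}
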
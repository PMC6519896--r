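# Factorial experiment runner and summary operations.

#' Default true models of graded complexity
#'
#' Three true models spanning the complexity gradient of the space: the
#' single-main model, an intermediate four-predictor model with one
#' interaction, and the full seven-predictor model. These identities are a
#' package default (configurable in [factorial_design()]).
#' @return named list of \code{mc_model}.
#' @export
default_true_models <- function() {
  list(TM1 = parse_model("1"),
       TM2 = parse_model("1+2+3+12"),
       TM3 = parse_model("1+2+3+12+13+23+123"))
}

#' Specify a factorial ABM experiment
#'
#' Fully crossed design over true models, noise ratios, populations, and
#' comparison statistics, each cell replicated with its own deterministic
#' seed derived from \code{base_seed}, the cell index, and the replicate
#' index, so runs are reproducible and independent of execution order.
#'
#' @param true_models named list of \code{mc_model} (default
#'   [default_true_models()]).
#' @param noise_ratios numeric or \code{"a:b"} strings (default 1:4, 1:1,
#'   4:1).
#' @param populations named list of [population()]s (default the four
#'   dominant ABM presets plus the diverse preset).
#' @param stats character subset of \code{c("AIC", "SC")}.
#' @param mode an [strategy_mode()].
#' @param replicates runs per cell (default 100).
#' @param iterations,burn_in per-run lengths (defaults 11000 / 1000).
#' @param base_seed integer seed anchoring the whole design.
#' @param sample_size observations per generated dataset.
#' @param stop_at_truth passed to [abm_config()] (first-passage-only runs).
#' @return list of class \code{mc_design} with a \code{cells} data.frame.
#' @export
factorial_design <- function(true_models = default_true_models(),
                             noise_ratios = c("1:4", "1:1", "4:1"),
                             populations = NULL,
                             stats = c("AIC", "SC"),
                             mode = strategy_mode("hard"),
                             replicates = 100L,
                             iterations = 11000L, burn_in = 1000L,
                             base_seed = 20190515L,
                             sample_size = 100L,
                             stop_at_truth = FALSE) {
  if (is.null(populations)) {
    populations <- lapply(
      setNames(nm = c("rey", "tess", "bo", "mave", "diverse")),
      population_preset, system = "abm")
  }
  stopifnot(length(true_models) > 0, length(noise_ratios) > 0,
            length(populations) > 0, length(stats) > 0)
  stats <- vapply(stats, .match_stat, character(1))
  if (is.null(names(true_models)))
    names(true_models) <- vapply(true_models, model_label, character(1))
  cells <- expand.grid(true_model = names(true_models),
                       noise_ratio = as.character(noise_ratios),
                       population = names(populations),
                       stat = unname(stats),
                       stringsAsFactors = FALSE)
  cells$cell <- seq_len(nrow(cells))
  structure(list(cells = cells, true_models = true_models,
                 populations = populations, mode = mode,
                 replicates = as.integer(replicates),
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in),
                 base_seed = as.integer(base_seed),
                 sample_size = as.integer(sample_size),
                 stop_at_truth = isTRUE(stop_at_truth)),
            class = "mc_design")
}

#' @export
print.mc_design <- function(x, ...) {
  cat("<factorial design> ", nrow(x$cells), " cells x ", x$replicates,
      " replicates (", x$iterations, " iterations each)\n", sep = "")
  invisible(x)
}

#' Deterministic per-run seed
#'
#' \code{(base_seed + 1000003 * cell + 7919 * replicate) mod (2^31 - 1)}:
#' documented, order-independent, and within R's integer range.
#' @param base_seed,cell,replicate integers.
#' @return integer seed.
#' @export
run_seed <- function(base_seed, cell, replicate) {
  as.integer((as.double(base_seed) + 1000003 * cell + 7919 * replicate) %%
               2147483647)
}

#' Execute a factorial design
#'
#' Runs [abm_run()] for every cell and replicate and collects one row of
#' metrics per run in a long-format data.frame (plot- and CSV-ready).
#' Execution order does not affect results: every run is seeded by
#' [run_seed()].
#'
#' @param design an [factorial_design()].
#' @param engine passed to [abm_run()].
#' @param verbose print per-cell progress.
#' @return list of class \code{mc_design_result}: \code{runs} (data.frame:
#'   cell factors, replicate, seed, first_passage, censored, time_at_truth,
#'   stickiness, repro_* rates), \code{design}.
#' @export
run_design <- function(design, engine = c("cpp", "r"), verbose = FALSE) {
  engine <- match.arg(engine)
  stopifnot(inherits(design, "mc_design"))
  rows <- vector("list", nrow(design$cells) * design$replicates)
  k <- 0L
  for (ci in seq_len(nrow(design$cells))) {
    cell <- design$cells[ci, ]
    truth <- true_model_config(design$true_models[[cell$true_model]],
                               noise_ratio = cell$noise_ratio,
                               sample_size = design$sample_size)
    pop <- design$populations[[cell$population]]
    if (verbose)
      message(sprintf("cell %d/%d: TM=%s ratio=%s pop=%s stat=%s",
                      ci, nrow(design$cells), cell$true_model,
                      cell$noise_ratio, cell$population, cell$stat))
    for (r in seq_len(design$replicates)) {
      seed <- run_seed(design$base_seed, ci, r)
      cfg <- abm_config(pop, truth, cell$stat, design$mode,
                        design$iterations, design$burn_in, seed = seed,
                        stop_at_truth = design$stop_at_truth)
      run <- abm_run(cfg, engine)
      m <- run$metrics
      k <- k + 1L
      rows[[k]] <- data.frame(cell = ci, true_model = cell$true_model,
                              noise_ratio = cell$noise_ratio,
                              population = cell$population, stat = cell$stat,
                              replicate = r, seed = seed,
                              first_passage = m$first_passage,
                              censored = m$censored,
                              time_at_truth = m$time_at_truth,
                              stickiness = m$stickiness,
                              repro_overall = m$repro_overall,
                              repro_at_truth = m$repro_at_truth,
                              repro_elsewhere = m$repro_elsewhere,
                              stringsAsFactors = FALSE)
    }
  }
  structure(list(runs = do.call(rbind, rows[seq_len(k)]), design = design),
            class = "mc_design_result")
}

#' @export
print.mc_design_result <- function(x, ...) {
  cat("<design result> ", nrow(x$runs), " runs\n", sep = "")
  invisible(x)
}

#' Summarize a factorial result
#'
#' Medians, interquartile ranges, and means of the run-level properties,
#' marginal over the given grouping factors, plus the Spearman rank
#' correlation between the overall reproducibility rate and each other
#' property within each group.
#'
#' @param result an \code{mc_design_result} (or its \code{runs} data.frame).
#' @param by character vector of grouping columns (default
#'   \code{"population"}; use \code{character(0)} for a single overall
#'   summary row).
#' @return data.frame with one row per group: median/IQR/mean of
#'   \code{time_at_truth}, \code{stickiness}, \code{first_passage} (censored
#'   runs excluded, with a \code{censored_frac} column), \code{repro_overall},
#'   and Spearman correlations \code{r_repro_*}.
#' @export
summarize_design <- function(result, by = "population") {
  runs <- if (inherits(result, "mc_design_result")) result$runs else result
  groups <- if (length(by) == 0) list(all = runs) else
    split(runs, runs[by], drop = TRUE, sep = ":")
  out <- lapply(names(groups), function(g) {
    d <- groups[[g]]
    fp <- d$first_passage[!d$censored]
    s <- function(x) c(median = median(x, na.rm = TRUE),
                       iqr = unname(diff(quantile(x, c(0.25, 0.75),
                                                  na.rm = TRUE))),
                       mean = mean(x, na.rm = TRUE))
    tt <- s(d$time_at_truth); st <- s(d$stickiness); rp <- s(d$repro_overall)
    fps <- if (length(fp)) s(fp) else c(median = NA, iqr = NA, mean = NA)
    data.frame(group = g,
               n_runs = nrow(d),
               time_at_truth_median = tt[1], time_at_truth_iqr = tt[2],
               time_at_truth_mean = tt[3],
               stickiness_median = st[1], stickiness_iqr = st[2],
               stickiness_mean = st[3],
               first_passage_median = fps[1], first_passage_iqr = fps[2],
               first_passage_mean = fps[3],
               censored_frac = mean(d$censored),
               repro_median = rp[1], repro_iqr = rp[2], repro_mean = rp[3],
               r_repro_time_at_truth = spearman_r(d$repro_overall,
                                                  d$time_at_truth),
               r_repro_first_passage = spearman_r(d$repro_overall,
                                                  d$first_passage),
               r_repro_stickiness = spearman_r(d$repro_overall,
                                               d$stickiness),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Spearman rank correlation
#'
#' Rank-transforms both vectors (average ranks for ties) and applies the
#' Pearson correlation to the ranks; pairs with missing values are dropped.
#'
#' @param xs,ys numeric vectors of equal length (at least 3 complete pairs).
#' @return correlation in \[-1, 1\], or \code{NA} (with a warning) when
#'   either input is constant so the correlation is undefined.
#' @export
spearman_r <- function(xs, ys) {
  stopifnot(length(xs) == length(ys))
  ok <- is.finite(xs) & is.finite(ys)
  xs <- xs[ok]; ys <- ys[ok]
  if (length(xs) < 3L) {
    warning("fewer than 3 complete pairs: correlation undefined",
            call. = FALSE)
    return(NA_real_)
  }
  if (sd(xs) == 0 || sd(ys) == 0) {
    warning("constant input: correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  cor(xs, ys, method = "spearman")
}

#' Exact chain summaries for the no-replication system
#'
#' For every combination of (Rey-free) population, statistic, and true
#' model, estimates the win-probability tables, builds the transition
#' matrix, and reports the true model's stationary probability, stickiness,
#' and mean first passage time (averaged over initial models other than the
#' truth). Covers all 14 true models by default.
#'
#' @param populations named list of Rey-free [population()]s (default: the
#'   three dominant Markov presets plus the diverse preset).
#' @param stats character subset of \code{c("AIC", "SC")}.
#' @param noise_ratio noise ratio for the data-generating configurations.
#' @param mode an [strategy_mode()] (default soft, which keeps every chain
#'   irreducible).
#' @param reps Monte Carlo replicates per win table.
#' @param true_models list of \code{mc_model} (default: all space models).
#' @param space the model space.
#' @param mfpt_long if \code{TRUE}, also return the per-initial-state MFPT
#'   table in long format (initial_model, true_model, population, stat,
#'   mfpt), heat-map ready.
#' @return data.frame with one row per (population, stat, true model):
#'   \code{time_at_truth}, \code{stickiness}, \code{mfpt_mean}
#'   (experiment clock), \code{mfpt_updates_mean} (consensus-update
#'   clock); with
#'   \code{mfpt_long = TRUE}, a list with elements \code{summary} and
#'   \code{mfpt}.
#' @export
markov_summary <- function(populations = NULL, stats = c("AIC", "SC"),
                           noise_ratio = "1:4", mode = strategy_mode(),
                           reps = 10000L, true_models = NULL,
                           space = the_space(), mfpt_long = FALSE) {
  if (is.null(populations)) {
    populations <- lapply(setNames(nm = c("tess", "mave", "bo", "diverse")),
                          population_preset, system = "markov")
  }
  stats <- vapply(stats, .match_stat, character(1))
  if (is.null(true_models)) true_models <- space$models
  rows <- list()
  longs <- list()
  for (tm in true_models) {
    truth <- true_model_config(tm, noise_ratio = noise_ratio, space = space)
    wt <- win_table(truth, reps = reps)
    for (pn in names(populations)) {
      for (st in stats) {
        ch <- transition_matrix(populations[[pn]], wt, st, mode)
        cm <- chain_metrics(ch)
        rows[[length(rows) + 1L]] <- data.frame(
          population = pn, stat = st, true_model = model_label(tm),
          time_at_truth = cm$time_at_truth, stickiness = cm$stickiness,
          mfpt_mean = cm$mfpt_mean,
          mfpt_updates_mean = cm$mfpt_updates_mean,
          stringsAsFactors = FALSE)
        if (mfpt_long) {
          longs[[length(longs) + 1L]] <- data.frame(
            initial_model = names(cm$mfpt), true_model = model_label(tm),
            population = pn, stat = st, mfpt = unname(cm$mfpt),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  summary <- do.call(rbind, rows)
  if (mfpt_long) list(summary = summary, mfpt = do.call(rbind, longs))
  else summary
}
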
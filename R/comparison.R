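# Gaussian maximum-likelihood fits and penalized-likelihood model contests.

#' Fit a model to a dataset by Gaussian maximum likelihood
#'
#' Least-squares fit of the model's terms (products of factor columns for
#' interactions, no intercept) to the response. The error-variance MLE is
#' \eqn{\hat\sigma^2 = RSS/n}, giving a maximized log-likelihood of
#' \eqn{-(n/2)(\log(2\pi\hat\sigma^2) + 1)}. The parameter count \code{k}
#' includes the error variance: \code{k = #predictors + 1}, the convention
#' used by \code{stats::logLik.lm}/\code{stats::AIC}. A zero-RSS (perfect)
#' fit gets an infinite log-likelihood sentinel; contests then fall back to
#' comparing \code{k}.
#'
#' @param model an \code{mc_model}.
#' @param data an \code{mc_dataset} from [generate_dataset()].
#' @param space the model space (for design-column lookup).
#' @return list of class \code{mc_fit}: \code{coefficients} (named by term
#'   label), \code{rss}, \code{max_loglik}, \code{k}, \code{n}.
#' @section Errors: a rank-deficient design signals \code{mc_degenerate_fit}.
#' @export
fit_mle <- function(model, data, space = the_space()) {
  stopifnot(inherits(data, "mc_dataset"))
  cols <- space$model_cols[[.model_index(model, space)]]
  X <- data$design[, cols, drop = FALSE]
  y <- data$response
  n <- length(y)
  fit <- .lm.fit(X, y)
  if (fit$rank < ncol(X))
    stop(structure(class = c("mc_degenerate_fit", "error", "condition"),
                   list(message = "design matrix is rank deficient",
                        call = sys.call())))
  rss <- sum(fit$residuals^2)
  k <- ncol(X) + 1L
  # a fit is perfect when the residual sum is at rounding-noise level
  # relative to the response scale; its likelihood sentinel is +Inf and
  # contests then compare parameter counts only
  perfect <- rss <= 1e-20 * sum(y^2)
  ll <- if (perfect) Inf else -(n / 2) * (log(2 * pi * rss / n) + 1)
  coefs <- setNames(fit$coefficients[order(fit$pivot)],
                    vapply(model$terms, .term_label, character(1)))
  structure(list(coefficients = coefs, rss = rss, max_loglik = ll,
                 k = k, n = n, model = model),
            class = "mc_fit")
}

#' @export
print.mc_fit <- function(x, ...) {
  cat("<fit> ", model_label(x$model), ": rss = ", format(x$rss),
      ", logLik = ", format(x$max_loglik), ", k = ", x$k, "\n", sep = "")
  invisible(x)
}

.match_stat <- function(stat) {
  match.arg(toupper(stat), c("AIC", "SC"))
}

#' Penalized-likelihood score of a fit
#'
#' \code{AIC = 2k - 2 logLik}; \code{SC = k log(n) - 2 logLik} (the Schwarz
#' Criterion, a.k.a. BIC). Smaller is better. For perfect (zero-RSS) fits the
#' score degenerates to the penalty term alone so that contests reduce to
#' comparing parameter counts.
#'
#' @param fit an \code{mc_fit}.
#' @param stat \code{"AIC"} or \code{"SC"} (case-insensitive).
#' @return numeric score.
#' @export
ic_score <- function(fit, stat = c("AIC", "SC")) {
  stat <- .match_stat(stat)
  penalty <- switch(stat, AIC = 2 * fit$k, SC = fit$k * log(fit$n))
  if (!is.finite(fit$max_loglik))
    stop("perfect (zero-RSS) fit: score undefined, contests compare k",
         call. = FALSE)
  penalty - 2 * fit$max_loglik
}

# Scores for every model in the space on one dataset. Perfect fits (residual
# sum at rounding-noise level relative to the response scale) score as the
# penalty minus an offset dominating every attainable non-perfect score
# while keeping penalty arithmetic exact, so ties among them resolve by
# parameter count.
.score_all <- function(data, space, stat) {
  y <- data$response
  n <- length(y)
  yss <- sum(y^2)
  vapply(space$model_cols, function(cols) {
    f <- .lm.fit(data$design[, cols, drop = FALSE], y)
    rss <- sum(f$residuals^2)
    k <- length(cols) + 1L
    pen <- if (stat == "AIC") 2 * k else k * log(n)
    if (rss <= 1e-20 * yss) pen - 1e4 * n
    else pen + n * (log(2 * pi * rss / n) + 1)
  }, numeric(1))
}

#' Contest a proposed model against the global model
#'
#' Both models are fit to the same dataset and scored; the proposed model
#' dethrones the global model only if its score is strictly smaller
#' (\eqn{S(M_P) < S(M_G)}). Ties — including a self-proposal, where the
#' proposed and global model coincide — retain the global model. If both fits
#' are perfect (zero RSS), the contest is decided by parameter count, the
#' limiting behavior of the penalty.
#'
#' @param proposed,global_m \code{mc_model}s in \code{space}.
#' @param data an \code{mc_dataset}.
#' @param stat \code{"AIC"} or \code{"SC"}.
#' @param space the model space.
#' @return list of class \code{mc_contest}: \code{winner} (an
#'   \code{mc_model}), \code{proposed_won} (logical), \code{score_proposed},
#'   \code{score_global}.
#' @export
contest <- function(proposed, global_m, data, stat = c("AIC", "SC"),
                    space = the_space()) {
  stat <- .match_stat(stat)
  if (model_label(proposed) == model_label(global_m)) {
    f <- fit_mle(global_m, data, space)
    s <- ic_score_safe(f, stat)
    return(structure(list(winner = global_m, proposed_won = FALSE,
                          score_proposed = s, score_global = s),
                     class = "mc_contest"))
  }
  fp <- fit_mle(proposed, data, space)
  fg <- fit_mle(global_m, data, space)
  if (!is.finite(fp$max_loglik) && !is.finite(fg$max_loglik)) {
    won <- fp$k < fg$k
    sp <- -Inf; sg <- -Inf
  } else {
    sp <- ic_score_safe(fp, stat)
    sg <- ic_score_safe(fg, stat)
    won <- sp < sg
  }
  structure(list(winner = if (won) proposed else global_m,
                 proposed_won = won,
                 score_proposed = sp, score_global = sg),
            class = "mc_contest")
}

# ic_score with the zero-RSS sentinel mapped to -Inf rather than an error.
ic_score_safe <- function(fit, stat) {
  if (!is.finite(fit$max_loglik)) return(-Inf)
  ic_score(fit, stat)
}

#' @export
print.mc_contest <- function(x, ...) {
  cat("<contest> winner: ", model_label(x$winner),
      " (S_P = ", format(x$score_proposed),
      ", S_G = ", format(x$score_global), ")\n", sep = "")
  invisible(x)
}

#' Monte Carlo win probability of a proposed model over a global model
#'
#' Estimates, over \code{reps} independently generated datasets from the true
#' model, the probability that the proposed model beats the global model in a
#' [contest()]. A self-contest has probability exactly 0 (the tie rule).
#'
#' @param proposed,global_m \code{mc_model}s.
#' @param truth an \code{mc_truth} configuration.
#' @param stat \code{"AIC"} or \code{"SC"}.
#' @param reps number of Monte Carlo replicates.
#' @param n_override optional sample size replacing the configured one (used
#'   e.g. to study large-sample consistency of SC).
#' @return list of class \code{mc_winprob}: \code{estimate}, \code{se}
#'   (binomial), \code{reps}.
#' @export
win_probability <- function(proposed, global_m, truth, stat = c("AIC", "SC"),
                            reps = 10000L, n_override = NULL) {
  stat <- .match_stat(stat)
  stopifnot(reps >= 1L)
  if (!is.null(n_override)) {
    truth <- true_model_config(truth$model, truth$coefficients,
                               truth$noise_ratio, n_override,
                               truth$predictor_mean, truth$predictor_sd,
                               truth$predictor_law, truth$space)
  }
  if (model_label(proposed) == model_label(global_m)) {
    return(structure(list(estimate = 0, se = 0, reps = as.integer(reps)),
                     class = "mc_winprob"))
  }
  wins <- 0L
  for (r in seq_len(reps)) {
    d <- generate_dataset(truth)
    wins <- wins + contest(proposed, global_m, d, stat, truth$space)$proposed_won
  }
  p <- wins / reps
  structure(list(estimate = p, se = sqrt(p * (1 - p) / reps),
                 reps = as.integer(reps)),
            class = "mc_winprob")
}

#' @export
print.mc_winprob <- function(x, ...) {
  cat("<win probability> ", format(x$estimate), " (SE ", format(x$se),
      ", ", x$reps, " reps)\n", sep = "")
  invisible(x)
}

#' All-pairs win-probability tables for a true model
#'
#' Estimates, from a shared set of \code{reps} Monte Carlo datasets, the full
#' matrix \eqn{W[p, g] = P(S(M_p) < S(M_g))} of pairwise win probabilities
#' for every ordered pair of space models, under both AIC and SC at once
#' (each dataset is fit once per model; scores are then compared across all
#' pairs). Diagonals are 0 by the tie rule. These tables are the input to
#' [transition_matrix()].
#'
#' @param truth an \code{mc_truth}.
#' @param reps Monte Carlo replicates (default 10000, binomial SE <= 0.005).
#' @param engine \code{"cpp"} (compiled kernel, default) or \code{"r"}
#'   (reference implementation; identical estimator, slower).
#' @return list of class \code{mc_wintable}: \code{aic} and \code{sc}, each a
#'   \code{14 x 14} matrix with rows = proposed, columns = global, dimnames
#'   the model labels; plus \code{reps} and \code{truth}.
#' @export
win_table <- function(truth, reps = 10000L, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(truth, "mc_truth"), reps >= 1L)
  space <- truth$space
  nm <- length(space$models)
  truth_cols <- space$model_cols[[.model_index(truth$model, space)]]
  if (engine == "cpp") {
    res <- cpp_win_table(as.integer(truth$sample_size), as.integer(reps),
                         lapply(space$model_cols, as.integer),
                         as.integer(truth_cols),
                         as.numeric(truth$coefficients),
                         sqrt(calibrate_sigma2(truth)),
                         as.numeric(truth$predictor_mean),
                         as.numeric(truth$predictor_sd),
                         as.integer(space$n_factors),
                         vapply(space$design_terms, function(t)
                           sum(2^(t - 1L)), numeric(1)),
                         if (identical(truth$predictor_law, "uniform")) 1L
                         else 0L)
    aic <- res$aic / reps
    sc <- res$sc / reps
  } else {
    aic <- matrix(0, nm, nm)
    sc <- matrix(0, nm, nm)
    for (r in seq_len(reps)) {
      d <- generate_dataset(truth)
      sa <- .score_all(d, space, "AIC")
      ss <- .score_all(d, space, "SC")
      aic <- aic + outer(sa, sa, `<`)
      sc <- sc + outer(ss, ss, `<`)
    }
    aic <- aic / reps
    sc <- sc / reps
  }
  dimnames(aic) <- dimnames(sc) <- list(proposed = space$labels,
                                        global = space$labels)
  structure(list(aic = aic, sc = sc, reps = as.integer(reps), truth = truth),
            class = "mc_wintable")
}

#' @export
print.mc_wintable <- function(x, ...) {
  cat("<win-probability tables> true model ", model_label(x$truth$model),
      ", ", x$reps, " Monte Carlo reps\n", sep = "")
  invisible(x)
}
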
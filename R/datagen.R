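# Data generation from a configured true model, with the error variance
# calibrated against the model expectation at the predictor means.

#' Configure the true data-generating model
#'
#' Bundles everything the simulator needs to generate data: the true model,
#' its coefficients, the noise calibration, the sample size, and the
#' predictor law. The noise level is specified as the ratio of the error
#' variance to the expected value of the deterministic part at the predictor
#' means, \eqn{\sigma^2 : E(y \mid \mu_x)}; e.g. \code{noise_ratio = 1/4}
#' (the default, "1:4") puts the error variance at a quarter of the signal.
#'
#' @param model the true \code{mc_model} (default: x1 + x2 + x3 + x1x2).
#' @param coefficients named numeric vector of per-term coefficients, names
#'   being term labels as in [model_label()]; defaults to 1 for every term.
#' @param noise_ratio positive scalar \eqn{\rho} with
#'   \eqn{\sigma^2 = \rho \, E(y \mid \mu_x)}. Accepts a number or a string
#'   \code{"a:b"} meaning \eqn{a/b}.
#' @param sample_size observations per generated dataset (default 100).
#' @param predictor_mean,predictor_sd per-factor mean and sd of the i.i.d.
#'   predictor law; scalars are recycled. Defaults: mean 1, sd 1, so the
#'   expectation at the means equals the number of unit-coefficient terms
#'   and is strictly positive.
#' @param predictor_law \code{"normal"} (default) or \code{"uniform"}; the
#'   uniform law is centered at \code{predictor_mean} with half-width
#'   \code{sqrt(3) * predictor_sd} (same mean and variance).
#' @param space the model space the true model must belong to.
#' @return an object of class \code{mc_truth}.
#' @examples
#' cfg <- true_model_config(parse_model("1+2+12"), noise_ratio = "1:4")
#' expected_value_at_mean(cfg)   # 3 (three unit terms at unit means)
#' calibrate_sigma2(cfg)         # 0.75
#' @export
true_model_config <- function(model = parse_model("1+2+3+12"),
                              coefficients = NULL,
                              noise_ratio = 1 / 4,
                              sample_size = 100L,
                              predictor_mean = 1,
                              predictor_sd = 1,
                              predictor_law = c("normal", "uniform"),
                              space = the_space()) {
  predictor_law <- match.arg(predictor_law)
  stopifnot(inherits(model, "mc_model"))
  if (!in_space(model, space))
    stop("true model must be a member of the model space", call. = FALSE)
  labs <- vapply(model$terms, .term_label, character(1))
  if (is.null(coefficients)) coefficients <- setNames(rep(1, length(labs)), labs)
  if (is.null(names(coefficients)) ||
      !setequal(names(coefficients), labs))
    stop("'coefficients' must be named exactly by the model's term labels (",
         paste(labs, collapse = ", "), ")", call. = FALSE)
  coefficients <- coefficients[labs]
  rho <- parse_ratio(noise_ratio)
  if (!is.finite(rho) || rho < 0)
    stop("'noise_ratio' must be a nonnegative ratio", call. = FALSE)
  n <- as.integer(sample_size)
  if (n < length(labs) + 1L)
    stop("sample_size must exceed the number of predictors", call. = FALSE)
  nf <- space$n_factors
  mu <- rep_len(predictor_mean, nf)
  sdv <- rep_len(predictor_sd, nf)
  if (any(sdv < 0)) stop("'predictor_sd' must be nonnegative", call. = FALSE)
  cfg <- structure(list(model = model, coefficients = coefficients,
                        noise_ratio = rho, sample_size = n,
                        predictor_mean = mu, predictor_sd = sdv,
                        predictor_law = predictor_law, space = space),
                   class = "mc_truth")
  if (expected_value_at_mean(cfg) <= 0)
    stop(structure(class = c("mc_calibration_failure", "error", "condition"),
                   list(message = paste("expected value at the predictor means",
                                        "is not positive; the noise ratio is",
                                        "not meaningful for this configuration"),
                        call = sys.call())))
  cfg
}

#' Parse a noise ratio given as a number or an "a:b" string
#' @param x numeric scalar or string like \code{"1:4"}.
#' @return numeric scalar a/b.
#' @export
parse_ratio <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  parts <- as.numeric(strsplit(as.character(x), ":", fixed = TRUE)[[1]])
  if (length(parts) != 2L || any(is.na(parts)) || parts[2] == 0)
    stop("ratio must be numeric or of the form 'a:b'", call. = FALSE)
  parts[1] / parts[2]
}

#' @export
print.mc_truth <- function(x, ...) {
  cat("<true model config>\n",
      "  model:       ", model_label(x$model), "\n",
      "  noise ratio: ", format(x$noise_ratio), " (sigma^2 : E[y|mu_x])\n",
      "  sigma^2:     ", format(calibrate_sigma2(x)), "\n",
      "  n:           ", x$sample_size, "\n", sep = "")
  invisible(x)
}

#' Expected value of the true model at the predictor means
#'
#' Evaluates the deterministic part of the model at \eqn{\mu_x = E(x)}:
#' \eqn{\sum_T \theta_T \prod_{j \in T} \mu_j}. Note this is the plug-in
#' value at the means, the calibration anchor for the noise ratio, not
#' \eqn{E(y)} (which would include interaction covariances).
#'
#' @param config an \code{mc_truth}.
#' @return numeric scalar.
#' @export
expected_value_at_mean <- function(config) {
  stopifnot(inherits(config, "mc_truth"))
  mu <- config$predictor_mean
  sum(vapply(seq_along(config$model$terms), function(i) {
    config$coefficients[[i]] * prod(mu[config$model$terms[[i]]])
  }, numeric(1)))
}

#' Calibrated error variance for a true-model configuration
#'
#' \eqn{\sigma^2 = \rho \, E(y \mid \mu_x)} where \eqn{\rho} is the
#' configured noise ratio; e.g. ratio 1:4 with expectation 7 gives 1.75.
#'
#' @param config an \code{mc_truth}.
#' @return numeric scalar \eqn{\sigma^2}.
#' @export
calibrate_sigma2 <- function(config) {
  base <- expected_value_at_mean(config)
  if (base <= 0)
    stop(structure(class = c("mc_calibration_failure", "error", "condition"),
                   list(message = "nonpositive expectation at predictor means",
                        call = sys.call())))
  config$noise_ratio * base
}

# Full design matrix for the space (one column per term of the full model).
.design_matrix <- function(x, space) {
  do.call(cbind, lapply(space$design_terms, function(t) {
    out <- x[, t[1]]
    for (j in t[-1]) out <- out * x[, j]
    out
  }))
}

#' Generate one dataset from the true model
#'
#' Draws \code{n} predictor rows i.i.d. from the configured Gaussian law and
#' responses \eqn{y_i = \sum_T \theta_T \prod_{j\in T} x_{ij} + \epsilon_i}
#' with \eqn{\epsilon_i \sim N(0, \sigma^2)} at the calibrated variance.
#' Reproducible under \code{set.seed()}.
#'
#' @param config an \code{mc_truth}.
#' @return a list of class \code{mc_dataset} with \code{predictors} (an
#'   \eqn{n \times} \code{n_factors} matrix, columns \code{x1,x2,...}),
#'   \code{response}, and \code{design} (the full design matrix of the space,
#'   one column per term, used by the fitters).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "mc_truth"))
  n <- config$sample_size
  nf <- config$space$n_factors
  mu <- rep(config$predictor_mean, each = n)
  sdv <- rep(config$predictor_sd, each = n)
  draws <- if (identical(config$predictor_law, "uniform"))
    runif(n * nf, mu - sqrt(3) * sdv, mu + sqrt(3) * sdv)
  else rnorm(n * nf, mean = mu, sd = sdv)
  x <- matrix(draws, nrow = n, ncol = nf,
              dimnames = list(NULL, paste0("x", seq_len(nf))))
  X <- .design_matrix(x, config$space)
  truth_cols <- config$space$model_cols[[.model_index(config$model,
                                                      config$space)]]
  sigma <- sqrt(calibrate_sigma2(config))
  y <- drop(X[, truth_cols, drop = FALSE] %*% config$coefficients) +
    rnorm(n, 0, sigma)
  structure(list(predictors = x, response = y, design = X),
            class = "mc_dataset")
}

#' @export
print.mc_dataset <- function(x, ...) {
  cat("<dataset> n = ", length(x$response), ", ",
      ncol(x$predictors), " factors\n", sep = "")
  invisible(x)
}

#' Export a dataset as a data frame
#' @param x an \code{mc_dataset}.
#' @param row.names,optional,... passed on conventions of [as.data.frame()].
#' @return data.frame with columns x1..x3 and y.
#' @export
as.data.frame.mc_dataset <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  data.frame(x$predictors, y = x$response)
}
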
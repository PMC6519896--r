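#' @useDynLib modelcentric, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif setNames median quantile cor sd var
NULL

# Terms are sorted integer vectors of factor indices; a model is a set of
# terms closed under the hierarchy (every interaction carries its sub-terms).

.term_label <- function(term) paste0(sort(term), collapse = "")

.canonical_terms <- function(terms) {
  terms <- lapply(terms, function(t) sort(unique(as.integer(t))))
  labels <- vapply(terms, .term_label, character(1))
  terms <- terms[!duplicated(labels)]
  ord <- order(lengths(terms), vapply(terms, .term_label, character(1)))
  terms[ord]
}

#' Construct a linear model as a set of predictor terms
#'
#' A model is a set of terms, each term a nonempty set of factor indices:
#' \code{list(1)} is the main effect of factor 1, \code{list(c(1, 2))} the
#' two-way interaction between factors 1 and 2, and so on. Models carry no
#' intercept. The constructor canonicalizes term order (main effects first,
#' then interactions, ties broken lexicographically) but does not enforce
#' hierarchical closure; use [hierarchical_closure()] for that.
#'
#' @param terms list of integer vectors (one per term), or a single integer
#'   vector for a one-term model.
#' @return An object of class \code{mc_model}.
#' @seealso [model_label()], [parse_model()], [hierarchical_closure()]
#' @examples
#' mc_model(list(1, 2, c(1, 2)))   # y = b1 x1 + b2 x2 + b12 x1 x2 + e
#' @export
mc_model <- function(terms) {
  if (is.numeric(terms)) terms <- list(terms)
  if (!is.list(terms) || length(terms) == 0L)
    stop("'terms' must be a nonempty list of integer vectors", call. = FALSE)
  terms <- .canonical_terms(terms)
  bad <- vapply(terms, function(t) length(t) == 0L || any(t < 1L), logical(1))
  if (any(bad))
    stop("each term must be a nonempty set of positive factor indices",
         call. = FALSE)
  structure(list(terms = terms), class = "mc_model")
}

#' Canonical string form of a model
#'
#' Models serialize as \code{"+"}-joined term labels, each label the
#' concatenated factor indices of the term: \code{"1+2+12"} is the model with
#' mains x1, x2 and their interaction. This string is the model's identity in
#' CSV/JSON output and CLI arguments.
#'
#' @param model an \code{mc_model}.
#' @return length-1 character.
#' @export
model_label <- function(model) {
  stopifnot(inherits(model, "mc_model"))
  paste(vapply(model$terms, .term_label, character(1)), collapse = "+")
}

#' Parse a model from its canonical string form
#'
#' Inverse of [model_label()]: \code{parse_model("1+2+12")} returns the model
#' with terms x1, x2, x1x2.
#'
#' @param label character string such as \code{"1+2+12"}.
#' @return an \code{mc_model}.
#' @export
parse_model <- function(label) {
  parts <- strsplit(trimws(label), "+", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0L) stop("empty model label", call. = FALSE)
  terms <- lapply(parts, function(p) {
    as.integer(strsplit(p, "")[[1]])
  })
  mc_model(terms)
}

#' @export
format.mc_model <- function(x, ...) model_label(x)

#' @export
print.mc_model <- function(x, ...) {
  cat("<model> ", model_label(x), "\n", sep = "")
  invisible(x)
}

#' @export
`==.mc_model` <- function(e1, e2) model_label(e1) == model_label(e2)

#' Number of predictor terms in a model
#' @param model an \code{mc_model}.
#' @return integer count of predictors (terms).
#' @export
n_predictors <- function(model) length(model$terms)

#' Number of interaction terms in a model
#' @param model an \code{mc_model}.
#' @return integer count of terms of order two or higher.
#' @export
n_interactions <- function(model) sum(lengths(model$terms) >= 2L)

.has_term <- function(model, term) {
  .term_label(term) %in% vapply(model$terms, .term_label, character(1))
}

#' Hierarchical closure of a term set
#'
#' Returns the smallest model containing the given terms in which every
#' interaction's lower-order terms (all nonempty proper subsets) are present.
#' For example, the closure of the three-way interaction x1x2x3 alone is the
#' full 7-predictor model.
#'
#' @param terms a list of integer vectors, a single integer vector, or an
#'   \code{mc_model}.
#' @return a hierarchically closed \code{mc_model}.
#' @export
hierarchical_closure <- function(terms) {
  if (inherits(terms, "mc_model")) terms <- terms$terms
  if (is.numeric(terms)) terms <- list(terms)
  out <- list()
  for (t in terms) {
    t <- sort(unique(as.integer(t)))
    k <- length(t)
    for (m in seq_len(2^k - 1L)) {
      sub <- t[bitwAnd(m, 2^(seq_len(k) - 1L)) > 0L]
      out[[length(out) + 1L]] <- sub
    }
  }
  mc_model(out)
}

#' Enumerate the hierarchical model space
#'
#' Builds the space of hierarchical linear models the discovery process walks
#' on. For three factors the space has exactly 14 models: the 7 nonempty
#' subsets of main effects; the three models \{xi, xj, xixj\} pairing two
#' mains with their interaction; the three models with all mains plus one
#' two-way interaction; and the full model with all 7 predictors (three
#' mains, three two-way interactions, the three-way interaction). Models with
#' two two-way interactions but no three-way term are deliberately absent.
#' Models are ordered simple to complex: by predictor count, then interaction
#' count, then lexicographically.
#'
#' @param n_factors number of factors; 3 is the canonical, fully supported
#'   space. 1 and 2 are provided for toy analyses (with a warning); larger
#'   spaces are out of scope.
#' @return An object of class \code{mc_space}: list with \code{models} (list
#'   of \code{mc_model}), \code{labels}, \code{n_factors}, and design-matrix
#'   bookkeeping used by the fitting kernels (\code{design_terms}: the term of
#'   each column of the full design matrix; \code{model_cols}: per-model
#'   column indices into it).
#' @examples
#' sp <- enumerate_space(3)
#' length(sp$models)                 # 14
#' max(vapply(sp$models, n_predictors, integer(1)))   # 7
#' @export
enumerate_space <- function(n_factors = 3L) {
  n_factors <- as.integer(n_factors)
  if (length(n_factors) != 1L || is.na(n_factors) || n_factors < 1L)
    stop("'n_factors' must be a positive integer", call. = FALSE)
  if (n_factors > 3L)
    stop("model spaces on more than 3 factors are not supported", call. = FALSE)
  if (n_factors != 3L)
    warning("n_factors != 3 is experimental (toy space)", call. = FALSE)

  mains_subsets <- function(n) {
    idx <- seq_len(n)
    out <- list()
    for (m in seq_len(2^n - 1L)) {
      out[[length(out) + 1L]] <- as.list(idx[bitwAnd(m, 2^(idx - 1L)) > 0L])
    }
    out
  }

  models <- lapply(mains_subsets(n_factors), mc_model)
  if (n_factors >= 2L) {
    pairs <- utils::combn(n_factors, 2L, simplify = FALSE)
    for (p in pairs) {  # {xi, xj, xixj}
      models[[length(models) + 1L]] <- mc_model(c(as.list(p), list(p)))
    }
    if (n_factors == 3L) {
      for (p in pairs) {  # all mains + one two-way interaction
        models[[length(models) + 1L]] <- mc_model(c(list(1, 2, 3), list(p)))
      }
      models[[length(models) + 1L]] <-
        hierarchical_closure(list(c(1, 2, 3)))   # full 7-predictor model
    }
  }

  ord <- order(vapply(models, n_predictors, integer(1)),
               vapply(models, n_interactions, integer(1)),
               vapply(models, model_label, character(1)))
  models <- models[ord]
  labels <- vapply(models, model_label, character(1))
  stopifnot(!anyDuplicated(labels))

  design_terms <- .canonical_terms(
    hierarchical_closure(list(seq_len(n_factors)))$terms)
  design_labels <- vapply(design_terms, .term_label, character(1))
  model_cols <- lapply(models, function(m) {
    match(vapply(m$terms, .term_label, character(1)), design_labels)
  })

  structure(list(models = models, labels = labels, n_factors = n_factors,
                 design_terms = design_terms, model_cols = model_cols),
            class = "mc_space")
}

#' @export
print.mc_space <- function(x, ...) {
  cat("<model space> ", length(x$models), " hierarchical models on ",
      x$n_factors, " factors\n", sep = "")
  cat(paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Test membership of a model in a space
#' @param model an \code{mc_model}.
#' @param space an \code{mc_space}.
#' @return logical.
#' @export
in_space <- function(model, space) model_label(model) %in% space$labels

.model_index <- function(model, space) {
  i <- match(model_label(model), space$labels)
  if (is.na(i)) stop("model ", model_label(model), " is not in the space",
                     call. = FALSE)
  i
}

#' Drop a main effect (hierarchically) from a model
#'
#' Removes the main effect of \code{factor} together with every interaction
#' term containing that factor, so the result stays hierarchical.
#'
#' @param model an \code{mc_model} containing the main effect of \code{factor}.
#' @param factor factor index.
#' @return the reduced \code{mc_model}.
#' @section Errors: dropping a factor whose main effect is absent signals an
#'   \code{mc_invalid_proposal} condition; a drop that would empty the model
#'   signals \code{mc_empty_model} (the empty model is not a state of the
#'   process, so callers must exclude such moves).
#' @export
drop_main <- function(model, factor) {
  factor <- as.integer(factor)
  if (!.has_term(model, factor))
    stop(structure(class = c("mc_invalid_proposal", "error", "condition"),
                   list(message = sprintf("main effect %d not in model %s",
                                          factor, model_label(model)),
                        call = sys.call())))
  keep <- model$terms[!vapply(model$terms, function(t) factor %in% t,
                              logical(1))]
  if (length(keep) == 0L)
    stop(structure(class = c("mc_empty_model", "error", "condition"),
                   list(message = "dropping this main effect empties the model",
                        call = sys.call())))
  mc_model(keep)
}

#' Add a main effect to a model
#'
#' @param model an \code{mc_model} not containing the main effect of
#'   \code{factor}.
#' @param factor factor index to add.
#' @param space the model space used to validate the result (defaults to the
#'   canonical 3-factor space).
#' @return the enlarged \code{mc_model}.
#' @section Errors: adding an already-present main signals
#'   \code{mc_invalid_proposal}; a result outside the space signals
#'   \code{mc_out_of_space}.
#' @export
add_main <- function(model, factor, space = the_space()) {
  factor <- as.integer(factor)
  if (.has_term(model, factor))
    stop(structure(class = c("mc_invalid_proposal", "error", "condition"),
                   list(message = sprintf("main effect %d already in model %s",
                                          factor, model_label(model)),
                        call = sys.call())))
  out <- mc_model(c(model$terms, list(factor)))
  if (!in_space(out, space))
    stop(structure(class = c("mc_out_of_space", "error", "condition"),
                   list(message = sprintf("model %s is outside the space",
                                          model_label(out)),
                        call = sys.call())))
  out
}

#' Hierarchical interaction supersets of a model within a space
#'
#' For every interaction term not in \code{model}, forms the hierarchical
#' closure of the model plus that term and keeps the distinct results that lie
#' in the space. This is the proposal set of the boundary-testing strategy:
#' each member strictly contains the input and adds at least one interaction.
#' At the full model the set is empty.
#'
#' @param model an \code{mc_model} belonging to \code{space}.
#' @param space an \code{mc_space}.
#' @return list of \code{mc_model} (possibly empty).
#' @export
interaction_supersets <- function(model, space = the_space()) {
  stopifnot(in_space(model, space))
  cands <- space$design_terms[lengths(space$design_terms) >= 2L]
  out <- list()
  seen <- character(0)
  for (t in cands) {
    if (.has_term(model, t)) next
    m2 <- hierarchical_closure(c(model$terms, list(t)))
    lab <- model_label(m2)
    if (lab %in% seen || !lab %in% space$labels) next
    seen <- c(seen, lab)
    out[[length(out) + 1L]] <- m2
  }
  out
}

# The canonical 3-factor space, built once per session.
.mc_env <- new.env(parent = emptyenv())

#' The canonical 14-model space on three factors
#'
#' Memoised convenience accessor for \code{enumerate_space(3)}; most functions
#' in the package default to this space.
#' @return an \code{mc_space}.
#' @export
the_space <- function() {
  if (is.null(.mc_env$space3)) .mc_env$space3 <- enumerate_space(3L)
  .mc_env$space3
}
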
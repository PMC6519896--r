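# Proposal strategies: Tess (theory tester), Mave (maverick), Bo (boundary
# tester). Rey (replicator) proposes nothing herself; her semantics live in
# the ABM engine.

.SCIENTIST_TYPES <- c("tess", "mave", "bo", "rey")

#' Proposal set of the theory tester (Tess)
#'
#' Tess refines the consensus: she proposes models exactly one main-effect
#' move away from the global model, either adding a missing main effect or
#' dropping a present one. Drops are hierarchical (every interaction
#' containing the dropped factor goes too). Moves that would empty the model
#' or leave the space are excluded. Within the 14-model space every state has
#' at least two such neighbours.
#'
#' @param global_m the current global \code{mc_model}.
#' @param space an \code{mc_space}.
#' @return list of \code{mc_model}.
#' @export
tess_proposals <- function(global_m, space = the_space()) {
  stopifnot(in_space(global_m, space))
  mains_in <- unlist(global_m$terms[lengths(global_m$terms) == 1L])
  mains_out <- setdiff(seq_len(space$n_factors), mains_in)
  out <- list()
  for (f in mains_out) {
    m2 <- tryCatch(add_main(global_m, f, space), mc_out_of_space = function(e) NULL)
    if (!is.null(m2)) out[[length(out) + 1L]] <- m2
  }
  for (f in mains_in) {
    m2 <- tryCatch(drop_main(global_m, f), mc_empty_model = function(e) NULL)
    if (!is.null(m2) && in_space(m2, space)) out[[length(out) + 1L]] <- m2
  }
  out
}

#' Proposal distribution of the maverick (Mave)
#'
#' Mave ignores the consensus entirely and proposes uniformly from the whole
#' model space (including the current global model; a self-proposal resolves
#' as a retained contest).
#'
#' @param space an \code{mc_space}.
#' @param include_global kept for sensitivity analyses: if \code{FALSE} the
#'   caller should renormalize after removing the global model. The default
#'   (\code{TRUE}) matches the uniform-over-all-models strategy.
#' @return named numeric vector of probabilities over \code{space$labels}.
#' @export
mave_proposals <- function(space = the_space(), include_global = TRUE) {
  nm <- length(space$models)
  setNames(rep(1 / nm, nm), space$labels)
}

#' Proposal set of the boundary tester (Bo)
#'
#' Bo probes the limits of the consensus by adding interactions: her
#' candidates are the hierarchical interaction supersets of the global model
#' that lie in the space ([interaction_supersets()]). At the full model this
#' set is empty; the documented fallback is to propose the global model
#' itself, a guaranteed-retain contest, so the step stays well defined
#' without injecting off-strategy behavior.
#'
#' @param global_m the current global \code{mc_model}.
#' @param space an \code{mc_space}.
#' @return list of \code{mc_model} (the fallback returns the global model as
#'   the single element).
#' @export
bo_proposals <- function(global_m, space = the_space()) {
  out <- interaction_supersets(global_m, space)
  if (length(out) == 0L) list(global_m) else out
}

#' Strategy mode (hard or soft proposals)
#'
#' Under hard strategies a scientist proposes only strategy-consistent
#' models. Under soft strategies she departs from her strategy with total
#' probability \code{epsilon}, spread uniformly over the models outside her
#' strategy set; the strategy set keeps \code{1 - epsilon} spread uniformly.
#' Soft strategies with \code{epsilon > 0} make every model proposable by
#' every type, which is what keeps the induced Markov chain irreducible.
#'
#' @param mode \code{"hard"} or \code{"soft"}.
#' @param epsilon off-strategy probability mass in \[0, 1); forced to 0 in
#'   hard mode. Default 0.1.
#' @param spread \code{"complement"} (default: off-strategy mass goes only to
#'   models outside the strategy set) or \code{"all"} (off-strategy mass is
#'   uniform over the whole space).
#' @return list of class \code{mc_mode}.
#' @export
strategy_mode <- function(mode = c("soft", "hard"), epsilon = 0.1,
                          spread = c("complement", "all")) {
  mode <- match.arg(mode)
  spread <- match.arg(spread)
  epsilon <- if (mode == "hard") 0 else as.numeric(epsilon)
  if (epsilon < 0 || epsilon >= 1)
    stop("'epsilon' must be in [0, 1)", call. = FALSE)
  structure(list(mode = mode, epsilon = epsilon, spread = spread),
            class = "mc_mode")
}

#' @export
print.mc_mode <- function(x, ...) {
  cat("<strategy mode> ", x$mode,
      if (x$mode == "soft") paste0(" (epsilon = ", x$epsilon, ")"), "\n",
      sep = "")
  invisible(x)
}

#' Proposal distribution of a scientist type given the global model
#'
#' Hard mode: uniform over the type's strategy set. Soft mode: mixture of
#' \code{1 - epsilon} uniform over the strategy set and \code{epsilon}
#' uniform over the off-strategy models (or over all models, depending on
#' the mode's \code{spread}); if the off-strategy set is empty all mass
#' stays on the strategy set.
#'
#' @param type \code{"tess"}, \code{"mave"} or \code{"bo"} (Rey has no
#'   proposal distribution of her own).
#' @param global_m the current global \code{mc_model}.
#' @param space an \code{mc_space}.
#' @param mode an [strategy_mode()].
#' @return named probability vector over \code{space$labels}, summing to 1.
#' @export
proposal_distribution <- function(type, global_m, space = the_space(),
                                  mode = strategy_mode()) {
  type <- match.arg(tolower(type), c("tess", "mave", "bo"))
  nm <- length(space$models)
  p <- setNames(numeric(nm), space$labels)
  strat <- switch(type,
    tess = vapply(tess_proposals(global_m, space), model_label, character(1)),
    mave = space$labels,
    bo = vapply(bo_proposals(global_m, space), model_label, character(1)))
  p[strat] <- (1 - mode$epsilon) / length(strat)
  if (mode$epsilon > 0) {
    off <- if (mode$spread == "all") space$labels else
      setdiff(space$labels, strat)
    if (length(off) == 0L) {
      p[strat] <- p[strat] + mode$epsilon / length(strat)
    } else {
      p[off] <- p[off] + mode$epsilon / length(off)
    }
  }
  p
}

#' Per-type proposal probability matrix over the space
#'
#' Stacks [proposal_distribution()] over every possible global model into a
#' row-stochastic matrix \code{Q[g, m] = P(type proposes m | global g)}, the
#' form consumed by [transition_matrix()] and the ABM engine, and convenient
#' for CSV export.
#'
#' @inheritParams proposal_distribution
#' @return \code{14 x 14} row-stochastic matrix, dimnames
#'   \code{(global, proposed)}.
#' @export
proposal_matrix <- function(type, space = the_space(),
                            mode = strategy_mode()) {
  q <- t(vapply(space$models,
                function(g) proposal_distribution(type, g, space, mode),
                numeric(length(space$models))))
  dimnames(q) <- list(global = space$labels, proposed = space$labels)
  q
}

#' Scientist population composition
#'
#' Proportions of the four scientist types in the (infinite) population. The
#' exact Markov analysis of the no-replication process requires
#' \code{rey = 0}; the ABM accepts any composition.
#'
#' @param tess,mave,bo,rey nonnegative weights; normalized to sum to 1.
#' @return named numeric vector of class \code{mc_population}.
#' @seealso [population_preset()]
#' @export
population <- function(tess = 0, mave = 0, bo = 0, rey = 0) {
  w <- c(tess = tess, mave = mave, bo = bo, rey = rey)
  if (any(w < 0) || sum(w) <= 0)
    stop("population weights must be nonnegative and not all zero",
         call. = FALSE)
  structure(w / sum(w), class = "mc_population")
}

#' @export
print.mc_population <- function(x, ...) {
  cat("<population> ", paste(sprintf("%s %.3f", names(x), unclass(x)),
                             collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Standard population presets
#'
#' Dominant presets put 99\% of the population on one type and split the
#' remaining 1\% equally over the other types represented in the system:
#' over the other two proposer types in the no-replication (Markov) system,
#' over the other three types in the replication (ABM) system. The diverse
#' preset represents all system types equally.
#'
#' @param name one of \code{"tess"}, \code{"mave"}, \code{"bo"},
#'   \code{"rey"} (ABM only), \code{"diverse"}.
#' @param system \code{"markov"} (three proposer types, no Rey) or
#'   \code{"abm"} (all four types).
#' @return an [population()] object.
#' @export
population_preset <- function(name = c("tess", "mave", "bo", "rey", "diverse"),
                              system = c("markov", "abm")) {
  name <- match.arg(name)
  system <- match.arg(system)
  types <- if (system == "markov") c("tess", "mave", "bo") else .SCIENTIST_TYPES
  if (name == "diverse") {
    w <- setNames(rep(1 / length(types), length(types)), types)
  } else {
    if (!name %in% types)
      stop("preset '", name, "' is not available in the ", system, " system",
           call. = FALSE)
    w <- setNames(rep(0.01 / (length(types) - 1L), length(types)), types)
    w[name] <- 0.99
  }
  do.call(population, as.list(w))
}
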
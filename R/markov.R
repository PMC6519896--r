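# Exact Markov-chain analysis of the no-replication discovery process.

#' Transition matrix of the no-replication discovery chain
#'
#' With no replicator in the population the global model evolves as a
#' first-order Markov chain on the model space. The off-diagonal transition
#' probability from global model g to model m is
#' \deqn{T[g, m] = \sum_{types} w_t \, q_t(m \mid g) \, p_{win}(m, g),}
#' the chance that a scientist of some type is drawn, proposes m, and m wins
#' the contest; the diagonal absorbs lost contests, self-proposals, and
#' ties. Win probabilities come from a Monte Carlo [win_table()].
#'
#' @param pop an [population()] with zero weight on Rey.
#' @param wintable an \code{mc_wintable} for the chain's true model.
#' @param stat \code{"AIC"} or \code{"SC"}.
#' @param mode an [strategy_mode()]; soft mode keeps the chain irreducible.
#' @return list of class \code{mc_chain}: \code{T} (row-stochastic matrix),
#'   \code{labels}, \code{truth_label}, \code{stat}, \code{mode},
#'   \code{pop}, \code{space}.
#' @export
transition_matrix <- function(pop, wintable, stat = c("AIC", "SC"),
                              mode = strategy_mode()) {
  stat <- .match_stat(stat)
  stopifnot(inherits(pop, "mc_population"), inherits(wintable, "mc_wintable"))
  if (pop[["rey"]] > 0)
    stop("the exact chain analysis requires a population without Rey",
         call. = FALSE)
  space <- wintable$truth$space
  W <- if (stat == "AIC") wintable$aic else wintable$sc   # W[p, g]
  nm <- length(space$models)
  Tm <- matrix(0, nm, nm, dimnames = list(from = space$labels,
                                          to = space$labels))
  types <- c("tess", "mave", "bo")
  Q <- lapply(setNames(types, types),
              function(ty) proposal_matrix(ty, space, mode))
  for (ty in types) {
    w <- pop[[ty]]
    if (w == 0) next
    # proposal prob (row g, col m) times the proposal's win prob vs g
    Tm <- Tm + w * (Q[[ty]] * t(W))
  }
  diag(Tm) <- 0
  diag(Tm) <- 1 - rowSums(Tm)
  stopifnot(all(Tm >= -1e-12), all(abs(rowSums(Tm) - 1) < 1e-12))
  Tm[Tm < 0] <- 0
  structure(list(T = Tm, labels = space$labels,
                 truth_label = model_label(wintable$truth$model),
                 stat = stat, mode = mode, pop = pop, space = space),
            class = "mc_chain")
}

#' @export
print.mc_chain <- function(x, ...) {
  cat("<discovery chain> ", length(x$labels), " states, statistic ", x$stat,
      ", true model ", x$truth_label, "\n", sep = "")
  invisible(x)
}

# Strongly-connected check by boolean reachability (matrix squaring).
.irreducible <- function(Tm, tol = 0) {
  A <- (Tm > tol) | diag(nrow(Tm)) > 0
  for (i in seq_len(ceiling(log2(nrow(Tm))) + 1L)) {
    A <- (A %*% A) > 0
  }
  all(A)
}

# Closed (recurrent) communicating classes: classes with no escape.
.closed_classes <- function(Tm) {
  cls <- .comm_classes(Tm)
  Filter(function(members) {
    idx <- match(members, rownames(Tm))
    sum(Tm[idx, -idx, drop = FALSE]) == 0
  }, cls)
}

#' Stationary distribution of a discovery chain
#'
#' Solves \eqn{\pi T = \pi}, \eqn{\sum \pi = 1} as a linear system. The
#' stationary probability of the true model is the long-run proportion of
#' time the community's consensus is the truth. \eqn{\pi} is unique when the
#' chain has a single closed communicating class (soft strategies keep the
#' chain connected up to Monte Carlo zeros in the win table, which can only
#' leave some states transient — those get \eqn{\pi = 0}); an aperiodicity
#' check is included because the ergodic reading of \eqn{\pi} as a long-run
#' frequency additionally needs it (self-loops from retained contests make
#' the chain aperiodic in practice).
#'
#' @param chain an \code{mc_chain} (or a bare row-stochastic matrix).
#' @return named probability vector \eqn{\pi}.
#' @section Errors: a reducible chain signals \code{mc_reducible_chain} with
#'   the communicating-class structure in the condition's \code{classes}
#'   field rather than returning a meaningless \eqn{\pi}.
#' @export
stationary_distribution <- function(chain) {
  Tm <- if (inherits(chain, "mc_chain")) chain$T else chain
  nm <- nrow(Tm)
  if (!.irreducible(Tm)) {
    # A Monte Carlo win table can put exact zeros on transitions into very
    # weak models, leaving them transient. The stationary distribution is
    # still unique (zero on transient states) as long as there is a single
    # closed class; only multiple closed classes make pi ill-defined.
    closed <- .closed_classes(Tm)
    if (length(closed) != 1L) {
      cls <- .comm_classes(Tm)
      stop(structure(class = c("mc_reducible_chain", "error", "condition"),
                     list(message = paste("chain has", length(closed),
                                          "closed communicating classes;",
                                          "stationary distribution undefined"),
                          call = sys.call(), classes = cls)))
    }
  }
  if (all(diag(Tm) == 0))
    warning("no self-loops: aperiodicity not guaranteed", call. = FALSE)
  A <- t(diag(nm) - Tm)
  A[nm, ] <- 1
  b <- c(rep(0, nm - 1L), 1)
  pi_ <- solve(A, b)
  pi_[pi_ < 0 & pi_ > -1e-12] <- 0
  setNames(pi_ / sum(pi_), rownames(Tm))
}

.comm_classes <- function(Tm) {
  A <- (Tm > 0) | diag(nrow(Tm)) > 0
  for (i in seq_len(ceiling(log2(nrow(Tm))) + 1L)) A <- (A %*% A) > 0
  mutual <- A & t(A)
  cls <- list()
  left <- seq_len(nrow(Tm))
  while (length(left)) {
    i <- left[1]
    members <- which(mutual[i, ])
    cls[[length(cls) + 1L]] <- rownames(Tm)[members]
    left <- setdiff(left, members)
  }
  cls
}

#' Mean first passage time to a target state
#'
#' Expected time until the chain first reaches \code{target} from each
#' initial state, solving \eqn{m_i = 1 + \sum_{j \ne target} T_{ij} m_j}
#' with \eqn{m_{target} = 0}. Time can be counted on two clocks:
#' \code{"experiments"} counts every experiment, including the (dominant
#' share of) contests whose outcome retains the consensus;
#' \code{"updates"} counts only consensus changes, i.e. first passage of
#' the embedded jump chain obtained by deleting self-loops and
#' renormalizing rows. Under low noise most contests retain the global
#' model, so the two clocks differ by an order of magnitude; both are
#' reported by [chain_metrics()].
#'
#' @param chain an \code{mc_chain} (or row-stochastic matrix).
#' @param target state label (defaults to the chain's true model).
#' @param time \code{"experiments"} (default) or \code{"updates"}.
#' @return named numeric vector of MFPTs, 0 at the target.
#' @section Errors: if the target is unreachable from some state the system
#'   has no finite solution; this signals \code{mc_unreachable_target}.
#' @export
mean_first_passage <- function(chain, target = NULL,
                               time = c("experiments", "updates")) {
  time <- match.arg(time)
  Tm <- if (inherits(chain, "mc_chain")) chain$T else chain
  if (is.null(target)) {
    stopifnot(inherits(chain, "mc_chain"))
    target <- chain$truth_label
  }
  if (time == "updates") {
    stay <- diag(Tm)
    if (any(stay >= 1 & rownames(Tm) != target))
      stop(structure(class = c("mc_unreachable_target", "error", "condition"),
                     list(message = "an absorbing non-target state blocks the jump chain",
                          call = sys.call())))
    Tm <- Tm / (1 - stay)
    diag(Tm) <- 0
  }
  ti <- match(target, rownames(Tm))
  if (is.na(ti)) stop("unknown target state '", target, "'", call. = FALSE)
  Q <- Tm[-ti, -ti, drop = FALSE]
  m <- tryCatch(solve(diag(nrow(Q)) - Q, rep(1, nrow(Q))),
                error = function(e) NULL)
  if (is.null(m) || any(!is.finite(m)) || any(m < 0))
    stop(structure(class = c("mc_unreachable_target", "error", "condition"),
                   list(message = paste("target", target,
                                        "is not reachable from every state"),
                        call = sys.call())))
  out <- numeric(nrow(Tm))
  out[-ti] <- m
  setNames(out, rownames(Tm))
}

#' Stickiness of a state
#'
#' The one-step probability that the chain stays put: \code{T[state, state]}.
#' Applied to the true model this is the chance the consensus survives one
#' more experiment once the community has found the truth.
#'
#' @param chain an \code{mc_chain} (or row-stochastic matrix).
#' @param state state label (defaults to the chain's true model).
#' @return probability in \[0, 1\].
#' @export
stickiness <- function(chain, state = NULL) {
  Tm <- if (inherits(chain, "mc_chain")) chain$T else chain
  if (is.null(state)) {
    stopifnot(inherits(chain, "mc_chain"))
    state <- chain$truth_label
  }
  si <- match(state, rownames(Tm))
  if (is.na(si)) stop("unknown state '", state, "'", call. = FALSE)
  unname(Tm[si, si])
}

#' Summary metrics of a discovery chain
#'
#' Convenience wrapper computing the three chain-level properties of the
#' discovery process for the chain's true model: stationary probability
#' (long-run time at truth), stickiness, and the mean first passage time
#' averaged uniformly over initial states other than the truth.
#'
#' @param chain an \code{mc_chain}.
#' @return list of class \code{mc_chain_metrics}: \code{stationary} (full
#'   vector), \code{time_at_truth}, \code{stickiness}, \code{mfpt} (full
#'   vector, experiment clock), \code{mfpt_mean} (over initial states !=
#'   truth), and the consensus-update clock analogues \code{mfpt_updates},
#'   \code{mfpt_updates_mean} (see [mean_first_passage()]).
#' @export
chain_metrics <- function(chain) {
  stopifnot(inherits(chain, "mc_chain"))
  pi_ <- stationary_distribution(chain)
  m <- mean_first_passage(chain)
  mu_ <- mean_first_passage(chain, time = "updates")
  keep <- setdiff(names(m), chain$truth_label)
  structure(list(stationary = pi_,
                 time_at_truth = unname(pi_[chain$truth_label]),
                 stickiness = stickiness(chain),
                 mfpt = m,
                 mfpt_mean = mean(m[keep]),
                 mfpt_updates = mu_,
                 mfpt_updates_mean = mean(mu_[keep]),
                 truth_label = chain$truth_label,
                 stat = chain$stat),
            class = "mc_chain_metrics")
}

#' @export
print.mc_chain_metrics <- function(x, ...) {
  cat("<chain metrics> true model ", x$truth_label, " (", x$stat, ")\n",
      "  time at truth (stationary): ", sprintf("%.4f", x$time_at_truth), "\n",
      "  stickiness:                 ", sprintf("%.4f", x$stickiness), "\n",
      "  mean first passage (avg):   ", sprintf("%.3f", x$mfpt_mean),
      " experiments / ", sprintf("%.3f", x$mfpt_updates_mean),
      " consensus updates\n", sep = "")
  invisible(x)
}
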
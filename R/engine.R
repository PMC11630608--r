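# Core propagation engine: integer <-> probability transforms, the per-parent
# Bayesian update, the dual posterior formulas with max-certainty selection,
# synchronous iteration with prior pinning, and bbn_predict().

P_MIN <- 0.1
P_MAX <- 0.9
INFORMATIVE_TOL <- 1e-9

#' Convert an integer change value to its working probability
#'
#' Node priors and edge strengths are supplied on an ordinal integer scale
#' from -4 (strong decrease / strong negative interaction) to 4 (strong
#' increase / strong positive interaction). Internally the engine works with
#' the probability that a node increases, obtained by the linear map
#' `0.5 + 0.1 * v`. The extremes are 0.1 and 0.9 rather than 0 and 1,
#' reflecting irreducible uncertainty in complex systems.
#'
#' @param v integer (or vector of integers) in -4..4.
#' @return numeric probability in \[0.1, 0.9\] of the same length as `v`.
#' @examples
#' to_probability(-4) # 0.1
#' to_probability(0)  # 0.5
#' to_probability(4)  # 0.9
#' @export
to_probability <- function(v) {
  if (length(v) == 0L) stop("`v` must have length >= 1", call. = FALSE)
  if (!is.numeric(v) || anyNA(v) || any(v != round(v))) {
    stop("change values must be integers in -4..4, got: ",
         paste(utils::head(v[is.na(v) | v != round(v)], 3L), collapse = ", "),
         call. = FALSE)
  }
  if (any(v < -4 | v > 4)) {
    stop("change values must lie in -4..4, got: ",
         paste(utils::head(v[v < -4 | v > 4], 3L), collapse = ", "),
         call. = FALSE)
  }
  # (5 + v) / 10 rather than 0.5 + 0.1 * v: algebraically identical, but
  # exact in floating point at the table rows (0.5 + 0.1 * -4 lands one ulp
  # below 0.1 and would sit outside the probability bounds)
  (5 + as.numeric(v)) / 10
}

#' Convert a probability of increase back to the -4..4 change scale
#'
#' The reported "final change" of a node is `10 * (p - 0.5)`: a posterior of
#' 0.9 maps to +4, 0.1 to -4, and 0.5 to no change. Final posteriors are not
#' integers, so reported changes are continuous values in \[-4, 4\].
#'
#' @param p numeric probability (vector allowed) in \[0, 1\].
#' @return numeric change value(s) in \[-5, 5\] (\[-4, 4\] for clamped
#'   engine states).
#' @examples
#' from_probability(0.9)  # 4
#' from_probability(0.82) # 3.2
#' @export
from_probability <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stop("`p` must be a probability in [0, 1]", call. = FALSE)
  }
  10 * (p - 0.5)
}

clamp_prob <- function(p) pmin(P_MAX, pmax(P_MIN, p))

is_informative <- function(p) abs(p - 0.5) > INFORMATIVE_TOL

#' Probability a child increases given one parent's state
#'
#' Marginalises one parent out of the child's conditional: with `e` the
#' probability the child increases given the parent increases, and `q` the
#' parent's current probability of increase, returns
#' `e * q + (1 - e) * (1 - q)`. The complement `1 - e` is used for the
#' probability the child increases given the parent decreases, which makes
#' the whole pipeline odd-symmetric about 0.5 (negating a scenario negates
#' every prediction).
#'
#' @param edge_p edge probability in \[0.1, 0.9\] (see [to_probability()]).
#' @param parent_p parent's current probability of increase.
#' @return probability the child increases given this parent alone.
#' @examples
#' conditional_given_parent(0.9, 0.9) # 0.82
#' @export
conditional_given_parent <- function(edge_p, parent_p) {
  edge_p * parent_p + (1 - edge_p) * (1 - parent_p)
}

#' Posterior blending the node's own prior with parent evidence
#'
#' One of the two candidate posteriors: the current prior `p` is moved by the
#' average prior-weighted deviation of the per-parent conditionals from 0.5,
#' `p + (1 - p) * mean(p * (c - 0.5))`, then clamped to \[0.1, 0.9\]. Evidence
#' agreeing with the prior makes the node more certain; it never erases an
#' informative prior on its own.
#'
#' @param prior_p the node's current probability of increase.
#' @param conditionals numeric vector of per-parent conditionals
#'   (one per informative parent); must be non-empty.
#' @return clamped posterior probability.
#' @examples
#' posterior_with_prior(0.5, 0.82) # 0.58
#' @export
posterior_with_prior <- function(prior_p, conditionals) {
  if (length(conditionals) == 0L) {
    stop("`conditionals` must be non-empty; pass the prior through unchanged ",
         "when a node has no informative parents", call. = FALSE)
  }
  clamp_prob(prior_p + (1 - prior_p) * mean(prior_p * (conditionals - 0.5)))
}

#' Posterior from parent evidence alone
#'
#' The second candidate posterior: the arithmetic mean of the per-parent
#' conditionals, ignoring the node's own prior, clamped to \[0.1, 0.9\].
#' This route lets strong evidence from interactions override an
#' uninformative prior, preventing signal loss deep in the network.
#'
#' @param conditionals numeric vector of per-parent conditionals; non-empty.
#' @return clamped posterior probability.
#' @examples
#' posterior_from_interactions(c(0.82, 0.6)) # 0.71
#' @export
posterior_from_interactions <- function(conditionals) {
  if (length(conditionals) == 0L) {
    stop("`conditionals` must be non-empty; pass the prior through unchanged ",
         "when a node has no informative parents", call. = FALSE)
  }
  clamp_prob(mean(conditionals))
}

#' Select the more certain of two posterior candidates
#'
#' Certainty is distance from the neutral probability 0.5. On a tie (within
#' 1e-9, so that equally certain mirror values such as 0.3 and 0.7 tie
#' regardless of floating-point representation) the first argument wins;
#' callers pass the prior-bearing candidate first so prior information is
#' preserved when evidence is equivocal.
#'
#' @param a first candidate (by convention from [posterior_with_prior()]).
#' @param b second candidate (from [posterior_from_interactions()]).
#' @return whichever of `a`, `b` lies further from 0.5.
#' @export
select_most_certain <- function(a, b) {
  if (abs(b - 0.5) - abs(a - 0.5) > INFORMATIVE_TOL) b else a
}

#' Create a probability state for a network and scenario
#'
#' Initialises every node at the probability implied by its scenario prior
#' (0.5 for nodes with no known change). Nodes with nonzero priors are
#' "pinned": during iteration they are never allowed to become less certain
#' than their initial prior, so an imposed change is not washed out by
#' feedback (to observe feedback on a manipulated node, add an explicit
#' policy node driving it instead).
#'
#' @param network a `bbn_network`.
#' @param scenario a `bbn_scenario` (or NULL for the neutral state).
#' @return an object of class `bbn_state`: list with `p_inc` (named numeric),
#'   `pinned` (character) and `pin_values` (named numeric).
#' @export
initial_state <- function(network, scenario = NULL) {
  stopifnot(inherits(network, "bbn_network"))
  p <- rep(0.5, length(network$nodes))
  names(p) <- network$nodes
  pinned <- character(0)
  if (!is.null(scenario)) {
    stopifnot(inherits(scenario, "bbn_scenario"))
    bad <- setdiff(names(scenario$priors), network$nodes)
    if (length(bad) > 0L) {
      stop("scenario nodes not in network: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (length(scenario$priors) > 0L) {
      p[names(scenario$priors)] <- to_probability(scenario$priors)
      pinned <- names(scenario$priors)
    }
  }
  structure(
    list(p_inc = p, pinned = pinned, pin_values = p[pinned]),
    class = "bbn_state"
  )
}

# Precompute, for each node, its parents' indices and edge probabilities.
# Edge probabilities may later be overridden (bootstrap perturbs them on the
# probability scale), hence the separation from the integer strengths.
compile_network <- function(network, edge_probs = NULL) {
  nodes <- network$nodes
  idx <- seq_along(nodes)
  names(idx) <- nodes
  ep <- if (!is.null(edge_probs)) {
    edge_probs
  } else if (nrow(network$edges) > 0L) {
    to_probability(network$edges$strength)
  } else {
    numeric(0)
  }
  child_i <- idx[network$edges$child]
  parent_i <- idx[network$edges$parent]
  parents <- vector("list", length(nodes))
  eprobs <- vector("list", length(nodes))
  for (k in seq_along(child_i)) {
    ci <- child_i[[k]]
    parents[[ci]] <- c(parents[[ci]], parent_i[[k]])
    eprobs[[ci]] <- c(eprobs[[ci]], ep[[k]])
  }
  list(nodes = nodes, parents = parents, eprobs = eprobs)
}

# One synchronous update on the bare numeric state. `pin_idx`/`pin_vals`
# implement signal-loss prevention; all reads use `p` from the previous
# iteration.
step_probs <- function(p, compiled, pin_idx, pin_vals) {
  new_p <- p
  for (i in seq_along(p)) {
    pa <- compiled$parents[[i]]
    if (is.null(pa)) next
    pp <- p[pa]
    keep <- abs(pp - 0.5) > INFORMATIVE_TOL
    if (!any(keep)) next
    ep <- compiled$eprobs[[i]][keep]
    pp <- pp[keep]
    cond <- ep * pp + (1 - ep) * (1 - pp)
    prior <- p[[i]]
    a <- clamp_prob(prior + (1 - prior) * mean(prior * (cond - 0.5)))
    b <- clamp_prob(mean(cond))
    new_p[[i]] <- if (abs(b - 0.5) - abs(a - 0.5) > INFORMATIVE_TOL) b else a
  }
  if (length(pin_idx) > 0L) {
    lost <- abs(new_p[pin_idx] - 0.5) < abs(pin_vals - 0.5)
    new_p[pin_idx[lost]] <- pin_vals[lost]
  }
  new_p
}

#' Advance a probability state by one synchronous iteration
#'
#' Every node is updated from the *previous* state: for each informative
#' parent (probability differing from 0.5) a conditional is computed via
#' [conditional_given_parent()]; the node's posterior is then the more
#' certain of [posterior_with_prior()] and [posterior_from_interactions()].
#' Nodes with no informative parents keep their value. Pinned nodes are
#' restored to their pin value if the update made them less certain.
#'
#' @param state a `bbn_state`.
#' @param network the `bbn_network` the state was built for.
#' @return the updated `bbn_state`.
#' @export
bbn_step <- function(state, network) {
  stopifnot(inherits(state, "bbn_state"), inherits(network, "bbn_network"))
  if (!setequal(names(state$p_inc), network$nodes)) {
    stop("state does not cover the network's nodes", call. = FALSE)
  }
  compiled <- compile_network(network)
  pin_idx <- match(state$pinned, network$nodes)
  p <- state$p_inc[network$nodes]
  p <- step_probs(p, compiled, pin_idx, unname(state$pin_values[state$pinned]))
  state$p_inc[network$nodes] <- p
  state
}

run_engine <- function(compiled, p0, pin_idx, pin_vals, iterations) {
  p <- p0
  for (it in seq_len(iterations)) {
    p <- step_probs(p, compiled, pin_idx, pin_vals)
  }
  p
}

#' Predict node changes under one or more scenarios
#'
#' The main predictive routine. For each scenario the state is initialised
#' from the scenario priors, iterated `iterations` times (default 4; with a
#' synchronous update, information travels one edge per iteration), and the
#' final probabilities are mapped back to the -4..4 change scale.
#'
#' @param network a `bbn_network`.
#' @param scenarios a single `bbn_scenario` or a list of them (1..12;
#'   more are accepted with a warning since only plotting is limited to 12).
#' @param iterations number of propagation iterations (default 4).
#' @return a list of `bbn_prediction` objects, one per scenario, each with
#'   `scenario_name`, `change` (named numeric, -4..4), `posterior`
#'   (named numeric probabilities) and NULL `ci_low`/`ci_high`.
#' @examples
#' net <- toy_fixtures()$chain2$network
#' sc <- toy_fixtures()$chain2$scenario
#' bbn_predict(net, sc)[[1]]$change
#' @export
bbn_predict <- function(network, scenarios, iterations = 4L) {
  stopifnot(inherits(network, "bbn_network"))
  if (inherits(scenarios, "bbn_scenario")) scenarios <- list(scenarios)
  if (length(scenarios) == 0L) stop("at least one scenario is required", call. = FALSE)
  if (length(scenarios) > 12L) {
    warning("more than 12 scenarios: predictions run, but combined plotting ",
            "supports at most 12", call. = FALSE)
  }
  if (iterations < 1L || iterations != round(iterations)) {
    stop("`iterations` must be a positive integer", call. = FALSE)
  }
  compiled <- compile_network(network)
  lapply(scenarios, function(sc) {
    state <- initial_state(network, sc)
    pin_idx <- match(state$pinned, network$nodes)
    p <- run_engine(compiled, unname(state$p_inc[network$nodes]), pin_idx,
                    unname(state$pin_values[state$pinned]), iterations)
    names(p) <- network$nodes
    new_prediction(sc$name, from_probability(p), posterior = p)
  })
}

new_prediction <- function(name, change, posterior = NULL,
                           ci_low = NULL, ci_high = NULL) {
  structure(
    list(scenario_name = name, change = change, posterior = posterior,
         ci_low = ci_low, ci_high = ci_high),
    class = "bbn_prediction"
  )
}

#' @export
print.bbn_prediction <- function(x, digits = 3, ...) {
  cat("Scenario:", x$scenario_name, "\n")
  df <- data.frame(node = names(x$change), change = round(x$change, digits))
  if (!is.null(x$ci_low)) {
    df$ci_low <- round(x$ci_low[df$node], digits)
    df$ci_high <- round(x$ci_high[df$node], digits)
  }
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
print.bbn_state <- function(x, ...) {
  cat("Probability state over", length(x$p_inc), "nodes;",
      length(x$pinned), "pinned\n")
  print(round(x$p_inc, 4))
  invisible(x)
}
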
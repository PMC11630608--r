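# Bootstrap uncertainty: each replicate perturbs a random 10% of edges by up
# to +/- 0.1 on the probability scale, reruns the prediction, and per-node
# 95% confidence intervals are taken by trimming 2.5% of replicate values
# from each tail (nearest rank: the bounds are the extreme survivors).

#' Bootstrap settings
#'
#' @param boot_max number of bootstrap replicates (default 1 = no
#'   bootstrapping: only the unperturbed point estimate is computed).
#' @param edge_fraction fraction of edges perturbed per replicate
#'   (default 0.10; the count is rounded up).
#' @param max_delta maximum absolute perturbation on the probability scale
#'   (default 0.10); deltas are Uniform(-max_delta, +max_delta).
#' @param tail fraction trimmed from each tail for the confidence interval
#'   (default 0.025, i.e. a 95% interval).
#' @param seed integer seed; every random draw flows from it.
#' @return a `bbn_boot_settings` list.
#' @export
bootstrap_settings <- function(boot_max = 1L, edge_fraction = 0.10,
                               max_delta = 0.10, tail = 0.025, seed = 1L) {
  stopifnot(boot_max >= 1, edge_fraction > 0, edge_fraction <= 1,
            max_delta >= 0, max_delta < 0.4, tail >= 0, tail < 0.5)
  structure(list(boot_max = as.integer(boot_max),
                 edge_fraction = edge_fraction, max_delta = max_delta,
                 tail = tail, seed = as.integer(seed)),
            class = "bbn_boot_settings")
}

#' Perturb edge probabilities for one bootstrap replicate
#'
#' Selects `ceiling(edge_fraction * n_edges)` distinct edges uniformly at
#' random, adds an independent Uniform(-max_delta, +max_delta) delta to each
#' on the probability scale, and clamps the result to \[0.1, 0.9\]. All other
#' edges are untouched. Uses the session RNG: the caller seeds it.
#'
#' @param edge_probs numeric vector of edge probabilities (one per edge).
#' @param settings a [bootstrap_settings()] object.
#' @return list with `probs` (perturbed vector) and `modified` (integer
#'   indices of the edges that were selected).
#' @export
perturb_edge_probs <- function(edge_probs, settings = bootstrap_settings()) {
  n <- length(edge_probs)
  if (n == 0L) stop("cannot perturb an empty network", call. = FALSE)
  k <- ceiling(settings$edge_fraction * n)
  modified <- sort(sample.int(n, k))
  delta <- stats::runif(k, -settings$max_delta, settings$max_delta)
  probs <- edge_probs
  probs[modified] <- clamp_prob(probs[modified] + delta)
  list(probs = probs, modified = modified)
}

# nearest-rank trimmed bounds: drop floor(tail * n) values from each tail,
# return the extreme surviving values
trimmed_bounds <- function(x, tail) {
  s <- sort(x)
  n <- length(s)
  k <- floor(tail * n)
  c(low = s[k + 1L], high = s[n - k])
}

#' Predict with bootstrap confidence intervals
#'
#' The point estimate is always the unperturbed run of [bbn_predict()].
#' When `boot_max > 1`, `boot_max` additional replicates rerun the
#' prediction on networks with randomly perturbed edge probabilities
#' (see [perturb_edge_probs()]); per node, the confidence bounds are the
#' empirical nearest-rank percentiles of the replicate distribution after
#' trimming `tail` from each end. With the default `boot_max = 1` no
#' replicates are run and no intervals are attached.
#'
#' @param network a `bbn_network`.
#' @param scenario a single `bbn_scenario`.
#' @param settings a [bootstrap_settings()] object.
#' @param iterations propagation iterations per run (default 4).
#' @return a `bbn_prediction`, with `ci_low`/`ci_high` when bootstrapped.
#' @export
bbn_bootstrap <- function(network, scenario,
                          settings = bootstrap_settings(), iterations = 4L) {
  stopifnot(inherits(network, "bbn_network"),
            inherits(scenario, "bbn_scenario"),
            inherits(settings, "bbn_boot_settings"))
  point <- bbn_predict(network, scenario, iterations = iterations)[[1]]
  if (settings$boot_max <= 1L) return(point)

  compiled <- compile_network(network)
  base_probs <- if (nrow(network$edges) > 0L) {
    to_probability(network$edges$strength)
  } else {
    stop("cannot bootstrap an edgeless network", call. = FALSE)
  }
  state <- initial_state(network, scenario)
  pin_idx <- match(state$pinned, network$nodes)
  pin_vals <- unname(state$pin_values[state$pinned])
  p0 <- unname(state$p_inc[network$nodes])

  set.seed(settings$seed)
  reps <- matrix(NA_real_, nrow = settings$boot_max,
                 ncol = length(network$nodes))
  for (b in seq_len(settings$boot_max)) {
    pert <- perturb_edge_probs(base_probs, settings)
    comp_b <- compiled
    comp_b_probs <- pert$probs
    # rebuild the per-child probability lists with the perturbed values
    comp_b <- compile_network(network, edge_probs = comp_b_probs)
    reps[b, ] <- from_probability(
      run_engine(comp_b, p0, pin_idx, pin_vals, iterations))
  }
  bounds <- apply(reps, 2L, trimmed_bounds, tail = settings$tail)
  point$ci_low <- stats::setNames(bounds["low", ], network$nodes)
  point$ci_high <- stats::setNames(bounds["high", ], network$nodes)
  point
}
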
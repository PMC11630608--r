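# Edge sensitivity: which interaction strengths most affect chosen outcome
# nodes. Replicates perturb 10% of edges and 10% of node priors; replicates
# whose outcome-node changes deviate most from the unperturbed baseline form
# the top 25%, and every edge modified in a top replicate scores a count.

#' Rank edges by their influence on outcome nodes
#'
#' Runs `boot_max` perturbed replicates (edge perturbation exactly as in
#' [perturb_edge_probs()]; additionally `ceiling(10%)` of node priors get an
#' independent Uniform(-max_delta, +max_delta) shift on the probability
#' scale). Each replicate's impact is the summed absolute deviation of the
#' outcome nodes' predicted changes from the unperturbed baseline. For every
#' replicate in the top 25% by impact (ties at the cutoff included), the
#' count of each edge modified in that replicate is incremented. Frequent
#' edges are the ones whose exact strength most deserves scrutiny.
#'
#' @param network a `bbn_network`.
#' @param nodes_of_interest 1..3 node labels, spelled exactly as in the
#'   network (a misspelling is an error with a nearest-label suggestion).
#' @param scenario optional driving `bbn_scenario` (default: neutral — all
#'   variation then comes from the prior perturbation).
#' @param settings a [bootstrap_settings()]; the default here is
#'   `boot_max = 1000`.
#' @param iterations propagation iterations per run (default 4).
#' @return a `bbn_sensitivity` object: data.frame `frequency` with columns
#'   `parent`, `child`, `strength`, `count` sorted by decreasing count, plus
#'   `nodes_of_interest` and `replicates`.
#' @export
bbn_sensitivity <- function(network, nodes_of_interest, scenario = NULL,
                            settings = bootstrap_settings(boot_max = 1000L),
                            iterations = 4L) {
  stopifnot(inherits(network, "bbn_network"))
  if (length(nodes_of_interest) == 0L) {
    stop("at least one node of interest is required", call. = FALSE)
  }
  if (length(nodes_of_interest) > 3L) {
    warning("more than 3 nodes of interest; results may be hard to interpret",
            call. = FALSE)
  }
  bad <- setdiff(nodes_of_interest, network$nodes)
  if (length(bad) > 0L) {
    stop("unknown node(s) of interest: ",
         paste(vapply(bad, function(b) {
           paste0("'", b, "'", suggest_label(b, network$nodes))
         }, character(1)), collapse = "; "), call. = FALSE)
  }
  if (nrow(network$edges) == 0L) {
    stop("network has no edges to perturb", call. = FALSE)
  }
  if (is.null(scenario)) scenario <- bbn_scenario(integer(0), name = "neutral")

  out_idx <- match(nodes_of_interest, network$nodes)
  n_nodes <- length(network$nodes)
  base_probs <- to_probability(network$edges$strength)
  compiled <- compile_network(network)
  state <- initial_state(network, scenario)
  pin_idx <- match(state$pinned, network$nodes)
  p0 <- unname(state$p_inc[network$nodes])

  baseline <- run_engine(compiled, p0, pin_idx,
                         unname(state$pin_values[state$pinned]), iterations)
  baseline_change <- from_probability(baseline[out_idx])

  set.seed(settings$seed)
  B <- settings$boot_max
  impact <- numeric(B)
  modified <- vector("list", B)
  n_prior <- ceiling(0.10 * n_nodes)
  for (b in seq_len(B)) {
    pert <- perturb_edge_probs(base_probs, settings)
    modified[[b]] <- pert$modified
    which_priors <- sample.int(n_nodes, n_prior)
    p_b <- p0
    p_b[which_priors] <- clamp_prob(
      p_b[which_priors] +
        stats::runif(n_prior, -settings$max_delta, settings$max_delta))
    pin_vals_b <- p_b[pin_idx]
    comp_b <- compile_network(network, edge_probs = pert$probs)
    final <- run_engine(comp_b, p_b, pin_idx, pin_vals_b, iterations)
    impact[b] <- sum(abs(from_probability(final[out_idx]) - baseline_change))
  }

  k <- ceiling(0.25 * B)
  cutoff <- sort(impact, decreasing = TRUE)[k]
  top <- which(impact >= cutoff)  # ties at the cutoff included
  counts <- integer(nrow(network$edges))
  for (b in top) counts[modified[[b]]] <- counts[modified[[b]]] + 1L
  keep <- counts > 0L
  freq <- data.frame(parent = network$edges$parent[keep],
                     child = network$edges$child[keep],
                     strength = network$edges$strength[keep],
                     count = counts[keep])
  freq <- freq[order(-freq$count, freq$parent, freq$child), , drop = FALSE]
  rownames(freq) <- NULL
  structure(list(frequency = freq,
                 nodes_of_interest = nodes_of_interest,
                 replicates = B, n_top = length(top)),
            class = "bbn_sensitivity")
}

#' @export
print.bbn_sensitivity <- function(x, ...) {
  cat("Edge sensitivity over", x$replicates, "replicates; outcome node(s):",
      paste(x$nodes_of_interest, collapse = ", "), "\n")
  print(utils::head(x$frequency, 15L), row.names = FALSE)
  invisible(x)
}
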
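# Synthetic networks and scenarios, plus small hand-built toys used across
# the documentation and tests. The toys are deliberately tiny and structural:
# chains probe one-hop-per-iteration propagation, the reciprocal pair probes
# competition feedback with pinning, and web8 is a synthetic 8-node web with
# the structural motifs of a rocky-shore style model (top-down trophic edges,
# reciprocal competition, a policy-style input node and a revenue-style
# output node). No ecological realism is claimed.

#' Specification for the random network/scenario generator
#'
#' @param n_nodes number of nodes (>= 2).
#' @param density probability each ordered non-self node pair carries an
#'   edge (in (0, 1\]).
#' @param strength_set integer strengths sampled uniformly for edges and
#'   scenario priors (subset of -4..-1, 1..4; default all eight).
#' @param n_manipulated number of nodes given nonzero priors by
#'   [random_scenario()] (default 1).
#' @param seed integer seed; generation is deterministic given it.
#' @return a `bbn_generator_spec` list.
#' @export
generator_spec <- function(n_nodes = 8L, density = 0.3,
                           strength_set = c(-4:-1, 1:4),
                           n_manipulated = 1L, seed = 1L) {
  stopifnot(n_nodes >= 2, density > 0, density <= 1,
            length(strength_set) >= 1,
            all(strength_set %in% c(-4:-1, 1:4)),
            n_manipulated >= 1, n_manipulated <= n_nodes)
  structure(list(n_nodes = as.integer(n_nodes), density = density,
                 strength_set = as.integer(strength_set),
                 n_manipulated = as.integer(n_manipulated),
                 seed = as.integer(seed)),
            class = "bbn_generator_spec")
}

#' Generate a random signed interaction network
#'
#' Each ordered non-self pair of nodes independently carries an edge with
#' probability `density`; edge strengths are uniform over `strength_set`.
#' Regenerates until at least one edge exists (relevant only at tiny
#' densities). Deterministic given `spec$seed`.
#'
#' @param spec a [generator_spec()].
#' @return a `bbn_network` with nodes "N1".."Nk".
#' @export
random_network <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "bbn_generator_spec"))
  set.seed(spec$seed)
  nodes <- paste0("N", seq_len(spec$n_nodes))
  pairs <- expand.grid(parent = nodes, child = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$parent != pairs$child, , drop = FALSE]
  repeat {
    keep <- stats::runif(nrow(pairs)) < spec$density
    if (any(keep)) break
  }
  edges <- pairs[keep, , drop = FALSE]
  edges$strength <- sample(spec$strength_set, nrow(edges), replace = TRUE)
  bbn_network(nodes, edges)
}

#' Generate a random scenario for a network
#'
#' `spec$n_manipulated` distinct nodes receive nonzero priors drawn
#' uniformly from `spec$strength_set`. Deterministic given `spec$seed`
#' (offset so the scenario is independent of the network draw).
#'
#' @param network a `bbn_network`.
#' @param spec a [generator_spec()].
#' @return a `bbn_scenario`.
#' @export
random_scenario <- function(network, spec = generator_spec()) {
  stopifnot(inherits(network, "bbn_network"),
            inherits(spec, "bbn_generator_spec"),
            spec$n_manipulated <= length(network$nodes))
  set.seed(spec$seed + 1000003L)
  picked <- sample(network$nodes, spec$n_manipulated)
  vals <- sample(spec$strength_set, spec$n_manipulated, replace = TRUE)
  bbn_scenario(stats::setNames(vals, picked),
               name = paste0("random_seed", spec$seed), network = network)
}

#' Canonical toy networks and scenarios
#'
#' Returns a named list of fixtures used throughout the tests and examples:
#' \describe{
#'   \item{chain2}{A -> B at +4, scenario A = +4, with the hand-traced
#'     expected predictions (both nodes reach +4 after the default four
#'     iterations).}
#'   \item{chain6}{a six-node +4 chain A..F, scenario A = +4: with four
#'     iterations the signal reaches E but not F.}
#'   \item{recip2}{reciprocal -4 competition pair; raising one node drives
#'     the other down while pinning holds the raised node.}
#'   \item{web8}{a synthetic 8-node web with four node classes
#'     (see [bbn_diagram_network()]) and mixed-sign edges, plus a
#'     removal-style scenario.}
#' }
#' @return named list; each element has `network`, `scenario`, and for
#'   chain2 an `expected` named vector, for web8 a `diagram`.
#' @export
toy_fixtures <- function() {
  chain2 <- bbn_network(c("A", "B"),
                        data.frame(parent = "A", child = "B", strength = 4L))
  chain6_nodes <- LETTERS[1:6]
  chain6 <- bbn_network(
    chain6_nodes,
    data.frame(parent = chain6_nodes[1:5], child = chain6_nodes[2:6],
               strength = 4L))
  recip2 <- bbn_network(
    c("SpeciesA", "SpeciesB"),
    data.frame(parent = c("SpeciesA", "SpeciesB"),
               child = c("SpeciesB", "SpeciesA"),
               strength = c(-4L, -4L)))
  web8_nodes <- c("Policy", "Predator", "GrazerA", "GrazerB", "AlgaeTurf",
                  "AlgaeCanopy", "FilterFeeder", "Revenue")
  web8_edges <- data.frame(
    parent = c("Policy",  "Predator", "Predator", "GrazerA",  "GrazerB",
               "GrazerA", "GrazerB",  "AlgaeTurf",   "AlgaeCanopy",
               "AlgaeCanopy", "FilterFeeder", "Predator"),
    child  = c("Predator", "GrazerA",  "GrazerB",  "AlgaeTurf", "AlgaeTurf",
               "GrazerB", "GrazerA",  "AlgaeCanopy", "AlgaeTurf",
               "FilterFeeder", "Revenue", "Revenue"),
    strength = c(4L, -3L, -2L, -4L, -2L, -2L, -2L, -1L, -2L, 1L, 2L, 3L))
  web8 <- bbn_network(web8_nodes, web8_edges)
  web8_diagram <- bbn_diagram_network(
    web8, id = sprintf("s%02d", 1:8),
    node_type = c(1L, 2L, 3L, 3L, 4L, 4L, 3L, 1L))
  list(
    chain2 = list(
      network = chain2,
      scenario = bbn_scenario(c(A = 4L), name = "raise_A", network = chain2),
      expected = c(A = 4.0, B = 4.0)),
    chain6 = list(
      network = chain6,
      scenario = bbn_scenario(c(A = 4L), name = "raise_A", network = chain6)),
    recip2 = list(
      network = recip2,
      scenario = bbn_scenario(c(SpeciesA = 4L), name = "raise_A",
                              network = recip2)),
    web8 = list(
      network = web8,
      diagram = web8_diagram,
      scenario = bbn_scenario(c(Predator = -4L), name = "predator_removal",
                              network = web8))
  )
}

#' Export the toy fixtures as CSV files
#'
#' Writes every toy network (matrix dialect), scenario (two-column dialect)
#' and the web8 diagram file (id/node.type/node.name dialect) into `dir`.
#' Scenario files list every node, with 0 for unmanipulated nodes, matching
#' the shape of hand-built input files.
#'
#' @param dir output directory (created if needed).
#' @return character vector of files written, invisibly.
#' @export
export_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  toys <- toy_fixtures()
  files <- character(0)
  for (nm in names(toys)) {
    toy <- toys[[nm]]
    net_path <- file.path(dir, paste0(nm, "_network.csv"))
    write_network(toy$network, net_path)
    files <- c(files, net_path)
    sc <- stats::setNames(rep(0L, length(toy$network$nodes)),
                          toy$network$nodes)
    sc[names(toy$scenario$priors)] <- toy$scenario$priors
    sc_path <- file.path(dir, paste0(nm, "_scenario_",
                                     toy$scenario$name, ".csv"))
    utils::write.csv(data.frame(node = names(sc), value = unname(sc)),
                     sc_path, row.names = FALSE, fileEncoding = "UTF-8")
    files <- c(files, sc_path)
    if (!is.null(toy$diagram)) {
      dg_path <- file.path(dir, paste0(nm, "_diagram.csv"))
      write_diagram_network(toy$diagram, dg_path)
      files <- c(files, dg_path)
    }
  }
  invisible(files)
}

# inverse of read_diagram_network, used by export_fixtures
write_diagram_network <- function(dn, path) {
  stopifnot(inherits(dn, "bbn_diagram_network"))
  n <- length(dn$nodes)
  m <- matrix("", nrow = n, ncol = n, dimnames = list(dn$nodes, dn$nodes))
  if (nrow(dn$edges) > 0L) {
    m[cbind(dn$edges$parent, dn$edges$child)] <- as.character(dn$edges$strength)
  }
  df <- data.frame(id = dn$id, node.type = dn$node_type, node.name = dn$nodes,
                   m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
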
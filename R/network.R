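# Constructors and validators for the three in-memory types: the signed
# interaction network, a scenario of prior changes, and the diagram variant
# carrying node ids and colour classes.

#' Construct a signed interaction network
#'
#' A directed network over uniquely labelled nodes. Each edge carries an
#' integer strength in -4..-1 or 1..4: the sign gives the direction of the
#' interaction (positive = child changes with the parent, negative = against)
#' and the magnitude its reliability/strength. Strength-0 edges do not exist
#' (0 means "no interaction") and self-edges are rejected.
#'
#' @param nodes character vector of node labels (trimmed, unique).
#' @param edges data.frame with columns `parent`, `child`, `strength`
#'   (may have zero rows).
#' @return an object of class `bbn_network`.
#' @export
bbn_network <- function(nodes, edges = data.frame(parent = character(0),
                                                  child = character(0),
                                                  strength = integer(0))) {
  nodes <- trimws(as.character(nodes))
  if (length(nodes) < 1L || anyNA(nodes) || any(nodes == "")) {
    stop("node labels must be non-empty strings", call. = FALSE)
  }
  if (anyDuplicated(nodes)) {
    stop("duplicate node labels: ",
         paste(unique(nodes[duplicated(nodes)]), collapse = ", "),
         call. = FALSE)
  }
  edges <- as.data.frame(edges)
  stopifnot(all(c("parent", "child", "strength") %in% names(edges)))
  edges$parent <- trimws(as.character(edges$parent))
  edges$child <- trimws(as.character(edges$child))
  bad <- setdiff(unique(c(edges$parent, edges$child)), nodes)
  if (length(bad) > 0L) {
    stop("edge endpoints not in node list: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  s <- edges$strength
  if (length(s) > 0L &&
      (!is.numeric(s) || anyNA(s) || any(s != round(s)) ||
       any(s < -4 | s > 4))) {
    stop("edge strengths must be integers in -4..4", call. = FALSE)
  }
  if (any(s == 0)) stop("edges of strength 0 are absent edges, not stored",
                        call. = FALSE)
  if (any(edges$parent == edges$child)) {
    stop("self-edges are not allowed (found on: ",
         paste(unique(edges$parent[edges$parent == edges$child]),
               collapse = ", "), ")", call. = FALSE)
  }
  if (anyDuplicated(edges[c("parent", "child")])) {
    stop("duplicate edges", call. = FALSE)
  }
  edges <- data.frame(parent = edges$parent, child = edges$child,
                      strength = as.integer(s))
  structure(list(nodes = nodes, edges = edges), class = "bbn_network")
}

#' Construct a scenario of prior node changes
#'
#' A scenario assigns integer prior changes (-4..4) to the nodes that are
#' directly manipulated or directly influenced; all other nodes carry no
#' prior knowledge. Zero-valued entries are dropped — a 0 means "no known
#' change" and is represented by absence.
#'
#' @param priors named integer vector (names are node labels); zeros dropped.
#' @param name scenario label used in outputs and plots.
#' @param network optional `bbn_network` to validate labels against.
#' @return an object of class `bbn_scenario`.
#' @export
bbn_scenario <- function(priors, name = "scenario", network = NULL) {
  if (length(priors) > 0L) {
    if (is.null(names(priors)) || any(names(priors) == "")) {
      stop("`priors` must be a named vector of node labels", call. = FALSE)
    }
    if (!is.numeric(priors) || anyNA(priors) || any(priors != round(priors)) ||
        any(priors < -4 | priors > 4)) {
      stop("prior changes must be integers in -4..4", call. = FALSE)
    }
    names(priors) <- trimws(names(priors))
    if (anyDuplicated(names(priors))) {
      stop("duplicate node labels in scenario", call. = FALSE)
    }
    priors <- priors[priors != 0]
  }
  priors <- stats::setNames(as.integer(priors), names(priors))
  if (!is.null(network)) {
    bad <- setdiff(names(priors), network$nodes)
    if (length(bad) > 0L) {
      stop("scenario nodes not in network: ",
           paste(vapply(bad, function(b) {
             paste0(b, suggest_label(b, network$nodes))
           }, character(1)), collapse = "; "),
           call. = FALSE)
    }
  }
  structure(list(priors = priors, name = name), class = "bbn_scenario")
}

# "did you mean" helper for misspelled node labels
suggest_label <- function(label, candidates) {
  d <- utils::adist(label, candidates, ignore.case = TRUE)
  best <- candidates[which.min(d)]
  if (min(d) <= max(3L, nchar(label) %/% 2L)) {
    paste0(" (did you mean '", best, "'?)")
  } else {
    ""
  }
}

#' Construct a diagram network (network plus node ids and colour classes)
#'
#' The diagram input dialect adds, per node, an `id` of the form "s" followed
#' by a two-digit number (s01, s02, ...) and a `node_type` in 1..4 selecting
#' one of four node colours (e.g. functional groups: algae, predators,
#' grazers, filter feeders).
#'
#' @param network a `bbn_network`.
#' @param id character vector of node ids, pattern `^s[0-9]{2}$`, unique,
#'   in node order.
#' @param node_type integer vector in 1..4, in node order.
#' @return an object of class `bbn_diagram_network` (also a `bbn_network`).
#' @export
bbn_diagram_network <- function(network, id, node_type) {
  stopifnot(inherits(network, "bbn_network"))
  n <- length(network$nodes)
  id <- as.character(id)
  if (length(id) != n || !all(grepl("^s[0-9]{2}$", id))) {
    stop("node ids must be 's' + 2 digits (s01, s02, ...), one per node",
         call. = FALSE)
  }
  if (anyDuplicated(id)) stop("node ids must be unique", call. = FALSE)
  if (length(node_type) != n || !is.numeric(node_type) || anyNA(node_type) ||
      any(node_type != round(node_type)) || any(node_type < 1 | node_type > 4)) {
    stop("node.type must be an integer in 1..4 for every node", call. = FALSE)
  }
  network$id <- id
  network$node_type <- as.integer(node_type)
  class(network) <- c("bbn_diagram_network", "bbn_network")
  network
}

#' @export
print.bbn_network <- function(x, ...) {
  cat("Signed interaction network:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  cat("Nodes:", paste(x$nodes, collapse = ", "), "\n")
  if (nrow(x$edges) > 0L) print(utils::head(x$edges, 10L), row.names = FALSE)
  invisible(x)
}

#' @export
print.bbn_scenario <- function(x, ...) {
  cat("Scenario '", x$name, "': ", sep = "")
  if (length(x$priors) == 0L) {
    cat("no known changes\n")
  } else {
    cat(paste(names(x$priors), x$priors, sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}
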
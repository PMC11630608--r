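# CSV dialects:
#  * network matrix: (n+1) x n; header row = node names, first column = row
#    labels; the node in each ROW affects the node in each COLUMN; blank
#    cells = no edge.
#  * scenario: one row per node, two columns (node, integer prior in -4..4).
#  * diagram matrix: as the network matrix but with leading id / node.type /
#    node.name columns.
# All files are comma-delimited UTF-8. Node-name matching is exact after
# trimming leading/trailing whitespace; names may contain spaces.

read_csv_cells <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, header = TRUE, check.names = FALSE,
                  colClasses = "character", fileEncoding = "UTF-8",
                  strip.white = TRUE)
}

# Parse one matrix cell; "" -> NA (no edge), "0" -> NA with a warning,
# anything non-integer or out of range is an error naming the cell.
parse_cell <- function(x, parent, child) {
  x <- trimws(x)
  if (is.na(x) || x == "") return(NA_integer_)
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v) || v != round(v)) {
    stop("cell (", parent, " -> ", child, ") is not an integer: '", x,
         "' (decimal or non-numeric edge strengths are invalid)",
         call. = FALSE)
  }
  if (v < -4 || v > 4) {
    stop("cell (", parent, " -> ", child, ") is out of range -4..4: ", x,
         call. = FALSE)
  }
  if (v == 0) {
    warning("cell (", parent, " -> ", child,
            ") is 0; treated as no edge (leave blank instead)", call. = FALSE)
    return(NA_integer_)
  }
  as.integer(v)
}

matrix_to_network <- function(cells, row_labels, col_labels, what = "network") {
  row_labels <- trimws(row_labels)
  col_labels <- trimws(col_labels)
  if (anyDuplicated(col_labels)) {
    stop(what, " has duplicate node names in header: ",
         paste(unique(col_labels[duplicated(col_labels)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(row_labels)) {
    stop(what, " has duplicate row labels: ",
         paste(unique(row_labels[duplicated(row_labels)]), collapse = ", "),
         call. = FALSE)
  }
  if (!setequal(row_labels, col_labels)) {
    stop(what, " row labels and column headers disagree; missing from rows: ",
         paste(setdiff(col_labels, row_labels), collapse = ", "),
         "; missing from header: ",
         paste(setdiff(row_labels, col_labels), collapse = ", "),
         call. = FALSE)
  }
  edges <- list()
  for (r in seq_along(row_labels)) {
    for (c in seq_along(col_labels)) {
      v <- parse_cell(cells[r, c], row_labels[r], col_labels[c])
      if (!is.na(v)) {
        if (row_labels[r] == col_labels[c]) {
          stop(what, " has a self-edge on '", row_labels[r],
               "' (diagonal cells must be blank)", call. = FALSE)
        }
        edges[[length(edges) + 1L]] <-
          data.frame(parent = row_labels[r], child = col_labels[c],
                     strength = v)
      }
    }
  }
  edges <- if (length(edges) > 0L) {
    do.call(rbind, edges)
  } else {
    data.frame(parent = character(0), child = character(0),
               strength = integer(0))
  }
  bbn_network(col_labels, edges)
}

#' Read an interaction network from a matrix CSV
#'
#' The file is an (n+1) by n matrix: the header row holds the n node names,
#' the first column repeats them as row labels, and cell (row, column) holds
#' the integer strength of the edge from the row node (parent) to the column
#' node (child). Blank cells mean no edge; a literal 0 is accepted as "no
#' edge" with a warning. Decimal or out-of-range values raise a validation
#' error naming the offending cell.
#'
#' @param path path to a CSV file.
#' @return a [bbn_network()].
#' @export
read_network <- function(path) {
  df <- read_csv_cells(path)
  if (ncol(df) < 2L) stop("network matrix needs at least 2 columns", call. = FALSE)
  matrix_to_network(as.matrix(df[, -1, drop = FALSE]),
                    df[[1]], names(df)[-1])
}

#' Read a scenario of prior changes
#'
#' A two-column CSV (node label, integer change in -4..4), one row per node.
#' Zeros mean "no known change" and are stored as absence. Labels not present
#' in the network are an error (with a nearest-label suggestion); network
#' nodes missing from the file are treated as 0 with a warning.
#'
#' @param path path to a CSV file.
#' @param network the `bbn_network` the scenario applies to.
#' @param name scenario label; defaults to the file name without extension.
#' @return a [bbn_scenario()].
#' @export
read_scenario <- function(path, network, name = NULL) {
  stopifnot(inherits(network, "bbn_network"))
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  df <- read_csv_cells(path)
  if (ncol(df) < 2L) stop("scenario file needs 2 columns (node, value)",
                          call. = FALSE)
  labels <- trimws(df[[1]])
  vals <- suppressWarnings(as.numeric(trimws(df[[2]])))
  bad <- is.na(vals) | vals != round(vals) | vals < -4 | vals > 4
  if (any(bad)) {
    stop("scenario values must be integers in -4..4; offending node(s): ",
         paste(labels[bad], collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(labels, network$nodes)
  if (length(unknown) > 0L) {
    stop("scenario lists unknown node(s): ",
         paste(vapply(unknown, function(b) {
           paste0("'", b, "'", suggest_label(b, network$nodes))
         }, character(1)), collapse = "; "), call. = FALSE)
  }
  missing <- setdiff(network$nodes, labels)
  if (length(missing) > 0L) {
    warning("scenario omits node(s) treated as 0: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  bbn_scenario(stats::setNames(as.integer(vals), labels), name = name,
               network = network)
}

#' Read a diagram network (id / node.type / node.name dialect)
#'
#' Like [read_network()] but the first three columns are `id` ("s" plus a
#' two-digit number), `node.type` (integer 1..4 selecting the node colour
#' class) and `node.name`; the remaining columns are the usual edge matrix.
#'
#' @param path path to a CSV file.
#' @return a [bbn_diagram_network()].
#' @export
read_diagram_network <- function(path) {
  df <- read_csv_cells(path)
  need <- c("id", "node.type", "node.name")
  if (ncol(df) < 4L || !identical(names(df)[1:3], need)) {
    stop("diagram file must start with columns id, node.type, node.name",
         call. = FALSE)
  }
  nt <- suppressWarnings(as.numeric(trimws(df[["node.type"]])))
  net <- matrix_to_network(as.matrix(df[, -(1:3), drop = FALSE]),
                           df[["node.name"]], names(df)[-(1:3)],
                           what = "diagram network")
  # matrix columns define node order; reorder the per-node metadata to match
  ord <- match(net$nodes, trimws(df[["node.name"]]))
  bbn_diagram_network(net, id = trimws(df[["id"]])[ord], node_type = nt[ord])
}

#' Write an interaction network back to the matrix CSV dialect
#'
#' Inverse of [read_network()]: absent edges become blank cells, so a
#' read/write round trip reproduces the original cell set exactly.
#'
#' @param network a `bbn_network`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "bbn_network"))
  n <- length(network$nodes)
  m <- matrix("", nrow = n, ncol = n,
              dimnames = list(network$nodes, network$nodes))
  if (nrow(network$edges) > 0L) {
    m[cbind(network$edges$parent, network$edges$child)] <-
      as.character(network$edges$strength)
  }
  df <- data.frame(node = network$nodes, m, check.names = FALSE)
  names(df)[1] <- ""
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write prediction results to CSV
#'
#' One row per node; per scenario a point-estimate column, plus `.lower` /
#' `.upper` columns when bootstrap confidence intervals are present.
#'
#' @param results a `bbn_prediction` or list of them.
#' @param path output path.
#' @return invisibly, the data.frame written.
#' @export
write_predictions <- function(results, path) {
  if (inherits(results, "bbn_prediction")) results <- list(results)
  if (length(results) == 0L) stop("no results to write", call. = FALSE)
  nodes <- names(results[[1]]$change)
  df <- data.frame(node = nodes)
  for (res in results) {
    stopifnot(inherits(res, "bbn_prediction"))
    df[[res$scenario_name]] <- unname(res$change[nodes])
    if (!is.null(res$ci_low)) {
      df[[paste0(res$scenario_name, ".lower")]] <- unname(res$ci_low[nodes])
      df[[paste0(res$scenario_name, ".upper")]] <- unname(res$ci_high[nodes])
    }
  }
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(df)
}
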
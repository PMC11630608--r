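# Stepwise dynamics for visualising the order of events (trophic-cascade
# style propagation). Deliberately simpler than bbn_predict(): each step a
# node takes the plain mean of its informative-parent conditionals (no
# prior-blending posterior, no max-certainty selection, no signal-loss
# machinery), so values here do NOT match bbn_predict() and timesteps are
# ordinal, not calendar time.

#' Stepwise press/pulse dynamics of a scenario
#'
#' Column 1 of the result is the scenario itself (manipulated nodes at their
#' prior change, everything else 0). At each later timestep a node with
#' informative parents (probability differing from 0.5) takes the mean of
#' the per-parent conditionals ([conditional_given_parent()]); a node with
#' none keeps its value. Under a press disturbance each manipulated node is
#' then restored to the more certain of its computed value and its prior —
#' the manipulation is sustained. Under a pulse the prior is imposed at
#' timestep 1 only: afterwards a manipulated node evolves like any other,
#' and if it has no informative parents it relaxes to neutral, letting peaks
#' and troughs travel through the network.
#'
#' @param network a `bbn_network`.
#' @param scenario one `bbn_scenario` (a list of several is an error).
#' @param timesteps number of timesteps including the initial one
#'   (default 5).
#' @param disturbance `"press"` (sustained) or `"pulse"` (one-off).
#' @return a `bbn_timeseries`: list with `values` (node x timestep matrix of
#'   change values in \[-4, 4\]), `disturbance` and `timesteps`.
#' @export
bbn_timeseries <- function(network, scenario, timesteps = 5L,
                           disturbance = c("press", "pulse")) {
  stopifnot(inherits(network, "bbn_network"))
  if (is.list(scenario) && !inherits(scenario, "bbn_scenario")) {
    stop("only one scenario can be analysed at once", call. = FALSE)
  }
  stopifnot(inherits(scenario, "bbn_scenario"))
  disturbance <- match.arg(disturbance)
  if (timesteps < 1L || timesteps != round(timesteps)) {
    stop("`timesteps` must be a positive integer", call. = FALSE)
  }
  compiled <- compile_network(network)
  state <- initial_state(network, scenario)
  manip <- match(state$pinned, network$nodes)
  pin_vals <- unname(state$pin_values[state$pinned])
  p <- unname(state$p_inc[network$nodes])
  n <- length(network$nodes)

  values <- matrix(NA_real_, nrow = n, ncol = timesteps,
                   dimnames = list(network$nodes,
                                   paste0("t", seq_len(timesteps))))
  values[, 1L] <- from_probability(p)
  if (timesteps > 1L) {
    for (t in 2:timesteps) {
      new_p <- p
      for (i in seq_len(n)) {
        pa <- compiled$parents[[i]]
        informative <- FALSE
        if (!is.null(pa)) {
          pp <- p[pa]
          keep <- abs(pp - 0.5) > INFORMATIVE_TOL
          if (any(keep)) {
            ep <- compiled$eprobs[[i]][keep]
            pp <- pp[keep]
            new_p[[i]] <- mean(ep * pp + (1 - ep) * (1 - pp))
            informative <- TRUE
          }
        }
        if (!informative && disturbance == "pulse" && i %in% manip) {
          new_p[[i]] <- 0.5  # injection released, nothing holds the node
        }
      }
      if (disturbance == "press" && length(manip) > 0L) {
        weaker <- abs(new_p[manip] - 0.5) < abs(pin_vals - 0.5)
        new_p[manip[weaker]] <- pin_vals[weaker]
      }
      p <- new_p
      values[, t] <- from_probability(p)
    }
  }
  structure(list(values = values, disturbance = disturbance,
                 timesteps = as.integer(timesteps),
                 scenario_name = scenario$name),
            class = "bbn_timeseries")
}

#' Plot stepwise dynamics, one panel per node
#'
#' Points are the per-timestep change values; with enough timesteps a loess
#' trend line is overlaid (when smoothing is impossible — too few points —
#' the panels degrade to plain points).
#'
#' @param x a `bbn_timeseries`.
#' @param path optional output file (pdf/png/svg by extension); NULL returns
#'   the ggplot object without writing.
#' @return the ggplot object, invisibly when written to file.
#' @export
plot_timeseries <- function(x, path = NULL) {
  stopifnot(inherits(x, "bbn_timeseries"))
  df <- data.frame(
    node = factor(rep(rownames(x$values), ncol(x$values)),
                  levels = rownames(x$values)),
    timestep = rep(seq_len(ncol(x$values)), each = nrow(x$values)),
    change = as.vector(x$values)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = timestep, y = change)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~node) +
    ggplot2::coord_cartesian(ylim = c(-4, 4)) +
    ggplot2::labs(x = "timestep (ordinal)", y = "change (-4..4)",
                  title = paste0(x$scenario_name, " (", x$disturbance, ")")) +
    ggplot2::theme_bw()
  if (x$timesteps >= 4L) {
    p <- p + suppressWarnings(
      ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                           linewidth = 0.5, span = 1))
  }
  if (is.null(path)) return(p)
  save_figure(p, path, width = 8, height = 6)
  invisible(p)
}
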
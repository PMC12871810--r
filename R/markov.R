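#' Quartile-based three-state classification of a per-spike series
#'
#' Discretizes a scalar series (peak onset rapidness, per-spike Lyapunov
#' values, ...) into three classes by its own distribution: class 1 from
#' the minimum to the first quartile, class 2 from the first to the third
#' quartile, class 3 above the third quartile. Quartiles use linear
#' interpolation of order statistics (\code{type = 7} by default); values
#' exactly at Q1 fall in class 1 and exactly at Q3 in class 2.
#'
#' @param values numeric series, length >= 4.
#' @param source label recorded in the result (e.g. "rapidness",
#'   "lyapunov").
#' @param type quantile convention passed to [stats::quantile()].
#' @return a \code{state_sequence}: integer \code{states} in \{1,2,3\},
#'   \code{quartiles} (Q1, Q3), \code{source}, and \code{degenerate}
#'   (TRUE when all values are identical, in which case everything is
#'   class 2).
#' @examples
#' classify_quartiles(1:8)$states  # 1 1 2 2 2 2 3 3
#' @export
classify_quartiles <- function(values, source = "rapidness", type = 7) {
  values <- as.numeric(values)
  if (length(values) < 4L) stop("need at least 4 values")
  if (any(!is.finite(values))) stop("values must be finite")
  if (max(values) == min(values)) {
    warning("all values identical; degenerate quartiles, everything class 2")
    return(structure(list(states = rep(2L, length(values)),
                          quartiles = c(Q1 = values[1], Q3 = values[1]),
                          source = source, degenerate = TRUE),
                     class = "state_sequence"))
  }
  q <- stats::quantile(values, c(0.25, 0.75), type = type, names = FALSE)
  states <- ifelse(values <= q[1], 1L, ifelse(values <= q[2], 2L, 3L))
  structure(list(states = as.integer(states),
                 quartiles = c(Q1 = q[1], Q3 = q[2]),
                 source = source, degenerate = FALSE),
            class = "state_sequence")
}

#' @export
print.state_sequence <- function(x, ...) {
  cat(sprintf("<state_sequence> %d states (%s), Q1 = %.4g, Q3 = %.4g%s\n",
              length(x$states), x$source, x$quartiles[1], x$quartiles[2],
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Discrete-time Markov transition matrix from a state sequence
#'
#' Counts one-step transitions between states 1..3 and row-normalizes.
#' States never visited as a source yield an empty row: its probability
#' row is set to the uniform placeholder 1/3 and flagged in
#' \code{empty_rows} rather than silently treated as informative.
#'
#' @param states a \code{state_sequence} or an integer vector over
#'   \{1,2,3\}, length >= 2.
#' @return a \code{transition_matrix}: \code{P} (3x3 row-stochastic),
#'   \code{counts} (3x3 integer), \code{n_transitions},
#'   \code{empty_rows} (logical length 3).
#' @examples
#' transition_matrix(c(1, 1, 2, 3, 2, 2))$P
#' @export
transition_matrix <- function(states) {
  if (inherits(states, "state_sequence")) states <- states$states
  states <- as.integer(states)
  if (length(states) < 2L) stop("need at least 2 states")
  if (!all(states %in% 1:3)) stop("states must be in {1, 2, 3}")
  f <- factor(states, levels = 1:3)
  counts <- table(from = f[-length(f)], to = f[-1])
  counts <- matrix(as.integer(counts), 3, 3,
                   dimnames = list(from = 1:3, to = 1:3))
  rs <- rowSums(counts)
  empty <- rs == 0L
  P <- counts / ifelse(rs == 0, 1, rs)
  P[empty, ] <- 1 / 3
  structure(list(P = P, counts = counts,
                 n_transitions = length(states) - 1L,
                 empty_rows = empty),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> %d transitions%s\n", x$n_transitions,
              if (any(x$empty_rows))
                paste0(" (empty rows: ",
                       paste(which(x$empty_rows), collapse = ","), ")")
              else ""))
  print(round(x$P, 3))
  invisible(x)
}

#' State-persistence index of a transition matrix
#'
#' Mean of the diagonal transition probabilities over non-empty rows:
#' 1 under absolute persistence, 1/3 under memoryless switching. A
#' summary added for testing and group comparison; not itself a standard
#' chain statistic.
#'
#' @param tm a [transition_matrix()] result.
#' @return scalar in [0, 1].
#' @export
persistence_index <- function(tm) {
  stopifnot(inherits(tm, "transition_matrix"))
  ok <- !tm$empty_rows
  if (!any(ok)) stop("all rows empty; persistence undefined")
  mean(diag(tm$P)[ok])
}
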
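#' Adjacent interspike-interval pairs
#'
#' Builds the (T_i, T_{i+1}) point cloud of consecutive ISI pairs across
#' a list of spike trains, the feature space for Gaussian-mixture
#' clustering of latent spike patterns. Trains with fewer than 3 spikes
#' are skipped with a warning.
#'
#' @param trains list of [spike_train()] objects or numeric spike-time
#'   vectors.
#' @param log_scale take natural logs of the ISIs (recommended for
#'   right-skewed ISI distributions; the [fit_gmm()] default pipeline
#'   uses it).
#' @return an \code{adjacent_isi} data.frame: \code{isi1}, \code{isi2},
#'   \code{train} (integer provenance).
#' @export
adjacent_isi <- function(trains, log_scale = FALSE) {
  if (inherits(trains, "spike_train") || is.numeric(trains))
    trains <- list(trains)
  rows <- lapply(seq_along(trains), function(k) {
    tt <- trains[[k]]
    if (inherits(tt, "spike_train")) tt <- tt$times
    if (length(tt) < 3L) {
      warning("train ", k, " has < 3 spikes; skipped")
      return(NULL)
    }
    isis <- diff(tt)
    if (any(isis <= 0)) stop("train ", k, ": non-positive ISI")
    if (log_scale) isis <- log(isis)
    data.frame(isi1 = isis[-length(isis)], isi2 = isis[-1], train = k)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) stop("no usable trains")
  class(out) <- c("adjacent_isi", "data.frame")
  out
}

#' Gaussian mixture model on adjacent-ISI pairs
#'
#' EM fit (via mclust, full covariances) of a Gaussian mixture on the
#' adjacent-ISI point cloud. The mixture weights are the emergence
#' probabilities of the latent ISI-pair motifs. Because choosing the
#' number of components by eye is not reproducible, the component count
#' is a required input and a BIC table over k = 1..\code{kmax} is
#' returned to document the choice.
#'
#' @param data an [adjacent_isi()] data.frame (or a 2-column numeric
#'   matrix).
#' @param n_components number of Gaussian components (n_points >= 10 per
#'   component required).
#' @param seed integer RNG seed (the EM initialization is deterministic;
#'   the seed fixes any residual randomness).
#' @param kmax upper bound of the BIC model-selection table.
#' @return a \code{gmm_result}: \code{n_components}, \code{weights},
#'   \code{means} (components x 2), \code{covariances} (2 x 2 x
#'   components), \code{responsibilities}, \code{loglik},
#'   \code{ic_table} (k, bic).
#' @importFrom mclust Mclust mclustBIC
#' @export
fit_gmm <- function(data, n_components, seed = 1, kmax = 6) {
  X <- if (is.data.frame(data)) as.matrix(data[, c("isi1", "isi2")])
       else as.matrix(data)
  stopifnot(ncol(X) == 2L)
  if (nrow(X) < 10 * n_components)
    stop("need at least 10 points per component")
  set.seed(as.integer(seed))
  fit <- mclust::Mclust(X, G = n_components, modelNames = "VVV",
                        verbose = FALSE)
  if (is.null(fit)) stop("GMM fit failed")
  bic <- mclust::mclustBIC(X, G = 1:kmax, modelNames = "VVV",
                           verbose = FALSE)
  means <- t(fit$parameters$mean)
  structure(list(n_components = n_components,
                 weights = as.numeric(fit$parameters$pro),
                 means = means,
                 covariances = fit$parameters$variance$sigma,
                 responsibilities = fit$z,
                 loglik = fit$loglik,
                 ic_table = data.frame(k = 1:kmax,
                                       bic = as.numeric(bic[, "VVV"]))),
            class = "gmm_result")
}

#' @export
print.gmm_result <- function(x, ...) {
  cat(sprintf("<gmm_result> %d components, weights: %s (loglik %.2f)\n",
              x$n_components,
              paste(sprintf("%.3f", x$weights), collapse = ", "),
              x$loglik))
  invisible(x)
}

# non-overlapping windows of win consecutive values -> feature matrix
isi_windows <- function(values, win) {
  n_win <- length(values) %/% win
  if (n_win < 1L) return(NULL)
  matrix(values[seq_len(n_win * win)], nrow = n_win, ncol = win,
         byrow = TRUE)
}

#' Probabilistic distance between groups of spike trains
#'
#' For each pair of groups, non-overlapping windows of
#' \code{window_len} consecutive ISIs (or instantaneous frequencies,
#' 1/ISI) are classified by a bootstrap-aggregated decision-tree
#' ensemble (random forest); the distance is
#' \code{2 * (balanced out-of-bag accuracy - 0.5)}, clipped to [0, 1]:
#' 0 when the groups are exchangeable (chance-level discrimination), 1
#' when perfectly separable. An average-linkage dendrogram over the
#' distance matrix is returned, with a Newick export.
#'
#' @param groups named list: one ISI vector (or list of spike
#'   trains/time vectors, pooled) per group; each group must yield >= 50
#'   windows.
#' @param window_len window length in ISIs.
#' @param n_trees trees per ensemble.
#' @param seed integer RNG seed.
#' @param feature \code{"isi"} (default) or \code{"rate"}
#'   (instantaneous frequency).
#' @return a \code{distance_result}: \code{distance} (symmetric matrix
#'   in [0,1], zero diagonal), \code{balanced_accuracy},
#'   \code{dendrogram} (hclust, average linkage), \code{newick}.
#' @export
probabilistic_distance <- function(groups, window_len = 20, n_trees = 500,
                                   seed = 1, feature = c("isi", "rate")) {
  feature <- match.arg(feature)
  if (length(groups) < 2L || is.null(names(groups)))
    stop("need a named list of at least 2 groups")
  win_mats <- lapply(names(groups), function(g) {
    x <- groups[[g]]
    if (is.list(x))
      x <- unlist(lapply(x, function(tt) {
        if (inherits(tt, "spike_train")) tt <- tt$times
        diff(tt)
      }))
    if (inherits(x, "spike_train")) x <- diff(x$times)
    x <- as.numeric(x)
    if (any(x <= 0)) stop("group '", g, "': non-positive ISI")
    if (feature == "rate") x <- 1 / x
    m <- isi_windows(x, window_len)
    if (is.null(m) || nrow(m) < 50L)
      stop("group '", g, "' yields fewer than 50 windows of length ",
           window_len)
    m
  })
  names(win_mats) <- names(groups)
  k <- length(groups)
  D <- matrix(0, k, k, dimnames = list(names(groups), names(groups)))
  B <- D
  set.seed(as.integer(seed))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    X <- rbind(win_mats[[i]], win_mats[[j]])
    colnames(X) <- paste0("f", seq_len(ncol(X)))
    y <- factor(rep(c(names(groups)[i], names(groups)[j]),
                    c(nrow(win_mats[[i]]), nrow(win_mats[[j]]))))
    rf <- randomForest::randomForest(X, y, ntree = n_trees)
    pred <- rf$predicted  # out-of-bag predictions
    recall <- vapply(levels(y), function(l)
      mean(pred[y == l] == l, na.rm = TRUE), 1)
    bacc <- mean(recall)
    B[i, j] <- B[j, i] <- bacc
    D[i, j] <- D[j, i] <- min(max(2 * (bacc - 0.5), 0), 1)
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  nwk <- ape::write.tree(ape::as.phylo(hc))
  structure(list(distance = D, balanced_accuracy = B, dendrogram = hc,
                 newick = nwk),
            class = "distance_result")
}

#' @export
print.distance_result <- function(x, ...) {
  cat("<distance_result> probabilistic distances:\n")
  print(round(x$distance, 3))
  invisible(x)
}
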
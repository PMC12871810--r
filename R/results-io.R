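#' Serialize an analysis result to disk
#'
#' Data frames go to CSV; everything else (including the package's S3
#' result objects) goes to JSON with a class tag and a schema version so
#' that [read_results()] restores the object field-for-field. Numeric
#' fidelity is full double precision.
#'
#' @param results a data.frame or any (possibly classed) list of scalars,
#'   vectors and matrices.
#' @param path output path; extension picks the format (\code{.csv} for
#'   data frames, anything else JSON).
#' @return the path, invisibly.
#' @export
write_results <- function(results, path) {
  if (is.data.frame(results) && grepl("\\.csv$", path)) {
    utils::write.csv(results, path, row.names = FALSE)
    return(invisible(path))
  }
  payload <- list(schema = "neurodyn/1",
                  class = class(results),
                  data = strip_class(results))
  ok <- tryCatch({
    jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                         complex = "list", matrix = "rowmajor", null = "null")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write results to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

strip_class <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    x <- unclass(x)
    x[] <- lapply(x, strip_class)
    attr(x, "matrix_fields") <- NULL
  } else if (is.matrix(x)) {
    x <- list(.matrix = TRUE, dim = dim(x), values = as.numeric(t(x)))
  }
  x
}

restore_fields <- function(x) {
  if (is.list(x)) {
    if (isTRUE(x$.matrix))
      return(matrix(as.numeric(unlist(x$values)), nrow = x$dim[[1]],
                    byrow = TRUE))
    x[] <- lapply(x, restore_fields)
    # scalars and homogeneous vectors arrive as lists from JSON
    if (length(x) && all(vapply(x, function(e)
        is.atomic(e) && length(e) == 1L && !is.null(e), logical(1))) &&
        length(unique(vapply(x, typeof, character(1)))) == 1L &&
        is.null(names(x)))
      x <- unlist(x)
  }
  x
}

#' Read back a result written by [write_results()]
#' @param path path written by [write_results()].
#' @return the restored object, with its original class.
#' @export
read_results <- function(path) {
  if (grepl("\\.csv$", path)) return(utils::read.csv(path))
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyMatrix = FALSE,
                                 simplifyDataFrame = FALSE)
  out <- restore_fields(payload$data)
  class(out) <- unlist(payload$class)
  out
}

#' Compare labelled groups of scalar summaries
#'
#' Generic group-comparison plumbing for per-recording summaries (Lv,
#' onset rapidness, OU parameters, ...): one-way ANOVA with post-hoc
#' Tukey HSD, plus two-group Welch t and Mann-Whitney options.
#'
#' @param values_by_group named list of numeric vectors, >= 2 groups with
#'   >= 2 values each.
#' @return a \code{group_comparison}: \code{anova_p}, \code{tukey}
#'   (data.frame pair/diff/p_adj), \code{pairwise_t}, \code{pairwise_wilcox}.
#' @examples
#' compare_groups(list(a = rnorm(10), b = rnorm(10, 2)))
#' @export
compare_groups <- function(values_by_group) {
  if (!is.list(values_by_group) || length(values_by_group) < 2L)
    stop("need a named list of at least 2 groups")
  if (is.null(names(values_by_group)) || any(names(values_by_group) == ""))
    stop("groups must be named")
  if (any(vapply(values_by_group, length, 1L) < 2L))
    stop("every group needs at least 2 values")
  g <- factor(rep(names(values_by_group), lengths(values_by_group)),
              levels = names(values_by_group))
  y <- unlist(values_by_group, use.names = FALSE)
  fit <- stats::aov(y ~ g)
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit)$g
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  pairs <- utils::combn(names(values_by_group), 2)
  pw <- apply(pairs, 2, function(p) {
    a <- values_by_group[[p[1]]]; b <- values_by_group[[p[2]]]
    c(t = stats::t.test(a, b)$p.value,
      wilcox = suppressWarnings(stats::wilcox.test(a, b)$p.value))
  })
  structure(list(
    anova_p = anova_p, tukey = tukey,
    pairwise_t = data.frame(pair = paste(pairs[2, ], pairs[1, ], sep = "-"),
                            p = pw["t", ]),
    pairwise_wilcox = data.frame(pair = paste(pairs[2, ], pairs[1, ],
                                              sep = "-"),
                                 p = pw["wilcox", ]),
    group_means = vapply(values_by_group, mean, 1),
    group_n = lengths(values_by_group)
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %d groups, one-way ANOVA p = %.3g\n",
              length(x$group_n), x$anova_p))
  print(x$tukey, ...)
  invisible(x)
}
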
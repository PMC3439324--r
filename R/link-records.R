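#' Link records across datasets
#'
#' The package's main entry point: pools the given records, clusters them
#' under the spec's distance mode and threshold with the chosen algorithm,
#' and returns a classed result holding the clustering (and, for `"bia"`,
#' the full dendrogram, which can be re-cut at other thresholds without
#' recomputation).
#'
#' Algorithms: `"bia"` builds the full single-linkage dendrogram and cuts
#' it; `"pcd"` agglomerates only up to the threshold; `"ids"` grows
#' threshold-connected clusters one at a time without a distance matrix;
#' `"tpa"` blocks records by last-name l-mers and runs `"ids"` per block.
#' All but `"tpa"` produce the same partition; `"tpa"` refines it.
#'
#' @param records a record data.frame (or list of data.frames, pooled
#'   with global record-id uniqueness enforced).
#' @param spec a [distance_spec()].
#' @param algorithm `"ids"`, `"bia"`, `"pcd"` or `"tpa"`.
#' @param threshold cut level; defaults to the spec's threshold.
#' @param lmer_length block-key length for `"tpa"`.
#' @return object of class `"reclink"` with elements `clustering`,
#'   `algorithm`, `spec`, `threshold`, `n_records` and (for `"bia"`)
#'   `dendrogram`.
#' @examples
#' cohort <- generate_datasets(generator_params(n_entities = 20, seed = 7))
#' fit <- link_records(cohort$records, distance_spec("rded", threshold = 3))
#' fit
#' @export
link_records <- function(records, spec = distance_spec(),
                         algorithm = c("ids", "bia", "pcd", "tpa"),
                         threshold = spec$threshold,
                         lmer_length = spec$lmer_length) {
  algorithm <- match.arg(algorithm)
  if (is.list(records) && !is.data.frame(records))
    records <- pool_records(records)
  if (anyDuplicated(records$record_id))
    stop("duplicate record_id(s) in input")
  dend <- NULL
  cl <- switch(algorithm,
               bia = {
                 warn_quadratic(nrow(records), "bia")
                 dend <- build_dendrogram(records, spec)
                 cut_dendrogram(dend, threshold)
               },
               pcd = pcd_cluster(records, spec, threshold),
               ids = ids_cluster(records, spec, threshold),
               tpa = tpa_cluster(records, spec, threshold, lmer_length))
  structure(list(clustering = cl, algorithm = algorithm, spec = spec,
                 threshold = threshold, n_records = nrow(records),
                 dendrogram = dend, call = match.call()),
            class = "reclink")
}

#' @export
print.reclink <- function(x, ...) {
  cat("Record linkage (", toupper(x$algorithm), ", mode ", x$spec$mode,
      ", ", x$spec$threshold_kind, " threshold ", x$threshold, ")\n",
      sep = "")
  cat("  ", x$n_records, " records -> ", length(x$clustering),
      " clusters\n", sep = "")
  invisible(x)
}

#' @export
summary.reclink <- function(object, ...) {
  sizes <- lengths(object$clustering)
  out <- list(algorithm = object$algorithm, mode = object$spec$mode,
              threshold_kind = object$spec$threshold_kind,
              threshold = object$threshold,
              n_records = object$n_records,
              n_clusters = length(object$clustering),
              size_table = table(sizes))
  class(out) <- "summary.reclink"
  out
}

#' @export
print.summary.reclink <- function(x, ...) {
  cat("Record linkage summary\n")
  cat(sprintf("  algorithm %s, mode %s, %s threshold %s\n",
              toupper(x$algorithm), x$mode, x$threshold_kind,
              format(x$threshold)))
  cat(sprintf("  %d records in %d clusters\n", x$n_records, x$n_clusters))
  cat("  cluster-size distribution:\n")
  print(x$size_table)
  invisible(x)
}

#' @export
plot.reclink <- function(x, ...) {
  if (is.null(x$dendrogram))
    stop("only BIA fits carry a dendrogram; refit with algorithm = 'bia'")
  plot(as.hclust(x$dendrogram), ...)
  invisible(x)
}

#' Evaluate a linkage fit against ground truth
#'
#' @param fit a [link_records()] result (or a [clustering()]).
#' @param truth named character vector `record_id -> entity_id` or a
#'   two-column data.frame.
#' @return a [evaluate_clustering()] report.
#' @export
evaluate_linkage <- function(fit, truth) {
  cl <- if (inherits(fit, "reclink")) fit$clustering else fit
  evaluate_clustering(cl, truth)
}

#' Sweep thresholds and evaluate each cut
#'
#' For BIA under a constant threshold the dendrogram is built once and cut
#' repeatedly — re-running the clustering per threshold is unnecessary.
#' Other algorithms are re-run per grid point.
#'
#' @param records a record data.frame.
#' @param spec a [distance_spec()].
#' @param thresholds numeric grid of cut levels.
#' @param truth ground truth as in [evaluate_linkage()].
#' @param algorithm as in [link_records()].
#' @return data.frame with one row per threshold: `threshold`,
#'   `n_clusters`, `accuracy`, `completeness`.
#' @export
sweep_thresholds <- function(records, spec, thresholds, truth,
                             algorithm = "bia") {
  if (!length(thresholds)) stop("threshold grid is empty")
  thresholds <- sort(thresholds)
  evals <- if (algorithm %in% c("bia", "pcd")) {
    dend <- build_dendrogram(records, spec)
    lapply(thresholds, function(t)
      evaluate_clustering(cut_dendrogram(dend, t), truth))
  } else {
    lapply(thresholds, function(t)
      evaluate_clustering(link_records(records, spec, algorithm,
                                       threshold = t)$clustering, truth))
  }
  data.frame(threshold = thresholds,
             n_clusters = vapply(evals, `[[`, 1L, "n_clusters"),
             accuracy = vapply(evals, `[[`, 1, "accuracy"),
             completeness = vapply(evals, `[[`, 1, "completeness"))
}
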
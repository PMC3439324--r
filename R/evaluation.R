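# Ground-truth evaluation. Truth is a named character vector mapping
# record_id -> entity_id. A cluster is "correct" when it contains exactly
# the full record set of exactly one entity; accuracy = C/N over output
# clusters, completeness = C/N* over entities.

truth_vector <- function(truth) {
  if (is.data.frame(truth)) {
    stopifnot(all(c("record_id", "entity_id") %in% names(truth)))
    truth <- setNames(as.character(truth$entity_id),
                      as.character(truth$record_id))
  }
  truth
}

# Restrict a clustering to records with ground truth; drop clusters that
# lose every member. Returns list(clusters, n_excluded).
evaluated_clusters <- function(cl, truth) {
  known <- names(truth)[nzchar(truth)]
  kept <- lapply(cl, function(m) m[m %in% known])
  n_excluded <- sum(lengths(cl)) - sum(lengths(kept))
  list(clusters = kept[lengths(kept) > 0], n_excluded = n_excluded)
}

correct_count <- function(clusters, truth) {
  # per-entity record counts over the evaluated universe
  eval_ids <- unlist(clusters, use.names = FALSE)
  ent_size <- table(truth[eval_ids])
  sum(vapply(clusters, function(m) {
    e <- unique(truth[m])
    length(e) == 1 && length(m) == ent_size[[e]]
  }, TRUE))
}

#' Cluster-level accuracy
#'
#' `C/N`: the fraction of output clusters that contain all the records of
#' exactly one entity and no others. Records without ground truth are
#' excluded before counting.
#'
#' @param cl a [clustering()].
#' @param truth named character vector `record_id -> entity_id` (or a
#'   data.frame with those two columns).
#' @return a fraction in \[0, 1\].
#' @export
linkage_accuracy <- function(cl, truth) {
  truth <- truth_vector(truth)
  ec <- evaluated_clusters(cl, truth)
  if (!length(ec$clusters)) stop("no evaluable clusters")
  correct_count(ec$clusters, truth) / length(ec$clusters)
}

#' Cluster-level completeness
#'
#' `C/N*`: the fraction of distinct entities whose full record set was
#' recovered as a correct cluster.
#'
#' @inheritParams linkage_accuracy
#' @return a fraction in \[0, 1\].
#' @export
linkage_completeness <- function(cl, truth) {
  truth <- truth_vector(truth)
  ec <- evaluated_clusters(cl, truth)
  if (!length(ec$clusters)) stop("no evaluable clusters")
  eval_ids <- unlist(ec$clusters, use.names = FALSE)
  n_entities <- length(unique(truth[eval_ids]))
  correct_count(ec$clusters, truth) / n_entities
}

#' Four-category cluster analysis
#'
#' Assigns every output cluster exactly one type:
#' \describe{
#'   \item{Type I}{one entity's records, all of them (a correct cluster).}
#'   \item{Type II}{one entity's records, but not all of them.}
#'   \item{Type III}{all records of some entity plus records of others.}
#'   \item{Type IV}{anything else — the true errors.}
#' }
#' Fractions are over the number of output clusters, so they sum to 1 and
#' the Type I fraction equals the accuracy.
#'
#' @inheritParams linkage_accuracy
#' @return named numeric vector `c(type_i, type_ii, type_iii, type_iv)`.
#' @export
four_category <- function(cl, truth) {
  truth <- truth_vector(truth)
  ec <- evaluated_clusters(cl, truth)
  if (!length(ec$clusters)) stop("no evaluable clusters")
  clusters <- ec$clusters
  eval_ids <- unlist(clusters, use.names = FALSE)
  ent_size <- table(truth[eval_ids])
  type_of <- vapply(clusters, function(m) {
    ents <- unique(truth[m])
    complete <- vapply(ents, function(e)
      sum(truth[m] == e) == ent_size[[e]], TRUE)
    if (length(ents) == 1) {
      if (complete) "type_i" else "type_ii"
    } else if (any(complete)) "type_iii" else "type_iv"
  }, "")
  counts <- table(factor(type_of,
                         levels = c("type_i", "type_ii", "type_iii",
                                    "type_iv")))
  setNames(as.numeric(counts) / length(clusters),
           c("type_i", "type_ii", "type_iii", "type_iv"))
}

#' Full evaluation report
#'
#' Bundles the cluster-level metrics into one object: the number of output
#' clusters N, correct clusters C, distinct entities N*, accuracy C/N,
#' completeness C/N*, and the four-category fractions.
#'
#' @inheritParams linkage_accuracy
#' @return object of class `"linkage_evaluation"`.
#' @export
evaluate_clustering <- function(cl, truth) {
  truth <- truth_vector(truth)
  ec <- evaluated_clusters(cl, truth)
  if (!length(ec$clusters)) stop("no evaluable clusters")
  clusters <- ec$clusters
  eval_ids <- unlist(clusters, use.names = FALSE)
  C <- correct_count(clusters, truth)
  N <- length(clusters)
  Nstar <- length(unique(truth[eval_ids]))
  structure(list(n_clusters = N, n_correct = C, n_entities = Nstar,
                 accuracy = C / N, completeness = C / Nstar,
                 type_fractions = four_category(cl, truth),
                 n_excluded = ec$n_excluded),
            class = "linkage_evaluation")
}

#' @export
print.linkage_evaluation <- function(x, ...) {
  cat("Linkage evaluation\n")
  cat(sprintf("  clusters (N): %d   correct (C): %d   entities (N*): %d\n",
              x$n_clusters, x$n_correct, x$n_entities))
  cat(sprintf("  accuracy C/N:      %.1f%%\n", 100 * x$accuracy))
  cat(sprintf("  completeness C/N*: %.1f%%\n", 100 * x$completeness))
  tf <- x$type_fractions
  cat(sprintf("  type I-IV: %.1f%% / %.1f%% / %.1f%% / %.1f%%\n",
              100 * tf[1], 100 * tf[2], 100 * tf[3], 100 * tf[4]))
  if (x$n_excluded > 0)
    cat(sprintf("  (%d records without ground truth excluded)\n",
                x$n_excluded))
  invisible(x)
}

#' @export
as.list.linkage_evaluation <- function(x, ...) {
  list(n_clusters = x$n_clusters, n_correct = x$n_correct,
       n_entities = x$n_entities, accuracy = x$accuracy,
       completeness = x$completeness,
       type_fractions = as.list(x$type_fractions),
       n_excluded = x$n_excluded)
}
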
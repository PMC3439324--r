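# The three non-blocking integration strategies. All three produce the
# same partition — a single-linkage cut at level t equals the connected
# components of the graph joining every record pair within distance t —
# but they trade memory for generality differently: BIA keeps the whole
# tree (re-cuttable at any level), PCD stops agglomerating at the
# threshold, IDS never materializes a distance matrix at all.

#' Basic integration: full dendrogram plus threshold cut
#'
#' @param records a normalized record data.frame.
#' @param spec a [distance_spec()].
#' @param threshold cut level (defaults to the spec's threshold).
#' @return a [clustering()].
#' @export
bia_cluster <- function(records, spec = distance_spec(),
                        threshold = spec$threshold) {
  warn_quadratic(nrow(records), "bia")
  cut_dendrogram(build_dendrogram(records, spec), threshold)
}

#' Partial construction of the dendrogram
#'
#' Agglomerates exactly like [bia_cluster()] but keeps per-cluster
#' nearest-neighbour bookkeeping and stops at the first inter-cluster
#' distance above the threshold, never building the upper part of the
#' tree. The partition is identical to cutting the full dendrogram.
#'
#' @inheritParams bia_cluster
#' @return a [clustering()].
#' @export
pcd_cluster <- function(records, spec = distance_spec(),
                        threshold = spec$threshold) {
  n <- nrow(records)
  if (is.null(n) || n < 1) stop("at least one record is required")
  warn_quadratic(n, "pcd")
  if (n == 1) return(clustering(list(records$record_id)))
  D <- normalized_distance_matrix(records, spec)
  diag(D) <- Inf
  labels <- records$record_id
  active <- rep(TRUE, n)
  clab <- labels
  members <- as.list(labels)
  # nearest neighbour per cluster
  nn_dist <- apply(D, 1, min)
  repeat {
    sub <- which(active)
    if (length(sub) == 1) break
    dmin <- min(nn_dist[sub])
    if (dmin > threshold) break     # stop: no pair within the threshold
    Dsub <- D[sub, sub, drop = FALSE]
    ij <- pick_min_pair(Dsub, clab[sub], dmin)
    i <- sub[ij[1]]; j <- sub[ij[2]]
    newd <- pmin(D[i, ], D[j, ])
    D[i, ] <- newd; D[, i] <- newd; D[i, i] <- Inf; D[j, ] <- Inf; D[, j] <- Inf
    active[j] <- FALSE
    members[[i]] <- c(members[[i]], members[[j]])
    clab[i] <- min(clab[i], clab[j])
    nn_dist[j] <- Inf
    # single-linkage distances to the merged cluster only ever shrink, so
    # every other cluster's nearest-neighbour distance is refreshed by one
    # comparison against the merged slot
    others <- active & seq_len(n) != i
    nn_dist[others] <- pmin(nn_dist[others], D[others, i])
    nn_dist[i] <- if (any(others)) min(D[i, others]) else Inf
  }
  clustering(members[active])
}

#' Structure-free cluster growth
#'
#' Grows one cluster at a time: pick the unassigned record with the
#' smallest id as a seed, repeatedly pull in every unassigned record
#' within the threshold of any cluster member (breadth-first closure),
#' emit the cluster, and repeat. Equivalent to the connected components of
#' the threshold graph, but no distance matrix is ever materialized —
#' memory stays linear in the number of records.
#'
#' All pair tests run through the budgeted [record_distance_bounded()]
#' machinery, so comparisons stop early once a pair is hopeless.
#'
#' @inheritParams bia_cluster
#' @return a [clustering()] (empty input gives an empty clustering).
#' @export
ids_cluster <- function(records, spec = distance_spec(),
                        threshold = spec$threshold) {
  n <- if (is.null(nrow(records))) 0L else nrow(records)
  if (n == 0) return(clustering(list()))
  ord <- order(records$record_id)
  records <- records[ord, , drop = FALSE]
  ids <- records$record_id
  unassigned <- rep(TRUE, n)
  out <- list()
  while (any(unassigned)) {
    seed <- which(unassigned)[1]
    cluster <- seed
    frontier <- seed
    unassigned[seed] <- FALSE
    while (length(frontier)) {
      nxt <- integer(0)
      cand <- which(unassigned)
      if (!length(cand)) break
      for (r in frontier) {
        if (!length(cand)) break
        hit <- pair_within_threshold(records[r, ], records[cand, ,
                                                           drop = FALSE],
                                     spec, threshold)
        if (any(hit)) {
          found <- cand[hit]
          nxt <- c(nxt, found)
          unassigned[found] <- FALSE
          cand <- cand[!hit]
        }
      }
      cluster <- c(cluster, nxt)
      frontier <- nxt
    }
    out[[length(out) + 1L]] <- ids[cluster]
  }
  clustering(out)
}

# Threshold test for one record against a block of candidates, honouring
# the spec's threshold kind. `threshold` overrides the spec value (same
# kind). Returns a logical vector.
pair_within_threshold <- function(rec, cands, spec, threshold) {
  if (spec$threshold_kind == "constant") {
    d <- record_distance_block(rec, cands, spec, threshold)
    return(!is.na(d))
  }
  # proportional: per-pair real thresholds p * base_length
  att <- mode_attributes(spec)
  r1 <- as_attr_vec(rec, spec$schema)
  m1 <- nzchar(r1[att])
  len2 <- sapply(att, function(a) {
    v <- cands[[a]]; if (is.null(v)) v <- rep("", nrow(cands))
    nchar(v)
  })
  if (is.null(dim(len2))) len2 <- matrix(len2, nrow = nrow(cands))
  common <- sweep(len2 > 0, 2, m1, `&`)
  l2 <- rowSums(len2 * common)
  l1 <- as.vector(common %*% nchar(r1[att]))
  tvec <- threshold * pair_base_length(l1, l2, spec$proportional_base)
  d <- record_distance_block(rec, cands, spec, tvec)
  !is.na(d) & d <= tvec
}

warn_quadratic <- function(n, alg) {
  if (!is.null(n) && n > 20000)
    warning(sprintf(paste0("%s builds an O(n^2) distance matrix and was ",
                           "given %d records; consider ids or tpa"),
                    toupper(alg), n), call. = FALSE)
}
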
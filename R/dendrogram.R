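# Single-linkage dendrogram over record distances, built and cut by the
# package's own agglomeration so the threshold-cut semantics and tie-breaks
# are fully specified (stats::hclust serves as an independent cross-check
# in the test suite, never as the implementation).

# Pairwise distances from record i's attributes to a block of candidate
# rows, on the comparison scale: raw record distance under a constant
# threshold, record distance / pair base length under a proportional one.
# Incomparable pairs are Inf.
normalized_distance_rows <- function(rec, cands, spec) {
  d <- record_distance_block(rec, cands, spec, Inf)
  d <- as.numeric(d)
  d[is.na(d)] <- Inf
  if (spec$threshold_kind == "proportional") {
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
    base <- pair_base_length(l1, l2, spec$proportional_base)
    out <- ifelse(base > 0, d / base, ifelse(d == 0, 0, Inf))
    out[!is.finite(d)] <- Inf
    return(out)
  }
  d
}

# Full symmetric matrix of comparison-scale distances.
normalized_distance_matrix <- function(records, spec) {
  n <- nrow(records)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (i < n) {
      idx <- (i + 1):n
      D[i, idx] <- normalized_distance_rows(records[i, ], records[idx, ,
                                                                  drop = FALSE],
                                            spec)
      D[idx, i] <- D[i, idx]
    }
  }
  dimnames(D) <- list(records$record_id, records$record_id)
  D
}

# Deterministic choice among ties: the pair whose (smaller label, larger
# label) is lexicographically least; cluster labels inherit the least
# member record_id.
pick_min_pair <- function(D, labels, dmin) {
  hits <- which(D == dmin & upper.tri(D), arr.ind = TRUE)
  lo <- pmin(labels[hits[, 1]], labels[hits[, 2]])
  hi <- pmax(labels[hits[, 1]], labels[hits[, 2]])
  k <- order(lo, hi)[1]
  c(hits[k, 1], hits[k, 2])
}

#' Build the single-linkage dendrogram over a record set
#'
#' Full agglomerative single-linkage clustering: start from one cluster
#' per record at level 0 and repeatedly merge the two closest clusters,
#' with the inter-cluster distance after a merge given by
#' `d(i+j, k) = min(d(i,k), d(j,k))`. Under a proportional threshold the
#' distances are length-normalized record distances, so one cut level
#' exists. Ties are broken deterministically by cluster label, and the
#' result does not depend on record order.
#'
#' @param records a normalized record data.frame.
#' @param spec a [distance_spec()].
#' @return an object of class `"record_dendrogram"` with hclust-style
#'   fields `merge`, `height`, `labels`; convert with [as.hclust()] to
#'   plot.
#' @export
build_dendrogram <- function(records, spec = distance_spec()) {
  n <- nrow(records)
  if (is.null(n) || n < 1) stop("at least one record is required")
  labels <- records$record_id
  if (n == 1)
    return(structure(list(merge = matrix(integer(0), 0, 2),
                          height = numeric(0), labels = labels),
                     class = "record_dendrogram"))
  D <- normalized_distance_matrix(records, spec)
  diag(D) <- Inf
  active <- rep(TRUE, n)
  clab <- labels                # current cluster label (least member id)
  cidx <- -seq_len(n)           # hclust merge coding: negative = leaf
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (s in seq_len(n - 1)) {
    sub <- which(active)
    Dsub <- D[sub, sub, drop = FALSE]
    dmin <- min(Dsub)
    ij <- pick_min_pair(Dsub, clab[sub], dmin)
    i <- sub[ij[1]]; j <- sub[ij[2]]
    merge[s, ] <- sort(c(cidx[i], cidx[j]))
    height[s] <- dmin
    # single-linkage update into slot i; retire slot j
    newd <- pmin(D[i, ], D[j, ])
    D[i, ] <- newd; D[, i] <- newd; D[i, i] <- Inf
    active[j] <- FALSE
    clab[i] <- min(clab[i], clab[j])
    cidx[i] <- s
  }
  structure(list(merge = merge, height = height, labels = labels),
            class = "record_dendrogram")
}

#' @export
print.record_dendrogram <- function(x, ...) {
  cat("Record dendrogram: ", length(x$labels), " leaves, ",
      nrow(x$merge), " merges", sep = "")
  if (length(x$height))
    cat("; merge levels ", format(min(x$height)), " .. ",
        format(max(x$height)), sep = "")
  cat("\n")
  invisible(x)
}

#' @export
as.hclust.record_dendrogram <- function(x, ...) {
  n <- length(x$labels)
  if (n < 2) stop("cannot convert a single-leaf dendrogram to hclust")
  h <- x$height
  # hclust insists on finite heights; incomparable groups merge at a level
  # above every finite one
  if (any(!is.finite(h))) {
    top <- if (any(is.finite(h))) max(h[is.finite(h)]) + 1 else 1
    h[!is.finite(h)] <- top
  }
  structure(list(merge = x$merge, height = h,
                 order = dendrogram_leaf_order(x$merge, n),
                 labels = x$labels, method = "single",
                 call = match.call(), dist.method = "record"),
            class = "hclust")
}

dendrogram_leaf_order <- function(merge, n) {
  walk <- function(k) {
    if (k < 0) return(-k)
    c(walk(merge[k, 1]), walk(merge[k, 2]))
  }
  if (nrow(merge) == 0) return(seq_len(n))
  walk(nrow(merge))
}

#' Cut a dendrogram at a threshold level
#'
#' Maximal subtrees whose merge level is at most the threshold become the
#' output clusters (leaves sit at level 0, so a threshold below every merge
#' level yields all singletons).
#'
#' @param dend a [build_dendrogram()] result.
#' @param threshold non-negative cut level.
#' @return a [clustering()].
#' @export
cut_dendrogram <- function(dend, threshold) {
  if (threshold < 0) stop("threshold must be >= 0")
  n <- length(dend$labels)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  node_rep <- integer(nrow(dend$merge))  # leaf representative of each merge
  for (s in seq_len(nrow(dend$merge))) {
    reps <- vapply(dend$merge[s, ], function(k)
      if (k < 0) -k else node_rep[k], 1L)
    node_rep[s] <- reps[1]
    if (dend$height[s] <= threshold)
      parent[find(reps[2])] <- find(reps[1])
  }
  roots <- vapply(seq_len(n), find, 1L)
  clustering(unname(split(dend$labels, roots)))
}

#' Newick-style rendering of a dendrogram
#'
#' Debug/interchange dump: nested parentheses with merge levels as branch
#' annotations.
#'
#' @param dend a [build_dendrogram()] result.
#' @return a single string.
#' @export
dendrogram_newick <- function(dend) {
  walk <- function(k) {
    if (k < 0) return(dend$labels[-k])
    paste0("(", walk(dend$merge[k, 1]), ",", walk(dend$merge[k, 2]), "):",
           format(dend$height[k]))
  }
  if (nrow(dend$merge) == 0) return(paste0(dend$labels, ";"))
  paste0(walk(nrow(dend$merge)), ";")
}
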
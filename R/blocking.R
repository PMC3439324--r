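# Two-phase algorithm: index records into blocks keyed by l-mers of the
# last name, integrate each block independently with IDS, then merge
# clusters that share records. Comparisons only ever happen within a
# block, which is what buys the speedup — and what costs accuracy when two
# versions of a name share no l-mer at all.

#' Index records by last-name l-mers
#'
#' Each record is indexed under every distinct length-`l` substring of its
#' normalized last name ("rueckl" with `l = 3` lands in the four blocks
#' rue, uec, eck, ckl). A last name shorter than `l` contributes itself as
#' the key, so short names are not silently dropped; records with an empty
#' last name get no key (the two-phase driver keeps them as singletons).
#'
#' @param records a normalized record data.frame.
#' @param l l-mer length (>= 1).
#' @param schema an [attribute_schema()] naming the last-name column.
#' @return object of class `"block_index"`: a named list mapping block key
#'   to record ids, with attributes `l` and `b` (number of non-empty
#'   blocks).
#' @export
lmer_blocks <- function(records, l = 3L, schema = default_schema()) {
  l <- as.integer(l)
  if (is.na(l) || l < 1) stop("l must be >= 1")
  last_attr <- schema_last(schema)
  if (is.null(last_attr) || is.null(records[[last_attr]]))
    stop("blocking needs a last-name attribute")
  nm <- records[[last_attr]]
  keys <- lapply(seq_len(nrow(records)), function(i) lmers(nm[i], l))
  idx <- split(rep(records$record_id, lengths(keys)),
               unlist(keys, use.names = FALSE))
  idx <- idx[order(names(idx))]
  structure(idx, l = l, b = length(idx), class = "block_index")
}

# distinct l-mers of one name (whole name when shorter than l, nothing
# when empty)
lmers <- function(name, l) {
  n <- nchar(name)
  if (n == 0) return(character(0))
  if (n < l) return(name)
  unique(substring(name, 1:(n - l + 1), l:n))
}

#' @export
print.block_index <- function(x, ...) {
  sizes <- lengths(x)
  cat("Block index: ", attr(x, "b"), " non-empty blocks (l = ",
      attr(x, "l"), "), block sizes ",
      paste(range(sizes), collapse = ".."), "\n", sep = "")
  invisible(x)
}

#' Number of possible block keys
#'
#' Over the 26-letter lowercase alphabet there are `26^l` possible l-mer
#' keys (17,576 for 3-mers; 456,976 for 4-mers).
#'
#' @param l l-mer length.
#' @return a number.
#' @export
n_possible_blocks <- function(l) 26^as.integer(l)

#' Merge clusters that share records
#'
#' Union-find over the clusters of several (possibly overlapping)
#' clusterings: any two clusters sharing at least one record id are
#' unioned. The result is a partition of the union of all records.
#'
#' @param clusterings list of [clustering()] objects (each internally
#'   disjoint; they may overlap each other).
#' @return a [clustering()].
#' @export
merge_overlapping_clusters <- function(clusterings) {
  all_ids <- sort(unique(unlist(lapply(clusterings, unlist),
                                use.names = FALSE)))
  if (!length(all_ids)) return(clustering(list()))
  parent <- seq_along(all_ids)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  pos <- setNames(seq_along(all_ids), all_ids)
  for (cl in clusterings) {
    for (members in cl) {
      p <- pos[members]
      r0 <- find(p[1])
      for (k in p[-1]) parent[find(k)] <- r0
    }
  }
  roots <- vapply(seq_along(all_ids), find, 1L)
  clustering(unname(split(all_ids, roots)))
}

#' Two-phase integration (blocking + per-block IDS)
#'
#' Phase one indexes the records by last-name l-mers; phase two runs
#' [ids_cluster()] inside every block independently (sorted key order, for
#' reproducible logs) and merges clusters sharing records. Records whose
#' last name shares no l-mer with any other record end up in singletons;
#' two records whose last names share no l-mer are never compared, even if
#' their full-record distance is small — the method's deliberate
#' speed/accuracy trade-off.
#'
#' @inheritParams bia_cluster
#' @param l l-mer length (defaults to the spec's `lmer_length`).
#' @return a [clustering()].
#' @export
tpa_cluster <- function(records, spec = distance_spec(),
                        threshold = spec$threshold, l = spec$lmer_length) {
  n <- if (is.null(nrow(records))) 0L else nrow(records)
  if (n == 0) return(clustering(list()))
  blocks <- lmer_blocks(records, l)
  rows <- setNames(seq_len(n), records$record_id)
  parts <- lapply(blocks, function(ids)
    ids_cluster(records[rows[ids], , drop = FALSE], spec, threshold))
  # records with no block key (empty last name) stay singletons
  blocked <- unique(unlist(blocks, use.names = FALSE))
  loose <- setdiff(records$record_id, blocked)
  if (length(loose))
    parts <- c(parts, list(clustering(as.list(loose))))
  merge_overlapping_clusters(parts)
}
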
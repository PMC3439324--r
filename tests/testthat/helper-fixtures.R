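# Shared fixtures: tiny record builders, random-string generators, and an
# independent partition comparator.

# record frame from parallel vectors; default schema columns
make_records <- function(first, last, dob = "19900101", gender = "m",
                         zip = "06510", ids = NULL, entity = NULL) {
  n <- max(length(first), length(last))
  df <- data.frame(record_id = if (is.null(ids)) sprintf("r%03d", seq_len(n))
                   else ids,
                   dataset_id = "d1",
                   first_name = rep_len(first, n),
                   last_name = rep_len(last, n),
                   dob = rep_len(dob, n), gender = rep_len(gender, n),
                   zip = rep_len(zip, n), stringsAsFactors = FALSE)
  if (!is.null(entity)) df$entity_id <- rep_len(entity, n)
  df
}

# single-attribute records whose pairwise edit distances are easy to stage
make_string_records <- function(values, ids = NULL) {
  data.frame(record_id = if (is.null(ids)) sprintf("r%03d", seq_along(values))
             else ids,
             dataset_id = "d1", name = values, stringsAsFactors = FALSE)
}

string_schema <- function() attribute_schema("name")

random_string <- function(max_len = 12, alphabet = letters[1:5]) {
  n <- sample(0:max_len, 1)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# canonical form of a partition: sorted list of sorted member vectors
# (labels are a convention, not part of the partition)
canon_partition <- function(cl) {
  m <- unname(lapply(unclass(cl), sort))
  m[order(vapply(m, `[`, "", 1L))]
}

expect_same_partition <- function(a, b) {
  expect_identical(canon_partition(a), canon_partition(b))
}

# independent connected-components oracle over an explicit edge list
components_oracle <- function(ids, edges_from, edges_to) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges_from, to = edges_to),
    directed = FALSE, vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership
  clustering(unname(split(names(comp), comp)))
}

# explicit threshold-graph oracle built from the scalar, unbounded record
# distance (a different code path from the banded machinery the
# algorithms use)
threshold_graph_oracle <- function(records, spec, threshold) {
  n <- nrow(records)
  from <- character(0); to <- character(0)
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d <- record_distance(records[i, ], records[j, ], spec)
      # callers bake the tested threshold into the spec, so pair_threshold
      # yields the per-pair acceptance level for both threshold kinds
      stopifnot(isTRUE(all.equal(threshold, spec$threshold)))
      tt <- pair_threshold(records[i, ], records[j, ], spec)
      if (is.finite(d) && d <= tt) {
        from <- c(from, records$record_id[i])
        to <- c(to, records$record_id[j])
      }
    }
  }
  components_oracle(records$record_id, from, to)
}

# small random cohort for property tests
random_cohort <- function(seed, n_entities = NULL) {
  if (is.null(n_entities)) n_entities <- sample(3:25, 1)
  generate_datasets(generator_params(
    n_entities = n_entities, seed = seed,
    p_typo = sample(c(0.1, 0.2, 0.4), 1),
    p_swap = sample(c(0, 0.1), 1),
    p_nickname = sample(c(0, 0.15), 1)))
}
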
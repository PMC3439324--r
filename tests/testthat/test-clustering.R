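test_that("dendrogram construction follows single linkage on staged distances", {
  # strings aa/ab/bb: d(aa,ab) = 1, d(ab,bb) = 1, d(aa,bb) = 2
  recs <- make_string_records(c("aa", "ab", "bb"))
  s <- distance_spec("ed_all", threshold = 1, schema = string_schema())
  dend <- build_dendrogram(recs, s)
  # first merge at level 1; single linkage min(1, 2) = 1 for the final merge
  expect_equal(dend$height, c(1, 1))

  expect_same_partition(cut_dendrogram(dend, 1),
                        clustering(list(recs$record_id)))
  expect_same_partition(cut_dendrogram(dend, 0.5),
                        clustering(as.list(recs$record_id)))

  one <- build_dendrogram(recs[1, ], s)
  expect_identical(nrow(one$merge), 0L)

  dup <- make_string_records(rep("same", 4))
  dd <- build_dendrogram(dup, s)
  expect_equal(dd$height, rep(0, 3))
})

test_that("cut thresholds below/above all levels give singletons/one cluster", {
  recs <- make_string_records(c("abc", "abd", "xbd", "qqq"))
  s <- distance_spec("ed_all", threshold = 1, schema = string_schema())
  dend <- build_dendrogram(recs, s)
  expect_identical(length(cut_dendrogram(dend, 0)), 4L)
  expect_identical(length(cut_dendrogram(dend, max(dend$height))), 1L)
})

test_that("dendrogram agrees with the standard single-linkage oracle", {
  set.seed(710)
  for (k in 1:10) {
    co <- random_cohort(seed = 7000 + k)
    recs <- co$records
    s <- distance_spec("ed_all", threshold = 2)
    dend <- build_dendrogram(recs, s)
    # oracle: stats::hclust on the same distance matrix
    D <- outer(seq_len(nrow(recs)), seq_len(nrow(recs)),
               Vectorize(function(i, j)
                 record_distance(recs[i, ], recs[j, ], s)))
    dimnames(D) <- list(recs$record_id, recs$record_id)
    D[!is.finite(D)] <- 9999
    h <- stats::hclust(stats::as.dist(D), method = "single")
    expect_equal(sort(dend$height[is.finite(dend$height)]),
                 sort(h$height[h$height < 9000]))
    for (t in c(0, 1, 2, 3)) {
      ours <- cut_dendrogram(dend, t)
      oracle <- clustering(unname(split(recs$record_id,
                                        stats::cutree(h, h = t))))
      expect_same_partition(ours, oracle)
    }
  }
})

test_that("partial construction stops early yet matches the full cut", {
  set.seed(720)
  for (k in 1:12) {
    co <- random_cohort(seed = 7200 + k)
    kind <- if (k %% 2) "constant" else "proportional"
    t <- if (kind == "constant") sample(0:5, 1) else runif(1, 0, 0.3)
    s <- distance_spec(sample(c("ed_all", "rded", "pded"), 1), kind, t)
    full <- cut_dendrogram(build_dendrogram(co$records, s), t)
    partial <- pcd_cluster(co$records, s, t)
    expect_same_partition(full, partial)
  }
  # degenerate cases
  recs <- make_string_records(c("aaa", "bbb", "aaa"))
  s <- distance_spec("ed_all", threshold = 0, schema = string_schema())
  expect_same_partition(pcd_cluster(recs, s, 0),
                        clustering(list(c("r001", "r003"), "r002")))
})

test_that("cluster growth equals threshold-graph components, matrix-free", {
  skip_if_not_installed("igraph")
  # transitive chain: a-b and b-c pass, a-c does not, yet one cluster
  recs <- make_string_records(c("aaaa", "aaab", "aabb"))
  s <- distance_spec("ed_all", threshold = 1, schema = string_schema())
  expect_same_partition(ids_cluster(recs, s, 1),
                        clustering(list(recs$record_id)))
  # no passing pairs -> all singletons
  far <- make_string_records(c("aaaa", "bbbb", "cccc"))
  expect_same_partition(ids_cluster(far, s, 0),
                        clustering(as.list(far$record_id)))
  expect_identical(length(ids_cluster(far[0, ], s, 1)), 0L)

  set.seed(730)
  for (k in 1:10) {
    co <- random_cohort(seed = 7300 + k)
    kind <- if (k %% 2) "constant" else "proportional"
    t <- if (kind == "constant") sample(0:4, 1) else runif(1, 0, 0.25)
    s <- distance_spec(sample(c("ed_all", "ed_name", "rded"), 1), kind, t)
    expect_same_partition(ids_cluster(co$records, s, t),
                          threshold_graph_oracle(co$records, s, t))
  }
})

test_that("raising the threshold only coarsens the partition", {
  co <- random_cohort(seed = 7400, n_entities = 15)
  s <- distance_spec("rded", threshold = 0)
  grid <- c(0, 1, 2, 4, 8)
  parts <- lapply(grid, function(t) ids_cluster(co$records, s, t))
  for (i in seq_along(grid)[-1]) {
    finer <- parts[[i - 1]]; coarser <- parts[[i]]
    look <- setNames(rep(names(coarser), lengths(coarser)), unlist(coarser))
    for (m in finer)
      expect_identical(length(unique(look[m])), 1L)
    expect_lte(length(coarser), length(finer))
  }
})

test_that("partitions are invariant to record order", {
  co <- random_cohort(seed = 7500, n_entities = 12)
  s <- distance_spec("rded", threshold = 3)
  recs <- co$records
  set.seed(1)
  shuf <- recs[sample(nrow(recs)), ]
  expect_same_partition(ids_cluster(recs, s), ids_cluster(shuf, s))
  expect_same_partition(bia_cluster(recs, s), bia_cluster(shuf, s))
  expect_same_partition(pcd_cluster(recs, s), pcd_cluster(shuf, s))
})

test_that("records with no common attributes never merge", {
  df <- data.frame(record_id = c("a", "b"), dataset_id = "d",
                   first_name = c("john", ""), last_name = c("smith", ""),
                   dob = c("", "19900101"), gender = c("", "m"),
                   zip = c("", "06510"), stringsAsFactors = FALSE)
  s <- distance_spec("ed_all", threshold = 50)
  expect_identical(length(ids_cluster(df, s)), 2L)
  expect_identical(length(cut_dendrogram(build_dendrogram(df, s), 50)), 2L)
})

test_that("the dendrogram converts to hclust and renders as newick", {
  recs <- make_string_records(c("aa", "ab", "bb"))
  s <- distance_spec("ed_all", threshold = 1, schema = string_schema())
  dend <- build_dendrogram(recs, s)
  h <- as.hclust(dend)
  expect_s3_class(h, "hclust")
  expect_identical(sort(h$order), 1:3)
  nwk <- dendrogram_newick(dend)
  expect_match(nwk, "^\\(.*\\):.*;$")
  expect_true(all(vapply(recs$record_id, grepl, TRUE, x = nwk,
                         fixed = TRUE)))
})
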
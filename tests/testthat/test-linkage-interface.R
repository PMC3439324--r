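test_that("link_records dispatches algorithms and carries the dendrogram", {
  co <- generate_datasets(generator_params(n_entities = 12, seed = 21))
  s <- distance_spec("rded", threshold = 3)
  fit <- link_records(co$records, s, "bia")
  expect_s3_class(fit, "reclink")
  expect_s3_class(fit$clustering, "clustering")
  expect_s3_class(fit$dendrogram, "record_dendrogram")
  expect_output(print(fit), "BIA")
  expect_output(print(summary(fit)), "cluster-size")

  for (alg in c("ids", "pcd")) {
    f2 <- link_records(co$records, s, alg)
    expect_null(f2$dendrogram)
    expect_same_partition(f2$clustering, fit$clustering)
  }
  expect_error(plot(link_records(co$records, s, "ids")), "dendrogram")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("threshold sweeps reuse the dendrogram and coarsen monotonically", {
  co <- generate_datasets(generator_params(n_entities = 15, seed = 22))
  s <- distance_spec("rded", threshold = 0)
  tab <- sweep_thresholds(co$records, s, c(0, 1, 2, 4, 6), co$truth, "bia")
  expect_identical(nrow(tab), 5L)
  expect_true(all(diff(tab$n_clusters) <= 0))
  expect_error(sweep_thresholds(co$records, s, numeric(0), co$truth),
               "empty")

  # zero corruption: the t = 0 cut is already perfect
  clean <- generate_datasets(generator_params(
    n_entities = 10, seed = 23, p_typo = 0, p_swap = 0, p_nickname = 0,
    p_truncate = 0, p_phonetic = 0))
  tab0 <- sweep_thresholds(clean$records, s, 0, clean$truth, "bia")
  expect_equal(tab0$accuracy, 1)
  expect_equal(tab0$completeness, 1)
})

test_that("evaluate_linkage accepts fits and bare clusterings", {
  co <- generate_datasets(generator_params(n_entities = 10, seed = 24,
                                           p_typo = 0, p_swap = 0,
                                           p_nickname = 0, p_truncate = 0,
                                           p_phonetic = 0))
  fit <- link_records(co$records, distance_spec("ed_all", threshold = 0))
  ev1 <- evaluate_linkage(fit, co$truth)
  ev2 <- evaluate_linkage(fit$clustering, co$truth)
  expect_equal(ev1$accuracy, 1)
  expect_identical(ev1$n_clusters, ev2$n_clusters)
  expect_output(print(ev1), "accuracy")
})

test_that("the integrate/evaluate command pipeline runs end to end", {
  dir <- withr::local_tempdir()
  co <- generate_datasets(generator_params(n_entities = 15, seed = 25))
  write_cohort_csv(co, dir)
  inputs <- list.files(dir, pattern = "^d\\d+\\.csv$", full.names = TRUE)
  clusters <- file.path(dir, "clusters.csv")
  expect_message(
    status <- cli_integrate(inputs, clusters, algorithm = "ids",
                            mode = "rded", threshold_kind = "constant",
                            threshold = 3),
    "clusters")
  expect_identical(status, 0L)
  expect_true(file.exists(clusters))
  expect_true(file.exists(paste0(clusters, ".manifest.json")))

  # byte-determinism of a repeated run
  clusters2 <- file.path(dir, "clusters2.csv")
  cli_integrate(inputs, clusters2, algorithm = "ids", mode = "rded",
                threshold_kind = "constant", threshold = 3)
  expect_identical(readLines(clusters), readLines(clusters2))

  report <- file.path(dir, "report.json")
  expect_output(
    expect_identical(cli_evaluate(clusters, file.path(dir, "truth.csv"),
                                  report), 0L),
    "accuracy")
  rep <- jsonlite::read_json(report)
  expect_true(rep$accuracy >= 0 && rep$accuracy <= 1)

  # errors surface as status 2 without partial outputs
  expect_identical(suppressMessages(
    cli_integrate("no-such-file.csv", clusters)), 2L)
  bad <- file.path(dir, "bad-truth.csv")
  writeLines("record_id,entity_id\nnobody,E1", bad)
  expect_identical(suppressMessages(
    cli_evaluate(clusters, bad, report)), 2L)
})

test_that("config-driven integration honours the config file", {
  dir <- withr::local_tempdir()
  co <- generate_datasets(generator_params(n_entities = 10, seed = 26))
  write_cohort_csv(co, dir)
  inputs <- list.files(dir, pattern = "^d\\d+\\.csv$", full.names = TRUE)
  cfg <- file.path(dir, "cfg.yaml")
  writeLines(c("mode: pded", "threshold_kind: proportional",
               "threshold: 0.2", "algorithm: ids"), cfg)
  out <- file.path(dir, "out.csv")
  expect_identical(suppressMessages(cli_integrate(inputs, out,
                                                  config = cfg)), 0L)
  manifest <- jsonlite::read_json(paste0(out, ".manifest.json"))
  expect_identical(manifest$mode, "pded")
  expect_identical(manifest$threshold_kind, "proportional")
})

test_that("the sweep command writes one row per grid point", {
  dir <- withr::local_tempdir()
  co <- generate_datasets(generator_params(n_entities = 10, seed = 27))
  write_cohort_csv(co, dir)
  inputs <- list.files(dir, pattern = "^d\\d+\\.csv$", full.names = TRUE)
  report <- file.path(dir, "sweep.csv")
  expect_output(
    expect_identical(
      cli_sweep(inputs, file.path(dir, "truth.csv"), c(0, 2, 4), report,
                algorithm = "bia", mode = "rded"), 0L),
    "threshold")
  tab <- read.csv(report)
  expect_identical(nrow(tab), 3L)
})
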
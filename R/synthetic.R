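# Seeded generator of multi-source person records with ground truth.
# Each entity gets a true attribute profile and 1..k duplicate records;
# duplicates are corrupted by the error types the distances are built to
# absorb: single-character typos, first/last name swaps, nickname
# substitution, attribute truncation, and phonetically plausible
# misspellings. One RNG stream is split per entity, so enlarging a cohort
# never perturbs earlier entities' draws.

#' Parameters for the synthetic-record generator
#'
#' Defaults describe a mildly corrupted multi-source cohort: one to three
#' records per entity, a 0.2 per-field chance of a single-character typo
#' (at most `max_edits_per_record` character edits in total), and small
#' probabilities for the structured errors (name swap 0.05, nickname 0.1,
#' truncation 0.05, phonetic misspelling 0.05).
#'
#' @param n_entities number of distinct persons.
#' @param n_datasets number of source datasets records are spread over.
#' @param duplicates integer vector of allowed records-per-entity counts,
#'   drawn uniformly (default `1:3`).
#' @param p_typo per-field probability of one random character edit
#'   (insert, delete or substitute, equally likely).
#' @param max_edits_per_record cap on total character edits per record.
#' @param p_swap probability of exchanging first and last name.
#' @param p_nickname probability of replacing the first name by a table
#'   variant (when the table has one).
#' @param p_truncate probability of truncating a name to its first
#'   `truncation_length` characters.
#' @param p_phonetic probability of applying one homophone rewrite
#'   (ph->f, y->i, ck->k, ...) to a name.
#' @param truncation_length prefix kept by the truncation corruption.
#' @param nickname_table a [nickname_table()] used for nickname
#'   substitution.
#' @param seed integer seed; a fixed seed makes the output byte-identical.
#' @return object of class `"generator_params"`.
#' @export
generator_params <- function(n_entities = 500L,
                             n_datasets = 4L,
                             duplicates = 1:3,
                             p_typo = 0.2,
                             max_edits_per_record = 2L,
                             p_swap = 0.05,
                             p_nickname = 0.1,
                             p_truncate = 0.05,
                             p_phonetic = 0.05,
                             truncation_length = 5L,
                             nickname_table = default_nickname_table(),
                             seed = 1L) {
  n_entities <- as.integer(n_entities)
  if (is.na(n_entities) || n_entities < 1) stop("n_entities must be >= 1")
  probs <- c(p_typo, p_swap, p_nickname, p_truncate, p_phonetic)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(duplicates < 1)) stop("duplicates must be >= 1")
  structure(list(n_entities = n_entities,
                 n_datasets = as.integer(n_datasets),
                 duplicates = as.integer(duplicates),
                 p_typo = p_typo,
                 max_edits_per_record = as.integer(max_edits_per_record),
                 p_swap = p_swap, p_nickname = p_nickname,
                 p_truncate = p_truncate, p_phonetic = p_phonetic,
                 truncation_length = as.integer(truncation_length),
                 nickname_table = nickname_table,
                 seed = as.integer(seed)),
            class = "generator_params")
}

# run code under a derived, entity-local seed without disturbing the
# caller's RNG state
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# deterministic per-entity sub-seed, kept within 32-bit integer range
entity_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 9973) %% 2147483647)
}

#' Generate entity originals
#'
#' Draws one uncorrupted record per entity: first/last name from the
#' bundled pools, date of birth uniform over 1940-2005, gender, 5-digit
#' zip.
#'
#' @param params a [generator_params()].
#' @return a normalized record data.frame with `entity_id` set.
#' @export
generate_entities <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  n <- params$n_entities
  firsts <- reclink_first_names()
  lasts <- reclink_last_names()
  rows <- lapply(seq_len(n), function(i) {
    with_local_seed(entity_seed(params$seed, i), {
      dob <- sprintf("%04d%02d%02d", sample(1940:2005, 1), sample(12, 1),
                     sample(28, 1))
      data.frame(record_id = sprintf("e%05d", i),
                 dataset_id = "originals",
                 entity_id = sprintf("ent%05d", i),
                 first_name = sample(firsts, 1),
                 last_name = sample(lasts, 1),
                 dob = dob,
                 gender = sample(c("m", "f"), 1),
                 zip = sprintf("%05d", sample(0:99999, 1)),
                 stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, rows)
}

# one random single-character edit on a lowercase string
apply_typo <- function(x, alphabet = letters) {
  n <- nchar(x)
  op <- sample(c("insert", "delete", "substitute"), 1)
  if (n == 0) op <- "insert"
  if (op == "insert") {
    pos <- sample(0:n, 1)
    paste0(substr(x, 1, pos), sample(alphabet, 1), substr(x, pos + 1, n))
  } else if (op == "delete") {
    pos <- sample(n, 1)
    paste0(substr(x, 1, pos - 1), substr(x, pos + 1, n))
  } else {
    pos <- sample(n, 1)
    paste0(substr(x, 1, pos - 1), sample(alphabet, 1), substr(x, pos + 1, n))
  }
}

# homophone rewrite rules for phonetically plausible misspellings
phonetic_rules <- function() list(
  c("ph", "f"), c("f", "ph"), c("y", "i"), c("i", "y"), c("ck", "k"),
  c("k", "ck"), c("ee", "ea"), c("ea", "ee"), c("s", "z"), c("z", "s"),
  c("ai", "ay"), c("mm", "m"), c("nn", "n"), c("ll", "l")
)

apply_phonetic_misspell <- function(x) {
  rules <- phonetic_rules()
  hits <- which(vapply(rules, function(r) grepl(r[1], x, fixed = TRUE),
                       TRUE))
  if (!length(hits)) return(x)
  r <- rules[[if (length(hits) == 1) hits else sample(hits, 1)]]
  sub(r[1], r[2], x, fixed = TRUE)
}

#' Corrupt one record
#'
#' Draws the structured corruptions by their probabilities (name swap,
#' nickname substitution, name truncation, phonetic misspelling), then
#' per-field single-character typos capped at `max_edits_per_record` in
#' total. The duplicate keeps the original's `entity_id`; callers assign
#' the new `record_id`.
#'
#' @param original one-row record data.frame (normalized).
#' @param params a [generator_params()].
#' @return a one-row record data.frame.
#' @export
corrupt_record <- function(original, params = generator_params()) {
  rec <- original
  fields <- c("first_name", "last_name", "dob", "gender", "zip")
  if (runif(1) < params$p_swap) {
    tmp <- rec$first_name
    rec$first_name <- rec$last_name
    rec$last_name <- tmp
  }
  if (runif(1) < params$p_nickname) {
    v <- setdiff(name_variants(params$nickname_table, rec$first_name),
                 rec$first_name)
    if (length(v)) rec$first_name <- if (length(v) == 1) v else sample(v, 1)
  }
  if (runif(1) < params$p_truncate) {
    which_name <- sample(c("first_name", "last_name"), 1)
    rec[[which_name]] <- substr(rec[[which_name]], 1,
                                params$truncation_length)
  }
  if (runif(1) < params$p_phonetic) {
    which_name <- sample(c("first_name", "last_name"), 1)
    rec[[which_name]] <- apply_phonetic_misspell(rec[[which_name]])
  }
  edits_left <- params$max_edits_per_record
  for (f in fields) {
    if (edits_left <= 0) break
    if (runif(1) < params$p_typo) {
      alphabet <- if (f %in% c("dob", "zip")) as.character(0:9) else letters
      rec[[f]] <- apply_typo(rec[[f]], alphabet)
      edits_left <- edits_left - 1L
    }
  }
  rec
}

#' Generate a multi-source cohort with ground truth
#'
#' Every entity receives a uniform draw from `params$duplicates` records,
#' each independently corrupted and assigned to a dataset uniformly at
#' random. Output order (and therefore CSV bytes) is fully determined by
#' the seed.
#'
#' @param params a [generator_params()].
#' @return a list with `records` (data.frame, including `entity_id`) and
#'   `truth` (named character vector `record_id -> entity_id`).
#' @export
generate_datasets <- function(params = generator_params()) {
  originals <- generate_entities(params)
  rows <- vector("list", params$n_entities)
  for (i in seq_len(params$n_entities)) {
    orig <- originals[i, , drop = FALSE]
    rows[[i]] <- with_local_seed(entity_seed(params$seed, i) + 1L, {
      k <- if (length(params$duplicates) == 1) params$duplicates
           else sample(params$duplicates, 1)
      dups <- lapply(seq_len(k), function(j) {
        rec <- corrupt_record(orig, params)
        rec$record_id <- sprintf("r%05d_%02d", i, j)
        rec$dataset_id <- sprintf("d%02d", sample(params$n_datasets, 1))
        rec
      })
      do.call(rbind, dups)
    })
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  truth <- setNames(records$entity_id, records$record_id)
  list(records = records, truth = truth)
}

#' Write a generated cohort to CSV files
#'
#' One records CSV per dataset plus a truth CSV mapping record ids to
#' entity ids; deterministic bytes under a fixed seed.
#'
#' @param cohort result of [generate_datasets()].
#' @param dir output directory (created if needed).
#' @return character vector of written file paths, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  recs <- cohort$records
  for (d in sort(unique(recs$dataset_id))) {
    p <- file.path(dir, paste0(d, ".csv"))
    sub <- recs[recs$dataset_id == d,
                setdiff(names(recs), "entity_id"), drop = FALSE]
    write.csv(sub, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  tp <- file.path(dir, "truth.csv")
  write.csv(data.frame(record_id = names(cohort$truth),
                       entity_id = unname(cohort$truth)),
            tp, row.names = FALSE, quote = FALSE)
  invisible(c(paths, tp))
}
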
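# Records travel as a data.frame with columns record_id, dataset_id,
# (optional) entity_id, plus one character column per schema attribute.
# Empty strings mark missing values.

#' Normalize raw attribute values
#'
#' Applies the canonical value normalization: lowercase and trim everywhere;
#' name-role attributes additionally keep only the letters a-z (so all name
#' distances operate on a 26-letter alphabet); values that parse as dates
#' become the digit string YYYYMMDD; any other value keeps its lowercase
#' letters and digits.
#'
#' @param x character vector of raw values.
#' @param role `"first_name"`, `"last_name"` or `"other"`.
#' @return character vector of normalized values.
#' @export
normalize_value <- function(x, role = "other") {
  x <- tolower(trimws(as.character(x)))
  x[is.na(x)] <- ""
  if (role %in% c("first_name", "last_name")) {
    return(gsub("[^a-z]", "", x))
  }
  # date-like values -> YYYYMMDD
  iso <- grepl("^\\d{4}[-/]\\d{1,2}[-/]\\d{1,2}$", x)
  if (any(iso)) {
    p <- strsplit(x[iso], "[-/]")
    x[iso] <- vapply(p, function(v)
      sprintf("%04d%02d%02d", as.integer(v[1]), as.integer(v[2]),
              as.integer(v[3])), "")
  }
  us <- grepl("^\\d{1,2}[-/]\\d{1,2}[-/]\\d{4}$", x)
  if (any(us)) {
    p <- strsplit(x[us], "[-/]")
    x[us] <- vapply(p, function(v)
      sprintf("%04d%02d%02d", as.integer(v[3]), as.integer(v[1]),
              as.integer(v[2])), "")
  }
  gsub("[^a-z0-9]", "", x)
}

#' Normalize a record or a whole record frame
#'
#' @param records a data.frame with a `record_id` column and the schema's
#'   attribute columns (a single record may be given as a one-row frame or a
#'   named list/vector with a `record_id` entry).
#' @param schema an [attribute_schema()].
#' @return the records with all attribute values normalized; `dataset_id`
#'   defaults to `"default"` when absent.
#' @export
normalize_records <- function(records, schema = default_schema()) {
  if (!is.data.frame(records))
    records <- as.data.frame(as.list(records), stringsAsFactors = FALSE)
  if (!"record_id" %in% names(records) || any(is.na(records$record_id)) ||
      any(!nzchar(records$record_id)))
    stop("every record needs a non-empty record_id")
  missing_cols <- setdiff(schema$attributes, names(records))
  if (length(missing_cols))
    stop("missing schema column(s): ", paste(missing_cols, collapse = ", "))
  records$record_id <- as.character(records$record_id)
  if (!"dataset_id" %in% names(records)) records$dataset_id <- "default"
  records$dataset_id <- as.character(records$dataset_id)
  for (a in schema$attributes)
    records[[a]] <- normalize_value(records[[a]], schema$roles[[a]])
  rownames(records) <- NULL
  records
}

#' @rdname normalize_records
#' @export
normalize_record <- normalize_records

#' Read person records from a CSV file
#'
#' Expects a header row with `record_id` plus the schema's attribute
#' columns; `dataset_id` and `entity_id` columns are picked up when present.
#' Values are normalized on the way in and row order is preserved.
#'
#' @param path CSV file path.
#' @param schema an [attribute_schema()].
#' @param dataset_id optional override for the dataset id of every row
#'   (used when the file itself carries no `dataset_id` column).
#' @return a normalized record data.frame.
#' @export
read_records_csv <- function(path, schema = default_schema(),
                             dataset_id = NULL) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  df <- read.csv(path, colClasses = "character", check.names = FALSE)
  if (!is.null(dataset_id)) df$dataset_id <- dataset_id
  df <- normalize_records(df, schema)
  dup <- unique(df$record_id[duplicated(df$record_id)])
  if (length(dup))
    stop("duplicate record_id(s): ", paste(dup, collapse = ", "))
  df
}

#' Pool records from several sources
#'
#' Binds record frames row-wise and enforces global record-id uniqueness
#' (all algorithms operate on the pooled collection).
#'
#' @param ... record data.frames (or a single list of them).
#' @return one pooled record data.frame.
#' @export
pool_records <- function(...) {
  frames <- list(...)
  if (length(frames) == 1 && is.list(frames[[1]]) && !is.data.frame(frames[[1]]))
    frames <- frames[[1]]
  out <- do.call(rbind, frames)
  rownames(out) <- NULL
  dup <- unique(out$record_id[duplicated(out$record_id)])
  if (length(dup))
    stop("duplicate record_id(s) across inputs: ", paste(dup, collapse = ", "))
  out
}

#' Construct a clustering (a partition of record ids)
#'
#' @param members list of character vectors of record ids; names become
#'   cluster ids (when unnamed, each cluster is labelled by its
#'   lexicographically smallest member).
#' @param universe optional character vector of record ids the clustering
#'   must partition exactly.
#' @return object of class `"clustering"`: a named list of sorted record-id
#'   vectors.
#' @export
clustering <- function(members, universe = NULL) {
  members <- lapply(members, function(m) sort(unique(as.character(m))))
  members <- members[lengths(members) > 0]
  all_ids <- unlist(members, use.names = FALSE)
  if (anyDuplicated(all_ids))
    stop("clusters are not disjoint: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  if (is.null(names(members)) || any(!nzchar(names(members))))
    names(members) <- vapply(members, `[`, "", 1L)
  if (!is.null(universe)) {
    universe <- as.character(universe)
    if (!setequal(all_ids, universe))
      stop("clustering is not a partition of the given record set")
  }
  members <- members[order(names(members))]
  structure(members, class = "clustering")
}

#' @export
print.clustering <- function(x, ...) {
  sizes <- lengths(x)
  cat("Clustering: ", length(x), " clusters over ", sum(sizes),
      " records\n", sep = "")
  if (length(sizes))
    cat("cluster sizes: ", paste(names(table(sizes)), "records x",
                                 as.integer(table(sizes)), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

cluster_ids_of <- function(cl) {
  # record_id -> cluster id lookup
  setNames(rep(names(cl), lengths(cl)), unlist(cl, use.names = FALSE))
}

#' Write / read a clustering as CSV
#'
#' Rows `(cluster_id, record_id)`, sorted by cluster id then record id, so
#' the same clustering always produces byte-identical output.
#'
#' @param cl a [clustering()].
#' @param path output CSV path.
#' @return `write_clusters_csv` returns `path` invisibly;
#'   `read_clusters_csv` returns a [clustering()].
#' @export
write_clusters_csv <- function(cl, path) {
  stopifnot(inherits(cl, "clustering"))
  df <- data.frame(cluster_id = rep(names(cl), lengths(cl)),
                   record_id = as.character(unlist(cl, use.names = FALSE)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$cluster_id, df$record_id), , drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("cluster_id,record_id", con)
  if (nrow(df))
    writeLines(paste(df$cluster_id, df$record_id, sep = ","), con)
  invisible(path)
}

#' @rdname write_clusters_csv
#' @export
read_clusters_csv <- function(path) {
  df <- read.csv(path, colClasses = "character")
  clustering(split(df$record_id, df$cluster_id))
}
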
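#' Distance specification
#'
#' Bundles everything a record comparison needs: the distance mode, the
#' threshold kind and value, the truncation length, the nickname table, the
#' phonetic encoder, and the attribute schema.
#'
#' Modes:
#' \describe{
#'   \item{`ed_all`}{edit distance on every schema attribute.}
#'   \item{`ed_name`}{edit distance on the first and last name only.}
#'   \item{`rded`}{reversal distance on the name pair (handles swapped
#'     first/last names) + edit distance on the other attributes.}
#'   \item{`nded`}{name distance (min of edit, reversal, nickname and
#'     truncation distances) on the name pair + edit distance elsewhere.}
#'   \item{`pded`}{phonetic (Metaphone) distance on the names + edit
#'     distance elsewhere.}
#'   \item{`pd_name`}{phonetic distance on the names only.}
#' }
#'
#' A `constant` threshold is an absolute error budget `t` (non-negative
#' integer); a `proportional` threshold is a fraction `p` in \[0, 1\] of the
#' record length, where the per-pair base length is, by default, the mean of
#' the two records' summed compared-attribute lengths (configurable to
#' `min`, `max` or `sum` — the mean keeps the threshold symmetric and
#' bounded by the longer record).
#'
#' @param mode one of `"ed_all"`, `"ed_name"`, `"rded"`, `"nded"`,
#'   `"pded"`, `"pd_name"`.
#' @param threshold_kind `"constant"` or `"proportional"`.
#' @param threshold the threshold value `t` (constant: non-negative integer)
#'   or `p` (proportional: in \[0, 1\]).
#' @param truncation_length prefix length `L` used by the truncation
#'   distance (default 5).
#' @param lmer_length substring length `l` for last-name blocking
#'   (default 3).
#' @param nickname_table a [nickname_table()] (default: the bundled table).
#' @param phonetic_encoder name of the phonetic encoder; `"metaphone"` is
#'   the only bundled encoder, but any function mapping a string to a code
#'   may be registered via `encoder_fn`.
#' @param encoder_fn optional encoder function overriding the named one.
#' @param proportional_base `"mean"`, `"min"`, `"max"` or `"sum"`.
#' @param nickname_last_names also apply nickname lookup to last names in
#'   `nded` mode (default `FALSE`).
#' @param schema an [attribute_schema()].
#' @return object of class `"distance_spec"`.
#' @export
distance_spec <- function(mode = c("ed_all", "ed_name", "rded", "nded",
                                   "pded", "pd_name"),
                          threshold_kind = c("constant", "proportional"),
                          threshold = 1,
                          truncation_length = 5L,
                          lmer_length = 3L,
                          nickname_table = default_nickname_table(),
                          phonetic_encoder = "metaphone",
                          encoder_fn = NULL,
                          proportional_base = c("mean", "min", "max", "sum"),
                          nickname_last_names = FALSE,
                          schema = default_schema()) {
  mode <- match.arg(tolower(mode[1]), c("ed_all", "ed_name", "rded", "nded",
                                        "pded", "pd_name"))
  threshold_kind <- match.arg(threshold_kind)
  proportional_base <- match.arg(proportional_base)
  if (!is.numeric(threshold) || length(threshold) != 1 || is.na(threshold) ||
      threshold < 0)
    stop("threshold must be a single non-negative number")
  if (threshold_kind == "constant" && threshold != floor(threshold))
    stop("a constant threshold must be a non-negative integer")
  if (threshold_kind == "proportional" && threshold > 1)
    stop("a proportional threshold must lie in [0, 1]")
  truncation_length <- as.integer(truncation_length)
  lmer_length <- as.integer(lmer_length)
  if (is.na(truncation_length) || truncation_length < 1)
    stop("truncation_length must be >= 1")
  if (is.na(lmer_length) || lmer_length < 1)
    stop("lmer_length must be >= 1")
  if (is.null(encoder_fn)) {
    encoder_fn <- switch(phonetic_encoder,
                         metaphone = metaphone_encode,
                         stop("unknown phonetic encoder: ", phonetic_encoder))
  }
  structure(list(mode = mode, threshold_kind = threshold_kind,
                 threshold = as.numeric(threshold),
                 truncation_length = truncation_length,
                 lmer_length = lmer_length,
                 nickname_table = nickname_table,
                 phonetic_encoder = phonetic_encoder,
                 encoder_fn = encoder_fn,
                 proportional_base = proportional_base,
                 nickname_last_names = isTRUE(nickname_last_names),
                 schema = schema),
            class = "distance_spec")
}

#' @export
print.distance_spec <- function(x, ...) {
  cat("Distance spec: mode=", x$mode, ", ", x$threshold_kind,
      " threshold=", x$threshold, ", L=", x$truncation_length,
      ", l-mer=", x$lmer_length, "\n", sep = "")
  invisible(x)
}

#' Load a run configuration from YAML or JSON
#'
#' Recognized keys: `mode`, `threshold_kind`, `threshold`,
#' `truncation_length`, `lmer_length`, `nickname_path`, `algorithm`,
#' `proportional_base`, `seed`. Absent keys fall back to the package
#' defaults (truncation length 5, 3-mers, constant threshold).
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @param schema an [attribute_schema()] for the resulting spec.
#' @return a list with elements `spec` (a [distance_spec()]), `algorithm`
#'   and `seed`.
#' @export
load_config <- function(path, schema = default_schema()) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg)) cfg <- list()
  known <- c("mode", "threshold_kind", "threshold", "truncation_length",
             "lmer_length", "nickname_path", "algorithm",
             "proportional_base", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  nick <- if (!is.null(cfg$nickname_path)) read_nickname_csv(cfg$nickname_path)
          else default_nickname_table()
  spec <- distance_spec(
    mode = if (!is.null(cfg$mode)) cfg$mode else "ed_all",
    threshold_kind = if (!is.null(cfg$threshold_kind)) cfg$threshold_kind
                     else "constant",
    threshold = if (!is.null(cfg$threshold)) cfg$threshold else 1,
    truncation_length = if (!is.null(cfg$truncation_length))
                          cfg$truncation_length else 5L,
    lmer_length = if (!is.null(cfg$lmer_length)) cfg$lmer_length else 3L,
    nickname_table = nick,
    proportional_base = if (!is.null(cfg$proportional_base))
                          cfg$proportional_base else "mean",
    schema = schema)
  algorithm <- if (!is.null(cfg$algorithm)) cfg$algorithm else "ids"
  if (!algorithm %in% c("bia", "pcd", "ids", "tpa"))
    stop("unknown algorithm: ", algorithm)
  list(spec = spec, algorithm = algorithm,
       seed = if (!is.null(cfg$seed)) as.integer(cfg$seed) else NULL)
}
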
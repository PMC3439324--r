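#' Nickname lookup table
#'
#' Builds a symmetric nickname table from (name, variant) pairs. The
#' symmetric closure is applied: if `bob` is a variant of `robert` then
#' `robert` is a variant of `bob`; every name is implicitly a variant of
#' itself (handled at lookup).
#'
#' @param pairs two-column data.frame or matrix of (name, variant) pairs;
#'   values are normalized like name attributes.
#' @return object of class `"nickname_table"`: a named list mapping each
#'   name to its variant set.
#' @export
nickname_table <- function(pairs = NULL) {
  tab <- new.env(parent = emptyenv())
  if (!is.null(pairs) && NROW(pairs)) {
    a <- normalize_value(pairs[[1]], "first_name")
    b <- normalize_value(pairs[[2]], "first_name")
    keep <- nzchar(a) & nzchar(b) & a != b
    a <- a[keep]; b <- b[keep]
    add <- function(x, y) {
      cur <- if (!is.null(tab[[x]])) tab[[x]] else character()
      tab[[x]] <- union(cur, y)
    }
    for (i in seq_along(a)) { add(a[i], b[i]); add(b[i], a[i]) }
  }
  out <- as.list(tab)
  out <- out[order(names(out))]
  structure(out, class = "nickname_table")
}

#' Load a nickname table from a two-column CSV
#'
#' @param path CSV with a header row and two columns (name, variant).
#' @return a [nickname_table()].
#' @export
read_nickname_csv <- function(path) {
  if (!file.exists(path)) stop("nickname file does not exist: ", path)
  df <- read.csv(path, colClasses = "character")
  if (ncol(df) < 2) stop("nickname table needs two columns (name, variant)")
  nickname_table(df[, 1:2])
}

#' @export
print.nickname_table <- function(x, ...) {
  cat("Nickname table: ", length(x), " names, ",
      sum(lengths(x)) %/% 2L, " symmetric pairs\n", sep = "")
  invisible(x)
}

#' Variant set of a name
#'
#' The name itself plus its table variants (a name is always a variant of
#' itself).
#'
#' @param table a [nickname_table()] (or `NULL` for the empty table).
#' @param name a single normalized name.
#' @return character vector of variants.
#' @export
name_variants <- function(table, name) {
  v <- if (!is.null(table)) table[[name]] else NULL
  unique(c(name, v))
}

#' Bundled default nickname table
#'
#' A small table of common English given-name/nickname pairs, shared by the
#' synthetic generator (which uses it to corrupt first names) and the
#' nickname distance (which uses it to undo that corruption).
#'
#' @return a [nickname_table()].
#' @export
default_nickname_table <- function() {
  nickname_table(reclink_nickname_pairs())
}
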
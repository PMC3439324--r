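#' Attribute schema for person records
#'
#' Declares the ordered set of attribute columns a record carries and which
#' of them play the first-name / last-name roles. The order fixes the
#' comparison order used by the bounded record distance, so results are
#' deterministic.
#'
#' @param attributes character vector of attribute (column) names, in
#'   comparison order.
#' @param first_name,last_name names of the attributes holding the first and
#'   last name, or `NULL` if absent. At most one attribute may hold each
#'   role.
#' @return An object of class `"attribute_schema"`.
#' @examples
#' attribute_schema(c("first", "last", "dob"), first_name = "first",
#'                  last_name = "last")
#' @export
attribute_schema <- function(attributes, first_name = NULL, last_name = NULL) {
  attributes <- as.character(attributes)
  if (length(attributes) == 0 || anyDuplicated(attributes) || any(!nzchar(attributes)))
    stop("attributes must be a non-empty set of distinct non-empty names")
  roles <- rep("other", length(attributes))
  names(roles) <- attributes
  for (nm in c(first_name, last_name)) {
    if (!is.null(nm) && !nm %in% attributes)
      stop("role attribute '", nm, "' is not in the schema")
  }
  if (!is.null(first_name)) roles[first_name] <- "first_name"
  if (!is.null(last_name)) {
    if (identical(last_name, first_name))
      stop("first_name and last_name roles must differ")
    roles[last_name] <- "last_name"
  }
  structure(list(attributes = attributes, roles = roles),
            class = "attribute_schema")
}

#' @export
print.attribute_schema <- function(x, ...) {
  cat("Attribute schema (", length(x$attributes), " attributes)\n", sep = "")
  cat(paste0("  ", x$attributes, " [", x$roles, "]"), sep = "\n")
  invisible(x)
}

#' Default person-record schema
#'
#' First name, last name, date of birth, gender and zip code — the attribute
#' set the synthetic generator produces and the distances were designed
#' around.
#'
#' @return An [attribute_schema()].
#' @export
default_schema <- function() {
  attribute_schema(c("first_name", "last_name", "dob", "gender", "zip"),
                   first_name = "first_name", last_name = "last_name")
}

schema_first <- function(schema) {
  i <- which(schema$roles == "first_name")
  if (length(i)) schema$attributes[i] else NULL
}

schema_last <- function(schema) {
  i <- which(schema$roles == "last_name")
  if (length(i)) schema$attributes[i] else NULL
}
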
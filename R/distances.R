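#' Levenshtein edit distance
#'
#' Minimum number of unit-cost insertions, deletions and exchanges turning
#' one string into the other. Vectorized over its arguments (recycling
#' length-1 inputs).
#'
#' @param s1,s2 character vectors.
#' @return integer vector of distances.
#' @examples
#' edit_distance("kitten", "sitting")  # 3
#' @export
edit_distance <- function(s1, s2) {
  .lev_full_vec(as.character(s1), as.character(s2))
}

#' Threshold-bounded (banded) edit distance
#'
#' Returns the exact edit distance whenever it is at most `t`, and the OVER
#' sentinel (`NA`) otherwise. Three devices make it fast: the
#' length-difference lower bound rejects a pair before any table work; the
#' dynamic programme is restricted to the band of width `2t + 1` around the
#' main diagonal (only paths within that band can cost at most `t`); and
#' the computation stops as soon as every cell on the current row of the
#' band exceeds `t`, which is final because values along any diagonal of
#' the edit-distance table never decrease.
#'
#' @param s1,s2 character vectors.
#' @param t non-negative integer bound(s).
#' @return integer vector; `NA` means "distance strictly greater than `t`"
#'   (test with [is_over()]).
#' @examples
#' bounded_edit_distance("abc", "abd", 1)      # 1
#' bounded_edit_distance("abc", "xyz", 1)      # NA (over)
#' @export
bounded_edit_distance <- function(s1, s2, t) {
  t <- as.integer(t)
  if (any(!is.na(t) & t < 0)) stop("bound t must be >= 0")
  .lev_bounded_vec(as.character(s1), as.character(s2), t)
}

#' Is a bounded distance the OVER sentinel?
#'
#' @param x result of a bounded distance computation.
#' @return logical vector: `TRUE` where the distance exceeded its bound.
#' @export
is_over <- function(x) is.na(x)

#' Reversal distance between two (first, last) name pairs
#'
#' The smaller of the straight pairing `ed(f1,f2) + ed(l1,l2)` and the
#' swapped pairing `ed(f1,l2) + ed(l1,f2)`; an exact first/last swap
#' therefore costs nothing.
#'
#' @param first1,last1,first2,last2 normalized name strings (vectorized).
#' @return integer vector.
#' @export
reversal_distance <- function(first1, last1, first2, last2) {
  straight <- edit_distance(first1, first2) + edit_distance(last1, last2)
  swapped <- edit_distance(first1, last2) + edit_distance(last1, first2)
  pmin(straight, swapped)
}

#' Nickname distance between two names
#'
#' The smallest edit distance over the variant sets of both names (each
#' name is a variant of itself), so "robert" vs "bob" costs 0 when the
#' table links them.
#'
#' @param n1,n2 single normalized names.
#' @param table a [nickname_table()] (or `NULL`).
#' @return a single integer.
#' @export
nickname_distance <- function(n1, n2, table = default_nickname_table()) {
  v1 <- name_variants(table, n1)
  v2 <- name_variants(table, n2)
  g <- expand.grid(a = v1, b = v2, stringsAsFactors = FALSE)
  min(edit_distance(g$a, g$b))
}

#' Truncation distance between two names
#'
#' Edit distance of the length-`L` prefixes (shorter names are used whole),
#' capturing abbreviation errors such as "christopher" recorded as
#' "christina" sharing the prefix "chris".
#'
#' @param n1,n2 character vectors of normalized names.
#' @param L prefix length (>= 1).
#' @return integer vector.
#' @export
truncation_distance <- function(n1, n2, L = 5L) {
  L <- as.integer(L)
  if (is.na(L) || L < 1) stop("L must be >= 1")
  edit_distance(substr(n1, 1L, L), substr(n2, 1L, L))
}

#' Name distance between two (first, last) name pairs
#'
#' The smallest of four readings of the name pair: (a) the straight edit
#' distances, (b) the reversal distance, (c) the nickname distance on the
#' first names plus the edit distance on the last names (optionally
#' nickname lookup on last names too), and (d) the truncation distance on
#' both names.
#'
#' @param first1,last1,first2,last2 single normalized names.
#' @param spec a [distance_spec()] supplying the truncation length and the
#'   nickname table.
#' @return a single integer, no larger than any of its four ingredients.
#' @export
name_distance <- function(first1, last1, first2, last2,
                          spec = distance_spec()) {
  straight <- edit_distance(first1, first2) + edit_distance(last1, last2)
  rev <- reversal_distance(first1, last1, first2, last2)
  last_part <- if (spec$nickname_last_names)
    nickname_distance(last1, last2, spec$nickname_table)
  else edit_distance(last1, last2)
  nick <- nickname_distance(first1, first2, spec$nickname_table) + last_part
  trunc <- truncation_distance(first1, first2, spec$truncation_length) +
    truncation_distance(last1, last2, spec$truncation_length)
  min(straight, rev, nick, trunc)
}

#' Phonetic distance between two attribute values
#'
#' Zero when the Metaphone codes agree; otherwise the edit distance of the
#' two codes.
#'
#' @param a1,a2 character vectors.
#' @param encoder encoding function (default [metaphone_encode()]).
#' @return integer vector.
#' @export
phonetic_distance <- function(a1, a2, encoder = metaphone_encode) {
  edit_distance(encoder(a1), encoder(a2))
}

# ---- record-level machinery ---------------------------------------------

# Attribute names entering the comparison for a mode.
mode_attributes <- function(spec) {
  sch <- spec$schema
  f <- schema_first(sch); l <- schema_last(sch)
  names_only <- spec$mode %in% c("ed_name", "pd_name")
  if (names_only) c(f, l) else sch$attributes
}

# Logical matrix-free helper: which attributes are compared for a pair =
# mode attributes non-missing in both records.
compared_attributes <- function(a1, a2, spec) {
  att <- mode_attributes(spec)
  att[nzchar(a1[att]) & nzchar(a2[att])]
}

#' Per-pair acceptance threshold
#'
#' For a constant threshold this is just `t`. For a proportional threshold
#' it is `p` times the base length of the pair — by default the mean of the
#' two records' summed compared-attribute lengths (only attributes
#' non-missing in both records count). Symmetric in its two records.
#'
#' @param r1,r2 named character vectors (or one-row data.frames) of
#'   normalized attribute values.
#' @param spec a [distance_spec()].
#' @return a single non-negative number.
#' @export
pair_threshold <- function(r1, r2, spec) {
  if (spec$threshold_kind == "constant") return(spec$threshold)
  r1 <- as_attr_vec(r1, spec$schema); r2 <- as_attr_vec(r2, spec$schema)
  att <- compared_attributes(r1, r2, spec)
  spec$threshold * pair_base_length(nchar_sum(r1, att), nchar_sum(r2, att),
                                    spec$proportional_base)
}

nchar_sum <- function(r, att) sum(nchar(r[att]))

pair_base_length <- function(l1, l2, base) {
  switch(base,
         mean = (l1 + l2) / 2,
         min = pmin(l1, l2),
         max = pmax(l1, l2),
         sum = l1 + l2)
}

as_attr_vec <- function(r, schema) {
  if (is.data.frame(r)) {
    stopifnot(nrow(r) == 1)
    r <- unlist(r[1, intersect(names(r), schema$attributes), drop = FALSE])
  }
  out <- setNames(rep("", length(schema$attributes)), schema$attributes)
  common <- intersect(names(r), schema$attributes)
  out[common] <- as.character(r[common])
  out[is.na(out)] <- ""
  out
}

#' Record distance under a distance specification
#'
#' The sum over common non-missing attributes of per-attribute distances,
#' where the attribute distance is chosen by the spec's mode (see
#' [distance_spec()]): names may be compared by edit, reversal, name or
#' phonetic distance; all other attributes by edit distance. Pairs with no
#' common non-missing attribute are incomparable and get `Inf`, which no
#' finite threshold accepts.
#'
#' @param r1,r2 named character vectors (or one-row data.frames) of
#'   normalized attribute values.
#' @param spec a [distance_spec()].
#' @return a single non-negative number (integer-valued, or `Inf`).
#' @export
record_distance <- function(r1, r2, spec = distance_spec()) {
  r1 <- as_attr_vec(r1, spec$schema); r2 <- as_attr_vec(r2, spec$schema)
  att <- compared_attributes(r1, r2, spec)
  if (length(att) == 0) return(Inf)
  sum(attribute_distances(r1, r2, att, spec))
}

# Vector of per-comparison distances for the compared attributes `att`,
# with name-role attributes possibly collapsed into one joint comparison.
# Returns a numeric vector (one element per comparison, schema order).
attribute_distances <- function(r1, r2, att, spec) {
  sch <- spec$schema
  f <- schema_first(sch); l <- schema_last(sch)
  f_in <- !is.null(f) && f %in% att
  l_in <- !is.null(l) && l %in% att
  joint <- spec$mode %in% c("rded", "nded") && f_in && l_in
  out <- numeric(0)
  done <- character(0)
  for (a in att) {
    if (a %in% done) next
    is_name <- !is.null(f) && a == f || !is.null(l) && a == l
    d <- if (joint && is_name) {
      done <- c(done, f, l)
      if (spec$mode == "rded")
        reversal_distance(r1[f], r1[l], r2[f], r2[l])
      else
        name_distance(r1[f], r1[l], r2[f], r2[l], spec)
    } else if (is_name && spec$mode %in% c("pded", "pd_name")) {
      phonetic_distance(r1[a], r2[a], spec$encoder_fn)
    } else if (is_name && spec$mode %in% c("rded", "nded")) {
      # only one of the two names is comparable: fall back to edit distance
      edit_distance(r1[a], r2[a])
    } else {
      edit_distance(r1[a], r2[a])
    }
    out <- c(out, as.numeric(d))
  }
  out
}

#' Bounded record distance with budget propagation
#'
#' Walks the compared attributes in schema order keeping a remaining error
#' budget, initially `floor(t)`. Every string comparison runs through the
#' banded [bounded_edit_distance()] with the current budget as its bound,
#' and the budget shrinks by each distance spent; the walk stops with OVER
#' (`NA`) the moment an attribute overruns the remaining budget. The
#' accept/reject outcome always equals `record_distance(r1, r2, spec) <=
#' floor(t)`.
#'
#' @param r1,r2 named character vectors (or one-row data.frames) of
#'   normalized attribute values.
#' @param spec a [distance_spec()].
#' @param t non-negative real threshold for this pair.
#' @return the exact integer record distance when it is `<= floor(t)`,
#'   otherwise `NA` (OVER; see [is_over()]).
#' @export
record_distance_bounded <- function(r1, r2, spec = distance_spec(),
                                    t = spec$threshold) {
  if (t < 0) stop("t must be >= 0")
  r2v <- as_attr_vec(r2, spec$schema)
  d <- record_distance_block(r1, as.data.frame(as.list(r2v),
                                               stringsAsFactors = FALSE),
                             spec, t)
  d[1]
}

# Vectorized core: distances from one record `r1` to every row of the
# record frame `cands` (attribute columns), bounded per pair by `t`
# (scalar or per-row). NA = OVER; incomparable pairs are NA as well.
record_distance_block <- function(r1, cands, spec, t) {
  r1 <- as_attr_vec(r1, spec$schema)
  sch <- spec$schema
  att <- mode_attributes(spec)
  m <- nrow(cands)
  for (a in att) if (is.null(cands[[a]])) cands[[a]] <- ""
  unbounded <- all(is.infinite(t))
  budget <- if (unbounded) rep(.Machine$integer.max %/% 4L, m)
            else as.integer(floor(rep_len(as.numeric(t), m)))
  # raw kernel: banded when a finite budget applies; the banded kernel
  # tolerates negative / NA bounds (both yield OVER)
  bed <- if (unbounded) {
    function(a, b, tt) .lev_full_vec(as.character(a), as.character(b))
  } else {
    function(a, b, tt)
      .lev_bounded_vec(as.character(a), as.character(b), as.integer(tt))
  }
  total <- integer(m)
  any_common <- logical(m)

  f <- schema_first(sch); l <- schema_last(sch)
  joint_modes <- c("rded", "nded")
  spend <- function(d) {
    # d: integer vector with NA = over; update totals and budget
    total <<- total + d
    budget <<- budget - d
  }
  done <- character(0)
  for (a in att) {
    if (a %in% done) next
    is_f <- !is.null(f) && a == f
    is_l <- !is.null(l) && a == l
    v1 <- r1[[a]]; v2 <- cands[[a]]
    if ((is_f || is_l) && spec$mode %in% joint_modes &&
        !is.null(f) && !is.null(l)) {
      f2 <- cands[[f]]; l2 <- cands[[l]]
      both <- nzchar(r1[[f]]) & nzchar(r1[[l]]) & nzchar(f2) & nzchar(l2)
      d <- rep(NA_integer_, m)
      if (spec$mode == "rded") {
        # straight pairing within budget
        s1 <- bed(r1[[f]], f2, budget)
        s2 <- bed(r1[[l]], l2, budget - s1)
        straight <- s1 + s2
        w1 <- bed(r1[[f]], l2, budget)
        w2 <- bed(r1[[l]], f2, budget - w1)
        swapped <- w1 + w2
        d <- pmin(straight, swapped, na.rm = TRUE)
        d[is.na(straight) & is.na(swapped)] <- NA_integer_
      } else {
        d <- vapply(seq_len(m), function(i) {
          if (!both[i] || is.na(budget[i]) || budget[i] < 0)
            return(NA_integer_)
          nd <- name_distance(r1[[f]], r1[[l]], f2[i], l2[i], spec)
          if (nd <= budget[i]) as.integer(nd) else NA_integer_
        }, 1L)
      }
      # partial name pairs: fall back to per-attribute edit distance on
      # whichever name is common
      partial <- !both
      if (any(partial)) {
        pf <- nzchar(r1[[f]]) & nzchar(f2) & partial
        pl <- nzchar(r1[[l]]) & nzchar(l2) & partial
        dp <- integer(m)
        bp <- budget
        if (any(pf)) {
          df <- bed(r1[[f]], f2, bp)
          dp[pf] <- dp[pf] + df[pf]; bp[pf] <- bp[pf] - df[pf]
        }
        if (any(pl)) {
          dl <- bed(r1[[l]], l2, bp)
          dp[pl] <- dp[pl] + dl[pl]
        }
        d[partial] <- dp[partial]
        d[partial & !pf & !pl] <- 0L  # neither name common: contributes 0
      }
      any_common <- any_common | (nzchar(r1[[f]]) & nzchar(f2)) |
        (nzchar(r1[[l]]) & nzchar(l2))
      done <- c(done, f, l)
      spend(d)
    } else {
      common <- nzchar(v1) & nzchar(v2)
      d <- rep(0L, m)
      if (any(common)) {
        if ((is_f || is_l) && spec$mode %in% c("pded", "pd_name")) {
          code1 <- spec$encoder_fn(v1)
          codes2 <- spec$encoder_fn(v2)
          dc <- bed(code1, codes2, budget)
        } else {
          dc <- bed(v1, v2, budget)
        }
        d[common] <- dc[common]
      }
      any_common <- any_common | common
      done <- c(done, a)
      spend(d)
    }
  }
  total[!any_common] <- NA_integer_  # incomparable
  total[!is.na(budget) & budget < 0] <- NA_integer_
  total
}
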
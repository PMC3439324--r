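# Original Metaphone (Lawrence Philips' 1990 rule set), implemented from
# the published rules. Input is expected to be a normalized name (lowercase
# a-z); anything else is stripped first. The code alphabet is
# 0BFHJKLMNPRSTWXY plus vowels kept only in initial position ("0" is the
# digraph TH).

mp_is_vowel <- function(ch) ch %in% c("a", "e", "i", "o", "u")

mp_encode_one <- function(s) {
  s <- gsub("[^a-z]", "", tolower(s))
  n <- nchar(s)
  if (n == 0) return("")
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  at <- function(i) if (i >= 1 && i <= n) ch[i] else ""

  # initial-letter exceptions
  start <- 1L
  first2 <- paste0(at(1), at(2))
  if (first2 %in% c("ae", "gn", "kn", "pn", "wr")) {
    start <- 2L
  } else if (at(1) == "x") {
    ch[1] <- "s"
  } else if (first2 == "wh") {
    start <- 2L
    ch[2] <- "w"
  }

  out <- character(0)
  i <- start
  while (i <= n) {
    c0 <- ch[i]; nxt <- at(i + 1); nxt2 <- at(i + 2); prv <- at(i - 1)
    # duplicate adjacent letters collapse, except c
    if (i > start && c0 == prv && c0 != "c") { i <- i + 1; next }
    code <- NULL
    if (mp_is_vowel(c0)) {
      if (i == start) code <- toupper(c0)
    } else if (c0 == "b") {
      if (!(i == n && prv == "m")) code <- "B"
    } else if (c0 == "c") {
      if (nxt == "i" && nxt2 == "a") code <- "X"
      else if (nxt == "h") { code <- if (prv == "s") "K" else "X" }
      else if (nxt %in% c("i", "e", "y")) code <- if (prv == "s") NULL else "S"
      else code <- "K"
    } else if (c0 == "d") {
      if (nxt == "g" && nxt2 %in% c("e", "y", "i")) { code <- "J"; i <- i + 1 }
      else code <- "T"
    } else if (c0 == "f") {
      code <- "F"
    } else if (c0 == "g") {
      if (nxt == "h" && !mp_is_vowel(nxt2) && i + 1 < n) code <- NULL
      else if (nxt == "h" && i + 1 == n) code <- NULL        # silent -gh
      else if (nxt == "n") code <- NULL                       # gn, gned
      else if (nxt %in% c("i", "e", "y")) code <- "J"
      else code <- "K"
    } else if (c0 == "h") {
      if (mp_is_vowel(prv) && !mp_is_vowel(nxt)) code <- NULL
      else if (prv %in% c("c", "s", "p", "t", "g")) code <- NULL # digraphs
      else code <- "H"
    } else if (c0 == "j") {
      code <- "J"
    } else if (c0 == "k") {
      if (prv != "c") code <- "K"
    } else if (c0 == "l") {
      code <- "L"
    } else if (c0 == "m") {
      code <- "M"
    } else if (c0 == "n") {
      code <- "N"
    } else if (c0 == "p") {
      if (nxt == "h") code <- "F" else code <- "P"
    } else if (c0 == "q") {
      code <- "K"
    } else if (c0 == "r") {
      code <- "R"
    } else if (c0 == "s") {
      if (nxt == "h") code <- "X"
      else if (nxt == "i" && nxt2 %in% c("o", "a")) code <- "X"
      else code <- "S"
    } else if (c0 == "t") {
      if (nxt == "h") code <- "0"
      else if (nxt == "i" && nxt2 %in% c("o", "a")) code <- "X"
      else if (nxt == "c" && nxt2 == "h") code <- NULL        # -tch-
      else code <- "T"
    } else if (c0 == "v") {
      code <- "F"
    } else if (c0 == "w") {
      if (mp_is_vowel(nxt)) code <- "W"
    } else if (c0 == "x") {
      code <- "KS"
    } else if (c0 == "y") {
      if (mp_is_vowel(nxt)) code <- "Y"
    } else if (c0 == "z") {
      code <- "S"
    }
    if (!is.null(code)) out <- c(out, code)
    i <- i + 1
  }
  paste(out, collapse = "")
}

#' Metaphone phonetic encoding
#'
#' Encodes names by their approximate English pronunciation so that
#' common misspellings ("smith"/"smyth", "philip"/"fillip") map to the same
#' code. A pure function: equal inputs give equal codes; the empty string
#' encodes to the empty code.
#'
#' @param s character vector of names (normalized; non-letters are
#'   stripped).
#' @return character vector of Metaphone codes.
#' @examples
#' metaphone_encode(c("smith", "smyth"))   # both "SM0"
#' metaphone_encode("knight")              # "NT"
#' @export
metaphone_encode <- function(s) {
  vapply(as.character(s), mp_encode_one, "", USE.NAMES = FALSE)
}
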
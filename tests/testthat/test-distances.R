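test_that("edit distance matches the full-DP oracle and the metric axioms", {
  expect_identical(edit_distance("abc", "abc"), 0L)
  expect_identical(edit_distance("", "abcd"), 4L)
  expect_identical(edit_distance("kitten", "sitting"), 3L)

  set.seed(101)
  strs <- replicate(60, random_string())
  for (k in 1:200) {
    s <- sample(strs, 3, replace = TRUE)
    d12 <- edit_distance(s[1], s[2])
    # oracle: base R generalized Levenshtein
    expect_identical(d12, as.integer(adist(s[1], s[2])))
    expect_identical(edit_distance(s[1], s[1]), 0L)
    expect_identical(d12, edit_distance(s[2], s[1]))
    expect_lte(d12, edit_distance(s[1], s[3]) + edit_distance(s[3], s[2]))
    # length-difference lower bound and max-length upper bound
    expect_gte(d12, abs(nchar(s[1]) - nchar(s[2])))
    expect_lte(d12, max(nchar(s[1]), nchar(s[2])))
  }
})

test_that("bounded edit distance is exact under the bound, OVER above it", {
  expect_true(is_over(bounded_edit_distance("ab", "abcdef", 2)))
  expect_identical(bounded_edit_distance("abc", "abd", 1), 1L)
  expect_true(is_over(bounded_edit_distance("abc", "xyz", 1)))
  expect_identical(bounded_edit_distance("whatever", "whatever", 0), 0L)
  expect_error(bounded_edit_distance("a", "b", -1), ">= 0")

  set.seed(202)
  for (k in 1:2000) {
    s1 <- random_string(); s2 <- random_string()
    t <- sample(0:6, 1)
    d_true <- as.integer(adist(s1, s2))
    got <- bounded_edit_distance(s1, s2, t)
    if (d_true <= t) expect_identical(got, d_true) else expect_true(is_over(got))
  }
})

test_that("reversal distance takes the cheaper of straight and swapped", {
  expect_identical(reversal_distance("john", "smith", "smith", "john"), 0L)
  expect_identical(reversal_distance("john", "smith", "john", "smith"), 0L)
  # straight = ed(ann,lee) + ed(lee,anne); swapped = ed(ann,anne) + 0 = 1
  expect_identical(reversal_distance("ann", "lee", "lee", "anne"), 1L)
})

test_that("nickname distance searches both variant sets", {
  tab <- nickname_table(data.frame(a = "robert", b = "bob"))
  expect_identical(nickname_distance("robert", "bob", tab), 0L)
  expect_identical(nickname_distance("robert", "bobb", tab), 1L)
  expect_identical(nickname_distance("xavier", "yolanda", tab),
                   edit_distance("xavier", "yolanda"))
  expect_identical(nickname_distance("bob", "robert", tab), 0L)  # symmetric
})

test_that("truncation distance compares prefixes", {
  expect_identical(truncation_distance("christopher", "christina", 5), 0L)
  expect_identical(truncation_distance("maria", "mario", 5), 1L)
  expect_identical(truncation_distance("al", "albert", 5), 3L)
  expect_error(truncation_distance("a", "b", 0), ">= 1")
})

test_that("name distance is the min of its four ingredients", {
  tab <- nickname_table(data.frame(a = "robert", b = "bob"))
  spec <- distance_spec("nded", threshold = 5, nickname_table = tab)
  expect_identical(name_distance("ann", "lee", "ann", "lee", spec), 0L)
  expect_identical(name_distance("ann", "lee", "lee", "ann", spec), 0L)
  expect_identical(name_distance("robert", "jones", "bob", "jones", spec), 0L)

  set.seed(303)
  for (k in 1:50) {
    f1 <- random_string(8, letters[1:4]); l1 <- random_string(8, letters[1:4])
    f2 <- random_string(8, letters[1:4]); l2 <- random_string(8, letters[1:4])
    nd <- name_distance(f1, l1, f2, l2, spec)
    ingredients <- c(
      edit_distance(f1, f2) + edit_distance(l1, l2),
      reversal_distance(f1, l1, f2, l2),
      nickname_distance(f1, f2, tab) + edit_distance(l1, l2),
      truncation_distance(f1, f2, 5) + truncation_distance(l1, l2, 5))
    expect_identical(as.integer(nd), as.integer(min(ingredients)))
    for (ing in ingredients) expect_lte(nd, ing)
  }
})

test_that("metaphone encoding is pure and merges sound-alike spellings", {
  expect_identical(metaphone_encode("smith"), metaphone_encode("smyth"))
  expect_identical(metaphone_encode(""), "")
  expect_identical(metaphone_encode("catherine"), metaphone_encode("catherine"))
  # rule-derived codes
  expect_identical(metaphone_encode("smith"), "SM0")
  expect_identical(metaphone_encode("knight"), "NT")
  expect_identical(metaphone_encode("wright"), "RT")
  expect_identical(metaphone_encode("philip"), "FLP")
  expect_identical(metaphone_encode("john"), "JN")
  # initial-letter exceptions
  expect_identical(metaphone_encode("xavier"), substring(metaphone_encode("savier"), 1, 10))
})

test_that("phonetic distance is zero on code-equal names, symmetric otherwise", {
  expect_identical(phonetic_distance("smith", "smyth"), 0L)
  expect_identical(phonetic_distance("smith", "smith"), 0L)
  d <- phonetic_distance("smith", "jones")
  expect_gt(d, 0)
  expect_identical(d, edit_distance(metaphone_encode("smith"),
                                    metaphone_encode("jones")))
  expect_identical(phonetic_distance("jones", "smith"), d)
})

test_that("pair thresholds: constant passes through, proportional scales", {
  r1 <- c(first_name = "abcde", last_name = "fghij", dob = "19900101",
          gender = "m", zip = "0")
  r2 <- c(first_name = "abcdx", last_name = "fghiy", dob = "19900101",
          gender = "m", zip = "0")
  s_const <- distance_spec("ed_all", "constant", 30)
  expect_identical(pair_threshold(r1, r2, s_const), 30)
  # compared lengths: 5+5+8+1+1 = 20 for both records -> mean base 20
  s_prop <- distance_spec("ed_all", "proportional", 0.35)
  expect_equal(pair_threshold(r1, r2, s_prop), 7.0)
  s_zero <- distance_spec("ed_all", "proportional", 0)
  expect_identical(pair_threshold(r1, r2, s_zero), 0)
})

test_that("record distance sums per-attribute distances by mode", {
  sch <- attribute_schema(c("a", "b"))
  s <- distance_spec("ed_all", threshold = 10, schema = sch)
  expect_identical(record_distance(c(a = "xx", b = "yy"),
                                   c(a = "xx", b = "yy"), s), 0)
  # attribute distances 1 and 2 add up
  expect_identical(record_distance(c(a = "ab", b = "abc"),
                                   c(a = "ax", b = "xyc"), s), 3)
  # missing on either side drops the attribute from the comparison
  expect_identical(record_distance(c(a = "ab", b = ""),
                                   c(a = "ab", b = "zzz"), s), 0)
  expect_identical(record_distance(c(a = "", b = ""),
                                   c(a = "x", b = "y"), s), Inf)

  swap <- distance_spec("rded", threshold = 10)
  r1 <- c(first_name = "john", last_name = "smith", dob = "19900101",
          gender = "m", zip = "06510")
  r2 <- r1; r2["first_name"] <- "smith"; r2["last_name"] <- "john"
  expect_identical(record_distance(r1, r2, swap), 0)
})

test_that("bounded record distance agrees with the unbounded decision", {
  r1 <- c(first_name = "ann", last_name = "lee", dob = "19900101",
          gender = "f", zip = "06510")
  r2 <- r1; r2["zip"] <- "06512"  # 1 substitution... plus check below
  s <- distance_spec("ed_all", threshold = 0)
  expect_identical(record_distance_bounded(r1, r1, s, 0), 0L)
  expect_true(is_over(record_distance_bounded(r1, r2, s, 0)))

  r3 <- r1; r3["dob"] <- "19910102"  # two edits in one attribute
  expect_true(is_over(record_distance_bounded(r1, r3, s, 1)))

  set.seed(404)
  specs <- list(distance_spec("ed_all", threshold = 3),
                distance_spec("ed_name", threshold = 2),
                distance_spec("rded", threshold = 3),
                distance_spec("nded", threshold = 3),
                distance_spec("pded", threshold = 2),
                distance_spec("pd_name", threshold = 1))
  for (k in 1:300) {
    sp <- specs[[sample(length(specs), 1)]]
    t <- sample(0:5, 1)
    mk <- function() c(first_name = random_string(7, letters[1:6]),
                       last_name = random_string(7, letters[1:6]),
                       dob = random_string(8, as.character(0:3)),
                       gender = sample(c("m", "f", ""), 1),
                       zip = random_string(5, as.character(0:3)))
    a <- mk(); b <- mk()
    d_full <- record_distance(a, b, sp)
    got <- record_distance_bounded(a, b, sp, t)
    if (is.finite(d_full) && d_full <= t) {
      expect_identical(as.numeric(got), d_full)
    } else {
      expect_true(is_over(got))
    }
  }
})

test_that("accept/reject is invariant to attribute comparison order", {
  sch1 <- attribute_schema(c("first_name", "last_name", "dob", "gender",
                             "zip"), "first_name", "last_name")
  sch2 <- attribute_schema(c("zip", "gender", "dob", "first_name",
                             "last_name"), "first_name", "last_name")
  set.seed(505)
  for (k in 1:100) {
    a <- c(first_name = random_string(6), last_name = random_string(6),
           dob = random_string(6, as.character(0:4)), gender = "m",
           zip = random_string(4, as.character(0:4)))
    b <- c(first_name = random_string(6), last_name = random_string(6),
           dob = random_string(6, as.character(0:4)), gender = "f",
           zip = random_string(4, as.character(0:4)))
    t <- sample(0:6, 1)
    s1 <- distance_spec("rded", threshold = t, schema = sch1)
    s2 <- distance_spec("rded", threshold = t, schema = sch2)
    expect_identical(is_over(record_distance_bounded(a, b, s1, t)),
                     is_over(record_distance_bounded(a, b, s2, t)))
  }
})

test_that("all string distances are symmetric", {
  set.seed(606)
  tab <- default_nickname_table()
  for (k in 1:40) {
    s1 <- random_string(); s2 <- random_string()
    expect_identical(edit_distance(s1, s2), edit_distance(s2, s1))
    expect_identical(truncation_distance(s1, s2, 4),
                     truncation_distance(s2, s1, 4))
    expect_identical(nickname_distance(s1, s2, tab),
                     nickname_distance(s2, s1, tab))
    expect_identical(phonetic_distance(s1, s2), phonetic_distance(s2, s1))
  }
})
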
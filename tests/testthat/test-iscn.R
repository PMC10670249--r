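test_that("single-clone karyotypes parse into the expected events", {
  k <- parse_karyotype("46,XY,−7,+r")
  expect_length(k$clones, 1)
  cl <- k$clones[[1]]
  expect_identical(modal_number(cl), 46L)
  expect_identical(cl$sex, "XY")
  kinds <- vapply(cl$abnormalities, function(a) a$kind, character(1))
  expect_identical(kinds, c("whole_loss", "ring_unknown"))
  expect_identical(cl$abnormalities[[1]]$chromosomes, "7")
  expect_length(cl$abnormalities[[2]]$chromosomes, 0)

  norm <- parse_karyotype("46,XX[15]")
  expect_length(norm$clones[[1]]$abnormalities, 0)
  expect_identical(norm$clones[[1]]$cell_count, 15L)
})

test_that("mosaic multi-clone karyotypes keep clone order, counts and breakpoints", {
  k <- parse_karyotype(noncomplex_karyotypes()[4])
  expect_length(k$clones, 3)
  expect_identical(vapply(k$clones, function(cl) cl$cell_count, integer(1)),
                   c(2L, 2L, 15L))
  ring <- k$clones[[1]]$abnormalities[[1]]
  expect_identical(ring$kind, "ring_derived")
  expect_identical(ring$chromosomes, "18")
  expect_identical(vapply(ring$breakpoints, format, character(1)),
                   c("18p11.3", "18q23"))
  tr <- k$clones[[2]]$abnormalities[[1]]
  expect_identical(tr$kind, "t")
  expect_identical(tr$chromosomes, c("7", "17"))
  expect_identical(vapply(tr$breakpoints, format, character(1)),
                   c("7q36", "17q21"))
  expect_length(k$clones[[3]]$abnormalities, 0)
})

test_that("modal numbers report exact values and interval bounds", {
  expect_identical(modal_number(parse_karyotype("48,XX,+4,+r")$clones[[1]]), 48L)
  expect_identical(modal_number(parse_karyotype("45,XX,−7")$clones[[1]]), 45L)
  expect_identical(modal_number(parse_karyotype("41~44,XX,-7[5]")$clones[[1]]),
                   c(41L, 44L))
})

test_that("loss signs are accepted in ASCII and Unicode and canonicalized", {
  for (s in c("46,XY,−7,+r", "46,XY,-7,+r", "46,XY,–7,+r")) {
    expect_true(iscn_equal(parse_karyotype(s), parse_karyotype("46,XY,-7,+r")))
  }
  expect_identical(serialize_karyotype(parse_karyotype("46,XY,−7,+r")),
                   "46,XY,-7,+r")
})

test_that("internal whitespace inside band lists is ignored", {
  a <- parse_karyotype("46,XX,t(7;17) (q36;q21)")
  b <- parse_karyotype("46,XX,t(7;17)(q36;q21)")
  expect_true(iscn_equal(a, b))
})

test_that("idem clones expand the stemline ahead of private events", {
  k <- parse_karyotype("46,XX,t(9;22)(q34;q11.2)[12]/47,XX,idem,+8[5]")
  stem <- k$clones[[1]]$abnormalities
  sub <- k$clones[[2]]$abnormalities
  expect_length(sub, 2)
  expect_true(sub[[1]]$inherited)
  expect_false(sub[[2]]$inherited)
  # inherited events form a superset of the stemline's
  stem_raw <- vapply(stem, function(a) a$raw_token, character(1))
  sub_raw <- vapply(sub, function(a) a$raw_token, character(1))
  expect_true(all(stem_raw %in% sub_raw))
})

test_that("uncertain tokens are retained and flagged, never dropped", {
  k <- parse_karyotype("46,XX,add(17)(p?),?del(7)(q22),+r")
  abns <- k$clones[[1]]$abnormalities
  expect_length(abns, 3)
  expect_true(abns[[1]]$uncertain)
  expect_true(abns[[2]]$uncertain)
  expect_identical(abns[[1]]$kind, "add")
  # a token outside the grammar is kept as 'other' with uncertain = TRUE
  k2 <- parse_karyotype("46,XY,blob17,+r")
  expect_identical(k2$clones[[1]]$abnormalities[[1]]$kind, "other")
  expect_true(k2$clones[[1]]$abnormalities[[1]]$uncertain)
})

test_that("composite and incomplete designations flag the karyotype", {
  expect_true(parse_karyotype("46,XX,del(5)(q13),+r,inc[10]")$incomplete)
  expect_true(parse_karyotype("44~46,XX,-7,+r[cp10]")$incomplete)
  expect_false(parse_karyotype("46,XY,-7,+r")$incomplete)
})

test_that("unparseable ploidy and empty input raise informative errors", {
  expect_error(parse_karyotype(""), "non-empty")
  expect_error(parse_karyotype("abc,XX,+r"), "abc")
  expect_error(parse_karyotype("46,XX[0]"), "cell count")
})

test_that("band comparison reproduces brute-force cytogenetic order", {
  # frozen distal -> proximal reference orders (p arm descends toward
  # the centromere, q arm ascends away from it)
  p_ref <- c("13.3", "13.1", "13", "12", "11.2", "11.1")
  shuffled <- c("11.2", "13.1", "13", "11.1", "13.3", "12")
  addr <- lapply(shuffled, function(b) band_address("17", "p", b))
  rank <- vapply(addr, function(a) a$position_rank, numeric(1))
  expect_identical(vapply(addr[order(rank)], function(a) a$band,
                          character(1)), p_ref)
  expect_identical(compare_bands(band_address("17", "p", "13"),
                                 band_address("17", "p", "11.2")), -1L)
  expect_identical(compare_bands(band_address("17", "p", "13.1"),
                                 band_address("17", "p", "13.1")), 0L)

  q_ref <- c("11.2", "21", "23", "25")
  qaddr <- lapply(rev(q_ref), function(b) band_address("17", "q", b))
  qrank <- vapply(qaddr, function(a) a$position_rank, numeric(1))
  expect_identical(vapply(qaddr[order(qrank)], function(a) a$band,
                          character(1)), q_ref)

  expect_error(compare_bands(band_address("17", "p", "13"),
                             band_address("17", "q", "21")),
               "different chromosome arms")
  expect_error(band_address("17", "p", "x1"), "invalid band")
})

test_that("serialization round-trips generated karyotypes", {
  co <- generate_cohort(cohort_config(n_patients = 60, seed = 11))
  for (s in co$patients$karyotype) {
    k <- parse_karyotype(s)
    expect_identical(serialize_karyotype(k), s)
    expect_true(iscn_equal(parse_karyotype(serialize_karyotype(k)), k))
  }
})

test_that("cell counts are conserved through parse and serialize", {
  co <- generate_cohort(cohort_config(n_patients = 40, seed = 12))
  for (s in co$patients$karyotype) {
    k <- parse_karyotype(s)
    counted <- sum(vapply(k$clones, function(cl) cl$cell_count, integer(1)))
    from_text <- sum(as.integer(
      gsub("\\D", "", regmatches(s, gregexpr("\\[\\d+\\]", s))[[1]])))
    expect_identical(counted, from_text)
  }
})
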
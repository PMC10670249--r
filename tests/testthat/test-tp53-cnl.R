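test_that("chromosome-17 abnormalities map to loss mechanisms", {
  call_of <- function(s) infer_cnl_from_karyotype(parse_karyotype(s))
  m <- call_of("45,XX,-17")
  expect_identical(m$status, "loss")
  expect_identical(m$mechanism, "monosomy17")
  expect_identical(call_of("46,XX,i(17)(q10)")$mechanism, "i17q")
  expect_identical(call_of("46,XY,idic(17)(p11.2)")$mechanism, "idic17")
  expect_identical(call_of("46,XX,del(17)(p11.2)")$mechanism, "del17p")
  expect_identical(call_of("46,XX,add(17)(p11.2)")$mechanism, "add17p")
  expect_identical(call_of("46,XX,add(17)(p13.1)")$mechanism, "add17p")
  expect_identical(call_of("46,XX,der(17)t(5;17)(q13;p11.2)")$mechanism,
                   "der17")
  expect_identical(call_of("45,XX,dic(5;17)(q11;p11.2)")$mechanism, "dic17")
  expect_identical(call_of("46,XX")$status, "no_evidence")
})

test_that("breakpoint position relative to 17p13.1 decides loss vs ambiguity", {
  call_of <- function(s) infer_cnl_from_karyotype(parse_karyotype(s))
  # add with a breakpoint distal to the locus may retain it
  expect_identical(call_of("46,XX,add(17)(p13.3)")$status,
                   "ambiguous_diminished")
  # unspecified breakpoint resolves only by FISH
  expect_identical(call_of("46,XX,add(17)(p?)")$status,
                   "ambiguous_diminished")
  # derivative without a usable 17p breakpoint is ambiguous
  expect_identical(call_of("46,XX,der(17)t(11;17)(q13;q25)")$status,
                   "ambiguous_diminished")
  # interstitial deletion spanning the locus is a loss ...
  expect_identical(call_of("46,XX,del(17)(p11.2p13.3)")$mechanism, "del17p")
  # ... a distal terminal deletion sparing it is not
  expect_identical(call_of("46,XX,del(17)(p13.3)")$status, "normal")
  # q-arm events carry no evidence about the locus
  expect_identical(call_of("46,XX,add(17)(q21)")$status, "normal")
  expect_identical(call_of("46,XX,t(7;17)(q36;q21)")$status, "normal")
  expect_length(call_of("46,XX,t(7;17)(q36;q21)")$evidence, 0)
})

test_that("loss mechanisms aggregate with fixed precedence and clone-order invariance", {
  k1 <- parse_karyotype("45,XX,-17,add(17)(p11.2)[5]")
  call1 <- infer_cnl_from_karyotype(k1)
  expect_identical(call1$mechanism, "monosomy17")  # single-count precedence
  expect_length(call1$evidence, 2)

  a <- parse_karyotype("45,XX,-17[5]/46,XX,del(5)(q13)[3]")
  b <- parse_karyotype("46,XX,del(5)(q13)[3]/45,XX,-17[5]")
  expect_identical(infer_cnl_from_karyotype(a)$mechanism,
                   infer_cnl_from_karyotype(b)$mechanism)
  # unrelated abnormalities do not alter the call
  c1 <- infer_cnl_from_karyotype(
    parse_karyotype("46,XY,add(17)(p11.2),del(5)(q13q33),+8,+r"))
  expect_identical(c1$mechanism, "add17p")
  expect_length(c1$evidence, 1)
})

test_that("FISH patterns parse into signal counts and round-trip", {
  p <- parse_fish_pattern("2Rdim1R2G")
  expect_identical(p$n_target_dim, 2L)
  expect_identical(p$n_target_normal, 1L)
  expect_identical(p$n_centromere, 2L)
  expect_identical(format(p), "2Rdim1R2G")
  for (s in c("2R2G", "1R2G", "1R1G", "2Rdim1R2G")) {
    q <- parse_fish_pattern(format(parse_fish_pattern(s)))
    expect_identical(q$n_target_normal, parse_fish_pattern(s)$n_target_normal)
    expect_identical(q$n_target_dim, parse_fish_pattern(s)$n_target_dim)
    expect_identical(q$n_centromere, parse_fish_pattern(s)$n_centromere)
  }
  expect_error(parse_fish_pattern("2B1G"), "invalid FISH pattern")
})

test_that("FISH interpretation is a pure function of the counts", {
  expect_identical(interpret_fish("2R2G"), "normal")
  expect_identical(interpret_fish("1R2G"), "tp53_loss_disomic17")
  expect_identical(interpret_fish("1R1G"), "monosomy17")
  expect_identical(interpret_fish("2Rdim1R2G"), "abnormal_diminished")
  expect_identical(interpret_fish("3R3G"), "normal")
  expect_error(interpret_fish("2R"), "centromere")
  # same raw string, same call
  expect_identical(interpret_fish("1R2G"), interpret_fish("1R2G"))
})

test_that("reconciliation refines ambiguity by FISH and surfaces discordance", {
  loss_call <- infer_cnl_from_karyotype(parse_karyotype("46,XX,add(17)(p11.2)"))
  r1 <- reconcile_cnl(loss_call, "1R2G")
  expect_identical(r1$concordance, "concordant")
  expect_identical(r1$final_status, "loss")

  amb_call <- infer_cnl_from_karyotype(parse_karyotype("46,XX,add(17)(p?)"))
  r2 <- reconcile_cnl(amb_call, "2Rdim1R2G")
  expect_identical(r2$concordance, "fish_refines")
  expect_identical(r2$final_status, "ambiguous_diminished")
  r2b <- reconcile_cnl(amb_call, "1R1G")
  expect_identical(r2b$final_status, "loss")

  norm_call <- infer_cnl_from_karyotype(parse_karyotype("46,XX"))
  r3 <- reconcile_cnl(norm_call, "2R2G")
  expect_identical(r3$concordance, "concordant")
  expect_identical(r3$final_status, "normal")

  r4 <- reconcile_cnl(loss_call, "2R2G")
  expect_identical(r4$concordance, "discordant")
  expect_true(is.na(r4$final_status))
  expect_identical(r4$fish_call, "normal")  # both calls retained
})

test_that("the mechanism census single-counts patients against the generator ledger", {
  co <- generate_cohort(cohort_config(n_patients = 150, seed = 77))
  tp53_ids <- co$ledger$patient_id[co$ledger$n_tp53 > 0]
  calls <- lapply(tp53_ids, function(pid) {
    infer_cnl_from_karyotype(
      parse_karyotype(co$patients$karyotype[co$patients$patient_id == pid]))
  })
  census <- cnl_mechanism_census(calls)
  truth <- table(factor(
    co$ledger$cnl_mechanism[co$ledger$patient_id %in% tp53_ids &
                              co$ledger$cnl_status == "loss"],
    levels = census$mechanism))
  expect_identical(census$n, as.integer(truth))
  expect_identical(attr(census, "n_cnl"), sum(census$n))
  expect_identical(attr(census, "n_cohort"), length(calls))
  expect_equal(census$pct_of_cnl[census$n > 0],
               100 * census$n[census$n > 0] / sum(census$n))

  # cohort with no chromosome-17 events: all zeros
  none <- cnl_mechanism_census(list(
    infer_cnl_from_karyotype(parse_karyotype("46,XY,-7,+r"))))
  expect_identical(sum(none$n), 0L)
})

test_that("two-hit accounting adds one hit for CNL and grows monotonically", {
  expect_identical(tp53_hit_count(c(1L, 2L, 0L),
                                  c("loss", "no_evidence", "loss")),
                   c(2L, 2L, 1L))
  # adding CNL evidence can only add hits
  expect_true(all(tp53_hit_count(0:3, "loss") >=
                    tp53_hit_count(0:3, "no_evidence")))
})
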
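test_that("candidate-somatic filter keeps exactly the passing variants with reasons", {
  tab <- eight_variant_table()
  report <- variant_filter_report(tab)
  expect_identical(report$kept,
                   c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_identical(report$reject_reasons[2], "vaf")
  expect_identical(report$reject_reasons[3], "strand")
  expect_identical(report$reject_reasons[4], "strand")
  expect_identical(report$reject_reasons[5], "qscore")
  expect_identical(report$reject_reasons[6], "not_known_cancer")
  expect_identical(report$reject_reasons[7], "not_damaging")
  expect_identical(report$reject_reasons[c(1, 8)], c("", ""))

  kept <- filter_candidate_somatic(tab)
  expect_identical(kept$patient_id, c("v01", "v08"))
})

test_that("missing QC fields reject the variant with a named reason", {
  tab <- eight_variant_table()[1:2, ]
  tab$vaf[1] <- NA
  report <- variant_filter_report(tab)
  expect_false(report$kept[1])
  expect_match(report$reject_reasons[1], "missing_vaf")
})

test_that("the filter is idempotent", {
  kept <- filter_candidate_somatic(eight_variant_table())
  expect_identical(filter_candidate_somatic(kept), kept)
})

test_that("mutation types classify from protein-change tokens", {
  expect_identical(
    classify_mutation_type(c("p.R248W", "p.Y220C", "p.Q192*", "p.N131fs",
                             "p.I255del", "p.R306Ter")),
    c("missense", "missense", "nonsense", "frameshift",
      "inframe_del", "nonsense"))
  expect_identical(classify_mutation_type(NA_character_, "intron inclusion"),
                   "splice_or_intron")
  expect_warning(
    out <- classify_mutation_type("p.=?!"),
    "unclassifiable")
  expect_identical(out, "other")
})

test_that("TP53 residues map to protein domains", {
  expect_identical(tp53_domain_of(c(248, 273, 220)),
                   rep("dna_binding", 3))
  expect_identical(tp53_domain_of(1), "transactivation")
  expect_identical(tp53_domain_of(c(62, 300, 340, 393)),
                   c("proline_rich", "nls", "tetramerization", "regulatory"))
  expect_error(tp53_domain_of(0), "out of range")
  expect_error(tp53_domain_of(394), "out of range")
  # boundaries are configurable
  custom <- tibble::tibble(domain = "everything", start = 1L, end = 393L)
  expect_identical(tp53_domain_of(248, custom), "everything")
})

test_that("patients stratify into overlapping gene groups plus no_TP53", {
  v <- tibble::tibble(
    patient_id = c("a", "a", "b", "b", "c"),
    gene = c("NRAS", "TP53", "TET2", "TET2", "TP53"),
    genomic_change = c("g.1 A>T", "g.2 C>T", "g.3 G>A", "g.4 G>C", "g.2 C>T"),
    protein_change = c("p.G12D", "p.R248W", "p.Q100*", "p.K200fs", "p.R248W")
  )
  groups <- stratify_patients(v, c("TP53", "TET2", "NRAS"),
                              profiled_ids = c("a", "b", "c", "d"))
  expect_identical(groups$TP53, c("a", "c"))
  expect_identical(groups$TET2, "b")   # two variants, one membership
  expect_identical(groups$NRAS, "a")   # co-mutated patient in both groups
  expect_identical(groups$no_TP53, c("b", "d"))
  # TP53 and no_TP53 partition the profiled patients
  expect_identical(sort(c(groups$TP53, groups$no_TP53)),
                   c("a", "b", "c", "d"))
  expect_length(intersect(groups$TP53, groups$no_TP53), 0)
})

test_that("mutation tallies count totals, unique changes and multiplicity", {
  v <- tibble::tibble(
    patient_id = c("a", "a", "b", "c"),
    gene = "TP53",
    genomic_change = c("g.10 A>T", "g.11 C>G", "g.10 A>T", "g.12 T>C"),
    protein_change = c("p.R248W", "p.Q192*", "p.R248W", "p.Y220C")
  )
  tl <- mutation_tally(v)
  expect_identical(tl$n_mutations, 4L)
  expect_identical(tl$n_unique, 3L)
  expect_identical(tl$n_patients, 3L)
  expect_identical(sum(tl$per_type$count), tl$n_mutations)
  expect_identical(tl$per_type$count[tl$per_type$type == "missense"], 3L)
  expect_identical(tl$multiplicity$n_patients[tl$multiplicity$n_distinct_mutations == 2], 1L)

  empty <- mutation_tally(v[0, ])
  expect_identical(empty$n_mutations, 0L)
  expect_identical(empty$n_unique, 0L)
})

test_that("shared mutations across patients count total vs unique", {
  v <- tibble::tibble(
    patient_id = c("x", "y"), gene = "IDH1",
    genomic_change = "g.209113113 G>A", protein_change = "p.R132C")
  tl <- mutation_tally(v, gene = "IDH1")
  expect_identical(tl$n_mutations, 2L)
  expect_identical(tl$n_unique, 1L)
})

test_that("oncoplot matrix is deterministic with waterfall ordering", {
  v <- tibble::tibble(
    patient_id = c("p1", "p1", "p2", "p3", "p3"),
    gene = c("TP53", "TP53", "TP53", "TET2", "NRAS"),
    genomic_change = c("g.1 A>T", "g.2 C>G", "g.3 G>A", "g.4 T>A", "g.5 C>A"),
    protein_change = c("p.R248W", "p.Q192*", "p.Y220C", "p.K100fs", "p.G12D")
  )
  m <- oncoplot_matrix(v)
  expect_identical(colnames(m)[1], "TP53")  # most mutated gene first
  expect_identical(rownames(m)[1:2], c("p1", "p2"))
  expect_identical(m["p1", "TP53"], "missense;nonsense")  # multi-hit kept
  expect_identical(m["p2", "TP53"], "missense")
  expect_identical(m["p3", "TP53"], "")
  # permuting input rows leaves the matrix unchanged
  perm <- v[c(4, 2, 5, 1, 3), ]
  expect_identical(oncoplot_matrix(perm), m)
  # single patient, single mutation
  m1 <- oncoplot_matrix(v[1, ])
  expect_identical(dim(m1), c(1L, 1L))
  expect_identical(unname(m1[1, 1]), "missense")
})
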
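# --- synthetic ring-chromosome cohort generator ------------------------

#' Configuration for the synthetic cohort generator
#'
#' Holds the statistical structure of the simulated cohort. The defaults
#' are the observed frequencies of a 90-patient myeloid ring-chromosome
#' cohort: 90% complex karyotypes, 17.3% multiple rings, 89% of rings of
#' unknown origin (mapped rings split 3:3:2:1:1 across chromosomes
#' 7/6/3/2/18), 63% of complex karyotypes with a marker chromosome,
#' TP53/TET2/NRAS mutation rates of 67.2%/13.8%/12.1% among profiled
#' complex karyotypes (36% of TP53-mutant patients carry a second
#' distinct TP53 mutation), 54% TP53 copy-number loss given a TP53
#' mutation (mechanisms split 12:4:2:1:1:1 across monosomy 17, add(17p),
#' der(17), dic(17), del(17p), i(17q)), and an 8/98 lymphoid fraction.
#' Non-complex patients never receive TP53 mutations and instead carry
#' TET2/DNMT3A or IDH1 p.R132C profiles, mirroring the observed
#' non-complex cases.
#'
#' @param n_patients Number of patients to simulate.
#' @param seed Base seed; each patient draws from an independent stream
#'   derived from `(seed, patient index)`, so cohorts extend without
#'   reshuffling earlier patients.
#' @param complex_fraction Probability a myeloid karyotype is complex.
#' @param multiple_rc_fraction Probability a complex karyotype carries
#'   more than one ring.
#' @param ring_origin_distribution Named probabilities over `"unknown"`
#'   and chromosome labels; must sum to 1.
#' @param marker_given_complex Probability of `+mar` given a complex
#'   karyotype.
#' @param dmin_rate Probability of double minutes (complex karyotypes).
#' @param per_chromosome_structural_rates Named sampling weights over
#'   chromosomes for random structural/numerical events (chromosome 17
#'   is reserved for explicit CNL mechanism events and is excluded from
#'   random draws).
#' @param tp53_mutation_rate,tet2_rate,nras_rate Gene mutation
#'   probabilities among complex karyotypes.
#' @param second_tp53_given_tp53 Probability of a second distinct TP53
#'   mutation.
#' @param cnl_given_tp53 Probability of a 17p copy-number-loss mechanism
#'   given a TP53 mutation.
#' @param cnl_mechanism_distribution Named probabilities over loss
#'   mechanisms.
#' @param lymphoid_fraction Probability a patient is lymphoid (always
#'   complex, single unknown-origin ring).
#' @param fail_variant_rate Probability a patient carries one additional
#'   variant deliberately violating a candidate-somatic criterion.
#' @param subclone_prob Probability a complex karyotype gains a derived
#'   subclone with one private event.
#' @param normal_sideline_prob Probability of an accompanying normal
#'   clone.
#' @param fish_given_cnl,fish_given_normal Probabilities of an attached
#'   FISH pattern.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 90L,
                          seed = 20231116L,
                          complex_fraction = 0.9,
                          multiple_rc_fraction = 0.173,
                          ring_origin_distribution = c(
                            unknown = 0.89, `7` = 0.033, `6` = 0.033,
                            `3` = 0.022, `2` = 0.011, `18` = 0.011),
                          marker_given_complex = 0.63,
                          dmin_rate = 0.022,
                          per_chromosome_structural_rates = NULL,
                          tp53_mutation_rate = 0.672,
                          tet2_rate = 0.138,
                          nras_rate = 0.121,
                          second_tp53_given_tp53 = 0.36,
                          cnl_given_tp53 = 0.54,
                          cnl_mechanism_distribution = c(
                            monosomy17 = 12, add17p = 4, der17 = 2,
                            dic17 = 1, del17p = 1, i17q = 1) / 21,
                          lymphoid_fraction = 8 / 98,
                          fail_variant_rate = 0.3,
                          subclone_prob = 0.2,
                          normal_sideline_prob = 0.6,
                          fish_given_cnl = 0.5,
                          fish_given_normal = 0.1) {
  if (is.null(per_chromosome_structural_rates)) {
    w <- stats::setNames(rep(1, 23), c(as.character(1:22), "X"))
    w[c("5", "7", "18")] <- 4
    w["11"] <- 5
    w["22"] <- 2
    w["X"] <- 0.3
    w["17"] <- 0  # reserved for explicit CNL mechanism events
    per_chromosome_structural_rates <- w
  }
  cfg <- structure(
    list(
      n_patients = as.integer(n_patients), seed = as.integer(seed),
      complex_fraction = complex_fraction,
      multiple_rc_fraction = multiple_rc_fraction,
      ring_origin_distribution = ring_origin_distribution,
      marker_given_complex = marker_given_complex,
      dmin_rate = dmin_rate,
      per_chromosome_structural_rates = per_chromosome_structural_rates,
      tp53_mutation_rate = tp53_mutation_rate,
      tet2_rate = tet2_rate, nras_rate = nras_rate,
      second_tp53_given_tp53 = second_tp53_given_tp53,
      cnl_given_tp53 = cnl_given_tp53,
      cnl_mechanism_distribution = cnl_mechanism_distribution,
      lymphoid_fraction = lymphoid_fraction,
      fail_variant_rate = fail_variant_rate,
      subclone_prob = subclone_prob,
      normal_sideline_prob = normal_sideline_prob,
      fish_given_cnl = fish_given_cnl,
      fish_given_normal = fish_given_normal
    ),
    class = "cohort_config"
  )
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (is.na(cfg$n_patients) || cfg$n_patients < 0L) {
    stop("n_patients must be a non-negative integer", call. = FALSE)
  }
  probs <- c("complex_fraction", "multiple_rc_fraction",
             "marker_given_complex", "dmin_rate", "tp53_mutation_rate",
             "tet2_rate", "nras_rate", "second_tp53_given_tp53",
             "cnl_given_tp53", "lymphoid_fraction", "fail_variant_rate",
             "subclone_prob", "normal_sideline_prob", "fish_given_cnl",
             "fish_given_normal")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("configuration field '", p, "' must be a probability in [0, 1]",
           call. = FALSE)
    }
  }
  rd <- cfg$ring_origin_distribution
  if (any(rd < 0) || abs(sum(rd) - 1) > 1e-6) {
    stop("ring_origin_distribution must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (!all(names(rd) %in% c("unknown", chromosome_labels))) {
    stop("ring_origin_distribution names must be chromosome labels or 'unknown'",
         call. = FALSE)
  }
  md <- cfg$cnl_mechanism_distribution
  if (any(md < 0) || abs(sum(md) - 1) > 1e-6 ||
      !all(names(md) %in% cnl_mechanism_precedence)) {
    stop("cnl_mechanism_distribution must be probabilities over known mechanisms",
         call. = FALSE)
  }
  invisible(cfg)
}

# --- token builders -----------------------------------------------------

iscn_chr_rank <- function(chr) match(chr, c(as.character(1:22), "X", "Y"))

sample_band <- function(catalogue, chr, arm) {
  bands <- catalogue$band[catalogue$chromosome == chr & catalogue$arm == arm]
  bands[sample.int(length(bands), 1L)]
}

sample_chr <- function(weights, n = 1L) {
  sample(names(weights), n, replace = FALSE, prob = weights)
}

# proximal-first band pair on one arm (ISCN order for interstitial spans)
sample_band_pair <- function(catalogue, chr, arm) {
  bands <- catalogue$band[catalogue$chromosome == chr & catalogue$arm == arm]
  if (length(bands) < 2L) return(bands[1L])
  pick <- sample(bands, 2L)
  pick[order(band_centromere_distance(pick))]
}

make_ring_token <- function(origin, catalogue) {
  if (origin == "unknown") return("+r")
  paste0("r(", origin, ")(",
         "p", sample_band(catalogue, origin, "p"),
         "q", sample_band(catalogue, origin, "q"), ")")
}

make_random_event <- function(weights, catalogue) {
  kind <- sample(
    c("loss", "gain", "del", "add", "t", "der", "dup", "inv", "dic", "i"),
    1L, prob = c(0.20, 0.12, 0.18, 0.16, 0.13, 0.07, 0.05, 0.04, 0.03, 0.02))
  chr <- sample_chr(weights)
  arm <- sample(c("p", "q"), 1L, prob = c(0.3, 0.7))
  switch(
    kind,
    loss = paste0("-", chr),
    gain = paste0("+", chr),
    del = {
      if (stats::runif(1) < 0.5) {
        paste0("del(", chr, ")(", arm, sample_band(catalogue, chr, arm), ")")
      } else {
        bp <- sample_band_pair(catalogue, chr, arm)
        paste0("del(", chr, ")(", paste0(arm, bp, collapse = ""), ")")
      }
    },
    add = paste0("add(", chr, ")(", arm, sample_band(catalogue, chr, arm), ")"),
    dup = {
      bp <- sample_band_pair(catalogue, chr, arm)
      paste0("dup(", chr, ")(", paste0(arm, bp, collapse = ""), ")")
    },
    inv = paste0("inv(", chr, ")(",
                 "p", sample_band(catalogue, chr, "p"),
                 "q", sample_band(catalogue, chr, "q"), ")"),
    t = {
      chrs <- sample_chr(weights, 2L)
      chrs <- chrs[order(iscn_chr_rank(chrs))]
      arms <- sample(c("p", "q"), 2L, replace = TRUE)
      paste0("t(", chrs[1], ";", chrs[2], ")(",
             arms[1], sample_band(catalogue, chrs[1], arms[1]), ";",
             arms[2], sample_band(catalogue, chrs[2], arms[2]), ")")
    },
    der = {
      chrs <- sample_chr(weights, 2L)
      ordered <- chrs[order(iscn_chr_rank(chrs))]
      arms <- sample(c("p", "q"), 2L, replace = TRUE)
      paste0("der(", chrs[1], ")t(", ordered[1], ";", ordered[2], ")(",
             arms[1], sample_band(catalogue, ordered[1], arms[1]), ";",
             arms[2], sample_band(catalogue, ordered[2], arms[2]), ")")
    },
    dic = {
      chrs <- sample_chr(weights, 2L)
      chrs <- chrs[order(iscn_chr_rank(chrs))]
      paste0("dic(", chrs[1], ";", chrs[2], ")(",
             "p", sample_band(catalogue, chrs[1], "p"), ";",
             "q", sample_band(catalogue, chrs[2], "q"), ")")
    },
    i = paste0("i(", chr, ")(q10)")
  )
}

make_cnl_event <- function(mechanism, weights, catalogue) {
  proximal_p <- c("11.2", "12", "13.1")
  partner <- sample_chr(weights)
  both <- c(partner, "17")
  both <- both[order(iscn_chr_rank(both))]
  switch(
    mechanism,
    monosomy17 = "-17",
    add17p = paste0("add(17)(p", sample(proximal_p, 1L), ")"),
    del17p = paste0("del(17)(p", sample(proximal_p, 1L), ")"),
    i17q = "i(17)(q10)",
    der17 = {
      bands <- vapply(both, function(ch) {
        if (ch == "17") paste0("p", sample(proximal_p, 1L))
        else paste0("q", sample_band(catalogue, ch, "q"))
      }, character(1))
      paste0("der(17)t(", both[1], ";", both[2], ")(",
             bands[1], ";", bands[2], ")")
    },
    dic17 = {
      bands <- vapply(both, function(ch) {
        if (ch == "17") paste0("p", sample(proximal_p, 1L))
        else paste0("q", sample_band(catalogue, ch, "q"))
      }, character(1))
      paste0("dic(", both[1], ";", both[2], ")(",
             bands[1], ";", bands[2], ")")
    },
    stop("unknown CNL mechanism: ", mechanism, call. = FALSE)
  )
}

token_signature <- function(tok) sub("[x×]\\d+$", "", tok)

# --- variant builders ---------------------------------------------------

tp53_hotspots <- list(
  list(genomic = "g.7577538 C>T", protein = "p.R248W"),
  list(genomic = "g.7577539 G>A", protein = "p.R248Q"),
  list(genomic = "g.7577539 G>C", protein = "p.R248G"),
  list(genomic = "g.7578190 T>C", protein = "p.Y220C"),
  list(genomic = "g.7577120 C>T", protein = "p.R273H"),
  list(genomic = "g.7577120 C>A", protein = "p.R273L")
)

aa_letters <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_genomic_id <- function(prefix = 757) {
  bases <- c("A", "C", "G", "T")
  sub <- sample(bases, 2L)
  paste0("g.", prefix, sample.int(89999, 1L) + 10000L, " ",
         sub[1], ">", sub[2])
}

# one synthetic TP53 variant; ~40% hotspot spellings, the rest generic
# DNA-binding-domain mutations with the observed type spectrum
make_tp53_variant <- function() {
  if (stats::runif(1) < 0.4) {
    hs <- tp53_hotspots[[sample.int(length(tp53_hotspots), 1L)]]
    return(list(genomic = hs$genomic, protein = hs$protein,
                annotation = NA_character_))
  }
  type <- sample(
    c("missense", "nonsense", "frameshift", "splice_or_intron", "inframe_del"),
    1L, prob = c(0.81, 0.064, 0.064, 0.043, 0.019))
  res <- sample(94:292, 1L)
  aa <- sample(aa_letters, 2L)
  protein <- switch(
    type,
    missense = paste0("p.", aa[1], res, aa[2]),
    nonsense = paste0("p.", aa[1], res, "*"),
    frameshift = paste0("p.", aa[1], res, "fs"),
    inframe_del = paste0("p.", aa[1], res, "del"),
    splice_or_intron = NA_character_
  )
  list(genomic = random_genomic_id(), protein = protein,
       annotation = if (type == "splice_or_intron") "intron inclusion"
                    else NA_character_)
}

passing_qc <- function() {
  list(vaf = round(stats::runif(1, 2, 60), 1),
       alt_reads_fwd = sample(5:150, 1L),
       alt_reads_rev = sample(5:150, 1L),
       mean_qscore = round(stats::runif(1, 20, 40), 1),
       known_cancer_flag = TRUE, damaging_flag = TRUE)
}

variant_row <- function(patient_id, gene, genomic, protein,
                        annotation = NA_character_, qc = passing_qc()) {
  tibble::tibble(
    patient_id = patient_id, gene = gene, genomic_change = genomic,
    protein_change = protein, annotation = annotation,
    vaf = qc$vaf, alt_reads_fwd = qc$alt_reads_fwd,
    alt_reads_rev = qc$alt_reads_rev, mean_qscore = qc$mean_qscore,
    known_cancer_flag = qc$known_cancer_flag,
    damaging_flag = qc$damaging_flag
  )
}

failing_variant <- function(patient_id) {
  qc <- passing_qc()
  reason <- sample(c("vaf", "strand", "qscore", "not_known_cancer",
                     "not_damaging"), 1L)
  if (reason == "vaf") qc$vaf <- round(stats::runif(1, 0.1, 0.9), 2)
  if (reason == "strand") qc$alt_reads_rev <- sample(0:1, 1L)
  if (reason == "qscore") qc$mean_qscore <- round(stats::runif(1, 3, 10), 1)
  if (reason == "not_known_cancer") qc$known_cancer_flag <- FALSE
  if (reason == "not_damaging") qc$damaging_flag <- FALSE
  gene <- sample(c("KRAS", "ASXL1", "SF3B1", "CEBPA"), 1L)
  res <- sample(20:500, 1L)
  aa <- sample(aa_letters, 2L)
  variant_row(patient_id, gene, random_genomic_id(prefix = 101),
              paste0("p.", aa[1], res, aa[2]), qc = qc)
}

# --- the generator ------------------------------------------------------

#' Generate a synthetic ring-chromosome cohort with a truth ledger
#'
#' Simulates per-patient ISCN karyotype strings, candidate-somatic
#' variant tables and FISH signal patterns with the statistical
#' structure configured in [cohort_config()]. Every karyotype contains
#' at least one ring chromosome and is emitted in canonical ISCN (so it
#' is always accepted by [parse_karyotype()]); generation is noiseless,
#' and the returned truth ledger records the intended feature values per
#' patient (complexity class, event count, ring inventory, marker and
#' dmin flags, kept mutation counts, CNL status and mechanism) for
#' recovery testing against the pipeline. Each patient is drawn from an
#' RNG stream derived from `(seed, patient index)`, so the same seed
#' reproduces the cohort exactly and extending `n_patients` preserves
#' earlier patients.
#'
#' @param cfg A [cohort_config()].
#' @param seed Base seed; defaults to `cfg$seed`.
#' @return A list of class `rc_cohort` with tibbles `patients`
#'   (`patient_id`, `diagnosis`, `karyotype`, `fish_pattern`),
#'   `variants`, `ledger`, and the `config`.
#' @export
generate_cohort <- function(cfg = cohort_config(), seed = cfg$seed) {
  validate_cohort_config(cfg)
  catalogue <- iscn_band_catalogue()
  weights <- cfg$per_chromosome_structural_rates
  weights <- weights[weights > 0]

  patients <- list()
  ledger <- list()
  variants <- list()

  for (i in seq_len(cfg$n_patients)) {
    set.seed((cfg$seed %% 1000003L) * 2011L + i * 7919L)
    pid <- sprintf("SP%03d", i)

    lymphoid <- stats::runif(1) < cfg$lymphoid_fraction
    if (lymphoid) {
      diagnosis <- sample(c("MM", "ALL", "CLL"), 1L,
                          prob = c(0.625, 0.25, 0.125))
      complex <- TRUE
      n_rings <- 1L
      origins <- "unknown"
    } else {
      diagnosis <- sample(c("AML", "MDS", "CMML to AML", "CML to AML", "CML"),
                          1L, prob = c(0.522, 0.411, 0.033, 0.022, 0.011))
      complex <- stats::runif(1) < cfg$complex_fraction
      n_rings <- if (complex && stats::runif(1) < cfg$multiple_rc_fraction) {
        sample(2:3, 1L, prob = c(0.8, 0.2))
      } else 1L
      origins <- sample(names(cfg$ring_origin_distribution), n_rings,
                        replace = TRUE,
                        prob = cfg$ring_origin_distribution)
    }

    tp53 <- complex && !lymphoid && stats::runif(1) < cfg$tp53_mutation_rate
    n_tp53 <- if (tp53) 1L + (stats::runif(1) < cfg$second_tp53_given_tp53)
              else 0L
    cnl <- tp53 && stats::runif(1) < cfg$cnl_given_tp53
    mechanism <- if (cnl) {
      sample(names(cfg$cnl_mechanism_distribution), 1L,
             prob = cfg$cnl_mechanism_distribution)
    } else "none"
    tet2 <- complex && !lymphoid && stats::runif(1) < cfg$tet2_rate
    nras <- complex && !lymphoid && stats::runif(1) < cfg$nras_rate
    marker <- complex && stats::runif(1) < cfg$marker_given_complex
    dmin <- complex && stats::runif(1) < cfg$dmin_rate

    # --- karyotype token assembly ---
    tokens <- vapply(origins, make_ring_token, character(1),
                     catalogue = catalogue)
    if (cnl) tokens <- c(tokens, make_cnl_event(mechanism, weights, catalogue))
    if (marker) tokens <- c(tokens, "+mar")
    if (dmin) tokens <- c(tokens, "dmin")
    target <- if (complex) max(sample(4:12, 1L), length(tokens) + 1L)
              else sample(seq_len(3L), 1L)
    sigs <- token_signature(tokens)
    attempts <- 0L
    while (length(tokens) < target && attempts < 200L) {
      attempts <- attempts + 1L
      cand <- make_random_event(weights, catalogue)
      if (token_signature(cand) %in% sigs) next
      tokens <- c(tokens, cand)
      sigs <- c(sigs, token_signature(cand))
    }
    subclone_extra <- NULL
    if (complex && stats::runif(1) < cfg$subclone_prob) {
      for (a in seq_len(50L)) {
        cand <- make_random_event(weights, catalogue)
        if (!token_signature(cand) %in% sigs) {
          subclone_extra <- cand
          sigs <- c(sigs, token_signature(cand))
          break
        }
      }
    }
    n_events <- length(tokens) + length(subclone_extra)

    sex <- sample(c("XX", "XY"), 1L)
    modal_of <- function(toks) {
      46L + sum(startsWith(toks, "+")) - sum(startsWith(toks, "-")) -
        sum(startsWith(toks, "dic("))
    }
    clone_str <- function(toks, cells) {
      paste0(modal_of(toks), ",", sex, ",", paste(toks, collapse = ","),
             "[", cells, "]")
    }
    clones <- clone_str(tokens, sample(5:20, 1L))
    if (!is.null(subclone_extra)) {
      clones <- c(clones,
                  clone_str(c(tokens, subclone_extra), sample(2:8, 1L)))
    }
    if (stats::runif(1) < cfg$normal_sideline_prob) {
      clones <- c(clones, paste0("46,", sex, "[", sample(5:20, 1L), "]"))
    }
    naive <- paste(clones, collapse = "/")
    karyotype <- serialize_karyotype(parse_karyotype(naive))

    # --- variants ---
    pv <- list()
    if (tp53) {
      seen <- character()
      while (length(pv) < n_tp53) {
        v <- make_tp53_variant()
        if (v$genomic %in% seen) next
        seen <- c(seen, v$genomic)
        pv[[length(pv) + 1L]] <-
          variant_row(pid, "TP53", v$genomic, v$protein, v$annotation)
      }
    }
    n_tet2 <- 0L
    n_other <- 0L
    if (!complex && !lymphoid) {
      # non-complex profiles: biallelic TET2 + DNMT3A, or the shared
      # IDH1 p.R132C substitution
      if (stats::runif(1) < 0.5) {
        for (j in 1:2) {
          res <- sample(100:1900, 1L)
          pv[[length(pv) + 1L]] <- variant_row(
            pid, "TET2", random_genomic_id(prefix = 105),
            paste0("p.", sample(aa_letters, 1L), res,
                   sample(c("*", "fs"), 1L)))
        }
        n_tet2 <- 2L
        pv[[length(pv) + 1L]] <- variant_row(
          pid, "DNMT3A", random_genomic_id(prefix = 254),
          paste0("p.R", sample(600:900, 1L), "H"))
        n_other <- 1L
      } else {
        pv[[length(pv) + 1L]] <- variant_row(
          pid, "IDH1", "g.209113113 G>A", "p.R132C")
        n_other <- 1L
      }
    }
    if (tet2) {
      res <- sample(100:1900, 1L)
      pv[[length(pv) + 1L]] <- variant_row(
        pid, "TET2", random_genomic_id(prefix = 105),
        paste0("p.", sample(aa_letters, 1L), res, "fs"))
      n_tet2 <- n_tet2 + 1L
    }
    if (nras) {
      hs <- sample(c("p.G12D", "p.G13D", "p.Q61K"), 1L)
      pv[[length(pv) + 1L]] <- variant_row(
        pid, "NRAS", random_genomic_id(prefix = 115), hs)
    }
    if (stats::runif(1) < cfg$fail_variant_rate) {
      pv[[length(pv) + 1L]] <- failing_variant(pid)
    }

    fish <- NA_character_
    if (cnl && stats::runif(1) < cfg$fish_given_cnl) {
      fish <- if (mechanism == "monosomy17") "1R1G" else "1R2G"
    } else if (!cnl && stats::runif(1) < cfg$fish_given_normal) {
      fish <- "2R2G"
    }

    patients[[i]] <- tibble::tibble(
      patient_id = pid, diagnosis = diagnosis, karyotype = karyotype,
      fish_pattern = fish
    )
    ledger[[i]] <- tibble::tibble(
      patient_id = pid,
      lineage = if (lymphoid) "lymphoid" else "myeloid",
      complexity_class = classify_complexity(n_events),
      n_events = n_events,
      n_rings = n_rings,
      ring_origins = paste(sort_ring_origins(origins), collapse = ","),
      has_marker = marker,
      has_dmin = dmin,
      n_tp53 = n_tp53,
      n_tet2 = n_tet2,
      n_nras = as.integer(nras),
      cnl_status = if (cnl) "loss" else "no_evidence",
      cnl_mechanism = mechanism
    )
    if (length(pv)) variants[[length(variants) + 1L]] <- do.call(rbind, pv)
  }

  empty_patients <- tibble::tibble(
    patient_id = character(), diagnosis = character(),
    karyotype = character(), fish_pattern = character())
  empty_variants <- variant_row("x", "x", "x", "x")[0, ]
  structure(
    list(
      patients = if (length(patients)) do.call(rbind, patients)
                 else empty_patients,
      variants = if (length(variants)) do.call(rbind, variants)
                 else empty_variants,
      ledger = if (length(ledger)) do.call(rbind, ledger)
               else tibble::tibble(),
      config = cfg
    ),
    class = "rc_cohort"
  )
}

#' @export
print.rc_cohort <- function(x, ...) {
  cat("<rc_cohort> ", nrow(x$patients), " patients, ",
      nrow(x$variants), " variants\n", sep = "")
  invisible(x)
}
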
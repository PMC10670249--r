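# --- truth-ledger recovery testing -------------------------------------

#' Check pipeline recovery of the generator's truth ledger
#'
#' Runs the full pipeline (karyotype parsing, feature extraction,
#' variant filtering, CNL inference) on a generated cohort and compares
#' the recovered values against the truth ledger, feature by feature.
#' Generation is noiseless, so every discrete feature is expected to
#' agree exactly; any mismatch is reported together with the offending
#' karyotype string.
#'
#' @param cohort An `rc_cohort` from [generate_cohort()].
#' @param ledger Truth ledger (defaults to `cohort$ledger`; pass a
#'   modified copy to verify the report's sensitivity).
#' @return A tibble with one row per feature (`feature`, `n_checked`,
#'   `n_agree`, `agreement`), with a `mismatches` attribute listing
#'   `patient_id`, `feature`, `expected`, `observed`, `karyotype`.
#' @export
ledger_recovery_report <- function(cohort, ledger = cohort$ledger) {
  stopifnot(inherits(cohort, "rc_cohort"))
  pts <- cohort$patients
  stopifnot(nrow(pts) == nrow(ledger),
            all(pts$patient_id == ledger$patient_id))
  kept <- filter_candidate_somatic(cohort$variants)
  kept_count <- function(pid, gene) {
    length(unique(kept$genomic_change[kept$patient_id == pid &
                                        kept$gene == gene]))
  }

  features <- c("complexity_class", "n_events", "n_rings", "ring_origins",
                "has_marker", "has_dmin", "cnl_status", "cnl_mechanism",
                "n_tp53_kept", "n_tet2_kept", "n_nras_kept")
  agree <- stats::setNames(integer(length(features)), features)
  mism <- list()
  n <- nrow(pts)
  for (i in seq_len(n)) {
    k <- parse_karyotype(pts$karyotype[i])
    f <- patient_features(k)
    cnl <- infer_cnl_from_karyotype(k)
    observed <- list(
      complexity_class = f$complexity_class,
      n_events = f$n_independent_abnormalities,
      n_rings = f$n_rings,
      ring_origins = paste(f$ring_origins, collapse = ","),
      has_marker = f$has_marker,
      has_dmin = f$has_dmin,
      cnl_status = cnl$status,
      cnl_mechanism = cnl$mechanism,
      n_tp53_kept = kept_count(pts$patient_id[i], "TP53"),
      n_tet2_kept = kept_count(pts$patient_id[i], "TET2"),
      n_nras_kept = kept_count(pts$patient_id[i], "NRAS")
    )
    expected <- list(
      complexity_class = ledger$complexity_class[i],
      n_events = ledger$n_events[i],
      n_rings = ledger$n_rings[i],
      ring_origins = ledger$ring_origins[i],
      has_marker = ledger$has_marker[i],
      has_dmin = ledger$has_dmin[i],
      cnl_status = ledger$cnl_status[i],
      cnl_mechanism = ledger$cnl_mechanism[i],
      n_tp53_kept = ledger$n_tp53[i],
      n_tet2_kept = ledger$n_tet2[i],
      n_nras_kept = ledger$n_nras[i]
    )
    for (ft in features) {
      same <- isTRUE(all.equal(unname(observed[[ft]]),
                               unname(expected[[ft]]),
                               check.attributes = FALSE)) ||
        identical(as.character(observed[[ft]]), as.character(expected[[ft]]))
      if (same) {
        agree[ft] <- agree[ft] + 1L
      } else {
        mism[[length(mism) + 1L]] <- tibble::tibble(
          patient_id = pts$patient_id[i], feature = ft,
          expected = as.character(expected[[ft]]),
          observed = as.character(observed[[ft]]),
          karyotype = pts$karyotype[i]
        )
      }
    }
  }
  out <- tibble::tibble(
    feature = features,
    n_checked = n,
    n_agree = as.integer(agree),
    agreement = if (n) as.integer(agree) / n else NA_real_
  )
  attr(out, "mismatches") <- if (length(mism)) do.call(rbind, mism) else
    tibble::tibble(patient_id = character(), feature = character(),
                   expected = character(), observed = character(),
                   karyotype = character())
  out
}
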
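# --- independent abnormality accounting --------------------------------

# Distinct abnormality events over the union of a karyotype's abnormal
# clones. Each listed ISCN token is one event; within a clone identical
# tokens (or xN multipliers) accumulate multiplicity, while the same
# event recurring across clones (including idem-inherited copies) is
# counted once, via a per-signature maximum.
abnormality_units <- function(k) {
  stopifnot(inherits(k, "iscn_karyotype"))
  all_sigs <- character()
  all_mult <- integer()
  all_rep <- list()
  for (cl in k$clones) {
    sigs <- character()
    mult <- integer()
    rep_ab <- list()
    for (ab in cl$abnormalities) {
      sig <- sub("[x×]\\d+$", "", ab$raw_token)
      i <- match(sig, sigs)
      if (is.na(i)) {
        sigs <- c(sigs, sig)
        mult <- c(mult, ab$copies)
        rep_ab[[length(rep_ab) + 1L]] <- ab
      } else {
        mult[i] <- mult[i] + ab$copies
      }
    }
    for (j in seq_along(sigs)) {
      i <- match(sigs[j], all_sigs)
      if (is.na(i)) {
        all_sigs <- c(all_sigs, sigs[j])
        all_mult <- c(all_mult, mult[j])
        all_rep[[length(all_rep) + 1L]] <- rep_ab[[j]]
      } else {
        all_mult[i] <- max(all_mult[i], mult[j])
      }
    }
  }
  list(signature = all_sigs, multiplicity = all_mult,
       abnormality = all_rep)
}

#' Count independent cytogenetic abnormalities
#'
#' Counts the distinct abnormality events of a karyotype across all of
#' its abnormal clones. Each listed ISCN token counts once (a
#' translocation or derivative chromosome is a single event regardless
#' of how many chromosomes it involves); identical events repeated
#' across clones are counted once; repeated tokens within one clone
#' (e.g. `+r,+r`) retain their multiplicity. Uncertain (`?`) events are
#' included. A karyotype is conventionally called complex when this
#' count exceeds three.
#'
#' @param k An `iscn_karyotype`.
#' @return Non-negative integer.
#' @examples
#' count_independent_abnormalities(parse_karyotype("46,XY,-7,+r"))
#' @export
count_independent_abnormalities <- function(k) {
  sum(abnormality_units(k)$multiplicity)
}

#' Classify karyotype complexity
#'
#' More than three independent abnormalities is a complex karyotype;
#' exactly three is kept as its own class; two or fewer is simple.
#'
#' @param n Integer vector of independent-abnormality counts.
#' @return Character vector in `{"simple", "exactly_three", "complex"}`.
#' @export
classify_complexity <- function(n) {
  stopifnot(all(n >= 0))
  ifelse(n > 3, "complex", ifelse(n == 3, "exactly_three", "simple"))
}

# --- ring and marker inventory -----------------------------------------

sort_ring_origins <- function(origins) {
  if (!length(origins)) return(character())
  rank <- match(origins, c(as.character(1:22), "X", "Y", "unknown"))
  origins[order(rank)]
}

#' Ring chromosome inventory of a karyotype
#'
#' Counts ring chromosomes over the clone union: every chromosome-derived
#' ring `r(N)(..)` contributes its chromosome of origin, every
#' supernumerary `+r` contributes `"unknown"`, and multiple rings are
#' counted with multiplicity (within and across clones).
#'
#' @param k An `iscn_karyotype`.
#' @return List with `n_rings` (integer) and `origins` (character vector,
#'   chromosome labels sorted ahead of `"unknown"`).
#' @examples
#' ring_inventory(parse_karyotype("46,XX,r(18)(p11.3q23)[2]/46,XX[15]"))
#' @export
ring_inventory <- function(k) {
  units <- abnormality_units(k)
  origins <- character()
  for (j in seq_along(units$signature)) {
    ab <- units$abnormality[[j]]
    n <- units$multiplicity[j]
    if (ab$kind == "ring_unknown") {
      origins <- c(origins, rep("unknown", n))
    } else if (ab$kind == "ring_derived") {
      origins <- c(origins, rep(ab$chromosomes[[1]], n))
    }
  }
  origins <- sort_ring_origins(origins)
  list(n_rings = length(origins), origins = origins)
}

#' Chromosomes with structural involvement
#'
#' The set of chromosomes named in at least one structural abnormality
#' (add/del/dup/der/dic/idic/i/ins/inv/t or a chromosome-derived ring).
#' Whole-chromosome gains and losses, markers, `+r` of unknown origin,
#' and double minutes do not contribute.
#'
#' @param k An `iscn_karyotype`.
#' @return Character vector of chromosome labels, in karyotype order
#'   (1-22, X, Y).
#' @export
structural_involvement <- function(k) {
  units <- abnormality_units(k)
  chroms <- character()
  for (ab in units$abnormality) {
    if (ab$kind %in% structural_kinds) chroms <- c(chroms, ab$chromosomes)
  }
  chroms <- unique(chroms)
  chroms[order(match(chroms, chromosome_labels))]
}

abnormality_arm <- function(ab) {
  if (length(ab$breakpoints)) return(ab$breakpoints[[1L]]$arm)
  if (length(ab$arm_hints)) {
    arm <- regmatches(ab$arm_hints[[1L]],
                      regexpr("[pq]$", ab$arm_hints[[1L]]))
    if (length(arm)) return(arm)
  }
  "unknown"
}

#' Arm-level additions and deletions
#'
#' One record per `add`/`del` event, located on the arm of its first
#' breakpoint (`"unknown"` when the event carries no usable breakpoint,
#' e.g. `add(17)(p?)` still resolves to the p arm via its arm token,
#' whereas `add(3)` does not).
#'
#' @param k An `iscn_karyotype`.
#' @return A tibble with columns `chromosome`, `arm`, `kind`.
#' @export
arm_level_add_del <- function(k) {
  units <- abnormality_units(k)
  rows <- list()
  for (j in seq_along(units$signature)) {
    ab <- units$abnormality[[j]]
    if (!ab$kind %in% c("add", "del")) next
    chr <- if (length(ab$chromosomes)) ab$chromosomes[[1L]] else NA_character_
    rows[[length(rows) + 1L]] <- tibble::tibble(
      chromosome = rep(chr, units$multiplicity[j]),
      arm = abnormality_arm(ab),
      kind = ab$kind
    )
  }
  if (!length(rows)) {
    return(tibble::tibble(chromosome = character(), arm = character(),
                          kind = character()))
  }
  do.call(rbind, rows)
}

# --- per-patient features ----------------------------------------------

#' Per-patient cytogenetic features
#'
#' Derives the feature set used in the cohort summaries from one parsed
#' karyotype: independent-abnormality count and complexity class, ring
#' count and origins, marker and double-minute flags, chromosomes with
#' structural involvement, arm-level add/del events, and whole-chromosome
#' losses/gains.
#'
#' @param k An `iscn_karyotype`.
#' @return A list of class `patient_features`.
#' @export
patient_features <- function(k) {
  units <- abnormality_units(k)
  kinds <- vapply(units$abnormality, function(ab) ab$kind, character(1))
  n_abn <- sum(units$multiplicity)
  rings <- ring_inventory(k)
  whole_of <- function(kind) {
    out <- character()
    for (j in seq_along(kinds)) {
      if (kinds[j] == kind) {
        out <- c(out, units$abnormality[[j]]$chromosomes)
      }
    }
    unique(out)
  }
  structure(
    list(
      n_independent_abnormalities = n_abn,
      complexity_class = classify_complexity(n_abn),
      n_rings = rings$n_rings,
      ring_origins = rings$origins,
      has_marker = any(kinds == "mar"),
      marker_copies = sum(units$multiplicity[kinds == "mar"]),
      has_dmin = any(kinds == "dmin"),
      structural_chromosomes = structural_involvement(k),
      arm_events = arm_level_add_del(k),
      whole_losses = whole_of("whole_loss"),
      whole_gains = whole_of("whole_gain")
    ),
    class = "patient_features"
  )
}

has_loss_or_arm_del <- function(feat, chromosome, arm) {
  if (chromosome %in% feat$whole_losses) return(TRUE)
  ae <- feat$arm_events
  any(ae$kind == "del" & ae$chromosome == chromosome & ae$arm == arm,
      na.rm = TRUE)
}

#' Cohort feature table
#'
#' Applies [patient_features()] to a set of karyotypes and flattens the
#' result into one row per patient, including the composite
#' loss-or-deletion flags used in the frequency tables (`-7/7q-`,
#' `-5/5q-`, `-17/17p-`).
#'
#' @param karyotypes A list of `iscn_karyotype` objects, or a character
#'   vector of ISCN strings (parsed on the fly).
#' @param patient_ids Optional patient identifiers (default `p1`, `p2`, ...).
#' @return A tibble with one row per patient.
#' @export
cohort_features <- function(karyotypes, patient_ids = NULL) {
  if (is.character(karyotypes)) karyotypes <- lapply(karyotypes, parse_karyotype)
  n <- length(karyotypes)
  if (is.null(patient_ids)) patient_ids <- sprintf("p%d", seq_len(n))
  stopifnot(length(patient_ids) == n)
  if (n == 0L) {
    return(tibble::tibble(
      patient_id = character(), n_abnormalities = integer(),
      complexity_class = character(), n_rings = integer(),
      ring_origins = character(), multiple_rc = logical(),
      has_marker = logical(), has_dmin = logical(),
      loss7_or_del7q = logical(), loss5_or_del5q = logical(),
      loss17_or_del17p = logical(), chr11_structural = logical(),
      chr18_structural = logical()))
  }
  rows <- lapply(seq_len(n), function(i) {
    f <- patient_features(karyotypes[[i]])
    tibble::tibble(
      patient_id = patient_ids[[i]],
      n_abnormalities = f$n_independent_abnormalities,
      complexity_class = f$complexity_class,
      n_rings = f$n_rings,
      ring_origins = paste(f$ring_origins, collapse = ","),
      multiple_rc = f$n_rings >= 2L,
      has_marker = f$has_marker,
      has_dmin = f$has_dmin,
      loss7_or_del7q = has_loss_or_arm_del(f, "7", "q"),
      loss5_or_del5q = has_loss_or_arm_del(f, "5", "q"),
      loss17_or_del17p = has_loss_or_arm_del(f, "17", "p"),
      chr11_structural = "11" %in% f$structural_chromosomes,
      chr18_structural = "18" %in% f$structural_chromosomes
    )
  })
  do.call(rbind, rows)
}

#' Cohort frequency summary
#'
#' Emits the frequency tables characterizing a ring-chromosome cohort:
#' composite CNV statistics (`-7/7q-`, `-5/5q-`, `-17/17p-`), marker and
#' double-minute prevalence, chromosome 11/18 structural involvement,
#' multiple-ring patients, a ring-origin histogram, and the complexity
#' distribution. Every statistic records its count and denominator
#' explicitly; `denominator_rule = "complex"` computes the CNV-style
#' statistics over the complex-karyotype subset (the convention used for
#' this cohort's published percentages), `"all"` over every patient. The
#' complexity distribution and ring histogram are always over all
#' patients.
#'
#' @param features A tibble from [cohort_features()], or input accepted
#'   by it.
#' @param denominator_rule `"complex"` or `"all"`.
#' @return A list of class `cohort_summary` with tibbles `stats`,
#'   `complexity`, and `ring_origins`.
#' @export
summarize_cohort <- function(features, denominator_rule = c("complex", "all")) {
  denominator_rule <- match.arg(denominator_rule)
  if (!is.data.frame(features)) features <- cohort_features(features)
  if (nrow(features) == 0L) {
    stop("cannot summarize an empty cohort", call. = FALSE)
  }
  subset <- if (denominator_rule == "complex") {
    features[features$complexity_class == "complex", , drop = FALSE]
  } else {
    features
  }
  denom <- nrow(subset)
  stat_row <- function(name, flag_col) {
    count <- if (denom) sum(subset[[flag_col]]) else 0L
    tibble::tibble(
      statistic = name, count = as.integer(count),
      denominator = as.integer(denom),
      percent = if (denom) 100 * count / denom else NA_real_
    )
  }
  stats <- do.call(rbind, list(
    stat_row("loss7_or_del7q", "loss7_or_del7q"),
    stat_row("loss5_or_del5q", "loss5_or_del5q"),
    stat_row("loss17_or_del17p", "loss17_or_del17p"),
    stat_row("marker", "has_marker"),
    stat_row("dmin", "has_dmin"),
    stat_row("chr11_structural", "chr11_structural"),
    stat_row("chr18_structural", "chr18_structural"),
    stat_row("multiple_rc", "multiple_rc")
  ))

  n_all <- nrow(features)
  cx <- table(factor(features$complexity_class,
                     levels = c("simple", "exactly_three", "complex")))
  complexity <- tibble::tibble(
    complexity_class = names(cx),
    count = as.integer(cx),
    denominator = n_all,
    percent = 100 * as.integer(cx) / n_all
  )

  origins <- unlist(strsplit(features$ring_origins[nzchar(features$ring_origins)], ","))
  ro <- if (length(origins)) {
    tab <- table(origins)
    ord <- order(match(names(tab), c(as.character(1:22), "X", "Y", "unknown")))
    tibble::tibble(origin = names(tab)[ord], count = as.integer(tab)[ord])
  } else {
    tibble::tibble(origin = character(), count = integer())
  }

  structure(
    list(stats = stats, complexity = complexity, ring_origins = ro,
         denominator_rule = denominator_rule, n_patients = n_all),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary> ", x$n_patients, " patients (denominator rule: ",
      x$denominator_rule, ")\n", sep = "")
  print(x$stats)
  print(x$complexity)
  print(x$ring_origins)
  invisible(x)
}
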
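# --- candidate-somatic variant filtering -------------------------------

variant_qc_fields <- c("vaf", "alt_reads_fwd", "alt_reads_rev",
                       "mean_qscore", "known_cancer_flag", "damaging_flag")

#' Annotate variants with candidate-somatic filter decisions
#'
#' Applies the candidate-somatic criteria, conjunctively, to a variant
#' table: variant allele frequency >= 1%, at least two alternate reads
#' on each strand, alternate-allele mean base Qscore >= 11, a
#' COSMIC/ClinVar known-cancer annotation, and an in-silico damaging
#' classification. Every rejected variant carries machine-readable
#' reason codes (`vaf`, `strand`, `qscore`, `not_known_cancer`,
#' `not_damaging`, or `missing_<field>` when a QC field is absent —
#' a variant with a missing QC field is rejected).
#'
#' @param variants A data.frame/tibble with columns `gene`,
#'   `genomic_change`, `protein_change`, `vaf` (percent, 0-100),
#'   `alt_reads_fwd`, `alt_reads_rev`, `mean_qscore`,
#'   `known_cancer_flag`, `damaging_flag`.
#' @return The input as a tibble with appended logical `kept` and
#'   character `reject_reasons` (empty string when kept).
#' @export
variant_filter_report <- function(variants) {
  variants <- tibble::as_tibble(variants)
  missing_cols <- setdiff(variant_qc_fields, names(variants))
  if (length(missing_cols)) {
    stop("variant table lacks QC columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n <- nrow(variants)
  reasons <- vector("list", n)
  for (i in seq_len(n)) {
    r <- character()
    for (f in variant_qc_fields) {
      if (is.na(variants[[f]][i])) r <- c(r, paste0("missing_", f))
    }
    chk <- function(field, ok, code) {
      v <- variants[[field]][i]
      if (!is.na(v) && !ok(v)) code else character()
    }
    r <- c(
      r,
      chk("vaf", function(v) v >= 1, "vaf"),
      if (!is.na(variants$alt_reads_fwd[i]) &&
          !is.na(variants$alt_reads_rev[i]) &&
          (variants$alt_reads_fwd[i] < 2 || variants$alt_reads_rev[i] < 2))
        "strand",
      chk("mean_qscore", function(v) v >= 11, "qscore"),
      chk("known_cancer_flag", isTRUE, "not_known_cancer"),
      chk("damaging_flag", isTRUE, "not_damaging")
    )
    reasons[[i]] <- r
  }
  variants$kept <- lengths(reasons) == 0L
  variants$reject_reasons <- vapply(reasons, paste, character(1),
                                    collapse = ";")
  variants
}

#' Filter variants to candidate somatic mutations
#'
#' Keeps only the variants passing all candidate-somatic criteria (see
#' [variant_filter_report()] for the criteria and per-variant rejection
#' reasons). The filter is idempotent.
#'
#' @inheritParams variant_filter_report
#' @return The kept rows, original columns only.
#' @export
filter_candidate_somatic <- function(variants) {
  report <- variant_filter_report(variants)
  report[report$kept,
         setdiff(names(report), c("kept", "reject_reasons")),
         drop = FALSE]
}

# --- mutation-type classification --------------------------------------

mutation_types <- c("missense", "nonsense", "frameshift",
                    "splice_or_intron", "inframe_del", "other")

classify_one_mutation <- function(p) {
  if (is.na(p) || !nzchar(p)) return(NA_character_)
  x <- sub("^p\\.", "", p)
  x <- gsub("[()]", "", x)
  if (grepl("splice|intron", x, ignore.case = TRUE)) return("splice_or_intron")
  if (grepl("fs", x)) return("frameshift")
  if (grepl("(\\*|Ter)\\d*$", x)) return("nonsense")
  if (grepl("del$|delins", x)) return("inframe_del")
  if (grepl("^[A-Z]\\d+[A-Z]$", x) ||
      grepl("^[A-Z][a-z]{2}\\d+[A-Z][a-z]{2}$", x)) {
    return("missense")
  }
  NA_character_
}

#' Classify mutation type from protein-change notation
#'
#' Maps HGVS-style `p.` strings to a mutation-type label: `fs` tokens
#' are frameshifts, terminal `*`/`Ter` nonsense, single-residue
#' substitutions missense, `del` without `fs` in-frame deletions, and
#' splice/intron annotations `splice_or_intron`. Variants without a
#' protein change are classified from the optional `annotation`
#' argument; anything unparseable returns `"other"` with a warning.
#'
#' @param protein_change Character vector of `p.` strings (NA/"" when
#'   the variant has no protein-level consequence).
#' @param annotation Optional character vector of consequence
#'   annotations (e.g. `"intron inclusion"`), recycled to length.
#' @return Character vector over
#'   `{missense, nonsense, frameshift, splice_or_intron, inframe_del, other}`.
#' @examples
#' classify_mutation_type(c("p.R248W", "p.Q192*", "p.N131fs"))
#' @export
classify_mutation_type <- function(protein_change, annotation = NULL) {
  n <- length(protein_change)
  if (is.null(annotation)) annotation <- rep(NA_character_, n)
  annotation <- rep_len(annotation, n)
  out <- character(n)
  for (i in seq_len(n)) {
    cls <- classify_one_mutation(protein_change[i])
    if (is.na(cls) && !is.na(annotation[i]) &&
        grepl("splice|intron", annotation[i], ignore.case = TRUE)) {
      cls <- "splice_or_intron"
    }
    if (is.na(cls)) {
      warning("unclassifiable mutation notation: '",
              protein_change[i], "'", call. = FALSE)
      cls <- "other"
    }
    out[i] <- cls
  }
  out
}

# --- TP53 protein domains ----------------------------------------------

#' TP53 protein domain boundary table
#'
#' Residue ranges of the canonical TP53 (393 aa) functional domains used
#' to localize mutations: transactivation 1-61, proline-rich 62-93,
#' DNA-binding 94-292, nuclear localization signal 293-322,
#' tetramerization 323-355, C-terminal regulatory 356-393. The table is
#' a plain tibble and can be overridden in [tp53_domain_of()].
#'
#' @return A tibble with columns `domain`, `start`, `end`.
#' @export
tp53_domains <- function() {
  tibble::tibble(
    domain = c("transactivation", "proline_rich", "dna_binding",
               "nls", "tetramerization", "regulatory"),
    start = c(1L, 62L, 94L, 293L, 323L, 356L),
    end = c(61L, 93L, 292L, 322L, 355L, 393L)
  )
}

#' Locate a TP53 residue in its protein domain
#'
#' @param residue Integer vector of residue positions (1-393).
#' @param domains Domain boundary table, by default [tp53_domains()].
#' @return Character vector of domain labels (`"other"` for a residue
#'   falling in no configured domain).
#' @examples
#' tp53_domain_of(248)
#' @export
tp53_domain_of <- function(residue, domains = tp53_domains()) {
  residue <- as.integer(residue)
  lo <- min(domains$start)
  hi <- max(domains$end)
  if (any(is.na(residue)) || any(residue < lo | residue > hi)) {
    stop("TP53 residue out of range [", lo, ", ", hi, "]", call. = FALSE)
  }
  vapply(residue, function(r) {
    hit <- which(domains$start <= r & r <= domains$end)
    if (length(hit)) domains$domain[hit[[1]]] else "other"
  }, character(1))
}

# Residue number from a p. string, NA when absent.
protein_residue <- function(protein_change) {
  m <- regmatches(protein_change,
                  regexec("^p\\.?[A-Za-z]{1,3}(\\d+)", protein_change))
  vapply(m, function(g) {
    if (length(g)) as.integer(g[[2]]) else NA_integer_
  }, integer(1))
}

# --- stratification and tallies ----------------------------------------

#' Stratify patients by mutated gene
#'
#' Assigns each NGS-profiled patient to the group of every gene in which
#' it carries at least one kept variant (groups overlap; a patient with
#' several variants in one gene appears once in that group), plus a
#' `no_TP53` group of profiled patients with no kept TP53 variant.
#'
#' @param variants Filtered variant tibble with `patient_id` and `gene`
#'   columns (see [filter_candidate_somatic()]).
#' @param genes Genes to stratify by, e.g. `c("TP53", "TET2", "NRAS")`.
#' @param profiled_ids Patient ids with NGS data (defaults to the
#'   patients present in `variants`; pass the full profiled set so that
#'   variant-free patients land in `no_TP53`).
#' @return Named list of patient-id vectors, one per gene plus `no_TP53`.
#' @export
stratify_patients <- function(variants, genes,
                              profiled_ids = unique(variants$patient_id)) {
  groups <- lapply(genes, function(g) {
    sort(unique(variants$patient_id[variants$gene == g]))
  })
  names(groups) <- genes
  tp53 <- unique(variants$patient_id[variants$gene == "TP53"])
  groups$no_TP53 <- sort(setdiff(profiled_ids, tp53))
  groups
}

#' Tally mutations of one gene across a cohort
#'
#' Counts total and unique mutations (uniqueness keyed on the
#' `genomic_change` string), the mutation-type spectrum, and a
#' per-patient multiplicity histogram of distinct mutations.
#'
#' @param variants Filtered variant tibble.
#' @param gene Gene symbol to tally (default `"TP53"`).
#' @return List with `n_mutations`, `n_unique`, `n_patients`,
#'   `per_type` (tibble `type`/`count`), and `multiplicity` (tibble
#'   `n_distinct_mutations`/`n_patients`).
#' @export
mutation_tally <- function(variants, gene = "TP53") {
  v <- variants[variants$gene == gene, , drop = FALSE]
  if (nrow(v) == 0L) {
    return(list(
      n_mutations = 0L, n_unique = 0L, n_patients = 0L,
      per_type = tibble::tibble(type = character(), count = integer()),
      multiplicity = tibble::tibble(n_distinct_mutations = integer(),
                                    n_patients = integer())
    ))
  }
  types <- classify_mutation_type(
    v$protein_change,
    if ("annotation" %in% names(v)) v$annotation else NULL)
  tt <- table(factor(types, levels = mutation_types))
  per_patient <- tapply(v$genomic_change, v$patient_id,
                        function(x) length(unique(x)))
  mh <- table(per_patient)
  list(
    n_mutations = nrow(v),
    n_unique = length(unique(v$genomic_change)),
    n_patients = length(unique(v$patient_id)),
    per_type = tibble::tibble(type = names(tt), count = as.integer(tt)),
    multiplicity = tibble::tibble(
      n_distinct_mutations = as.integer(names(mh)),
      n_patients = as.integer(mh)
    )
  )
}

# --- oncoplot matrix ----------------------------------------------------

#' Oncoplot (waterfall) mutation matrix
#'
#' Builds the patient-by-gene matrix behind an oncoplot: each cell holds
#' the ordered, `;`-separated mutation-type labels of that patient's
#' kept variants in that gene (multi-hit preserved), columns are genes
#' in descending order of mutated-patient count (alphabetical on ties),
#' and rows follow the usual waterfall order (patients sorted by
#' mutation presence across the ordered genes). The result is
#' deterministic under permutation of the input rows.
#'
#' @param variants Filtered variant tibble (`patient_id`, `gene`,
#'   `protein_change`).
#' @param patients Patient ids forming the rows (default: patients in
#'   `variants`).
#' @param genes Genes forming the columns (default: genes in `variants`).
#' @return Character matrix with patient rownames and gene colnames;
#'   empty string marks wild type.
#' @export
oncoplot_matrix <- function(variants, patients = NULL, genes = NULL) {
  if (is.null(patients)) patients <- sort(unique(variants$patient_id))
  if (is.null(genes)) genes <- sort(unique(variants$gene))
  v <- variants[variants$patient_id %in% patients &
                  variants$gene %in% genes, , drop = FALSE]
  if (nrow(v)) {
    v <- v[order(v$patient_id, v$gene, v$genomic_change), , drop = FALSE]
    v$type <- classify_mutation_type(
      v$protein_change,
      if ("annotation" %in% names(v)) v$annotation else NULL)
  }
  mat <- matrix("", nrow = length(patients), ncol = length(genes),
                dimnames = list(patients, genes))
  for (i in seq_len(nrow(v))) {
    cell <- mat[v$patient_id[i], v$gene[i]]
    mat[v$patient_id[i], v$gene[i]] <-
      if (nzchar(cell)) paste(cell, v$type[i], sep = ";") else v$type[i]
  }
  mutated <- mat != ""
  n_mut <- colSums(mutated)
  col_order <- order(-n_mut, colnames(mat))
  mat <- mat[, col_order, drop = FALSE]
  mutated <- mutated[, col_order, drop = FALSE]
  row_keys <- c(
    lapply(seq_len(ncol(mat)), function(j) -as.integer(mutated[, j])),
    list(rownames(mat))
  )
  mat[do.call(order, row_keys), , drop = FALSE]
}
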
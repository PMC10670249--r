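# The four published non-complex ring-chromosome karyotypes, verbatim
# (Unicode minus and the line-break space inside the band list included,
# exactly as printed).
noncomplex_karyotypes <- function() {
  c(
    "46,XY,−7,+r",
    "46,XY,−18,+r",
    "48,XX,+4,+r",
    "46,XX,r(18)(p11.3q23)[2]/46,XX,t(7;17) (q36;q21)[2]/46,XX[15]"
  )
}

# Eight-variant table exercising each candidate-somatic criterion
# independently: rows 1 and 8 pass (row 8 exactly at every threshold),
# rows 2-7 each violate a single criterion.
eight_variant_table <- function() {
  base <- tibble::tibble(
    patient_id = sprintf("v%02d", 1:8),
    gene = "TP53",
    genomic_change = sprintf("g.75771%02d C>T", 1:8),
    protein_change = "p.R248W",
    vaf = 40, alt_reads_fwd = 50, alt_reads_rev = 50,
    mean_qscore = 30, known_cancer_flag = TRUE, damaging_flag = TRUE
  )
  base$vaf[2] <- 0.5               # below the 1% VAF floor
  base$alt_reads_fwd[3] <- 1       # <2 forward alternate reads
  base$alt_reads_rev[4] <- 0       # <2 reverse alternate reads
  base$mean_qscore[5] <- 10.5      # below Qscore 11
  base$known_cancer_flag[6] <- FALSE
  base$damaging_flag[7] <- FALSE
  base$vaf[8] <- 1                 # boundary values all pass
  base$alt_reads_fwd[8] <- 2
  base$alt_reads_rev[8] <- 2
  base$mean_qscore[8] <- 11
  base
}

# Abnormality token set for the brute-force counting oracle.
oracle_tokens <- function() {
  c("-7", "+8", "del(5)(q13q33)", "t(7;17)(q36;q21)",
    "+r", "+mar", "add(17)(p11.2)", "i(17)(q10)")
}

# Independent counting oracle: distinct events over clones, counted from
# the raw token lists (per-token maximum multiplicity across clones).
oracle_count <- function(clone_token_lists) {
  tab <- list()
  for (toks in clone_token_lists) {
    cnt <- table(toks)
    for (tk in names(cnt)) {
      tab[[tk]] <- max(tab[[tk]] %||% 0L, cnt[[tk]])
    }
  }
  sum(unlist(tab))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# All multisets of the given size from a token vector.
token_multisets <- function(tokens, size) {
  idx <- utils::combn(length(tokens) + size - 1L, size, simplify = FALSE)
  lapply(idx, function(comb) tokens[comb - seq_len(size) + 1L])
}

build_karyotype_string <- function(clone_token_lists, sex = "XY") {
  paste(vapply(clone_token_lists, function(toks) {
    paste0("46,", sex, ",", paste(toks, collapse = ","))
  }, character(1)), collapse = "/")
}
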
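# --- TP53 CNL inference from chromosome-17 abnormalities ---------------

cnl_statuses <- c("loss", "ambiguous_diminished", "normal", "no_evidence")
cnl_mechanisms <- c("monosomy17", "add17p", "der17", "dic17", "del17p",
                    "i17q", "idic17", "none")
# precedence when several loss mechanisms coexist in one karyotype
cnl_mechanism_precedence <- c("monosomy17", "add17p", "der17", "dic17",
                              "del17p", "i17q", "idic17")

new_cnl_call <- function(status, mechanism, evidence) {
  structure(list(status = status, mechanism = mechanism,
                 evidence = evidence),
            class = "cnl_call")
}

# chr-17 breakpoints of one abnormality on a given arm
bp17 <- function(ab, arm) {
  Filter(function(b) b$chromosome == "17" && b$arm == arm, ab$breakpoints)
}

has_arm_hint17 <- function(ab, arm) paste0("17", arm) %in% ab$arm_hints

# Assess one abnormality for TP53 copy-number loss relative to `locus`.
# Returns status "loss", "ambiguous" or "none", plus the mechanism label.
assess_tp53_abn <- function(ab, locus) {
  none <- list(status = "none", mechanism = "none")
  if (!"17" %in% ab$chromosomes) return(none)
  p_bps <- bp17(ab, "p")
  q_bps <- bp17(ab, "q")
  covers_locus <- function(bps) {
    d <- vapply(bps, function(b) band_centromere_distance(b$band),
                numeric(1))
    dl <- band_centromere_distance(locus$band)
    if (length(d) == 1L) d[1] <= dl else min(d) <= dl && dl <= max(d)
  }
  switch(
    ab$kind,
    whole_loss = list(status = "loss", mechanism = "monosomy17"),
    i = {
      # i(17)(q10) retains only the q arm; i(17)(p10) would retain p
      if (length(p_bps) || has_arm_hint17(ab, "p")) none
      else list(status = "loss", mechanism = "i17q")
    },
    idic = {
      if (length(q_bps) && !length(p_bps)) none
      else list(status = "loss", mechanism = "idic17")
    },
    del = {
      if (length(p_bps)) {
        if (covers_locus(p_bps)) list(status = "loss", mechanism = "del17p")
        else none
      } else if (has_arm_hint17(ab, "p")) {
        list(status = "ambiguous", mechanism = "del17p")
      } else none
    },
    add = {
      if (length(p_bps)) {
        if (covers_locus(p_bps[1])) list(status = "loss", mechanism = "add17p")
        else list(status = "ambiguous", mechanism = "add17p")
      } else if (has_arm_hint17(ab, "p")) {
        list(status = "ambiguous", mechanism = "add17p")
      } else if (length(q_bps) || has_arm_hint17(ab, "q")) {
        none
      } else {
        list(status = "ambiguous", mechanism = "add17p")
      }
    },
    der = ,
    dic = {
      mech <- if (ab$kind == "der") "der17" else "dic17"
      if (length(p_bps) && any(vapply(p_bps, band_proximal_or_equal,
                                      logical(1), ref = locus))) {
        list(status = "loss", mechanism = mech)
      } else {
        # material of unknown origin may retain the locus
        list(status = "ambiguous", mechanism = mech)
      }
    },
    none
  )
}

#' Infer TP53 copy-number-loss status from a karyotype
#'
#' Scans the chromosome-17 abnormalities of a karyotype (over the clone
#' union) for events implying loss of the TP53 locus: monosomy 17,
#' 17p deletions spanning the locus, `add(17p)` with a breakpoint
#' proximal to or at the locus (a distal or unspecified breakpoint is
#' called ambiguous, matching how such cases are resolved by FISH),
#' isochromosome 17q / isodicentric 17p, and derivative or dicentric
#' chromosomes with a proximal 17p breakpoint (derivatives without a
#' usable 17p breakpoint are ambiguous). Any loss event makes the
#' overall call a loss; the reported mechanism follows a fixed,
#' single-count precedence (monosomy17 > add17p > der17 > dic17 >
#' del17p > i17q > idic17). The call is invariant to clone order and to
#' abnormalities of other chromosomes.
#'
#' @param k An `iscn_karyotype`.
#' @param locus Target `band_address`, by default [tp53_band()] (17p13.1).
#' @return A `cnl_call`: list with `status`
#'   (`loss`/`ambiguous_diminished`/`normal`/`no_evidence`), `mechanism`,
#'   and `evidence` (the contributing abnormalities).
#' @examples
#' infer_cnl_from_karyotype(parse_karyotype("45,XX,-17"))$mechanism
#' @export
infer_cnl_from_karyotype <- function(k, locus = tp53_band()) {
  units <- abnormality_units(k)
  loss_mechs <- character()
  loss_evidence <- list()
  amb_evidence <- list()
  any17 <- FALSE
  for (ab in units$abnormality) {
    if (!"17" %in% ab$chromosomes) next
    any17 <- TRUE
    res <- assess_tp53_abn(ab, locus)
    if (res$status == "loss") {
      loss_mechs <- c(loss_mechs, res$mechanism)
      loss_evidence[[length(loss_evidence) + 1L]] <- ab
    } else if (res$status == "ambiguous") {
      amb_evidence[[length(amb_evidence) + 1L]] <- ab
    }
  }
  if (length(loss_mechs)) {
    mech <- cnl_mechanism_precedence[
      min(match(loss_mechs, cnl_mechanism_precedence))]
    return(new_cnl_call("loss", mech, loss_evidence))
  }
  if (length(amb_evidence)) {
    return(new_cnl_call("ambiguous_diminished", "none", amb_evidence))
  }
  if (any17) new_cnl_call("normal", "none", list())
  else new_cnl_call("no_evidence", "none", list())
}

#' @export
print.cnl_call <- function(x, ...) {
  cat("<cnl_call> status=", x$status, " mechanism=", x$mechanism,
      " (", length(x$evidence), " evidence event(s))\n", sep = "")
  invisible(x)
}

# --- FISH signal patterns ----------------------------------------------

#' Parse a TP53/centromere-17 FISH signal-pattern string
#'
#' Patterns count fluorescent signals per nucleus: `R` is the TP53 locus
#' probe, `G` the chromosome-17 centromere probe, and `dim` bound to the
#' preceding count marks diminished-intensity target signals (e.g.
#' `"2Rdim1R2G"` = two dim TP53, one full TP53, two centromeres).
#'
#' @param x A pattern string such as `"1R2G"`.
#' @return A `fish_pattern`: list with `n_target_normal`, `n_target_dim`,
#'   `n_centromere`, and the `raw` string.
#' @export
parse_fish_pattern <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, nzchar(x))
  s <- gsub("[[:space:]]", "", x)
  m <- gregexpr("(\\d+)(Rdim|R|G)", s)
  toks <- regmatches(s, m)[[1]]
  if (sum(nchar(toks)) != nchar(s) || !length(toks)) {
    stop("invalid FISH pattern: '", x, "'", call. = FALSE)
  }
  counts <- c(R = 0L, Rdim = 0L, G = 0L)
  for (tk in toks) {
    g <- regmatches(tk, regexec("^(\\d+)(Rdim|R|G)$", tk))[[1]]
    counts[g[[3]]] <- counts[g[[3]]] + as.integer(g[[2]])
  }
  structure(
    list(n_target_normal = unname(counts["R"]),
         n_target_dim = unname(counts["Rdim"]),
         n_centromere = unname(counts["G"]),
         raw = s),
    class = "fish_pattern"
  )
}

#' @export
format.fish_pattern <- function(x, ...) {
  parts <- c(
    if (x$n_target_dim > 0) paste0(x$n_target_dim, "Rdim"),
    if (x$n_target_normal > 0) paste0(x$n_target_normal, "R"),
    if (x$n_centromere > 0) paste0(x$n_centromere, "G")
  )
  paste(parts, collapse = "")
}

#' Interpret a TP53 FISH signal pattern
#'
#' A pure function of the signal counts: any diminished target signal is
#' `abnormal_diminished`; otherwise a single centromere-17 signal is
#' `monosomy17`, fewer full-intensity TP53 signals than centromere
#' signals (with two or more centromeres) is `tp53_loss_disomic17`, and
#' balanced signals (2R2G and higher euploid patterns) are `normal`.
#'
#' @param p A `fish_pattern` from [parse_fish_pattern()], or a pattern
#'   string.
#' @return One of `"normal"`, `"tp53_loss_disomic17"`, `"monosomy17"`,
#'   `"abnormal_diminished"`.
#' @examples
#' interpret_fish("1R2G")
#' @export
interpret_fish <- function(p) {
  if (is.character(p)) p <- parse_fish_pattern(p)
  stopifnot(inherits(p, "fish_pattern"))
  if (p$n_centromere == 0L) {
    stop("invalid FISH pattern '", p$raw,
         "': no centromere-17 signal", call. = FALSE)
  }
  if (p$n_target_dim > 0L) return("abnormal_diminished")
  if (p$n_centromere == 1L) return("monosomy17")
  if (p$n_target_normal < p$n_centromere) return("tp53_loss_disomic17")
  "normal"
}

# --- karyotype/FISH reconciliation -------------------------------------

fish_to_status <- function(fish_call) {
  switch(fish_call,
         normal = "normal",
         tp53_loss_disomic17 = "loss",
         monosomy17 = "loss",
         abnormal_diminished = "ambiguous_diminished",
         stop("unknown FISH call: ", fish_call, call. = FALSE))
}

#' Reconcile a karyotype-based CNL call with FISH
#'
#' FISH refines ambiguous karyotype calls (its status is adopted);
#' agreement between a definite karyotype call and FISH is reported as
#' concordant; disagreement is surfaced as discordant and never silently
#' resolved (the joint report retains both calls).
#'
#' @param karyotype_call A `cnl_call` from [infer_cnl_from_karyotype()].
#' @param fish_call A call from [interpret_fish()] (or a pattern
#'   string/`fish_pattern`, interpreted on the fly).
#' @return List with `concordance` (`concordant`/`fish_refines`/
#'   `discordant`), `final_status`, `karyotype_call`, `fish_call`.
#' @export
reconcile_cnl <- function(karyotype_call, fish_call) {
  stopifnot(inherits(karyotype_call, "cnl_call"))
  known_calls <- c("normal", "tp53_loss_disomic17", "monosomy17",
                   "abnormal_diminished")
  if (!(is.character(fish_call) && fish_call %in% known_calls)) {
    fish_call <- interpret_fish(fish_call)
  }
  fish_status <- fish_to_status(fish_call)
  k_status <- karyotype_call$status
  if (k_status == "ambiguous_diminished") {
    out <- list(concordance = "fish_refines", final_status = fish_status)
  } else {
    k_def <- if (k_status == "no_evidence") "normal" else k_status
    if (k_def == fish_status) {
      out <- list(concordance = "concordant", final_status = k_def)
    } else {
      out <- list(concordance = "discordant", final_status = NA_character_)
    }
  }
  c(out, list(karyotype_call = karyotype_call, fish_call = fish_call))
}

# --- mechanism census ---------------------------------------------------

#' Census of TP53 CNL mechanisms across a cohort
#'
#' Counts patients by primary loss mechanism (precedence already applied
#' per patient by [infer_cnl_from_karyotype()]). Percentages are emitted
#' over two denominators: the subset with a CNL loss call, and all
#' patients supplied (typically the TP53-mutant subset).
#'
#' @param calls A list of `cnl_call` objects, one per patient.
#' @return A tibble with columns `mechanism`, `n`, `pct_of_cnl`,
#'   `pct_of_cohort`, plus attributes `n_cnl` and `n_cohort`.
#' @export
cnl_mechanism_census <- function(calls) {
  stopifnot(all(vapply(calls, inherits, logical(1), "cnl_call")))
  mechs <- vapply(calls, function(cc) {
    if (cc$status == "loss") cc$mechanism else NA_character_
  }, character(1))
  n_cnl <- sum(!is.na(mechs))
  tab <- table(factor(mechs, levels = cnl_mechanism_precedence))
  out <- tibble::tibble(
    mechanism = names(tab),
    n = as.integer(tab),
    pct_of_cnl = if (n_cnl) 100 * as.integer(tab) / n_cnl else NA_real_,
    pct_of_cohort = if (length(calls)) {
      100 * as.integer(tab) / length(calls)
    } else NA_real_
  )
  attr(out, "n_cnl") <- n_cnl
  attr(out, "n_cohort") <- length(calls)
  out
}

#' Two-hit accounting for TP53
#'
#' Number of TP53 "hits" per patient: distinct TP53 mutations plus one
#' when the karyotype (or reconciled) CNL status is a loss.
#'
#' @param n_tp53_mutations Integer vector of distinct TP53 mutation
#'   counts.
#' @param cnl_status Character vector of CNL statuses (recycled).
#' @return Integer vector of hit counts.
#' @export
tp53_hit_count <- function(n_tp53_mutations, cnl_status) {
  cnl_status <- rep_len(cnl_status, length(n_tp53_mutations))
  as.integer(n_tp53_mutations) + as.integer(cnl_status == "loss")
}
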
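# --- canonical ordering and serialization ------------------------------

# Sort key for abnormality tokens within a clone, following ISCN listing
# conventions: sex-chromosome events first, then autosomes in ascending
# number (numerical gains/losses ahead of structural events of the same
# chromosome), then +r of unknown origin, +mar, dmin, and finally
# unclassified tokens. The raw token breaks remaining ties.
abnormality_order <- function(abns) {
  if (!length(abns)) return(integer())
  key <- vapply(abns, function(ab) {
    chr <- if (length(ab$chromosomes)) ab$chromosomes[[1]] else NA_character_
    if (!is.na(chr)) {
      cat <- if (chr %in% c("X", "Y")) 0L else 1L
      num <- match(chr, c("X", "Y", as.character(1:22)))
    } else {
      cat <- switch(ab$kind, ring_unknown = 2L, mar = 3L, dmin = 4L, 5L)
      num <- 0L
    }
    kindp <- if (ab$kind %in% c("whole_gain", "whole_loss")) 0L else 1L
    sprintf("%d|%02d|%d|%s", cat, num, kindp, ab$raw_token)
  }, character(1))
  order(key)
}

serialize_clone <- function(clone) {
  modal <- paste(clone$modal, collapse = "~")
  abns <- clone$abnormalities[abnormality_order(clone$abnormalities)]
  tokens <- vapply(abns, function(ab) ab$raw_token, character(1))
  parts <- c(modal, if (nzchar(clone$sex)) clone$sex, tokens)
  out <- paste(parts, collapse = ",")
  if (!is.na(clone$cell_count)) {
    out <- paste0(out, "[", if (clone$composite) "cp", clone$cell_count, "]")
  }
  out
}

#' Serialize a karyotype back to ISCN text
#'
#' Emits canonical ISCN: whitespace-free, ASCII hyphen for losses, and
#' abnormality tokens sorted in conventional listing order
#' (sex-chromosome events, autosomes by ascending number with numerical
#' events ahead of structural ones, then `+r`, `+mar`, `dmin`).
#' For karyotypes already in canonical order,
#' `parse_karyotype(serialize_karyotype(k))` reproduces `k`
#' (see [iscn_equal()]); composite (`cp`) and incomplete (`inc`)
#' karyotypes are outside that guarantee.
#'
#' @param k An `iscn_karyotype`.
#' @return A single ISCN string.
#' @examples
#' serialize_karyotype(parse_karyotype("46,XY,−7,+r"))
#' @export
serialize_karyotype <- function(k) {
  stopifnot(inherits(k, "iscn_karyotype"))
  paste(vapply(k$clones, serialize_clone, character(1)), collapse = "/")
}

# --- model equality -----------------------------------------------------

abnormality_equal <- function(a, b) {
  fmt_bp <- function(bps) vapply(bps, format, character(1))
  identical(a$kind, b$kind) &&
    identical(a$chromosomes, b$chromosomes) &&
    identical(fmt_bp(a$breakpoints), fmt_bp(b$breakpoints)) &&
    identical(sort(a$arm_hints), sort(b$arm_hints)) &&
    identical(a$copies, b$copies) &&
    identical(a$uncertain, b$uncertain)
}

clone_equal <- function(a, b) {
  if (!identical(a$modal, b$modal)) return(FALSE)
  if (!identical(a$sex, b$sex)) return(FALSE)
  if (!identical(a$cell_count, b$cell_count)) return(FALSE)
  if (!identical(a$composite, b$composite)) return(FALSE)
  if (length(a$abnormalities) != length(b$abnormalities)) return(FALSE)
  aa <- a$abnormalities[abnormality_order(a$abnormalities)]
  bb <- b$abnormalities[abnormality_order(b$abnormalities)]
  all(mapply(abnormality_equal, aa, bb))
}

#' Model equality of two parsed karyotypes
#'
#' Compares two `iscn_karyotype` objects on the abnormality model:
#' clone count and order, modal numbers, sex designations, cell counts,
#' and per-clone abnormality multisets (kind, chromosomes, breakpoints,
#' copies, uncertainty). Source text, token spelling and `idem`
#' provenance flags are ignored, so a karyotype compares equal to the
#' parse of its own serialization.
#'
#' @param a,b `iscn_karyotype` objects.
#' @return `TRUE` or `FALSE`.
#' @export
iscn_equal <- function(a, b) {
  stopifnot(inherits(a, "iscn_karyotype"), inherits(b, "iscn_karyotype"))
  if (length(a$clones) != length(b$clones)) return(FALSE)
  all(mapply(clone_equal, a$clones, b$clones))
}
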
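#' @keywords internal
"_PACKAGE"

# Abnormality kind vocabulary. "ring_derived" is r(N)(..), "ring_unknown"
# the supernumerary +r of unknown origin; "other" is the permissive
# fallback so that no token is ever dropped.
abnormality_kinds <- c(
  "whole_gain", "whole_loss", "add", "del", "dup", "der", "dic", "idic",
  "i", "ins", "inv", "t", "ring_derived", "ring_unknown", "mar", "dmin",
  "other"
)

structural_kinds <- c(
  "add", "del", "dup", "der", "dic", "idic", "i", "ins", "inv", "t",
  "ring_derived"
)

chromosome_labels <- c(as.character(1:22), "X", "Y")

new_abnormality <- function(kind, chromosomes = character(),
                            breakpoints = list(),
                            arm_hints = character(),
                            copies = 1L, uncertain = FALSE,
                            raw_token = "", inherited = FALSE) {
  stopifnot(kind %in% abnormality_kinds)
  structure(
    list(
      kind = kind,
      chromosomes = as.character(chromosomes),
      breakpoints = breakpoints,
      # arms seen without a usable band number, as "17p" style strings
      arm_hints = as.character(arm_hints),
      copies = as.integer(copies),
      uncertain = isTRUE(uncertain),
      raw_token = raw_token,
      inherited = isTRUE(inherited)
    ),
    class = "iscn_abnormality"
  )
}

new_clone <- function(modal, sex, abnormalities, cell_count = NA_integer_,
                      composite = FALSE, idem = FALSE, raw = "") {
  structure(
    list(
      modal = as.integer(modal),
      sex = sex,
      abnormalities = abnormalities,
      cell_count = as.integer(cell_count),
      composite = isTRUE(composite),
      idem = isTRUE(idem),
      raw = raw
    ),
    class = "iscn_clone"
  )
}

# --- text canonicalization ---------------------------------------------

# Published karyotypes mix ASCII hyphen, Unicode minus and en/em dashes
# for losses, and contain line-break whitespace inside band lists.
clean_iscn_text <- function(text) {
  text <- gsub("[−–—]", "-", text)
  gsub("[[:space:]]+", "", text)
}

#' Parse an ISCN karyotype string
#'
#' Parses a (possibly mosaic, multi-clone) karyotype written in ISCN
#' nomenclature into a structured model of clones and abnormality events.
#' Clones are separated by `/`; each clone carries a modal chromosome
#' number (single value or `41~44`-style interval), a sex designation,
#' comma-separated abnormality tokens, and an optional metaphase cell
#' count in square brackets. `idem` clones are expanded at parse time:
#' the stemline's abnormalities are copied in (flagged `inherited`)
#' ahead of the clone's own events. Tokens that cannot be interpreted are
#' retained as `other` events with `uncertain = TRUE` rather than being
#' dropped. Unicode minus and dashes are accepted as loss signs and
#' canonicalized to the ASCII hyphen; internal whitespace is ignored.
#'
#' @param text A non-empty ISCN karyotype string, e.g.
#'   `"46,XX,r(18)(p11.3q23)[2]/46,XX,t(7;17)(q36;q21)[2]/46,XX[15]"`.
#' @return An object of class `iscn_karyotype`: a list with `clones`
#'   (list of `iscn_clone`), `source_text`, and an `incomplete` flag set
#'   by `inc`/composite (`cp`) designations.
#' @examples
#' k <- parse_karyotype("46,XY,-7,+r")
#' length(k$clones[[1]]$abnormalities)
#' @export
parse_karyotype <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text))) {
    stop("karyotype string must be a single non-empty string", call. = FALSE)
  }
  source_text <- text
  text <- clean_iscn_text(text)
  clone_strings <- strsplit(text, "/", fixed = TRUE)[[1]]
  clone_strings <- clone_strings[nzchar(clone_strings)]
  if (length(clone_strings) == 0L) {
    stop("karyotype string contains no clones: '", source_text, "'",
         call. = FALSE)
  }
  clones <- vector("list", length(clone_strings))
  incomplete <- FALSE
  for (i in seq_along(clone_strings)) {
    stemline <- if (i > 1L) clones[[1L]] else NULL
    parsed <- parse_clone(clone_strings[[i]], stemline)
    clones[[i]] <- parsed$clone
    incomplete <- incomplete || parsed$incomplete
  }
  structure(
    list(clones = clones, source_text = source_text,
         incomplete = incomplete),
    class = "iscn_karyotype"
  )
}

parse_clone <- function(txt, stemline = NULL) {
  raw <- txt
  incomplete <- FALSE
  cell_count <- NA_integer_
  composite <- FALSE
  m <- regexec("\\[(cp)?(\\d+)\\]$", txt)
  g <- regmatches(txt, m)[[1]]
  if (length(g)) {
    composite <- g[[2]] == "cp"
    incomplete <- incomplete || composite
    cell_count <- as.integer(g[[3]])
    if (cell_count < 1L) {
      stop("cell count must be >= 1 in clone '", raw, "'", call. = FALSE)
    }
    txt <- sub("\\[(cp)?\\d+\\]$", "", txt)
  }
  fields <- strsplit(txt, ",", fixed = TRUE)[[1]]
  fields <- fields[nzchar(fields)]
  if (length(fields) == 0L) {
    stop("empty clone in karyotype: '", raw, "'", call. = FALSE)
  }

  mm <- regexec("^\\??(\\d+)(~(\\d+))?$", fields[[1]])
  gg <- regmatches(fields[[1]], mm)[[1]]
  if (!length(gg)) {
    stop("cannot parse ploidy field '", fields[[1]], "' in clone '",
         raw, "'", call. = FALSE)
  }
  modal <- as.integer(gg[[2]])
  if (nzchar(gg[[4]])) modal <- c(modal, as.integer(gg[[4]]))
  fields <- fields[-1L]

  sex <- ""
  if (length(fields) && grepl("^\\??[XY]{1,4}$", fields[[1]])) {
    sex <- sub("^\\?", "", fields[[1]])
    fields <- fields[-1L]
  }

  idem <- FALSE
  abns <- list()
  for (tok in fields) {
    if (tok == "idem" || grepl("^idem", tok)) {
      idem <- TRUE
      next
    }
    if (tok == "inc") {
      incomplete <- TRUE
      next
    }
    abns[[length(abns) + 1L]] <- parse_token(tok)
  }
  if (idem) {
    if (is.null(stemline)) {
      stop("'idem' used in the first clone of '", raw, "'", call. = FALSE)
    }
    inherited <- lapply(stemline$abnormalities, function(ab) {
      ab$inherited <- TRUE
      ab
    })
    abns <- c(inherited, abns)
  }
  list(
    clone = new_clone(modal, sex, abns, cell_count,
                      composite = composite, idem = idem, raw = raw),
    incomplete = incomplete
  )
}

# --- token parsing ------------------------------------------------------

parse_token <- function(tok) {
  raw <- tok
  uncertain <- grepl("[?~]", tok)

  copies <- 1L
  m <- regexec("^(.*)[x×](\\d+)$", tok)
  g <- regmatches(tok, m)[[1]]
  if (length(g)) {
    tok <- g[[2]]
    copies <- as.integer(g[[3]])
  }

  sign <- ""
  if (grepl("^[+-]", tok)) {
    sign <- substr(tok, 1L, 1L)
    tok <- substring(tok, 2L)
  }
  body <- gsub("\\?", "", tok)

  # whole-chromosome gain/loss: +8, -7, -X
  if (nzchar(sign) && body %in% chromosome_labels) {
    kind <- if (sign == "+") "whole_gain" else "whole_loss"
    return(new_abnormality(kind, chromosomes = body, copies = copies,
                           uncertain = uncertain, raw_token = raw))
  }
  # supernumerary ring of unknown origin
  if (body == "r") {
    return(new_abnormality("ring_unknown", copies = copies,
                           uncertain = uncertain, raw_token = raw))
  }
  # marker chromosome(s), possibly with a leading count (+2mar)
  mm <- regexec("^(\\d*)mar$", body)
  gm <- regmatches(body, mm)[[1]]
  if (length(gm)) {
    if (nzchar(gm[[2]])) copies <- copies * as.integer(gm[[2]])
    return(new_abnormality("mar", copies = copies,
                           uncertain = uncertain, raw_token = raw))
  }
  # double minutes, possibly with a count range (1~5dmin)
  if (grepl("^\\d*(~\\d+)?dmin$", body)) {
    return(new_abnormality("dmin", copies = copies,
                           uncertain = uncertain, raw_token = raw))
  }

  ab <- parse_structural_token(tok, copies = copies,
                               uncertain = uncertain, raw = raw)
  if (!is.null(ab)) return(ab)

  new_abnormality("other", copies = copies, uncertain = TRUE,
                  raw_token = raw)
}

# Parses chained structural expressions such as
#   r(18)(p11.3q23)  t(7;17)(q36;q21)  der(5)t(5;17)(p11;q11)
#   ins(5;2)(q13;p13p23)  i(17)(q10)  add(17)(p?)
# Returns NULL when the expression does not fit the structural grammar.
parse_structural_token <- function(tok, copies, uncertain, raw) {
  op_map <- c(
    add = "add", del = "del", dup = "dup", der = "der", dic = "dic",
    idic = "idic", i = "i", ins = "ins", inv = "inv", t = "t",
    r = "ring_derived", trp = "dup"
  )
  rest <- tok
  units <- list()
  while (nzchar(rest)) {
    m <- regexec("^\\??([a-z]+)\\(([^()]*)\\)", rest)
    g <- regmatches(rest, m)[[1]]
    if (length(g)) {
      units[[length(units) + 1L]] <-
        list(op = g[[2]], chroms = g[[3]], bands = NULL)
      rest <- substring(rest, nchar(g[[1]]) + 1L)
      next
    }
    m2 <- regexec("^\\(([^()]*)\\)", rest)
    g2 <- regmatches(rest, m2)[[1]]
    if (length(g2) && length(units) &&
        is.null(units[[length(units)]]$bands)) {
      units[[length(units)]]$bands <- g2[[2]]
      rest <- substring(rest, nchar(g2[[1]]) + 1L)
      next
    }
    return(NULL)
  }
  if (!length(units)) return(NULL)
  head_op <- units[[1L]]$op
  if (!head_op %in% names(op_map)) return(NULL)
  kind <- unname(op_map[[head_op]])

  chroms <- character()
  breakpoints <- list()
  arm_hints <- character()
  for (u in units) {
    slots <- strsplit(u$chroms, ";", fixed = TRUE)[[1]]
    slots <- gsub("\\?", "", slots)
    keep <- slots %in% chromosome_labels
    if (any(!keep & nzchar(slots))) uncertain <- TRUE
    slot_chroms <- slots
    chroms <- c(chroms, slot_chroms[keep])
    if (!is.null(u$bands)) {
      band_slots <- strsplit(u$bands, ";", fixed = TRUE)[[1]]
      for (j in seq_along(band_slots)) {
        chr <- if (j <= length(slot_chroms) && keep[j]) slot_chroms[j] else NA
        parsed <- parse_band_list(band_slots[[j]], chr)
        breakpoints <- c(breakpoints, parsed$breakpoints)
        arm_hints <- c(arm_hints, parsed$arm_hints)
        uncertain <- uncertain || parsed$uncertain
      }
    }
  }
  chroms <- unique(chroms)
  # a derived ring names exactly one chromosome; anything else falls back
  if (kind == "ring_derived" && length(chroms) != 1L) {
    return(new_abnormality("other", chromosomes = chroms,
                           breakpoints = breakpoints, arm_hints = arm_hints,
                           copies = copies, uncertain = TRUE,
                           raw_token = raw))
  }
  new_abnormality(kind, chromosomes = chroms, breakpoints = breakpoints,
                  arm_hints = arm_hints, copies = copies,
                  uncertain = uncertain, raw_token = raw)
}

# One band-list slot, e.g. "p11.3q23", "q36", "p?", "p13p23".
parse_band_list <- function(s, chromosome) {
  breakpoints <- list()
  arm_hints <- character()
  uncertain <- FALSE
  pat <- "([pq])(\\d+(\\.\\d+)?)|([pq])(ter|\\?)|cen|\\?"
  matches <- regmatches(s, gregexpr(pat, s))[[1]]
  consumed <- sum(nchar(matches))
  if (consumed != nchar(s)) uncertain <- TRUE
  for (tk in matches) {
    g <- regmatches(tk, regexec("^([pq])(\\d+(\\.\\d+)?)$", tk))[[1]]
    if (length(g)) {
      if (!is.na(chromosome)) {
        breakpoints[[length(breakpoints) + 1L]] <-
          band_address(chromosome, g[[2]], g[[3]])
      }
      next
    }
    g2 <- regmatches(tk, regexec("^([pq])(ter|\\?)$", tk))[[1]]
    if (length(g2)) {
      if (g2[[3]] == "?") uncertain <- TRUE
      if (!is.na(chromosome)) {
        arm_hints <- c(arm_hints, paste0(chromosome, g2[[2]]))
      }
      next
    }
    if (tk == "?") uncertain <- TRUE
  }
  list(breakpoints = breakpoints, arm_hints = arm_hints,
       uncertain = uncertain)
}

#' Modal chromosome number of a clone
#'
#' Returns the leading ISCN count field of a clone: a single integer, or
#' both bounds for interval counts such as `41~44`.
#'
#' @param clone An `iscn_clone` (element of `parse_karyotype(...)$clones`).
#' @return Integer vector of length 1 (exact) or 2 (interval bounds).
#' @export
modal_number <- function(clone) {
  stopifnot(inherits(clone, "iscn_clone"))
  clone$modal
}

is_normal_clone <- function(clone) {
  length(clone$abnormalities) == 0L &&
    length(clone$modal) == 1L && clone$modal == 46L
}

#' @export
print.iscn_karyotype <- function(x, ...) {
  cat("<iscn_karyotype> ", length(x$clones), " clone(s)\n", sep = "")
  for (cl in x$clones) {
    n <- length(cl$abnormalities)
    cells <- if (is.na(cl$cell_count)) "" else paste0(" [", cl$cell_count, "]")
    cat("  ", paste(cl$modal, collapse = "~"), ",", cl$sex,
        ": ", n, " abnormalit", if (n == 1) "y" else "ies", cells, "\n",
        sep = "")
  }
  invisible(x)
}

#' @export
print.iscn_abnormality <- function(x, ...) {
  cat("<abnormality> ", x$kind,
      if (length(x$chromosomes)) paste0(" chr ", paste(x$chromosomes, collapse = ";")),
      " '", x$raw_token, "'\n", sep = "")
  invisible(x)
}
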
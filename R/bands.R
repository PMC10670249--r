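#' Cytogenetic band addresses
#'
#' A `band_address` locates a G-band on a chromosome arm, e.g. 17p13.1.
#' Within one arm, bands are totally ordered by physical position: p-arm
#' band numbers increase away from the centromere (so higher p bands are
#' more distal), and q-arm band numbers increase toward qter. The
#' `position_rank` field is a scalar that sorts bands pter -> qter, so
#' ascending rank on a p arm runs distal -> proximal and on a q arm
#' proximal -> distal.
#'
#' @param chromosome Chromosome label: `"1"`..`"22"`, `"X"` or `"Y"`.
#' @param arm `"p"` or `"q"`.
#' @param band Band designation string matching `\d+(\.\d+)?`, e.g.
#'   `"13.1"`. Band `"10"` denotes the centromeric border.
#' @return An object of class `band_address`.
#' @examples
#' band_address("17", "p", "13.1")
#' @export
band_address <- function(chromosome, arm, band) {
  chromosome <- as.character(chromosome)
  if (!chromosome %in% c(as.character(1:22), "X", "Y")) {
    stop("invalid chromosome label: ", chromosome, call. = FALSE)
  }
  if (!arm %in% c("p", "q")) {
    stop("arm must be 'p' or 'q', got: ", arm, call. = FALSE)
  }
  band <- as.character(band)
  if (!grepl("^\\d+(\\.\\d+)?$", band)) {
    stop("invalid band designation: ", band, call. = FALSE)
  }
  structure(
    list(
      chromosome = chromosome,
      arm = arm,
      band = band,
      position_rank = band_position_rank(arm, band)
    ),
    class = "band_address"
  )
}

# Scalar rank sorting bands pter -> qter. The digit string of a band
# (region digit, band digit, then sub-bands after the dot) orders
# positionally like a decimal fraction away from the centromere;
# p-arm distances are negated so that ascending rank runs pter -> qter.
band_position_rank <- function(arm, band) {
  dist <- band_centromere_distance(band)
  if (arm == "p") -dist else dist
}

# Distance-from-centromere key: "11.3" -> 0.113, "13" -> 0.13, "10" -> 0.10.
band_centromere_distance <- function(band) {
  as.numeric(paste0("0.", gsub("\\.", "", band)))
}

#' @export
format.band_address <- function(x, ...) {
  paste0(x$chromosome, x$arm, x$band)
}

#' @export
print.band_address <- function(x, ...) {
  cat("<band> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Compare two bands on the same chromosome arm
#'
#' Returns the cytogenetic ordering of two bands, oriented pter -> qter:
#' on a p arm the more distal (higher-numbered) band sorts first, on a
#' q arm the more proximal band sorts first. Ties occur only for
#' identical band strings.
#'
#' @param a,b `band_address` objects on the same chromosome and arm.
#' @return `-1L` if `a` precedes `b` (closer to pter), `0L` if equal,
#'   `1L` otherwise.
#' @examples
#' compare_bands(band_address("17", "p", "13"), band_address("17", "p", "11.2"))
#' @export
compare_bands <- function(a, b) {
  stopifnot(inherits(a, "band_address"), inherits(b, "band_address"))
  if (a$chromosome != b$chromosome || a$arm != b$arm) {
    stop("bands are on different chromosome arms: ",
         format(a), " vs ", format(b), call. = FALSE)
  }
  if (a$band == b$band) return(0L)
  if (a$position_rank < b$position_rank) -1L else 1L
}

# TRUE if `a` is at least as close to the centromere as `ref`
# (same chromosome + arm). Used to decide whether a breakpoint is
# proximal to the TP53 locus.
band_proximal_or_equal <- function(a, ref) {
  stopifnot(a$chromosome == ref$chromosome, a$arm == ref$arm)
  band_centromere_distance(a$band) <= band_centromere_distance(ref$band)
}

#' The TP53 locus band
#'
#' TP53 maps to chromosome band 17p13.1; chromosome-17 structural
#' abnormalities are evaluated for copy-number loss relative to this
#' address.
#'
#' @return A `band_address` for 17p13.1.
#' @export
tp53_band <- function() band_address("17", "p", "13.1")

#' Bundled chromosome band catalogue
#'
#' A small static table of major G-band designations per chromosome arm,
#' used by the synthetic cohort generator to draw realistic breakpoints.
#' It lists major bands only and is not a complete ideogram.
#'
#' @return A data.frame with columns `chromosome`, `arm`, `band`.
#' @export
iscn_band_catalogue <- function() {
  spec <- list(
    `1`  = list(p = c("36.3", "34", "22", "13"),    q = c("21", "25", "32", "42")),
    `2`  = list(p = c("25", "23", "16", "13"),      q = c("21", "24", "31", "37")),
    `3`  = list(p = c("26", "24", "21", "13"),      q = c("13", "21", "26", "29")),
    `4`  = list(p = c("16", "15", "13"),            q = c("21", "25", "31", "35")),
    `5`  = list(p = c("15", "13"),                  q = c("13", "15", "22", "31", "33", "35")),
    `6`  = list(p = c("25", "22", "21"),            q = c("15", "21", "23", "27")),
    `7`  = list(p = c("22", "15", "13"),            q = c("11.2", "22", "31", "36")),
    `8`  = list(p = c("23", "21", "11.2"),          q = c("13", "21", "22", "24")),
    `9`  = list(p = c("24", "21", "13"),            q = c("13", "22", "34")),
    `10` = list(p = c("15", "13", "11.2"),          q = c("21", "23", "25")),
    `11` = list(p = c("15", "13", "11.2"),          q = c("13", "14", "21", "23", "25")),
    `12` = list(p = c("13", "12", "11.2"),          q = c("13", "15", "21", "24")),
    `13` = list(p = c("12", "11.2"),                q = c("12", "14", "21", "31", "34")),
    `14` = list(p = c("12", "11.2"),                q = c("11.2", "22", "24", "32")),
    `15` = list(p = c("12", "11.2"),                q = c("11.2", "15", "22", "24")),
    `16` = list(p = c("13.3", "12", "11.2"),        q = c("12", "22", "24")),
    `17` = list(p = c("13.1", "12", "11.2"),        q = c("11.2", "21", "23", "25")),
    `18` = list(p = c("11.3", "11.2"),              q = c("12", "21", "23")),
    `19` = list(p = c("13.3", "13.1"),              q = c("13.1", "13.3")),
    `20` = list(p = c("13", "12", "11.2"),          q = c("11.2", "13.1", "13.3")),
    `21` = list(p = c("12", "11.2"),                q = c("21", "22")),
    `22` = list(p = c("12", "11.2"),                q = c("11.2", "12", "13")),
    X    = list(p = c("22.1", "21", "11.2"),        q = c("13", "21", "24", "27")),
    Y    = list(p = c("11.3", "11.2"),              q = c("11.2", "12"))
  )
  rows <- lapply(names(spec), function(chr) {
    do.call(rbind, lapply(c("p", "q"), function(arm) {
      bands <- spec[[chr]][[arm]]
      data.frame(chromosome = chr, arm = arm, band = bands,
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}
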
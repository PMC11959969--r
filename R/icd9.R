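# Major-group ranges: code value x matches group g when lo <= x < hi + 1,
# so "319.99" still falls in the psychiatric 291-319 range.
icd9_ranges <- list(
  PSY = c(291, 319), BLO = c(280, 289), CCD = c(390, 459),
  NEU = c(320, 359), RES = c(460, 519), GAS = c(520, 579),
  GEN = c(580, 629), END = c(240, 279), INF = c(1, 139),
  NEO = c(140, 239), SEN = c(360, 389))
# MUS spans two ranges (rheumatic/connective plus fracture codes).
icd9_mus_ranges <- list(c(710, 739), c(800, 829))
# Explicit single-code rules checked before any range: dementia-related
# codes assigned to the neurological group, and neoplasm V-codes.
icd9_neu_specials <- c("290", "2941")
icd9_neo_vcodes <- c("V10", "V580", "V581", "V671", "V672")

#' Map ICD-9-CM codes to the 12 major disease groups
#'
#' Maps numeric ICD-9-CM codes (with optional decimal part) and V-codes to
#' the 12 major-group labels `PSY, BLO, CCD, NEU, MUS, RES, GAS, GEN, END,
#' INF, NEO, SEN`. Explicit single-code rules take precedence over the
#' numeric ranges: `290.x` and `294.1x` map to NEU although they lie
#' outside 320–359, and the V-codes `V10, V58.0, V58.1, V67.1, V67.2` map
#' to NEO. MUS covers both 710–739 and the fracture codes 800–829. Codes
#' matching no rule return `NA`; malformed codes are an error.
#'
#' @param code character vector of ICD-9-CM codes (e.g. `"401.9"`,
#'   `"294.1"`, `"V10"`).
#' @return Character vector of group labels (`NA` where unmapped).
#' @export
icd9_group <- function(code) {
  code <- trimws(toupper(as.character(code)))
  out <- rep(NA_character_, length(code))
  for (k in seq_along(code)) {
    cc <- code[k]
    if (is.na(cc) || cc == "") stop_morbnet("empty ICD-9 code at position ", k)
    nodot <- gsub(".", "", cc, fixed = TRUE)
    if (startsWith(cc, "V")) {
      if (!grepl("^V[0-9]+$", nodot)) {
        stop_morbnet("malformed ICD-9 code: '", cc, "'")
      }
      hit <- icd9_neo_vcodes[startsWith(nodot, icd9_neo_vcodes)]
      if (length(hit)) out[k] <- "NEO"
      next
    }
    if (!grepl("^[0-9]{1,3}(\\.[0-9]+)?$", cc)) {
      stop_morbnet("malformed ICD-9 code: '", cc, "'")
    }
    if (any(startsWith(nodot, icd9_neu_specials))) {
      out[k] <- "NEU"
      next
    }
    x <- as.numeric(cc)
    for (r in icd9_mus_ranges) {
      if (x >= r[1L] && x < r[2L] + 1) out[k] <- "MUS"
    }
    if (!is.na(out[k])) next
    for (g in names(icd9_ranges)) {
      r <- icd9_ranges[[g]]
      if (x >= r[1L] && x < r[2L] + 1) {
        out[k] <- g
        break
      }
    }
  }
  out
}

#' Build disease indicators from person-level ICD-9-CM records
#'
#' Aggregates longitudinal (person, code) diagnosis records into a binary
#' cohort: a disease-group indicator is 1 for a person if any of their
#' recorded codes maps to that group. Unmapped codes are ignored.
#'
#' @param records data frame with columns `person_id` and `icd9_code`.
#' @param persons optional vector of person ids fixing the cohort (persons
#'   with no mappable record get all-zero rows); defaults to the ids
#'   present in `records`.
#' @return Data frame with one row per person: `person_id` plus the 12
#'   group indicator columns.
#' @export
aggregate_icd9_records <- function(records, persons = NULL) {
  stopifnot(all(c("person_id", "icd9_code") %in% names(records)))
  groups <- c("PSY", "BLO", "CCD", "NEU", "MUS", "RES",
              "GAS", "GEN", "END", "INF", "NEO", "SEN")
  persons <- persons %||% unique(records$person_id)
  g <- icd9_group(records$icd9_code)
  out <- matrix(0L, length(persons), length(groups),
                dimnames = list(NULL, groups))
  keep <- !is.na(g) & records$person_id %in% persons
  pi <- match(records$person_id[keep], persons)
  gi <- match(g[keep], groups)
  out[cbind(pi, gi)] <- 1L
  cbind(data.frame(person_id = persons), as.data.frame(out))
}
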
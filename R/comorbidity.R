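#' Charlson age-comorbidity index (CACI) from ICD-10 codes
#'
#' Scores one patient: the sum of Charlson category weights over the
#' comorbidities present in `icd10_codes` plus age points (one point per
#' decade from age 50: 50-59 scores 1, 60-69 scores 2, 70-79 scores 3, and
#' 80 or older scores 4). Each Charlson category counts once regardless of
#' how many codes map to it, and the usual severity hierarchies apply:
#' metastatic solid tumor supersedes any (non-metastatic) malignancy,
#' moderate/severe liver disease supersedes mild liver disease, and
#' complicated diabetes supersedes uncomplicated diabetes.
#'
#' ICD-10 codes are matched case-insensitively by prefix against the
#' Quan (2005) ICD-10 coding algorithm with the original Charlson weights;
#' dots are ignored, so `"C780"` and `"C78.0"` are equivalent. The mapping
#' ships as a plain-text resource (see [charlson_map()]) so an
#' institution-specific code list can be dropped in.
#'
#' @param age Age in completed years (non-negative integer).
#' @param icd10_codes Character vector of ICD-10 diagnosis codes. Strings
#'   that do not look like ICD-10 codes (letter followed by digits) are
#'   ignored with a warning; valid codes outside the Charlson map simply
#'   contribute nothing.
#' @param map Charlson mapping table, by default [charlson_map()].
#' @return A list of class `"caci_result"` with elements `score`
#'   (non-negative integer) and `stratum` (`"high"` if score > 3, else
#'   `"low"`).
#' @examples
#' caci_score(65, c("C78.0"))       # metastatic disease (6) + age 60s (2) = 8
#' caci_score(55, c("I21.9"))       # myocardial infarction (1) + age 50s (1) = 2
#' @seealso [caci_stratum()], [add_caci()]
#' @export
caci_score <- function(age, icd10_codes = character(), map = charlson_map()) {
  if (length(age) != 1L || !is.finite(age) || age < 0)
    stop_domain("age must be a single non-negative number")
  codes <- as.character(icd10_codes)
  codes <- codes[!is.na(codes) & nzchar(codes)]
  bad <- !grepl("^[A-Za-z][0-9]", codes)
  if (any(bad)) {
    warning("ignoring unparseable ICD-10 code(s): ",
            paste(unique(codes[bad]), collapse = ", "))
    codes <- codes[!bad]
  }
  norm <- toupper(gsub(".", "", codes, fixed = TRUE))

  hit <- vapply(seq_len(nrow(map)), function(i) {
    pref <- map$prefix_norm[[i]]
    any(outer(norm, pref, startsWith))
  }, logical(1))

  present <- map[hit, , drop = FALSE]
  # severity hierarchies: within a hierarchy group keep only the top weight
  if (nrow(present) > 1L && any(nzchar(present$hierarchy_group))) {
    keep <- rep(TRUE, nrow(present))
    for (g in unique(present$hierarchy_group[nzchar(present$hierarchy_group)])) {
      in_g <- which(present$hierarchy_group == g)
      if (length(in_g) > 1L)
        keep[in_g[-which.max(present$weight[in_g])]] <- FALSE
    }
    present <- present[keep, , drop = FALSE]
  }

  score <- sum(present$weight) + age_points(age)
  structure(list(score = as.integer(score), stratum = caci_stratum(score)),
            class = "caci_result")
}

age_points <- function(age) {
  pmin(pmax(floor(age / 10) - 4L, 0L), 4L)
}

#' CACI risk stratum
#'
#' High-risk when the Charlson age-comorbidity index exceeds 3; low-risk at
#' 3 or below. The stratum is an exact-match criterion in all three matching
#' designs.
#'
#' @param score CACI score(s), non-negative.
#' @return Character vector, `"high"` or `"low"`.
#' @export
caci_stratum <- function(score) {
  if (any(!is.finite(score)) || any(score < 0))
    stop_domain("CACI score must be non-negative and finite")
  ifelse(score > 3, "high", "low")
}

#' @export
print.caci_result <- function(x, ...) {
  cat("CACI score:", x$score, "->", x$stratum, "risk stratum\n")
  invisible(x)
}

#' Charlson ICD-10 mapping table
#'
#' Reads the packaged Quan-2005 ICD-10 coding algorithm (original Charlson
#' weights) from `inst/extdata/charlson_icd10_map.tsv`. Columns: `category`,
#' `weight`, `hierarchy_group` (categories sharing a group are mutually
#' exclusive, highest weight wins), and a comma-separated code-prefix list.
#'
#' @param path Alternative mapping file in the same four-column layout, e.g.
#'   an institutional code list.
#' @return Data frame with a list-column `prefix_norm` of normalised
#'   (dot-stripped, upper-case) prefixes.
#' @export
charlson_map <- function(path = NULL) {
  if (is.null(path)) {
    cached <- .dip_cache$charlson
    if (!is.null(cached)) return(cached)
    path <- system.file("extdata", "charlson_icd10_map.tsv",
                        package = "dipburden", mustWork = TRUE)
  }
  m <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                  colClasses = c("character", "numeric", "character", "character"))
  m$prefix_norm <- lapply(strsplit(m$prefixes, ","),
                          function(p) toupper(gsub(".", "", trimws(p), fixed = TRUE)))
  if (is.null(attr(path, "nocache")))
    .dip_cache$charlson <- m
  m
}

.dip_cache <- new.env(parent = emptyenv())

#' Append CACI columns to an episode table
#'
#' Splits the semicolon-joined `icd10_codes` field of each episode, scores
#' the Charlson age-comorbidity index and appends `caci_score` and
#' `caci_stratum` columns.
#'
#' @param episodes Episode data frame with `age` and `icd10_codes` columns
#'   (codes joined by `";"`).
#' @param map Charlson mapping table.
#' @return `episodes` with `caci_score` (integer) and `caci_stratum`
#'   (`"high"`/`"low"`) columns.
#' @export
add_caci <- function(episodes, map = charlson_map()) {
  codes <- episodes$icd10_codes %||% character(nrow(episodes))
  # score each distinct code set once (cohorts repeat a few hundred sets)
  uniq <- unique(codes)
  charlson <- vapply(uniq, function(s) {
    caci_score(0, strsplit(s, ";", fixed = TRUE)[[1]], map = map)$score
  }, integer(1))
  scores <- charlson[match(codes, uniq)] + age_points(episodes$age)
  episodes$caci_score <- as.integer(scores)
  episodes$caci_stratum <- caci_stratum(scores)
  episodes
}
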
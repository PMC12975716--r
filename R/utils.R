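#' @importFrom methods new validObject slot slotNames is show
#' @importFrom stats phyper p.adjust pnorm rnbinom
#' @importFrom utils read.delim write.table combn head
NULL

# Locale-independent (byte-order) sort; all deterministic orderings in the
# package go through this so results do not depend on the session locale.
sortC <- function(x) {
  if (!length(x)) return(character(0))
  sort(x, method = "radix")
}

orderC <- function(...) order(..., method = "radix")

#' Round half away from zero
#'
#' Rubric criterion points are proportional credit rounded to whole points;
#' ties at .5 round up (base `round()` rounds half to even, which would turn
#' 22.5 into 22).
#'
#' @param x numeric vector (non-negative in rubric use).
#' @return numeric vector of rounded values.
#' @export
roundHalfUp <- function(x) floor(x + 0.5)

# Gene symbols are matched case-insensitively by upper-casing once at entry.
normalizeGenes <- function(x) {
  x <- toupper(trimws(x))
  x[nzchar(x)]
}

#' Normalize a cell-type or tissue label for matching
#'
#' Lower-cases, maps `-` and `_` to spaces, and collapses runs of
#' whitespace. Case and hyphenation variants ("B-cell" vs "b cell") are the
#' dominant failure mode when harmonizing free-text labels.
#'
#' @param x character vector of labels.
#' @return character vector of normalized labels.
#' @export
normalizeLabel <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[-_]", " ", x)
  gsub("[[:space:]]+", " ", x)
}

# Split a "|"-delimited list cell from the KB TSV.
splitListCell <- function(x) {
  if (length(x) == 0L || is.na(x[1]) || !nzchar(trimws(x[1])))
    return(character(0))
  x <- x[1]
  out <- trimws(strsplit(x, "|", fixed = TRUE)[[1]])
  out[nzchar(out)]
}

joinListCell <- function(x) paste(x, collapse = "|")

# FNV-1a 32-bit hash over the UTF-8 bytes of a string. Used to key replay
# recordings and to fingerprint effective configurations in report metadata.
fnv1a32 <- function(txt) {
  bytes <- as.integer(charToRaw(enc2utf8(txt)))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # multiply by the FNV prime mod 2^32 without losing double precision
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- ((lo * 16777619) + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

# Canonical JSON used for hashing (sorted names, no pretty-printing).
canonicalJSON <- function(x) {
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                null = "null"))
}
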
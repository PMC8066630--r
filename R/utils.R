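#' Round half away from zero
#'
#' Decimal rounding with halves always rounded up (the convention used for
#' reporting percent identities and survey percentages), as opposed to
#' [base::round()]'s round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' round_half_up(66.5)   # 67, where round(66.5) gives 66
#' round_half_up(99.695, 2)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Normalize a trade name or menu label
#'
#' Case-folds, transliterates diacritics to ASCII, collapses internal
#' whitespace and trims. Used as the lookup key for name rules so that
#' "Tuna", "tuna " and "TUNA" resolve identically.
#'
#' @param x Character vector of labels.
#' @return Character vector of normalized keys.
#' @export
normalize_name <- function(x) {
  tr <- iconv(x, from = "", to = "ASCII//TRANSLIT")
  x[!is.na(tr)] <- tr[!is.na(tr)]
  # glibc transliterates accented letters as accent-mark + letter; drop the marks
  x <- gsub("[`'^\"~]", "", x)
  x <- tolower(x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

# Genus component of a binomial ("Thunnus albacares" -> "Thunnus").
genus_of <- function(species) {
  vapply(strsplit(species, "\\s+"), `[`, character(1), 1L)
}

# Assert nucleotide alphabet {A,C,G,T,N}; returns the upper-cased, U->T
# converted sequence or stops with the offending ids.
check_alphabet <- function(sequences, ids = NULL) {
  sequences <- chartr("U", "T", toupper(sequences))
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) {
    who <- if (is.null(ids)) which(bad) else ids[bad]
    stop("non-IUPAC (non-ACGTN) characters in sequence record(s): ",
         paste(who, collapse = ", "), call. = FALSE)
  }
  sequences
}

`%||%` <- function(a, b) if (is.null(a)) b else a
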
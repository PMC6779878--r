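# Shared vocabularies and small helpers used across the pipeline.

#' Consequence classes recognised by the filtering cascade
#'
#' Annotated consequences are mapped onto a fixed seven-class vocabulary.
#' Anything that cannot be mapped is read as "other" (with a warning at
#' parse time) and is removed by the consequence filter.
#'
#' @return Character vector of the seven consequence labels.
#' @export
consequence_levels <- function() {
  c("missense", "stop_gained", "frameshift", "inframe_indel",
    "splice_site", "synonymous", "other")
}

#' Secondary-cause exclusion flags
#'
#' Flags that disqualify a hypouricemic subject from case status: chronic
#' kidney disease, hypertension, diabetes, other metabolic disease, any
#' smoking history, and poor nutrition status.
#'
#' @return Character vector of the six flag labels.
#' @export
exclusion_flag_levels <- function() {
  c("ckd", "hypertension", "diabetes", "metabolic_disease",
    "smoker", "malnutrition")
}

# Chromosome labels treated as X for hemizygosity logic.
x_chrom_labels_default <- function() c("X", "chrX")

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonical variant key: the only identity the pipeline matches on.
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# Stable non-cryptographic hash (31-base polynomial mod 2^31-1) for
# provenance stamps; content fingerprint, not integrity protection.
stable_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# Percent string with fixed decimals; the only rounding used for reports.
percent_string <- function(num, denom, digits = 1) {
  sprintf(paste0("%.", digits, "f%%"), 100 * num / denom)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Split a comma-separated flag string into a character vector ("" -> none).
split_flags <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ",", fixed = TRUE)[[1]]
}
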
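# Internal helpers shared across modules.

# Round half away from zero (printed-table convention; base round() is
# banker's rounding and gives 9.95 -> 9.9).
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Case-folded, whitespace-collapsed comparison key for names.
name_key <- function(x) {
  x <- gsub("\\s+", " ", trimws(x))
  tolower(x)
}

# Collapse internal whitespace but keep original case (first-seen spelling).
squash_ws <- function(x) gsub("\\s+", " ", trimws(x))

# Derive a stage seed from a master seed, staying within 32-bit range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% (.Machine$integer.max - 1L)) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
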
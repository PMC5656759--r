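# Shared internals: codon tables, seeded RNG, small validators.

.pcv <- new.env(parent = emptyenv())

# Standard genetic code (NCBI table 1) as a named character vector.
pcv_code <- function() {
  if (is.null(.pcv$gc)) {
    gc <- Biostrings::GENETIC_CODE
    .pcv$gc <- gc
    .pcv$stop_codons <- names(gc)[gc == "*"]
    .pcv$sense_codons <- names(gc)[gc != "*"]
    .pcv$codons_for <- split(names(gc), unname(gc))
    .pcv$aa <- sort(unique(unname(gc[gc != "*"])))
  }
  .pcv$gc
}

pcv_stop_codons <- function() {
  pcv_code()
  .pcv$stop_codons
}

pcv_sense_codons <- function() {
  pcv_code()
  .pcv$sense_codons
}

# Codons encoding a given amino acid (single-letter).
pcv_codons_for <- function(aa) {
  pcv_code()
  .pcv$codons_for[[aa]]
}

pcv_amino_acids <- function() {
  pcv_code()
  .pcv$aa
}

# Translate a character vector of codons; fuzzy/ambiguous codons become "X".
pcv_translate_codons <- function(codons) {
  gc <- pcv_code()
  out <- unname(gc[codons])
  out[is.na(out)] <- "X"
  out
}

# Evaluate `expr` under a private RNG stream so generators are pure
# functions of their seed and never disturb the caller's RNG state.
pcv_with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

pcv_assert <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Normalize a nucleotide string: uppercase, RNA U mapped to T.
normalize_nt <- function(x) {
  x <- chartr("u", "t", x)
  x <- toupper(x)
  bad <- gsub("[ACGTN]", "", x)
  if (any(nzchar(bad))) {
    stop("sequence contains characters outside {A,C,G,T,N,U}: '",
         substr(bad[nzchar(bad)][1], 1, 10), "'", call. = FALSE)
  }
  x
}
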
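# Coverage summarization and SNP filtering/classification from pileup
# input. Read mapping itself is out of scope: the pileup TSV is the
# contract, produced by the simulator or converted from any mapper.

#' Filter SNPs from a pileup
#'
#' Emits one record per (position, alternative base) whose frequency is
#' strictly above `min_frac` — matching a "present in more than 10 % of
#' reads" rule at the default — with the reference base taken from the
#' genome.
#'
#' @param pileup Pileup data frame (see [read_pileup()]).
#' @param ref_genome A [genome_record()] for the mapped genome.
#' @param min_frac Strict lower bound on the alternative-allele fraction.
#' @param min_depth Minimum depth for a position to be considered.
#' @return A data frame of SNP records: `genome_id`, `pos`, `ref`, `alt`,
#'   `depth`, `alt_frac`, ordered by position then base, independent of
#'   pileup row order.
#' @export
filter_snps <- function(pileup, ref_genome, min_frac = 0.10,
                        min_depth = 1L) {
  pcv_assert(inherits(ref_genome, "genome_record"), "need a genome_record")
  empty <- data.frame(genome_id = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      depth = integer(0), alt_frac = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(pileup) == 0L) return(empty)
  if (!all(pileup$genome_id == ref_genome$id)) {
    stop("pileup genome_id does not match the reference genome",
         call. = FALSE)
  }
  n <- nchar(ref_genome$seq)
  pcv_assert(all(pileup$pos >= 1 & pileup$pos <= n),
             "pileup positions outside the genome")
  bases <- c("A", "C", "G", "T")
  rows <- list()
  keep <- pileup$depth >= min_depth & pileup$depth > 0
  pu <- pileup[keep, , drop = FALSE]
  if (nrow(pu) == 0L) return(empty)
  refs <- substr(rep(ref_genome$seq, nrow(pu)), pu$pos, pu$pos)
  for (b in bases) {
    cnt <- pu[[paste0("count", b)]]
    frac <- cnt / pu$depth
    hit <- b != refs & frac > min_frac
    if (any(hit)) {
      rows[[b]] <- data.frame(genome_id = pu$genome_id[hit],
                              pos = pu$pos[hit], ref = refs[hit], alt = b,
                              depth = pu$depth[hit], alt_frac = frac[hit],
                              stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a SNP by coding effect
#'
#' For each main ORF (ORF1-ORF5; overlapping accessory ORFs ORF2b/ORF3a
#' are excluded from the main tally and classified separately when
#' `include_accessory = TRUE`) containing the position, the affected
#' codon is read in the ORF's frame and the effect is `synonymous` when
#' the substituted codon encodes the same amino acid, `stop_affecting`
#' when the substitution gains or loses a stop codon, otherwise
#' `nonsynonymous`. A SNP inside an ORF-ORF overlap yields one call per
#' containing ORF; a SNP outside all ORFs yields a single `noncoding`
#' call.
#'
#' @param snp One SNP record (single-row data frame or list with
#'   `pos`, `ref`, `alt`).
#' @param layout A `genome_layout` (or `layout_table_row`) for the genome.
#' @param genome A [genome_record()] (or nucleotide string).
#' @param include_accessory Also classify against ORF2b/ORF3a (calls
#'   flagged by `accessory = TRUE`).
#' @return A data frame of calls: `pos`, `ref`, `alt`, `orf_id`,
#'   `codon_index`, `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`,
#'   `effect`, `accessory`.
#' @export
classify_snp <- function(snp, layout, genome, include_accessory = FALSE) {
  if (inherits(genome, "genome_record")) genome <- genome$seq
  genome <- normalize_nt(genome)
  pos <- as.integer(snp$pos)
  ref <- toupper(snp$ref)
  alt <- toupper(snp$alt)
  if (identical(ref, alt)) {
    stop("alt equal to ref at position ", pos, call. = FALSE)
  }
  obs <- substr(genome, pos, pos)
  if (obs != ref) {
    stop(sprintf("reference base mismatch at %d: genome has %s, SNP ref %s",
                 pos, obs, ref), call. = FALSE)
  }
  lc <- layout_coords(layout)
  orf_ids <- names(lc$coords)
  main <- intersect(.main_orfs, orf_ids)
  acc <- setdiff(orf_ids, .main_orfs)
  targets <- c(main, if (include_accessory) acc)
  calls <- list()
  for (orf in targets) {
    co <- lc$coords[[orf]]
    s <- co[["start"]]; e <- co[["end"]]
    if (is.na(s) || is.na(e) || pos < s || pos > e) next
    ci <- (pos - s) %/% 3L
    cstart <- s + 3L * ci
    ref_codon <- substr(genome, cstart, cstart + 2L)
    off <- pos - cstart + 1L
    alt_codon <- ref_codon
    substr(alt_codon, off, off) <- alt
    ref_aa <- pcv_translate_codons(ref_codon)
    alt_aa <- pcv_translate_codons(alt_codon)
    effect <- if (ref_aa == alt_aa) {
      "synonymous"
    } else if (ref_aa == "*" || alt_aa == "*") {
      "stop_affecting"
    } else {
      "nonsynonymous"
    }
    calls[[length(calls) + 1L]] <- data.frame(
      pos = pos, ref = ref, alt = alt, orf_id = orf,
      codon_index = ci + 1L, ref_codon = ref_codon, alt_codon = alt_codon,
      ref_aa = ref_aa, alt_aa = alt_aa, effect = effect,
      accessory = !(orf %in% .main_orfs), stringsAsFactors = FALSE)
  }
  if (length(calls) == 0L) {
    return(data.frame(pos = pos, ref = ref, alt = alt,
                      orf_id = NA_character_, codon_index = NA_integer_,
                      ref_codon = NA_character_, alt_codon = NA_character_,
                      ref_aa = NA_character_, alt_aa = NA_character_,
                      effect = "noncoding", accessory = FALSE,
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' @rdname classify_snp
#' @param snps Data frame of SNP records (e.g. from [filter_snps()]).
#' @export
classify_snps <- function(snps, layout, genome, include_accessory = FALSE) {
  if (nrow(snps) == 0L) {
    return(classify_snp(list(pos = 1L, ref = "A", alt = "C"),
                        layout, "A")[0, ])
  }
  out <- do.call(rbind, lapply(seq_len(nrow(snps)), function(i)
    classify_snp(snps[i, ], layout, genome, include_accessory)))
  rownames(out) <- NULL
  out
}

#' Aggregate SNP calls into per-ORF synonymous/total tallies
#'
#' Produces the "s/t" pairs per main ORF, grand totals over the coding
#' calls, and a separate count of noncoding SNPs. Calls against accessory
#' ORFs (ORF2b/ORF3a) are tallied separately and never enter the main
#' totals.
#'
#' @param calls Data frame of calls from [classify_snp()] (one genome).
#' @return A list: `per_orf` data frame (`orf_id`, `synonymous`, `total`,
#'   `label`), `total_snps`, `total_synonymous`, `noncoding`, and
#'   `accessory` (tally over accessory-ORF calls).
#' @export
aggregate_counts <- function(calls) {
  per <- data.frame(orf_id = .main_orfs, synonymous = 0L, total = 0L,
                    stringsAsFactors = FALSE)
  noncoding <- 0L
  acc_syn <- 0L; acc_tot <- 0L
  if (nrow(calls) > 0L) {
    noncoding <- sum(calls$effect == "noncoding")
    coding <- calls[calls$effect != "noncoding", , drop = FALSE]
    main <- coding[!coding$accessory, , drop = FALSE]
    accc <- coding[coding$accessory, , drop = FALSE]
    for (i in seq_len(nrow(per))) {
      sel <- main$orf_id == per$orf_id[i]
      per$total[i] <- sum(sel)
      per$synonymous[i] <- sum(sel & main$effect == "synonymous")
    }
    acc_tot <- nrow(accc)
    acc_syn <- sum(accc$effect == "synonymous")
  }
  per$label <- sprintf("%d/%d", per$synonymous, per$total)
  list(per_orf = per,
       total_snps = sum(per$total),
       total_synonymous = sum(per$synonymous),
       noncoding = noncoding,
       accessory = list(synonymous = acc_syn, total = acc_tot))
}

#' Coverage summaries from a pileup
#'
#' `coverage_windows()` computes the centered sliding-window mean depth
#' at every genome position, truncating the window at the genome ends;
#' `mean_coverage()` is total mapped depth divided by genome length
#' (positions absent from the pileup count as depth 0).
#'
#' @param pileup Pileup data frame (one genome).
#' @param genome_len Genome length (nt).
#' @param window Window width (nt, >= 1).
#' @return `coverage_windows()`: numeric vector of per-position window
#'   means (length `genome_len`). `mean_coverage()`: a single number.
#' @export
coverage_windows <- function(pileup, genome_len, window = 1000L) {
  pcv_assert(is_scalar_number(window) && window >= 1, "window must be >= 1")
  pcv_assert(is_scalar_number(genome_len) && genome_len >= 1,
             "genome_len must be >= 1")
  depth <- numeric(genome_len)
  if (nrow(pileup) > 0L) {
    pcv_assert(all(pileup$pos >= 1 & pileup$pos <= genome_len),
               "pileup positions outside the genome")
    depth[pileup$pos] <- pileup$depth
  }
  half_lo <- (as.integer(window) - 1L) %/% 2L
  half_hi <- as.integer(window) - 1L - half_lo
  cs <- c(0, cumsum(depth))
  pos <- seq_len(genome_len)
  lo <- pmax(1L, pos - half_lo)
  hi <- pmin(genome_len, pos + half_hi)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' @rdname coverage_windows
#' @export
mean_coverage <- function(pileup, genome_len) {
  pcv_assert(is_scalar_number(genome_len) && genome_len >= 1,
             "genome_len must be >= 1")
  if (nrow(pileup) == 0L) return(0)
  sum(pileup$depth) / genome_len
}
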
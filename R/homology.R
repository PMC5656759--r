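# Translated search, pairwise alignment, and the reciprocal-best-hit
# discovery filter used to retain candidate family members.

#' Translate a nucleotide sequence in a given frame
#'
#' Standard genetic code (NCBI table 1); stops are rendered `*`, the
#' trailing partial codon is dropped, ambiguous codons become `X`.
#' Negative frames translate the reverse complement.
#'
#' @param seq Nucleotide string.
#' @param frame One of `+1, +2, +3, -1, -2, -3`.
#' @return Peptide string.
#' @export
translate_nt <- function(seq, frame = 1L) {
  pcv_assert(frame %in% c(1L, 2L, 3L, -1L, -2L, -3L),
             "frame must be one of +1,+2,+3,-1,-2,-3")
  seq <- normalize_nt(seq)
  if (frame < 0) {
    seq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seq)))
    frame <- -frame
  }
  n <- nchar(seq)
  f <- frame - 1L
  sublen <- n - f
  sublen <- sublen - sublen %% 3L
  if (sublen <= 0L) return("")
  translate_string(substr(seq, f + 1L, f + sublen))
}

#' @rdname translate_nt
#' @return `six_frame_translate()` returns a named character vector of the
#'   six frame translations (`+1, +2, +3, -1, -2, -3`).
#' @export
six_frame_translate <- function(seq) {
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  setNames(vapply(frames, function(f) translate_nt(seq, f), character(1)),
           c("+1", "+2", "+3", "-1", "-2", "-3"))
}

#' Peptide of the longest ORF across all six frames
#'
#' The single longest ATG-initiated, stop-terminated ORF over both strands
#' is translated (stop excluded). Exact length ties prefer the forward
#' strand, then the 5'-most start.
#'
#' @param seq Nucleotide string.
#' @return Peptide string (empty when no ORF exists).
#' @export
longest_orf_peptide <- function(seq) {
  seq <- normalize_nt(seq)
  if (nchar(seq) < 6L) return("")
  fwd <- find_orfs(seq, 6L)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  rev <- find_orfs(rc, 6L)
  if (nrow(fwd) > 0L) fwd$strand <- 0L
  if (nrow(rev) > 0L) rev$strand <- 1L
  all <- rbind(fwd, rev)
  if (nrow(all) == 0L) return("")
  all <- all[order(-all$length_nt, all$strand, all$start), , drop = FALSE]
  all$peptide[1L]
}

align_result <- function(aln, type) {
  p <- as.character(Biostrings::alignedPattern(aln))
  s <- as.character(Biostrings::alignedSubject(aln))
  columns <- nchar(p)
  pc <- strsplit(p, "", fixed = TRUE)[[1]]
  sc <- strsplit(s, "", fixed = TRUE)[[1]]
  identities <- sum(pc == sc & pc != "-")
  structure(
    list(score = Biostrings::score(aln),
         identities = identities,
         columns = columns,
         pct_identity = 100 * identities / columns,
         q_span = c(start = Biostrings::start(Biostrings::pattern(aln)),
                    end = Biostrings::end(Biostrings::pattern(aln))),
         s_span = c(start = Biostrings::start(Biostrings::subject(aln)),
                    end = Biostrings::end(Biostrings::subject(aln))),
         type = type,
         aligned_query = p,
         aligned_subject = s),
    class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result:%s> score %.1f, %d/%d identical (%.1f%%)\n",
              x$type, x$score, x$identities, x$columns, x$pct_identity))
  invisible(x)
}

#' Pairwise peptide alignment
#'
#' Affine-gap Smith-Waterman (`local_align`) and Needleman-Wunsch
#' (`global_align`) optima under BLOSUM62 with gap open 11 / extend 1 (a
#' gap of length L costs `11 + L`). Percent identity uses all alignment
#' columns (gaps included) as the denominator; this convention is stated
#' in the result.
#'
#' @param q,s Non-empty peptide strings.
#' @param matrix Substitution matrix name (a matrix shipped with
#'   Biostrings, e.g. `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return An `alignment_result`: `score`, `identities`, `columns`,
#'   `pct_identity`, query/subject spans (1-based inclusive), and the
#'   aligned strings.
#' @export
local_align <- function(q, s, matrix = "BLOSUM62", gap_open = 11,
                        gap_extend = 1) {
  pcv_assert(nzchar(q) && nzchar(s), "peptides must be non-empty")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(q), Biostrings::AAString(s),
    substitutionMatrix = matrix, gapOpening = gap_open,
    gapExtension = gap_extend, type = "local")
  align_result(aln, "local")
}

#' @rdname local_align
#' @export
global_align <- function(q, s, matrix = "BLOSUM62", gap_open = 11,
                         gap_extend = 1) {
  pcv_assert(nzchar(q) && nzchar(s), "peptides must be non-empty")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(q), Biostrings::AAString(s),
    substitutionMatrix = matrix, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  align_result(aln, "global")
}

# Score-only local alignment (fast path for ranking).
local_score <- function(q, s, matrix = "BLOSUM62", gap_open = 11,
                        gap_extend = 1) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(q), Biostrings::AAString(s),
    substitutionMatrix = matrix, gapOpening = gap_open,
    gapExtension = gap_extend, type = "local", scoreOnly = TRUE)
}

#' Karlin-Altschul expectation value
#'
#' `E = K * m * n * exp(-lambda * score)` with the standard gapped
#' BLOSUM62 constants as defaults. Here the E-value is a thresholding
#' device for the discovery filter, not a calibrated statistic: the
#' constants are fixed, not fitted.
#'
#' @param score Raw alignment score.
#' @param m,n Query and database lengths (>= 1).
#' @param lambda,K Karlin-Altschul parameters.
#' @return Expectation value (monotone decreasing in `score`).
#' @export
evalue <- function(score, m, n, lambda = 0.267, K = 0.041) {
  pcv_assert(all(m >= 1) && all(n >= 1), "m and n must be >= 1")
  K * m * n * exp(-lambda * score)
}

#' Search a peptide against a panel
#'
#' Locally aligns the query against every panel member and returns one hit
#' record per member, ranked by score (descending), with ties broken by
#' percent identity (descending) then subject id (ascending).
#'
#' @param query_peptide Query peptide string.
#' @param panel Named character vector of panel peptides (names are ids),
#'   or a list of `(id, peptide)` pairs.
#' @param query_id Id recorded in the hit records.
#' @param identity Compute full alignments (identity, aligned length) for
#'   every member; when `FALSE` only scores are computed (fast path) and
#'   identity columns are `NA`.
#' @return A data frame of hit records (`query_id`, `subject_id`,
#'   `pct_identity`, `aln_len`, `score`, `evalue`), best hit first.
#' @export
search_panel <- function(query_peptide, panel, query_id = "query",
                         identity = TRUE) {
  panel <- as_panel(panel)
  pcv_assert(length(panel) > 0L, "panel must be non-empty")
  n_db <- sum(nchar(panel))
  m <- nchar(query_peptide)
  rows <- lapply(names(panel), function(id) {
    if (identity) {
      al <- local_align(query_peptide, panel[[id]])
      data.frame(query_id = query_id, subject_id = id,
                 pct_identity = al$pct_identity, aln_len = al$columns,
                 score = al$score, evalue = evalue(al$score, m, n_db),
                 stringsAsFactors = FALSE)
    } else {
      sc <- local_score(query_peptide, panel[[id]])
      data.frame(query_id = query_id, subject_id = id,
                 pct_identity = NA_real_, aln_len = NA_integer_,
                 score = sc, evalue = evalue(sc, m, n_db),
                 stringsAsFactors = FALSE)
    }
  })
  df <- do.call(rbind, rows)
  key_pct <- ifelse(is.na(df$pct_identity), -1, df$pct_identity)
  df <- df[order(-df$score, -key_pct, df$subject_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

as_panel <- function(panel) {
  if (is.character(panel)) {
    pcv_assert(!is.null(names(panel)) && all(nzchar(names(panel))),
               "panel must be named")
    return(as.list(panel))
  }
  if (is.list(panel)) {
    if (length(panel) == 0L) return(list())
    if (!is.null(names(panel)) && all(nzchar(names(panel)))) {
      return(lapply(panel, as.character))
    }
    ids <- vapply(panel, function(p) p[[1]], character(1))
    peps <- lapply(panel, function(p) p[[2]])
    return(setNames(peps, ids))
  }
  stop("panel must be a named character vector or list", call. = FALSE)
}

#' Reciprocal-best-hit discovery filter
#'
#' Reimplements the contig-retention procedure used to mine transcriptome
#' assemblies for family members. Per candidate genome: (i) discard if
#' shorter than `min_len_nt` (`too_short`); (ii) search the candidate's
#' longest-ORF peptide against the panel — if the best hit is not in
#' `reference_set`, discard (`wrong_best_target`, the fate of iflavirus-
#' and dicistrovirus-matching contigs); the forward best hit must also
#' clear the E-value and aligned-length thresholds (`no_hit` otherwise);
#' (iii) search the best panel member's peptide back against the
#' candidates plus the rest of the panel — the candidate is retained
#' (`reciprocal_best`) only when every entry ranking above it belongs to
#' the reference set.
#'
#' Verdicts are invariant under candidate input order: candidates are
#' processed independently.
#'
#' @param candidates List of [genome_record()] objects (or named character
#'   vector of sequences).
#' @param reference_set Character vector of panel ids considered "the
#'   reference" (e.g. the type species).
#' @param panel Named peptide panel (reference members plus decoys).
#' @param min_len_nt Minimum candidate length.
#' @param evalue_max Maximum forward-hit E-value.
#' @param min_cds_nt Minimum forward-hit aligned length, in nucleotide
#'   equivalents (aa columns * 3).
#' @return A data frame with one row per candidate: `candidate_id`,
#'   `fwd_best`, `fwd_score`, `fwd_evalue`, `fwd_aln_nt`, `rev_best`,
#'   `retained`, `reason`.
#' @export
rbh_filter <- function(candidates, reference_set, panel,
                       min_len_nt = 10000L, evalue_max = 1e-6,
                       min_cds_nt = 300L) {
  panel <- as_panel(panel)
  pcv_assert(length(panel) > 0L, "panel must be non-empty")
  pcv_assert(all(reference_set %in% names(panel)),
             "reference_set members must be in the panel")
  if (is.character(candidates)) {
    candidates <- lapply(names(candidates), function(id)
      genome_record(id, candidates[[id]]))
  }
  cand_ids <- vapply(candidates, function(r) r$id, character(1))
  cand_peps <- setNames(lapply(candidates, function(r)
    longest_orf_peptide(r$seq)), cand_ids)
  rows <- lapply(candidates, function(rec) {
    out <- data.frame(candidate_id = rec$id, fwd_best = NA_character_,
                      fwd_score = NA_real_, fwd_evalue = NA_real_,
                      fwd_aln_nt = NA_integer_, rev_best = NA_character_,
                      retained = FALSE, reason = NA_character_,
                      stringsAsFactors = FALSE)
    if (nchar(rec$seq) < min_len_nt) {
      out$reason <- "too_short"
      return(out)
    }
    qpep <- cand_peps[[rec$id]]
    if (!nzchar(qpep)) {
      out$reason <- "no_hit"
      return(out)
    }
    fwd <- search_panel(qpep, panel, query_id = rec$id, identity = FALSE)
    best <- fwd[1L, ]
    out$fwd_best <- best$subject_id
    out$fwd_score <- best$score
    if (!(best$subject_id %in% reference_set)) {
      out$reason <- "wrong_best_target"
      return(out)
    }
    al <- local_align(qpep, panel[[best$subject_id]])
    out$fwd_evalue <- evalue(al$score, nchar(qpep), sum(nchar(panel)))
    out$fwd_aln_nt <- 3L * al$columns
    if (out$fwd_evalue > evalue_max || out$fwd_aln_nt < min_cds_nt) {
      out$reason <- "no_hit"
      return(out)
    }
    # Reciprocal: the best reference member searches the candidate set
    # plus the rest of the panel, so a reference is free to "choose" a
    # decoy over the candidate.
    db <- c(cand_peps, panel[setdiff(names(panel), best$subject_id)])
    db <- db[nzchar(unlist(db))]
    rev <- search_panel(panel[[best$subject_id]], db,
                        query_id = best$subject_id, identity = FALSE)
    out$rev_best <- rev$subject_id[1L]
    above <- character(0)
    pos <- match(rec$id, rev$subject_id)
    if (!is.na(pos) && pos > 1L) above <- rev$subject_id[seq_len(pos - 1L)]
    ok <- !is.na(pos) && all(above %in% c(reference_set, cand_ids[
      cand_ids == rec$id]))
    if (ok) {
      out$retained <- TRUE
      out$reason <- "reciprocal_best"
    } else {
      out$reason <- "wrong_best_target"
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
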
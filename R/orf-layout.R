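# ORF enumeration and inference of the family-characteristic polycistronic
# layout: four closely spaced (often overlapping) 5' ORFs, an intergenic
# region, and one long 3' ORF carrying the Hel/Pro/RdRp polyprotein.

# Translate a nucleotide string (length a multiple of 3) to a peptide
# string via a vectorized lookup of the standard code table; ambiguous
# codons become "X", stops are "*".
translate_string <- function(nt) {
  n <- nchar(nt)
  if (n < 3L) return("")
  codons <- substring(nt, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
  paste(pcv_translate_codons(codons), collapse = "")
}

#' Strip a trailing poly(A) tail
#'
#' Removes the trailing run of `A` when it is at least `min_run` long,
#' records the removed length in `polya_trimmed_len`, and flags the record
#' as extending to the poly(A) tail. Idempotent on already-stripped
#' records.
#'
#' @param record A [genome_record()].
#' @param min_run Minimum run of trailing `A` treated as a tail (>= 1).
#' @return The record, possibly with the tail removed.
#' @export
strip_polya <- function(record, min_run = 10L) {
  pcv_assert(inherits(record, "genome_record"), "need a genome_record")
  pcv_assert(is_scalar_number(min_run) && min_run >= 1, "min_run must be >= 1")
  m <- regexpr("A+$", record$seq)
  if (m > 0) {
    run <- attr(m, "match.length")
    if (run >= min_run) {
      record$seq <- substr(record$seq, 1L, m - 1L)
      record$polya_trimmed_len <- record$polya_trimmed_len + as.integer(run)
      record$extends_to_polya <- TRUE
    }
  }
  record
}

#' Enumerate forward-strand open reading frames
#'
#' Finds every ATG-initiated, stop-terminated span of at least `min_len_nt`
#' nucleotides in the three forward frames. For each (frame, stop codon)
#' pair only the longest span — the one starting at the 5'-most ATG — is
#' kept. Coordinates are 1-based inclusive and include the stop codon.
#'
#' @param seq Nucleotide string (normalized on entry).
#' @param min_len_nt Minimum ORF length in nucleotides; must be a multiple
#'   of 3.
#' @return A data frame sorted by `start` with columns `start`, `end`,
#'   `frame` (0/1/2, equal to `(start - 1) %% 3`), `length_nt` and
#'   `peptide` (stop symbol excluded). Zero rows when nothing qualifies.
#' @export
find_orfs <- function(seq, min_len_nt = 150L) {
  pcv_assert(is_scalar_number(min_len_nt) && min_len_nt >= 6 &&
               min_len_nt %% 3 == 0,
             "min_len_nt must be a positive multiple of 3 (>= 6)")
  seq <- normalize_nt(seq)
  n <- nchar(seq)
  empty <- data.frame(start = integer(0), end = integer(0),
                      frame = integer(0), length_nt = integer(0),
                      peptide = character(0), stringsAsFactors = FALSE)
  out <- list()
  for (f in 0:2) {
    sublen <- n - f
    sublen <- sublen - sublen %% 3L
    if (sublen < min_len_nt) next
    pep <- translate_string(substr(seq, f + 1L, f + sublen))
    chars <- strsplit(pep, "", fixed = TRUE)[[1]]
    stops <- which(chars == "*")
    ms <- which(chars == "M")
    if (length(stops) == 0L || length(ms) == 0L) next
    prev <- c(0L, stops[-length(stops)])
    idx <- findInterval(prev, ms) + 1L
    mstart <- ifelse(idx <= length(ms), ms[idx], NA_integer_)
    keep <- !is.na(mstart) & mstart < stops
    mstart <- mstart[keep]
    sp <- stops[keep]
    len_nt <- 3L * (sp - mstart + 1L)
    long <- len_nt >= min_len_nt
    if (!any(long)) next
    mstart <- mstart[long]; sp <- sp[long]; len_nt <- len_nt[long]
    out[[length(out) + 1L]] <- data.frame(
      start = f + 3L * (mstart - 1L) + 1L,
      end = f + 3L * sp,
      frame = f,
      length_nt = len_nt,
      peptide = substr(rep(pep, length(mstart)), mstart, sp - 1L),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Test for the 5'-completeness signature
#'
#' Complete genomes in the family begin with a 5'-terminal `UUU` followed
#' by an AU-rich tract. The test is `TRUE` when the sequence starts with
#' `TTT` (DNA alphabet) and the A+T fraction of the first `window`
#' nucleotides is at least `au_frac`.
#'
#' @param seq Nucleotide string of length >= `window`.
#' @param window Prefix length examined (nt).
#' @param au_frac Minimum A+T fraction over the prefix.
#' @return Logical scalar.
#' @export
five_prime_signature <- function(seq, window = 25L, au_frac = 0.7) {
  seq <- normalize_nt(seq)
  pcv_assert(nchar(seq) >= window, "sequence shorter than signature window")
  if (substr(seq, 1L, 3L) != "TTT") return(FALSE)
  prefix <- strsplit(substr(seq, 1L, window), "", fixed = TRUE)[[1]]
  mean(prefix %in% c("A", "T")) >= au_frac
}

.main_orfs <- c("ORF1", "ORF2", "ORF3", "ORF4", "ORF5")

# Extract a named list of c(start, end) per ORF plus seq_len from either a
# layout_table_row or a genome_layout.
layout_coords <- function(x) {
  if (inherits(x, "layout_table_row")) {
    list(coords = x$orf_coords, seq_len = x$seq_len, id = x$name)
  } else if (inherits(x, "genome_layout")) {
    coords <- lapply(seq_len(nrow(x$orfs)), function(i)
      c(start = x$orfs$start[i], end = x$orfs$end[i]))
    names(coords) <- x$orfs$orf_id
    list(coords = coords, seq_len = x$seq_len, id = x$genome_id)
  } else {
    stop("need a layout_table_row or genome_layout", call. = FALSE)
  }
}

# Map a start-position difference relative to ORF5 onto the display
# convention used in the family's genome maps: 0 -> 0, 1 -> +1, 2 -> -1.
frame_offset_vs <- function(start, orf5_start) {
  d <- (start - orf5_start) %% 3
  c(`0` = 0L, `1` = 1L, `2` = -1L)[as.character(d)]
}

#' Layout summary statistics
#'
#' Applies the layout arithmetic verbatim: `utr5 = ORF1.start - 1`,
#' `utr3 = seq_len - ORF5.end`, `igr = ORF5.start - ORF4.end - 1`,
#' junction gaps `ORFk+1.start - ORFk.end - 1` between consecutive main
#' ORFs 1..4 (negative values are overlaps), and reading-frame offsets of
#' every annotated ORF relative to ORF5. Statistics whose coordinates are
#' missing come back as `NA`, never as 0.
#'
#' @param x A `layout_table_row` (from [read_layout_table()]) or a
#'   `genome_layout` (from [infer_layout()]).
#' @return A list with `utr5_len`, `utr3_len`, `igr_len`, `junction_gaps`
#'   (named numeric: `ORF1-ORF2`, `ORF2-ORF3`, `ORF3-ORF4`) and
#'   `frame_offsets` (named integer vector).
#' @export
layout_stats <- function(x) {
  lc <- layout_coords(x)
  co <- lc$coords
  g <- function(orf, what) {
    if (is.null(co[[orf]])) return(NA_integer_)
    v <- co[[orf]][[what]]
    if (is.null(v)) NA_integer_ else as.integer(v)
  }
  utr5 <- if (!is.na(g("ORF1", "start"))) g("ORF1", "start") - 1L else NA_integer_
  utr3 <- if (!is.na(g("ORF5", "end"))) lc$seq_len - g("ORF5", "end") else NA_integer_
  igr <- if (!is.na(g("ORF5", "start")) && !is.na(g("ORF4", "end")))
    g("ORF5", "start") - g("ORF4", "end") - 1L else NA_integer_
  if (!is.na(igr) && igr < 0) {
    stop(sprintf("%s: ORF4 and ORF5 overlap (negative intergenic region)",
                 lc$id), call. = FALSE)
  }
  gaps <- vapply(1:3, function(k) {
    a <- g(.main_orfs[k], "end"); b <- g(.main_orfs[k + 1L], "start")
    if (is.na(a) || is.na(b)) NA_integer_ else b - a - 1L
  }, integer(1))
  names(gaps) <- paste0(.main_orfs[1:3], "-", .main_orfs[2:4])
  s5 <- g("ORF5", "start")
  offs <- if (is.na(s5)) {
    setNames(integer(0), character(0))
  } else {
    present <- names(co)[!vapply(co, function(v) is.na(v[["start"]]), logical(1))]
    setNames(vapply(present, function(orf)
      frame_offset_vs(co[[orf]][["start"]], s5), integer(1)), present)
  }
  list(utr5_len = utr5, utr3_len = utr3, igr_len = igr,
       junction_gaps = gaps, frame_offsets = offs)
}

new_genome_layout <- function(genome_id, seq_len, orfs, status,
                              orf5_motifs_found = NA,
                              five_prime_signature = NA,
                              extends_to_polya = NA,
                              evidence = character(0)) {
  lay <- structure(
    list(genome_id = genome_id, seq_len = as.integer(seq_len), orfs = orfs,
         status = status, orf5_motifs_found = orf5_motifs_found,
         utr5_len = NA_integer_, utr3_len = NA_integer_,
         igr_len = NA_integer_,
         junction_gaps = setNames(rep(NA_integer_, 3),
                                  paste0(.main_orfs[1:3], "-",
                                         .main_orfs[2:4])),
         five_prime_signature = five_prime_signature,
         extends_to_polya = extends_to_polya,
         evidence = evidence),
    class = "genome_layout")
  if (!is.null(orfs) && nrow(orfs) > 0L && "ORF5" %in% orfs$orf_id) {
    st <- layout_stats(lay)
    lay$utr5_len <- st$utr5_len
    lay$utr3_len <- st$utr3_len
    lay$igr_len <- st$igr_len
    lay$junction_gaps <- st$junction_gaps
  }
  lay
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("<genome_layout> %s (%d nt), status: %s\n", x$genome_id,
              x$seq_len, x$status))
  if (!is.null(x$orfs) && nrow(x$orfs) > 0L) {
    print(x$orfs[, c("orf_id", "start", "end", "length_nt",
                     "frame_offset_vs_orf5")])
  }
  cat(sprintf("5'UTR %s nt | IGR %s nt | 3'UTR %s nt\n",
              x$utr5_len, x$igr_len, x$utr3_len))
  invisible(x)
}

# Deterministic chain selection: pick the chain of four candidate ORFs
# upstream of ORF5 maximizing total coding length, each junction gap within
# [-max_overlap, max_gap]. At most one junction may exceed max_gap when an
# intervening short "bridge" ORF (reported as ORF3a-style extra ORF) links
# the two sides and extra_orf_allowed is TRUE.
select_chain <- function(cands, max_gap, max_overlap, extra_orf_allowed) {
  m <- nrow(cands)
  if (m < 4L) return(NULL)
  gap <- outer(seq_len(m), seq_len(m), function(i, j)
    cands$start[j] - cands$end[i] - 1L)
  ordered <- outer(seq_len(m), seq_len(m), function(i, j)
    cands$start[j] > cands$start[i] & cands$end[j] > cands$end[i])
  direct <- ordered & gap >= -max_overlap & gap <= max_gap
  bridge_of <- matrix(NA_integer_, m, m)
  bridged <- matrix(FALSE, m, m)
  if (extra_orf_allowed) {
    for (i in seq_len(m)) for (j in seq_len(m)) {
      if (!ordered[i, j] || gap[i, j] <= max_gap) next
      ok <- which(ordered[i, ] & ordered[, j] &
                    gap[i, ] >= -max_overlap & gap[i, ] <= max_gap &
                    gap[, j] >= -max_overlap & gap[, j] <= max_gap &
                    cands$length_nt < pmin(cands$length_nt[i],
                                           cands$length_nt[j]))
      if (length(ok) > 0L) {
        ok <- ok[order(-cands$length_nt[ok], cands$start[ok])][1]
        bridged[i, j] <- TRUE
        bridge_of[i, j] <- ok
      }
    }
  }
  # dp[k, j, b]: best total length of a k-ORF chain ending at j having used
  # b bridges (b in 0:1); predecessor arrays for traceback.
  NEG <- -1e18
  dp <- array(NEG, dim = c(4L, m, 2L))
  pred <- array(NA_integer_, dim = c(4L, m, 2L))
  dp[1L, , 1L] <- cands$length_nt
  for (k in 2:4) {
    for (j in seq_len(m)) {
      for (b in 1:2) {
        best <- NEG; bi <- NA_integer_
        for (i in seq_len(m)) {
          v <- NEG
          if (direct[i, j] && dp[k - 1L, i, b] > NEG) {
            v <- dp[k - 1L, i, b] + cands$length_nt[j]
          } else if (b == 2L && bridged[i, j] && dp[k - 1L, i, 1L] > NEG) {
            v <- dp[k - 1L, i, 1L] + cands$length_nt[j]
          }
          if (v > best || (v == best && !is.na(bi) && i < bi)) {
            if (v > NEG) { best <- v; bi <- i }
          }
        }
        dp[k, j, b] <- best
        pred[k, j, b] <- bi
      }
    }
  }
  best <- NEG; bj <- NA_integer_; bb <- NA_integer_
  for (b in 1:2) for (j in seq_len(m)) {
    if (dp[4L, j, b] > best ||
        (dp[4L, j, b] == best && !is.na(bj) &&
         (cands$start[j] < cands$start[bj]))) {
      if (dp[4L, j, b] > NEG) { best <- dp[4L, j, b]; bj <- j; bb <- b }
    }
  }
  if (is.na(bj)) return(NULL)
  chain <- integer(4L); chain[4L] <- bj
  b <- bb
  for (k in 4:2) {
    i <- pred[k, chain[k], b]
    if (b == 2L && !direct[i, chain[k]] && bridged[i, chain[k]]) b <- 1L
    chain[k - 1L] <- i
  }
  bridge_idx <- NA_integer_; bridge_junction <- NA_integer_
  for (k in 1:3) {
    i <- chain[k]; j <- chain[k + 1L]
    if (!direct[i, j]) {
      bridge_idx <- bridge_of[i, j]
      bridge_junction <- k
    }
  }
  list(chain = chain, bridge_idx = bridge_idx,
       bridge_junction = bridge_junction)
}

#' Infer the polycistronic genome layout
#'
#' Identifies ORF5 as the longest ORF whose polypeptide carries helicase,
#' protease and polymerase motifs in that order (falling back to the
#' longest ORF, flagged, when no candidate has the motif complement), then
#' selects ORF1-ORF4 as the chain of four upstream ORFs maximizing total
#' coding length subject to every junction gap lying in
#' `[-max_overlap, max_gap]`. One junction may exceed `max_gap` when a
#' short intervening ORF bridges it (reported as `ORF3a`), mirroring
#' genomes with an extra ORF between ORF2 and ORF3. When no qualifying
#' chain exists the returned layout carries status
#' `"not_polycipivirus_like"` with the partial evidence rather than an
#' error.
#'
#' The result is invariant to the presence or length of a 3' poly(A) tail:
#' the record is poly(A)-stripped internally.
#'
#' @param record A [genome_record()] (or a plain nucleotide string).
#' @param scan_provider Function mapping a peptide to a
#'   [scan_motifs()]-style result; defaults to scanning with the packaged
#'   motif library.
#' @param max_gap Maximum junction gap between consecutive 5' ORFs (nt).
#' @param max_overlap Maximum junction overlap (nt).
#' @param extra_orf_allowed Allow one bridged junction (see above).
#' @param min_orf_nt Minimum ORF length passed to [find_orfs()].
#' @return A `genome_layout`: annotated ORFs with frame offsets relative
#'   to ORF5, UTR/IGR statistics, junction gaps, the 5' completeness
#'   signature, and a status flag.
#' @export
infer_layout <- function(record, scan_provider = NULL, max_gap = 60L,
                         max_overlap = 20L, extra_orf_allowed = TRUE,
                         min_orf_nt = 150L) {
  if (is.character(record)) record <- genome_record("genome", record)
  pcv_assert(inherits(record, "genome_record"), "need a genome_record")
  record <- strip_polya(record)
  if (is.null(scan_provider)) {
    lib <- default_motif_library()
    scan_provider <- function(pep) scan_motifs(pep, lib)
  }
  seq <- record$seq
  n <- nchar(seq)
  sig <- if (n >= 25L) five_prime_signature(seq) else FALSE
  cands <- find_orfs(seq, min_orf_nt)
  fail <- function(evidence, orfs = NULL) {
    if (is.null(orfs)) {
      orfs <- data.frame(orf_id = character(0), start = integer(0),
                         end = integer(0), frame_offset_vs_orf5 = integer(0),
                         length_nt = integer(0), peptide = character(0),
                         stringsAsFactors = FALSE)
    }
    new_genome_layout(record$id, n, orfs, "not_polycipivirus_like",
                      orf5_motifs_found = FALSE,
                      five_prime_signature = sig,
                      extends_to_polya = record$extends_to_polya,
                      evidence = evidence)
  }
  if (nrow(cands) == 0L) return(fail("no ORFs found"))
  ord <- order(-cands$length_nt, cands$start)
  orf5_idx <- NA_integer_
  motifs_found <- FALSE
  for (i in ord) {
    sc <- scan_provider(cands$peptide[i])
    if (all(sc$domains_present) && isTRUE(sc$ordered_ok)) {
      orf5_idx <- i; motifs_found <- TRUE; break
    }
  }
  if (is.na(orf5_idx)) orf5_idx <- ord[1]
  s5 <- cands$start[orf5_idx]
  upstream <- cands[cands$end < s5, , drop = FALSE]
  sel <- select_chain(upstream, max_gap, max_overlap, extra_orf_allowed)
  if (is.null(sel)) {
    orf5row <- cands[orf5_idx, , drop = FALSE]
    orf5row$orf_id <- "ORF5"
    orf5row$frame_offset_vs_orf5 <- 0L
    ev <- c(if (!motifs_found) "orf5_motifs_missing" else "orf5_motifs_ok",
            sprintf("upstream_candidates=%d", nrow(upstream)),
            "no_four_orf_chain")
    return(fail(ev, orf5row[, c("orf_id", "start", "end",
                                "frame_offset_vs_orf5", "length_nt",
                                "peptide")]))
  }
  rows <- upstream[sel$chain, , drop = FALSE]
  rows$orf_id <- paste0("ORF", 1:4)
  if (!is.na(sel$bridge_idx)) {
    br <- upstream[sel$bridge_idx, , drop = FALSE]
    br$orf_id <- paste0("ORF", sel$bridge_junction + 1L, "a")
    rows <- rbind(rows, br)
  }
  orf5row <- cands[orf5_idx, , drop = FALSE]
  orf5row$orf_id <- "ORF5"
  rows <- rbind(rows, orf5row)
  rows <- rows[order(rows$start, rows$end), , drop = FALSE]
  rows$frame_offset_vs_orf5 <- vapply(rows$start, frame_offset_vs,
                                      integer(1), orf5_start = s5)
  rows <- rows[, c("orf_id", "start", "end", "frame_offset_vs_orf5",
                   "length_nt", "peptide")]
  rownames(rows) <- NULL
  new_genome_layout(record$id, n, rows, "polycipivirus_like",
                    orf5_motifs_found = motifs_found,
                    five_prime_signature = sig,
                    extends_to_polya = record$extends_to_polya,
                    evidence = if (motifs_found) "orf5_motifs_ok"
                               else "orf5_motifs_missing")
}

#' Detect the overlapping ORF2b gene
#'
#' ORF2b overlaps the 5' end of ORF2 in the +1 frame relative to ORF2 and
#' encodes a small protein with a predicted transmembrane helix near the
#' middle of its sequence. A candidate must start within
#' `max_start_offset` nt of the ORF2 start, satisfy
#' `(start - ORF2.start) %% 3 == 1`, be at least `min_len_nt` long, end at
#' or before `ORF2.end + max_gap`, and have a central transmembrane
#' prediction. The longest qualifying candidate (earliest on ties) is
#' returned.
#'
#' @param layout A `genome_layout` containing ORF2.
#' @param seq The genome sequence the layout was inferred from.
#' @param tm_predictor Function mapping a peptide to a prediction with a
#'   `has_central_tm` flag; defaults to the Kyte-Doolittle predictor
#'   ([predict_tm()] over [hydropathy_profile()]).
#' @param max_start_offset Maximum offset of the ORF2b start from the ORF2
#'   start (nt).
#' @param min_len_nt Minimum ORF2b length (nt).
#' @param max_gap Slack allowed past the ORF2 end (nt).
#' @return A one-row ORF annotation data frame, or `NULL` when absent.
#' @export
detect_orf2b <- function(layout, seq, tm_predictor = NULL,
                         max_start_offset = 120L, min_len_nt = 200L,
                         max_gap = 60L) {
  pcv_assert(inherits(layout, "genome_layout"), "need a genome_layout")
  orfs <- layout$orfs
  pcv_assert("ORF2" %in% orfs$orf_id, "layout has no ORF2")
  if (is.null(tm_predictor)) {
    tm_predictor <- function(pep) predict_tm(hydropathy_profile(pep))
  }
  seq <- normalize_nt(seq)
  s2 <- orfs$start[orfs$orf_id == "ORF2"]
  e2 <- orfs$end[orfs$orf_id == "ORF2"]
  cands <- find_orfs(seq, 150L)
  keep <- cands$start > s2 &
    cands$start <= s2 + max_start_offset &
    (cands$start - s2) %% 3L == 1L &
    cands$length_nt >= min_len_nt &
    cands$end <= e2 + max_gap
  cands <- cands[keep, , drop = FALSE]
  if (nrow(cands) == 0L) return(NULL)
  tm_ok <- vapply(cands$peptide, function(p) isTRUE(tm_predictor(p)$has_central_tm),
                  logical(1))
  cands <- cands[tm_ok, , drop = FALSE]
  if (nrow(cands) == 0L) return(NULL)
  cands <- cands[order(-cands$length_nt, cands$start), , drop = FALSE]
  out <- cands[1L, , drop = FALSE]
  out$orf_id <- "ORF2b"
  s5 <- orfs$start[orfs$orf_id == "ORF5"]
  out$frame_offset_vs_orf5 <- if (length(s5) == 1L)
    frame_offset_vs(out$start, s5) else NA_integer_
  rownames(out) <- NULL
  out[, c("orf_id", "start", "end", "frame_offset_vs_orf5", "length_nt",
          "peptide")]
}

#' Add a detected ORF2b annotation to a layout
#'
#' @param layout A `genome_layout`.
#' @param orf2b A one-row annotation from [detect_orf2b()] (or `NULL`,
#'   returned unchanged).
#' @return The layout with the ORF2b row merged into `orfs`.
#' @export
add_orf2b <- function(layout, orf2b) {
  if (is.null(orf2b)) return(layout)
  orfs <- rbind(layout$orfs, orf2b)
  orfs <- orfs[order(orfs$start, orfs$end), , drop = FALSE]
  rownames(orfs) <- NULL
  layout$orfs <- orfs
  layout
}

#' Construct a genome layout from explicit coordinates
#'
#' Builds a `genome_layout` from user-supplied ORF coordinates (e.g.
#' curated annotations or coordinates read back from GFF3) without
#' running inference. Peptides are translated from `seq` when given.
#'
#' @param genome_id Genome identifier.
#' @param seq_len Genome length in nt (poly(A) excluded).
#' @param orfs Data frame with columns `orf_id`, `start`, `end`
#'   (1-based inclusive, stop codon included).
#' @param seq Optional genome sequence used to fill peptides.
#' @return A `genome_layout` with status `"manual"`.
#' @export
genome_layout <- function(genome_id, seq_len, orfs, seq = NULL) {
  pcv_assert(is.data.frame(orfs) &&
               all(c("orf_id", "start", "end") %in% names(orfs)),
             "orfs must have columns orf_id, start, end")
  pcv_assert(all(orfs$start >= 1 & orfs$start < orfs$end &
                   orfs$end <= seq_len),
             "ORF coordinates out of range")
  bad <- (orfs$end - orfs$start + 1L) %% 3L != 0L
  if (any(bad)) {
    stop(sprintf("%s: length not a multiple of 3", orfs$orf_id[bad][1]),
         call. = FALSE)
  }
  orfs <- orfs[order(orfs$start, orfs$end), , drop = FALSE]
  orfs$length_nt <- orfs$end - orfs$start + 1L
  s5 <- orfs$start[orfs$orf_id == "ORF5"]
  orfs$frame_offset_vs_orf5 <- if (length(s5) == 1L) {
    vapply(orfs$start, frame_offset_vs, integer(1), orf5_start = s5)
  } else {
    NA_integer_
  }
  orfs$peptide <- if (!is.null(seq)) {
    seq <- normalize_nt(seq)
    vapply(seq_len(nrow(orfs)), function(i)
      translate_string(substr(seq, orfs$start[i], orfs$end[i] - 3L)),
      character(1))
  } else {
    NA_character_
  }
  rownames(orfs) <- NULL
  new_genome_layout(genome_id, seq_len,
                    orfs[, c("orf_id", "start", "end",
                             "frame_offset_vs_orf5", "length_nt",
                             "peptide")],
                    "manual")
}
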
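# Sequence and table I/O. One coordinate convention throughout the
# package: 1-based, inclusive, with the stop codon included in every ORF.

#' Create a genome record
#'
#' A lightweight container for an identified nucleotide sequence. The
#' sequence is normalized to the uppercase DNA alphabet (`U` mapped to `T`);
#' `polya_trimmed_len` records how many trailing poly(A) nucleotides have
#' been removed, so the original deposit length is
#' `nchar(seq) + polya_trimmed_len`.
#'
#' @param id Accession-like identifier.
#' @param seq Nucleotide string over `{A,C,G,T,N}` (lowercase and `U`
#'   accepted and normalized).
#' @param description Free-text description.
#' @param polya_trimmed_len Number of trailing poly(A) nucleotides already
#'   removed from `seq` (non-negative integer).
#' @param extends_to_polya Logical; `TRUE` when the deposit ran into the
#'   3' poly(A) tail (set by [strip_polya()]).
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(id, seq, description = "", polya_trimmed_len = 0L,
                          extends_to_polya = FALSE) {
  pcv_assert(is.character(id) && length(id) == 1L && nzchar(id),
             "'id' must be a non-empty string")
  pcv_assert(is_scalar_number(polya_trimmed_len) && polya_trimmed_len >= 0,
             "'polya_trimmed_len' must be a non-negative number")
  structure(
    list(id = id,
         description = as.character(description),
         seq = unname(normalize_nt(seq)),
         polya_trimmed_len = as.integer(polya_trimmed_len),
         extends_to_polya = isTRUE(extends_to_polya)),
    class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s (%d nt%s)\n", x$id, nchar(x$seq),
              if (x$polya_trimmed_len > 0)
                sprintf(", %d nt poly(A) trimmed", x$polya_trimmed_len)
              else ""))
  invisible(x)
}

#' Read a FASTA file into genome records
#'
#' Sequences are normalized on read: lowercase to uppercase and RNA `U` to
#' `T`. Record order follows file order; the record id is the first
#' whitespace-delimited token of the header, the remainder becomes the
#' description.
#'
#' @param path Path to a FASTA file.
#' @return A list of [genome_record()] objects (empty list for an empty
#'   file).
#' @export
read_fasta <- function(path) {
  pcv_assert(file.exists(path), paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || all(!nzchar(trimws(lines)))) return(list())
  first <- which(nzchar(trimws(lines)))[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("malformed FASTA: expected '>' header at line ", first, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  seqs <- as.character(set)
  lapply(seq_along(set), function(i) {
    toks <- strsplit(headers[i], "\\s+")[[1]]
    genome_record(id = toks[1],
                  seq = seqs[i],
                  description = paste(toks[-1], collapse = " "))
  })
}

#' Write sequences to FASTA
#'
#' @param x A list of [genome_record()] objects, or a named character
#'   vector of sequences (nucleotide or peptide).
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.list(x) && length(x) > 0L && inherits(x[[1]], "genome_record")) {
    seqs <- vapply(x, function(r) r$seq, character(1))
    ids <- vapply(x, function(r) {
      if (nzchar(r$description)) paste(r$id, r$description) else r$id
    }, character(1))
    names(seqs) <- ids
  } else if (is.character(x)) {
    pcv_assert(!is.null(names(x)) && all(nzchar(names(x))),
               "character input to write_fasta() must be named")
    seqs <- x
  } else if (is.list(x) && length(x) == 0L) {
    seqs <- character(0)
  } else {
    stop("unsupported input to write_fasta()", call. = FALSE)
  }
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Write a genome layout as GFF3
#'
#' Emits one CDS feature per annotated ORF, on the forward strand, phase 0,
#' with the ORF identifier in the `ID` attribute. Coordinates are 1-based
#' inclusive and include the stop codon, matching the package-wide
#' convention.
#'
#' @param layout A `genome_layout` object (see [infer_layout()]) or any
#'   list with `genome_id`, `seq_len` and an `orfs` data frame holding
#'   `orf_id`, `start`, `end`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(layout, path) {
  orfs <- layout$orfs
  if (is.null(orfs) || nrow(orfs) == 0L) {
    gr <- GenomicRanges::GRanges()
  } else {
    pcv_assert(all(orfs$start >= 1 & orfs$end <= layout$seq_len &
                     orfs$start < orfs$end),
               "layout coordinates out of range")
    gr <- GenomicRanges::GRanges(
      seqnames = layout$genome_id,
      ranges = IRanges::IRanges(start = orfs$start, end = orfs$end),
      strand = "+")
    S4Vectors::mcols(gr)$source <- "polycivir"
    S4Vectors::mcols(gr)$type <- "CDS"
    S4Vectors::mcols(gr)$phase <- 0L
    S4Vectors::mcols(gr)$ID <- orfs$orf_id
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read CDS features back from a GFF3 file
#'
#' Convenience reader for files produced by [write_gff3()].
#'
#' @param path Path to a GFF3 file.
#' @return A data frame with `genome_id`, `orf_id`, `start`, `end`.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L) {
    return(data.frame(genome_id = character(0), orf_id = character(0),
                      start = integer(0), end = integer(0)))
  }
  data.frame(genome_id = as.character(GenomicRanges::seqnames(gr)),
             orf_id = as.character(S4Vectors::mcols(gr)$ID),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

.pcv_orf_ids <- c("ORF1", "ORF2b", "ORF2", "ORF3", "ORF3a", "ORF4", "ORF5")

#' Read the packaged genome-layout table
#'
#' Parses a tab-separated transcription of the family's published
#' annotation table: one row per sequence with host, length and the printed
#' ORF coordinates (1-based, inclusive, stop codon included). Missing cells
#' are encoded as empty fields and come back as absent coordinates, never
#' as zero. Rows flagged as extending into the 3' poly(A) tail carry
#' `extends_to_polya = TRUE`.
#'
#' Every complete coordinate pair is checked against the reading-frame
#' invariant (`end - start + 1` divisible by 3); a violation is an error
#' naming the row and ORF. Partial entries (one coordinate missing) are
#' kept with an `NA` in the missing slot.
#'
#' @param path Path to the TSV; defaults to the table shipped with the
#'   package.
#' @return A list of `layout_table_row` objects.
#' @export
read_layout_table <- function(path = system.file("extdata",
                                                 "polycipiviridae_layout.tsv",
                                                 package = "polycivir")) {
  pcv_assert(file.exists(path), paste0("file not found: ", path))
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = c("", "NA"), check.names = FALSE)
  rows <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    coords <- list()
    for (orf in .pcv_orf_ids) {
      key <- tolower(orf)
      s <- r[[paste0(key, "_start")]]
      e <- r[[paste0(key, "_end")]]
      if (is.na(s) && is.na(e)) next
      if (!is.na(s) && !is.na(e)) {
        len <- e - s + 1
        if (s < 1 || s >= e || e > r$seq_len) {
          stop(sprintf("row '%s', %s: coordinates (%s, %s) out of range",
                       r$name, orf, s, e), call. = FALSE)
        }
        if (len %% 3 != 0) {
          stop(sprintf(
            "row '%s', %s: length %d not a multiple of 3 (frame invariant)",
            r$name, orf, len), call. = FALSE)
        }
      }
      coords[[orf]] <- c(start = as.integer(s), end = as.integer(e))
    }
    structure(
      list(name = r$name,
           accessions = strsplit(r$accessions, "\\s+")[[1]],
           species = r$species,
           host = r$host,
           seq_len = as.integer(r$seq_len),
           orf_coords = coords,
           printed_utr5_len = as.integer(r$utr5_len),
           printed_igr_len = as.integer(r$igr_len),
           printed_utr3_len = as.integer(r$utr3_len),
           extends_to_polya = isTRUE(as.logical(r$extends_to_polya))),
      class = "layout_table_row")
  })
  names(rows) <- vapply(rows, `[[`, character(1), "name")
  rows
}

#' Read a per-position pileup table
#'
#' The pileup TSV is the package's read-mapping exchange contract: columns
#' `genome_id`, `pos` (1-based), `depth`, `countA`, `countC`, `countG`,
#' `countT`. Base counts must not exceed the depth on any row; positions
#' absent from the file are implicitly depth 0.
#'
#' @param path Path to the TSV.
#' @return A data frame of the pileup rows (zero rows for an empty file).
#' @export
read_pileup <- function(path) {
  pcv_assert(file.exists(path), paste0("file not found: ", path))
  cols <- c("genome_id", "pos", "depth", "countA", "countC", "countG",
            "countT")
  info <- file.info(path)
  if (info$size == 0) {
    df <- as.data.frame(setNames(
      c(list(character(0)), rep(list(integer(0)), 6)), cols))
    return(df)
  }
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  pcv_assert(all(cols %in% names(df)),
             paste0("pileup must have columns: ", paste(cols, collapse = ", ")))
  df <- df[, cols]
  csum <- df$countA + df$countC + df$countG + df$countT
  if (any(csum > df$depth)) {
    bad <- which(csum > df$depth)[1]
    stop(sprintf("pileup row %d (%s:%d): base counts sum above depth",
                 bad, df$genome_id[bad], df$pos[bad]), call. = FALSE)
  }
  pcv_assert(all(df$pos >= 1), "pileup positions must be 1-based (>= 1)")
  df
}

#' Write a pileup table
#'
#' @param pileup Data frame in the [read_pileup()] column layout.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pileup <- function(pileup, path) {
  write.table(pileup, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write tabular homology hits
#'
#' A fixed six-column exchange record (a named subset of BLAST's tabular
#' output): `query_id`, `subject_id`, `pct_identity`, `aln_len`, `score`,
#' `evalue`. Decouples the discovery filter from any particular search
#' engine.
#'
#' @param path Path to the TSV.
#' @return `read_hits()` returns a data frame of hit records.
#' @export
read_hits <- function(path) {
  pcv_assert(file.exists(path), paste0("file not found: ", path))
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  cols <- c("query_id", "subject_id", "pct_identity", "aln_len", "score",
            "evalue")
  pcv_assert(all(cols %in% names(df)),
             paste0("hits table must have columns: ",
                    paste(cols, collapse = ", ")))
  df <- df[, cols]
  pcv_assert(all(df$aln_len >= 1), "aln_len must be >= 1")
  pcv_assert(all(df$pct_identity >= 0 & df$pct_identity <= 100),
             "pct_identity must lie in [0, 100]")
  pcv_assert(all(df$evalue >= 0), "evalue must be >= 0")
  df
}

#' @rdname read_hits
#' @param hits Data frame of hit records.
#' @export
write_hits <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
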
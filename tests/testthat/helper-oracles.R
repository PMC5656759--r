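# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: alignment scores come from exhaustive path
# enumeration, translations from seqinr's codon table, window means and
# ORF scans from naive loops.

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Exhaustive affine-gap global alignment score: enumerate every monotone
# alignment path; a gap of length L costs open + L * ext.
oracle_global_score <- function(a, b, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, sc, prev) {
    if (i > length(A) && j > length(B)) {
      best <<- max(best, sc)
      return(invisible(NULL))
    }
    if (i <= length(A) && j <= length(B)) {
      rec(i + 1L, j + 1L, sc + blosum62[A[i], B[j]], "m")
    }
    if (i <= length(A)) {
      rec(i + 1L, j, sc - (if (prev == "d") ext else open + ext), "d")
    }
    if (j <= length(B)) {
      rec(i, j + 1L, sc - (if (prev == "i") ext else open + ext), "i")
    }
  }
  rec(1L, 1L, 0, "s")
  best
}

# Exhaustive local score: best over all start pairs of any path prefix
# (the empty alignment scores 0).
oracle_local_score <- function(a, b, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  best <- 0
  rec <- function(i, j, sc, prev) {
    best <<- max(best, sc)
    if (i <= length(A) && j <= length(B)) {
      rec(i + 1L, j + 1L, sc + blosum62[A[i], B[j]], "m")
    }
    if (i <= length(A) && prev != "s") {
      rec(i + 1L, j, sc - (if (prev == "d") ext else open + ext), "d")
    }
    if (j <= length(B) && prev != "s") {
      rec(i, j + 1L, sc - (if (prev == "i") ext else open + ext), "i")
    }
  }
  for (i0 in seq_along(A)) {
    for (j0 in seq_along(B)) {
      rec(i0, j0, 0, "s")
    }
  }
  best
}

oracle_translate_codon <- function(codon) {
  seqinr::translate(strsplit(codon, "")[[1]], numcode = 1)
}

# Naive ORF scan: every (ATG, first in-frame stop) pair, longest span per
# (frame, stop).
oracle_find_orfs <- function(seq, min_len_nt) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  stops <- c("TAA", "TAG", "TGA")
  found <- list()
  for (i in seq_len(n - 2L)) {
    if (paste(chars[i:(i + 2L)], collapse = "") != "ATG") next
    j <- i
    end <- NA_integer_
    while (j + 2L <= n) {
      cod <- paste(chars[j:(j + 2L)], collapse = "")
      if (j > i && cod %in% stops) {
        end <- j + 2L
        break
      }
      j <- j + 3L
    }
    if (is.na(end)) next
    len <- end - i + 1L
    if (len < min_len_nt) next
    key <- paste((i - 1L) %% 3L, end)
    if (is.null(found[[key]]) || found[[key]]["start"] > i) {
      found[[key]] <- c(start = i, end = end)
    }
  }
  if (length(found) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  df <- do.call(rbind, lapply(found, function(v)
    data.frame(start = v[["start"]], end = v[["end"]])))
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Naive sliding-window mean, truncated at the ends.
oracle_window_means <- function(depth, window) {
  n <- length(depth)
  half_lo <- (window - 1L) %/% 2L
  half_hi <- window - 1L - half_lo
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half_lo)
    hi <- min(n, i + half_hi)
    mean(depth[lo:hi])
  }, numeric(1))
}

random_peptide <- function(len, alphabet = rownames(blosum62)[1:20]) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Random tree with strictly positive edge lengths and its additive
# distance matrix.
random_additive_case <- function(n_taxa) {
  tree <- ape::rtree(n_taxa, rooted = FALSE, br = NULL)
  tree$edge.length <- runif(nrow(tree$edge), 0.05, 1)
  list(tree = tree, d = ape::cophenetic.phylo(tree))
}

# Coordinate frame of main-chain rows for comparing layouts.
main_coords <- function(layout) {
  df <- layout$orfs[layout$orfs$orf_id %in%
                      c("ORF1", "ORF2", "ORF3", "ORF4", "ORF5"),
                    c("orf_id", "start", "end")]
  df <- df[order(df$orf_id), ]
  rownames(df) <- NULL
  df
}
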
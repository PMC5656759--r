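# Hel/Pro/RdRp motif scanning on the ORF5 polyprotein, protease-triad and
# RdRp motif-VI variant calls, and the hydropathy-based transmembrane
# predictor used for ORF2b.

#' Read a motif library
#'
#' A motif library is a flat YAML config: a `motifs` list whose entries
#' carry `motif_id`, `domain` (`Hel`, `Pro` or `RdRp`), `pattern`
#' (regular-expression semantics over amino-acid classes) and `required`.
#' Patterns are data, not logic: curated patterns can replace the packaged
#' defaults without code changes.
#'
#' @param path Path to a YAML motif library.
#' @return A data frame with columns `motif_id`, `domain`, `pattern`,
#'   `required`.
#' @export
read_motif_library <- function(path) {
  pcv_assert(file.exists(path), paste0("file not found: ", path))
  y <- yaml::read_yaml(path)
  pcv_assert(!is.null(y$motifs), "motif library must have a 'motifs' list")
  df <- do.call(rbind, lapply(y$motifs, function(m) {
    data.frame(motif_id = m$motif_id, domain = m$domain,
               pattern = m$pattern, required = isTRUE(m$required),
               stringsAsFactors = FALSE)
  }))
  pcv_assert(!anyDuplicated(df$motif_id), "motif_ids must be unique")
  pcv_assert(all(nzchar(df$pattern)), "patterns must be non-empty")
  pcv_assert(all(df$domain %in% c("Hel", "Pro", "RdRp")),
             "domain must be one of Hel, Pro, RdRp")
  df
}

#' The packaged default motif library
#'
#' Consensus-style patterns for the picorna-like Hel/Pro/RdRp motif
#' complement (Walker A/B/C helicase motifs, the G-x-[C/S]-G protease
#' catalytic site, and the eight polymerase motifs with the
#' magnesium-coordinating `[A-Z]DD` motif VI).
#'
#' @return A motif-library data frame (see [read_motif_library()]).
#' @export
default_motif_library <- function() {
  if (is.null(.pcv$motif_lib)) {
    .pcv$motif_lib <- read_motif_library(
      system.file("extdata", "motif_library.yml", package = "polycivir"))
  }
  .pcv$motif_lib
}

# Compile a pattern so that X and gap characters never match: '.' outside
# a character class becomes [A-Z], and the subject peptide has X/gaps
# rewritten to '0' before matching (no pattern class contains '0').
compile_motif_pattern <- function(pattern) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  out <- character(length(chars))
  in_class <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "[") in_class <- TRUE
    if (ch == "]") in_class <- FALSE
    out[i] <- if (ch == "." && !in_class) "[A-Z]" else ch
  }
  paste(out, collapse = "")
}

mask_unknown <- function(peptide) {
  gsub("[X*-]", "0", peptide)
}

motif_matches <- function(peptide_masked, pattern) {
  m <- gregexpr(compile_motif_pattern(pattern), peptide_masked, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  data.frame(start = as.integer(m),
             end = as.integer(m) + attr(m, "match.length") - 1L)
}

#' Scan a polypeptide for the Hel/Pro/RdRp motif complement
#'
#' Records every match of every library motif (the leftmost match is the
#' primary one) and evaluates the domain-order constraint
#' Hel < Pro < RdRp via a left-to-right assignment: the protease catalytic
#' site is taken as the first occurrence downstream of the helicase
#' motifs, and the required polymerase motifs are assigned left to right
#' downstream of the protease site, motif VI downstream of motif V (this
#' anchoring keeps the short `[A-Z]DD` pattern from binding to chance
#' acidic pairs elsewhere in the polyprotein). The scan result is
#' invariant under appending residues after the last hit.
#'
#' @param peptide Polypeptide string over the 20-letter alphabet (`X` and
#'   gap characters allowed; they never match a pattern class).
#' @param library Motif library data frame; defaults to the packaged one.
#' @return An object of class `domain_scan`: `hits` (all matches),
#'   `anchors` (the assigned per-motif loci), `domains_present` (named
#'   logical for Hel/Pro/RdRp), `ordered_ok`, `triad_variant`
#'   (`GxSG`/`GxCG`/`absent`) and `motif6_variant`
#'   (`GDD`/`ADD`/`SDD`/`other`/`absent`).
#' @export
scan_motifs <- function(peptide, library = default_motif_library()) {
  pcv_assert(is.character(peptide) && length(peptide) == 1L,
             "peptide must be a single string")
  empty_hits <- data.frame(motif_id = character(0), domain = character(0),
                           start_aa = integer(0), end_aa = integer(0),
                           matched = character(0), stringsAsFactors = FALSE)
  res <- structure(
    list(hits = empty_hits, anchors = empty_hits,
         domains_present = c(Hel = FALSE, Pro = FALSE, RdRp = FALSE),
         ordered_ok = FALSE, triad_variant = "absent",
         motif6_variant = "absent", peptide_length = nchar(peptide)),
    class = "domain_scan")
  if (nchar(peptide) == 0L) return(res)
  masked <- mask_unknown(toupper(peptide))
  all_hits <- list()
  match_tab <- list()
  for (i in seq_len(nrow(library))) {
    mm <- motif_matches(masked, library$pattern[i])
    match_tab[[library$motif_id[i]]] <- mm
    if (nrow(mm) > 0L) {
      all_hits[[length(all_hits) + 1L]] <- data.frame(
        motif_id = library$motif_id[i], domain = library$domain[i],
        start_aa = mm$start, end_aa = mm$end,
        matched = substr(rep(peptide, nrow(mm)), mm$start, mm$end),
        stringsAsFactors = FALSE)
    }
  }
  if (length(all_hits) > 0L) res$hits <- do.call(rbind, all_hits)

  req <- library[library$required, , drop = FALSE]
  present_any <- vapply(req$motif_id,
                        function(id) nrow(match_tab[[id]]) > 0L, logical(1))
  for (dom in c("Hel", "Pro", "RdRp")) {
    ids <- req$motif_id[req$domain == dom]
    res$domains_present[[dom]] <- length(ids) > 0L && all(present_any[ids])
  }

  anchors <- list()
  take <- function(id, min_start) {
    mm <- match_tab[[id]]
    mm <- mm[mm$start >= min_start, , drop = FALSE]
    if (nrow(mm) == 0L) return(NULL)
    mm[1L, ]
  }
  ok <- TRUE
  # Helicase: leftmost match of each required Hel motif.
  hel_end <- 0L
  for (id in req$motif_id[req$domain == "Hel"]) {
    a <- take(id, 1L)
    if (is.null(a)) { ok <- FALSE; next }
    anchors[[id]] <- a
    hel_end <- max(hel_end, a$end)
  }
  # Protease catalytic site: first occurrence downstream of the helicase.
  pro_end <- hel_end
  for (id in req$motif_id[req$domain == "Pro"]) {
    a <- take(id, hel_end + 1L)
    if (is.null(a)) { ok <- FALSE; next }
    anchors[[id]] <- a
    pro_end <- max(pro_end, a$end)
  }
  # Polymerase motifs left to right downstream of the protease site;
  # motif VI is anchored downstream of motif V.
  pos <- pro_end + 1L
  rdrp_ids <- req$motif_id[req$domain == "RdRp"]
  for (id in rdrp_ids) {
    a <- take(id, pos)
    if (is.null(a)) { ok <- FALSE; next }
    anchors[[id]] <- a
    pos <- a$end + 1L
  }
  res$ordered_ok <- ok && all(res$domains_present)
  if (length(anchors) > 0L) {
    adf <- do.call(rbind, lapply(names(anchors), function(id) {
      a <- anchors[[id]]
      data.frame(motif_id = id,
                 domain = library$domain[library$motif_id == id],
                 start_aa = a$start, end_aa = a$end,
                 matched = substr(peptide, a$start, a$end),
                 stringsAsFactors = FALSE)
    }))
    res$anchors <- adf
  }
  res$triad_variant <- call_triad_variant(peptide, res)
  res$motif6_variant <- call_motif6_variant(peptide, res)
  res
}

#' @export
print.domain_scan <- function(x, ...) {
  cat(sprintf(
    "<domain_scan> Hel:%s Pro:%s RdRp:%s | ordered:%s | triad:%s | motif VI:%s\n",
    x$domains_present[["Hel"]], x$domains_present[["Pro"]],
    x$domains_present[["RdRp"]], x$ordered_ok, x$triad_variant,
    x$motif6_variant))
  invisible(x)
}

anchor_of <- function(scan, motif_id) {
  a <- scan$anchors
  if (is.null(a) || nrow(a) == 0L) return(NULL)
  a <- a[a$motif_id == motif_id, , drop = FALSE]
  if (nrow(a) == 0L) NULL else a[1L, ]
}

#' Call the protease catalytic-triad variant
#'
#' Classifies the catalytic-site tetrapeptide `G-x-[C/S]-G`. When both
#' flanking domains were located, the search is restricted to the
#' interval between the helicase and polymerase regions; otherwise the
#' whole peptide is searched. The upstream catalytic-triad members H and D
#' are searched within `h_d_window` residues upstream of the site and
#' reported as attributes `h_found` / `d_found` (the window is a
#' configurable default, flagged here because the exact spacing is not
#' conserved across the order).
#'
#' @param peptide Polypeptide string.
#' @param scan Optional [scan_motifs()] result (computed if missing).
#' @param h_d_window Residue window searched upstream for H and D.
#' @return `"GxSG"`, `"GxCG"` or `"absent"`, with attributes `site_start`,
#'   `h_found`, `d_found`.
#' @export
call_triad_variant <- function(peptide, scan = NULL, h_d_window = 200L) {
  if (is.null(scan)) scan <- scan_motifs(peptide)
  masked <- mask_unknown(toupper(peptide))
  mm <- motif_matches(masked, "G.[CS]G")
  if (nrow(mm) == 0L) return(structure("absent", site_start = NA_integer_,
                                       h_found = NA, d_found = NA))
  hel <- scan$anchors[scan$anchors$domain == "Hel", , drop = FALSE]
  rdrp <- scan$anchors[scan$anchors$domain == "RdRp", , drop = FALSE]
  if (nrow(hel) > 0L && nrow(rdrp) > 0L) {
    lo <- max(hel$end_aa)
    hi <- min(rdrp$start_aa)
    inside <- mm[mm$start > lo & mm$end < hi, , drop = FALSE]
    if (nrow(inside) > 0L) mm <- inside
  }
  site <- mm[1L, ]
  third <- substr(peptide, site$start + 2L, site$start + 2L)
  variant <- if (third == "S") "GxSG" else "GxCG"
  upstream <- substr(peptide, max(1L, site$start - h_d_window), site$start - 1L)
  structure(variant, site_start = site$start,
            h_found = grepl("H", upstream, fixed = TRUE),
            d_found = grepl("D", upstream, fixed = TRUE))
}

#' Call the RdRp motif-VI variant
#'
#' Classifies the residue triplet at the motif-VI (motif C) locus, the
#' magnesium-coordinating `[A-Z]DD`. The locus is the occurrence anchored
#' by the surrounding polymerase motifs: the first `[A-Z]DD` downstream of
#' the motif-V anchor when one exists, otherwise the rightmost occurrence
#' downstream of the helicase region. The variant is named by the first
#' residue of the triplet; `GDD` is the canonical form, `ADD` and `SDD`
#' are the rare natural variants.
#'
#' @param peptide Polypeptide string.
#' @param scan Optional [scan_motifs()] result (computed if missing).
#' @return `"GDD"`, `"ADD"`, `"SDD"`, `"other"` or `"absent"`, with
#'   attribute `site_start`.
#' @export
call_motif6_variant <- function(peptide, scan = NULL) {
  if (is.null(scan)) scan <- scan_motifs(peptide)
  masked <- mask_unknown(toupper(peptide))
  mm <- motif_matches(masked, "[A-Z]DD")
  if (nrow(mm) == 0L) return(structure("absent", site_start = NA_integer_))
  v <- anchor_of(scan, "RdRp-V")
  if (!is.null(v)) {
    cand <- mm[mm$start > v$end_aa, , drop = FALSE]
    if (nrow(cand) == 0L) return(structure("absent",
                                           site_start = NA_integer_))
    site <- cand[1L, ]
  } else {
    hel <- scan$anchors[scan$anchors$domain == "Hel", , drop = FALSE]
    lo <- if (nrow(hel) > 0L) max(hel$end_aa) else 0L
    cand <- mm[mm$start > lo, , drop = FALSE]
    if (nrow(cand) == 0L) return(structure("absent",
                                           site_start = NA_integer_))
    site <- cand[nrow(cand), ]
  }
  first <- substr(peptide, site$start, site$start)
  variant <- switch(first, G = "GDD", A = "ADD", S = "SDD", "other")
  structure(variant, site_start = site$start)
}

# Kyte-Doolittle hydropathy index.
.kd_index <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
               E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
               M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
               Y = -1.3, V = 4.2)

#' Sliding-window hydropathy profile
#'
#' Mean Kyte-Doolittle hydropathy over a sliding window of odd width.
#' Unknown residues (X, gaps) contribute 0. A peptide shorter than the
#' window yields an empty profile.
#'
#' @param peptide Polypeptide string.
#' @param window_aa Odd window width in residues (>= 5).
#' @return An object of class `hydropathy_profile`: data frame `windows`
#'   with `start_aa`, `end_aa`, `center_aa`, `mean_hydropathy`, plus the
#'   window width and peptide length.
#' @export
hydropathy_profile <- function(peptide, window_aa = 19L) {
  pcv_assert(is_scalar_number(window_aa) && window_aa >= 5 &&
               window_aa %% 2 == 1,
             "window_aa must be an odd integer >= 5")
  chars <- strsplit(toupper(peptide), "", fixed = TRUE)[[1]]
  vals <- unname(.kd_index[chars])
  vals[is.na(vals)] <- 0
  n <- length(vals)
  if (n < window_aa) {
    windows <- data.frame(start_aa = integer(0), end_aa = integer(0),
                          center_aa = integer(0),
                          mean_hydropathy = numeric(0))
  } else {
    cs <- c(0, cumsum(vals))
    starts <- seq_len(n - window_aa + 1L)
    ends <- starts + window_aa - 1L
    means <- (cs[ends + 1L] - cs[starts]) / window_aa
    windows <- data.frame(start_aa = starts, end_aa = ends,
                          center_aa = starts + (window_aa - 1L) %/% 2L,
                          mean_hydropathy = means)
  }
  structure(list(windows = windows, window_aa = as.integer(window_aa),
                 peptide_length = n),
            class = "hydropathy_profile")
}

#' Predict a central transmembrane helix from a hydropathy profile
#'
#' A window whose mean hydropathy exceeds `threshold` is a candidate
#' transmembrane segment; `has_central_tm` is `TRUE` when some such
#' window's center lies in the middle half of the peptide (25-75% of its
#' length) — quantifying "a transmembrane domain in the middle of the
#' protein".
#'
#' @param profile A [hydropathy_profile()].
#' @param threshold Hydropathy threshold for a transmembrane window.
#' @return A list of class `tm_prediction`: `windows` (the
#'   above-threshold windows), `has_central_tm`, `threshold`.
#' @export
predict_tm <- function(profile, threshold = 1.6) {
  pcv_assert(inherits(profile, "hydropathy_profile"),
             "need a hydropathy_profile")
  w <- profile$windows
  hot <- w[w$mean_hydropathy > threshold, , drop = FALSE]
  n <- profile$peptide_length
  central <- hot$center_aa >= 0.25 * n & hot$center_aa <= 0.75 * n
  structure(list(windows = hot, has_central_tm = any(central),
                 threshold = threshold),
            class = "tm_prediction")
}
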
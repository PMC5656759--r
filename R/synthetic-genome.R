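# Seeded synthetic genome generator. Genomes are constructed codon-wise
# with rejection (bounded retries) so that every planted feature is
# realized exactly: ATG-initiated, internally stop-free, stop-terminated
# ORFs at the specified coordinates (including overlapping junctions and
# the +1-frame ORF2b), Hel/Pro/RdRp motif blocks at known offsets in the
# ORF5 polyprotein, the 5'-completeness signature, and a poly(A) tail.
# Ground-truth annotations are returned alongside the sequence.
#
# Overlapping ORF junctions are solved as isolated constraint windows: a
# handful of bases jointly satisfying both reading frames (upstream reads
# sense codons then a stop; downstream reads ATG then sense codons) is
# rejection-sampled and locked before the surrounding ORF bodies are
# filled. Windows of distinct junctions never touch (overlaps are tens of
# nt, ORFs hundreds), so each window can be solved independently.

# Planted motif instances (matching the packaged default library) and the
# fixed spacing of the ORF5 polyprotein blueprint, in residues. The
# "decoy" flavor uses different instances of the same patterns, so decoy
# genomes carry the generic motif complement without sharing the family's
# exact sequences (as a real out-of-family picorna-like virus would).
.orf5_blueprint <- function(triad, motif6, flavor = "family") {
  procat <- if (triad == "GxSG") "GDSG" else "GQCG"
  if (flavor == "family") {
    list(
      list(id = "Hel-A",    inst = "GPPGSGKS",  gap_after = 18L),
      list(id = "Hel-B",    inst = "IVLDD",     gap_after = 18L),
      list(id = "Hel-C",    inst = "VAGNSAT",   gap_after = NA),  # flex
      list(id = "Pro-H",    inst = "H",         gap_after = 25L),
      list(id = "Pro-D",    inst = "D",         gap_after = 25L),
      list(id = "Pro-cat",  inst = procat,      gap_after = NA),  # flex
      list(id = "RdRp-I",   inst = "KPLAAE",    gap_after = 12L),
      list(id = "RdRp-II",  inst = "SGAAAT",    gap_after = 12L),
      list(id = "RdRp-III", inst = "DAADFAAF",  gap_after = 12L),
      list(id = "RdRp-IV",  inst = "DYSKAD",    gap_after = 12L),
      list(id = "RdRp-V",   inst = "GLPASAAAN", gap_after = 10L),
      list(id = "RdRp-VI",  inst = paste0(substr(motif6, 1, 1), "DD"),
           gap_after = 12L),
      list(id = "RdRp-VII", inst = "FLKR",      gap_after = 12L),
      list(id = "RdRp-VIII", inst = "EYYAAW",   gap_after = NA))  # tail
  } else {
    list(
      list(id = "Hel-A",    inst = "GESGSGKT",  gap_after = 18L),
      list(id = "Hel-B",    inst = "MLVDD",     gap_after = 18L),
      list(id = "Hel-C",    inst = "LKPNPQT",   gap_after = NA),
      list(id = "Pro-H",    inst = "H",         gap_after = 25L),
      list(id = "Pro-D",    inst = "D",         gap_after = 25L),
      list(id = "Pro-cat",  inst = procat,      gap_after = NA),
      list(id = "RdRp-I",   inst = "KGMPWE",    gap_after = 12L),
      list(id = "RdRp-II",  inst = "TGLPGT",    gap_after = 12L),
      list(id = "RdRp-III", inst = "EPKDFQWF",  gap_after = 12L),
      list(id = "RdRp-IV",  inst = "DWEPTD",    gap_after = 12L),
      list(id = "RdRp-V",   inst = "GIRETWPAN", gap_after = 10L),
      list(id = "RdRp-VI",  inst = paste0(substr(motif6, 1, 1), "DD"),
           gap_after = 12L),
      list(id = "RdRp-VII", inst = "FLKK",      gap_after = 12L),
      list(id = "RdRp-VIII", inst = "DFFPGW",   gap_after = NA))
  }
}

#' Specify a synthetic genome
#'
#' Encodes the architecture of one family-like genome: UTR/IGR lengths,
#' ORF lengths (multiples of 3, stop codon included), signed junction
#' gaps between the 5' ORFs (negative = overlap), an optional overlapping
#' ORF2b, an optional extra ORF3a, the protease-triad and RdRp motif-VI
#' variants planted in ORF5, the 5'-completeness signature, and the
#' poly(A) tail length. Defaults mirror the family's published coordinate
#' ranges.
#'
#' @param utr5_len,utr3_len,igr_len Region lengths (nt).
#' @param orf_lens Named numeric: lengths (nt) of `ORF1`, `ORF2`, `ORF3`,
#'   `ORF4`, `ORF5`.
#' @param junction_gaps Numeric of length 3: signed gaps for the
#'   ORF1-ORF2, ORF2-ORF3 and ORF3-ORF4 junctions (negative = overlap).
#' @param orf2b `NULL`, or a list with `offset` (nt past the ORF2 start;
#'   `offset %% 3 == 1`, and at least the ORF1 overlap depth so the gene
#'   starts past the ORF1 stop), `len` (nt) and `hydrophobic_core`
#'   (logical: plant an I/L/V/F core, or a charged one when `FALSE`).
#' @param orf3a `NULL`, or a list with `offset` (signed nt gap from the
#'   ORF2 end to the ORF3a start) and `len` (nt); the ORF2-ORF3 junction
#'   gap must leave room for it.
#' @param motif6_variant `"GDD"`, `"ADD"` or `"SDD"`.
#' @param triad `"GxSG"` or `"GxCG"`.
#' @param five_prime_signature Plant the `UUU` + AU-rich 5' signature.
#' @param polya_len Poly(A) tail length (nt).
#' @param seed Integer seed; the generator is a pure function of the
#'   spec including this seed.
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(utr5_len = 250L, utr3_len = 420L, igr_len = 600L,
                        orf_lens = c(ORF1 = 777L, ORF2 = 804L, ORF3 = 777L,
                                     ORF4 = 1149L, ORF5 = 6462L),
                        junction_gaps = c(-4L, -8L, -4L),
                        orf2b = list(offset = 4L, len = 231L,
                                     hydrophobic_core = TRUE),
                        orf3a = NULL,
                        motif6_variant = "GDD", triad = "GxSG",
                        five_prime_signature = TRUE, polya_len = 30L,
                        seed = 1L) {
  pcv_assert(all(c("ORF1", "ORF2", "ORF3", "ORF4", "ORF5") %in%
                   names(orf_lens)), "orf_lens must name ORF1..ORF5")
  pcv_assert(all(orf_lens %% 3 == 0), "ORF lengths must be multiples of 3")
  pcv_assert(all(orf_lens >= 150), "ORF lengths must be >= 150 nt")
  pcv_assert(orf_lens[["ORF5"]] >= 1800,
             "ORF5 must be >= 1800 nt to hold the motif blueprint")
  pcv_assert(length(junction_gaps) == 3L, "need 3 junction gaps")
  ids <- paste0("ORF", 1:4)
  for (k in 1:3) {
    v <- -junction_gaps[k]
    if (v > 0) {
      # the family's printed junction overlaps are all <= 14 nt; the
      # joint-frame window solver is designed for such shallow overlaps
      pcv_assert(v <= 30,
                 "junction overlap too deep for the flanking ORFs")
    }
  }
  pcv_assert(all(utr5_len >= 0, utr3_len >= 0, igr_len >= 3, polya_len >= 0),
             "region lengths must be non-negative (igr >= 3)")
  pcv_assert(motif6_variant %in% c("GDD", "ADD", "SDD"),
             "motif6_variant must be GDD, ADD or SDD")
  pcv_assert(triad %in% c("GxSG", "GxCG"), "triad must be GxSG or GxCG")
  if (!is.null(orf2b)) {
    pcv_assert(orf2b$offset %% 3 == 1 && orf2b$offset >= 4,
               "orf2b offset must be >= 4 with offset %% 3 == 1")
    pcv_assert(orf2b$offset >= -junction_gaps[1],
               "orf2b must start past the end of ORF1")
    pcv_assert(orf2b$len %% 3 == 0 && orf2b$len >= 150,
               "orf2b len must be a multiple of 3, >= 150")
    pcv_assert(orf2b$offset + orf2b$len <= orf_lens[["ORF2"]] - 3,
               "ORF2b must end before the ORF2 stop codon")
  }
  if (!is.null(orf3a)) {
    pcv_assert(orf3a$len %% 3 == 0 && orf3a$len >= 150,
               "orf3a len must be a multiple of 3, >= 150")
    pcv_assert(orf3a$offset >= -14, "ORF3a/ORF2 overlap too deep")
    # overlap of ORF3a into ORF3 = (offset + len) - gap23; keep it shallow
    pcv_assert(orf3a$offset + orf3a$len - junction_gaps[2] <= 14,
               "ORF3a/ORF3 overlap too deep")
  }
  structure(list(utr5_len = as.integer(utr5_len),
                 utr3_len = as.integer(utr3_len),
                 igr_len = as.integer(igr_len),
                 orf_lens = vapply(orf_lens, as.integer, integer(1)),
                 junction_gaps = as.integer(junction_gaps),
                 orf2b = orf2b, orf3a = orf3a,
                 motif6_variant = motif6_variant, triad = triad,
                 five_prime_signature = isTRUE(five_prime_signature),
                 polya_len = as.integer(polya_len),
                 seed = as.integer(seed)),
            class = "genome_spec")
}

#' Sample a family-like genome spec
#'
#' Draws region and ORF lengths from the family's published ranges
#' (5' UTR 130-370 nt, IGR 336-768 nt, 3' UTR 385-479 nt; ORF lengths and
#' junction gaps from the span of the curated table) and plants the
#' genus-defining features: ORF2b for `Sopolycivirus`, the ADD motif-VI
#' variant for `Chipolycivirus`, neither for `Hupolycivirus`.
#'
#' @param seed Integer seed.
#' @param genus Genus whose defining features to plant.
#' @return A `genome_spec`.
#' @export
sample_genome_spec <- function(seed,
                               genus = c("Sopolycivirus", "Hupolycivirus",
                                         "Chipolycivirus")) {
  genus <- match.arg(genus)
  r3 <- function(lo, hi) {
    v <- sample(seq(lo, hi), 1L)
    as.integer(v - v %% 3)
  }
  pcv_with_seed(seed, {
    orf_lens <- c(ORF1 = r3(678, 867), ORF2 = r3(519, 915),
                  ORF3 = r3(621, 975), ORF4 = r3(939, 1488),
                  ORF5 = r3(6462, 7347))
    gap_pool <- c(-14L, -11L, -8L, -4L, -1L, 0L, 2L)
    gaps <- sample(gap_pool, 3L, replace = TRUE)
    orf2b <- NULL
    if (genus == "Sopolycivirus") {
      # the observed ORF1 overlaps in ORF2b-carrying genomes are <= 4 nt,
      # which keeps ORF2b (offset >= 4) clear of the ORF1 stop
      gaps[1] <- sample(c(-4L, -1L, 0L, 2L), 1L)
      len2b <- r3(231, 372)
      max_off <- orf_lens[["ORF2"]] - 3L - len2b
      offs <- seq(4L, max(4L, min(52L, max_off)), by = 3L)
      orf2b <- list(offset = sample(offs, 1L), len = len2b,
                    hydrophobic_core = TRUE)
    }
    genome_spec(
      utr5_len = sample(130:370, 1L), utr3_len = sample(385:479, 1L),
      igr_len = sample(336:768, 1L), orf_lens = orf_lens,
      junction_gaps = gaps, orf2b = orf2b,
      motif6_variant = if (genus == "Chipolycivirus") "ADD" else "GDD",
      triad = "GxSG", five_prime_signature = TRUE, polya_len = 30L,
      seed = seed)
  })
}

# --- construction internals ------------------------------------------------

# Build the ORF5 peptide from the blueprint; returns residues and the
# 1-based aa offset of every planted motif instance.
build_orf5_peptide <- function(len_aa, triad, motif6, flavor = "family") {
  bp <- .orf5_blueprint(triad, motif6, flavor)
  inst_len <- sum(vapply(bp, function(b) nchar(b$inst), integer(1)))
  fixed_gaps <- sum(vapply(bp, function(b)
    if (is.na(b$gap_after)) 0L else b$gap_after, integer(1)))
  flex_total <- len_aa - inst_len - fixed_gaps
  pcv_assert(flex_total >= 40L, "ORF5 too short for the motif blueprint")
  # flexible filler split pre / after Hel-C / after Pro-cat / tail 3:2:2:3
  w <- c(3, 2, 2, 3)
  flex <- floor(flex_total * w / sum(w))
  flex[1] <- flex[1] + (flex_total - sum(flex))
  # Spacer residues come from a 16-letter alphabet excluding D, N, C and
  # S: every required motif pattern needs at least one of those, so the
  # planted instances are the only possible required-motif matches and
  # the scan anchors land on them deterministically.
  aa <- setdiff(pcv_amino_acids(), c("D", "N", "C", "S"))
  residues <- sample(aa, flex[1], replace = TRUE)
  offsets <- integer(0)
  inst_lens <- integer(0)
  flex_i <- 2L
  for (b in bp) {
    # aa offset within the translated ORF peptide (leading Met included)
    offsets[b$id] <- length(residues) + 2L
    inst_lens[b$id] <- nchar(b$inst)
    residues <- c(residues, strsplit(b$inst, "", fixed = TRUE)[[1]])
    gap <- b$gap_after
    if (is.na(gap)) {
      if (flex_i <= 4L) {
        residues <- c(residues, sample(aa, flex[flex_i], replace = TRUE))
        flex_i <- flex_i + 1L
      }
    } else {
      residues <- c(residues, sample(aa, gap, replace = TRUE))
    }
  }
  pcv_assert(length(residues) == len_aa, "blueprint length mismatch")
  list(residues = residues, offsets = offsets, inst_lens = inst_lens)
}

# Random sense codon(s) for residues; each codon drawn uniformly from the
# residue's synonymous codons.
codons_for_residues <- function(residues) {
  vapply(residues, function(a) {
    cs <- pcv_codons_for(a)
    if (length(cs) == 1L) cs else sample(cs, 1L)
  }, character(1), USE.NAMES = FALSE)
}

split_bases <- function(codons) {
  unlist(strsplit(codons, "", fixed = TRUE), use.names = FALSE)
}

random_stop <- function() {
  strsplit(sample(pcv_stop_codons(), 1L), "", fixed = TRUE)[[1]]
}

# Construction state: base vector, lock mask, ORF registry.
new_state <- function(n) {
  env <- new.env(parent = emptyenv())
  env$g <- rep(NA_character_, n)
  env$locked <- rep(FALSE, n)
  env$orfs <- data.frame(orf_id = character(0), start = integer(0),
                         end = integer(0), stringsAsFactors = FALSE)
  env
}

write_bases <- function(state, at, bases, lock = FALSE) {
  idx <- seq(at, length.out = length(bases))
  state$g[idx] <- bases
  if (lock) state$locked[idx] <- TRUE
  invisible(NULL)
}

register_orf <- function(state, orf_id, s, e) {
  state$orfs <- rbind(state$orfs,
                      data.frame(orf_id = orf_id, start = s, end = e,
                                 stringsAsFactors = FALSE))
}

codons_in <- function(g, from, to) {
  vapply(seq(from, to, by = 3L), function(p)
    paste(g[p:(p + 2L)], collapse = ""), character(1))
}

# Solve one overlapping junction: jointly sample the shared window so the
# upstream frame reads sense codons then its stop at e_u, and the
# downstream frame reads ATG at s_d then sense codons. The window covers
# whole codons of both frames and is locked on success.
solve_junction_window <- function(state, s_u, e_u, s_d) {
  v <- e_u - s_d + 1L
  # window starts at the earlier of: the upstream codon slot containing
  # s_d, and the upstream stop-codon slot (for shallow overlaps the stop
  # slot starts before s_d)
  jstart <- min(s_d - (s_d - s_u) %% 3L, e_u - 2L)
  win_end <- s_d + 3L * as.integer(ceiling(v / 3)) - 1L  # whole downstream slots
  win <- jstart:win_end
  atg_rel <- (s_d - jstart + 1L):(s_d - jstart + 3L)
  n_win <- length(win)
  up_slots <- seq(jstart, e_u - 2L, by = 3L)
  dn_slots <- seq(s_d, win_end - 2L, by = 3L)
  for (try in seq_len(8000L)) {
    w <- sample(c("A", "C", "G", "T"), n_win, replace = TRUE)
    w[atg_rel] <- c("A", "T", "G")
    upcod <- vapply(up_slots, function(p) {
      r <- p - jstart + 1L
      paste(w[r:(r + 2L)], collapse = "")
    }, character(1))
    n_up <- length(upcod)
    if (!(upcod[n_up] %in% pcv_stop_codons())) next
    if (n_up > 1L && any(upcod[-n_up] %in% pcv_stop_codons())) next
    dncod <- vapply(dn_slots[-1L], function(p) {
      r <- p - jstart + 1L
      paste(w[r:(r + 2L)], collapse = "")
    }, character(1))
    if (length(dncod) > 0L && any(dncod %in% pcv_stop_codons())) next
    write_bases(state, jstart, w, lock = TRUE)
    return(invisible(TRUE))
  }
  stop(sprintf("unsatisfiable junction (overlap %d nt)", v), call. = FALSE)
}

# Write one ORF around any previously locked windows: per codon slot,
# write only if the slot is entirely unwritten (window slots already hold
# the ATG / stop / joint content).
write_chain_orf <- function(state, orf_id, s, e) {
  slots <- seq(s, e - 2L, by = 3L)
  n_body <- length(slots) - 2L
  body <- if (n_body > 0L)
    sample(pcv_sense_codons(), n_body, replace = TRUE) else character(0)
  for (i in seq_along(slots)) {
    p <- slots[i]
    if (!all(is.na(state$g[p:(p + 2L)]))) next
    bases <- if (i == 1L) {
      c("A", "T", "G")
    } else if (i == length(slots)) {
      random_stop()
    } else {
      strsplit(body[i - 1L], "", fixed = TRUE)[[1]]
    }
    write_bases(state, p, bases)
  }
  state$locked[s:(s + 2L)] <- TRUE
  state$locked[(e - 2L):e] <- TRUE
  register_orf(state, orf_id, s, e)
}

# Plant ORF2b in the +1 frame inside ORF2: ATG, body with a 21-residue
# hydrophobic (or charged) core at its center, stop. ORF2's frame is kept
# free of stops by per-codon rejection. The region lies strictly inside
# ORF2 (past any ORF1 overlap, before the ORF2 stop), so only ORF2's
# frame constrains it.
plant_orf2b <- function(state, s2, e2, offset, len, hydrophobic_core) {
  s2b <- s2 + offset
  e2b <- s2b + len - 1L
  n_res <- len %/% 3L - 2L
  core_set <- if (hydrophobic_core) c("I", "L", "V", "F")
              else c("D", "E", "K", "R")
  core_len <- min(21L, n_res)
  core_from <- max(1L, (n_res - core_len) %/% 2L + 1L)
  core_to <- min(n_res, core_from + core_len - 1L)
  aa <- pcv_amino_acids()
  f0_start <- function(p) s2 + 3L * ((p - s2) %/% 3L)
  f0_ok <- function(w, from, to) {
    cs <- unique(vapply(seq(from, to), f0_start, integer(1)))
    cs <- cs[cs >= s2 & cs + 2L <= e2 - 3L]  # never the ORF2 stop slot
    for (c0 in cs) {
      if (paste(w[c0:(c0 + 2L)], collapse = "") %in% pcv_stop_codons()) {
        return(FALSE)
      }
    }
    TRUE
  }
  put <- function(p, gen) {
    for (try in seq_len(500L)) {
      w <- state$g
      w[p:(p + 2L)] <- gen()
      if (f0_ok(w, p - 2L, p + 4L)) {
        state$g <- w
        return(TRUE)
      }
    }
    FALSE
  }
  pcv_assert(put(s2b, function() c("A", "T", "G")),
             "cannot place ORF2b start codon")
  for (r in seq_len(n_res)) {
    p <- s2b + 3L * r
    pool <- if (r >= core_from && r <= core_to) core_set else aa
    ok <- put(p, function() {
      res <- sample(pool, 1L)
      strsplit(sample(pcv_codons_for(res), 1L), "", fixed = TRUE)[[1]]
    })
    pcv_assert(ok, "cannot place ORF2b body codon")
  }
  pcv_assert(put(e2b - 2L, function() random_stop()),
             "cannot place ORF2b stop codon")
  body_cod <- codons_in(state$g, s2b + 3L, e2b - 5L)
  pcv_assert(!any(body_cod %in% pcv_stop_codons()),
             "ORF2b body acquired a stop")
  state$locked[s2b:e2b] <- TRUE
  register_orf(state, "ORF2b", s2b, e2b)
  c(start = s2b, end = e2b)
}

# Plant a stop codon in the reading frame of a downstream ORF start,
# shortly upstream of it, so that no upstream in-frame ATG can extend the
# ORF past its planted start. Positions inside another ORF's body are
# resampled jointly (keeping that frame sense); locked positions are
# skipped. Failure is tolerated: the post-hoc verification rerolls the
# genome.
plant_guard <- function(state, s_d) {
  owner_of <- function(idx) {
    o <- state$orfs
    hit <- which(o$start <= max(idx) & o$end >= min(idx))
    if (length(hit) == 0L) return(NULL)
    o[hit[1L], ]
  }
  for (m in 1:10) {
    t <- s_d - 3L * m
    if (t < 1L) return(FALSE)
    idx <- t:(t + 2L)
    if (any(state$locked[idx])) next
    own <- owner_of(idx)
    if (is.null(own)) {
      if (any(is.na(state$g[idx]))) next
      state$g[idx] <- random_stop()
      state$locked[idx] <- TRUE
      return(TRUE)
    }
    # same frame as the downstream start: the owner's own stop guards it
    if ((own$start - s_d) %% 3L == 0L) return(TRUE)
    c1 <- own$start + 3L * ((t - own$start) %/% 3L)
    c2 <- own$start + 3L * ((t + 2L - own$start) %/% 3L)
    cods <- seq(c1, c2, by = 3L)
    cods <- cods[cods >= own$start + 3L & cods + 2L <= own$end - 3L]
    if (length(cods) == 0L) next
    cover <- unlist(lapply(cods, function(p) p:(p + 2L)))
    if (any(state$locked[cover])) next
    for (try in seq_len(800L)) {
      w <- state$g
      for (p in cods) {
        w[p:(p + 2L)] <- strsplit(sample(pcv_sense_codons(), 1L), "",
                                  fixed = TRUE)[[1]]
      }
      if (all(!is.na(w[idx])) &&
          paste(w[idx], collapse = "") %in% pcv_stop_codons()) {
        state$g <- w
        state$locked[idx] <- TRUE
        return(TRUE)
      }
    }
  }
  FALSE
}

# Intrinsic verification that the realized sequence carries exactly the
# planted architecture. Uses the independently tested primitives
# find_orfs / scan_motifs / hydropathy_profile — not the layout inference
# whose round-trip behaviour the generator exists to test.
verify_synthetic <- function(seq, truth, spec) {
  orfs <- find_orfs(seq, 150L)
  key <- paste(orfs$start, orfs$end)
  planted <- truth$orfs
  for (i in seq_len(nrow(planted))) {
    if (planted$length_nt[i] >= 150L &&
        !(paste(planted$start[i], planted$end[i]) %in% key)) {
      return(FALSE)
    }
  }
  main_min <- min(planted$length_nt[planted$orf_id %in% .main_orfs])
  unplanned <- !(key %in% paste(planted$start, planted$end))
  if (any(orfs$length_nt[unplanned] >= main_min)) return(FALSE)
  # ORF5 motif content at the planted offsets
  pep5 <- planted$peptide[planted$orf_id == "ORF5"]
  sc <- scan_motifs(pep5)
  if (!all(sc$domains_present) || !isTRUE(sc$ordered_ok)) return(FALSE)
  if (!identical(as.character(sc$triad_variant), spec$triad)) return(FALSE)
  if (!identical(as.character(sc$motif6_variant), spec$motif6_variant)) {
    return(FALSE)
  }
  offs <- attr(truth, "motif_offsets")
  for (id in intersect(sc$anchors$motif_id, names(offs))) {
    if (sc$anchors$start_aa[sc$anchors$motif_id == id] != offs[[id]]) {
      return(FALSE)
    }
  }
  # ORF2b: planted peptide must (not) carry the central TM, and no
  # +1-frame ATG upstream of the planted start may reach it stop-free
  if ("ORF2b" %in% planted$orf_id) {
    p2b <- planted[planted$orf_id == "ORF2b", ]
    s2 <- planted$start[planted$orf_id == "ORF2"]
    tm <- predict_tm(hydropathy_profile(p2b$peptide))
    if (!identical(tm$has_central_tm,
                   isTRUE(spec$orf2b$hydrophobic_core))) {
      return(FALSE)
    }
    if (p2b$start - 3L >= s2 + 1L) {
      upstream_starts <- seq(s2 + 1L, p2b$start - 3L, by = 3L)
      cods <- vapply(upstream_starts, function(p)
        substr(seq, p, p + 2L), character(1))
      atg <- which(cods == "ATG")
      if (length(atg) > 0L) {
        last_stop <- max(c(0L, which(cods %in% pcv_stop_codons())))
        if (any(atg > last_stop)) return(FALSE)
      }
    }
  }
  # 5' signature matches the flag
  if (nchar(seq) >= 25L &&
      !identical(five_prime_signature(seq), spec$five_prime_signature)) {
    return(FALSE)
  }
  TRUE
}

#' Generate a synthetic genome with known ground truth
#'
#' Codon-wise construction with rejection: the genome realizes every
#' feature of the spec exactly, and is re-rolled (bounded retries) until
#' post-hoc checks confirm that no unplanned ORF rivals the planted ones,
#' that the motif scan recovers the planted variants at the planted
#' offsets, and that the 5' signature and the ORF2b hydropathy match the
#' spec. The generator is a pure function of the spec (including its
#' seed): the same spec yields a byte-identical genome.
#'
#' @param spec A [genome_spec()].
#' @return An object of class `synthetic_genome`: `record` (the
#'   [genome_record()], poly(A) tail attached), `truth` (a
#'   `genome_layout` of the planted coordinates, with per-motif aa
#'   offsets in the `"motif_offsets"` attribute), `locked` (positions
#'   that must not mutate during evolution), and `spec`.
#' @export
generate_genome <- function(spec) {
  pcv_assert(inherits(spec, "genome_spec"), "need a genome_spec")
  pcv_with_seed(spec$seed, {
    for (attempt in seq_len(60L)) {
      out <- try(build_genome_once(spec), silent = TRUE)
      if (!inherits(out, "try-error") &&
          verify_synthetic(out$seq, out$truth, spec)) {
        rec <- genome_record(
          id = sprintf("synth_%d", spec$seed),
          seq = paste0(out$seq, strrep("A", spec$polya_len)),
          description = "synthetic polycipivirus-like genome")
        return(structure(list(record = rec, truth = out$truth,
                              locked = out$locked, spec = spec),
                         class = "synthetic_genome"))
      }
    }
    stop("could not realize genome spec after 60 attempts", call. = FALSE)
  })
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("<synthetic_genome> %s: %d nt + %d nt poly(A), seed %d\n",
              x$record$id, x$truth$seq_len, x$spec$polya_len, x$spec$seed))
  print(x$truth)
  invisible(x)
}

build_genome_once <- function(spec) {
  L <- spec$orf_lens
  s <- integer(5); e <- integer(5)
  s[1] <- spec$utr5_len + 1L
  e[1] <- s[1] + L[["ORF1"]] - 1L
  for (k in 2:4) {
    s[k] <- e[k - 1L] + spec$junction_gaps[k - 1L] + 1L
    e[k] <- s[k] + L[[paste0("ORF", k)]] - 1L
  }
  s[5] <- e[4] + spec$igr_len + 1L
  e[5] <- s[5] + L[["ORF5"]] - 1L
  n <- e[5] + spec$utr3_len
  pcv_assert(all(s >= 1) && all(diff(s) > 0) && all(diff(e) > 0),
             "spec produces non-ordered ORFs")
  state <- new_state(n)

  # ORF5 with planted motif blocks
  len5_aa <- L[["ORF5"]] %/% 3L - 1L
  bp <- build_orf5_peptide(len5_aa, spec$triad, spec$motif6_variant)
  write_bases(state, s[5], c("A", "T", "G"), lock = TRUE)
  write_bases(state, s[5] + 3L, split_bases(codons_for_residues(bp$residues)))
  write_bases(state, e[5] - 2L, random_stop(), lock = TRUE)
  register_orf(state, "ORF5", s[5], e[5])
  for (id in names(bp$offsets)) {
    # peptide position q (Met = 1) occupies nt s5 + 3*(q-1) .. + 2
    from <- s[5] + 3L * (bp$offsets[[id]] - 1L)
    state$locked[from:(from + 3L * bp$inst_lens[[id]] - 1L)] <- TRUE
  }

  # 5' ORF chain (plus optional ORF3a), in start order
  chain <- data.frame(orf_id = paste0("ORF", 1:4), start = s[1:4],
                      end = e[1:4], stringsAsFactors = FALSE)
  if (!is.null(spec$orf3a)) {
    s3a <- e[2] + spec$orf3a$offset + 1L
    e3a <- s3a + spec$orf3a$len - 1L
    pcv_assert(s3a > s[2] && e3a < e[3] - 6L, "ORF3a outside its junction")
    chain <- rbind(chain, data.frame(orf_id = "ORF3a", start = s3a,
                                     end = e3a, stringsAsFactors = FALSE))
  }
  chain <- chain[order(chain$start), ]
  # solve every overlapping junction first, as an isolated locked window
  for (i in seq_len(nrow(chain) - 1L)) {
    if (chain$start[i + 1L] <= chain$end[i]) {
      solve_junction_window(state, chain$start[i], chain$end[i],
                            chain$start[i + 1L])
    }
  }
  for (i in seq_len(nrow(chain))) {
    write_chain_orf(state, chain$orf_id[i], chain$start[i], chain$end[i])
  }

  # ORF2b (strictly inside ORF2, past the ORF1 overlap)
  orf2b_coords <- NULL
  if (!is.null(spec$orf2b)) {
    orf2b_coords <- plant_orf2b(state, s[2], e[2], spec$orf2b$offset,
                                spec$orf2b$len,
                                isTRUE(spec$orf2b$hydrophobic_core))
  }

  # fill remaining free positions (UTRs, IGR, junction gaps)
  nas <- which(is.na(state$g))
  if (length(nas) > 0L) {
    state$g[nas] <- sample(c("A", "C", "G", "T"), length(nas),
                           replace = TRUE)
  }
  # the genome must not end in A, or the appended poly(A) tail would be
  # indistinguishable from genuine 3' UTR sequence
  if (spec$utr3_len >= 1L) {
    state$g[n] <- sample(c("C", "G", "T"), 1L)
    state$locked[n] <- TRUE
  }

  # 5' end: signature or an explicitly non-AU-rich prefix
  if (spec$utr5_len >= 25L) {
    if (spec$five_prime_signature) {
      state$g[1:3] <- c("T", "T", "T")
      state$g[4:25] <- sample(c("A", "T"), 22L, replace = TRUE)
    } else {
      state$g[1:3] <- c("G", "C", "G")
      state$g[4:25] <- sample(c("G", "C", "A", "T"), 22L, replace = TRUE,
                              prob = c(0.35, 0.35, 0.15, 0.15))
    }
    state$locked[1:25] <- TRUE
  }

  # guard stops upstream of every planted start
  for (gt in sort(unique(c(chain$start, s[5])))) plant_guard(state, gt)

  seqstr <- paste(state$g, collapse = "")

  # ground-truth layout
  rows <- data.frame(orf_id = paste0("ORF", 1:5), start = s, end = e,
                     stringsAsFactors = FALSE)
  if (!is.null(spec$orf3a)) {
    rows <- rbind(rows, chain[chain$orf_id == "ORF3a",
                              c("orf_id", "start", "end")])
  }
  if (!is.null(orf2b_coords)) {
    rows <- rbind(rows, data.frame(orf_id = "ORF2b",
                                   start = orf2b_coords[["start"]],
                                   end = orf2b_coords[["end"]],
                                   stringsAsFactors = FALSE))
  }
  rows <- rows[order(rows$start), ]
  rows$length_nt <- rows$end - rows$start + 1L
  rows$frame_offset_vs_orf5 <- vapply(rows$start, frame_offset_vs,
                                      integer(1), orf5_start = s[5])
  rows$peptide <- vapply(seq_len(nrow(rows)), function(i)
    translate_string(substr(seqstr, rows$start[i], rows$end[i] - 3L)),
    character(1))
  rows <- rows[, c("orf_id", "start", "end", "frame_offset_vs_orf5",
                   "length_nt", "peptide")]
  rownames(rows) <- NULL
  truth <- new_genome_layout(sprintf("synth_%d", spec$seed), n, rows,
                             "polycipivirus_like",
                             orf5_motifs_found = TRUE,
                             five_prime_signature = spec$five_prime_signature,
                             extends_to_polya = spec$polya_len >= 10L)
  attr(truth, "motif_offsets") <- bp$offsets
  list(seq = seqstr, truth = truth, locked = state$locked)
}
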
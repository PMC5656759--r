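test_that("the Walker A motif is found in a peptide containing it", {
  withr::local_seed(1)
  pep <- paste0(random_peptide(40, alphabet = c("A", "E", "R", "Q")),
                "GESGSGKS",
                random_peptide(40, alphabet = c("A", "E", "R", "Q")))
  sc <- scan_motifs(pep)
  hit <- sc$hits[sc$hits$motif_id == "Hel-A", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$start_aa, 41L)
  expect_equal(hit$matched, "GESGSGKS")
})

test_that("the generator ORF5 peptide scans clean and ordered", {
  g <- generate_genome(genome_spec(seed = 2))
  pep <- g$truth$orfs$peptide[g$truth$orfs$orf_id == "ORF5"]
  sc <- scan_motifs(pep)
  expect_true(all(sc$domains_present))
  expect_true(sc$ordered_ok)
  offs <- attr(g$truth, "motif_offsets")
  for (id in sc$anchors$motif_id) {
    expect_equal(sc$anchors$start_aa[sc$anchors$motif_id == id],
                 unname(offs[[id]]), info = id)
  }
})

test_that("moving the RdRp block upstream of Hel breaks the ordering", {
  g <- generate_genome(genome_spec(seed = 2))
  pep <- g$truth$orfs$peptide[g$truth$orfs$orf_id == "ORF5"]
  sc <- scan_motifs(pep)
  a <- sc$anchors
  rd_start <- min(a$start_aa[a$domain == "RdRp"])
  rd_end <- max(a$end_aa[a$domain == "RdRp"])
  hel_start <- min(a$start_aa[a$domain == "Hel"])
  rd_block <- substr(pep, rd_start, rd_end)
  # excise the polymerase block and reinsert it before the helicase, then
  # truncate shortly after the protease site so no chance matches remain
  pro_end <- a$end_aa[a$motif_id == "Pro-cat"]
  rest <- paste0(substr(pep, 1, rd_start - 1), substr(pep, rd_end + 1,
                                                      nchar(pep)))
  moved <- paste0(substr(rest, 1, hel_start - 1), rd_block,
                  substr(rest, hel_start, pro_end + 10))
  sc2 <- scan_motifs(moved)
  expect_false(sc2$ordered_ok)
})

test_that("an empty peptide yields an empty unordered result", {
  sc <- scan_motifs("")
  expect_equal(nrow(sc$hits), 0L)
  expect_false(sc$ordered_ok)
  expect_equal(as.character(sc$triad_variant), "absent")
})

test_that("triad variants classify by the catalytic-site residue", {
  expect_equal(as.character(call_triad_variant("AAAGLSGAAA")), "GxSG")
  expect_equal(as.character(call_triad_variant("AAAGQCGAAA")), "GxCG")
  expect_equal(as.character(call_triad_variant("AAAAAAA")), "absent")
  g <- generate_genome(genome_spec(seed = 4, triad = "GxSG"))
  pep <- g$truth$orfs$peptide[g$truth$orfs$orf_id == "ORF5"]
  expect_equal(as.character(scan_motifs(pep)$triad_variant), "GxSG")
  g2 <- generate_genome(genome_spec(seed = 4, triad = "GxCG"))
  pep2 <- g2$truth$orfs$peptide[g2$truth$orfs$orf_id == "ORF5"]
  expect_equal(as.character(scan_motifs(pep2)$triad_variant), "GxCG")
})

test_that("motif VI variants classify by the first triplet residue", {
  expect_equal(as.character(call_motif6_variant("AAAYGDDAAA")), "GDD")
  expect_equal(as.character(call_motif6_variant("AAAMADDAAA")), "ADD")
  expect_equal(as.character(call_motif6_variant("AAFSDDAA")), "SDD")
  expect_equal(as.character(call_motif6_variant("AAAAAA")), "absent")
})

test_that("planted motif-VI variants are recovered exactly", {
  for (variant in c("GDD", "ADD", "SDD")) {
    g <- generate_genome(genome_spec(seed = 6, motif6_variant = variant))
    pep <- g$truth$orfs$peptide[g$truth$orfs$orf_id == "ORF5"]
    expect_equal(as.character(scan_motifs(pep)$motif6_variant), variant,
                 info = variant)
  }
})

test_that("X and gap characters never match a pattern class", {
  expect_equal(as.character(call_triad_variant("AAGXCGAA")), "absent")
  expect_equal(as.character(call_triad_variant("AAG-SGAA")), "absent")
  sc <- scan_motifs("GXXGXGKS")
  expect_equal(nrow(sc$hits[sc$hits$motif_id == "Hel-A", ]), 0L)
})

test_that("scan results are invariant under trailing residues", {
  g <- generate_genome(genome_spec(seed = 8))
  pep <- g$truth$orfs$peptide[g$truth$orfs$orf_id == "ORF5"]
  sc1 <- scan_motifs(pep)
  sc2 <- scan_motifs(paste0(pep, strrep("A", 200)))
  expect_equal(sc1$anchors, sc2$anchors)
  expect_equal(as.character(sc1$triad_variant),
               as.character(sc2$triad_variant))
  expect_equal(as.character(sc1$motif6_variant),
               as.character(sc2$motif6_variant))
})

test_that("hydropathy windows behave at the extremes", {
  pep <- paste0(strrep("D", 30), strrep("I", 19), strrep("E", 30))
  tm <- predict_tm(hydropathy_profile(pep))
  expect_true(tm$has_central_tm)
  expect_false(predict_tm(hydropathy_profile(strrep("D", 60)))$has_central_tm)
  # a terminal hydrophobic run is not "central"
  pep_n <- paste0(strrep("I", 19), strrep("D", 100))
  expect_false(predict_tm(hydropathy_profile(pep_n))$has_central_tm)
  # short peptides yield an empty profile
  expect_equal(nrow(hydropathy_profile("MKV")$windows), 0L)
})

test_that("hydropathy profiles equal the naive windowed mean", {
  withr::local_seed(7)
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
          E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2)
  for (i in 1:20) {
    pep <- random_peptide(sample(30:120, 1))
    for (w in c(7L, 19L)) {
      prof <- hydropathy_profile(pep, window_aa = w)
      vals <- unname(kd[strsplit(pep, "")[[1]]])
      if (length(vals) < w) {
        expect_equal(nrow(prof$windows), 0L)
      } else {
        naive <- vapply(seq_len(length(vals) - w + 1L), function(s)
          mean(vals[s:(s + w - 1L)]), numeric(1))
        expect_equal(prof$windows$mean_hydropathy, naive, tolerance = 1e-12)
      }
    }
  }
})

test_that("a custom motif library can replace the packaged one", {
  f <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("motifs:",
               "  - motif_id: toy",
               "    domain: Hel",
               "    pattern: \"KKK\"",
               "    required: true"), f)
  lib <- read_motif_library(f)
  expect_equal(lib$pattern, "KKK")
  sc <- scan_motifs("AAKKKAA", library = lib)
  expect_true(sc$domains_present[["Hel"]])
})
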
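test_that("strip_polya removes only qualifying tails and is idempotent", {
  r <- genome_record("g", paste0(random_dna(60), "GCT", strrep("A", 25)))
  s <- strip_polya(r)
  expect_equal(s$polya_trimmed_len, 25L)
  expect_true(s$extends_to_polya)
  expect_equal(substr(s$seq, nchar(s$seq) - 2, nchar(s$seq)), "GCT")
  expect_equal(strip_polya(s)$seq, s$seq)
  r2 <- genome_record("g", paste0(random_dna(60), "GCT", strrep("A", 5)))
  s2 <- strip_polya(r2)
  expect_equal(s2$polya_trimmed_len, 0L)
  expect_false(s2$extends_to_polya)
})

test_that("strip_polya recovers the planted pre-tail length", {
  g <- generate_genome(genome_spec(seed = 3, polya_len = 30L))
  s <- strip_polya(g$record)
  expect_equal(nchar(s$seq), g$truth$seq_len)
  expect_equal(s$polya_trimmed_len, 30L)
})

test_that("find_orfs handles the textbook cases", {
  orfs <- find_orfs("ATGAAATAA", min_len_nt = 9L)
  expect_equal(nrow(orfs), 1L)
  expect_equal(orfs$start, 1L)
  expect_equal(orfs$end, 9L)
  expect_equal(orfs$peptide, "MK")
  expect_equal(nrow(find_orfs("CCCCCCCCCCCC", min_len_nt = 6L)), 0L)
})

test_that("find_orfs agrees with a brute-force scan on random sequences", {
  withr::local_seed(42)
  for (i in 1:60) {
    seq <- random_dna(1200)
    got <- find_orfs(seq, 99L)[, c("start", "end")]
    want <- oracle_find_orfs(seq, 99L)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, info = sprintf("sequence %d", i))
  }
})

test_that("the 5' completeness signature is detected", {
  expect_true(five_prime_signature(paste0("TTT", strrep("AT", 11))))
  expect_false(five_prime_signature(paste0("GGG", strrep("AT", 11))))
  g_on <- generate_genome(genome_spec(seed = 5, five_prime_signature = TRUE))
  g_off <- generate_genome(genome_spec(seed = 5, five_prime_signature = FALSE))
  expect_true(five_prime_signature(g_on$record$seq))
  expect_false(five_prime_signature(g_off$record$seq))
})

test_that("layout_stats reproduces the printed arithmetic", {
  rows <- read_layout_table()
  st <- layout_stats(rows[["SINV-2"]])
  expect_equal(st$utr5_len, 301L)
  expect_equal(st$igr_len, 662L)
  expect_equal(st$utr3_len, 387L)
  expect_equal(unname(st$junction_gaps), c(-4L, -8L, -4L))
  # an ORF1 at position 1 has a zero-length 5' UTR
  lay <- genome_layout("g", 3000L,
                       data.frame(orf_id = c("ORF1", "ORF2", "ORF3",
                                             "ORF4", "ORF5"),
                                  start = c(1L, 301L, 601L, 901L, 1501L),
                                  end = c(300L, 600L, 900L, 1200L, 2700L)))
  expect_equal(layout_stats(lay)$utr5_len, 0L)
})

test_that("overlapping ORF4/ORF5 (negative IGR) is an error", {
  expect_error(
    genome_layout("g", 3000L,
                  data.frame(orf_id = c("ORF4", "ORF5"),
                             start = c(1L, 290L),
                             end = c(300L, 2689L))),
    "negative intergenic")
})

test_that("infer_layout recovers a published-coordinate mirror exactly", {
  # geometry of the type species row: 301/662/387 UTRs, ORF lengths and
  # overlaps from the printed coordinates
  spec <- genome_spec(utr5_len = 301L, utr3_len = 387L, igr_len = 662L,
                      orf_lens = c(ORF1 = 777L, ORF2 = 804L, ORF3 = 777L,
                                   ORF4 = 1149L, ORF5 = 6462L),
                      junction_gaps = c(-4L, -8L, -4L),
                      orf2b = list(offset = 4L, len = 231L,
                                   hydrophobic_core = TRUE),
                      seed = 17)
  g <- generate_genome(spec)
  expect_equal(g$truth$seq_len, 11303L)
  lay <- infer_layout(g$record)
  expect_equal(lay$status, "polycipivirus_like")
  expect_equal(main_coords(lay), main_coords(g$truth))
  expect_equal(unname(lay$junction_gaps), c(-4L, -8L, -4L))
  expect_equal(lay$utr5_len, 301L)
  expect_equal(lay$igr_len, 662L)
  expect_equal(lay$utr3_len, 387L)
  # frame offsets follow the (start - ORF5.start) mod 3 convention
  offs <- setNames(lay$orfs$frame_offset_vs_orf5, lay$orfs$orf_id)
  expect_equal(unname(offs["ORF5"]), 0L)
  expect_true(all(offs %in% c(-1L, 0L, 1L)))
})

test_that("infer_layout is invariant to the poly(A) tail", {
  g <- generate_genome(genome_spec(seed = 23, polya_len = 60L))
  with_tail <- infer_layout(g$record)
  no_tail <- infer_layout(strip_polya(g$record))
  expect_equal(with_tail$orfs[, c("orf_id", "start", "end")],
               no_tail$orfs[, c("orf_id", "start", "end")])
})

test_that("a dicistrovirus-like decoy is not polycipivirus-like", {
  d <- generate_decoys("dicistro_like", n = 1, seed = 9)[[1]]
  lay <- infer_layout(d)
  expect_equal(lay$status, "not_polycipivirus_like")
  expect_true(any(grepl("no_four_orf_chain", lay$evidence)))
})

test_that("an oversized junction is bridged by ORF3a", {
  spec <- genome_spec(junction_gaps = c(-4L, 202L, -4L),
                      orf2b = NULL,
                      orf3a = list(offset = -4L, len = 210L),
                      seed = 31)
  g <- generate_genome(spec)
  lay <- infer_layout(g$record)
  expect_equal(lay$status, "polycipivirus_like")
  expect_true("ORF3a" %in% lay$orfs$orf_id)
  got <- lay$orfs[lay$orfs$orf_id == "ORF3a", c("start", "end")]
  want <- g$truth$orfs[g$truth$orfs$orf_id == "ORF3a", c("start", "end")]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
  expect_equal(main_coords(lay), main_coords(g$truth))
})

test_that("detect_orf2b applies the frame, position and TM rules", {
  g <- generate_genome(genome_spec(seed = 41))
  rec <- strip_polya(g$record)
  lay <- infer_layout(rec)
  hit <- detect_orf2b(lay, rec$seq)
  want <- g$truth$orfs[g$truth$orfs$orf_id == "ORF2b", ]
  expect_false(is.null(hit))
  expect_equal(hit$start, want$start)
  expect_equal(hit$end, want$end)
  expect_equal((hit$start - lay$orfs$start[lay$orfs$orf_id == "ORF2"]) %% 3,
               1)
  # shifting the claimed ORF2 start breaks the +1 frame rule
  shifted <- lay
  shifted$orfs$start[shifted$orfs$orf_id == "ORF2"] <-
    shifted$orfs$start[shifted$orfs$orf_id == "ORF2"] - 1L
  expect_null(detect_orf2b(shifted, rec$seq))
})

test_that("a scrambled hydrophobic core abolishes ORF2b detection", {
  spec_on <- genome_spec(seed = 43,
                         orf2b = list(offset = 4L, len = 231L,
                                      hydrophobic_core = TRUE))
  spec_off <- genome_spec(seed = 43,
                          orf2b = list(offset = 4L, len = 231L,
                                       hydrophobic_core = FALSE))
  g_on <- generate_genome(spec_on)
  g_off <- generate_genome(spec_off)
  rec_on <- strip_polya(g_on$record)
  rec_off <- strip_polya(g_off$record)
  expect_false(is.null(detect_orf2b(infer_layout(rec_on), rec_on$seq)))
  expect_null(detect_orf2b(infer_layout(rec_off), rec_off$seq))
})
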
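test_that("read_fasta normalizes sequences and preserves order", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x some virus", "acgu", ">y", "GGNNtt"), f)
  recs <- read_fasta(f)
  expect_length(recs, 2L)
  expect_equal(recs[[1]]$id, "x")
  expect_equal(recs[[1]]$description, "some virus")
  expect_equal(recs[[1]]$seq, "ACGT")
  expect_equal(recs[[2]]$seq, "GGNNTT")
  expect_equal(vapply(recs, `[[`, character(1), "id"), c("x", "y"))
})

test_that("read_fasta handles empty and malformed files", {
  f <- withr::local_tempfile(fileext = ".fasta")
  file.create(f)
  expect_identical(read_fasta(f), list())
  writeLines(c("ACGT", ">x", "ACGT"), f)
  expect_error(read_fasta(f), "line 1")
})

test_that("FASTA write/read round-trip is lossless on sequences", {
  withr::local_seed(11)
  recs <- lapply(1:100, function(i) {
    genome_record(sprintf("r%03d", i), random_dna(sample(50:200, 1)))
  })
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, f)
  back <- read_fasta(f)
  expect_equal(vapply(back, `[[`, character(1), "seq"),
               vapply(recs, `[[`, character(1), "seq"))
  expect_equal(vapply(back, `[[`, character(1), "id"),
               vapply(recs, `[[`, character(1), "id"))
})

test_that("GFF3 output carries the printed coordinates and round-trips", {
  rows <- read_layout_table()
  r <- rows[["SINV-2"]]
  co <- do.call(rbind, lapply(names(r$orf_coords), function(o)
    data.frame(orf_id = o, start = r$orf_coords[[o]][["start"]],
               end = r$orf_coords[[o]][["end"]])))
  lay <- genome_layout("SINV-2", r$seq_len, co)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(lay, f)
  txt <- readLines(f)
  expect_true(any(grepl("CDS\t302\t1078\t.*ID=ORF1", txt)))
  back <- read_gff3(f)
  back <- back[order(back$start), ]
  expect_equal(back$start, sort(co$start))
  expect_equal(back$end, co$end[order(co$start)])
})

test_that("an empty layout writes a header-only GFF3", {
  lay <- list(genome_id = "g", seq_len = 100L,
              orfs = data.frame(orf_id = character(0), start = integer(0),
                                end = integer(0)))
  class(lay) <- "genome_layout"
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(lay, f)
  expect_true(grepl("^##gff-version", readLines(f)[1]))
  expect_equal(nrow(read_gff3(f)), 0L)
})

test_that("the packaged layout table parses with all invariants", {
  rows <- read_layout_table()
  expect_length(rows, 15L)
  sinv2 <- rows[["SINV-2"]]
  expect_equal(sinv2$seq_len, 11303L)
  expect_equal(unname(sinv2$orf_coords$ORF5), c(4455L, 10916L))
  # the 3'-incomplete row keeps its ORF5 start but has no end
  expect_true(is.na(rows[["LniV-1"]]$orf_coords$ORF5[["end"]]))
  # the 5'-truncated row has no ORF1 or ORF2 entry
  part <- rows[["Hubei picorna-like virus 81 KX884540.1"]]
  expect_false("ORF1" %in% names(part$orf_coords))
  expect_false("ORF2" %in% names(part$orf_coords))
  # the extra ORF3a of the F. exsecta assembly
  expect_equal(unname(rows[["F. exsecta TSA"]]$orf_coords$ORF3a),
               c(1873L, 2082L))
  # frame invariant over every complete coordinate pair
  for (r in rows) {
    for (co in r$orf_coords) {
      if (!anyNA(co)) expect_equal((co[["end"]] - co[["start"]] + 1) %% 3, 0)
    }
  }
  expect_equal(sum(vapply(rows, `[[`, logical(1), "extends_to_polya")), 8L)
})

test_that("a frame-invariant violation is reported with row and ORF", {
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- read.delim(system.file("extdata", "polycipiviridae_layout.tsv",
                               package = "polycivir"), sep = "\t")
  df$orf1_end[df$name == "SINV-2"] <- 1079L
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  expect_error(read_layout_table(f), "SINV-2.*ORF1")
})

test_that("pileup parsing validates counts and handles empty input", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("genome_id\tpos\tdepth\tcountA\tcountC\tcountG\tcountT",
               "g1\t5\t100\t90\t10\t0\t0"), f)
  pu <- read_pileup(f)
  expect_equal(pu$depth, 100L)
  expect_equal(pu$countC / pu$depth, 0.10)
  file.create(f2 <- withr::local_tempfile(fileext = ".tsv"))
  expect_equal(nrow(read_pileup(f2)), 0L)
  writeLines(c("genome_id\tpos\tdepth\tcountA\tcountC\tcountG\tcountT",
               "g1\t5\t100\t90\t20\t0\t0"), f)
  expect_error(read_pileup(f), "above depth")
})

test_that("simulated pileups survive the write/read round-trip", {
  withr::local_seed(21)
  g <- genome_record("g1", random_dna(400))
  alt <- setdiff(c("A", "C", "G", "T"), substr(g$seq, 50, 50))[1]
  sim <- simulate_pileup(g, mean_depth = 30,
                         snps = data.frame(pos = 50L, alt = alt,
                                           freq = 0.3),
                         seed = 5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pileup(sim$pileup, f)
  back <- read_pileup(f)
  expect_equal(back, sim$pileup)
})

test_that("hit tables round-trip through the six-column TSV", {
  hits <- data.frame(query_id = "q", subject_id = c("a", "b"),
                     pct_identity = c(88.1, 17.2), aln_len = c(100L, 40L),
                     score = c(350.5, 33), evalue = c(1e-40, 0.2),
                     stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hits(hits, f)
  expect_equal(read_hits(f), hits)
})
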
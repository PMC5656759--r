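pileup_row <- function(id, pos, depth, a = 0, c = 0, g = 0, t = 0) {
  data.frame(genome_id = id, pos = pos, depth = depth, countA = a,
             countC = c, countG = g, countT = t, stringsAsFactors = FALSE)
}

test_that("the SNP frequency threshold is strict", {
  ref <- genome_record("g1", paste0("A", random_dna(99)))
  pu <- rbind(pileup_row("g1", 1, 100, a = 91, c = 9),
              pileup_row("g1", 1, 1000, a = 899, c = 101))
  # 9% excluded
  expect_equal(nrow(filter_snps(pu[1, ], ref)), 0L)
  # 10.1% included
  snps <- filter_snps(pu[2, ], ref)
  expect_equal(nrow(snps), 1L)
  expect_equal(snps$alt, "C")
  expect_equal(snps$alt_frac, 0.101)
  # exactly 10% is not "more than 10%"
  pu10 <- pileup_row("g1", 1, 100, a = 90, c = 10)
  expect_equal(nrow(filter_snps(pu10, ref)), 0L)
})

test_that("filter_snps recovers exactly the planted SNPs", {
  withr::local_seed(63)
  g <- genome_record("g1", random_dna(2000))
  pos <- sort(sample(2000, 12))
  alt <- vapply(pos, function(p)
    setdiff(c("A", "C", "G", "T"), substr(g$seq, p, p))[1], character(1))
  sim <- simulate_pileup(g, mean_depth = 500,
                         snps = data.frame(pos = pos, alt = alt,
                                           freq = 0.25),
                         seed = 64)
  snps <- filter_snps(sim$pileup, g)
  expect_equal(snps$pos, pos)
  expect_equal(snps$alt, alt)
  # row order of the pileup does not matter
  shuf <- sim$pileup[sample(nrow(sim$pileup)), ]
  expect_equal(filter_snps(shuf, g), snps)
})

test_that("recovered SNP frequencies are unbiased", {
  withr::local_seed(65)
  g <- genome_record("g1", random_dna(3000))
  errs <- c()
  for (s in 1:20) {
    pos <- sort(sample(3000, 5))
    alt <- vapply(pos, function(p)
      setdiff(c("A", "C", "G", "T"), substr(g$seq, p, p))[1], character(1))
    freq <- runif(5, 0.2, 0.8)
    sim <- simulate_pileup(g, 400, data.frame(pos = pos, alt = alt,
                                              freq = freq), seed = s)
    snps <- filter_snps(sim$pileup, g)
    m <- match(pos, snps$pos)
    errs <- c(errs, abs(snps$alt_frac[m] - freq))
  }
  expect_lt(mean(errs, na.rm = TRUE), 2 / sqrt(400))
})

test_that("pileup/genome id mismatches are errors", {
  ref <- genome_record("g1", random_dna(100))
  pu <- pileup_row("OTHER", 1, 10, a = 10)
  expect_error(filter_snps(pu, ref), "does not match")
})

test_that("synonymous substitutions are recognized by code degeneracy", {
  # GGA -> GGG at the third codon position: both glycine
  seq <- paste0("ATG", "GGA", "TAA", "CCCCCC")
  lay <- genome_layout("g", nchar(seq),
                       data.frame(orf_id = "ORF1", start = 1L, end = 9L))
  call <- classify_snp(list(pos = 6L, ref = "A", alt = "G"), lay, seq)
  expect_equal(call$effect, "synonymous")
  expect_equal(call$codon_index, 2L)
  call2 <- classify_snp(list(pos = 4L, ref = "G", alt = "A"), lay, seq)
  expect_equal(call2$effect, "nonsynonymous")
  expect_error(classify_snp(list(pos = 6L, ref = "A", alt = "A"), lay, seq),
               "alt equal to ref")
})

test_that("a SNP in an ORF-ORF overlap yields one call per ORF", {
  g <- generate_genome(genome_spec(seed = 67, junction_gaps = c(-4L, -8L, -4L)))
  seq <- strip_polya(g$record)$seq
  tr <- g$truth$orfs
  e1 <- tr$end[tr$orf_id == "ORF1"]
  s2 <- tr$start[tr$orf_id == "ORF2"]
  pos <- e1 - 3L  # inside the 4-nt overlap, clear of the planted stop/start
  # choose a position covered by both ORFs
  expect_true(pos >= s2 && pos <= e1)
  ref <- substr(seq, pos, pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  calls <- classify_snp(list(pos = pos, ref = ref, alt = alt), g$truth, seq)
  expect_equal(sort(calls$orf_id), c("ORF1", "ORF2"))
  expect_equal(nrow(calls), 2L)
})

test_that("positions outside every ORF are noncoding", {
  g <- generate_genome(genome_spec(seed = 69))
  seq <- strip_polya(g$record)$seq
  ref <- substr(seq, 5, 5)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  call <- classify_snp(list(pos = 5L, ref = ref, alt = alt), g$truth, seq)
  expect_equal(call$effect, "noncoding")
})

test_that("aggregate_counts reproduces per-ORF s/t bookkeeping", {
  expect_equal(aggregate_counts(classify_snps(
    data.frame(pos = integer(0), ref = character(0),
               alt = character(0)),
    genome_layout("g", 100L, data.frame(orf_id = "ORF1", start = 1L,
                                        end = 9L)),
    random_dna(100)))$total_snps, 0L)
  withr::local_seed(71)
  for (i in 1:10) {
    counts <- sapply(1:5, function(k) sample(0:20, 2))
    calls <- do.call(rbind, lapply(1:5, function(k) {
      syn <- min(counts[, k]); tot <- max(counts[, k])
      if (tot == 0) return(NULL)
      data.frame(pos = 1L, ref = "A", alt = "C",
                 orf_id = paste0("ORF", k), codon_index = 1L,
                 ref_codon = "AAA", alt_codon = "AAC", ref_aa = "K",
                 alt_aa = "N",
                 effect = c(rep("synonymous", syn),
                            rep("nonsynonymous", tot - syn)),
                 accessory = FALSE)
    }))
    agg <- aggregate_counts(calls)
    expect_equal(agg$total_snps, sum(agg$per_orf$total))
    expect_equal(agg$total_synonymous, sum(agg$per_orf$synonymous))
  }
})

test_that("coverage windows equal the naive mean and the uniform case", {
  pu <- pileup_row("g", 1:200, 50, a = 50)
  cw <- coverage_windows(pu, 200L, window = 21L)
  expect_equal(cw, rep(50, 200))
  expect_equal(mean_coverage(pu, 200L), 50)
  withr::local_seed(73)
  for (i in 1:10) {
    n <- sample(100:300, 1)
    pos <- sort(sample(n, sample(20:60, 1)))
    depth <- sample(0:100, length(pos), replace = TRUE)
    pu <- pileup_row("g", pos, depth, a = depth)
    full <- numeric(n)
    full[pos] <- depth
    w <- sample(c(7L, 50L, 101L), 1)
    expect_equal(coverage_windows(pu, n, w), oracle_window_means(full, w))
    expect_equal(mean_coverage(pu, n), sum(depth) / n)
  }
})
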
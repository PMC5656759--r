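test_that("p-distance matrices are symmetric with a zero diagonal", {
  withr::local_seed(37)
  peps <- setNames(vapply(1:6, function(i) random_peptide(60), character(1)),
                   paste0("t", 1:6))
  peps["t2"] <- peps["t1"]
  d <- pdistance_matrix(peps)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 6))
  expect_equal(d["t1", "t2"], 0)
  expect_error(pdistance_matrix(c(a = "MK", b = "", c = "MK")), "taxon 'b'")
})

test_that("family divergence matches an independent codon-level oracle", {
  # two leaves separated by a total path of 0.2 substitutions/site
  tr <- read_newick("(a:0.1,b:0.1);")
  fam <- evolve_family(family_spec(template = sample_genome_spec(7),
                                   tree = tr, seed = 7))
  pep <- vapply(fam$records, function(r) longest_orf_peptide(r$seq),
                character(1))
  obs <- 1 - global_align(pep[["a"]], pep[["b"]])$pct_identity / 100
  # oracle: evolve random sense codons under the same proposal/rejection
  # rule and measure the amino-acid mismatch fraction
  withr::local_seed(77)
  n_cod <- 6000L
  sense <- polycivir:::pcv_sense_codons()
  stops <- polycivir:::pcv_stop_codons()
  evolve_codons <- function(cods, p_site) {
    bases <- unlist(strsplit(cods, ""))
    n_sub <- rpois(1, p_site * length(bases))
    done <- 0L; tries <- 0L
    while (done < n_sub && tries < n_sub * 30L) {
      tries <- tries + 1L
      i <- sample.int(length(bases), 1)
      new <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1)
      ci <- (i - 1L) %/% 3L
      cod <- bases[(ci * 3L + 1L):(ci * 3L + 3L)]
      cod[(i - 1L) %% 3L + 1L] <- new
      if (paste(cod, collapse = "") %in% stops) next
      bases[i] <- new
      done <- done + 1L
    }
    apply(matrix(bases, nrow = 3L), 2, paste, collapse = "")
  }
  root <- sample(sense, n_cod, replace = TRUE)
  a <- evolve_codons(root, 0.1)
  b <- evolve_codons(root, 0.1)
  gc <- Biostrings::GENETIC_CODE
  expected <- mean(gc[a] != gc[b])
  expect_lt(abs(obs - expected), 0.03)
})

test_that("p-distance grows monotonically with branch scaling", {
  base <- ape::rtree(4, rooted = TRUE, br = NULL)
  base$tip.label <- paste0("x", 1:4)
  base$edge.length <- rep(0.02, nrow(base$edge))
  means <- vapply(c(0.5, 1, 2, 4, 8), function(sc) {
    tr <- base
    tr$edge.length <- tr$edge.length * sc
    fam <- evolve_family(family_spec(template = sample_genome_spec(11),
                                     tree = tr, seed = 11))
    pep <- vapply(fam$records, function(r) longest_orf_peptide(r$seq),
                  character(1))
    d <- pdistance_matrix(pep, window = c(1, 400))
    mean(d[upper.tri(d)])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("a zero-rate family reproduces the template exactly", {
  fam <- evolve_family(family_spec(template = genome_spec(seed = 13),
                                   n_taxa = 4, subs_rate = 0, seed = 13))
  seqs <- vapply(fam$records, `[[`, character(1), "seq")
  expect_true(all(seqs == fam$template$record$seq))
})

test_that("neighbor joining solves the three-taxon case in closed form", {
  d <- matrix(c(0, 0.3, 0.5,
                0.3, 0, 0.6,
                0.5, 0.6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  expect_equal(sort(tr$tip.label), c("a", "b", "c"))
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl["a"]), (0.3 + 0.5 - 0.6) / 2)
  expect_equal(unname(bl["b"]), (0.3 + 0.6 - 0.5) / 2)
  expect_equal(unname(bl["c"]), (0.5 + 0.6 - 0.3) / 2)
})

test_that("neighbor joining recovers additive matrices exactly", {
  withr::local_seed(41)
  for (i in 1:12) {
    case <- random_additive_case(sample(4:12, 1))
    tr <- nj_tree(case$d)
    expect_equal(phangorn::RF.dist(ape::unroot(case$tree), tr), 0)
    got <- ape::cophenetic.phylo(tr)[rownames(case$d), colnames(case$d)]
    expect_equal(got, case$d, tolerance = 1e-9)
  }
})

test_that("nj_tree validates its input matrix", {
  d <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(nj_tree(d), ">= 3 taxa")
  d3 <- matrix(c(0, 1, 2, 1.5, 0, 1, 2, 1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(d3), "symmetric")
})

test_that("midpoint rooting balances the deepest leaves", {
  tr2 <- read_newick("(a:1,b:3);")
  r2 <- midpoint_root(tr2)
  expect_equal(sort(r2$edge.length), c(2, 2))
  withr::local_seed(43)
  for (i in 1:30) {
    tr <- ape::rtree(sample(4:10, 1))
    r <- midpoint_root(tr)
    depths <- ape::node.depth.edgelength(r)[seq_along(r$tip.label)]
    two <- sort(depths, decreasing = TRUE)[1:2]
    expect_equal(two[1], two[2], tolerance = 1e-8)
  }
})

test_that("monophyly is exact leaf-set membership", {
  tr <- read_newick("(((a:1,b:1):1,c:2):1,(d:1,e:1):2);")
  expect_true(is_monophyletic(tr, c("a", "b")))
  expect_true(is_monophyletic(tr, c("a", "b", "c")))
  expect_false(is_monophyletic(tr, c("a", "c")))
  expect_true(is_monophyletic(tr, c("a", "b", "c", "d", "e")))
  expect_error(is_monophyletic(tr, c("a", "zzz")), "zzz")
})

test_that("Newick round-trips preserve topology, lengths and labels", {
  tr <- read_newick("(a:1,b:1);")
  expect_equal(sort(tr$tip.label), c("a", "b"))
  expect_equal(read_newick(write_newick(tr))$edge.length, tr$edge.length)
  withr::local_seed(47)
  case <- random_additive_case(8)
  tr2 <- nj_tree(case$d)
  back <- read_newick(write_newick(tr2))
  expect_equal(phangorn::RF.dist(tr2, back), 0)
  expect_equal(sort(back$edge.length), sort(tr2$edge.length),
               tolerance = 1e-6)
  # labels with spaces survive, quoted
  trq <- read_newick("('Solenopsis virus 2':1,other:2);")
  expect_true("Solenopsis virus 2" %in% trq$tip.label)
  s <- write_newick(trq)
  expect_true(grepl("'Solenopsis virus 2'", s))
  expect_true("Solenopsis virus 2" %in% read_newick(s)$tip.label)
})

test_that("malformed Newick strings fail with a position", {
  expect_error(read_newick("((a:1,b:1);"), "position")
  expect_error(read_newick("(a:1,b:1)));"), "position")
})
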
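# Evolving a synthetic genome along a tree, negative-control decoys, and
# pileup simulation — the remaining seeded generators with ground truth.

#' Specify a synthetic virus family
#'
#' A template genome spec plus a tree along which it is evolved. When no
#' tree is given, a random topology with `n_taxa` leaves is drawn and
#' each edge receives a length of `subs_rate` nucleotide substitutions
#' per site scaled by a uniform factor in `[0.5, 1.5]`.
#'
#' @param template A [genome_spec()] for the common ancestor.
#' @param n_taxa Number of leaves when `tree` is `NULL`.
#' @param tree Optional `phylo` tree with edge lengths in substitutions
#'   per site.
#' @param subs_rate Per-edge substitution rate (subs/site) used to scale
#'   the random tree.
#' @param seed Integer seed.
#' @return An object of class `family_spec`.
#' @export
family_spec <- function(template = genome_spec(), n_taxa = 12L,
                        tree = NULL, subs_rate = 0.05, seed = 1L) {
  pcv_assert(inherits(template, "genome_spec"), "template must be a genome_spec")
  pcv_assert(is.null(tree) || inherits(tree, "phylo"),
             "tree must be NULL or a phylo object")
  pcv_assert(is_scalar_number(subs_rate) && subs_rate >= 0,
             "subs_rate must be >= 0")
  structure(list(template = template, n_taxa = as.integer(n_taxa),
                 tree = tree, subs_rate = subs_rate,
                 seed = as.integer(seed)),
            class = "family_spec")
}

# Apply `n_sub` accepted substitutions to a base vector. Proposals are
# uniform over (site, new base); a proposal is rejected when the site is
# locked (start/stop codons, motif blocks, ORF2b, the 5' signature) or
# when the change would create a stop codon inside any ORF reading frame
# covering the site.
mutate_seq <- function(bases, n_sub, locked, orfs) {
  n <- length(bases)
  nt <- c("A", "C", "G", "T")
  accepted <- 0L
  tries <- 0L
  max_tries <- n_sub * 30L + 1000L
  while (accepted < n_sub && tries < max_tries) {
    tries <- tries + 1L
    p <- sample.int(n, 1L)
    if (locked[p]) next
    old <- bases[p]
    new <- sample(setdiff(nt, old), 1L)
    ok <- TRUE
    for (i in seq_len(nrow(orfs))) {
      s <- orfs$start[i]; e <- orfs$end[i]
      if (p < s || p > e) next
      cstart <- s + 3L * ((p - s) %/% 3L)
      if (cstart + 2L > e) next
      cod <- bases[cstart:(cstart + 2L)]
      cod[p - cstart + 1L] <- new
      if (cstart < e - 2L && paste(cod, collapse = "") %in%
            pcv_stop_codons()) {
        ok <- FALSE
        break
      }
    }
    if (!ok) next
    bases[p] <- new
    accepted <- accepted + 1L
  }
  bases
}

#' Evolve a synthetic family along a tree
#'
#' Generates the template genome, then applies substitutions along every
#' edge of the (given or sampled) tree: the number of substitutions on an
#' edge is Poisson with mean `edge length x genome length`, and proposals
#' that would create an in-frame stop or touch a planted feature are
#' rejected, so every leaf retains the full planted architecture. The
#' true tree is returned for topology-recovery tests.
#'
#' @param fspec A [family_spec()].
#' @return A list of class `synthetic_family`: `records` (leaf
#'   [genome_record()]s, poly(A) attached, named by tip label), `tree`
#'   (the true `phylo`), `template` (the [generate_genome()] result for
#'   the ancestor), and `truth` (the shared layout coordinates).
#' @export
evolve_family <- function(fspec) {
  pcv_assert(inherits(fspec, "family_spec"), "need a family_spec")
  base <- generate_genome(fspec$template)
  pcv_with_seed(fspec$seed + 1L, {
    tree <- fspec$tree
    if (is.null(tree)) {
      tree <- ape::rtree(fspec$n_taxa, rooted = TRUE, br = NULL)
      tree$tip.label <- sprintf("fam%02d", seq_len(fspec$n_taxa))
      tree$edge.length <- fspec$subs_rate *
        runif(nrow(tree$edge), 0.5, 1.5)
    }
    pre_len <- base$truth$seq_len
    root_seq <- strsplit(substr(base$record$seq, 1L, pre_len),
                         "", fixed = TRUE)[[1]]
    orfs <- base$truth$orfs[, c("orf_id", "start", "end")]
    n_node <- max(tree$edge)
    seqs <- vector("list", n_node)
    root <- length(tree$tip.label) + 1L
    seqs[[root]] <- root_seq
    # preorder over edges (parent always precedes child in ape's edge
    # matrix after reordering)
    ord <- ape::reorder.phylo(tree, "cladewise")
    for (k in seq_len(nrow(ord$edge))) {
      parent <- ord$edge[k, 1L]
      child <- ord$edge[k, 2L]
      bl <- ord$edge.length[k]
      n_sub <- rpois(1L, bl * pre_len)
      seqs[[child]] <- mutate_seq(seqs[[parent]], n_sub, base$locked, orfs)
    }
    tail <- strrep("A", fspec$template$polya_len)
    records <- lapply(seq_along(tree$tip.label), function(i) {
      genome_record(id = tree$tip.label[i],
                    seq = paste0(paste(seqs[[i]], collapse = ""), tail),
                    description = "synthetic family member")
    })
    names(records) <- tree$tip.label
    structure(list(records = records, tree = tree, template = base,
                   truth = base$truth),
              class = "synthetic_family")
  })
}

#' Generate negative-control decoy genomes
#'
#' Three kinds: `dicistro_like` builds a dicistrovirus-style genome — two
#' long ORFs only, the 5'-proximal one carrying the Hel/Pro/RdRp motif
#' blocks (the arrangement that contrasts with the family's split
#' structural module); `shuffled` applies a mononucleotide shuffle to a
#' source genome (base composition preserved exactly); `random` draws
#' i.i.d. uniform bases.
#'
#' @param kind `"dicistro_like"`, `"shuffled"` or `"random"`.
#' @param n Number of decoys.
#' @param seed Integer seed.
#' @param source A [genome_record()] (or string) to shuffle; required for
#'   `kind = "shuffled"`.
#' @param len Genome length for `kind = "random"`.
#' @return A list of [genome_record()] objects.
#' @export
generate_decoys <- function(kind = c("dicistro_like", "shuffled", "random"),
                            n = 1L, seed = 1L, source = NULL,
                            len = 11000L) {
  kind <- match.arg(kind)
  pcv_with_seed(seed, {
    lapply(seq_len(n), function(i) {
      id <- sprintf("decoy_%s_%d", kind, i)
      seq <- switch(kind,
        random = paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                       collapse = ""),
        shuffled = {
          pcv_assert(!is.null(source), "shuffled decoys need a source genome")
          src <- if (inherits(source, "genome_record")) source$seq
                 else normalize_nt(source)
          paste(sample(strsplit(src, "", fixed = TRUE)[[1]]), collapse = "")
        },
        dicistro_like = build_dicistro_decoy())
      genome_record(id = id, seq = seq,
                    description = sprintf("%s decoy", kind))
    })
  })
}

# Two-ORF decoy: 5' non-structural-style ORF with motif blocks, 3'
# structural-style ORF, ~11.3 kb plus poly(A).
build_dicistro_decoy <- function() {
  utr5 <- 600L; orfa_nt <- 5703L; igr <- 250L; orfb_nt <- 3999L
  utr3 <- 400L; polya <- 30L
  len_aa <- orfa_nt %/% 3L - 1L
  bp <- build_orf5_peptide(len_aa, "GxCG", "GDD", flavor = "decoy")
  orfa <- c("A", "T", "G", split_bases(codons_for_residues(bp$residues)),
            random_stop())
  orfb <- c("A", "T", "G",
            split_bases(sample(pcv_sense_codons(), orfb_nt %/% 3L - 2L,
                               replace = TRUE)),
            random_stop())
  paste(c(sample(c("A", "C", "G", "T"), utr5, replace = TRUE),
          orfa,
          sample(c("A", "C", "G", "T"), igr, replace = TRUE),
          orfb,
          sample(c("A", "C", "G", "T"), utr3, replace = TRUE),
          rep("A", polya)),
        collapse = "")
}

#' Simulate a read-mapping pileup
#'
#' Per-position depth is Poisson with mean `mean_depth`; at planted SNP
#' positions the alternative-base count is Binomial(depth, freq) and the
#' remainder supports the reference base; all other positions are purely
#' reference. No read-error model is applied. The same seed reproduces
#' the counts exactly.
#'
#' @param genome A [genome_record()] (or nucleotide string).
#' @param mean_depth Mean coverage depth (>= 0).
#' @param snps Data frame with columns `pos`, `alt`, `freq` (frequencies
#'   in (0, 1)); may be empty.
#' @param seed Integer seed.
#' @return A list: `pileup` (data frame in the [read_pileup()] layout)
#'   and `truth` (the planted SNP table).
#' @export
simulate_pileup <- function(genome, mean_depth,
                            snps = data.frame(pos = integer(0),
                                              alt = character(0),
                                              freq = numeric(0)),
                            seed = 1L) {
  if (!inherits(genome, "genome_record")) {
    genome <- genome_record("genome", genome)
  }
  pcv_assert(is_scalar_number(mean_depth) && mean_depth >= 0,
             "mean_depth must be >= 0")
  L <- nchar(genome$seq)
  if (nrow(snps) > 0L) {
    pcv_assert(all(snps$pos >= 1 & snps$pos <= L), "SNP positions invalid")
    pcv_assert(all(snps$freq > 0 & snps$freq < 1),
               "SNP frequencies must lie in (0, 1)")
    refs <- substr(rep(genome$seq, nrow(snps)), snps$pos, snps$pos)
    pcv_assert(all(refs != snps$alt), "SNP alt equals the reference base")
  }
  pcv_with_seed(seed, {
    depth <- rpois(L, mean_depth)
    counts <- matrix(0L, nrow = L, ncol = 4L,
                     dimnames = list(NULL, c("A", "C", "G", "T")))
    refbase <- strsplit(genome$seq, "", fixed = TRUE)[[1]]
    ref_idx <- match(refbase, colnames(counts))
    ok <- !is.na(ref_idx)
    counts[cbind(which(ok), ref_idx[ok])] <- depth[ok]
    if (nrow(snps) > 0L) {
      for (i in seq_len(nrow(snps))) {
        p <- snps$pos[i]
        d <- depth[p]
        a <- rbinom(1L, d, snps$freq[i])
        counts[p, snps$alt[i]] <- counts[p, snps$alt[i]] + a
        counts[p, refbase[p]] <- counts[p, refbase[p]] - a
      }
    }
    pileup <- data.frame(genome_id = genome$id, pos = seq_len(L),
                         depth = depth,
                         countA = counts[, "A"], countC = counts[, "C"],
                         countG = counts[, "G"], countT = counts[, "T"],
                         stringsAsFactors = FALSE)
    list(pileup = pileup, truth = snps)
  })
}
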
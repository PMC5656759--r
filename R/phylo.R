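# Distance-based phylogenetics: p-distance matrices from pairwise global
# peptide identities, neighbor joining, midpoint rooting, monophyly
# testing and Newick I/O. Deliberately desk-scale: the clade-structure
# claims exercised here (monophyly, genus clusters) do not need Bayesian
# machinery, and raw p-distances are used without rate correction.

#' Pairwise p-distance matrix from peptides
#'
#' `d(i, j) = 1 - identity(i, j) / 100` from global affine-gap alignments
#' (see [global_align()]); the diagonal is zero and the matrix is
#' symmetric by construction (identity is computed once per pair). An
#' optional residue window restricts the comparison to a subsequence,
#' e.g. a conserved polymerase core.
#'
#' @param peptides Named character vector (>= 3 entries, all non-empty).
#' @param window Optional `c(start, end)` (1-based, inclusive) applied to
#'   every peptide before alignment.
#' @return A symmetric numeric matrix with taxa as dimnames.
#' @export
pdistance_matrix <- function(peptides, window = NULL) {
  pcv_assert(is.character(peptides) && length(peptides) >= 3L,
             "need at least 3 peptides")
  pcv_assert(!is.null(names(peptides)) && all(nzchar(names(peptides))) &&
               !anyDuplicated(names(peptides)),
             "peptides must have unique non-empty names")
  empty <- names(peptides)[!nzchar(peptides)]
  if (length(empty) > 0L) {
    stop("empty peptide for taxon '", empty[1], "'", call. = FALSE)
  }
  if (!is.null(window)) {
    peptides <- vapply(peptides, substr, character(1),
                       start = window[1], stop = window[2])
    pcv_assert(all(nzchar(peptides)), "window leaves an empty peptide")
  }
  n <- length(peptides)
  d <- matrix(0, n, n, dimnames = list(names(peptides), names(peptides)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      al <- global_align(peptides[[i]], peptides[[j]])
      d[i, j] <- d[j, i] <- 1 - al$pct_identity / 100
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining (Studier-Keppler criterion) on a symmetric
#' distance matrix. Negative branch lengths are clamped to zero; the total
#' clamped deficit is recorded in the `"negative_length_deficit"`
#' attribute.
#'
#' @param d Symmetric numeric matrix with zero diagonal and taxa dimnames
#'   (>= 3 taxa).
#' @return An unrooted `phylo` tree (ape).
#' @export
nj_tree <- function(d) {
  pcv_assert(is.matrix(d) && nrow(d) == ncol(d) && nrow(d) >= 3L,
             "need a square matrix over >= 3 taxa")
  if (!isSymmetric(unname(d), tol = 1e-8)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  pcv_assert(all(diag(d) == 0), "distance matrix must have a zero diagonal")
  pcv_assert(all(d >= 0), "distances must be non-negative")
  tree <- ape::nj(d)
  deficit <- -sum(tree$edge.length[tree$edge.length < 0])
  tree$edge.length[tree$edge.length < 0] <- 0
  attr(tree, "negative_length_deficit") <- deficit
  tree
}

#' Midpoint rooting and monophyly testing
#'
#' `midpoint_root()` places the root at the midpoint of the longest
#' leaf-to-leaf path. `is_monophyletic()` is `TRUE` exactly when some node
#' of the rooted tree has the query taxa — and nothing else — as its leaf
#' set.
#'
#' @param tree A `phylo` tree with >= 2 leaves.
#' @return `midpoint_root()` returns a rooted `phylo` tree.
#' @export
midpoint_root <- function(tree) {
  pcv_assert(inherits(tree, "phylo"), "need a phylo tree")
  pcv_assert(length(tree$tip.label) >= 2L, "need >= 2 leaves")
  phangorn::midpoint(tree)
}

#' @rdname midpoint_root
#' @param taxa_subset Non-empty character vector of leaf labels.
#' @return `is_monophyletic()` returns a logical scalar.
#' @export
is_monophyletic <- function(tree, taxa_subset) {
  pcv_assert(inherits(tree, "phylo"), "need a phylo tree")
  pcv_assert(length(taxa_subset) >= 1L, "taxa_subset must be non-empty")
  missing <- setdiff(taxa_subset, tree$tip.label)
  if (length(missing) > 0L) {
    stop("taxa not in tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (setequal(taxa_subset, tree$tip.label)) return(TRUE)
  ape::is.monophyletic(tree, taxa_subset)
}

#' Newick serialization
#'
#' Round-trips preserve topology and branch lengths to at least six
#' decimals; labels containing spaces or Newick metacharacters are
#' quoted.
#'
#' @param tree A `phylo` tree.
#' @return `write_newick()` returns the Newick string.
#' @export
write_newick <- function(tree) {
  pcv_assert(inherits(tree, "phylo"), "need a phylo tree")
  labs <- tree$tip.label
  needs <- grepl("[] ():;,'[]", labs)
  if (any(needs)) {
    safe <- sprintf("pcvtip%04d", seq_along(labs))
    tree$tip.label <- ifelse(needs, safe, labs)
    s <- ape::write.tree(tree, digits = 10)
    for (i in which(needs)) {
      quoted <- paste0("'", gsub("'", "''", labs[i]), "'")
      s <- sub(safe[i], quoted, s, fixed = TRUE)
    }
    s
  } else {
    ape::write.tree(tree, digits = 10)
  }
}

#' @rdname write_newick
#' @param text Newick string.
#' @return `read_newick()` returns a `phylo` tree.
#' @export
read_newick <- function(text) {
  pcv_assert(is.character(text) && length(text) == 1L,
             "text must be a single string")
  bal <- cumsum(vapply(strsplit(text, "", fixed = TRUE)[[1]],
                       function(ch) (ch == "(") - (ch == ")"), numeric(1)))
  if (length(bal) > 0L && (any(bal < 0) || bal[length(bal)] != 0)) {
    pos <- if (any(bal < 0)) which(bal < 0)[1] else length(bal)
    stop("unbalanced parentheses in Newick string at position ", pos,
         call. = FALSE)
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) stop("failed to parse Newick string", call. = FALSE)
  # strip the quotes ape leaves on quoted labels
  quoted <- grepl("^'.*'$", tree$tip.label)
  if (any(quoted)) {
    inner <- sub("^'(.*)'$", "\\1", tree$tip.label[quoted])
    tree$tip.label[quoted] <- gsub("''", "'", inner, fixed = TRUE)
  }
  tree
}
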
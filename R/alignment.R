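# Alignments, distances and trees: the plumbing around the likelihood engine.
# Trees are ape "phylo" objects throughout; alignments are a light container
# with site-pattern compression.

# internal state coding: canonical order A=1, G=2, C=3, T=4; NA = gap/unknown
.lmm_code_seq <- function(chars) {
  chars <- toupper(chars)
  chars[chars == "U"] <- "T"
  match(chars, lmm_base_order("canonical"))
}

#' Construct an alignment object
#'
#' @param seqs named character vector (one string per taxon) or named list of
#'   character vectors.  Case-insensitive; `U` maps to `T`; anything outside
#'   `A,C,G,T,U` (gaps, ambiguity codes) is treated as missing data.
#' @return object of class `lmm_alignment`: `taxa`, `n_sites`, `states`
#'   (taxa x sites integer matrix, canonical coding, NA = missing),
#'   `patterns` (taxa x n_patterns), `weights` (pattern counts).
#' @export
lmm_alignment <- function(seqs) {
  if (is.character(seqs)) seqs <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  taxa <- names(seqs)
  if (is.null(taxa) || any(!nzchar(taxa))) stop("sequences must be named")
  if (anyDuplicated(taxa)) stop("duplicate taxon names: ",
                                paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  lens <- lengths(seqs)
  if (length(unique(lens)) != 1) {
    stop("ragged alignment: sequence lengths ", paste(unique(lens), collapse = ", "))
  }
  if (lens[1] == 0) stop("empty alignment")
  states <- matrix(NA_integer_, length(seqs), lens[[1]],
                   dimnames = list(taxa, NULL))
  for (i in seq_along(seqs)) states[i, ] <- .lmm_code_seq(seqs[[i]])
  key <- apply(states, 2, function(col) paste(ifelse(is.na(col), "-", col),
                                              collapse = ""))
  idx <- match(key, unique(key))
  first <- !duplicated(key)
  patterns <- states[, first, drop = FALSE]
  weights <- as.vector(table(factor(idx, levels = seq_len(sum(first)))))
  structure(list(taxa = taxa, n_sites = lens[[1]], states = states,
                 patterns = patterns, weights = weights),
            class = "lmm_alignment")
}

#' @export
print.lmm_alignment <- function(x, ...) {
  cat("Alignment: ", length(x$taxa), " taxa x ", x$n_sites, " sites (",
      ncol(x$patterns), " site patterns)\n", sep = "")
  invisible(x)
}

#' Jukes-Cantor pairwise distances
#'
#' d = -(3/4) log(1 - 4p/3) from the proportion p of differing sites
#' (pairwise deletion of missing data).
#'
#' @param alignment an [lmm_alignment()].
#' @return symmetric distance matrix with taxon dimnames.
#' @export
jc_distance <- function(alignment) {
  st <- alignment$states
  n <- nrow(st)
  if (n < 2) stop("need at least two taxa")
  d <- matrix(0, n, n, dimnames = list(alignment$taxa, alignment$taxa))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(st[i, ]) & !is.na(st[j, ])
    if (!any(ok)) stop("taxa ", alignment$taxa[i], " and ", alignment$taxa[j],
                       " share no sites")
    p <- mean(st[i, ok] != st[j, ok])
    if (p >= 0.75) {
      stop("saturated pair ", alignment$taxa[i], "/", alignment$taxa[j],
           ": proportion of differences ", format(p), " >= 3/4")
    }
    d[i, j] <- d[j, i] <- -0.75 * log(1 - 4 * p / 3)
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei neighbor joining (via ape); negative branch length
#' estimates are clamped to zero.
#'
#' @param distances symmetric distance matrix.
#' @return unrooted `phylo` tree.
#' @export
neighbor_joining <- function(distances) {
  if (nrow(distances) < 3) stop("neighbor joining needs at least 3 taxa")
  tr <- ape::nj(stats::as.dist(distances))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Midpoint rooting
#'
#' Places the root halfway along the longest leaf-to-leaf path.  Root
#' placement is material for nonreversible models.
#'
#' @param tree unrooted (or rooted) `phylo` with branch lengths.
#' @return rooted `phylo`.
#' @export
midpoint_root <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  ntip <- length(tree$tip.label)
  if (ntip == 2) {
    h <- sum(tree$edge.length) / 2
    out <- ape::read.tree(text = sprintf("(%s:%.10g,%s:%.10g);",
                                         tree$tip.label[1], h,
                                         tree$tip.label[2], h))
    return(out)
  }
  if (sum(tree$edge.length) < 1e-12) {
    warning("zero-diameter tree: rooting at an internal node")
    return(phangorn::midpoint(tree))
  }
  phangorn::midpoint(tree)
}

#' Maximum leaf-to-leaf path length
#'
#' Tree diameter in branch-length units; with rate matrices normalized to
#' trace -4 these are approximately substitutions per site.
#'
#' @param tree `phylo` with branch lengths.
#' @return numeric scalar.
#' @export
tree_diameter <- function(tree) {
  max(ape::cophenetic.phylo(tree))
}

# Rooted-binary check + postorder edge structure used by the pruning core.
.lmm_tree_struct <- function(tree, taxa) {
  if (!ape::is.rooted(tree)) {
    stop("tree must be rooted (see midpoint_root); root placement matters ",
         "for nonreversible models")
  }
  ord <- match(taxa, tree$tip.label)
  if (anyNA(ord)) stop("tree tips do not match alignment taxa: missing ",
                       paste(setdiff(taxa, tree$tip.label), collapse = ", "))
  tr <- ape::reorder.phylo(tree, "postorder")
  list(tree = tr, edge = tr$edge, lengths = tr$edge.length,
       ntip = length(tr$tip.label), root = length(tr$tip.label) + 1L,
       tip_of_taxon = match(taxa, tr$tip.label))
}
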
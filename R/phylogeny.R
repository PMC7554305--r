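#' Read a rooted phylogeny from Newick text
#'
#' Thin validated reader around [ape::read.tree()]. Topology, tip labels and
#' branch lengths are preserved; a tree written without branch lengths keeps
#' them absent (`NULL` edge lengths) rather than silently zero.
#'
#' @param source Path to a Newick file, or a Newick string (must end in
#'   `;`).
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(source) {
  txt <- if (length(source) == 1L && !file.exists(source)) {
    source
  } else {
    paste(readLines(source, warn = FALSE), collapse = "")
  }
  txt <- trimws(txt)
  if (!nzchar(txt)) stop("empty Newick source")
  if (!grepl(";\\s*$", txt)) stop("Newick string must end in ';'")
  depth <- 0L
  chars <- strsplit(txt, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) stop("unbalanced ')' at position ", i)
  }
  if (depth != 0L) stop("unbalanced '(': ", depth, " unclosed at end of string")
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stop("Newick parse failed")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  tree
}

#' Write a phylogeny as Newick
#'
#' @param tree A `phylo` object.
#' @param path Output path; if `NULL` the Newick string is returned.
#' @return The path (invisibly) or the Newick string.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree, digits = 17)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Prune a tree to a set of tips
#'
#' Drops all tips not in `keep`; unifurcations created by the pruning are
#' collapsed with branch lengths summed (the behaviour of
#' [ape::keep.tip()]).
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of tip labels to retain (at least 2, all
#'   present in the tree).
#' @return The pruned `phylo`.
#' @export
prune_to_taxa <- function(tree, keep) {
  keep <- unique(keep)
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing)) {
    stop("tip label(s) absent from tree: ", paste(missing, collapse = ", "))
  }
  if (length(keep) < 2L) stop("need at least 2 tips to keep")
  ape::keep.tip(tree, keep)
}

#' Resolve polytomies to a strictly bifurcating tree
#'
#' Each multifurcation is resolved by uniformly random pairing, inserting
#' zero-length branches, so the sum of branch lengths (and the Brownian
#' covariance structure) is unchanged. An already-binary tree is returned
#' untouched.
#'
#' @param tree A `phylo` object.
#' @param seed Integer seed; the resolution is reproducible.
#' @return A binary `phylo`.
#' @export
resolve_polytomies <- function(tree, seed = 1L) {
  if (ape::is.binary(tree)) return(tree)
  set.seed(seed)
  ape::multi2di(tree, random = TRUE)
}

#' Ensure branch lengths are present
#'
#' @param tree A `phylo` object.
#' @param policy `"ones"` substitutes 1.0 for every absent length (absent
#'   meaning a `NULL` edge-length vector or `NA` entries); `"keep"` errors
#'   if any length is absent.
#' @return The tree with a complete `edge.length` vector.
#' @export
ensure_branch_lengths <- function(tree, policy = c("ones", "keep")) {
  policy <- match.arg(policy)
  if (is.null(tree$edge.length)) {
    if (policy == "keep") stop("tree has no branch lengths (policy = 'keep')")
    tree$edge.length <- rep(1, nrow(tree$edge))
    return(tree)
  }
  if (anyNA(tree$edge.length)) {
    if (policy == "keep") stop("tree has missing branch lengths (policy = 'keep')")
    tree$edge.length[is.na(tree$edge.length)] <- 1
  }
  tree
}

#' Shared root-to-MRCA path length of two tips
#'
#' The summed branch length from the root down to the most recent common
#' ancestor of `tip_a` and `tip_b` — the Brownian covariance of the two tips
#' under a unit-rate Brownian motion started at the root.
#' `shared_path_length(t, a, a)` is the root-to-tip depth of `a`.
#'
#' @param tree A `phylo` with branch lengths.
#' @param tip_a,tip_b Tip labels.
#' @return Nonnegative numeric.
#' @export
shared_path_length <- function(tree, tip_a, tip_b) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  ia <- match(tip_a, tree$tip.label)
  ib <- match(tip_b, tree$tip.label)
  if (is.na(ia)) stop("unknown tip: ", tip_a)
  if (is.na(ib)) stop("unknown tip: ", tip_b)
  depths <- ape::node.depth.edgelength(tree)
  if (ia == ib) return(depths[ia])
  mrca <- ape::getMRCA(tree, c(ia, ib))
  depths[mrca]
}
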
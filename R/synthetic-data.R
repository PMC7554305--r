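# Synthetic trees and binary traits with known phylogenetic structure.
#
# The generators emulate the statistical structure the analysis assumes:
# a rooted, binary, ultrametric tree plus binary traits that are either
# clumped within a clade (with optional flip noise), evolved under a
# Brownian threshold model, or phylogenetically random.

#' Simulate a pure-birth (Yule) tree
#'
#' A constant-rate pure-birth tree conditioned on `n_tips` extant tips
#' (via [ape::rphylo()] with death rate 0). Tips are relabelled
#' `G0001, G0002, ...` so generated trait matrices and lineage tables line
#' up with the tree by construction. Branch lengths are strictly positive
#' and in units of expected waiting time (1 / birth rate per lineage).
#'
#' @param n_tips Number of tips, >= 2.
#' @param birth_rate Speciation rate, > 0 (default 1).
#' @param seed Integer seed.
#' @return A binary `phylo` with `n_tips` tips.
#' @export
yule_tree <- function(n_tips, birth_rate = 1, seed = 1L) {
  if (n_tips < 2L) stop("n_tips must be >= 2")
  if (birth_rate <= 0) stop("birth_rate must be positive")
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
  tree$tip.label <- sprintf("G%04d", seq_len(n_tips))
  tree
}

new_truth <- function(volatile, regime, focal_clade = NA_integer_,
                      flip_noise = 0, prevalence) {
  data.frame(volatile = volatile, regime = regime,
             focal_clade = as.integer(focal_clade),
             flip_noise = flip_noise, prevalence = as.integer(prevalence),
             stringsAsFactors = FALSE)
}

#' Phylogenetically random binary trait
#'
#' Presence assigned to a uniformly random subset of `k` tips.
#'
#' @param tips Character vector of tip labels.
#' @param k Number of present tips, `0 < k < length(tips)`.
#' @param seed Integer seed.
#' @param volatile Name recorded in the ground truth.
#' @return List with `trait` (named 0/1 vector) and `truth` (one-row data
#'   frame: volatile, regime, focal_clade, flip_noise, prevalence).
#' @export
random_trait <- function(tips, k, seed = 1L, volatile = "random") {
  n <- length(tips)
  if (k <= 0L || k >= n) stop("k must satisfy 0 < k < ", n)
  set.seed(seed)
  trait <- stats::setNames(integer(n), tips)
  trait[sample.int(n, k)] <- 1L
  list(trait = trait, truth = new_truth(volatile, "random", prevalence = k))
}

#' Brownian-threshold binary trait
#'
#' Brownian motion tip values ([simulate_brownian_tips()]) binarized at
#' prevalence `k` ([threshold_to_prevalence()]); the construction under
#' which the D statistic is expected to be 0.
#'
#' @param tree A `phylo` with branch lengths.
#' @param k Number of present tips.
#' @param seed Integer seed.
#' @param volatile Name recorded in the ground truth.
#' @return As [random_trait()], with regime `"brownian"`.
#' @export
brownian_trait <- function(tree, k, seed = 1L, volatile = "brownian") {
  x <- simulate_brownian_tips(tree, seed = seed)
  trait <- threshold_to_prevalence(x, k, seed = derive_seed(seed, 1L))
  list(trait = stats::setNames(as.integer(trait), names(trait)),
       truth = new_truth(volatile, "brownian", prevalence = k))
}

# Tip labels descending from an internal node.
clade_tips <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(tree$tip.label[node])
  ape::extract.clade(tree, node)$tip.label
}

#' Clade-conserved binary trait with flip noise
#'
#' Presence is the indicator of a focal clade, after which every tip is
#' independently flipped with probability `flip_noise` — emulating a
#' perfectly conserved production trait blurred by incomplete reporting.
#'
#' @param tree A `phylo`.
#' @param clade Internal node id of the focal clade; it must contain at
#'   least 2 tips and exclude at least 2.
#' @param flip_noise Flip probability in \[0, 0.5).
#' @param seed Integer seed.
#' @param volatile Name recorded in the ground truth.
#' @return As [random_trait()], with regime `"clade_conserved"` and the
#'   realized (post-noise) prevalence.
#' @export
clade_conserved_trait <- function(tree, clade, flip_noise = 0, seed = 1L,
                                  volatile = "conserved") {
  if (flip_noise < 0 || flip_noise >= 0.5) stop("flip_noise must lie in [0, 0.5)")
  tips <- tree$tip.label
  inside <- clade_tips(tree, clade)
  if (length(inside) < 2L || length(tips) - length(inside) < 2L) {
    stop("focal clade must contain >= 2 tips and exclude >= 2 tips")
  }
  trait <- stats::setNames(as.integer(tips %in% inside), tips)
  set.seed(seed)
  flips <- stats::runif(length(tips)) < flip_noise
  trait[flips] <- 1L - trait[flips]
  list(trait = trait,
       truth = new_truth(volatile, "clade_conserved", focal_clade = clade,
                         flip_noise = flip_noise, prevalence = sum(trait)))
}

# Internal nodes whose descendant tip count falls in [lo, hi] while leaving
# at least 2 tips outside.
candidate_clades <- function(tree, lo, hi) {
  n_tip <- length(tree$tip.label)
  sizes <- vapply((n_tip + 1L):(n_tip + tree$Nnode),
                  function(nd) length(clade_tips(tree, nd)), integer(1))
  nodes <- (n_tip + 1L):(n_tip + tree$Nnode)
  nodes[sizes >= lo & sizes <= hi & (n_tip - sizes) >= 2L]
}

# Fabricate a lineage table from the tree itself: the two root subtrees are
# the superkingdoms, deeper ancestors provide phylum/class/order/family.
fabricate_lineage <- function(tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  paths <- ape::nodepath(tree)  # root -> tip node sequences
  rank_label <- function(path, depth, prefix) {
    # ancestor at `depth` steps below the root; shallow tips reuse the tip
    node <- path[min(depth + 1L, length(path))]
    sprintf("%s%04d", prefix, node)
  }
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  sk_of_node <- stats::setNames(c("bacteria", "fungi"),
                                as.character(kids[1:2]))
  data.frame(
    genus = tree$tip.label,
    superkingdom = vapply(paths, function(p) sk_of_node[[as.character(p[2])]],
                          character(1)),
    phylum = vapply(paths, rank_label, character(1), depth = 2L, prefix = "P"),
    class = vapply(paths, rank_label, character(1), depth = 3L, prefix = "C"),
    order = vapply(paths, rank_label, character(1), depth = 4L, prefix = "O"),
    family = vapply(paths, rank_label, character(1), depth = 5L, prefix = "F"),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic volatilome trait matrix with ground truth
#'
#' Builds a genus-by-volatile incidence matrix over the tips of a tree:
#' `n_conserved` columns are clade-conserved traits on randomly chosen
#' clades whose sizes fall within `prevalence_range`, and `n_random` columns
#' are phylogenetically random traits with prevalences drawn uniformly from
#' the same range. A two-superkingdom lineage table is fabricated by
#' splitting the tree at the root ("bacteria" vs "fungi" subtrees), with
#' deeper clades providing the lower ranks.
#'
#' @param tree A binary `phylo` (e.g. from [yule_tree()]).
#' @param n_conserved,n_random Column counts (>= 0, at least one in total).
#' @param prevalence_range Integer pair `(lo, hi)` bounding clade sizes and
#'   random-trait prevalences.
#' @param flip_noise Flip probability for conserved columns.
#' @param seed Integer seed.
#' @return List with `matrix` (a [trait_matrix()] with fabricated lineage)
#'   and `truth` (data frame, one row per column).
#' @export
synthetic_volatilome <- function(tree, n_conserved, n_random,
                                 prevalence_range = c(5L, 20L),
                                 flip_noise = 0, seed = 1L) {
  if (n_conserved < 0L || n_random < 0L || n_conserved + n_random < 1L) {
    stop("need at least one volatile column")
  }
  lo <- prevalence_range[1]
  hi <- prevalence_range[2]
  tips <- tree$tip.label
  cand <- if (n_conserved > 0L) candidate_clades(tree, lo, hi) else integer(0)
  if (n_conserved > 0L && length(cand) == 0L) {
    stop("no clade with size in [", lo, ", ", hi,
         "]; widen prevalence_range")
  }
  set.seed(seed)
  clades <- if (n_conserved > 0L) sample(cand, n_conserved, replace = TRUE)
            else integer(0)
  ks <- if (n_random > 0L) sample(seq.int(lo, hi), n_random, replace = TRUE)
        else integer(0)
  cols <- vector("list", n_conserved + n_random)
  truths <- vector("list", n_conserved + n_random)
  for (i in seq_len(n_conserved)) {
    r <- clade_conserved_trait(tree, clades[i], flip_noise = flip_noise,
                               seed = derive_seed(seed, i),
                               volatile = sprintf("vol_cons_%03d", i))
    cols[[i]] <- r$trait
    truths[[i]] <- r$truth
  }
  for (j in seq_len(n_random)) {
    i <- n_conserved + j
    r <- random_trait(tips, ks[j], seed = derive_seed(seed, i),
                      volatile = sprintf("vol_rand_%03d", j))
    cols[[i]] <- r$trait
    truths[[i]] <- r$truth
  }
  truth <- do.call(rbind, truths)
  inc <- do.call(cbind, lapply(cols, function(x) x[tips]))
  dimnames(inc) <- list(tips, truth$volatile)
  list(matrix = trait_matrix(inc, lineage = fabricate_lineage(tree)),
       truth = truth)
}
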
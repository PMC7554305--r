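# Independent brute-force oracles used to check the implementation. These
# are written as plain recursions / enumerations, deliberately avoiding the
# package's vectorized code paths.

# Children of each node from the raw edge matrix.
oracle_children <- function(tree) {
  split(tree$edge[, 2], tree$edge[, 1])
}

# Nodal values by naive recursion from the root.
oracle_nodal <- function(tree, trait) {
  n_tip <- length(tree$tip.label)
  kids <- oracle_children(tree)
  val <- function(node) {
    if (node <= n_tip) return(unname(trait[tree$tip.label[node]]))
    mean(vapply(kids[[as.character(node)]], val, numeric(1)))
  }
  vapply(seq_len(n_tip + tree$Nnode), val, numeric(1))
}

# Sum of sister-clade differences by direct edge summation.
oracle_sumd <- function(tree, trait) {
  v <- oracle_nodal(tree, trait)
  sum(abs(v[tree$edge[, 1]] - v[tree$edge[, 2]]))
}

# Exact mean sum-of-differences over ALL tip arrangements at prevalence k
# (every permutation of a k-present trait reduces to a k-subset, each subset
# equally likely under uniform permutation).
oracle_mean_sumd_exhaustive <- function(tree, k) {
  tips <- tree$tip.label
  subsets <- utils::combn(length(tips), k)
  vals <- apply(subsets, 2, function(idx) {
    trait <- stats::setNames(as.integer(seq_along(tips) %in% idx), tips)
    oracle_sumd(tree, trait)
  })
  mean(vals)
}

# PERMANOVA sums of squares straight from the definitional formulas.
oracle_permanova_ss <- function(d, groups) {
  m <- as.matrix(d)
  n <- nrow(m)
  ss_total <- sum(m[upper.tri(m)]^2) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- m[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]^2) / length(idx)
  }
  list(ss_total = ss_total, ss_within = ss_within,
       ss_among = ss_total - ss_within)
}

# Jaccard distance between two binary vectors from set arithmetic.
oracle_jaccard <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(0)
  1 - sum(a & b) / u
}

# A balanced 8-tip tree used in several enumeration tests.
balanced8 <- function() {
  read_newick(paste0("(((t1:1,t2:1):1,(t3:1,t4:1):1):1,",
                     "((t5:1,t6:1):1,(t7:1,t8:1):1):1);"))
}

# Simple two-superkingdom lineage over a tree's tips, built independently of
# the package's generator.
fabricate_lineage_for_test <- function(tree) {
  n <- length(tree$tip.label)
  data.frame(genus = tree$tip.label,
             superkingdom = rep(c("bacteria", "fungi"),
                                c(ceiling(n / 2), floor(n / 2))),
             phylum = rep(c("p1", "p2"), length.out = n),
             class = "c", order = "o",
             family = rep(c("f1", "f2", "f3"), length.out = n),
             stringsAsFactors = FALSE)
}

# Small trait matrix with lineage for classification tests.
toy_matrix <- function() {
  inc <- matrix(c(1, 1, 0, 0,
                  1, 0, 1, 0,
                  0, 1, 1, 1), nrow = 4,
                dimnames = list(c("Ba", "Bb", "Fa", "Fb"),
                                c("v1", "v2", "v3")))
  lineage <- data.frame(
    genus = c("Ba", "Bb", "Fa", "Fb"),
    superkingdom = c("bacteria", "bacteria", "fungi", "fungi"),
    phylum = c("p1", "p1", "p2", "p2"),
    class = "c", order = "o",
    family = c("f1", "f1", "f2", "f2"),
    stringsAsFactors = FALSE
  )
  trait_matrix(inc, lineage = lineage)
}
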
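# Fritz-Purvis D statistic for binary traits.
#
# The engine works on batches: a traits matrix of n_tips rows and one column
# per trait vector, so the permutation and Brownian null samples for one
# observed trait are scored in two vectorized passes over the tree.

# Align a named 0/1 trait vector (or tips x m matrix) to tree$tip.label.
align_traits <- function(tree, trait) {
  if (is.null(dim(trait))) trait <- matrix(trait, ncol = 1,
                                           dimnames = list(names(trait), NULL))
  if (is.null(rownames(trait))) stop("trait must be named by tip label")
  if (!setequal(rownames(trait), tree$tip.label) ||
      nrow(trait) != length(tree$tip.label)) {
    stop("trait names must match the tree's tips exactly")
  }
  trait[match(tree$tip.label, rownames(trait)), , drop = FALSE]
}

# Nodal values for a batch of traits: tips keep their observed state, each
# internal node gets the unweighted mean of its two children, bottom-up.
# Returns an (n_tips + n_internal) x m matrix in ape node numbering.
nodal_matrix <- function(tree, traits) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  m <- ncol(traits)
  po <- stats::reorder(tree, "postorder")$edge
  V <- matrix(NA_real_, n_all, m)
  V[seq_len(n_tip), ] <- traits
  S <- matrix(0, n_all, m)
  cnt <- integer(n_all)
  for (e in seq_len(nrow(po))) {
    p <- po[e, 1L]
    ch <- po[e, 2L]
    if (ch > n_tip) {
      if (cnt[ch] != 2L) {
        stop("tree is not strictly binary (node ", ch,
             " has ", cnt[ch], " children); run resolve_polytomies() first")
      }
      V[ch, ] <- S[ch, ] / 2
    }
    S[p, ] <- S[p, ] + V[ch, ]
    cnt[p] <- cnt[p] + 1L
  }
  root <- n_tip + 1L
  if (cnt[root] != 2L) {
    stop("tree is not strictly binary at the root; run resolve_polytomies() first")
  }
  V[root, ] <- S[root, ] / 2
  V
}

# Sum of sister-clade differences for each trait column.
sumd_matrix <- function(tree, traits) {
  V <- nodal_matrix(tree, traits)
  e <- tree$edge
  colSums(abs(V[e[, 1L], , drop = FALSE] - V[e[, 2L], , drop = FALSE]))
}

#' Estimated nodal trait values
#'
#' Bottom-up nodal estimation underlying the D statistic: a tip carries its
#' observed 0/1 state and every internal node the unweighted mean of its two
#' children. Branch lengths play no role here; they enter only through the
#' Brownian null.
#'
#' @param tree A strictly binary `phylo`.
#' @param trait Named 0/1 vector over exactly the tree's tips.
#' @return Named numeric vector over all nodes, tips first (named by label),
#'   then internal nodes in ape numbering (named by node id).
#' @export
estimate_nodal_values <- function(tree, trait) {
  V <- nodal_matrix(tree, align_traits(tree, trait))
  n_tip <- length(tree$tip.label)
  stats::setNames(drop(V), c(tree$tip.label, seq.int(n_tip + 1L, nrow(V))))
}

#' Sum of sister-clade differences (the raw D-statistic score)
#'
#' The sum over every edge of the absolute difference between the estimated
#' nodal values at its two ends. Small when presences are clumped within
#' clades; zero only for a constant trait.
#'
#' @inheritParams estimate_nodal_values
#' @return Nonnegative numeric.
#' @export
sum_sister_clade_differences <- function(tree, trait) {
  unname(sumd_matrix(tree, align_traits(tree, trait)))
}

# Batch Brownian simulation: root at 0, each child = parent + N(0, branch
# length). Consumes the current RNG stream. Returns tips x m matrix.
sim_brownian_matrix <- function(tree, m) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  cw <- stats::reorder(tree, "cladewise")
  X <- matrix(0, n_all, m)
  Z <- matrix(stats::rnorm(nrow(cw$edge) * m), nrow(cw$edge), m)
  sdev <- sqrt(cw$edge.length)
  for (e in seq_len(nrow(cw$edge))) {
    X[cw$edge[e, 2L], ] <- X[cw$edge[e, 1L], ] + sdev[e] * Z[e, ]
  }
  X[seq_len(n_tip), , drop = FALSE]
}

#' Simulate Brownian motion tip values on a tree
#'
#' The root starts at 0 and each child node is its parent's value plus a
#' Gaussian increment with variance equal to the connecting branch length,
#' so tip variances equal root-to-tip depths and tip covariances equal
#' shared root-to-MRCA path lengths.
#'
#' @param tree A `phylo` with nonnegative branch lengths.
#' @param seed Integer seed.
#' @param n_sim Number of independent replicates.
#' @return For `n_sim = 1` a named numeric vector over tips; otherwise a
#'   tips-by-`n_sim` matrix.
#' @export
simulate_brownian_tips <- function(tree, seed = 1L, n_sim = 1L) {
  set.seed(seed)
  X <- sim_brownian_matrix(tree, n_sim)
  rownames(X) <- tree$tip.label
  if (n_sim == 1L) drop(X) else X
}

# Threshold each column of a tips x m matrix to exactly k presences; ties
# broken by the seeded RNG stream (rank ties.method = "random").
threshold_matrix <- function(X, k) {
  n <- nrow(X)
  apply(X, 2, function(v) {
    r <- rank(v, ties.method = "random")
    as.numeric(r > n - k)
  })
}

#' Binarize continuous tip values at a fixed prevalence
#'
#' Assigns presence to the `k` tips with the largest values (the Brownian
#' threshold construction). Ties — measure-zero under the Gaussian model —
#' are broken by a seeded random rank.
#'
#' @param values Named numeric vector over tips.
#' @param k Target number of present tips, `0 < k < length(values)`.
#' @param seed Integer seed used only for tie-breaking.
#' @return Named 0/1 vector with exactly `k` ones.
#' @export
threshold_to_prevalence <- function(values, k, seed = 1L) {
  n <- length(values)
  if (k <= 0L || k >= n) stop("k must satisfy 0 < k < ", n)
  set.seed(seed)
  out <- threshold_matrix(matrix(values, ncol = 1), k)[, 1]
  stats::setNames(out, names(values))
}

#' Phylogenetic D statistic for a binary trait
#'
#' Scores the observed trait by its sum of sister-clade differences and
#' scales it between two null expectations obtained by simulation on the
#' same tree at the same prevalence: (i) a phylogenetically random null
#' (uniform permutation of the trait across tips) and (ii) a Brownian
#' threshold null (Brownian motion tip values binarized at the observed
#' prevalence). Then
#' \deqn{D = (d_{obs} - \bar d_{Brownian}) / (\bar d_{random} - \bar d_{Brownian})}
#' so D is about 1 for a phylogenetically random trait, about 0 for a
#' Brownian-clumped trait, below 0 for extreme clumping and above 1 for
#' overdispersion. The reported `signal` is `1 - D`.
#'
#' Two one-tailed permutation P-values accompany the estimate: `p_random`,
#' the fraction of random-null scores at or below the observed score (small
#' when the trait is more clumped than random), and `p_brownian`, the
#' fraction of Brownian-null scores at or above it. By default these are raw
#' proportions, so an observed score below every permutation score yields an
#' exact 0; set `p_convention = "add_one"` for the (r+1)/(n+1) convention.
#'
#' @param tree A strictly binary `phylo` with branch lengths.
#' @param trait Named 0/1 vector over exactly the tree's tips, with at least
#'   2 present and 1 absent tip.
#' @param n_perm Number of permutations and of Brownian simulations.
#' @param seed Integer seed; all draws are reproducible.
#' @param p_convention `"raw"` (default) or `"add_one"`.
#' @param volatile Optional trait name carried into the result.
#' @return An object of class `phylo_d`: a list with `volatile`, `d_obs`,
#'   `mean_d_random`, `mean_d_brownian`, `D`, `signal`, `p_random`,
#'   `p_brownian`, `n_perm`, `n_present`, `n_tips`, `seed`, `p_convention`.
#' @export
phylo_d <- function(tree, trait, n_perm = 1000L, seed = 1L,
                    p_convention = c("raw", "add_one"), volatile = NA_character_) {
  p_convention <- match.arg(p_convention)
  traits <- align_traits(tree, trait)
  v <- traits[, 1]
  if (!all(v %in% c(0, 1))) stop("trait values must be 0 or 1")
  k <- sum(v)
  n <- length(v)
  if (k < 2L || n - k < 1L) {
    stop("trait must have >= 2 present and >= 1 absent tips (found ",
         k, " present of ", n, ")")
  }
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths; apply ensure_branch_lengths() first")
  }
  d_obs <- sumd_matrix(tree, traits)

  set.seed(seed)
  perms <- vapply(seq_len(n_perm), function(i) v[sample.int(n)], numeric(n))
  d_random <- sumd_matrix(tree, perms)

  bm <- sim_brownian_matrix(tree, n_perm)
  d_brownian <- sumd_matrix(tree, threshold_matrix(bm, k))

  mean_r <- mean(d_random)
  mean_b <- mean(d_brownian)
  denom <- mean_r - mean_b
  if (abs(denom) < 1e-10 * max(1, abs(mean_r))) {
    stop("degenerate null distributions: mean permutation and Brownian ",
         "scores coincide (tree too small?)")
  }
  D <- (d_obs - mean_b) / denom
  tail_p <- function(r) {
    if (p_convention == "raw") r / n_perm else (r + 1) / (n_perm + 1)
  }
  structure(list(
    volatile = volatile,
    d_obs = unname(d_obs),
    mean_d_random = mean_r,
    mean_d_brownian = mean_b,
    D = unname(D),
    signal = unname(1 - D),
    p_random = tail_p(sum(d_random <= d_obs)),
    p_brownian = tail_p(sum(d_brownian >= d_obs)),
    n_perm = as.integer(n_perm),
    n_present = as.integer(k),
    n_tips = as.integer(n),
    seed = as.integer(seed),
    p_convention = p_convention
  ), class = "phylo_d")
}

#' @export
print.phylo_d <- function(x, ...) {
  cat("Phylogenetic D statistic",
      if (!is.na(x$volatile)) paste0("for '", x$volatile, "'"), "\n")
  cat(sprintf("  D = %.5f  (signal 1 - D = %.5f)\n", x$D, x$signal))
  cat(sprintf("  d_obs = %.4f; null means: random %.4f, Brownian %.4f\n",
              x$d_obs, x$mean_d_random, x$mean_d_brownian))
  cat(sprintf("  P(random) = %.4g, P(Brownian) = %.4g  [%d permutations]\n",
              x$p_random, x$p_brownian, x$n_perm))
  invisible(x)
}

#' D statistic for every volatile of a trait matrix
#'
#' Runs [phylo_d()] on each testable column of a trait matrix against a
#' tree, deriving a per-volatile seed from the master seed. Columns that do
#' not meet the minimum prevalence (at least `min_present` ones and
#' `min_absent` zeros) are skipped.
#'
#' @param tree A binary `phylo` with branch lengths whose tips match the
#'   matrix taxa.
#' @param tm A [trait_matrix()].
#' @param n_perm Permutations / simulations per volatile.
#' @param seed Master integer seed.
#' @param min_present,min_absent Testability bounds (defaults 2 and 1).
#' @param p_convention Passed to [phylo_d()].
#' @return Data frame with one row per tested volatile: `volatile`, `d_obs`,
#'   `mean_d_random`, `mean_d_brownian`, `D`, `signal`, `p_random`,
#'   `p_brownian`, `n_present`, `n_perm`, `seed`.
#' @export
phylo_d_matrix <- function(tree, tm, n_perm = 1000L, seed = 1L,
                           min_present = 2L, min_absent = 1L,
                           p_convention = "raw") {
  stopifnot(inherits(tm, "trait_matrix"))
  if (!setequal(rownames(tm$incidence), tree$tip.label)) {
    stop("trait matrix taxa and tree tips differ; prune/match them first")
  }
  inc <- tm$incidence
  cs <- colSums(inc)
  testable <- cs >= min_present & (nrow(inc) - cs) >= min_absent
  vols <- colnames(inc)[testable]
  rows <- lapply(seq_along(vols), function(i) {
    res <- phylo_d(tree, stats::setNames(inc[, vols[i]], rownames(inc)),
                   n_perm = n_perm, seed = derive_seed(seed, i),
                   p_convention = p_convention, volatile = vols[i])
    data.frame(volatile = res$volatile, d_obs = res$d_obs,
               mean_d_random = res$mean_d_random,
               mean_d_brownian = res$mean_d_brownian,
               D = res$D, signal = res$signal,
               p_random = res$p_random, p_brownian = res$p_brownian,
               n_present = res$n_present, n_perm = res$n_perm,
               seed = res$seed, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(volatile = character(), d_obs = numeric(),
                      mean_d_random = numeric(), mean_d_brownian = numeric(),
                      D = numeric(), signal = numeric(), p_random = numeric(),
                      p_brownian = numeric(), n_present = integer(),
                      n_perm = integer(), seed = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Partition significant volatiles by producing superkingdom
#'
#' Keeps the volatiles whose phylogenetic-signal test is significant
#' (default rule: permutation P-value below `alpha`, strict inequality) and
#' splits them by who produces them: only bacterial genera, only fungal
#' genera, or both. Producing-genus counts per superkingdom are attached.
#'
#' @param results Data frame from [phylo_d_matrix()].
#' @param tm The [trait_matrix()] the results were computed from, with
#'   lineage attached.
#' @param alpha Significance level (default 0.05).
#' @param rule `"p_random"` (default): significance requires
#'   `p_random < alpha`; `"both"`: additionally `p_brownian < alpha`.
#' @return List with data frames `bacterial_only`, `fungal_only`, `both`,
#'   each the significant result rows plus `n_bacterial` and `n_fungal`
#'   producing-genus counts.
#' @export
classify_conservation <- function(results, tm, alpha = 0.05,
                                  rule = c("p_random", "both")) {
  rule <- match.arg(rule)
  stopifnot(inherits(tm, "trait_matrix"))
  lin <- matrix_lineage(tm, "classify_conservation")
  unknown <- setdiff(results$volatile, colnames(tm$incidence))
  if (length(unknown)) {
    stop("volatile(s) absent from trait matrix: ",
         paste(unknown, collapse = ", "))
  }
  sig <- results$p_random < alpha
  if (rule == "both") sig <- sig & results$p_brownian < alpha
  res <- results[sig, , drop = FALSE]
  is_bact <- lin$superkingdom == "bacteria"
  inc <- tm$incidence[, res$volatile, drop = FALSE]
  res$n_bacterial <- as.integer(colSums(inc[is_bact, , drop = FALSE]))
  res$n_fungal <- as.integer(colSums(inc[!is_bact, , drop = FALSE]))
  cat_of <- ifelse(res$n_fungal == 0L, "bacterial_only",
                   ifelse(res$n_bacterial == 0L, "fungal_only", "both"))
  split_df <- function(which) {
    out <- res[cat_of == which, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  list(bacterial_only = split_df("bacterial_only"),
       fungal_only = split_df("fungal_only"),
       both = split_df("both"))
}
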
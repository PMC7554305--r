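tree4 <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
tv <- function(x, tips = c("A", "B", "C", "D")) stats::setNames(x, tips)

test_that("nodal estimation averages children bottom-up", {
  v <- estimate_nodal_values(tree4, tv(c(1, 1, 0, 0)))
  expect_equal(unname(v[c("A", "B", "C", "D")]), c(1, 1, 0, 0))
  expect_equal(unname(v["5"]), 0.5)  # root
  expect_setequal(unname(v[c("6", "7")]), c(1, 0))

  const <- estimate_nodal_values(tree4, tv(c(1, 1, 1, 1)))
  expect_true(all(const == 1))

  alt <- estimate_nodal_values(tree4, tv(c(1, 0, 1, 0)))
  expect_equal(unname(alt[c("5", "6", "7")]), c(0.5, 0.5, 0.5))
})

test_that("sum of sister-clade differences matches hand enumeration", {
  expect_equal(sum_sister_clade_differences(tree4, tv(c(1, 1, 0, 0))), 1.0)
  expect_equal(sum_sister_clade_differences(tree4, tv(c(1, 0, 1, 0))), 2.0)
  expect_equal(sum_sister_clade_differences(tree4, tv(c(0, 0, 0, 0))), 0)
})

test_that("the score is invariant to tip input order and to complementation", {
  tr <- yule_tree(16, seed = 2)
  set.seed(3)
  for (i in 1:10) {
    trait <- stats::setNames(rbinom(16, 1, 0.4), tr$tip.label)
    shuffled <- trait[sample(names(trait))]
    expect_equal(sum_sister_clade_differences(tr, shuffled),
                 sum_sister_clade_differences(tr, trait))
    expect_equal(sum_sister_clade_differences(tr, 1 - trait),
                 sum_sister_clade_differences(tr, trait))
  }
})

test_that("the vectorized recursion agrees with a naive recursive oracle", {
  set.seed(11)
  for (i in 1:10) {
    tr <- yule_tree(8, seed = 100 + i)
    trait <- stats::setNames(rbinom(8, 1, 0.5), tr$tip.label)
    expect_equal(sum_sister_clade_differences(tr, trait),
                 oracle_sumd(tr, trait))
  }
})

test_that("a non-binary tree is refused with advice", {
  poly <- read_newick("(A:1,B:1,C:1);")
  expect_error(
    sum_sister_clade_differences(poly, stats::setNames(c(1, 0, 0), c("A", "B", "C"))),
    "resolve_polytomies"
  )
})

test_that("Brownian tip simulation reproduces the tree's covariance structure", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):2);")
  X <- simulate_brownian_tips(tr, seed = 4, n_sim = 10000)
  expect_equal(var(X["A", ]), shared_path_length(tr, "A", "A"), tolerance = 0.1)
  expect_equal(var(X["C", ]), shared_path_length(tr, "C", "C"), tolerance = 0.1)
  expect_equal(cov(X["A", ], X["B", ]), shared_path_length(tr, "A", "B"),
               tolerance = 0.1)
  expect_equal(cov(X["A", ], X["C", ]), 0, tolerance = 0.1)

  star0 <- read_newick("(A:0,B:0,C:0);")
  expect_equal(unname(simulate_brownian_tips(star0, seed = 1)), c(0, 0, 0))
  neg <- tr; neg$edge.length[1] <- -1
  expect_error(simulate_brownian_tips(neg, seed = 1), "negative")
})

test_that("thresholding assigns presence to the k largest values", {
  vals <- c(A = 2.0, B = 0.1, C = -1.0)
  expect_equal(threshold_to_prevalence(vals, 1), c(A = 1, B = 0, C = 0))
  expect_equal(threshold_to_prevalence(vals, 2), c(A = 1, B = 1, C = 0))
  expect_error(threshold_to_prevalence(vals, 3), "k must")
  set.seed(5)
  for (i in 1:100) {
    x <- stats::setNames(rnorm(12), paste0("t", 1:12))
    k <- sample(1:11, 1)
    expect_equal(sum(threshold_to_prevalence(x, k, seed = i)), k)
  }
})

test_that("phylo_d is reproducible and its stored fields are self-consistent", {
  tr <- yule_tree(30, seed = 6)
  trait <- random_trait(tr$tip.label, 10, seed = 7)$trait
  r1 <- phylo_d(tr, trait, n_perm = 100, seed = 8)
  r2 <- phylo_d(tr, trait, n_perm = 100, seed = 8)
  expect_identical(r1, r2)
  expect_equal(r1$signal, 1 - r1$D)
  expect_equal(r1$D, (r1$d_obs - r1$mean_d_brownian) /
                 (r1$mean_d_random - r1$mean_d_brownian))
  expect_gte(r1$p_random, 0); expect_lte(r1$p_random, 1)
  expect_gte(r1$p_brownian, 0); expect_lte(r1$p_brownian, 1)
})

test_that("a strongly clade-clustered trait yields a raw zero permutation P", {
  tr <- yule_tree(100, seed = 9)
  cand <- Filter(function(nd) {
    k <- length(ape::extract.clade(tr, nd)$tip.label)
    k >= 8 && k <= 15
  }, 101:199)
  trait <- clade_conserved_trait(tr, cand[1], flip_noise = 0, seed = 1)$trait
  r <- phylo_d(tr, trait, n_perm = 500, seed = 10)
  expect_identical(r$p_random, 0)
  expect_lt(r$D, 0.5)
  expect_gt(r$p_brownian, 0.5)
  # the add-one convention cannot return an exact zero
  r_add <- phylo_d(tr, trait, n_perm = 500, seed = 10, p_convention = "add_one")
  expect_gt(r_add$p_random, 0)
})

test_that("sampled permutation mean matches the exhaustive-subset oracle", {
  tr <- yule_tree(8, seed = 12)
  trait <- random_trait(tr$tip.label, 3, seed = 13)$trait
  exact <- oracle_mean_sumd_exhaustive(tr, 3)
  r <- phylo_d(tr, trait, n_perm = 4000, seed = 14)
  expect_equal(r$mean_d_random, exact, tolerance = 0.02)
})

test_that("a perfect clade trait minimizes the score among equal-prevalence traits", {
  tr <- balanced8()
  clade_trait <- stats::setNames(as.integer(tr$tip.label %in%
                                              paste0("t", 1:4)), tr$tip.label)
  d_clade <- sum_sister_clade_differences(tr, clade_trait)
  expect_equal(d_clade, 1.0)  # hand enumeration on the balanced topology
  subsets <- utils::combn(8, 4)
  all_d <- apply(subsets, 2, function(idx) {
    trait <- stats::setNames(as.integer(seq_len(8) %in% idx), tr$tip.label)
    sum_sister_clade_differences(tr, trait)
  })
  expect_equal(min(all_d), d_clade)
  # every single-swap perturbation scores strictly higher
  for (out_tip in 1:4) for (in_tip in 5:8) {
    idx <- c(setdiff(1:4, out_tip), in_tip)
    trait <- stats::setNames(as.integer(seq_len(8) %in% idx), tr$tip.label)
    expect_gt(sum_sister_clade_differences(tr, trait), d_clade)
  }
  # alternating trait on the same topology, by hand: every tip edge 0.5
  alt <- stats::setNames(rep(c(1L, 0L), 4), tr$tip.label)
  expect_equal(sum_sister_clade_differences(tr, alt), 4.0)
})

test_that("degenerate and contract violations are refused", {
  tr <- yule_tree(10, seed = 15)
  const <- stats::setNames(rep(1, 10), tr$tip.label)
  expect_error(phylo_d(tr, const, n_perm = 10, seed = 1), ">= 2 present")
  one <- stats::setNames(c(1, rep(0, 9)), tr$tip.label)
  expect_error(phylo_d(tr, one, n_perm = 10, seed = 1), ">= 2 present")
  bad_names <- stats::setNames(rep(c(1, 0), 5), paste0("x", 1:10))
  expect_error(phylo_d(tr, bad_names, n_perm = 10, seed = 1), "match")
})

test_that("matrix-wide testing skips untestable columns and derives seeds", {
  tr <- yule_tree(12, seed = 16)
  inc <- cbind(v_ok = c(1, 1, 1, rep(0, 9)),
               v_single = c(1, rep(0, 11)),
               v_const = rep(1, 12))
  rownames(inc) <- tr$tip.label
  tm <- trait_matrix(inc)
  res <- phylo_d_matrix(tr, tm, n_perm = 50, seed = 17)
  expect_equal(res$volatile, "v_ok")
  res2 <- phylo_d_matrix(tr, tm, n_perm = 50, seed = 17)
  expect_identical(res, res2)
})

test_that("classification splits significant volatiles by producing superkingdom", {
  tm <- toy_matrix()
  results <- data.frame(
    volatile = c("v1", "v2", "v3"),
    D = c(-1, -0.5, 0.2), signal = c(2, 1.5, 0.8),
    p_random = c(0.01, 0.05, 0.002), p_brownian = c(0.9, 0.5, 0.6),
    stringsAsFactors = FALSE
  )
  cls <- classify_conservation(results, tm, alpha = 0.05)
  # v2 sits exactly at alpha and must be excluded (strict inequality)
  expect_equal(cls$bacterial_only$volatile, "v1")
  expect_equal(cls$bacterial_only$n_bacterial, 2L)
  expect_equal(cls$bacterial_only$n_fungal, 0L)
  expect_equal(cls$both$volatile, "v3")
  expect_equal(cls$both$n_bacterial, 1L)
  expect_equal(cls$both$n_fungal, 2L)
  expect_equal(nrow(cls$fungal_only), 0L)
  expect_error(classify_conservation(
    data.frame(volatile = "nope", p_random = 0.01, p_brownian = 0.5),
    tm), "nope")
})
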
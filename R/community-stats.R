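#' Jaccard (asymmetric binary) distance between volatilome profiles
#'
#' For two presence/absence profiles the distance is 1 minus the ratio of
#' shared presences to the union of presences — the asymmetric binary
#' dissimilarity of [stats::dist()] (`method = "binary"`), which treats
#' joint absences as uninformative. A pair with an empty union (two all-zero
#' profiles) is assigned distance 0 with a warning.
#'
#' @param tm A [trait_matrix()].
#' @param axis `"taxa"` (default): distances between taxa profiles;
#'   `"volatiles"`: between volatile columns.
#' @return A [stats::dist] object with entries in \[0, 1\].
#' @export
jaccard_distance <- function(tm, axis = c("taxa", "volatiles")) {
  axis <- match.arg(axis)
  stopifnot(inherits(tm, "trait_matrix"))
  m <- tm$incidence
  if (length(m) == 0L) stop("empty trait matrix")
  if (axis == "volatiles") m <- t(m)
  zero_rows <- rowSums(m) == 0L
  if (any(zero_rows)) {
    warning("all-zero profile(s): ",
            paste(rownames(m)[zero_rows], collapse = ", "))
  }
  if (sum(zero_rows) >= 2L) {
    warning("pair(s) with empty union assigned distance 0")
  }
  d <- stats::dist(m, method = "binary")
  d[is.na(d)] <- 0
  d
}

#' Principal coordinates analysis (classical MDS)
#'
#' Embeds a distance matrix by eigendecomposition of the double-centered
#' squared-distance matrix ([stats::cmdscale()]). Coordinates are scaled by
#' the square root of their eigenvalue; axes with negative eigenvalues are
#' excluded from the coordinates and their absolute eigenvalue mass is
#' reported.
#'
#' @param d A [stats::dist] object.
#' @param k Number of axes requested (default 2); truncated with a warning
#'   if fewer positive eigenvalues exist.
#' @return List of class `pcoa_result`: `coordinates` (n x k matrix),
#'   `eigenvalues` (all, descending), `negative_eigenvalue_mass`.
#' @export
pcoa <- function(d, k = 2L) {
  if (k < 1L) stop("k must be >= 1")
  n <- attr(d, "Size")
  fit <- stats::cmdscale(d, k = n - 1L, eig = TRUE)
  eig <- sort(fit$eig, decreasing = TRUE)
  n_pos <- sum(eig > .Machine$double.eps * max(abs(eig), 1))
  if (k > n_pos) {
    warning("only ", n_pos, " positive eigenvalue(s); truncating k from ", k)
    k <- max(n_pos, 1L)
  }
  coords <- fit$points[, seq_len(min(k, ncol(fit$points))), drop = FALSE]
  colnames(coords) <- paste0("axis", seq_len(ncol(coords)))
  structure(list(
    coordinates = coords,
    eigenvalues = eig,
    negative_eigenvalue_mass = sum(abs(pmin(eig, 0)))
  ), class = "pcoa_result")
}

#' One-factor PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance for a single grouping
#' factor, computed with [vegan::adonis2()]: the total sum of squared
#' inter-point distances is partitioned into among- and within-group parts,
#' a pseudo-F is formed, and significance is assessed by permuting group
#' labels, with p = (1 + #\{F_perm >= F_obs\}) / (n_perm + 1).
#'
#' @param d A [stats::dist] object with labels.
#' @param groups Named vector (names = labels of `d`) or unnamed vector in
#'   label order, giving the group of each point; at least two distinct
#'   groups.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @param grouping_rank Optional name of the factor (e.g. a taxonomic rank)
#'   carried into the result.
#' @return Object of class `permanova_result`: `grouping_rank`, `ss_total`,
#'   `ss_among`, `ss_within`, `df_among`, `df_within`, `pseudo_F`, `R2`,
#'   `p`, `n_perm`, `seed`.
#' @export
permanova <- function(d, groups, n_perm = 999L, seed = 1L,
                      grouping_rank = NA_character_) {
  labs <- attr(d, "Labels")
  if (!is.null(names(groups))) {
    if (!setequal(names(groups), labs)) {
      stop("group names and distance labels differ")
    }
    groups <- groups[match(labs, names(groups))]
  } else if (length(groups) != attr(d, "Size")) {
    stop("groups must cover every point of the distance matrix")
  }
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least two distinct groups")
  if (any(table(g) < 1L)) stop("every group needs at least one member")
  set.seed(seed)
  df <- data.frame(group = g)
  fit <- vegan::adonis2(d ~ group, data = df, permutations = n_perm)
  ss <- fit$SumOfSqs
  f_obs <- fit$F[1]
  if (ss[2] <= .Machine$double.eps * ss[length(ss)]) f_obs <- Inf
  structure(list(
    grouping_rank = grouping_rank,
    ss_total = ss[length(ss)],
    ss_among = ss[1],
    ss_within = ss[2],
    df_among = fit$Df[1],
    df_within = fit$Df[2],
    pseudo_F = f_obs,
    R2 = fit$R2[1],
    p = fit$`Pr(>F)`[1],
    n_perm = as.integer(n_perm),
    seed = as.integer(seed)
  ), class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("PERMANOVA",
      if (!is.na(x$grouping_rank)) paste0("(", x$grouping_rank, ")"), "\n")
  cat(sprintf("  df = %d/%d  SS among/within/total = %.4f/%.4f/%.4f\n",
              x$df_among, x$df_within, x$ss_among, x$ss_within, x$ss_total))
  cat(sprintf("  pseudo-F = %.4f  R2 = %.5f  p = %.4g  (%d permutations)\n",
              x$pseudo_F, x$R2, x$p, x$n_perm))
  invisible(x)
}

#' Volatilome richness per taxon
#'
#' The total number of volatiles reported for each taxon (row sums of the
#' incidence matrix).
#'
#' @param tm A [trait_matrix()].
#' @return Named integer vector over taxa.
#' @export
richness <- function(tm) {
  stopifnot(inherits(tm, "trait_matrix"))
  rs <- rowSums(tm$incidence)
  stats::setNames(as.integer(rs), rownames(tm$incidence))
}

#' Volatile production frequency within a taxon group
#'
#' For each volatile, the fraction of the group's taxa that produce it
#' (unrounded).
#'
#' @param tm A [trait_matrix()].
#' @param group Character vector of taxa (must be non-empty and present in
#'   the matrix).
#' @return Named numeric vector over volatiles.
#' @export
volatile_frequency <- function(tm, group = rownames(tm$incidence)) {
  stopifnot(inherits(tm, "trait_matrix"))
  if (length(group) == 0L) stop("group must be non-empty")
  missing <- setdiff(group, rownames(tm$incidence))
  if (length(missing)) {
    stop("taxa absent from matrix: ", paste(missing, collapse = ", "))
  }
  colSums(tm$incidence[group, , drop = FALSE]) / length(group)
}

#' Mann-Whitney U test (two-sided, normal approximation)
#'
#' Rank-sum comparison of two samples with midranks for ties. U counts the
#' pairs in which the first sample exceeds the second (ties count one half).
#' The two-sided P-value uses the normal approximation with tie-corrected
#' variance and continuity correction, as in
#' `wilcox.test(exact = FALSE, correct = TRUE)`.
#'
#' @param x,y Numeric vectors (each of length >= 1).
#' @return List of class `rank_sum_result`: `U`, `z`, `p_two_sided`, `n_x`,
#'   `n_y`, `zero_variance`. When every value across both samples is
#'   identical, `p_two_sided = 1` and `zero_variance = TRUE`.
#' @export
mann_whitney_u <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  N <- n1 + n2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  varU <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  mu <- n1 * n2 / 2
  if (varU <= 0) {
    return(structure(list(U = U, z = 0, p_two_sided = 1,
                          n_x = n1, n_y = n2, zero_variance = TRUE),
                     class = "rank_sum_result"))
  }
  cc <- if (U == mu) 0 else sign(U - mu) * 0.5
  z <- (U - mu - cc) / sqrt(varU)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  structure(list(U = U, z = z, p_two_sided = p, n_x = n1, n_y = n2,
                 zero_variance = FALSE), class = "rank_sum_result")
}

#' @export
print.rank_sum_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.1f (n = %d, %d), z = %.4f, p = %.4g\n",
              x$U, x$n_x, x$n_y, x$z, x$p_two_sided))
  invisible(x)
}

#' Exclusive set intersections (UpSet-style counting)
#'
#' Assigns every item of the union to exactly one membership pattern — the
#' exact subset of input sets containing it — and counts items per pattern.
#' Pattern names join set names with `&` in input-set order; counts sum to
#' the size of the union.
#'
#' @param sets Named list of vectors.
#' @return Named integer vector of pattern counts.
#' @export
exclusive_intersections <- function(sets) {
  if (length(sets) < 1L || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("sets must be a non-empty named list")
  }
  items <- unique(unlist(sets, use.names = FALSE))
  if (length(items) == 0L) return(stats::setNames(integer(0), character(0)))
  member <- vapply(sets, function(s) items %in% s, logical(length(items)))
  if (length(items) == 1L) member <- matrix(member, nrow = 1,
                                            dimnames = list(NULL, names(sets)))
  pattern <- apply(member, 1, function(row) {
    paste(names(sets)[row], collapse = "&")
  })
  tab <- table(pattern)
  stats::setNames(as.integer(tab), names(tab))
}
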
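test_that("observation records parse with whitespace trimming and required columns", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon\tvolatile",
               "Serratia plymuthica\tdimethyl disulfide",
               "  Serratia marcescens \t 2-undecanone ",
               "Aspergillus flavus\t1-octen-3-ol"), f)
  obs <- read_observations(f)
  expect_equal(nrow(obs), 3L)
  expect_equal(obs$taxon[1], "Serratia plymuthica")
  expect_equal(obs$taxon[2], "Serratia marcescens")
  expect_equal(obs$volatile[2], "2-undecanone")

  g <- withr::local_tempfile(fileext = ".tsv")
  writeLines("taxon\tname", g)
  expect_error(read_observations(g), "volatile")

  h <- withr::local_tempfile(fileext = ".tsv")
  writeLines("taxon\tvolatile", h)
  expect_warning(empty <- read_observations(h), "no observation records")
  expect_equal(nrow(empty), 0L)
})

lin2 <- data.frame(genus = c("A", "B"), superkingdom = c("bacteria", "fungi"),
                   phylum = "p", class = "c", order = "o", family = "f",
                   stringsAsFactors = FALSE)

test_that("agglomeration takes the union over species and collapses duplicates", {
  obs <- data.frame(taxon = c("A x", "A y", "B z", "A x"),
                    volatile = c("v1", "v1", "v2", "v1"),
                    stringsAsFactors = FALSE)
  tm <- agglomerate_to_genus(obs, lin2)
  expect_equal(dim(tm), c(2L, 2L))
  expect_equal(unname(tm$incidence["A", ]), c(1L, 0L))
  expect_equal(unname(tm$incidence["B", ]), c(0L, 1L))
  expect_true(all(tm$incidence %in% 0:1))
})

test_that("volatile names are deduplicated on a case-folded key, first spelling kept", {
  obs <- data.frame(taxon = c("A x", "B y"),
                    volatile = c("Dimethyl Disulfide", "dimethyl  disulfide"),
                    stringsAsFactors = FALSE)
  tm <- agglomerate_to_genus(obs, lin2)
  # brute-force key comparison confirms a single distinct case-folded name
  keys <- unique(tolower(gsub("\\s+", " ", obs$volatile)))
  expect_equal(ncol(tm$incidence), length(keys))
  expect_equal(colnames(tm$incidence), "Dimethyl Disulfide")
  expect_equal(unname(colSums(tm$incidence)), 2)
})

test_that("strict agglomeration errors on uncovered genera; lax mode drops them", {
  obs <- data.frame(taxon = c("A x", "Zz y"), volatile = c("v1", "v2"),
                    stringsAsFactors = FALSE)
  expect_error(agglomerate_to_genus(obs, lin2), "Zz")
  expect_warning(tm <- agglomerate_to_genus(obs, lin2, strict = FALSE), "Zz")
  expect_equal(rownames(tm$incidence), "A")
})

test_that("agglomeration is idempotent on genus-level input", {
  obs <- data.frame(taxon = c("A", "B", "A"), volatile = c("v1", "v2", "v3"),
                    stringsAsFactors = FALSE)
  tm1 <- agglomerate_to_genus(obs, lin2)
  again <- data.frame(
    taxon = rep(rownames(tm1$incidence), ncol(tm1$incidence)),
    volatile = rep(colnames(tm1$incidence), each = nrow(tm1$incidence)),
    stringsAsFactors = FALSE
  )
  again <- again[as.vector(tm1$incidence) == 1L, ]
  tm2 <- agglomerate_to_genus(again, lin2)
  expect_equal(tm2$incidence[rownames(tm1$incidence),
                             colnames(tm1$incidence)], tm1$incidence)
})

test_that("the testability filter keeps columns by present/absent counts", {
  inc <- matrix(0L, 6, 3, dimnames = list(paste0("g", 1:6), c("a", "b", "c")))
  inc[1, "a"] <- 1L
  inc[1:2, "b"] <- 1L
  inc[1:5, "c"] <- 1L
  tm <- trait_matrix(inc)
  out <- filter_volatiles(tm)  # defaults: >= 2 present, >= 1 absent
  expect_equal(colnames(out$incidence), c("b", "c"))

  all_ones <- trait_matrix(matrix(1L, 4, 1, dimnames = list(paste0("g", 1:4), "x")))
  expect_warning(res <- filter_volatiles(all_ones), "all volatile columns")
  expect_equal(ncol(res$incidence), 0L)

  single <- trait_matrix(matrix(c(1L, rep(0L, 9)), 10, 1,
                                dimnames = list(paste0("g", 1:10), "x")))
  expect_warning(res2 <- filter_volatiles(single))
  expect_equal(ncol(res2$incidence), 0L)
})

test_that("the filter never alters retained column contents", {
  set.seed(42)
  inc <- matrix(rbinom(20 * 8, 1, 0.3), 20, 8,
                dimnames = list(paste0("g", 1:20), paste0("v", 1:8)))
  tm <- trait_matrix(inc)
  out <- suppressWarnings(filter_volatiles(tm, 3, 2))
  cs <- colSums(inc)
  keep <- cs >= 3 & (20 - cs) >= 2  # brute-force column selection
  expect_identical(out$incidence, inc[, keep, drop = FALSE])
})

make_prevalence_fixture <- function(col_sums, n_bact_producers,
                                    n_total = 221L, n_bact = 120L) {
  taxa <- c(sprintf("Bact%03d", seq_len(n_bact)),
            sprintf("Fung%03d", seq_len(n_total - n_bact)))
  inc <- matrix(0L, n_total, length(col_sums),
                dimnames = list(taxa, names(col_sums)))
  for (j in seq_along(col_sums)) {
    nb <- n_bact_producers[j]
    nf <- col_sums[j] - nb
    if (nb > 0) inc[seq_len(nb), j] <- 1L
    if (nf > 0) inc[n_bact + seq_len(nf), j] <- 1L
  }
  lineage <- data.frame(
    genus = taxa,
    superkingdom = rep(c("bacteria", "fungi"), c(n_bact, n_total - n_bact)),
    phylum = "p", class = "c", order = "o", family = "f",
    stringsAsFactors = FALSE
  )
  trait_matrix(inc, lineage = lineage)
}

test_that("prevalence percentages use half-away-from-zero one-decimal rounding", {
  cs <- c(`3-Methyl-1-butanol` = 71L, `2-pentylfuran` = 22L, none = 0L)
  nb <- c(39L, 2L, 0L)
  tm <- make_prevalence_fixture(cs, nb)
  pt <- prevalence_table(tm)
  expect_equal(pt$pct_total[pt$volatile == "3-Methyl-1-butanol"], 32.1)
  expect_equal(pt$pct_bacterial[pt$volatile == "3-Methyl-1-butanol"], 54.9)
  expect_equal(pt$pct_fungal[pt$volatile == "3-Methyl-1-butanol"], 45.1)
  # 22/221 = 9.9548% prints as 10.0
  expect_equal(pt$pct_total[pt$volatile == "2-pentylfuran"], 10.0)
  zero <- pt[pt$volatile == "none", ]
  expect_equal(zero$pct_total, 0)
  expect_true(zero$zero_flag)
  expect_equal(zero$pct_bacterial, 0)
  # sorted by n_genera descending
  expect_equal(pt$volatile[1], "3-Methyl-1-butanol")
})

test_that("bacterial and fungal producer counts always sum to n_genera", {
  set.seed(7)
  cs <- sample(0:100, 12)
  nb <- vapply(cs, function(n) if (n == 0) 0L else sample.int(n, 1), integer(1))
  names(cs) <- paste0("v", seq_along(cs))
  pt <- prevalence_table(make_prevalence_fixture(cs, nb))
  expect_equal(pt$n_bacterial + pt$n_fungal, pt$n_genera)
})

test_that("prevalence filter compares rounded percentages", {
  cs <- c(at10 = 22L, below = 21L, high = 71L)  # 21/221 = 9.5%
  pt <- prevalence_table(make_prevalence_fixture(cs, c(2L, 2L, 39L)))
  kept <- prevalence_filter(pt, 10)
  expect_setequal(kept$volatile, c("at10", "high"))
  expect_equal(nrow(prevalence_filter(pt, 0)), nrow(pt))
  expect_error(prevalence_filter(pt, 101), "0, 100")
})
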
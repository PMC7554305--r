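# End-to-end orchestration: ingest -> filter -> tree handling -> prevalence
# -> ordination + PERMANOVA -> per-volatile D statistic -> classification ->
# diversity -> exports + run manifest.

#' Assemble a run configuration
#'
#' Collects the inputs and tuning parameters of [run_pipeline()]. Inputs may
#' be file paths (long-format TSV or wide CSV trait table, lineage TSV,
#' Newick tree) or in-memory objects (a [trait_matrix()] and a `phylo`).
#' A YAML file with the same field names can be loaded with
#' [read_run_config()].
#'
#' @param trait_table Path to a long TSV (columns taxon, volatile) or wide
#'   CSV, or a `trait_matrix` object.
#' @param lineage_table Path to a lineage TSV or a lineage data frame
#'   (ignored when `trait_table` is a `trait_matrix` carrying one).
#' @param tree Path to a Newick file or a `phylo` object.
#' @param output_dir Directory for output files.
#' @param n_perm_d Permutations per volatile for the D statistic (default
#'   1000).
#' @param n_perm_permanova PERMANOVA permutations (default 999).
#' @param alpha Significance level (default 0.05, strict inequality).
#' @param prevalence_threshold_pct Prevalence cut for the reported table
#'   (default 10).
#' @param min_present,min_absent Testability filter (defaults 2 and 1).
#' @param seed Master integer seed.
#' @param branch_length_policy `"ones"` (default; substitute 1.0 for absent
#'   lengths) or `"keep"` (error on absent lengths).
#' @param permanova_ranks Taxonomic ranks tested one at a time (default
#'   superkingdom, phylum, family).
#' @return A list of class `run_config`.
#' @export
run_config <- function(trait_table, lineage_table = NULL, tree,
                       output_dir = tempfile("mvocphylo_run_"),
                       n_perm_d = 1000L, n_perm_permanova = 999L,
                       alpha = 0.05, prevalence_threshold_pct = 10,
                       min_present = 2L, min_absent = 1L, seed = 1L,
                       branch_length_policy = c("ones", "keep"),
                       permanova_ranks = c("superkingdom", "phylum", "family")) {
  branch_length_policy <- match.arg(branch_length_policy)
  stopifnot(n_perm_d >= 1L, n_perm_permanova >= 1L,
            alpha > 0, alpha < 1, min_present >= 1L, min_absent >= 0L)
  structure(list(trait_table = trait_table, lineage_table = lineage_table,
                 tree = tree, output_dir = output_dir, n_perm_d = n_perm_d,
                 n_perm_permanova = n_perm_permanova, alpha = alpha,
                 prevalence_threshold_pct = prevalence_threshold_pct,
                 min_present = min_present, min_absent = min_absent,
                 seed = as.integer(seed),
                 branch_length_policy = branch_length_policy,
                 permanova_ranks = permanova_ranks),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file whose keys are the arguments of [run_config()].
#' @param ... Overrides applied on top of the file values.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}

load_trait_input <- function(config) {
  tt <- config$trait_table
  lineage <- config$lineage_table
  if (is.character(lineage)) lineage <- read_lineage(lineage)
  if (inherits(tt, "trait_matrix")) {
    if (is.null(tt$lineage) && !is.null(lineage)) {
      tt <- trait_matrix(tt$incidence, lineage = lineage)
    }
    return(tt)
  }
  if (!is.character(tt)) stop("trait_table must be a path or a trait_matrix")
  if (grepl("\\.csv$", tt, ignore.case = TRUE)) {
    read_trait_csv(tt, lineage = lineage)
  } else {
    agglomerate_to_genus(read_observations(tt), lineage = lineage)
  }
}

#' Run the full volatilome phylogenetic-signal pipeline
#'
#' Executes, in order: ingestion/agglomeration, the testability filter,
#' matching of matrix taxa to tree tips (case-folded exact label match;
#' unmatched taxa are dropped with a logged list), pruning, random polytomy
#' resolution, branch-length policy, the prevalence table and its threshold
#' filter, Jaccard distance + PCoA + one PERMANOVA per configured taxonomic
#' rank, the per-volatile D statistic, conservation classification,
#' richness/frequency comparison between superkingdoms (Mann-Whitney), and
#' file exports including an iTOL binary annotation and a JSON run
#' manifest. Fully reproducible under the config seed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with all intermediate results (`matrix`,
#'   `tree`, `prevalence`, `prevalent`, `ordination`, `permanova`,
#'   `d_results`, `conservation`, `richness_test`, `frequency_test`,
#'   `manifest`). Output files are written under `config$output_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    message(msg)
    warnings_log <<- c(warnings_log, msg)
  }

  tm <- load_trait_input(config)
  n_volatiles_raw <- ncol(tm$incidence)
  tm <- suppressWarnings(
    filter_volatiles(tm, config$min_present, config$min_absent)
  )

  tree <- config$tree
  if (is.character(tree)) tree <- read_newick(tree)

  # case-folded exact label matching; unmatched taxa dropped, logged
  tip_key <- name_key(tree$tip.label)
  taxa_key <- name_key(rownames(tm$incidence))
  matched <- taxa_key %in% tip_key
  if (!any(matched)) stop("no overlap between matrix taxa and tree tips")
  if (!all(matched)) {
    note("dropping taxa absent from tree: ",
         paste(rownames(tm$incidence)[!matched], collapse = ", "))
  }
  keep_tips <- tree$tip.label[match(taxa_key[matched], tip_key)]
  inc <- tm$incidence[matched, , drop = FALSE]
  rownames(inc) <- keep_tips  # adopt the tree's spelling
  tm <- suppressWarnings(
    filter_volatiles(trait_matrix(inc, lineage = tm$lineage),
                     config$min_present, config$min_absent)
  )
  if (length(keep_tips) < length(tree$tip.label)) {
    tree <- prune_to_taxa(tree, keep_tips)
  }
  tree <- resolve_polytomies(tree, seed = derive_seed(config$seed, 101L))
  tree <- ensure_branch_lengths(tree, policy = config$branch_length_policy)

  prevalence <- prevalence_table(tm)
  prevalent <- prevalence_filter(prevalence, config$prevalence_threshold_pct)

  lin <- matrix_lineage(tm, "run_pipeline")
  if (ncol(tm$incidence) > 0L) {
    d <- jaccard_distance(tm, axis = "taxa")
    ordination <- pcoa(d, k = 2L)
    perm <- lapply(config$permanova_ranks, function(rank) {
      permanova(d, stats::setNames(lin[[rank]], rownames(tm$incidence)),
                n_perm = config$n_perm_permanova,
                seed = derive_seed(config$seed, 202L),
                grouping_rank = rank)
    })
    names(perm) <- config$permanova_ranks
  } else {
    note("no volatile columns left after filtering; ",
         "skipping ordination and PERMANOVA")
    ordination <- NULL
    perm <- list()
  }

  d_results <- phylo_d_matrix(tree, tm, n_perm = config$n_perm_d,
                              seed = derive_seed(config$seed, 303L),
                              min_present = config$min_present,
                              min_absent = config$min_absent)
  conservation <- classify_conservation(d_results, tm, alpha = config$alpha)

  rich <- richness(tm)
  is_bact <- lin$superkingdom == "bacteria"
  rich_test <- mann_whitney_u(rich[is_bact], rich[!is_bact])
  if (ncol(tm$incidence) > 0L) {
    freq_bact <- volatile_frequency(tm, rownames(tm$incidence)[is_bact])
    freq_fung <- volatile_frequency(tm, rownames(tm$incidence)[!is_bact])
    freq_test <- mann_whitney_u(freq_bact, freq_fung)
  } else {
    freq_test <- NULL
  }

  out <- function(f) file.path(config$output_dir, f)
  utils::write.csv(prevalence, out("prevalence.csv"), row.names = FALSE)
  utils::write.csv(d_results, out("d_results.csv"), row.names = FALSE)
  for (cat_name in names(conservation)) {
    utils::write.csv(conservation[[cat_name]],
                     out(sprintf("conservation_%s.csv",
                                 sub("_only", "", cat_name))),
                     row.names = FALSE)
  }
  perm_df <- do.call(rbind, lapply(perm, function(p) {
    data.frame(rank = p$grouping_rank, df_among = p$df_among,
               df_within = p$df_within, ss_among = p$ss_among,
               ss_within = p$ss_within, ss_total = p$ss_total,
               pseudo_F = p$pseudo_F, R2 = p$R2, p = p$p,
               n_perm = p$n_perm, stringsAsFactors = FALSE)
  }))
  if (!is.null(perm_df)) {
    utils::write.csv(perm_df, out("permanova.csv"), row.names = FALSE)
  }
  if (!is.null(ordination)) {
    ord_df <- data.frame(taxon = rownames(ordination$coordinates),
                         ordination$coordinates, stringsAsFactors = FALSE)
    utils::write.csv(ord_df, out("ordination.csv"), row.names = FALSE)
  }
  if (ncol(tm$incidence) > 0L) {
    export_itol_binary(tm, colnames(tm$incidence), out("itol_binary.txt"))
  }

  n_sig <- vapply(conservation, nrow, integer(1))
  manifest <- list(
    config = list(
      n_perm_d = config$n_perm_d,
      n_perm_permanova = config$n_perm_permanova,
      alpha = config$alpha,
      prevalence_threshold_pct = config$prevalence_threshold_pct,
      min_present = config$min_present, min_absent = config$min_absent,
      seed = config$seed,
      branch_length_policy = config$branch_length_policy,
      permanova_ranks = config$permanova_ranks
    ),
    software_version = as.character(utils::packageVersion("mvocphylo")),
    stage_seeds = list(polytomy = derive_seed(config$seed, 101L),
                       permanova = derive_seed(config$seed, 202L),
                       phylo_d = derive_seed(config$seed, 303L)),
    counts = list(
      taxa = nrow(tm$incidence),
      volatiles_raw = n_volatiles_raw,
      volatiles_after_filter = ncol(tm$incidence),
      volatiles_prevalent = nrow(prevalent),
      volatiles_tested = nrow(d_results),
      volatiles_significant = sum(n_sig),
      bacterial_only = unname(n_sig[["bacterial_only"]]),
      fungal_only = unname(n_sig[["fungal_only"]]),
      both = unname(n_sig[["both"]])
    ),
    warnings = warnings_log
  )
  stopifnot(manifest$counts$volatiles_significant ==
              manifest$counts$bacterial_only + manifest$counts$fungal_only +
              manifest$counts$both)
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(matrix = tm, tree = tree, prevalence = prevalence,
                 prevalent = prevalent, ordination = ordination,
                 permanova = perm, d_results = d_results,
                 conservation = conservation, richness_test = rich_test,
                 frequency_test = freq_test, manifest = manifest))
}

#' Export a trait matrix as an iTOL binary dataset annotation
#'
#' Writes a plain-text `DATASET_BINARY` file (comma separator, one field per
#' volatile, one data line per taxon with 1 = present, 0 = absent) suitable
#' for upload to the Interactive Tree of Life.
#'
#' @param tm A [trait_matrix()].
#' @param volatiles Volatile columns to export (subset of the matrix
#'   columns).
#' @param path Output path.
#' @param label Dataset label shown in iTOL.
#' @return The path, invisibly.
#' @export
export_itol_binary <- function(tm, volatiles, path,
                               label = "Volatilome presence/absence") {
  stopifnot(inherits(tm, "trait_matrix"))
  unknown <- setdiff(volatiles, colnames(tm$incidence))
  if (length(unknown)) {
    stop("volatile(s) absent from matrix: ", paste(unknown, collapse = ", "))
  }
  inc <- tm$incidence[, volatiles, drop = FALSE]
  # tab separator: volatile names routinely contain commas
  header <- c(
    "DATASET_BINARY",
    "SEPARATOR TAB",
    paste0("DATASET_LABEL\t", label),
    "COLOR\t#1f78b4",
    paste0("FIELD_SHAPES\t",
           paste(rep("2", length(volatiles)), collapse = "\t")),
    paste0("FIELD_LABELS\t", paste(volatiles, collapse = "\t")),
    paste0("FIELD_COLORS\t", paste(rep("#1f78b4", length(volatiles)),
                                   collapse = "\t")),
    "DATA"
  )
  data_lines <- vapply(seq_len(nrow(inc)), function(i) {
    paste(c(rownames(inc)[i], inc[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, data_lines), path)
  invisible(path)
}
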
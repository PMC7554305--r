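#' Construct a binary trait matrix
#'
#' The central container of the package: a genus-by-volatile incidence matrix
#' with entries in \{0, 1\}, optionally annotated with a lineage table mapping
#' each genus to superkingdom (bacteria or fungi), phylum, class, order, and
#' family.
#'
#' @param incidence Numeric or integer matrix with unique row names (taxa,
#'   typically genera) and unique column names (volatiles); every entry must
#'   be 0 or 1.
#' @param lineage Optional data frame with columns `genus`, `superkingdom`,
#'   `phylum`, `class`, `order`, `family`. `superkingdom` must be `"bacteria"`
#'   or `"fungi"`. Operations that need lineage information (prevalence
#'   percentages, conservation classification) error when it is missing.
#' @return An object of class `trait_matrix`: a list with elements
#'   `incidence` (integer matrix) and `lineage` (data frame or `NULL`).
#' @examples
#' m <- matrix(c(1, 0, 1, 1), 2, 2,
#'             dimnames = list(c("Serratia", "Aspergillus"),
#'                             c("dimethyl disulfide", "1-octen-3-ol")))
#' trait_matrix(m)
#' @export
trait_matrix <- function(incidence, lineage = NULL) {
  if (!is.matrix(incidence)) incidence <- as.matrix(incidence)
  if (nrow(incidence) > 0L && is.null(rownames(incidence))) {
    stop("incidence matrix must have taxon row names")
  }
  if (ncol(incidence) > 0L && is.null(colnames(incidence))) {
    stop("incidence matrix must have volatile column names")
  }
  if (is.null(rownames(incidence))) rownames(incidence) <- character(0)
  if (is.null(colnames(incidence))) colnames(incidence) <- character(0)
  if (anyDuplicated(rownames(incidence))) {
    stop("duplicate taxon names: ",
         paste(unique(rownames(incidence)[duplicated(rownames(incidence))]),
               collapse = ", "))
  }
  if (anyDuplicated(colnames(incidence))) {
    stop("duplicate volatile names: ",
         paste(unique(colnames(incidence)[duplicated(colnames(incidence))]),
               collapse = ", "))
  }
  if (length(incidence) && !all(incidence %in% c(0, 1))) {
    stop("incidence entries must all be 0 or 1")
  }
  storage.mode(incidence) <- "integer"
  if (!is.null(lineage)) lineage <- validate_lineage(lineage)
  structure(list(incidence = incidence, lineage = lineage),
            class = "trait_matrix")
}

validate_lineage <- function(lineage) {
  lineage <- as.data.frame(lineage, stringsAsFactors = FALSE)
  required <- c("genus", "superkingdom", "phylum", "class", "order", "family")
  missing <- setdiff(required, names(lineage))
  if (length(missing)) {
    stop("lineage table is missing column(s): ", paste(missing, collapse = ", "))
  }
  lineage$superkingdom <- tolower(trimws(lineage$superkingdom))
  bad <- setdiff(unique(lineage$superkingdom), c("bacteria", "fungi"))
  if (length(bad)) {
    stop("superkingdom must be 'bacteria' or 'fungi'; found: ",
         paste(bad, collapse = ", "))
  }
  if (anyDuplicated(lineage$genus)) {
    stop("duplicate genus in lineage table: ",
         paste(unique(lineage$genus[duplicated(lineage$genus)]), collapse = ", "))
  }
  lineage
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat("Binary trait matrix:", nrow(x$incidence), "taxa x",
      ncol(x$incidence), "volatiles\n")
  if (!is.null(x$lineage)) {
    tab <- table(x$lineage$superkingdom[match(rownames(x$incidence),
                                              x$lineage$genus)])
    cat("Lineage:", paste(names(tab), tab, collapse = ", "), "\n")
  } else {
    cat("Lineage: none attached\n")
  }
  invisible(x)
}

#' @export
dim.trait_matrix <- function(x) dim(x$incidence)

# Lineage rows aligned to the matrix taxa; errors if any taxon lacks one.
matrix_lineage <- function(tm, what = "this operation") {
  if (is.null(tm$lineage)) stop(what, " requires a lineage table")
  idx <- match(rownames(tm$incidence), tm$lineage$genus)
  if (anyNA(idx)) {
    stop(what, " requires lineage for every taxon; missing: ",
         paste(rownames(tm$incidence)[is.na(idx)], collapse = ", "))
  }
  tm$lineage[idx, , drop = FALSE]
}

#' Read long-format volatile observation records
#'
#' Reads a delimited text table of (taxon, volatile) observation records, one
#' row per reported detection of a volatile in a species or strain. Column
#' matching is case-insensitive on the header; an optional `source` column is
#' carried through as a provenance tag.
#'
#' @param path Path to a delimited text file with a header containing at
#'   least `taxon` and `volatile` columns.
#' @param sep Field separator, default tab.
#' @return Data frame with columns `taxon`, `volatile`, `source` (`NA` when
#'   absent), whitespace-trimmed. An empty file (header only) returns a
#'   zero-row data frame with a warning.
#' @export
read_observations <- function(path, sep = "\t") {
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "\"", comment.char = "")
  cols <- tolower(trimws(names(df)))
  need <- c("taxon", "volatile")
  for (col in need) {
    if (!col %in% cols) {
      stop("observation table is missing required column '", col, "'")
    }
  }
  out <- data.frame(
    taxon = squash_ws(as.character(df[[which(cols == "taxon")[1]]])),
    volatile = squash_ws(as.character(df[[which(cols == "volatile")[1]]])),
    stringsAsFactors = FALSE
  )
  out$source <- if ("source" %in% cols) {
    squash_ws(as.character(df[[which(cols == "source")[1]]]))
  } else {
    rep(NA_character_, nrow(out))
  }
  out <- out[nzchar(out$taxon) & nzchar(out$volatile), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("no observation records found in ", path)
  out
}

#' Read a wide 0/1 trait table
#'
#' First column holds taxon names, remaining columns are volatiles with 0/1
#' cells.
#'
#' @param path CSV path.
#' @param lineage Optional lineage data frame to attach.
#' @return A [trait_matrix()].
#' @export
read_trait_csv <- function(path, lineage = NULL) {
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                        check.names = FALSE)
  if (ncol(df) < 2L) stop("wide trait table needs a taxon column plus volatiles")
  taxa <- squash_ws(as.character(df[[1]]))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- taxa
  trait_matrix(m, lineage = lineage)
}

#' Read a lineage table
#'
#' Tab-separated table with columns genus, superkingdom, phylum, class,
#' order, family.
#'
#' @param path TSV path.
#' @return Validated lineage data frame.
#' @export
read_lineage <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  names(df) <- tolower(trimws(names(df)))
  df$genus <- squash_ws(df$genus)
  validate_lineage(df)
}

#' Agglomerate species-level observations to a genus-level trait matrix
#'
#' The genus of each record is its first whitespace-delimited token (the
#' source data mixes binomials, strain labels, and bare genus names).
#' Presence is the union over all species/strains of a genus: any single
#' report sets the cell to 1 and duplicates collapse, so the matrix is
#' qualitative by construction. Volatile names are deduplicated on a
#' case-folded, whitespace-collapsed key, keeping the first-seen spelling;
#' an optional synonym map is applied before deduplication.
#'
#' @param records Data frame as returned by [read_observations()].
#' @param lineage Lineage data frame covering the genera encountered.
#' @param strict If `TRUE` (default) a genus absent from `lineage` is an
#'   error; if `FALSE` its records are dropped with a warning.
#' @param synonyms Optional named character vector mapping volatile spellings
#'   (case-insensitive) to canonical names.
#' @return A [trait_matrix()] with the lineage attached.
#' @export
agglomerate_to_genus <- function(records, lineage, strict = TRUE,
                                 synonyms = NULL) {
  lineage <- validate_lineage(lineage)
  genus <- vapply(strsplit(records$taxon, "\\s+"), `[`, character(1), 1L)
  volatile <- records$volatile
  if (!is.null(synonyms)) {
    hit <- match(name_key(volatile), name_key(names(synonyms)))
    volatile[!is.na(hit)] <- unname(synonyms[hit[!is.na(hit)]])
  }
  known <- genus %in% lineage$genus
  if (!all(known)) {
    offending <- sort(unique(genus[!known]))
    if (strict) {
      stop("genera absent from lineage table: ",
           paste(offending, collapse = ", "))
    }
    warning("dropping records for genera absent from lineage table: ",
            paste(offending, collapse = ", "))
    genus <- genus[known]
    volatile <- volatile[known]
  }
  if (length(genus) == 0L) stop("no records left to agglomerate")
  vkey <- name_key(volatile)
  vcanon <- volatile[!duplicated(vkey)]
  names(vcanon) <- vkey[!duplicated(vkey)]
  taxa <- sort(unique(genus))
  vols <- unname(vcanon)
  inc <- matrix(0L, length(taxa), length(vols),
                dimnames = list(taxa, vols))
  inc[cbind(match(genus, taxa), match(vkey, names(vcanon)))] <- 1L
  trait_matrix(inc, lineage = lineage)
}

#' Drop volatiles too rare (or too common) to test
#'
#' Keeps only volatile columns with at least `min_present` producing taxa and
#' at least `min_absent` non-producing taxa. The defaults (2 present, 1
#' absent) are the minimum for a binary trait to carry a testable
#' phylogenetic signal: reported in more than one taxon, yet not constant.
#'
#' @param tm A [trait_matrix()].
#' @param min_present Minimum column sum, >= 1.
#' @param min_absent Minimum number of zero cells per column, >= 0.
#' @return The filtered `trait_matrix`; taxa are unchanged. If every column
#'   is removed the result has zero columns and a warning is raised (not an
#'   error).
#' @export
filter_volatiles <- function(tm, min_present = 2L, min_absent = 1L) {
  stopifnot(inherits(tm, "trait_matrix"))
  if (min_present < 1L) stop("min_present must be >= 1")
  if (min_absent < 0L) stop("min_absent must be >= 0")
  cs <- colSums(tm$incidence)
  keep <- cs >= min_present & (nrow(tm$incidence) - cs) >= min_absent
  if (!any(keep)) warning("all volatile columns removed by filter")
  trait_matrix(tm$incidence[, keep, drop = FALSE], lineage = tm$lineage)
}

#' Prevalence table of volatiles across genera
#'
#' For each volatile: the number of producing genera, the percentage of all
#' genera producing it, and the split of producers between bacteria and
#' fungi. Percentages are rounded half away from zero to one decimal, the
#' convention of printed prevalence tables (22 of 221 genera prints as
#' 10.0%).
#'
#' @param tm A [trait_matrix()] with lineage attached.
#' @param classes Optional named character vector of chemical class labels,
#'   passed through to a `chemical_class` column.
#' @return Data frame with columns `volatile`, (`chemical_class`,)
#'   `n_genera`, `pct_total`, `pct_bacterial`, `pct_fungal`, `zero_flag`,
#'   sorted by `n_genera` descending then volatile name ascending. For a
#'   volatile produced by no genus the producer split is reported as 0.0 with
#'   `zero_flag = TRUE`.
#' @export
prevalence_table <- function(tm, classes = NULL) {
  stopifnot(inherits(tm, "trait_matrix"))
  lin <- matrix_lineage(tm, "prevalence_table")
  inc <- tm$incidence
  n_total <- nrow(inc)
  is_bact <- lin$superkingdom == "bacteria"
  n_genera <- colSums(inc)
  n_bact <- colSums(inc[is_bact, , drop = FALSE])
  n_fung <- n_genera - n_bact
  zero <- n_genera == 0L
  pct_total <- round_half_up(100 * n_genera / n_total, 1)
  pct_bact <- ifelse(zero, 0, round_half_up(100 * n_bact / pmax(n_genera, 1L), 1))
  pct_fung <- ifelse(zero, 0, round_half_up(100 * n_fung / pmax(n_genera, 1L), 1))
  out <- data.frame(
    volatile = colnames(inc) %||% character(0),
    n_genera = as.integer(n_genera),
    n_bacterial = as.integer(n_bact),
    n_fungal = as.integer(n_fung),
    pct_total = pct_total,
    pct_bacterial = pct_bact,
    pct_fungal = pct_fung,
    zero_flag = zero,
    stringsAsFactors = FALSE
  )
  if (!is.null(classes)) {
    out$chemical_class <- unname(classes[match(out$volatile, names(classes))])
    out <- out[, c("volatile", "chemical_class", "n_genera", "n_bacterial",
                   "n_fungal", "pct_total", "pct_bacterial", "pct_fungal",
                   "zero_flag")]
  }
  out <- out[order(-out$n_genera, out$volatile), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter a prevalence table at a rounded percentage threshold
#'
#' Retains records whose one-decimal-rounded `pct_total` is at least
#' `threshold_pct`. The comparison is on the rounded value so that a
#' prevalence of 9.95% (printed 10.0%) passes a 10% cut, matching the
#' printed-table convention.
#'
#' @param records Data frame from [prevalence_table()].
#' @param threshold_pct Percentage in \[0, 100\].
#' @return The retained rows.
#' @export
prevalence_filter <- function(records, threshold_pct = 10) {
  if (threshold_pct < 0 || threshold_pct > 100) {
    stop("threshold_pct must lie in [0, 100]")
  }
  keep <- round_half_up(records$pct_total, 1) >= threshold_pct
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
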
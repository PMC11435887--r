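#' Relative-abundance table
#'
#' Proportions per sample (rows) over taxa (columns); every row sums to 1
#' within 1e-9.  Produced by [total_sum_scaling()].
#'
#' @param proportions numeric matrix, samples x taxa, rows summing to 1
#' @return object of class `rel_abund`
#' @export
rel_abund <- function(proportions) {
  if (!is.matrix(proportions)) proportions <- as.matrix(proportions)
  if (is.null(rownames(proportions)) || is.null(colnames(proportions)))
    stop("proportions must have sample row names and taxon column names")
  if (any(proportions < 0))
    stop("negative proportion")
  sums <- rowSums(proportions)
  off <- which(abs(sums - 1) > 1e-9)
  if (length(off) > 0)
    stop("sample '", rownames(proportions)[off[1L]],
         "' proportions sum to ", format(sums[off[1L]]), ", not 1")
  structure(list(proportions = proportions), class = "rel_abund")
}

#' @export
print.rel_abund <- function(x, ...) {
  cat(sprintf("rel_abund: %d samples x %d taxa\n",
              nrow(x$proportions), ncol(x$proportions)))
  invisible(x)
}

#' @export
dim.rel_abund <- function(x) dim(x$proportions)

keep_asvs <- function(table, keep) {
  counts <- table$counts[, keep, drop = FALSE]
  tx <- table$taxonomy
  if (!is.null(tx)) tx <- tx[tx$asv_id %in% colnames(counts), , drop = FALSE]
  asv_table(counts, taxonomy = tx)
}

#' Remove rare (singleton/doubleton) ASVs
#'
#' Drops every ASV whose summed count across all samples of the table is at
#' most `max_total`.  With the default `max_total = 2` this removes
#' singletons and doubletons, which would otherwise inflate presence-based
#' statistics such as engraftment rates.
#'
#' @param table an [asv_table()]
#' @param max_total drop ASVs with total count <= this value (default 2)
#' @return filtered `asv_table`; the sample set is unchanged
#' @export
remove_rare_asvs <- function(table, max_total = 2) {
  stopifnot(inherits(table, "asv_table"), max_total >= 0)
  totals <- colSums(table$counts)
  keep_asvs(table, totals > max_total)
}

#' Low-count prevalence filter
#'
#' Retains features having at least `min_count` counts in at least
#' `min_prevalence` of the samples (both boundaries inclusive).
#'
#' @param table an [asv_table()]
#' @param min_count minimum per-sample count for a sample to qualify
#' @param min_prevalence minimum fraction of qualifying samples
#' @return filtered `asv_table`
#' @export
low_count_filter <- function(table, min_count = 4, min_prevalence = 0.20) {
  stopifnot(inherits(table, "asv_table"),
            min_prevalence >= 0, min_prevalence <= 1)
  n <- nrow(table$counts)
  if (n == 0) return(table)
  prev <- colSums(table$counts >= min_count) / n
  keep_asvs(table, prev >= min_prevalence)
}

#' Low-variance filter by inter-quartile range
#'
#' Features are ranked by their IQR across samples and the lowest
#' `drop_fraction` (floor of fraction x feature count) are removed.  Ties
#' in IQR are broken by feature id, lexicographically smaller ids being
#' dropped first, so the result is deterministic.
#'
#' @param table an [asv_table()] or [rel_abund()]
#' @param drop_fraction fraction of features to drop (default 0.10)
#' @param spread spread measure; only `"iqr"` is implemented
#' @return filtered table of the same class
#' @export
low_variance_filter <- function(table, drop_fraction = 0.10,
                                spread = "iqr") {
  spread <- match.arg(spread, "iqr")
  m <- if (inherits(table, "rel_abund")) table$proportions else table$counts
  p <- ncol(m)
  if (p < 1) stop("low_variance_filter needs at least one feature")
  n_drop <- floor(drop_fraction * p)
  if (n_drop == 0) return(table)
  iqr <- apply(m, 2, stats::IQR, type = 7)
  ord <- order(iqr, colnames(m))
  drop_ids <- colnames(m)[ord[seq_len(n_drop)]]
  keep <- !(colnames(m) %in% drop_ids)
  if (inherits(table, "rel_abund"))
    structure(list(proportions = m[, keep, drop = FALSE]),
              class = "rel_abund")
  else keep_asvs(table, keep)
}

#' Total-sum scaling
#'
#' Converts counts to within-sample proportions by dividing each cell by
#' its sample total.  Samples whose total is zero cannot be scaled; they
#' are excluded from the output with a warning so that partial datasets
#' still process.
#'
#' @param table an [asv_table()]
#' @return a [rel_abund()] over the non-empty samples
#' @export
total_sum_scaling <- function(table) {
  stopifnot(inherits(table, "asv_table"))
  totals <- rowSums(table$counts)
  empty <- totals == 0
  if (all(empty)) stop("all samples have zero total count")
  if (any(empty))
    warning("excluding zero-total sample(s): ",
            paste(rownames(table$counts)[empty], collapse = ", "))
  m <- table$counts[!empty, , drop = FALSE]
  rel_abund(m / rowSums(m))
}

#' Resolve a rank label, falling back to "unclassified <parent>"
#'
#' @param taxonomy taxonomy data frame (asv_id + 7 ranks)
#' @param rank rank to resolve, e.g. `"genus"`
#' @return character vector of labels, one per taxonomy row
#' @keywords internal
resolve_rank_label <- function(taxonomy, rank) {
  ri <- match(rank, TAXONOMY_RANKS)
  if (is.na(ri)) stop("unknown rank: ", rank)
  vapply(seq_len(nrow(taxonomy)), function(i) {
    lab <- taxonomy[[rank]][i]
    if (!is.na(lab) && nzchar(lab)) return(lab)
    for (j in rev(seq_len(ri - 1L))) {
      parent <- taxonomy[[TAXONOMY_RANKS[j]]][i]
      if (!is.na(parent) && nzchar(parent)) {
        # a parent that is itself an "unclassified X" label is not repeated
        if (startsWith(parent, "unclassified "))
          return(parent)
        return(paste("unclassified", parent))
      }
    }
    "unclassified"
  }, character(1))
}

#' Aggregate ASV counts to a taxonomic rank
#'
#' Counts are summed over ASVs sharing the rank label.  ASVs with no label
#' at the requested rank are pooled under `"unclassified <nearest assigned
#' parent>"` (e.g. an ASV with empty genus but family Lachnospiraceae
#' contributes to "unclassified Lachnospiraceae").  Per-sample totals are
#' conserved exactly; ASVs missing from the taxonomy entirely are pooled
#' under `"unclassified"`.
#'
#' @param table an [asv_table()] with taxonomy
#' @param rank `"genus"` or `"species"`
#' @return an `asv_table` whose columns are rank labels (no taxonomy slot)
#' @export
aggregate_taxa <- function(table, rank = c("genus", "species")) {
  rank <- match.arg(rank)
  stopifnot(inherits(table, "asv_table"))
  if (is.null(table$taxonomy)) stop("aggregate_taxa requires taxonomy")
  tx <- table$taxonomy
  labels <- resolve_rank_label(tx, rank)
  names(labels) <- tx$asv_id
  all_labels <- labels[colnames(table$counts)]
  all_labels[is.na(all_labels)] <- "unclassified"
  groups <- unique(all_labels)
  agg <- sapply(groups, function(g)
    rowSums(table$counts[, all_labels == g, drop = FALSE]))
  if (nrow(table$counts) == 1)
    agg <- matrix(agg, nrow = 1,
                  dimnames = list(rownames(table$counts), groups))
  if (length(groups) == 1)
    agg <- matrix(agg, ncol = 1,
                  dimnames = list(rownames(table$counts), groups))
  asv_table(agg)
}

#' Pool low-abundance taxa into "Other"
#'
#' Taxa whose mean relative abundance across the displayed samples falls
#' below `min_mean_abundance` are summed into a single `"Other"` column;
#' taxa at or above the threshold are shown individually.  Row sums are
#' conserved.  Conventional thresholds for display are 1% at genus level
#' and 1.4% at species level.
#'
#' @param rel a [rel_abund()]
#' @param min_mean_abundance pooling threshold (default 0.01)
#' @return a `rel_abund`, possibly with an `Other` column
#' @export
collapse_other <- function(rel, min_mean_abundance = 0.01) {
  stopifnot(inherits(rel, "rel_abund"))
  m <- rel$proportions
  means <- colMeans(m)
  low <- means < min_mean_abundance
  if (!any(low)) return(rel)
  kept <- m[, !low, drop = FALSE]
  other <- rowSums(m[, low, drop = FALSE])
  out <- cbind(kept, Other = other)
  structure(list(proportions = out), class = "rel_abund")
}
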
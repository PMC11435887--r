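
TAXONOMY_RANKS <- c("domain", "phylum", "class", "order", "family",
                    "genus", "species")

#' Construct an ASV count table
#'
#' An `asv_table` holds a samples x ASVs matrix of non-negative integer
#' counts, optionally accompanied by a taxonomy assignment per ASV.  It is
#' the substrate of every downstream microbiome stage: filtering, scaling,
#' aggregation, diversity, differential abundance and engraftment.
#'
#' @param counts numeric matrix, samples in rows and ASVs in columns, with
#'   unique non-empty dimnames.  All entries must be non-negative integers
#'   (integer-valued doubles are accepted and coerced).
#' @param taxonomy optional data frame with column `asv_id` plus the seven
#'   ranks `domain, phylum, class, order, family, genus, species`.  It may
#'   cover any subset of the table's ASVs; empty strings or `NA` mark
#'   unassigned ranks.
#' @return an object of class `asv_table` with elements `counts` and
#'   `taxonomy` (NULL when absent).
#' @export
asv_table <- function(counts, taxonomy = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (nrow(counts) == 0 || ncol(counts) == 0) {
    # canonical empty-margin form so degenerate tables compare identical
    counts <- matrix(integer(0), nrow(counts), ncol(counts),
                     dimnames = list(rownames(counts) %||% character(0),
                                     colnames(counts) %||% character(0)))
  } else if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample row names and ASV column names")
  validate_counts(counts)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample id: ",
         rownames(counts)[duplicated(rownames(counts))][1L])
  if (anyDuplicated(colnames(counts)))
    stop("duplicate ASV id: ",
         colnames(counts)[duplicated(colnames(counts))][1L])
  if (!is.null(taxonomy)) taxonomy <- validate_taxonomy(taxonomy)
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, taxonomy = taxonomy),
            class = "asv_table")
}

validate_counts <- function(counts) {
  bad <- which(!is.finite(counts) | counts < 0 |
                 counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "non-integer or negative count %s at sample '%s', ASV '%s'",
      format(counts[bad[1L, 1L], bad[1L, 2L]]),
      rownames(counts)[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]]))
  }
  invisible(counts)
}

validate_taxonomy <- function(taxonomy) {
  taxonomy <- as.data.frame(taxonomy, stringsAsFactors = FALSE)
  needed <- c("asv_id", TAXONOMY_RANKS)
  missing <- setdiff(needed, names(taxonomy))
  if (length(missing) > 0)
    stop("taxonomy is missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(taxonomy$asv_id))
    stop("duplicate taxonomy asv_id: ",
         taxonomy$asv_id[duplicated(taxonomy$asv_id)][1L])
  taxonomy[, needed]
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("asv_table: %d samples x %d ASVs (total count %s)\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(as.numeric(x$counts)), big.mark = ",")))
  if (!is.null(x$taxonomy))
    cat(sprintf("  taxonomy: %d ASVs assigned\n", nrow(x$taxonomy)))
  invisible(x)
}

#' @export
dim.asv_table <- function(x) dim(x$counts)

#' Sample identifiers of a table
#' @param table an `asv_table` or `rel_abund`
#' @return character vector of sample ids, in table order
#' @export
sample_ids <- function(table) {
  rownames(if (inherits(table, "rel_abund")) table$proportions
           else table$counts)
}

#' ASV / taxon identifiers of a table
#' @inheritParams sample_ids
#' @return character vector of feature ids, in table order
#' @export
asv_ids <- function(table) {
  colnames(if (inherits(table, "rel_abund")) table$proportions
           else table$counts)
}

#' Read an ASV table from disk
#'
#' The TSV dialect has ASVs as rows and samples as columns: the first
#' column carries the ASV id, the remaining columns one sample each, with a
#' header row.  BIOM (JSON, format 1.0) is supported read-only.
#'
#' @param path file to read
#' @param format `"tsv"` or `"biom"`
#' @param taxonomy optional taxonomy data frame to attach (see
#'   [read_taxonomy()])
#' @return validated [asv_table()]
#' @export
read_asv_table <- function(path, format = c("tsv", "biom"),
                           taxonomy = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "biom") {
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")  # features x samples
    counts <- t(m)
    return(asv_table(counts, taxonomy = taxonomy))
  }
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  if (ncol(raw) < 1) stop("malformed header in ", path)
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate ASV id in '", path, "': ", ids[duplicated(ids)][1L])
  samples <- names(raw)[-1L]
  if (anyDuplicated(samples))
    stop("duplicate sample column in '", path, "': ",
         samples[duplicated(samples)][1L])
  if (length(samples) == 0 && nrow(raw) == 0) {
    counts <- matrix(integer(0), nrow = 0, ncol = 0,
                     dimnames = list(character(0), character(0)))
    return(asv_table(counts, taxonomy = taxonomy))
  }
  num <- matrix(NA_real_, nrow = nrow(raw), ncol = length(samples),
                dimnames = list(ids, samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad) > 0)
      stop(sprintf(
        "invalid count '%s' at ASV '%s', sample column '%s' in %s",
        raw[[j + 1L]][bad[1L]], ids[bad[1L]], samples[j], path))
    num[, j] <- v
  }
  asv_table(t(num), taxonomy = taxonomy)
}

#' Write an ASV table to TSV
#'
#' Inverse of [read_asv_table()]: `read_asv_table(write_asv_table(t))`
#' reproduces `t` exactly (ids, order, counts).  Output is byte-stable.
#'
#' @param table an [asv_table()]
#' @param path destination file
#' @export
write_asv_table <- function(table, path) {
  stopifnot(inherits(table, "asv_table"))
  m <- t(table$counts)  # ASVs as rows on disk
  df <- data.frame(asv_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0)
    df <- data.frame(asv_id = character(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Read a taxonomy TSV
#'
#' Expected columns: `asv_id` followed by the seven rank labels
#' `domain ... species`.  Empty cells mean "unassigned at this rank".
#'
#' @param path file to read
#' @return data frame suitable for the `taxonomy` slot of [asv_table()]
#' @export
read_taxonomy <- function(path) {
  tx <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  validate_taxonomy(tx)
}

#' Write a taxonomy TSV
#' @param taxonomy taxonomy data frame
#' @param path destination file
#' @export
write_taxonomy <- function(taxonomy, path) {
  taxonomy <- validate_taxonomy(taxonomy)
  utils::write.table(taxonomy, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

TRIAL_VISITS <- c("screening", "inclusion", "endoscopy", "treatment",
                  "post_treatment")
SAMPLE_GROUPS <- c("FMT", "placebo", "donor", "healthy")

#' Read sample metadata
#'
#' A metadata TSV maps each sample to its dog, treatment group and visit.
#' Groups are `FMT`, `placebo`, `donor`, `healthy`; trial visits are
#' `screening`, `inclusion`, `endoscopy`, `treatment`, `post_treatment`;
#' donor and healthy reference samples carry the visits `donor` and
#' `healthy` respectively (they are outside the trial timeline).
#'
#' @param path TSV with columns `sample_id`, `dog_id`, `group`, `visit`
#' @return validated metadata data frame
#' @export
read_metadata <- function(path) {
  md <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  validate_metadata(md)
}

validate_metadata <- function(md) {
  md <- as.data.frame(md, stringsAsFactors = FALSE)
  needed <- c("sample_id", "dog_id", "group", "visit")
  missing <- setdiff(needed, names(md))
  if (length(missing) > 0)
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(md$sample_id))
    stop("duplicate metadata sample_id: ",
         md$sample_id[duplicated(md$sample_id)][1L])
  bad_group <- setdiff(unique(md$group), SAMPLE_GROUPS)
  if (length(bad_group) > 0)
    stop("unknown group: ", paste(bad_group, collapse = ", "))
  ok_visit <- c(TRIAL_VISITS, "donor", "healthy")
  bad_visit <- setdiff(unique(md$visit), ok_visit)
  if (length(bad_visit) > 0)
    stop("unknown visit: ", paste(bad_visit, collapse = ", "))
  ref <- md$group %in% c("donor", "healthy")
  if (any(ref & md$visit %in% TRIAL_VISITS))
    stop("donor/healthy samples must not carry a trial-phase visit")
  md[, needed]
}

#' Write sample metadata to TSV
#' @param metadata metadata data frame
#' @param path destination file
#' @export
write_metadata <- function(metadata, path) {
  metadata <- validate_metadata(metadata)
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}
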
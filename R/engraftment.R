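#' Presence profile of a dog, donor or context
#'
#' A presence profile is the set of ASVs detected (count >= 1) in any of
#' the samples contributing to a context:
#' \describe{
#'   \item{pre_fmt}{the dog's endoscopy-visit samples (the last visit
#'     before capsules start), or an explicit `baseline_visit` override for
#'     dogs that skipped endoscopy}
#'   \item{post_fmt}{the union of the dog's treatment and post-treatment
#'     samples}
#'   \item{donor}{all donor samples, or a named subset (e.g. one capsule
#'     lot) via `donor_samples`}
#' }
#' Profiles must be built from a table already passed through
#' [remove_rare_asvs()] so that dataset-wide singletons and doubletons do
#' not inflate presence.
#'
#' @param table rare-ASV-filtered [asv_table()]
#' @param metadata metadata data frame (see [read_metadata()])
#' @param owner dog id, or `"donor"` for the donor context
#' @param context one of `"pre_fmt"`, `"post_fmt"`, `"donor"`
#' @param baseline_visit visit used as the pre-FMT baseline (default
#'   `"endoscopy"`)
#' @param donor_samples optional character vector restricting the donor
#'   context to specific sample ids
#' @return object of class `presence_profile` with fields `owner`,
#'   `context`, `present_asvs`
#' @export
build_presence <- function(table, metadata, owner,
                           context = c("pre_fmt", "post_fmt", "donor"),
                           baseline_visit = "endoscopy",
                           donor_samples = NULL) {
  context <- match.arg(context)
  stopifnot(inherits(table, "asv_table"))
  metadata <- validate_metadata(metadata)
  ids <- switch(context,
    pre_fmt = metadata$sample_id[metadata$dog_id == owner &
                                   metadata$visit == baseline_visit],
    post_fmt = metadata$sample_id[metadata$dog_id == owner &
                                    metadata$visit %in%
                                      c("treatment", "post_treatment")],
    donor = {
      d <- metadata$sample_id[metadata$group == "donor"]
      if (!is.null(donor_samples)) intersect(d, donor_samples) else d
    })
  ids <- intersect(ids, rownames(table$counts))
  if (length(ids) == 0)
    stop("no contributing sample for owner '", owner,
         "' in context '", context, "'")
  sub <- table$counts[ids, , drop = FALSE]
  present <- colnames(sub)[colSums(sub) >= 1]
  structure(list(owner = owner, context = context,
                 present_asvs = present),
            class = "presence_profile")
}

#' @export
print.presence_profile <- function(x, ...) {
  cat(sprintf("presence_profile: %s [%s], %d ASVs present\n",
              x$owner, x$context, length(x$present_asvs)))
  invisible(x)
}

#' Candidate donor ASVs for engraftment
#'
#' The denominator set of the engraftment rate: donor ASVs after excluding
#' those already shared with the recipient's pre-FMT (endoscopy) samples.
#' Only ASVs absent from the recipient before transplantation can evidence
#' engraftment.
#'
#' @param donor donor `presence_profile`
#' @param pre the recipient's pre-FMT `presence_profile`
#' @return character vector of candidate ASV ids (possibly empty)
#' @export
candidate_donor_set <- function(donor, pre) {
  stopifnot(inherits(donor, "presence_profile"),
            inherits(pre, "presence_profile"),
            donor$context == "donor", pre$context == "pre_fmt")
  setdiff(donor$present_asvs, pre$present_asvs)
}

#' Donor-ASV engraftment rate of one recipient
#'
#' rate = 100 * |candidates detected post-FMT| / |candidates|, where the
#' candidates are [candidate_donor_set()] and detection post-FMT means
#' presence in any treatment or post-treatment sample.
#'
#' @param donor donor `presence_profile`
#' @param pre recipient pre-FMT `presence_profile`
#' @param post recipient post-FMT `presence_profile`
#' @return object of class `engraftment_result` with fields `dog_id`,
#'   `candidate_donor_asvs`, `engrafted_asvs`, `rate_percent`
#' @export
engraftment_rate <- function(donor, pre, post) {
  stopifnot(inherits(post, "presence_profile"),
            post$context == "post_fmt")
  candidates <- candidate_donor_set(donor, pre)
  if (length(candidates) == 0)
    stop("dog '", post$owner, "' shares every donor ASV pre-FMT; ",
         "zero denominator - exclude it from the engraftment analysis")
  engrafted <- intersect(candidates, post$present_asvs)
  structure(list(dog_id = post$owner,
                 candidate_donor_asvs = candidates,
                 engrafted_asvs = engrafted,
                 rate_percent = 100 * length(engrafted) /
                   length(candidates)),
            class = "engraftment_result")
}

#' @export
print.engraftment_result <- function(x, ...) {
  cat(sprintf("engraftment_result: dog %s, %d/%d donor ASVs (%.2f%%)\n",
              x$dog_id, length(x$engrafted_asvs),
              length(x$candidate_donor_asvs), x$rate_percent))
  invisible(x)
}

#' Summarise engraftment across recipients
#'
#' @param results list of [engraftment_rate()] results
#' @return object of class `engraftment_summary`: per-dog rates, mean,
#'   median (midpoint for even counts), min, max, and the per-ASV
#'   engraftment frequency (number of recipients in whose engrafted set
#'   each ASV appears)
#' @export
summarize_engraftment <- function(results) {
  if (length(results) == 0) stop("no engraftment results to summarise")
  stopifnot(all(vapply(results, inherits, logical(1),
                       "engraftment_result")))
  rates <- vapply(results, `[[`, numeric(1), "rate_percent")
  names(rates) <- vapply(results, `[[`, character(1), "dog_id")
  engrafted <- unlist(lapply(results, `[[`, "engrafted_asvs"))
  freq <- if (length(engrafted) > 0) table(engrafted) else
    table(character(0))
  freq <- stats::setNames(as.integer(freq), names(freq))
  structure(list(rates = rates,
                 mean_percent = mean(rates),
                 median_percent = stats::median(rates),
                 min_percent = min(rates),
                 max_percent = max(rates),
                 asv_frequency = freq),
            class = "engraftment_summary")
}

#' @export
print.engraftment_summary <- function(x, ...) {
  cat(sprintf(paste0("engraftment_summary: %d recipients, mean %.2f%%, ",
                     "median %.2f%%, range %.2f-%.2f%%\n"),
              length(x$rates), x$mean_percent, x$median_percent,
              x$min_percent, x$max_percent))
  invisible(x)
}

#' Run the full engraftment analysis over a trial table
#'
#' Convenience wrapper: removes rare ASVs, builds the donor profile and,
#' per FMT dog with both a baseline and at least one post-FMT sample,
#' computes the engraftment rate.  Dogs with a zero candidate denominator
#' are excluded with a warning.
#'
#' @param table raw [asv_table()] (rare-ASV removal is applied internally
#'   over the entire dataset)
#' @param metadata metadata data frame
#' @param max_total passed to [remove_rare_asvs()]
#' @param baseline_visit per-dog baseline visit; either a single visit
#'   name or a named character vector keyed by dog id for overrides
#' @param donor_samples optional donor sample subset
#' @return list with `results` (per-dog [engraftment_rate()] objects),
#'   `summary` ([summarize_engraftment()]) and `excluded` (named character
#'   vector of reasons)
#' @export
engraftment_analysis <- function(table, metadata, max_total = 2,
                                 baseline_visit = "endoscopy",
                                 donor_samples = NULL) {
  metadata <- validate_metadata(metadata)
  filtered <- remove_rare_asvs(table, max_total = max_total)
  donor <- build_presence(filtered, metadata, "donor", "donor",
                          donor_samples = donor_samples)
  dogs <- unique(metadata$dog_id[metadata$group == "FMT"])
  results <- list()
  excluded <- character(0)
  for (dog in dogs) {
    bv <- if (length(baseline_visit) > 1 || !is.null(names(baseline_visit)))
      baseline_visit[[dog]] %||% "endoscopy" else baseline_visit
    pre <- try(build_presence(filtered, metadata, dog, "pre_fmt",
                              baseline_visit = bv), silent = TRUE)
    post <- try(build_presence(filtered, metadata, dog, "post_fmt"),
                silent = TRUE)
    if (inherits(pre, "try-error")) {
      excluded[dog] <- "no baseline sample"
      next
    }
    if (inherits(post, "try-error")) {
      excluded[dog] <- "no post-FMT sample"
      next
    }
    res <- try(engraftment_rate(donor, pre, post), silent = TRUE)
    if (inherits(res, "try-error")) {
      excluded[dog] <- "zero candidate denominator"
      warning("dog '", dog, "' excluded: zero candidate denominator")
      next
    }
    results[[dog]] <- res
  }
  summary <- if (length(results) > 0) summarize_engraftment(results)
  else NULL
  list(results = results, summary = summary, excluded = excluded)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export per-dog engraftment rates as a data frame
#' @param analysis result of [engraftment_analysis()]
#' @return data frame: dog_id, n_candidates, n_engrafted, rate_percent
#'   (rates reported to 2 decimals; stored values keep full precision)
#' @export
engraftment_table <- function(analysis) {
  res <- analysis$results
  data.frame(
    dog_id = vapply(res, `[[`, character(1), "dog_id"),
    n_candidates = vapply(res, function(r)
      length(r$candidate_donor_asvs), integer(1)),
    n_engrafted = vapply(res, function(r)
      length(r$engrafted_asvs), integer(1)),
    rate_percent = round(vapply(res, `[[`, numeric(1), "rate_percent"), 2),
    row.names = NULL, stringsAsFactors = FALSE)
}
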
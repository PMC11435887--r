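#' Configuration for bias-corrected differential abundance
#'
#' @param prevalence_cutoff keep taxa present (count >= 1) in at least this
#'   fraction of samples (default 0.30)
#' @param winsor_quantile per-taxon winsorisation quantile applied to the
#'   relative abundances before the log transform (default 0.97)
#' @param pseudocount multiplier of the smallest positive proportion used
#'   to shift zeros before taking logs (default 0.5)
#' @param adjust multiple-testing adjustment; only `"bh"`
#'   (Benjamini-Hochberg FDR) is implemented
#' @param random_effect metadata column holding the grouping factor for
#'   the random intercept (default `"dog_id"`, accounting for repeated
#'   measures on the same dog)
#' @return a `da_config` list
#' @export
da_config <- function(prevalence_cutoff = 0.30, winsor_quantile = 0.97,
                      pseudocount = 0.5, adjust = "bh",
                      random_effect = "dog_id") {
  stopifnot(prevalence_cutoff >= 0, prevalence_cutoff <= 1,
            winsor_quantile > 0, winsor_quantile <= 1, pseudocount > 0)
  adjust <- match.arg(adjust, "bh")
  structure(list(prevalence_cutoff = prevalence_cutoff,
                 winsor_quantile = winsor_quantile,
                 pseudocount = pseudocount, adjust = adjust,
                 random_effect = random_effect),
            class = "da_config")
}

#' Prevalence filter
#'
#' Retains taxa present (count >= 1) in at least `cutoff` of the samples,
#' boundary inclusive.
#'
#' @param table an [asv_table()]
#' @param cutoff prevalence fraction (default 0.30)
#' @return filtered `asv_table`
#' @export
prevalence_filter <- function(table, cutoff = 0.30) {
  stopifnot(inherits(table, "asv_table"))
  n <- nrow(table$counts)
  if (n == 0) return(table)
  prev <- colSums(table$counts >= 1) / n
  keep_asvs(table, prev >= cutoff)
}

#' Winsorise a relative-abundance table per taxon
#'
#' For each taxon, values above its empirical `quantile`-quantile (type-7,
#' linear interpolation) are capped at that quantile.  No re-normalisation
#' follows, so rows may sum to slightly less than 1 afterwards; the
#' operation is idempotent at fixed `quantile`.
#'
#' @param rel a [rel_abund()]
#' @param quantile winsorisation quantile in (0, 1]
#' @return object of class `rel_abund` (row sums may be < 1)
#' @export
winsorize <- function(rel, quantile = 0.97) {
  stopifnot(inherits(rel, "rel_abund"), quantile > 0, quantile <= 1)
  m <- rel$proportions
  caps <- apply(m, 2, stats::quantile, probs = quantile, type = 7,
                names = FALSE)
  out <- pmin(m, matrix(caps, nrow = nrow(m), ncol = ncol(m),
                        byrow = TRUE))
  dimnames(out) <- dimnames(m)
  structure(list(proportions = out), class = "rel_abund")
}

#' Benjamini-Hochberg FDR adjustment
#' @param p_values numeric vector of p-values in `[0, 1]`
#' @return step-up adjusted values, capped at 1
#' @export
bh_adjust <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH")
}

#' Bias-corrected differential abundance of log relative abundances
#'
#' For every taxon, fits a linear model of the log winsorised proportion
#' on a pre/post phase indicator with a per-dog random intercept, then
#' applies a compositional bias correction: because proportions are
#' constrained to sum to one, a change in truly differential taxa induces
#' an identical spurious log-scale shift in every other taxon, which is
#' estimated as the mode of the per-taxon raw coefficients (kernel density
#' mode; median when fewer than 10 taxa) and subtracted from each of them.
#'
#' Details of the fit:
#' \itemize{
#'   \item response: `log(w + pseudocount * m0)` with `w` the winsorised
#'     proportion and `m0` the smallest positive proportion in the table;
#'   \item predictor: `phase` (post vs pre), with `pre` the visits before
#'     capsules start (screening, inclusion, endoscopy) and `post` the
#'     treatment and post-treatment visits;
#'   \item random intercept per dog via \pkg{lme4}; if the variance
#'     component is singular or the fit fails, the taxon falls back to
#'     dog fixed effects and is flagged `model = "fixed"`;
#'   \item t-tests use the residual degrees of freedom of the
#'     fixed-effect parametrisation (`n - n_dogs - 1`) in both paths, so
#'     results are deterministic;
#'   \item p-values are computed from the bias-corrected coefficient and
#'     BH-adjusted across taxa.
#' }
#'
#' @param rel a [rel_abund()] (already prevalence-filtered; see
#'   [prevalence_filter()])
#' @param metadata metadata data frame covering the samples of `rel`
#' @param config a [da_config()]
#' @param contrast only `"pre_vs_post"` is implemented
#' @return data frame with one row per taxon: `taxon`, `raw_coefficient`,
#'   `corrected_coefficient`, `standard_error`, `p_value`, `adjusted_p`,
#'   `model` ("mixed" or "fixed"), `n_samples`
#' @export
fit_da <- function(rel, metadata, config = da_config(),
                   contrast = "pre_vs_post") {
  contrast <- match.arg(contrast, "pre_vs_post")
  stopifnot(inherits(rel, "rel_abund"), inherits(config, "da_config"))
  metadata <- validate_metadata(metadata)
  m <- rel$proportions
  md <- metadata[match(rownames(m), metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id))
    stop("metadata does not cover sample(s): ",
         paste(setdiff(rownames(m), metadata$sample_id), collapse = ", "))
  phase <- ifelse(md$visit %in% c("treatment", "post_treatment"),
                  "post", "pre")
  dog <- md[[config$random_effect]]
  per_dog <- table(dog, phase)
  if (!all(per_dog > 0))
    stop("every dog must contribute at least one pre and one post sample")
  if (length(unique(dog)) < 3) stop("need at least 3 dogs")

  w <- winsorize(rel, config$winsor_quantile)$proportions
  pos <- w[w > 0]
  if (length(pos) == 0) stop("table has no positive proportion")
  shift <- config$pseudocount * min(pos)
  y_all <- log(w + shift)
  phase_f <- factor(phase, levels = c("pre", "post"))
  dog_f <- factor(dog)
  n <- nrow(m)
  df_resid <- n - length(levels(dog_f)) - 1L

  taxa <- colnames(m)
  keep <- vapply(taxa, function(tx) stats::var(y_all[, tx]) > 0, logical(1))
  if (any(!keep))
    warning("excluding zero-variance taxa: ",
            paste(taxa[!keep], collapse = ", "))
  taxa <- taxa[keep]
  if (length(taxa) < 3)
    stop("fewer than 3 taxa with variance; bias not estimable")

  fit_one <- function(y) {
    mixed <- tryCatch({
      fm <- lme4::lmer(y ~ phase_f + (1 | dog_f),
                       REML = TRUE,
                       control = lme4::lmerControl(
                         calc.derivs = FALSE,
                         check.conv.singular = "ignore"))
      if (lme4::isSingular(fm, tol = 1e-6)) NULL else fm
    }, error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(mixed)) {
      cf <- lme4::fixef(mixed)[["phase_fpost"]]
      se <- sqrt(as.matrix(stats::vcov(mixed))[2, 2])
      list(coef = cf, se = se, model = "mixed")
    } else {
      fm <- stats::lm(y ~ phase_f + dog_f)
      sm <- summary(fm)$coefficients
      list(coef = sm["phase_fpost", "Estimate"],
           se = sm["phase_fpost", "Std. Error"], model = "fixed")
    }
  }

  fits <- lapply(taxa, function(tx) fit_one(y_all[, tx]))
  raw <- vapply(fits, `[[`, numeric(1), "coef")
  se <- vapply(fits, `[[`, numeric(1), "se")
  model <- vapply(fits, `[[`, character(1), "model")

  bias <- if (length(raw) >= 10) {
    dens <- stats::density(raw)
    dens$x[which.max(dens$y)]
  } else stats::median(raw)
  corrected <- raw - bias
  tstat <- corrected / se
  p <- 2 * stats::pt(abs(tstat), df = df_resid, lower.tail = FALSE)
  data.frame(taxon = taxa,
             raw_coefficient = raw,
             corrected_coefficient = corrected,
             standard_error = se,
             p_value = p,
             adjusted_p = bh_adjust(p),
             model = model,
             n_samples = n,
             row.names = NULL, stringsAsFactors = FALSE)
}
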
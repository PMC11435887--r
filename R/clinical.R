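CCECAI_ITEMS <- c("attitude_activity", "appetite", "vomiting",
                  "fecal_consistency", "defecation_frequency",
                  "weight_loss", "albumin", "ascites_edema", "pruritus")

#' Total CCECAI score
#'
#' The canine chronic enteropathy clinical activity index is the sum of
#' nine items (attitude/activity, appetite, vomiting, fecal consistency,
#' defecation frequency, weight loss, serum albumin, ascites/peripheral
#' edema, pruritus), each scored 0-3, for a total of 0-27.
#'
#' @param items numeric vector of the nine item scores, each in 0..3; a
#'   named vector is checked against the canonical item names
#' @return integer total in 0..27
#' @export
ccecai_total <- function(items) {
  if (length(items) != 9)
    stop("expected 9 CCECAI items, got ", length(items))
  nm <- names(items) %||% CCECAI_ITEMS
  bad <- which(!(items %in% 0:3))
  if (length(bad) > 0)
    stop("CCECAI item '", nm[bad[1L]], "' is ", items[bad[1L]],
         "; each item must be an integer 0-3")
  as.integer(sum(items))
}

#' CCECAI severity band
#'
#' Bands: 0-3 insignificant, 4-5 mild, 6-8 moderate, 9-11 severe,
#' >= 12 very severe.
#'
#' @param total CCECAI total in 0..27
#' @return one of `"insignificant"`, `"mild"`, `"moderate"`, `"severe"`,
#'   `"very_severe"`
#' @export
ccecai_band <- function(total) {
  if (length(total) != 1 || !total %in% 0:27)
    stop("CCECAI total must be a single integer in 0..27, got ",
         paste(total, collapse = ","))
  if (total <= 3) "insignificant"
  else if (total <= 5) "mild"
  else if (total <= 8) "moderate"
  else if (total <= 11) "severe"
  else "very_severe"
}

#' Validate fecal consistency scores (9-point scale)
#'
#' FCS values live on the half-point grid 1, 1.5, ..., 5; higher scores
#' mean looser stool.
#'
#' @param fcs numeric vector
#' @return the input, invisibly, after validation
#' @export
validate_fcs <- function(fcs) {
  ok <- fcs >= 1 & fcs <= 5 & (2 * fcs) == round(2 * fcs)
  if (!all(ok))
    stop("FCS value off the 1-5 half-point grid: ", fcs[!ok][1L])
  invisible(fcs)
}

#' Mean fecal consistency score over an evaluation window
#'
#' Pools every defecation event recorded in the window of `window_days`
#' days ending at `eval_day` (inclusive) and returns their arithmetic
#' mean; no per-day pre-averaging is applied.
#'
#' @param diary data frame with columns `day` (integer day index) and
#'   `fcs` (half-point grid values)
#' @param eval_day day the evaluation is anchored at (default: last diary
#'   day)
#' @param window_days window length in days (default 3)
#' @return mean FCS over the window's events
#' @export
mean_fcs <- function(diary, eval_day = max(diary$day), window_days = 3) {
  stopifnot(is.data.frame(diary), all(c("day", "fcs") %in% names(diary)))
  validate_fcs(diary$fcs)
  inside <- diary$day > eval_day - window_days & diary$day <= eval_day
  if (!any(inside))
    stop("no defecation events in the ", window_days,
         "-day window ending at day ", eval_day,
         "; mean FCS cannot be evaluated")
  mean(diary$fcs[inside])
}

#' Classify clinical remission
#'
#' Remission requires a CCECAI total of at most 3 (insignificant band)
#' and a mean FCS of three or fewer.
#'
#' @param ccecai_total CCECAI total, 0..27
#' @param mean_fcs mean fecal consistency score
#' @return logical
#' @export
classify_remission <- function(ccecai_total, mean_fcs) {
  ccecai_total <= 3 & mean_fcs <= 3
}

#' Classify clinical relapse
#'
#' Relapse is a CCECAI total above 3, or clinical signs of chronic
#' enteropathy together with an FCS of 4 or more; the precedence is
#' `(total > 3) OR (signs AND fcs >= 4)`, so a loose stool alone (no
#' signs, insignificant CCECAI) does not constitute relapse.
#'
#' @param ccecai_total CCECAI total, 0..27
#' @param ce_signs logical, clinical signs of chronic enteropathy present
#' @param fcs fecal consistency score
#' @return logical
#' @export
classify_relapse <- function(ccecai_total, ce_signs, fcs) {
  (ccecai_total > 3) | (ce_signs & fcs >= 4)
}

#' Fecal dry matter percentage
#'
#' Two conventions are offered.  `dry_over_wet` (the default) reports the
#' dry fraction `100 * dry / wet`, the quantity conventionally called
#' fecal dry matter and the scale on which reference medians (roughly
#' 28-49%) are reported.  `printed_formula` reports
#' `100 * (wet - dry) / wet`, i.e. the moisture content; the two
#' conventions are complementary (they sum to 100 for every input).
#'
#' @param wet_mass wet (moisture) mass in grams, > 0
#' @param dry_mass dry mass in grams, `0 <= dry <= wet`
#' @param convention `"dry_over_wet"` or `"printed_formula"`
#' @return percentage in `[0, 100]`
#' @export
fdm_percent <- function(wet_mass, dry_mass,
                        convention = c("dry_over_wet", "printed_formula")) {
  convention <- match.arg(convention)
  if (any(wet_mass <= 0)) stop("wet mass must be positive")
  if (any(dry_mass < 0)) stop("dry mass must be non-negative")
  if (any(dry_mass > wet_mass)) stop("dry mass exceeds wet mass")
  if (convention == "dry_over_wet") 100 * dry_mass / wet_mass
  else 100 * (wet_mass - dry_mass) / wet_mass
}

#' Duplicate fecal dry matter measurement
#'
#' Each fecal sample is measured twice; the reported FDM is the mean of
#' the two replicate percentages and the replicate coefficient of
#' variation is carried along as a quality metric.
#'
#' @param wet1,dry1,wet2,dry2 masses in grams of the two replicates
#' @param convention see [fdm_percent()]
#' @return list with `fdm_percent` (mean of replicates), `cv_percent`,
#'   and `replicates` (the two percentages)
#' @export
fdm_duplicate <- function(wet1, dry1, wet2, dry2,
                          convention = "dry_over_wet") {
  reps <- c(fdm_percent(wet1, dry1, convention),
            fdm_percent(wet2, dry2, convention))
  m <- mean(reps)
  cv <- if (m == 0) 0 else 100 * stats::sd(reps) / m
  list(fdm_percent = m, cv_percent = cv, replicates = reps)
}

#' Daily capsule dose by body weight
#'
#' Weight bands: 5-10 kg one capsule, >10-20 kg two, >20-30 kg three,
#' over 30 kg four.  Weights below the 5 kg floor of the dosing table are
#' rejected.
#'
#' @param body_weight_kg body weight in kilograms (>= 5)
#' @return integer number of capsules per day
#' @export
capsule_dose <- function(body_weight_kg) {
  if (any(body_weight_kg < 5))
    stop("body weight below the 5 kg floor of the dosing table")
  ifelse(body_weight_kg <= 10, 1L,
         ifelse(body_weight_kg <= 20, 2L,
                ifelse(body_weight_kg <= 30, 3L, 4L)))
}

#' Round half-up to a number of decimals
#'
#' Unlike [round()] (banker's rounding), halves always round away from
#' zero, matching how trial percentages are conventionally reported.
#'
#' @param x numeric
#' @param digits decimals to keep
#' @return rounded numeric
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Read a trial disposition CSV
#'
#' One row per dog per phase it entered, columns `dog_id`, `group`
#' (`FMT`/`placebo`), `phase` (`treatment`/`post_treatment`), `status`
#' (`responder`/`relapsed`/`excluded`) and `exclusion_reason`.
#'
#' @param path CSV file
#' @return validated disposition data frame
#' @export
read_disposition <- function(path) {
  d <- utils::read.csv(path, colClasses = "character")
  validate_disposition(d)
}

validate_disposition <- function(d) {
  needed <- c("dog_id", "group", "phase", "status")
  missing <- setdiff(needed, names(d))
  if (length(missing) > 0)
    stop("disposition is missing column(s): ",
         paste(missing, collapse = ", "))
  if (!"exclusion_reason" %in% names(d)) d$exclusion_reason <- ""
  bad <- setdiff(unique(d$status), c("responder", "relapsed", "excluded"))
  if (length(bad) > 0) stop("unknown status: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(d$phase), c("treatment", "post_treatment"))
  if (length(bad) > 0) stop("unknown phase: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(d$group), c("FMT", "placebo"))
  if (length(bad) > 0) stop("unknown group: ", paste(bad, collapse = ", "))
  if (anyDuplicated(d[c("dog_id", "phase")]))
    stop("duplicate dog/phase row in disposition")
  d[, c(needed, "exclusion_reason")]
}

#' Per-phase and cumulative trial outcomes
#'
#' For each group and phase, counts the evaluable dogs (those not
#' excluded), the relapses among them and the responder percentage
#' `100 * (evaluable - relapsed) / evaluable`, rounded half-up to one
#' decimal.  A `cumulative` row per group summarises the whole trial: a
#' dog that relapsed in any phase counts as relapsed; a dog excluded at
#' any point without relapsing is excluded from the cumulative
#' denominator.  Group differences per phase are tested with Fisher's
#' exact test on the 2x2 relapse table (exact at the small group sizes of
#' such trials).
#'
#' @param disposition disposition data frame (see [read_disposition()])
#' @return list with `outcomes` (data frame: group, phase, n_evaluable,
#'   n_relapsed, responder_percent, relapse_percent, excluded) and
#'   `tests` (data frame: phase, p_value, method)
#' @export
phase_outcomes <- function(disposition) {
  d <- validate_disposition(disposition)
  groups <- c("FMT", "placebo")
  phases <- c("treatment", "post_treatment")
  rows <- list()
  for (g in groups) {
    for (ph in phases) {
      sub <- d[d$group == g & d$phase == ph, , drop = FALSE]
      if (nrow(sub) == 0) next
      n_excl <- sum(sub$status == "excluded")
      n_eval <- nrow(sub) - n_excl
      if (n_eval == 0)
        stop("no evaluable dog in group ", g, ", phase ", ph)
      n_rel <- sum(sub$status == "relapsed")
      rows[[paste(g, ph)]] <- data.frame(
        group = g, phase = ph, n_evaluable = n_eval, n_relapsed = n_rel,
        responder_percent = round_half_up(100 * (n_eval - n_rel) / n_eval),
        relapse_percent = round_half_up(100 * n_rel / n_eval),
        excluded = n_excl, stringsAsFactors = FALSE)
    }
    # cumulative over the whole trial
    sub <- d[d$group == g, , drop = FALSE]
    per_dog <- vapply(split(sub$status, sub$dog_id), function(st) {
      if ("relapsed" %in% st) "relapsed"
      else if ("excluded" %in% st) "excluded"
      else "responder"
    }, character(1))
    n_eval <- sum(per_dog != "excluded")
    n_rel <- sum(per_dog == "relapsed")
    rows[[paste(g, "cumulative")]] <- data.frame(
      group = g, phase = "cumulative", n_evaluable = n_eval,
      n_relapsed = n_rel,
      responder_percent = round_half_up(100 * (n_eval - n_rel) / n_eval),
      relapse_percent = round_half_up(100 * n_rel / n_eval),
      excluded = sum(per_dog == "excluded"), stringsAsFactors = FALSE)
  }
  outcomes <- do.call(rbind, c(rows, make.row.names = FALSE))
  tests <- do.call(rbind, lapply(c(phases, "cumulative"), function(ph) {
    o <- outcomes[outcomes$phase == ph, , drop = FALSE]
    if (nrow(o) < 2) return(NULL)
    tab <- rbind(o$n_relapsed, o$n_evaluable - o$n_relapsed)
    data.frame(phase = ph,
               p_value = stats::fisher.test(tab)$p.value,
               method = "Fisher exact", stringsAsFactors = FALSE)
  }))
  list(outcomes = outcomes, tests = tests)
}

#' Recruitment funnel summary
#'
#' @param funnel data frame with columns `stage` and `n`, ordered from
#'   first contact to enrolment
#' @return the funnel with an added `percent_of_initial` column
#'   (`100 * n / n[1]`)
#' @export
funnel_summary <- function(funnel) {
  stopifnot(all(c("stage", "n") %in% names(funnel)), nrow(funnel) >= 1)
  n <- as.numeric(funnel$n)
  if (any(diff(n) > 0)) stop("funnel counts must be non-increasing")
  funnel$percent_of_initial <- 100 * n / n[1L]
  funnel
}

#' Simple linear regression of fecal consistency on dry matter
#'
#' Ordinary least squares of FCS on FDM%; the squared Pearson correlation
#' equals the regression R-squared for this single-predictor model.
#'
#' @param fdm_percent numeric vector of fecal dry matter percentages
#' @param fcs numeric vector of fecal consistency scores, same length
#' @return list with `slope`, `intercept`, `pearson_r`, `r_squared`, `n`
#' @export
fcs_fdm_regression <- function(fdm_percent, fcs) {
  if (length(fdm_percent) != length(fcs)) stop("length mismatch")
  if (length(fcs) < 3) stop("need at least 3 pairs")
  if (stats::var(fdm_percent) == 0) stop("constant FDM predictor")
  fit <- stats::lm(fcs ~ fdm_percent)
  r <- stats::cor(fdm_percent, fcs)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       pearson_r = r, r_squared = r^2, n = length(fcs))
}

#' Change from baseline adjusted for the baseline value
#'
#' Analysis-of-covariance: linear model of the follow-up value on the
#' treatment group plus the baseline value as a covariate; reports the
#' group coefficient (second level vs first) and its t-test p-value.
#'
#' @param baseline numeric vector of baseline values
#' @param followup numeric vector of follow-up values, same length
#' @param group two-level group labels, same length
#' @return list with `group_effect`, `p_value`, `baseline_slope`, `n`
#' @export
baseline_adjusted_change <- function(baseline, followup, group) {
  if (length(baseline) != length(followup) ||
      length(baseline) != length(group)) stop("length mismatch")
  g <- factor(group)
  if (nlevels(g) != 2) stop("exactly two groups required")
  if (any(table(g) < 2)) stop("fewer than 2 observations in a group")
  fit <- stats::lm(followup ~ g + baseline)
  sm <- summary(fit)$coefficients
  list(group_effect = sm[2L, "Estimate"],
       p_value = sm[2L, "Pr(>|t|)"],
       baseline_slope = sm["baseline", "Estimate"],
       n = length(baseline))
}
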
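test_that("CCECAI totals and severity bands follow the scoring scheme", {
  expect_equal(ccecai_total(rep(0, 9)), 0L)
  expect_equal(ccecai_total(rep(3, 9)), 27L)
  expect_equal(ccecai_total(c(1, 0, 2, 0, 0, 1, 0, 0, 0)), 4L)
  expect_error(ccecai_total(c(4, rep(0, 8))), "attitude_activity.*0-3")
  expect_error(ccecai_total(rep(0, 8)), "9 CCECAI items")
  bands <- vapply(0:27, ccecai_band, character(1))
  expect_equal(unique(bands[1:4]), "insignificant")   # 0-3
  expect_equal(unique(bands[5:6]), "mild")            # 4-5
  expect_equal(unique(bands[7:9]), "moderate")        # 6-8
  expect_equal(unique(bands[10:12]), "severe")        # 9-11
  expect_equal(unique(bands[13:28]), "very_severe")   # >= 12
  expect_error(ccecai_band(28), "0\\.\\.27")
})

test_that("mean FCS pools the events inside the evaluation window", {
  diary <- data.frame(day = c(1, 8, 9, 10), fcs = c(5, 2, 2.5, 3))
  expect_equal(mean_fcs(diary, eval_day = 10, window_days = 3), 2.5)
  expect_equal(mean_fcs(data.frame(day = 3, fcs = 4), eval_day = 3), 4)
  expect_error(mean_fcs(diary, eval_day = 20), "no defecation events")
  expect_error(mean_fcs(data.frame(day = 1, fcs = 2.3)), "half-point")
})

test_that("remission and relapse rules match their definitions at boundaries", {
  expect_true(classify_remission(3, 3.0))
  expect_false(classify_remission(4, 2.0))
  expect_false(classify_remission(2, 3.5))
  expect_true(classify_relapse(4, FALSE, 2.0))
  expect_true(classify_relapse(2, TRUE, 4.0))
  expect_false(classify_relapse(2, FALSE, 4.5))
})

test_that("remission and relapse are mutually exclusive over the score grids", {
  fcs_grid <- seq(1, 5, by = 0.5)
  for (total in 0:27) {
    for (fcs in fcs_grid) {
      for (signs in c(TRUE, FALSE)) {
        both <- classify_remission(total, fcs) &&
          classify_relapse(total, signs, fcs)
        expect_false(both)
      }
    }
  }
})

test_that("FDM conventions are complementary and validated", {
  expect_equal(fdm_percent(0.50, 0.18), 36)
  expect_equal(fdm_percent(0.4, 0.4), 100)
  expect_equal(fdm_percent(0.4, 0), 0)
  expect_equal(fdm_percent(0.50, 0.18, "printed_formula"), 64)
  set.seed(9)
  wet <- runif(50, 0.3, 0.7); dry <- wet * runif(50)
  expect_equal(fdm_percent(wet, dry) +
                 fdm_percent(wet, dry, "printed_formula"),
               rep(100, 50))
  expect_error(fdm_percent(0.5, 0.6), "exceeds")
  expect_error(fdm_percent(0, 0), "positive")
  dup <- fdm_duplicate(0.5, 0.18, 0.5, 0.20)
  expect_equal(dup$fdm_percent, 38)
  expect_equal(dup$cv_percent, 100 * sd(c(36, 40)) / 38)
})

test_that("capsule doses follow the weight bands", {
  expect_equal(capsule_dose(8), 1L)
  expect_equal(capsule_dose(18.9), 2L)
  expect_equal(capsule_dose(49.4), 4L)
  expect_equal(capsule_dose(c(5, 10, 10.5, 20, 25, 30, 31)),
               c(1L, 1L, 2L, 2L, 3L, 3L, 4L))
  expect_error(capsule_dose(4.9), "5 kg")
})

test_that("phase outcomes reconstruct the packaged trial disposition", {
  d <- read_disposition(system.file("extdata",
                                    "trial_disposition_ccecai.csv",
                                    package = "fmtkit"))
  po <- phase_outcomes(d)
  o <- po$outcomes
  pick <- function(g, ph, col)
    o[o$group == g & o$phase == ph, col]
  expect_equal(pick("FMT", "treatment", "responder_percent"), 71.4)
  expect_equal(pick("FMT", "treatment", "relapse_percent"), 28.6)
  expect_equal(pick("placebo", "treatment", "responder_percent"), 50)
  expect_equal(pick("FMT", "cumulative", "relapse_percent"), 66.7)
  expect_equal(pick("FMT", "cumulative", "n_evaluable"), 6)
  expect_equal(pick("placebo", "cumulative", "relapse_percent"), 50)
  # Fisher p for the treatment-phase 2x2 table matches the oracle
  p <- po$tests$p_value[po$tests$phase == "treatment"]
  expect_equal(p, oracle_fisher(2, 5, 3, 3), tolerance = 1e-12)
  # the FCS-scored disposition
  d2 <- read_disposition(system.file("extdata",
                                     "trial_disposition_fcs.csv",
                                     package = "fmtkit"))
  o2 <- phase_outcomes(d2)$outcomes
  expect_equal(o2[o2$group == "FMT" & o2$phase == "treatment",
                  "relapse_percent"], 16.7)
  expect_equal(o2[o2$group == "FMT" & o2$phase == "treatment",
                  "responder_percent"], 83.3)
})

test_that("Fisher exact p matches hypergeometric enumeration on small tables", {
  set.seed(12)
  for (i in 1:40) {
    x <- matrix(sample(0:6, 4, replace = TRUE), 2)
    if (any(rowSums(x) == 0) || any(colSums(x) == 0)) next
    expect_equal(fisher.test(x)$p.value,
                 oracle_fisher(x[1, 1], x[1, 2], x[2, 1], x[2, 2]),
                 tolerance = 1e-9)
  }
})

test_that("funnel summary computes retention against the initial stage", {
  funnel <- read.csv(system.file("extdata", "recruitment_funnel.csv",
                                 package = "fmtkit"))
  fs <- funnel_summary(funnel)
  expect_equal(fs$percent_of_initial[fs$stage == "enrolled"],
               100 * 14 / 55)
  expect_error(funnel_summary(data.frame(stage = c("a", "b"),
                                         n = c(3, 5))),
               "non-increasing")
})

test_that("FCS~FDM regression recovers exact and simulated relationships", {
  # perfectly linear decreasing data
  fdm <- seq(20, 50, length.out = 10)
  r <- fcs_fdm_regression(fdm, 5 - 0.09 * fdm)
  expect_equal(r$pearson_r, -1)
  expect_equal(r$r_squared, 1)
  expect_equal(r$slope, -0.09)
  # simulated with the analytic correlation -0.45/0.6 = -0.75
  pairs <- simulate_fcs_fdm_pairs(5000, seed = 4)
  r2 <- fcs_fdm_regression(pairs$fdm_percent, pairs$fcs)
  expect_equal(r2$pearson_r, -0.75, tolerance = 0.02)
  expect_error(fcs_fdm_regression(rep(30, 5), 1:5), "constant")
  expect_error(fcs_fdm_regression(1:2, 1:2), "3 pairs")
})

test_that("baseline-adjusted change recovers exact and simulated group effects", {
  base <- rep(c(2, 4, 6), 4)
  grp <- rep(c("A", "B"), each = 6)
  follow <- base + ifelse(grp == "B", 1.5, 0)
  r <- suppressWarnings(baseline_adjusted_change(base, follow, grp))
  expect_equal(r$group_effect, 1.5, tolerance = 1e-10)
  r0 <- suppressWarnings(baseline_adjusted_change(base, base, grp))
  expect_equal(r0$group_effect, 0, tolerance = 1e-10)
  set.seed(30)
  n <- 50
  base <- rnorm(2 * n, 6, 2)
  grp <- rep(c("A", "B"), each = n)
  follow <- 1 + 0.5 * base + ifelse(grp == "B", 2, 0) + rnorm(2 * n)
  r2 <- baseline_adjusted_change(base, follow, grp)
  se <- 2 * sqrt(2 / n)  # generous bound on the effect SE
  expect_lt(abs(r2$group_effect - 2), se)
  expect_lt(r2$p_value, 0.001)
  expect_error(baseline_adjusted_change(1:4, 1:4, c("A", "A", "A", "B")),
               "fewer than 2")
})
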
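test_that("presence profiles pool the correct samples per context", {
  counts <- rbind(
    d1_endoscopy = c(a = 5L, b = 0L, x = 2L),
    d1_treatment = c(a = 3L, b = 0L, x = 0L),
    d1_post      = c(a = 0L, b = 1L, x = 0L),
    donor_a      = c(a = 9L, b = 4L, x = 0L),
    donor_b      = c(a = 0L, b = 0L, x = 0L))
  tb <- asv_table(counts)
  md <- tiny_metadata()
  post <- build_presence(tb, md, "d1", "post_fmt")
  expect_setequal(post$present_asvs, c("a", "b"))
  pre <- build_presence(tb, md, "d1", "pre_fmt")
  expect_setequal(pre$present_asvs, c("a", "x"))
  donor <- build_presence(tb, md, "donor", "donor")
  expect_setequal(donor$present_asvs, c("a", "b"))
  # restricting the donor context to one lot changes the profile
  donor_b <- build_presence(tb, md, "donor", "donor",
                            donor_samples = "donor_b")
  expect_identical(donor_b$present_asvs, character(0))
  expect_error(build_presence(tb, md, "d2", "pre_fmt"), "d2.*pre_fmt")
})

test_that("candidate set, engrafted set and rate match the worked example", {
  donor <- profile_of("donor", "donor", c("a", "b", "c", "d", "e"))
  pre <- profile_of("d1", "pre_fmt", "a")
  post <- profile_of("d1", "post_fmt", c("b", "c", "x"))
  expect_setequal(candidate_donor_set(donor, pre), c("b", "c", "d", "e"))
  res <- engraftment_rate(donor, pre, post)
  expect_setequal(res$engrafted_asvs, c("b", "c"))
  expect_equal(res$rate_percent, 50)
  # bounds
  none <- engraftment_rate(donor, pre, profile_of("d1", "post_fmt", "z"))
  expect_equal(none$rate_percent, 0)
  all_in <- engraftment_rate(donor, pre,
                             profile_of("d1", "post_fmt", letters[1:5]))
  expect_equal(all_in$rate_percent, 100)
  # disjoint pre keeps the full donor set; superset pre empties it
  expect_setequal(candidate_donor_set(donor, profile_of("d", "pre_fmt", "z")),
                  c("a", "b", "c", "d", "e"))
  expect_length(candidate_donor_set(donor,
                                    profile_of("d", "pre_fmt", letters[1:6])),
                0)
  expect_error(engraftment_rate(donor,
                                profile_of("d1", "pre_fmt", letters[1:5]),
                                post),
               "zero denominator")
})

test_that("engraftment agrees bit-exact with the brute-force oracle", {
  set.seed(202)
  pool <- sprintf("asv%02d", 1:50)
  for (i in 1:300) {
    donor_ids <- sample(pool, sample(3:30, 1))
    pre_ids <- sample(pool, sample(0:30, 1))
    post_ids <- sample(pool, sample(0:30, 1))
    oracle <- oracle_engraftment(donor_ids, pre_ids, post_ids)
    cand <- candidate_donor_set(profile_of("donor", "donor", donor_ids),
                                profile_of("d", "pre_fmt", pre_ids))
    expect_identical(sort(cand), oracle$candidates)
    if (length(cand) == 0) next
    res <- engraftment_rate(profile_of("donor", "donor", donor_ids),
                            profile_of("d", "pre_fmt", pre_ids),
                            profile_of("d", "post_fmt", post_ids))
    expect_identical(sort(res$engrafted_asvs), oracle$engrafted)
    expect_identical(res$rate_percent, oracle$rate)
  }
})

test_that("rates are monotone in post additions and invariant to relabeling", {
  set.seed(77)
  pool <- sprintf("x%02d", 1:40)
  for (i in 1:50) {
    donor_ids <- sample(pool, 20)
    pre_ids <- sample(pool, 8)
    post_ids <- sample(pool, 10)
    donor <- profile_of("donor", "donor", donor_ids)
    pre <- profile_of("d", "pre_fmt", pre_ids)
    if (length(candidate_donor_set(donor, pre)) == 0) next
    r0 <- engraftment_rate(donor, pre,
                           profile_of("d", "post_fmt", post_ids))
    # adding any ASV to post never decreases the rate
    extra <- sample(setdiff(pool, post_ids), 1)
    r1 <- engraftment_rate(donor, pre,
                           profile_of("d", "post_fmt",
                                      c(post_ids, extra)))
    expect_gte(r1$rate_percent, r0$rate_percent)
    # adding a donor-and-pre shared ASV to post changes nothing
    shared <- intersect(donor_ids, pre_ids)
    if (length(shared) > 0) {
      r2 <- engraftment_rate(donor, pre,
                             profile_of("d", "post_fmt",
                                        union(post_ids, shared[1])))
      expect_equal(r2$rate_percent, r0$rate_percent)
    }
    # permutation of ASV ids leaves the rate unchanged
    perm <- setNames(sample(pool), pool)
    r3 <- engraftment_rate(
      profile_of("donor", "donor", unname(perm[donor_ids])),
      profile_of("d", "pre_fmt", unname(perm[pre_ids])),
      profile_of("d", "post_fmt", unname(perm[post_ids])))
    expect_equal(r3$rate_percent, r0$rate_percent)
  }
})

test_that("summaries report mean, median, range and per-ASV frequencies", {
  mk <- function(dog, cand, eng, rate)
    structure(list(dog_id = dog, candidate_donor_asvs = cand,
                   engrafted_asvs = eng, rate_percent = rate),
              class = "engraftment_result")
  res <- list(mk("d1", letters[1:10], c("a", "b"), 10),
              mk("d2", letters[1:10], c("a", "c"), 30),
              mk("d3", letters[1:10], c("a"), 50))
  s <- summarize_engraftment(res)
  expect_equal(s$mean_percent, 30)
  expect_equal(s$median_percent, 30)
  expect_equal(unname(c(s$min_percent, s$max_percent)), c(10, 50))
  expect_equal(s$asv_frequency[["a"]], 3L)
  expect_equal(s$asv_frequency[["b"]], 1L)
  # midpoint median for even counts
  s2 <- summarize_engraftment(res[1:2])
  expect_equal(s2$median_percent, 20)
  # degenerate single result
  s1 <- summarize_engraftment(res[1])
  expect_equal(unname(c(s1$mean_percent, s1$median_percent,
                        s1$min_percent, s1$max_percent)),
               rep(10, 4))
  expect_error(summarize_engraftment(list()), "no engraftment")
})

test_that("transfer probability is recovered on simulated trials", {
  # pooled engrafted/candidate fraction across recipients should sit in
  # the exact binomial interval of the configured transfer probability
  b <- make_fixture_dataset(trial_sim_config(engraft_prob = 0.5,
                                             seed = 303))
  eng <- engraftment_analysis(b$table, b$metadata)
  tab <- engraftment_table(eng)
  x <- sum(tab$n_engrafted); n <- sum(tab$n_candidates)
  lo <- qbinom(0.025, n, 0.5) / n
  hi <- qbinom(0.975, n, 0.5) / n
  expect_gte(x / n, lo)
  expect_lte(x / n, hi)
  # and with guaranteed-detection defaults the recovered sets equal truth
  tr <- b$ground_truth$transferred
  for (dog in names(eng$results))
    expect_setequal(eng$results[[dog]]$engrafted_asvs, tr[[dog]])
})
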
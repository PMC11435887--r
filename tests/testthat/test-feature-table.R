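test_that("TSV round-trip reproduces tables exactly, including edge cases", {
  cases <- list(
    small_table(matrix(c(1, 0, 5, 2, 3, 9), nrow = 2)),
    random_table(40, 120, seed = 11),
    random_table(1000, 200, seed = 5),
    asv_table(matrix(integer(0), 0, 0,
                     dimnames = list(character(0), character(0))))
  )
  for (tb in cases) {
    f <- withr::local_tempfile(fileext = ".tsv")
    write_asv_table(tb, f)
    back <- read_asv_table(f)
    expect_identical(back$counts, tb$counts)
  }
})

test_that("writing is byte-stable across repeated writes", {
  tb <- random_table(10, 30, seed = 3)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_asv_table(tb, f1)
  write_asv_table(tb, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("malformed inputs are rejected with the offending cell named", {
  f <- withr::local_tempfile()
  writeLines(c("asv_id\ts1\ts2", "a1\t2\t3", "a2\t2.5\t1"), f)
  expect_error(read_asv_table(f), "2\\.5.*a2.*s1")
  writeLines(c("asv_id\ts1\ts1", "a1\t2\t3"), f)
  expect_error(read_asv_table(f), "duplicate sample column.*s1")
  writeLines(c("asv_id\ts1", "a1\t2", "a1\t3"), f)
  expect_error(read_asv_table(f), "duplicate ASV id.*a1")
  writeLines(c("asv_id\ts1", "a1\t-2"), f)
  expect_error(read_asv_table(f), "-2")
  expect_error(asv_table(matrix(c(1, -1), 1, 2,
                                dimnames = list("s", c("a", "b")))),
               "negative")
})

test_that("BIOM (JSON) tables read back identical to the TSV dialect", {
  skip_if_not_installed("biomformat")
  tb <- random_table(6, 15, seed = 9)
  b <- biomformat::make_biom(t(tb$counts))
  f <- withr::local_tempfile(fileext = ".biom")
  biomformat::write_biom(b, f)
  back <- read_asv_table(f, format = "biom")
  expect_equal(back$counts[rownames(tb$counts), colnames(tb$counts)],
               tb$counts)
})

test_that("rare-ASV removal keeps exactly the ASVs above the total cutoff", {
  tb <- small_table(rbind(c(1, 2, 3, 1), c(0, 0, 2, 1)))
  out <- remove_rare_asvs(tb)  # totals 1, 2, 5, 2
  expect_identical(asv_ids(out), "a3")
  expect_identical(sample_ids(out), sample_ids(tb))
  # no-op when everything is abundant
  tb2 <- small_table(matrix(3, 2, 3))
  expect_identical(remove_rare_asvs(tb2)$counts, tb2$counts)
  # degenerate empty table passes through
  empty <- asv_table(matrix(integer(0), 0, 0,
                            dimnames = list(character(0), character(0))))
  expect_identical(dim(remove_rare_asvs(empty)), c(0L, 0L))
  # max_total = 0 is the identity when no column is all-zero
  tb3 <- random_table(5, 20, seed = 2)
  tb3$counts[tb3$counts == 0] <- 1L
  tb3 <- asv_table(tb3$counts)
  expect_identical(remove_rare_asvs(tb3, 0)$counts, tb3$counts)
})

test_that("low-count filter applies the min-count/prevalence rule inclusively", {
  tb <- small_table(cbind(c(5, 5, 0, 0, 0), c(3, 3, 3, 3, 3)))
  out <- low_count_filter(tb)  # a1 prevalence 0.40 at >=4; a2 never >=4
  expect_identical(asv_ids(out), "a1")
  # boundary: exactly ceil(0.2 * n) qualifying samples is retained
  tb2 <- small_table(cbind(c(4, 0, 0, 0, 0)))  # 1/5 = 0.20 exactly
  expect_identical(asv_ids(low_count_filter(tb2)), "a1")
})

test_that("low-variance filter drops the bottom IQR fraction deterministically", {
  set.seed(4)
  m <- matrix(rpois(100, 20), nrow = 10)
  m[, 3] <- 7  # constant => IQR 0
  tb <- small_table(m)
  out <- low_variance_filter(tb, 0.10)
  expect_false("a3" %in% asv_ids(out))
  expect_identical(ncol(out$counts), 9L)
  # drop_fraction 0 and floor(0.5) = 0 are identities
  expect_identical(low_variance_filter(tb, 0)$counts, tb$counts)
  tb5 <- small_table(matrix(rpois(25, 9), nrow = 5))
  expect_identical(low_variance_filter(tb5, 0.10)$counts, tb5$counts)
})

test_that("threshold filters are idempotent and no filter alters retained counts", {
  tb <- random_table(12, 80, seed = 21)
  for (filt in list(function(x) remove_rare_asvs(x, 5),
                    function(x) low_count_filter(x, 4, 0.25))) {
    once <- filt(tb)
    twice <- filt(once)
    expect_identical(twice$counts, once$counts)
  }
  # every filter, including the rank-based IQR one, is a pure column
  # selection: retained counts are untouched
  for (filt in list(function(x) remove_rare_asvs(x, 5),
                    function(x) low_count_filter(x, 4, 0.25),
                    function(x) low_variance_filter(x, 0.2))) {
    once <- filt(tb)
    expect_identical(once$counts,
                     tb$counts[, asv_ids(once), drop = FALSE])
  }
})

test_that("total-sum scaling normalises rows and excludes empty samples", {
  tb <- small_table(rbind(c(2, 1, 1), c(0, 0, 0)))
  expect_warning(rel <- total_sum_scaling(tb), "zero-total.*s2")
  expect_equal(unname(rel$proportions["s1", ]), c(0.5, 0.25, 0.25))
  expect_false("s2" %in% sample_ids(rel))
  expect_equal(rowSums(rel$proportions), c(s1 = 1))
  all_zero <- small_table(matrix(0, 2, 2))
  expect_error(total_sum_scaling(all_zero), "zero total")
})

test_that("taxonomic aggregation sums by label and pools unassigned ranks", {
  counts <- small_table(rbind(c(3, 4, 2, 7)), samples = "s1",
                        asvs = c("a1", "a2", "a3", "a4"))
  tax <- data.frame(
    asv_id = c("a1", "a2", "a3", "a4"),
    domain = "Bacteria", phylum = "Firmicutes", class = "Clostridia",
    order = "Lachnospirales",
    family = c("Lachnospiraceae", "Lachnospiraceae", "Lachnospiraceae", ""),
    genus = c("Blautia", "Blautia", "", ""),
    species = "", stringsAsFactors = FALSE)
  tb <- asv_table(counts$counts, taxonomy = tax)
  agg <- aggregate_taxa(tb, "genus")
  expect_equal(agg$counts[1, "Blautia"], 7L)
  expect_equal(agg$counts[1, "unclassified Lachnospiraceae"], 2L)
  expect_equal(agg$counts[1, "unclassified Lachnospirales"], 7L)
  # conservation of per-sample totals
  expect_identical(rowSums(agg$counts), rowSums(tb$counts))
  expect_error(aggregate_taxa(counts, "genus"), "taxonomy")
})

test_that("collapse_other pools sub-threshold taxa and conserves row sums", {
  m <- rbind(c(0.5, 0.492, 0.008), c(0.6, 0.39, 0.01))
  dimnames(m) <- list(c("s1", "s2"), c("t1", "t2", "t3"))
  rel <- rel_abund(m)
  out <- collapse_other(rel, 0.01)  # t3 mean 0.009 < threshold
  expect_true("Other" %in% colnames(out$proportions))
  expect_false("t3" %in% colnames(out$proportions))
  expect_equal(rowSums(out$proportions), rowSums(m),
               tolerance = 1e-12)
  # all taxa above threshold: untouched, no Other column
  out2 <- collapse_other(rel, 0.001)
  expect_identical(colnames(out2$proportions), colnames(m))
})
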
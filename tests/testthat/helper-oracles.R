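# Independent oracles and fixture builders used across the suite.
# Oracles are deliberately naive (exhaustive loops, closed forms) and share
# no code with the package implementation they check.

# random ASV table with reproducible contents
random_table <- function(n_samples, n_asvs, max_count = 50, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_samples * n_asvs, lambda = runif(1, 1, max_count)),
              nrow = n_samples,
              dimnames = list(sprintf("s%03d", seq_len(n_samples)),
                              sprintf("asv%04d", seq_len(n_asvs))))
  asv_table(m)
}

small_table <- function(counts, samples = NULL, asvs = NULL) {
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(nrow(counts)))
  if (is.null(asvs)) asvs <- sprintf("a%d", seq_len(ncol(counts)))
  dimnames(counts) <- list(samples, asvs)
  asv_table(counts)
}

# brute-force engraftment: exhaustive membership loops over id vectors
oracle_engraftment <- function(donor_ids, pre_ids, post_ids) {
  candidates <- character(0)
  for (a in donor_ids) {
    shared <- FALSE
    for (b in pre_ids) if (identical(a, b)) shared <- TRUE
    if (!shared) candidates <- c(candidates, a)
  }
  engrafted <- character(0)
  for (a in candidates) {
    found <- FALSE
    for (b in post_ids) if (identical(a, b)) found <- TRUE
    if (found) engrafted <- c(engrafted, a)
  }
  list(candidates = sort(candidates), engrafted = sort(engrafted),
       rate = if (length(candidates) == 0) NA_real_ else
         100 * length(engrafted) / length(candidates))
}

# presence profiles straight from id sets (no table needed)
profile_of <- function(owner, context, ids) {
  structure(list(owner = owner, context = context,
                 present_asvs = ids), class = "presence_profile")
}

# Fisher exact two-sided p by hypergeometric enumeration
oracle_fisher <- function(x11, x12, x21, x22) {
  m <- x11 + x21; n <- x12 + x22; k <- x11 + x12
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(x11, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# pseudo-F by direct partition of squared distances
oracle_pseudo_f <- function(d, labels) {
  n <- length(labels)
  groups <- unique(labels)
  a <- length(groups)
  sst <- sum(d[upper.tri(d)]^2) / n
  ssw <- 0
  for (g in groups) {
    idx <- which(labels == g)
    for (i in idx) for (j in idx) if (i < j)
      ssw <- ssw + d[i, j]^2 / length(idx)
  }
  ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}

# metadata for a minimal one-dog + donor layout
tiny_metadata <- function() {
  data.frame(
    sample_id = c("d1_endoscopy", "d1_treatment", "d1_post",
                  "donor_a", "donor_b"),
    dog_id = c("d1", "d1", "d1", "donor", "donor"),
    group = c("FMT", "FMT", "FMT", "donor", "donor"),
    visit = c("endoscopy", "treatment", "post_treatment",
              "donor", "donor"),
    stringsAsFactors = FALSE)
}
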
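#' Shannon diversity of a probability vector
#'
#' H = -sum p_i log p_i, natural log by default; zero entries contribute
#' nothing.  The vector must be a probability vector (non-negative,
#' summing to 1 within 1e-9), i.e. one row of a [rel_abund()].
#'
#' @param proportions numeric vector of proportions
#' @param base logarithm base (default `exp(1)`, i.e. nats)
#' @return Shannon index in `[0, log(k)]` for k taxa with nonzero mass
#' @export
shannon <- function(proportions, base = exp(1)) {
  if (any(proportions < 0)) stop("negative proportion")
  s <- sum(proportions)
  if (s == 0) stop("all-zero proportion vector")
  if (abs(s - 1) > 1e-9)
    stop("proportions sum to ", format(s), ", not 1")
  p <- proportions[proportions > 0]
  -sum(p * log(p, base = base))
}

#' Per-sample Shannon diversity of a relative-abundance table
#' @param rel a [rel_abund()]
#' @param base logarithm base
#' @return named numeric vector, one Shannon index per sample
#' @export
alpha_diversity <- function(rel, base = exp(1)) {
  stopifnot(inherits(rel, "rel_abund"))
  apply(rel$proportions, 1, shannon, base = base)
}

#' Kruskal-Wallis rank test over groups
#'
#' Rank-based H statistic with tie correction and chi-square p-value on
#' (number of groups - 1) degrees of freedom; two-group calls serve as
#' pairwise comparisons.  When every value is identical the statistic is 0
#' and p is 1 (no separation to detect).
#'
#' @param groups list of numeric vectors, one per group (>= 2 non-empty
#'   groups)
#' @return list with `statistic` (H), `p_value`, `df`
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least two groups")
  if (any(lengths(groups) == 0)) stop("empty group")
  values <- unlist(groups)
  if (length(unique(values)) == 1)
    return(list(statistic = 0, p_value = 1, df = length(groups) - 1L))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(values, g)
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter))
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' 1 - 2 sum_i min(x_i, y_i) / (sum x + sum y); ranges from 0 (identical)
#' to 1 (disjoint supports).  No normalisation is applied inside: the
#' value depends on the scale of its inputs, so callers pass relative
#' abundances when comparing samples of unequal depth.
#'
#' @param x,y non-negative numeric vectors of equal length, each with at
#'   least one positive entry
#' @return dissimilarity in `[0, 1]`
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (any(x < 0) || any(y < 0)) stop("negative abundance")
  sx <- sum(x); sy <- sum(y)
  if (sx == 0 || sy == 0) stop("zero-sum abundance vector")
  1 - 2 * sum(pmin(x, y)) / (sx + sy)
}

#' Bray-Curtis distance matrix over the samples of a table
#' @param rel a [rel_abund()] (or plain matrix, samples x taxa)
#' @return symmetric `dist_matrix` object: list with `sample_ids` and the
#'   square `distances` matrix (zero diagonal, entries in `[0, 1]`)
#' @export
bray_curtis_matrix <- function(rel) {
  m <- if (inherits(rel, "rel_abund")) rel$proportions else as.matrix(rel)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- bray_curtis(m[i, ], m[j, ])
    }
  }
  structure(list(sample_ids = rownames(m), distances = d),
            class = "dist_matrix")
}

# count of distinct assignments of a label multiset to positions
n_distinct_labelings <- function(labels) {
  tab <- table(labels)
  exp(lgamma(length(labels) + 1) - sum(lgamma(tab + 1)))
}

# all distinct permutations of a label vector (columns of the result)
enumerate_labelings <- function(labels) {
  uniq <- unique(labels)
  rec <- function(remaining, slots) {
    if (length(slots) == 0) return(matrix(character(0), nrow = 0, ncol = 1))
    out <- NULL
    for (u in unique(remaining)) {
      rest <- remaining[-match(u, remaining)]
      sub <- rec(rest, slots[-1])
      out <- cbind(out, rbind(u, sub))
    }
    out
  }
  m <- rec(labels, seq_along(labels))
  rownames(m) <- NULL
  m
}

#' PERMANOVA: permutational multivariate ANOVA on a distance matrix
#'
#' Partitions the squared-distance geometry (Gower centering) into
#' between- and within-group components and tests the pseudo-F
#' `(SS_between / (a-1)) / (SS_within / (n-a))` by permuting group labels.
#' The permutation p-value is `(exceedances + 1) / (n_permutations + 1)`;
#' when the number of distinct labelings is at most `exhaustive_limit` the
#' full enumeration is used instead and p is the exact exceedance
#' fraction.  Reproducible bit-exact for a fixed `(seed, n_permutations)`.
#'
#' @param dist a `dist_matrix` from [bray_curtis_matrix()], or a square
#'   symmetric matrix
#' @param labels group label per sample (>= 2 groups, each with >= 2
#'   samples)
#' @param n_permutations Monte-Carlo permutations (default 999, so the
#'   p-value grid includes 0.001)
#' @param seed RNG seed for the permutations (required)
#' @param exhaustive_limit enumerate all labelings when their count is at
#'   most this (default 10000)
#' @return object of class `permanova_result`: `pseudo_F`, `p_value`,
#'   `n_permutations` (actual draws, or the enumeration size), `seed`,
#'   `exhaustive`
#' @export
permanova <- function(dist, labels, n_permutations = 999, seed,
                      exhaustive_limit = 10000) {
  d <- if (inherits(dist, "dist_matrix")) dist$distances else as.matrix(dist)
  n <- nrow(d)
  if (length(labels) != n) stop("labels length must match samples")
  labels <- as.character(labels)
  sizes <- table(labels)
  if (length(sizes) < 2) stop("need at least two groups")
  if (any(sizes < 2))
    stop("group '", names(sizes)[sizes < 2][1L],
         "' has fewer than 2 samples")
  if (missing(seed)) stop("seed is required for reproducibility")
  a <- length(sizes)
  d2 <- d^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  # pseudo-F for every column of an n x B label matrix at once; group
  # sizes are permutation-invariant so the quadratic forms vectorise
  f_many <- function(lab_mat) {
    ss_within <- rep(0, ncol(lab_mat))
    for (g in names(sizes)) {
      z <- (lab_mat == g) * 1
      ss_within <- ss_within + colSums(z * (d2 %*% z)) / (2 * sizes[[g]])
    }
    ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
  }
  f_obs <- f_many(matrix(labels, ncol = 1))
  n_lab <- n_distinct_labelings(labels)
  if (n_lab <= exhaustive_limit) {
    all_lab <- enumerate_labelings(labels)
    fs <- f_many(all_lab)
    p <- mean(fs >= f_obs - 1e-12)
    n_perm_used <- ncol(all_lab)
    exhaustive <- TRUE
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    perm <- vapply(seq_len(n_permutations),
                   function(b) sample(labels), character(n))
    fs <- f_many(perm)
    p <- (sum(fs >= f_obs - 1e-12) + 1) / (n_permutations + 1)
    n_perm_used <- n_permutations
    exhaustive <- FALSE
  }
  structure(list(pseudo_F = unname(f_obs), p_value = unname(p),
                 n_permutations = n_perm_used, seed = seed,
                 exhaustive = exhaustive),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4f, p = %.4g (%s, %d permutations)\n",
              x$pseudo_F, x$p_value,
              if (x$exhaustive) "exhaustive" else "sampled",
              x$n_permutations))
  invisible(x)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
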
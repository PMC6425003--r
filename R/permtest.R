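#' Exhaustive leave-one individual-permutation scheme
#'
#' Enumerates all permutations that move exactly one individual of the
#' first group into the second position. In the study design this scheme
#' validates D(group1, group2; test, outgroup) when group2 is a single
#' individual (the anchor): each of the n group-1 individuals takes the
#' anchor's place in turn while the remaining n - 1 individuals -- plus
#' the anchor itself when `include_anchor` is `TRUE` -- form the permuted
#' first group. With `include_anchor = FALSE` the anchor is excluded
#' entirely, which probes the statistic's distribution *within* group 1.
#'
#' @param group1 character vector of individual ids (the observed first
#'   group; five individuals in the study design).
#' @param anchor single individual id (the observed second group).
#' @param include_anchor whether the anchor joins the permuted first
#'   group (default `TRUE`).
#' @return A `perm_scheme` object whose `assignments` list the permuted
#'   (group1, group2) pairs; the observed grouping is kept alongside.
#' @export
perm_scheme_leave_one <- function(group1, anchor, include_anchor = TRUE) {
  ids <- c(group1, anchor)
  if (anyDuplicated(ids)) stop("duplicate individual ids in scheme")
  if (length(anchor) != 1) stop("anchor must be a single individual id")
  if (length(group1) < 2) stop("group1 must have at least two individuals")
  assignments <- lapply(seq_along(group1), function(i) {
    g2 <- group1[i]
    g1 <- group1[-i]
    if (include_anchor) g1 <- c(g1, anchor)
    list(group1 = g1, group2 = g2)
  })
  structure(list(kind = "exhaustive-leave-one",
                 group1 = group1, group2 = anchor,
                 include_anchor = include_anchor,
                 assignments = assignments),
            class = "perm_scheme")
}

#' Random-split individual-permutation scheme
#'
#' Pools the two observed groups and draws `n_perm` random re-splits
#' preserving the group sizes: each permutation places a uniform random
#' subset of size `|group2|` (drawn without replacement within a
#' permutation; permutations may repeat) into the second position and
#' the rest into the first. In the study design this re-splits 30
#' individuals (25 + 5) a thousand times.
#'
#' @param group1,group2 character vectors of individual ids forming the
#'   observed split.
#' @param n_perm number of random permutations (default 1000).
#' @param seed optional integer seed making the draw reproducible
#'   without touching the caller's RNG state.
#' @return A `perm_scheme` object.
#' @export
perm_scheme_random <- function(group1, group2, n_perm = 1000, seed = NULL) {
  pooled <- c(group1, group2)
  if (anyDuplicated(pooled)) stop("duplicate individual ids in scheme")
  if (length(group1) < 1 || length(group2) < 1)
    stop("both groups must be non-empty")
  k <- length(group2)
  assignments <- with_seed(seed, lapply(seq_len(n_perm), function(i) {
    g2 <- sample(pooled, k)
    list(group1 = setdiff(pooled, g2), group2 = g2)
  }))
  structure(list(kind = "random-split",
                 group1 = group1, group2 = group2,
                 n_perm = n_perm, seed = seed,
                 assignments = assignments),
            class = "perm_scheme")
}

#' @export
print.perm_scheme <- function(x, ...) {
  cat("perm_scheme (", x$kind, "): ", length(x$group1), " + ",
      length(x$group2), " individuals, ", length(x$assignments),
      " permutations\n", sep = "")
  invisible(x)
}

# D statistics for many (group1, group2) assignments at once.
# Frequencies of the fixed test and outgroup populations are computed
# once; group frequencies for all assignments come from one matrix
# product with the group-membership indicator matrix.
perm_d_values <- function(data, groupings, test, outgroup) {
  ids <- unique(unlist(lapply(groupings, function(g) c(g$group1, g$group2))))
  cols <- match(ids, data$ind$individual_id)
  if (anyNA(cols)) stop("scheme individual ids absent from dataset: ",
                        paste(ids[is.na(cols)], collapse = ", "))
  g <- data$geno[, cols, drop = FALSE]
  ph <- data$pseudo_haploid[cols]
  w_tot <- ifelse(ph, 1, 2)
  w_alt <- ifelse(ph, 0.5, 1)
  gm <- g; gm[is.na(gm)] <- 0L
  A <- gm * rep(w_alt, each = nrow(gm))      # per-individual alt dose
  Cn <- (!is.na(g)) * rep(w_tot, each = nrow(g))  # per-individual allele count

  P <- length(groupings)
  M1 <- matrix(0, length(ids), P)
  M2 <- matrix(0, length(ids), P)
  for (j in seq_len(P)) {
    M1[match(groupings[[j]]$group1, ids), j] <- 1
    M2[match(groupings[[j]]$group2, ids), j] <- 1
  }
  alt1 <- A %*% M1; cnt1 <- Cn %*% M1
  alt2 <- A %*% M2; cnt2 <- Cn %*% M2
  W <- alt1 / cnt1   # NaN where count 0; masked below
  X <- alt2 / cnt2

  fo <- allele_frequencies(data, c(test, outgroup))
  yy <- fo$freq[, 1]; zz <- fo$freq[, 2]
  fixed_ok <- fo$count[, 1] > 0 & fo$count[, 2] > 0 & !is.na(yy) & !is.na(zz)
  r <- yy - zz
  s <- yy + zz - 2 * yy * zz

  num <- (W - X) * r
  den <- (W + X - 2 * W * X) * s
  ok <- (cnt1 > 0) & (cnt2 > 0) & fixed_ok
  num[!ok] <- 0; den[!ok] <- 0
  dsum <- colSums(den)
  if (any(dsum == 0)) stop("degenerate denominator in permuted D statistic")
  colSums(num) / dsum
}

#' Individual-label permutation test for a D statistic
#'
#' Computes the observed D(group1, group2; test, outgroup) with the
#' scheme's observed grouping pooled into two pseudo-populations, then
#' recomputes D under every permuted assignment of the scheme. The
#' empirical P-value counts the observed statistic as one permutation
#' (identity-inclusive): P = (1 + #\{permuted D >= observed D\}) /
#' (n_perm + 1), so with 1000 random permutations the denominator is
#' 1001 and P is never zero. Ties count toward the numerator
#' ("equal to or greater").
#'
#' @param data a `genotype_dataset`.
#' @param scheme a `perm_scheme` from [perm_scheme_leave_one()] or
#'   [perm_scheme_random()].
#' @param test,outgroup population labels for positions 3 and 4 of the
#'   D statistic.
#' @return Object of class `permutation_result`: `observed`, `permuted`
#'   (vector), `n_perm`, `n_ge`, `p_value`, and the identity-inclusive
#'   convention recorded in `p_convention`.
#' @export
permutation_test <- function(data, scheme, test, outgroup) {
  stopifnot(inherits(scheme, "perm_scheme"))
  groupings <- c(list(list(group1 = scheme$group1, group2 = scheme$group2)),
                 scheme$assignments)
  d <- perm_d_values(data, groupings, test, outgroup)
  observed <- d[1]
  permuted <- d[-1]
  n_perm <- length(permuted)
  n_ge <- sum(permuted >= observed)
  p <- (1 + n_ge) / (n_perm + 1)
  structure(list(observed = observed, permuted = permuted,
                 n_perm = n_perm, n_ge = n_ge,
                 total = n_perm + 1, p_value = p,
                 test = test, outgroup = outgroup,
                 p_convention = "identity-inclusive: P = (1 + #{perm >= obs}) / (n_perm + 1)"),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation test vs %s (outgroup %s)\n", x$test, x$outgroup))
  cat(sprintf("observed D = %.6f; %d of %d permutations >= observed\n",
              x$observed, x$n_ge, x$n_perm))
  cat(sprintf("empirical P = %.4g (denominator %d, ties count as greater)\n",
              x$p_value, x$total))
  invisible(x)
}
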
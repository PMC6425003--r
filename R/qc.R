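#' Genetic sex from relative X and Y chromosome coverage
#'
#' Assigns genetic sex by normalizing X and Y mean coverage by the
#' autosomal mean coverage. With `x_rate = X/autosomal` and
#' `y_rate = Y/autosomal`, a male call requires a substantial Y rate and
#' a roughly haploid X; a female call requires a near-zero Y rate and a
#' roughly diploid X; everything else is left unassigned. The ratio
#' computation is the contract; the cutoffs are configurable package
#' defaults in line with shotgun sex-typing practice.
#'
#' @param coverage data frame with columns `individual_id`, `autosomal`,
#'   `X`, `Y` (mean fold coverage per chromosome class).
#' @param y_male minimum y_rate for a male call (default 0.3).
#' @param x_male_max maximum x_rate for a male call (default 0.8).
#' @param y_female maximum y_rate for a female call (default 0.1).
#' @param x_female_min minimum x_rate for a female call (default 0.8).
#' @return Data frame with `individual_id`, `x_rate`, `y_rate`, `sex`
#'   ("male", "female" or "unassigned").
#' @export
genetic_sex <- function(coverage, y_male = 0.3, x_male_max = 0.8,
                        y_female = 0.1, x_female_min = 0.8) {
  need <- c("individual_id", "autosomal", "X", "Y")
  if (!all(need %in% names(coverage)))
    stop("coverage table must have columns: ", paste(need, collapse = ", "))
  if (any(coverage$autosomal <= 0))
    stop("autosomal coverage must be positive for: ",
         paste(coverage$individual_id[coverage$autosomal <= 0], collapse = ", "))
  if (any(coverage$X < 0 | coverage$Y < 0)) stop("coverages must be >= 0")
  x_rate <- coverage$X / coverage$autosomal
  y_rate <- coverage$Y / coverage$autosomal
  sex <- rep("unassigned", nrow(coverage))
  sex[y_rate >= y_male & x_rate <= x_male_max] <- "male"
  sex[y_rate <= y_female & x_rate >= x_female_min] <- "female"
  data.frame(individual_id = coverage$individual_id,
             x_rate = x_rate, y_rate = y_rate, sex = sex,
             stringsAsFactors = FALSE)
}

#' Pairwise mismatch rates between individuals
#'
#' For each pair, the fraction of SNPs at which the two genotype codes
#' differ, among SNPs non-missing in both. With pseudo-haploid samples
#' this is the standard single-allele mismatch rate used to screen for
#' close relatives before pooling individuals into analysis populations.
#'
#' @param x a `genotype_dataset`.
#' @param individuals character vector of individual ids (default: all).
#' @param pairs optional two-column matrix/data frame of individual ids;
#'   default is all unordered pairs of `individuals`.
#' @return Data frame with `id1`, `id2`, `n_overlap`, `mismatch`
#'   (`NA` with zero overlap, flagged in `undefined`).
#' @export
pairwise_mismatch <- function(x, individuals = NULL, pairs = NULL) {
  stopifnot(inherits(x, "genotype_dataset"))
  if (is.null(individuals)) individuals <- x$ind$individual_id
  if (is.null(pairs)) {
    if (length(individuals) < 2) stop("need at least two individuals")
    pairs <- t(utils::combn(individuals, 2))
  }
  pairs <- as.matrix(pairs)
  idx1 <- match(pairs[, 1], x$ind$individual_id)
  idx2 <- match(pairs[, 2], x$ind$individual_id)
  if (anyNA(idx1) || anyNA(idx2)) stop("unknown individual id in pairs")
  n <- nrow(pairs)
  n_overlap <- integer(n)
  rate <- numeric(n)
  for (k in seq_len(n)) {
    g1 <- x$geno[, idx1[k]]
    g2 <- x$geno[, idx2[k]]
    ok <- !is.na(g1) & !is.na(g2)
    n_overlap[k] <- sum(ok)
    rate[k] <- if (n_overlap[k] > 0) mean(g1[ok] != g2[ok]) else NA_real_
  }
  data.frame(id1 = pairs[, 1], id2 = pairs[, 2],
             n_overlap = n_overlap, mismatch = rate,
             undefined = n_overlap == 0,
             stringsAsFactors = FALSE)
}

#' Flag unusually similar pairs relative to the group baseline
#'
#' Close relatives are detected relative to the distribution of pairwise
#' mismatch rates within the compared group rather than by an absolute
#' cutoff: each pair gets a z-score against the mean and standard
#' deviation of all defined rates, and pairs below `z_threshold` are
#' flagged as candidate relatives.
#'
#' @param mismatch output of [pairwise_mismatch()].
#' @param z_threshold z-score below which a pair is flagged (default -3).
#' @return The input with added `z` and `flagged` columns.
#' @export
mismatch_zscores <- function(mismatch, z_threshold = -3) {
  r <- mismatch$mismatch
  mu <- mean(r, na.rm = TRUE)
  sd_ <- stats::sd(r, na.rm = TRUE)
  z <- if (isTRUE(sd_ > 0)) (r - mu) / sd_ else rep(NA_real_, length(r))
  mismatch$z <- z
  mismatch$flagged <- !is.na(z) & z < z_threshold
  mismatch
}
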
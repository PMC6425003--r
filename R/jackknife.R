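#' Assign SNPs to contiguous jackknife blocks
#'
#' Groups consecutive SNPs into blocks spanning at most `block_size`
#' morgans (when the genetic map is informative) or `fallback_bp` base
#' pairs otherwise, starting a new block at every chromosome boundary.
#' Blocks are the resampling unit of the delete-one-block jackknife,
#' chosen wide enough that linkage between blocks is negligible.
#'
#' @param snp SNP table of a `genotype_dataset` (or the dataset itself).
#' @param block_size block span in morgans (default 0.05, the
#'   ADMIXTOOLS convention).
#' @param fallback_bp physical span in base pairs used when genetic
#'   positions are absent or degenerate (default 5e6).
#' @return Object of class `block_assignment`: list with `block`
#'   (per-SNP 1-based block index), `n_blocks`, `sizes` (SNPs per
#'   block) and `unit` ("genetic" or "physical").
#' @export
assign_blocks <- function(snp, block_size = 0.05, fallback_bp = 5e6) {
  if (inherits(snp, "genotype_dataset")) snp <- snp$snp
  n <- nrow(snp)
  if (n == 0) stop("no SNPs to assign")
  o <- snp_order(snp)
  if (!identical(o, seq_len(n)))
    stop("SNPs must be sorted by (chromosome, physical_pos)")
  gp <- snp$genetic_pos
  chrom <- as.character(snp$chromosome)
  nondecreasing <- !anyNA(gp) &&
    all(vapply(split(gp, chrom), function(v) all(diff(v) >= 0), logical(1)))
  use_genetic <- nondecreasing && !all(gp == 0)
  if (use_genetic) {
    pos <- gp; size <- block_size; unit <- "genetic"
  } else {
    pos <- as.numeric(snp$physical_pos); size <- fallback_bp; unit <- "physical"
  }
  # greedy grouping: a block absorbs consecutive SNPs while its span
  # (pos - block start) stays <= size; sequential only over block starts
  block <- integer(n)
  b <- 0L
  runs <- rle(chrom)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (k in seq_along(starts)) {
    s <- starts[k]
    p <- pos[s:ends[k]]
    m <- length(p)
    ii <- 1L
    while (ii <= m) {
      b <- b + 1L
      jj <- findInterval(p[ii] + size, p)  # last index with p <= start + size
      block[(s - 1L + ii):(s - 1L + jj)] <- b
      ii <- jj + 1L
    }
  }
  structure(list(block = block, n_blocks = b,
                 sizes = tabulate(block, b), unit = unit),
            class = "block_assignment")
}

#' @export
print.block_assignment <- function(x, ...) {
  cat("block_assignment:", x$n_blocks, "blocks over", length(x$block),
      "SNPs (", x$unit, "units )\n")
  invisible(x)
}

#' Weighted delete-one-block jackknife for a ratio estimator
#'
#' The point estimate is the whole-data ratio `sum(num)/sum(den)`. The
#' standard error comes from the weighted delete-one jackknife: with
#' block weights m_j (usable SNP counts), n = sum(m_j), h_j = n/m_j and
#' leave-one-out estimates theta_(-j), the pseudovalues
#' tau_j = h_j * theta - (h_j - 1) * theta_(-j) give
#' var = mean( (tau_j - theta_J)^2 / (h_j - 1) ) where
#' theta_J = g * theta - sum( (1 - m_j/n) * theta_(-j) ). Under equal
#' weights this reduces exactly to the textbook unweighted delete-1
#' jackknife variance.
#'
#' @param num,den per-block numerator and denominator sums.
#' @param weights per-block weights (usable SNP counts); defaults to
#'   `den` if omitted.
#' @return List with `estimate`, `se`, `loo` (leave-one-out estimates)
#'   and `n_blocks` (blocks with positive weight).
#' @export
block_jackknife <- function(num, den, weights = NULL) {
  if (is.null(weights)) weights <- den
  keep <- weights > 0
  num <- num[keep]; den <- den[keep]; weights <- weights[keep]
  g <- length(num)
  if (g < 2) stop("need at least 2 blocks with nonzero weight")
  tot_num <- sum(num); tot_den <- sum(den)
  if (tot_den == 0) stop("zero total denominator")
  est <- tot_num / tot_den
  loo <- (tot_num - num) / (tot_den - den)
  n <- sum(weights)
  h <- n / weights
  theta_j <- g * est - sum((1 - weights / n) * loo)
  tau <- h * est - (h - 1) * loo
  v <- mean((tau - theta_j)^2 / (h - 1))
  list(estimate = est, se = sqrt(v), loo = loo, n_blocks = g)
}

# Weighted jackknife variance for a vector statistic given per-block
# leave-one-out estimates (rows of `loo`); returns the covariance matrix.
jackknife_cov <- function(est, loo, weights) {
  g <- nrow(loo)
  n <- sum(weights)
  h <- n / weights
  theta_j <- g * est - colSums((1 - weights / n) * loo)
  tau <- h * matrix(est, g, length(est), byrow = TRUE) - (h - 1) * loo
  dev <- sweep(tau, 2, theta_j) / sqrt(h - 1)
  crossprod(dev) / g
}

# Per-component jackknife SEs for a vector statistic (same scheme).
jackknife_se_vec <- function(est, loo, weights) {
  sqrt(diag(jackknife_cov(est, loo, weights)))
}
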
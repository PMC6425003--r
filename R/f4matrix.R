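#' f4 matrix between left and right population sets
#'
#' Builds the matrix X[i, j] = f4(left_1, left_{i+1}; right_1,
#' right_{j+1}) that underlies the qpWave rank test and qpAdm admixture
#' fits, together with the block-jackknife covariance of its vectorized
#' form. Under the default `snp_policy = "intersection"` all cells are
#' computed on the single SNP set usable in *every* left and right
#' population (the classic behaviour of the reference tools);
#' `"per_cell"` uses, per cell, all sites usable in that cell's four
#' populations.
#'
#' @param data a `genotype_dataset`.
#' @param left character vector of left populations; the first is the
#'   base (in qpAdm, the target).
#' @param right character vector of right (outgroup) populations; the
#'   first is the right base.
#' @param blocks a [assign_blocks()] result; computed with defaults
#'   when omitted.
#' @param snp_policy `"intersection"` (default) or `"per_cell"`.
#' @return Object of class `f4_matrix` with the value matrix, the
#'   vectorized estimate (column-major), its jackknife covariance,
#'   per-block leave-one-out estimates and block weights.
#' @export
build_f4_matrix <- function(data, left, right, blocks = NULL,
                            snp_policy = c("intersection", "per_cell")) {
  snp_policy <- match.arg(snp_policy)
  left <- as.character(left); right <- as.character(right)
  if (length(left) < 2 || length(right) < 2)
    stop("need at least 2 left and 2 right populations")
  if (length(common <- intersect(left, right)))
    stop("left and right population sets overlap: ",
         paste(common, collapse = ", "))
  if (anyDuplicated(left)) stop("duplicate population in left set")
  if (anyDuplicated(right)) stop("duplicate population in right set")
  fr <- allele_frequencies(data, c(left, right))
  L <- length(left) - 1L
  R <- length(right) - 1L
  nc <- L * R
  if (is.null(blocks)) blocks <- assign_blocks(data$snp)

  f <- fr$freq
  cnt <- fr$count
  if (snp_policy == "intersection") {
    usable <- rowSums(cnt > 0) == ncol(cnt)
    n_use <- sum(usable)
    if (n_use == 0) stop("empty usable-SNP intersection across populations")
    f <- f[usable, , drop = FALSE]
    bl <- blocks$block[usable]
    dl <- f[, 1] - f[, 1 + seq_len(L), drop = FALSE]       # left_1 - left_i
    dr <- f[, length(left) + 1] -
      f[, length(left) + 1 + seq_len(R), drop = FALSE]     # right_1 - right_j
    num <- matrix(0, n_use, nc)
    for (j in seq_len(R))
      num[, (j - 1L) * L + seq_len(L)] <- dl * dr[, j]
    ub <- sort(unique(bl))
    bidx <- match(bl, ub)
    bnum <- rowsum(num, bidx)
    m <- tabulate(bidx, length(ub))
    tot <- colSums(bnum)
    est <- tot / n_use
    loo <- sweep(-bnum, 2, tot, `+`) / (n_use - m)
    w <- m
    n_snps <- n_use
  } else {
    # per-cell usability: sites usable in the cell's four populations
    okL <- cnt[, 1 + seq_len(L), drop = FALSE] > 0 & cnt[, 1] > 0
    okR <- cnt[, length(left) + 1 + seq_len(R), drop = FALSE] > 0 &
      cnt[, length(left) + 1] > 0
    dl <- f[, 1] - f[, 1 + seq_len(L), drop = FALSE]
    dr <- f[, length(left) + 1] -
      f[, length(left) + 1 + seq_len(R), drop = FALSE]
    bl <- blocks$block
    ub <- sort(unique(bl))
    bidx <- match(bl, ub)
    num <- matrix(0, nrow(f), nc)
    use <- matrix(FALSE, nrow(f), nc)
    for (j in seq_len(R)) {
      cc <- (j - 1L) * L + seq_len(L)
      u <- okL & okR[, j]
      v <- dl * dr[, j]
      v[!u] <- 0
      num[, cc] <- v
      use[, cc] <- u
    }
    bnum <- rowsum(num, bidx)
    bcnt <- rowsum(use + 0, bidx)
    totn <- colSums(bnum)
    totc <- colSums(bcnt)
    if (any(totc == 0)) stop("a cell has zero usable SNPs")
    est <- totn / totc
    loo <- sweep(-bnum, 2, totn, `+`) / sweep(-bcnt, 2, totc, `+`)
    m <- blocks$sizes[ub]
    w <- m
    n_snps <- min(totc)
  }
  cov <- jackknife_cov(est, loo, w)
  structure(list(
    left = left, right = right,
    values = matrix(est, L, R,
                    dimnames = list(left[-1], right[-1])),
    est = est, cov = cov, loo = loo,
    block_weights = w, n_snps = n_snps, n_blocks = length(w),
    snp_policy = snp_policy
  ), class = "f4_matrix")
}

#' @export
print.f4_matrix <- function(x, ...) {
  cat("f4_matrix: left base", x$left[1], "| right base", x$right[1], "\n")
  print(signif(x$values, 4))
  cat(x$n_snps, "usable SNPs in", x$n_blocks, "blocks; policy:",
      x$snp_policy, "\n")
  invisible(x)
}
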
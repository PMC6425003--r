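# Shared engine for f2/f3/f4/D: per-site numerators and denominators from
# population allele frequencies, per-block sums, weighted block jackknife.
fstat_engine <- function(data, pops, kind, blocks = NULL, min_snps = 30000) {
  cols <- lapply(pops, function(p) pop_columns(data, p))
  fr <- lapply(cols, function(cc) group_freq(data, cc))
  f <- lapply(fr, `[[`, "freq")
  cnt <- lapply(fr, `[[`, "count")
  usable <- Reduce(`&`, lapply(cnt, function(v) v > 0))
  n_snps <- sum(usable)
  if (n_snps == 0) stop("zero usable SNPs for ", kind, "(",
                        paste(pops, collapse = ", "), ")")
  if (is.null(blocks)) blocks <- assign_blocks(data$snp)
  bl <- blocks$block[usable]
  f <- lapply(f, `[`, usable)
  num <- switch(kind,
    f2 = (f[[1]] - f[[2]])^2,
    f3 = (f[[1]] - f[[2]]) * (f[[1]] - f[[3]]),
    f4 = (f[[1]] - f[[2]]) * (f[[3]] - f[[4]]),
    D  = (f[[1]] - f[[2]]) * (f[[3]] - f[[4]])
  )
  den <- if (kind == "D") {
    (f[[1]] + f[[2]] - 2 * f[[1]] * f[[2]]) *
      (f[[3]] + f[[4]] - 2 * f[[3]] * f[[4]])
  } else rep(1, n_snps)

  ublocks <- sort(unique(bl))
  bidx <- match(bl, ublocks)
  bnum <- rowsum(num, bidx)[, 1]
  bden <- rowsum(den, bidx)[, 1]
  bcnt <- tabulate(bidx, length(ublocks))
  if (kind == "D" && sum(bden) == 0)
    stop("degenerate denominator: no polymorphism shared by the four populations")
  jk <- block_jackknife(bnum, bden, weights = bcnt)
  z <- if (is.finite(jk$se) && jk$se > 0) jk$estimate / jk$se else 0
  structure(list(
    kind = kind,
    pops = unlist(pops),
    estimate = jk$estimate, se = jk$se, z = z,
    n_snps = n_snps, n_blocks = jk$n_blocks,
    below_threshold = n_snps <= min_snps,
    block_num = bnum, block_den = bden, block_counts = bcnt
  ), class = "fstat")
}

#' Patterson's D statistic with block-jackknife standard error
#'
#' Computes D(W, X; Y, Z) from per-population allele frequencies
#' w, x, y, z: per usable site the numerator is (w - x)(y - z) and the
#' denominator (w + x - 2wx)(y + z - 2yz); D is the ratio of their sums
#' over sites usable in all four populations (at least one observed
#' allele each). A positive D(W, X; Y, Z) means the test population Y
#' shares excess alleles with W rather than X. The standard error and
#' Z-score come from the weighted delete-one-block jackknife of the
#' ratio, with block weights proportional to usable SNP counts.
#'
#' @param data a `genotype_dataset`.
#' @param w,x,y,z population labels (W, X; Y, Z).
#' @param blocks a [assign_blocks()] result; computed with defaults when
#'   omitted.
#' @param min_snps soft reporting threshold: results based on at most
#'   this many usable SNPs carry `below_threshold = TRUE` (default
#'   30000). Values are still returned for inspection.
#' @return An object of class `fstat` with fields `estimate`, `se`, `z`,
#'   `n_snps`, `n_blocks`, `below_threshold` and per-block accumulators.
#' @export
d_statistic <- function(data, w, x, y, z, blocks = NULL, min_snps = 30000) {
  fstat_engine(data, list(w, x, y, z), "D", blocks, min_snps)
}

#' f4 statistic with block-jackknife standard error
#'
#' The unnormalized numerator of D: the mean over usable sites of
#' (a - b)(c - d), additive along admixture graphs and the algebraic
#' basis of the qpWave/qpAdm machinery.
#'
#' @inheritParams d_statistic
#' @param a,b,c,d population labels.
#' @return An `fstat` object.
#' @export
f4_statistic <- function(data, a, b, c, d, blocks = NULL, min_snps = 30000) {
  fstat_engine(data, list(a, b, c, d), "f4", blocks, min_snps)
}

#' f2 statistic (mean squared frequency difference)
#'
#' Plain sample-frequency f2 = mean (a - b)^2 without small-sample
#' heterozygosity correction (see the methods vignette for why the
#' uncorrected form is the default).
#'
#' @inheritParams d_statistic
#' @param a,b population labels.
#' @return An `fstat` object.
#' @export
f2_statistic <- function(data, a, b, blocks = NULL, min_snps = 30000) {
  fstat_engine(data, list(a, b), "f2", blocks, min_snps)
}

#' f3 statistic
#'
#' f3(target; a, b) = mean (t - a)(t - b), uncorrected sample-frequency
#' form.
#'
#' @inheritParams d_statistic
#' @param target,a,b population labels.
#' @return An `fstat` object.
#' @export
f3_statistic <- function(data, target, a, b, blocks = NULL, min_snps = 30000) {
  fstat_engine(data, list(target, a, b), "f3", blocks, min_snps)
}

#' @export
print.fstat <- function(x, ...) {
  lab <- switch(x$kind,
    D = sprintf("D(%s, %s; %s, %s)", x$pops[1], x$pops[2], x$pops[3], x$pops[4]),
    f4 = sprintf("f4(%s, %s; %s, %s)", x$pops[1], x$pops[2], x$pops[3], x$pops[4]),
    f3 = sprintf("f3(%s; %s, %s)", x$pops[1], x$pops[2], x$pops[3]),
    f2 = sprintf("f2(%s, %s)", x$pops[1], x$pops[2])
  )
  cat(sprintf("%s = %.6f +/- %.6f (Z = %.2f)\n", lab, x$estimate, x$se, x$z))
  cat(sprintf("%d usable SNPs in %d blocks%s\n", x$n_snps, x$n_blocks,
              if (x$below_threshold) " [below reporting threshold]" else ""))
  invisible(x)
}

#' Batch D statistics over a table of population quadruples
#'
#' @param data a `genotype_dataset`.
#' @param quads data frame (or 4-column matrix) of population quadruples
#'   `(W, X, Y, Z)`, one statistic per row.
#' @inheritParams d_statistic
#' @return Data frame with columns `W, X, Y, Z, D, se, z, n_snps,
#'   n_blocks, below_threshold`, writable as TSV with
#'   [utils::write.table()].
#' @export
d_statistic_batch <- function(data, quads, blocks = NULL, min_snps = 30000) {
  quads <- as.matrix(quads)
  if (ncol(quads) != 4) stop("quads must have 4 columns (W, X, Y, Z)")
  if (is.null(blocks)) blocks <- assign_blocks(data$snp)
  rows <- lapply(seq_len(nrow(quads)), function(i) {
    s <- d_statistic(data, quads[i, 1], quads[i, 2], quads[i, 3], quads[i, 4],
                     blocks = blocks, min_snps = min_snps)
    data.frame(W = quads[i, 1], X = quads[i, 2], Y = quads[i, 3],
               Z = quads[i, 4], D = s$estimate, se = s$se, z = s$z,
               n_snps = s$n_snps, n_blocks = s$n_blocks,
               below_threshold = s$below_threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
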
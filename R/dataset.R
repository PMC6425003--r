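#' Construct a genotype dataset
#'
#' The central container of the package: a biallelic SNP-by-individual
#' matrix of alt-allele counts with SNP and individual metadata, as used
#' by all f-statistics, admixture models and QC routines.
#'
#' Genotypes are stored internally as counts of the *alternative* allele
#' (column `alt` of the SNP table): 0, 1, 2 or `NA` for missing.
#' Pseudo-haploid individuals carry a single sampled allele coded as a
#' homozygous call, so their genotypes are restricted to \{0, 2, NA\} and
#' each non-missing genotype represents exactly one observed allele.
#'
#' @param geno integer matrix, SNPs in rows and individuals in columns;
#'   values in \{0, 1, 2, NA\} (alt-allele counts).
#' @param snp data frame with columns `snp_id`, `chromosome`,
#'   `genetic_pos` (morgans; may be 0 when no genetic map is available),
#'   `physical_pos` (1-based base pairs), `ref`, `alt`.
#' @param ind data frame with columns `individual_id`, `sex`
#'   (one of "M", "F", "U") and `population`.
#' @param pseudo_haploid logical vector (recycled if scalar) flagging
#'   individuals whose genotypes are single sampled alleles.
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(geno, snp, ind, pseudo_haploid = FALSE) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  snp <- as.data.frame(snp, stringsAsFactors = FALSE)
  ind <- as.data.frame(ind, stringsAsFactors = FALSE)
  need_snp <- c("snp_id", "chromosome", "genetic_pos", "physical_pos", "ref", "alt")
  if (!all(need_snp %in% names(snp)))
    stop("snp table must have columns: ", paste(need_snp, collapse = ", "))
  need_ind <- c("individual_id", "sex", "population")
  if (!all(need_ind %in% names(ind)))
    stop("ind table must have columns: ", paste(need_ind, collapse = ", "))
  if (nrow(geno) != nrow(snp))
    stop("genotype matrix has ", nrow(geno), " rows but snp table has ",
         nrow(snp), " SNPs")
  if (ncol(geno) != nrow(ind))
    stop("genotype matrix has ", ncol(geno), " columns but ind table has ",
         nrow(ind), " individuals")
  if (anyDuplicated(ind$individual_id))
    stop("duplicate individual_id in ind table")
  if (nrow(snp)) {
    if (any(snp$physical_pos <= 0)) stop("physical_pos must be positive")
    if (any(snp$ref == snp$alt)) stop("ref and alt alleles must differ")
    o <- snp_order(snp)
    if (!identical(o, seq_len(nrow(snp))))
      stop("SNPs must be sorted by (chromosome, physical_pos)")
  }
  bad <- geno[!is.na(geno)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("genotypes must be 0, 1, 2 or NA")
  ph <- rep_len(as.logical(pseudo_haploid), nrow(ind))
  if (any(ph) && nrow(geno)) {
    het <- colSums(geno[, ph, drop = FALSE] == 1L, na.rm = TRUE)
    if (any(het > 0))
      stop("pseudo-haploid individuals cannot carry heterozygous genotypes: ",
           paste(ind$individual_id[ph][het > 0], collapse = ", "))
  }
  structure(
    list(geno = geno, snp = snp, ind = ind, pseudo_haploid = ph),
    class = "genotype_dataset"
  )
}

# canonical chromosome ordering: numeric chromosomes first, then X, Y, others
chrom_rank <- function(chrom) {
  ch <- as.character(chrom)
  num <- suppressWarnings(as.numeric(ch))
  r <- num
  r[is.na(num) & ch == "X"] <- 1e6
  r[is.na(num) & ch == "Y"] <- 1e6 + 1
  r[is.na(r)] <- 1e6 + 2
  r
}

snp_order <- function(snp) order(chrom_rank(snp$chromosome), snp$physical_pos)

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$snp), "SNPs x", nrow(x$ind), "individuals\n")
  pops <- table(x$ind$population)
  cat("populations:",
      paste0(names(pops), " (", as.integer(pops), ")", collapse = ", "), "\n")
  if (any(x$pseudo_haploid))
    cat(sum(x$pseudo_haploid), "pseudo-haploid individuals\n")
  miss <- mean(is.na(x$geno))
  cat(sprintf("missingness: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$geno)

#' Subset a genotype dataset
#'
#' @param x a `genotype_dataset`.
#' @param snps integer/logical index over SNPs (rows).
#' @param individuals integer/logical index or character vector of
#'   individual ids.
#' @return A `genotype_dataset` restricted to the selection.
#' @export
subset_dataset <- function(x, snps = NULL, individuals = NULL) {
  stopifnot(inherits(x, "genotype_dataset"))
  if (is.null(snps)) snps <- seq_len(nrow(x$snp))
  if (is.null(individuals)) {
    individuals <- seq_len(nrow(x$ind))
  } else if (is.character(individuals)) {
    individuals <- match(individuals, x$ind$individual_id)
    if (anyNA(individuals)) stop("unknown individual id(s)")
  }
  genotype_dataset(
    x$geno[snps, individuals, drop = FALSE],
    x$snp[snps, , drop = FALSE],
    x$ind[individuals, , drop = FALSE],
    x$pseudo_haploid[individuals]
  )
}

# column indices of the individuals belonging to one population
pop_columns <- function(x, population) {
  idx <- which(x$ind$population == population)
  if (!length(idx)) stop("population not in dataset: ", population)
  idx
}

# Alt-allele frequency and observed allele count for an arbitrary set of
# individual columns. A diploid genotype contributes 2 alleles with alt
# dose g; a pseudo-haploid genotype (coded 0/2) contributes 1 allele with
# alt dose g/2, so that a single sampled allele is not double-counted.
group_freq <- function(x, cols) {
  g <- x$geno[, cols, drop = FALSE]
  ph <- x$pseudo_haploid[cols]
  w_tot <- ifelse(ph, 1, 2)       # alleles contributed per non-missing call
  w_alt <- ifelse(ph, 0.5, 1)     # alt dose multiplier
  gm <- g
  gm[is.na(gm)] <- 0L
  alt <- as.vector(gm %*% w_alt)
  cnt <- as.vector((!is.na(g)) %*% w_tot)
  freq <- ifelse(cnt > 0, alt / cnt, NA_real_)
  list(freq = freq, count = cnt)
}

#' Per-population allele frequencies
#'
#' Computes the alternative-allele frequency and the number of observed
#' alleles per SNP for each requested population. Diploid genotypes
#' contribute two allele observations; pseudo-haploid genotypes contribute
#' one (their 0/2 coding represents a single sampled allele). Sites with
#' no observed alleles in a population get frequency `NA` and count 0.
#'
#' @param x a `genotype_dataset`.
#' @param populations character vector of population labels.
#' @return A list with matrices `freq` and `count`
#'   (SNPs x populations, columns named by population).
#' @export
allele_frequencies <- function(x, populations) {
  stopifnot(inherits(x, "genotype_dataset"))
  populations <- as.character(populations)
  res <- lapply(populations, function(p) group_freq(x, pop_columns(x, p)))
  freq <- do.call(cbind, lapply(res, `[[`, "freq"))
  count <- do.call(cbind, lapply(res, `[[`, "count"))
  colnames(freq) <- colnames(count) <- populations
  list(freq = freq, count = count)
}
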
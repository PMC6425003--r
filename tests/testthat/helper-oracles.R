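# Fixture builders and independent brute-force oracles used across the
# suite. Oracles are deliberately written as plain per-site loops so they
# share no code with the vectorized implementation they check.

# Quick dataset builder: geno is a matrix (SNPs x individuals); SNP and
# individual metadata are generated; populations recycled over columns.
toy_dataset <- function(geno, populations, pseudo_haploid = FALSE,
                        n_chrom = 1) {
  geno <- as.matrix(geno)
  n_snp <- nrow(geno); n_ind <- ncol(geno)
  chrom <- sort(rep_len(seq_len(n_chrom), n_snp))
  pos <- unlist(lapply(split(seq_len(n_snp), chrom), seq_along),
                use.names = FALSE)
  snp <- data.frame(
    snp_id = paste0("s", seq_len(n_snp)),
    chromosome = as.character(chrom),
    genetic_pos = 0,
    physical_pos = as.integer(pos * 1000L),
    ref = "A", alt = "G", stringsAsFactors = FALSE)
  pops <- rep_len(populations, n_ind)
  ind <- data.frame(
    individual_id = paste0(pops, "_", stats::ave(seq_len(n_ind), pops,
                                                 FUN = seq_along)),
    sex = "U", population = pops, stringsAsFactors = FALSE)
  genotype_dataset(geno, snp, ind, pseudo_haploid)
}

# Random multi-population dataset with independent per-population
# frequencies (no shared drift structure): sizes is a named vector of
# individuals per population.
random_dataset <- function(n_snps, sizes, pseudo_haploid = FALSE,
                           miss_rate = 0, n_chrom = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_ind <- sum(sizes)
  pops <- rep(names(sizes), sizes)
  ph <- rep_len(pseudo_haploid, n_ind)
  geno <- matrix(NA_integer_, n_snps, n_ind)
  for (p in unique(pops)) {
    fp <- stats::runif(n_snps, 0.05, 0.95)
    for (j in which(pops == p)) {
      g <- stats::rbinom(n_snps, 2L, fp)
      if (ph[j]) g <- 2L * stats::rbinom(n_snps, 1L, g / 2)
      geno[, j] <- g
    }
  }
  if (miss_rate > 0)
    geno[stats::runif(length(geno)) < miss_rate] <- NA_integer_
  toy_dataset(geno, pops, pseudo_haploid = ph, n_chrom = n_chrom)
}

# Brute-force per-site allele frequency for one population: explicit
# loop over individuals, counting alleles one by one.
oracle_freq <- function(ds, pop) {
  cols <- which(ds$ind$population == pop)
  n <- nrow(ds$geno)
  freq <- rep(NA_real_, n); cnt <- numeric(n)
  for (i in seq_len(n)) {
    alt <- 0; tot <- 0
    for (j in cols) {
      g <- ds$geno[i, j]
      if (is.na(g)) next
      if (ds$pseudo_haploid[j]) {
        tot <- tot + 1; alt <- alt + g / 2
      } else {
        tot <- tot + 2; alt <- alt + g
      }
    }
    cnt[i] <- tot
    if (tot > 0) freq[i] <- alt / tot
  }
  list(freq = freq, count = cnt)
}

# Brute-force f-statistic point estimates by per-site recomputation.
oracle_fstat <- function(ds, pops, kind) {
  fr <- lapply(pops, function(p) oracle_freq(ds, p))
  n <- nrow(ds$geno)
  num_sum <- 0; den_sum <- 0
  for (i in seq_len(n)) {
    f <- vapply(fr, function(x) x$freq[i], numeric(1))
    cnt <- vapply(fr, function(x) x$count[i], numeric(1))
    if (any(cnt == 0)) next
    num <- switch(kind,
      f2 = (f[1] - f[2])^2,
      f3 = (f[1] - f[2]) * (f[1] - f[3]),
      f4 = (f[1] - f[2]) * (f[3] - f[4]),
      D  = (f[1] - f[2]) * (f[3] - f[4]))
    den <- if (kind == "D")
      (f[1] + f[2] - 2 * f[1] * f[2]) * (f[3] + f[4] - 2 * f[3] * f[4])
    else 1
    num_sum <- num_sum + num
    den_sum <- den_sum + den
  }
  num_sum / den_sum
}

# Textbook unweighted delete-one jackknife SE of a ratio.
oracle_jackknife_equal <- function(num, den) {
  g <- length(num)
  loo <- vapply(seq_len(g), function(j)
    sum(num[-j]) / sum(den[-j]), numeric(1))
  sqrt((g - 1) / g * sum((loo - mean(loo))^2))
}

# Simple drift tree ((A,B),(C,D)) with no gene flow; used for null
# calibration of f4/D.
null_tree_graph <- function(F_tip = 0.02) {
  admixture_graph(edges = data.frame(
    parent = c("root", "root", "ab", "ab", "cd", "cd"),
    child = c("ab", "cd", "A", "B", "C", "D"),
    F = c(0.02, 0.02, F_tip, F_tip, F_tip, F_tip),
    stringsAsFactors = FALSE))
}

# Star phylogeny: four leaves radiating from the root.
star_graph <- function(F_tip = 0.02) {
  admixture_graph(edges = data.frame(
    parent = "root", child = c("A", "B", "C", "D"), F = F_tip,
    stringsAsFactors = FALSE))
}

clean_samples <- function(pops, n = 10) data.frame(
  population = pops, n = n, coverage = Inf, pseudo_haploid = FALSE,
  stringsAsFactors = FALSE)
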
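#' Specify an admixture graph for simulation
#'
#' An admixture graph is a rooted acyclic graph of populations: every
#' non-root node either descends from one parent along a drift edge
#' with Balding-Nichols parameter F in [0, 1), or is an admixture node
#' formed as a two-parent mixture with proportion `prop` on the first
#' parent (multi-way admixture is expressed by chaining two-parent
#' events). Leaves are the sampled populations.
#'
#' @param edges data frame with columns `parent`, `child`, `F` (drift
#'   parameter per edge; 0 copies the parent frequencies).
#' @param admixtures optional data frame with columns `child`,
#'   `parent1`, `parent2`, `prop` (weight on `parent1`).
#' @return Object of class `admixture_graph` with a topological node
#'   order, the root and the leaf set.
#' @export
admixture_graph <- function(edges, admixtures = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("parent", "child", "F") %in% names(edges)))
  if (any(edges$F < 0 | edges$F >= 1)) stop("drift F must be in [0, 1)")
  if (!is.null(admixtures)) {
    admixtures <- as.data.frame(admixtures, stringsAsFactors = FALSE)
    stopifnot(all(c("child", "parent1", "parent2", "prop") %in%
                    names(admixtures)))
    if (any(admixtures$prop < 0 | admixtures$prop > 1))
      stop("admixture proportions must be in [0, 1]")
  } else {
    admixtures <- data.frame(child = character(), parent1 = character(),
                             parent2 = character(), prop = numeric(),
                             stringsAsFactors = FALSE)
  }
  children <- c(edges$child, admixtures$child)
  if (anyDuplicated(children))
    stop("node with more than one defining edge/event: ",
         paste(unique(children[duplicated(children)]), collapse = ", "))
  parents_of <- c(
    stats::setNames(lapply(edges$parent, identity), edges$child),
    stats::setNames(Map(c, admixtures$parent1, admixtures$parent2),
                    admixtures$child)
  )
  nodes <- unique(c(edges$parent, edges$child, admixtures$parent1,
                    admixtures$parent2, admixtures$child))
  roots <- setdiff(nodes, children)
  if (length(roots) != 1)
    stop("graph must have exactly one root; found: ",
         paste(roots, collapse = ", "))
  # Kahn topological sort; failure to place every node means a cycle
  placed <- roots
  remaining <- setdiff(nodes, placed)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(nd)
      all(parents_of[[nd]] %in% placed), logical(1))]
    if (!length(ready)) stop("cyclic graph")
    placed <- c(placed, ready)
    remaining <- setdiff(remaining, ready)
  }
  leaves <- setdiff(nodes, c(edges$parent, admixtures$parent1,
                             admixtures$parent2))
  structure(list(edges = edges, admixtures = admixtures,
                 nodes = placed, root = roots, leaves = leaves),
            class = "admixture_graph")
}

#' @export
print.admixture_graph <- function(x, ...) {
  cat("admixture_graph:", length(x$nodes), "nodes,", nrow(x$edges),
      "drift edges,", nrow(x$admixtures), "admixture events\n")
  cat("root:", x$root, "| leaves:", paste(x$leaves, collapse = ", "), "\n")
  invisible(x)
}

#' Simulate allele frequencies on an admixture graph
#'
#' Root frequencies are drawn uniformly on `root_range` (truncated away
#' from fixation so that small-F edges stay informative). Along each
#' drift edge with F > 0 the child frequency is Balding-Nichols
#' Beta-distributed with mean equal to the parent frequency and
#' variance p(1 - p) F; F = 0 edges copy. An admixture node's
#' frequency is the per-SNP linear mix of its two parents.
#'
#' @param graph an [admixture_graph()].
#' @param n_snps number of independent SNPs.
#' @param root_range support of the root frequency distribution
#'   (default c(0.05, 0.95)).
#' @param seed optional integer seed.
#' @return Numeric matrix (n_snps x nodes) of allele frequencies, with
#'   a `leaves` attribute naming the sampled populations.
#' @export
simulate_frequencies <- function(graph, n_snps,
                                 root_range = c(0.05, 0.95), seed = NULL) {
  stopifnot(inherits(graph, "admixture_graph"), n_snps >= 1)
  with_seed(seed, {
    freq <- matrix(NA_real_, n_snps, length(graph$nodes),
                   dimnames = list(NULL, graph$nodes))
    freq[, graph$root] <- stats::runif(n_snps, root_range[1], root_range[2])
    ed <- graph$edges
    ad <- graph$admixtures
    for (nd in graph$nodes[-1]) {
      ei <- match(nd, ed$child)
      if (!is.na(ei)) {
        p <- freq[, ed$parent[ei]]
        F <- ed$F[ei]
        if (F == 0) {
          freq[, nd] <- p
        } else {
          q <- p
          inner <- p > 0 & p < 1
          a <- p[inner] * (1 - F) / F
          b <- (1 - p[inner]) * (1 - F) / F
          q[inner] <- stats::rbeta(sum(inner), a, b)
          freq[, nd] <- q
        }
      } else {
        ai <- match(nd, ad$child)
        freq[, nd] <- ad$prop[ai] * freq[, ad$parent1[ai]] +
          (1 - ad$prop[ai]) * freq[, ad$parent2[ai]]
      }
    }
    freq
  })
}

#' Sample genotypes from leaf allele frequencies
#'
#' Draws diploid genotypes Binomial(2, p) per individual and SNP. For
#' pseudo-haploid individuals one allele of the diploid pair is then
#' drawn at random and coded 0/2, emulating the random-draw genotyper
#' used for low-coverage ancient samples. Per-site missingness follows
#' a Poisson zero-read model: P(missing) = exp(-coverage).
#'
#' @param freq matrix of allele frequencies (n_snps x populations,
#'   columns named), e.g. from [simulate_frequencies()].
#' @param samples data frame with columns `population` (a column of
#'   `freq`), `n` (individuals), `coverage` (mean fold coverage;
#'   `Inf` for no missingness) and `pseudo_haploid` (logical).
#' @param n_chrom,morgans_per_chrom layout of the synthetic genetic
#'   map: SNPs are spread evenly over `n_chrom` chromosomes of
#'   `morgans_per_chrom` genetic length (1 cM / Mb physical spacing).
#' @param seed optional integer seed.
#' @return A [genotype_dataset()] whose individuals are named
#'   `<population>_<i>`.
#' @export
sample_genotypes <- function(freq, samples, n_chrom = 22,
                             morgans_per_chrom = 0.5, seed = NULL) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  stopifnot(all(c("population", "n", "coverage", "pseudo_haploid") %in%
                  names(samples)))
  miss <- setdiff(samples$population, colnames(freq))
  if (length(miss)) stop("populations without frequencies: ",
                         paste(miss, collapse = ", "))
  n_snps <- nrow(freq)
  snp <- synthetic_snp_table(n_snps, n_chrom, morgans_per_chrom)
  with_seed(seed, {
    geno_cols <- vector("list", sum(samples$n))
    ind_rows <- vector("list", nrow(samples))
    ph <- logical(0)
    col <- 0L
    for (si in seq_len(nrow(samples))) {
      p <- freq[, samples$population[si]]
      n_i <- samples$n[si]
      cov <- samples$coverage[si]
      pseudo <- isTRUE(samples$pseudo_haploid[si])
      p_miss <- if (is.finite(cov)) exp(-cov) else 0
      for (ii in seq_len(n_i)) {
        g <- stats::rbinom(n_snps, 2L, p)
        if (pseudo) {
          # draw one allele of the diploid pair: alt with prob g/2
          g <- 2L * stats::rbinom(n_snps, 1L, g / 2)
        }
        if (p_miss > 0)
          g[stats::runif(n_snps) < p_miss] <- NA_integer_
        col <- col + 1L
        geno_cols[[col]] <- g
      }
      ind_rows[[si]] <- data.frame(
        individual_id = sprintf("%s_%d", samples$population[si],
                                seq_len(n_i)),
        sex = "U", population = samples$population[si],
        stringsAsFactors = FALSE)
      ph <- c(ph, rep(pseudo, n_i))
    }
    genotype_dataset(do.call(cbind, geno_cols), snp,
                     do.call(rbind, ind_rows), ph)
  })
}

# Evenly spaced synthetic SNP map: n_chrom chromosomes, physical spacing
# 100 kb, genetic positions proportional (1 cM per Mb).
synthetic_snp_table <- function(n_snps, n_chrom = 22,
                                morgans_per_chrom = 0.5) {
  chrom <- rep(seq_len(n_chrom), length.out = n_snps)
  chrom <- sort(chrom)
  idx <- unlist(lapply(table(chrom), seq_len), use.names = FALSE)
  per <- table(chrom)[chrom]
  gpos <- (idx - 1) / pmax(as.integer(per) - 1, 1) * morgans_per_chrom
  data.frame(
    snp_id = sprintf("snp_%d", seq_len(n_snps)),
    chromosome = as.character(chrom),
    genetic_pos = gpos,
    physical_pos = as.integer(round(gpos * 1e8)) + 1L,
    ref = "A", alt = "G",
    stringsAsFactors = FALSE
  )
}

#' Simulate a complete dataset from a graph in one call
#'
#' @inheritParams simulate_frequencies
#' @inheritParams sample_genotypes
#' @return A [genotype_dataset()].
#' @export
simulate_dataset <- function(graph, n_snps, samples,
                             root_range = c(0.05, 0.95), n_chrom = 22,
                             morgans_per_chrom = 0.5, seed = NULL) {
  with_seed(seed, {
    freq <- simulate_frequencies(graph, n_snps, root_range)
    sample_genotypes(freq, samples, n_chrom, morgans_per_chrom)
  })
}
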
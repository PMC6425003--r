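#' Read an EIGENSTRAT geno/snp/ind triplet
#'
#' Reads the plain-text EIGENSTRAT format used by the ADMIXTOOLS/smartpca
#' ecosystem: a geno file with one line per SNP and one digit per
#' individual over \{0, 1, 2, 9\}, a 6-column snp file (id, chromosome,
#' genetic position in morgans, physical position, reference allele,
#' alternative allele) and a 3-column ind file (id, sex, population).
#'
#' The EIGENSTRAT digit counts copies of the *reference* allele (column 5
#' of the snp file); 9 is missing. Internally the package stores
#' alternative-allele counts, so a digit `d` is decoded as genotype
#' `2 - d` and encoded back symmetrically on writing.
#'
#' @param geno_path,snp_path,ind_path file paths of the three components.
#' @param pseudo_haploid logical scalar or vector flagging pseudo-haploid
#'   individuals (the format itself does not record this).
#' @return A [genotype_dataset()].
#' @export
read_eigenstrat <- function(geno_path, snp_path, ind_path,
                            pseudo_haploid = FALSE) {
  for (p in c(geno_path, snp_path, ind_path))
    if (!file.exists(p)) stop("file not found: ", p)
  snp_lines <- readLines(snp_path)
  snp_lines <- snp_lines[nzchar(trimws(snp_lines))]
  snp_fields <- strsplit(trimws(snp_lines), "[ \t]+")
  nf <- lengths(snp_fields)
  if (length(nf) && any(nf != 6))
    stop("snp file format error at line ", which(nf != 6)[1],
         ": expected 6 columns, found ", nf[nf != 6][1])
  sm <- matrix(as.character(unlist(snp_fields)), ncol = 6, byrow = TRUE)
  snp <- data.frame(
    snp_id = if (length(snp_lines)) sm[, 1] else character(),
    chromosome = if (length(snp_lines)) sm[, 2] else character(),
    genetic_pos = if (length(snp_lines)) as.numeric(sm[, 3]) else numeric(),
    physical_pos = if (length(snp_lines)) as.integer(sm[, 4]) else integer(),
    ref = if (length(snp_lines)) sm[, 5] else character(),
    alt = if (length(snp_lines)) sm[, 6] else character(),
    stringsAsFactors = FALSE
  )

  ind_lines <- readLines(ind_path)
  ind_lines <- ind_lines[nzchar(trimws(ind_lines))]
  ind_fields <- strsplit(trimws(ind_lines), "[ \t]+")
  nfi <- lengths(ind_fields)
  if (length(nfi) && any(nfi != 3))
    stop("ind file format error at line ", which(nfi != 3)[1],
         ": expected 3 columns")
  im <- matrix(as.character(unlist(ind_fields)), ncol = 3, byrow = TRUE)
  ind <- data.frame(
    individual_id = if (length(ind_lines)) im[, 1] else character(),
    sex = if (length(ind_lines)) im[, 2] else character(),
    population = if (length(ind_lines)) im[, 3] else character(),
    stringsAsFactors = FALSE
  )

  geno_lines <- readLines(geno_path)
  geno_lines <- geno_lines[nzchar(geno_lines)]
  if (length(geno_lines) != nrow(snp))
    stop("geno file has ", length(geno_lines), " lines but snp file has ",
         nrow(snp), " SNPs")
  n_ind <- nrow(ind)
  wrong <- which(nchar(geno_lines) != n_ind)
  if (length(wrong))
    stop("geno file line ", wrong[1], " has ", nchar(geno_lines[wrong[1]]),
         " characters but ", n_ind, " individuals are declared")
  if (length(geno_lines)) {
    chars <- matrix(unlist(strsplit(geno_lines, "", fixed = TRUE)),
                    nrow = length(geno_lines), byrow = TRUE)
    code <- match(chars, c("0", "1", "2", "9"))
    if (anyNA(code)) {
      bad <- which(is.na(matrix(code, nrow = nrow(chars))), arr.ind = TRUE)[1, ]
      stop("illegal genotype character '", chars[bad[1], bad[2]],
           "' at geno line ", bad[1])
    }
    # EIGENSTRAT digit = reference-allele count; internal = alt-allele count
    geno <- matrix(c(2L, 1L, 0L, NA_integer_)[code], nrow = nrow(chars))
  } else {
    geno <- matrix(integer(), nrow = 0, ncol = n_ind)
  }
  genotype_dataset(geno, snp, ind, pseudo_haploid)
}

#' Write an EIGENSTRAT geno/snp/ind triplet
#'
#' Inverse of [read_eigenstrat()]: internal alt-allele counts are encoded
#' back to EIGENSTRAT reference-allele-count digits (`d = 2 - g`, missing
#' as 9) so that a read/write cycle is the identity.
#'
#' @param x a [genotype_dataset()].
#' @param geno_path,snp_path,ind_path output file paths.
#' @return Invisibly, the three paths.
#' @export
write_eigenstrat <- function(x, geno_path, snp_path, ind_path) {
  stopifnot(inherits(x, "genotype_dataset"))
  g <- x$geno
  d <- 2L - g
  d[is.na(d)] <- 9L
  lines <- if (nrow(d)) {
    apply(d, 1, paste, collapse = "")
  } else character()
  writeLines(lines, geno_path)
  snp <- x$snp
  writeLines(sprintf("%s\t%s\t%.6f\t%d\t%s\t%s",
                     snp$snp_id, snp$chromosome, snp$genetic_pos,
                     snp$physical_pos, snp$ref, snp$alt),
             snp_path)
  ind <- x$ind
  writeLines(sprintf("%s\t%s\t%s",
                     ind$individual_id, ind$sex, ind$population),
             ind_path)
  invisible(c(geno = geno_path, snp = snp_path, ind = ind_path))
}

#' Pseudo-haploid genotype calling from base counts
#'
#' Implements the random-draw genotyper used for low-coverage ancient
#' samples: at each targeted SNP one base is drawn uniformly among the
#' high-quality bases observed in the pileup (quality filtering is
#' expected to have happened upstream), and the genotype is coded as a
#' homozygous call of the drawn allele: 0 if it matches the reference
#' allele, 2 if it matches the alternative, missing if no bases were
#' observed or the drawn base matches neither allele.
#'
#' @param counts matrix of non-negative base counts with columns named
#'   "A", "C", "G", "T" and one row per SNP.
#' @param ref,alt character vectors of reference/alternative alleles.
#' @return Integer vector of genotypes in \{0, 2, NA\}.
#' @export
pseudohaploid_call <- function(counts, ref, alt) {
  counts <- as.matrix(counts)
  bases <- c("A", "C", "G", "T")
  if (!all(bases %in% colnames(counts)))
    stop("counts must have columns A, C, G, T")
  counts <- counts[, bases, drop = FALSE]
  if (any(counts < 0)) stop("negative base counts")
  n <- nrow(counts)
  out <- rep(NA_integer_, n)
  tot <- rowSums(counts)
  has <- which(tot > 0)
  for (i in has) {
    b <- sample(bases, 1, prob = counts[i, ])
    if (b == ref[i]) out[i] <- 0L
    else if (b == alt[i]) out[i] <- 2L
    # a base matching neither allele stays missing
  }
  out
}

#' Merge two genotype datasets on shared SNP positions
#'
#' Intersects the two SNP lists on (chromosome, physical position),
#' reconciles allele coding (when the ref/alt pair of `b` is the swap of
#' `a`'s, `b`'s genotypes are flipped `g -> 2 - g`), drops SNPs whose
#' allele pairs are incompatible, and concatenates individuals. SNP
#' metadata (ids, genetic positions) is taken from `a`.
#'
#' @param a,b `genotype_dataset` objects.
#' @param drop_strand_ambiguous drop A/T and C/G SNPs (whose strand cannot
#'   be resolved from allele labels) instead of keeping them.
#' @return The merged `genotype_dataset`, with a `merge_log` attribute: a
#'   data frame of dropped SNPs and the reason for dropping each.
#' @export
merge_datasets <- function(a, b, drop_strand_ambiguous = FALSE) {
  stopifnot(inherits(a, "genotype_dataset"), inherits(b, "genotype_dataset"))
  if (any(b$ind$individual_id %in% a$ind$individual_id))
    stop("duplicate individual ids across datasets: ",
         paste(intersect(a$ind$individual_id, b$ind$individual_id),
               collapse = ", "))
  key_a <- paste(a$snp$chromosome, a$snp$physical_pos)
  key_b <- paste(b$snp$chromosome, b$snp$physical_pos)
  ia <- which(key_a %in% key_b)
  ib <- match(key_a[ia], key_b)

  ref_a <- a$snp$ref[ia]; alt_a <- a$snp$alt[ia]
  ref_b <- b$snp$ref[ib]; alt_b <- b$snp$alt[ib]
  same <- ref_a == ref_b & alt_a == alt_b
  swap <- ref_a == alt_b & alt_a == ref_b
  ambig <- (paste0(ref_a, alt_a) %in% c("AT", "TA", "CG", "GC"))

  keep <- same | swap
  reason <- rep(NA_character_, length(ia))
  reason[!keep] <- "incompatible_alleles"
  if (drop_strand_ambiguous) {
    reason[keep & ambig] <- "strand_ambiguous"
    keep <- keep & !ambig
  }
  log <- data.frame(
    snp_id = a$snp$snp_id[ia][!keep],
    chromosome = a$snp$chromosome[ia][!keep],
    physical_pos = a$snp$physical_pos[ia][!keep],
    reason = reason[!keep],
    stringsAsFactors = FALSE
  )
  ia_k <- ia[keep]; ib_k <- ib[keep]; swap_k <- swap[keep]
  gb <- b$geno[ib_k, , drop = FALSE]
  if (any(swap_k))
    gb[swap_k, ] <- 2L - gb[swap_k, , drop = FALSE]
  geno <- cbind(a$geno[ia_k, , drop = FALSE], gb)
  out <- genotype_dataset(
    geno,
    a$snp[ia_k, , drop = FALSE],
    rbind(a$ind, b$ind),
    c(a$pseudo_haploid, b$pseudo_haploid)
  )
  attr(out, "merge_log") <- log
  out
}

#' Write a merge log as TSV
#'
#' @param x a merged dataset from [merge_datasets()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_merge_log <- function(x, path) {
  log <- attr(x, "merge_log")
  if (is.null(log)) stop("no merge_log attribute on this dataset")
  utils::write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
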
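# Genotype container, EIGENSTRAT I/O, pseudo-haploid calling, merging,
# allele frequencies.

test_that("EIGENSTRAT read/write round-trips, including byte identity", {
  ds <- toy_dataset(matrix(c(0L, 1L, 2L, NA, NA, 0L), 2, 3),
                    c("P1", "P1", "P2"))
  paths <- file.path(tempdir(), c("a.geno", "a.snp", "a.ind"))
  write_eigenstrat(ds, paths[1], paths[2], paths[3])
  back <- read_eigenstrat(paths[1], paths[2], paths[3])
  expect_identical(back$geno, ds$geno)
  expect_identical(back$snp, ds$snp)
  expect_identical(back$ind, ds$ind)
  # writing the re-read dataset reproduces the files byte for byte
  paths2 <- file.path(tempdir(), c("b.geno", "b.snp", "b.ind"))
  write_eigenstrat(back, paths2[1], paths2[2], paths2[3])
  for (i in 1:3)
    expect_identical(readLines(paths2[i]), readLines(paths[i]))
  # missing value is encoded as 9 in the geno file
  expect_true(grepl("9", paste(readLines(paths[1]), collapse = "")))
})

test_that("empty dataset round-trips through empty-bodied files", {
  ds <- genotype_dataset(
    matrix(integer(), 0, 0),
    data.frame(snp_id = character(), chromosome = character(),
               genetic_pos = numeric(), physical_pos = integer(),
               ref = character(), alt = character()),
    data.frame(individual_id = character(), sex = character(),
               population = character()))
  paths <- file.path(tempdir(), c("e.geno", "e.snp", "e.ind"))
  write_eigenstrat(ds, paths[1], paths[2], paths[3])
  expect_identical(readLines(paths[1]), character(0))
  back <- read_eigenstrat(paths[1], paths[2], paths[3])
  expect_equal(dim(back$geno), c(0L, 0L))
})

test_that("round-trip identity holds on random datasets (property)", {
  for (seed in 1:10) {
    ds <- random_dataset(200, c(X = 3, Y = 2), seed = seed,
                         pseudo_haploid = c(TRUE, FALSE, FALSE, TRUE, FALSE),
                         miss_rate = 0.2, n_chrom = 3)
    paths <- file.path(tempdir(), c("r.geno", "r.snp", "r.ind"))
    write_eigenstrat(ds, paths[1], paths[2], paths[3])
    back <- read_eigenstrat(paths[1], paths[2], paths[3],
                            pseudo_haploid = ds$pseudo_haploid)
    expect_identical(back$geno, ds$geno)
    expect_equal(back$snp, ds$snp)
    expect_identical(back$ind, ds$ind)
  }
})

test_that("malformed EIGENSTRAT input is rejected with a format error", {
  d <- tempdir()
  writeLines(c("s1\t1\t0\t100\tA\tG", "s2\t1\t0\t200\tA\tG"),
             file.path(d, "m.snp"))
  writeLines(c("i1\tU\tP", "i2\tU\tP", "i3\tU\tP"), file.path(d, "m.ind"))
  # wrong line width: 2 characters for 3 declared individuals
  writeLines(c("09", "012"), file.path(d, "m.geno"))
  expect_error(read_eigenstrat(file.path(d, "m.geno"), file.path(d, "m.snp"),
                               file.path(d, "m.ind")),
               "line 1")
  # illegal character
  writeLines(c("093", "012"), file.path(d, "m.geno"))
  expect_error(read_eigenstrat(file.path(d, "m.geno"), file.path(d, "m.snp"),
                               file.path(d, "m.ind")),
               "illegal")
  # SNP count mismatch
  writeLines(c("012"), file.path(d, "m.geno"))
  expect_error(read_eigenstrat(file.path(d, "m.geno"), file.path(d, "m.snp"),
                               file.path(d, "m.ind")),
               "1 lines")
})

test_that("missing code 9 decodes to NA at the right cell only", {
  d <- tempdir()
  writeLines(c("s1\t1\t0\t100\tA\tG", "s2\t1\t0\t200\tA\tG"),
             file.path(d, "n.snp"))
  writeLines(c("i1\tU\tP", "i2\tU\tP", "i3\tU\tP"), file.path(d, "n.ind"))
  writeLines(c("092", "210"), file.path(d, "n.geno"))
  ds <- read_eigenstrat(file.path(d, "n.geno"), file.path(d, "n.snp"),
                        file.path(d, "n.ind"))
  expect_true(is.na(ds$geno[1, 2]))
  expect_equal(sum(is.na(ds$geno)), 1L)
  # digit is a reference-allele count: 0 -> alt count 2
  expect_identical(ds$geno[1, ], c(2L, NA, 0L))
})

test_that("pseudo-haploid calls never emit heterozygotes and follow the uniform-draw rule", {
  # only-reference pileup is called reference with probability 1
  counts <- matrix(0, 3, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  counts[1, "A"] <- 5           # pure ref
  counts[3, "C"] <- 2           # base matching neither allele
  set.seed(1)
  g <- pseudohaploid_call(counts, ref = rep("A", 3), alt = rep("G", 3))
  expect_identical(g[1], 0L)
  expect_true(is.na(g[2]))      # empty pileup
  expect_true(is.na(g[3]))      # third-allele base
  # Monte-Carlo: ref 3, alt 1 -> P(call = 0) = 0.75 within 3 binomial SE
  n <- 10000
  cm <- matrix(0, n, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  cm[, "A"] <- 3; cm[, "G"] <- 1
  set.seed(42)
  calls <- pseudohaploid_call(cm, ref = rep("A", n), alt = rep("G", n))
  expect_false(any(calls == 1L, na.rm = TRUE))
  p0 <- mean(calls == 0L)
  expect_lt(abs(p0 - 0.75), 3 * sqrt(0.75 * 0.25 / n))
})

test_that("merge intersects positions, flips swapped alleles, drops incompatibles", {
  g <- matrix(c(0L, 1L, 2L, 2L, 1L, 0L), 3, 2)
  snp_a <- data.frame(snp_id = c("s1", "s2", "s3"), chromosome = "1",
                      genetic_pos = 0, physical_pos = c(100L, 200L, 300L),
                      ref = "A", alt = "G", stringsAsFactors = FALSE)
  a <- genotype_dataset(g, snp_a, data.frame(
    individual_id = c("a1", "a2"), sex = "U", population = "PA"))
  # b: same positions; s2 has ref/alt swapped; s3 has incompatible alleles
  snp_b <- snp_a
  snp_b$ref <- c("A", "G", "A"); snp_b$alt <- c("G", "A", "T")
  b <- genotype_dataset(matrix(c(2L, 0L, 1L), 3, 1), snp_b, data.frame(
    individual_id = "b1", sex = "U", population = "PB"))
  m <- merge_datasets(a, b)
  expect_equal(nrow(m$snp), 2L)   # s3 dropped
  log <- attr(m, "merge_log")
  expect_equal(log$snp_id, "s3")
  expect_equal(log$reason, "incompatible_alleles")
  # s2 was coded on the swapped allele pair in b: genotype 0 -> 2
  expect_identical(m$geno[which(m$snp$snp_id == "s2"),
                          which(m$ind$individual_id == "b1")], 2L)
  # identical SNP lists, consistent alleles: counts add up
  c1 <- genotype_dataset(a$geno[, 1, drop = FALSE], a$snp, data.frame(
    individual_id = "c1", sex = "U", population = "PC"))
  m2 <- merge_datasets(a, c1)
  expect_equal(nrow(m2$snp), 3L)
  expect_equal(nrow(m2$ind), 3L)
  # duplicate ids across inputs
  expect_error(merge_datasets(a, a), "duplicate individual ids")
})

test_that("merge is symmetric in SNP content and genotype values", {
  a <- random_dataset(100, c(PA = 3), seed = 11, n_chrom = 2)
  b <- random_dataset(100, c(PB = 2), seed = 12, n_chrom = 2)
  # give b a partially shifted position set so intersection is proper
  snp_b <- b$snp
  snp_b$physical_pos <- snp_b$physical_pos +
    c(0L, 500000L)[1 + (seq_len(100) %% 2)]
  ind_b <- b$ind
  ind_b$individual_id <- paste0("b_", ind_b$individual_id)
  ord <- admixfit:::snp_order(snp_b)
  b <- genotype_dataset(b$geno[ord, , drop = FALSE], snp_b[ord, ], ind_b,
                        b$pseudo_haploid)
  ab <- merge_datasets(a, b)
  ba <- merge_datasets(b, a)
  key <- function(d) paste(d$snp$chromosome, d$snp$physical_pos)
  expect_setequal(key(ab), key(ba))
  ids <- ab$ind$individual_id
  ka <- key(ab); kb <- key(ba)
  for (id in ids) {
    ga <- ab$geno[order(ka), id == ab$ind$individual_id]
    gb <- ba$geno[order(kb), id == ba$ind$individual_id]
    expect_identical(ga, gb)
  }
})

test_that("strand-ambiguous SNPs are kept by default and droppable by flag", {
  snp <- data.frame(snp_id = c("s1", "s2"), chromosome = "1",
                    genetic_pos = 0, physical_pos = c(100L, 200L),
                    ref = c("A", "C"), alt = c("T", "G"),
                    stringsAsFactors = FALSE)
  a <- genotype_dataset(matrix(0L, 2, 1), snp, data.frame(
    individual_id = "a1", sex = "U", population = "PA"))
  b <- genotype_dataset(matrix(2L, 2, 1), snp, data.frame(
    individual_id = "b1", sex = "U", population = "PB"))
  expect_equal(nrow(merge_datasets(a, b)$snp), 2L)
  m <- merge_datasets(a, b, drop_strand_ambiguous = TRUE)
  expect_equal(nrow(m$snp), 0L)
  expect_setequal(attr(m, "merge_log")$reason, "strand_ambiguous")
})

test_that("allele frequencies match the brute-force per-site tally", {
  ds <- random_dataset(300, c(P1 = 4, P2 = 2), seed = 5, miss_rate = 0.25,
                       pseudo_haploid = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
  af <- allele_frequencies(ds, c("P1", "P2"))
  for (p in c("P1", "P2")) {
    o <- oracle_freq(ds, p)
    expect_equal(unname(af$freq[, p]), o$freq, tolerance = 1e-12)
    expect_equal(unname(af$count[, p]), o$count, tolerance = 1e-12)
  }
  expect_true(all(af$freq >= 0 & af$freq <= 1, na.rm = TRUE))
  # two diploids both hom-alt -> frequency 1; {0, NA} -> 0 with reduced count
  ds2 <- toy_dataset(matrix(c(2L, 0L, 2L, NA), 2, 2), "P")
  af2 <- allele_frequencies(ds2, "P")
  expect_equal(unname(af2$freq[1, 1]), 1)
  expect_equal(unname(af2$freq[2, 1]), 0)
  expect_equal(unname(af2$count[2, 1]), 2)  # one diploid observed
  expect_error(allele_frequencies(ds2, "nope"), "not in dataset")
})

test_that("pseudo-haploid flags forbid heterozygous genotypes", {
  expect_error(toy_dataset(matrix(1L, 2, 1), "P", pseudo_haploid = TRUE),
               "pseudo-haploid")
})
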
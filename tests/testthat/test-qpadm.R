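# f4 matrices, qpWave rank tests, qpAdm fits, basal alpha and the
# composed prediction.

two_way_graph <- function(lambda) admixture_graph(
  edges = data.frame(
    parent = c("root", "root", "eur", "e1", "east", "east", "e1", "sb",
               "sb", "eur", "west", "west", "sa", "sa", "T_adm"),
    child = c("O1", "eur", "e1", "east", "O2", "O3", "sb", "S2", "P2",
              "west", "O4", "sa", "S1", "P1", "T"),
    F = c(0.15, 0.03, 0.03, 0.03, 0.05, 0.06, 0.05, 0.03, 0.01, 0.03,
          0.06, 0.05, 0.02, 0.01, 0.01),
    stringsAsFactors = FALSE),
  admixtures = data.frame(child = "T_adm", parent1 = "P1", parent2 = "P2",
                          prop = lambda, stringsAsFactors = FALSE))

two_way_samples <- clean_samples(c("T", "S1", "S2", "O1", "O2", "O3", "O4"))

test_that("f4 matrix cells and covariance agree with the fstats module", {
  ds <- random_dataset(5000, c(A = 3, B = 3, C = 3, D = 3), seed = 61)
  f4m <- build_f4_matrix(ds, c("A", "B"), c("C", "D"))
  fs <- f4_statistic(ds, "A", "B", "C", "D")
  expect_equal(unname(f4m$est), fs$estimate, tolerance = 1e-12)
  expect_equal(unname(f4m$cov[1, 1]), fs$se^2, tolerance = 1e-10)
  # duplicated genotypes in the left set zero out the corresponding cells
  ds2 <- toy_dataset(cbind(ds$geno[, 1:3], ds$geno[, 1:3], ds$geno[, 7:12]),
                     c(rep("A", 3), rep("A2", 3), rep("C", 3), rep("D", 3)),
                     n_chrom = 4)
  f4m2 <- build_f4_matrix(ds2, c("A", "A2"), c("C", "D"))
  expect_equal(unname(f4m2$est), 0)
  expect_error(build_f4_matrix(ds, c("A", "B"), c("B", "C")), "overlap")
})

test_that("covariance diagonal tracks per-statistic jackknife SEs within 10%", {
  ds <- random_dataset(8000, c(A = 3, B = 3, C = 3, D = 3, E = 3),
                       seed = 62, miss_rate = 0.15, pseudo_haploid = TRUE)
  f4m <- build_f4_matrix(ds, c("A", "B"), c("C", "D", "E"))
  se_cells <- sqrt(diag(f4m$cov))
  se_direct <- c(f4_statistic(ds, "A", "B", "C", "D")$se,
                 f4_statistic(ds, "A", "B", "C", "E")$se)
  expect_true(all(abs(se_cells / se_direct - 1) < 0.1))
})

test_that("rank test recovers exact low-rank structure and the 1x1 closed form", {
  # constructed rank-1 matrix with a well-conditioned covariance
  set.seed(63)
  L <- 3; R <- 4
  X <- outer(rnorm(L), rnorm(R))
  f4m <- structure(list(left = letters[1:(L + 1)], right = LETTERS[1:(R + 1)],
                        est = as.vector(X), cov = diag(1e-4, L * R),
                        values = X), class = "f4_matrix")
  rt <- qpwave_rank_test(f4m, 1)
  expect_lt(rt$chisq, 1e-10)
  expect_gt(rt$p_value, 0.999)
  expect_equal(rt$dof, (L - 1) * (R - 1))
  # 1x1 rank-0 statistic is the squared f4 Z-score
  ds <- random_dataset(3000, c(A = 3, B = 3, C = 3, D = 3), seed = 64)
  f1 <- build_f4_matrix(ds, c("A", "B"), c("C", "D"))
  fs <- f4_statistic(ds, "A", "B", "C", "D")
  expect_equal(qpwave_rank_test(f1, 0)$chisq, (fs$estimate / fs$se)^2,
               tolerance = 1e-10)
  expect_error(qpwave_rank_test(f1, 1), "rank must satisfy")
})

test_that("rank-test chi-square is invariant to reordering right populations", {
  ds <- simulate_dataset(two_way_graph(0.6), 20000, two_way_samples,
                         seed = 65)
  a <- build_f4_matrix(ds, c("T", "S1", "S2"), c("O1", "O2", "O3", "O4"))
  b <- build_f4_matrix(ds, c("T", "S1", "S2"), c("O1", "O4", "O2", "O3"))
  expect_equal(qpwave_rank_test(a, 1)$chisq, qpwave_rank_test(b, 1)$chisq,
               tolerance = 1e-6)
})

test_that("qpAdm recovers a target that copies one source, with feasible weights", {
  ds <- random_dataset(4000, c(S1 = 5, S2 = 5, O1 = 5, O2 = 5, O3 = 5),
                       seed = 66)
  # target = exact copy of the S1 individuals
  ds2 <- toy_dataset(cbind(ds$geno, ds$geno[, 1:5]),
                     c(ds$ind$population, rep("T", 5)), n_chrom = 4)
  # exact duplication makes the jackknife covariance singular; the
  # documented ridge path applies, with a warning
  expect_warning(
    fit <- qpadm(ds2, "T", c("S1", "S2"), c("O1", "O2", "O3")),
    "ridge")
  expect_equal(unname(fit$weights), c(1, 0), tolerance = 1e-8)
  expect_true(fit$feasible)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-10)
})

test_that("weights sum to one and permute with the source order", {
  ds <- simulate_dataset(two_way_graph(0.7), 20000, two_way_samples,
                         seed = 67)
  f12 <- qpadm(ds, "T", c("S1", "S2"), c("O1", "O2", "O3", "O4"))
  f21 <- qpadm(ds, "T", c("S2", "S1"), c("O1", "O2", "O3", "O4"))
  expect_equal(sum(f12$weights), 1, tolerance = 1e-10)
  expect_equal(unname(f12$weights), unname(rev(f21$weights)),
               tolerance = 1e-6)
  expect_equal(f12$dof, 4 - 2)
})

test_that("a single-source qpAdm degenerates to the rank-0 cladality test", {
  ds <- simulate_dataset(two_way_graph(1.0), 10000, two_way_samples,
                         seed = 68)
  fit <- qpadm(ds, "T", "S1", c("O1", "O2", "O3", "O4"))
  expect_equal(unname(fit$weights), 1)
  f4m <- build_f4_matrix(ds, c("T", "S1"), c("O1", "O2", "O3", "O4"))
  rt <- qpwave_rank_test(f4m, 0)
  expect_equal(fit$chisq, rt$chisq, tolerance = 1e-10)
  expect_equal(fit$dof, rt$dof)
})

test_that("two-way parameter recovery is unbiased and well covered across a grid", {
  grid <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  bias <- numeric(length(grid))
  cover <- 0; total <- 0
  for (k in seq_along(grid)) {
    g <- two_way_graph(grid[k])
    err <- se <- numeric(10)
    for (i in 1:10) {
      ds <- simulate_dataset(g, 3e4, two_way_samples,
                             seed = 7000 + 1000 * k + i)
      f <- qpadm(ds, "T", c("S1", "S2"), c("O1", "O2", "O3", "O4"))
      err[i] <- unname(f$weights[1]) - grid[k]
      se[i] <- unname(f$se[1])
    }
    bias[k] <- mean(err)
    cover <- cover + sum(abs(err) < 2 * se)
    total <- total + length(err)
  }
  expect_lt(mean(abs(bias)), 0.03)
  expect_gte(cover / total, 0.86)  # ~95% nominal, 3-sigma binomial slack
})

test_that("a target from an independent branch is rejected or infeasible", {
  # T drifts independently from node `west`: not a mixture of S1 and S2
  bad_graph <- admixture_graph(edges = data.frame(
    parent = c("root", "root", "eur", "e1", "east", "east", "e1", "sb",
               "eur", "west", "west", "sa", "west"),
    child = c("O1", "eur", "e1", "east", "O2", "O3", "sb", "S2",
              "west", "O4", "sa", "S1", "T"),
    F = c(0.15, 0.03, 0.03, 0.03, 0.05, 0.06, 0.05, 0.03, 0.03,
          0.06, 0.05, 0.02, 0.08),
    stringsAsFactors = FALSE))
  reject <- 0
  for (i in 1:20) {
    ds <- simulate_dataset(bad_graph, 2e4, two_way_samples,
                           seed = 7100 + i)
    f <- qpadm(ds, "T", c("S1", "S2"), c("O1", "O2", "O3", "O4"))
    if (f$p_value < 0.05 || !f$feasible) reject <- reject + 1
  }
  expect_gt(reject, 10)  # majority of replicates
})

test_that("nested model comparison flags a truly needed extra source", {
  # full model true with a 10% second source
  hits <- 0
  for (i in 1:15) {
    ds <- simulate_dataset(two_way_graph(0.9), 3e4, two_way_samples,
                           seed = 7200 + i)
    cmp <- nested_model_comparison(ds, "T", c("S1", "S2"), "S1",
                                   c("O1", "O2", "O3", "O4"))
    if (cmp$reduced$p_value < 0.05 && cmp$full$p_value >= 0.05)
      hits <- hits + 1
  }
  expect_gt(hits, 7)  # majority
  # reduced model true: parsimony prefers it
  ok <- 0
  for (i in 1:10) {
    ds <- simulate_dataset(two_way_graph(1.0), 2e4, two_way_samples,
                           seed = 7300 + i)
    cmp <- nested_model_comparison(ds, "T", c("S1", "S2"), "S1",
                                   c("O1", "O2", "O3", "O4"))
    if (cmp$preferred == "reduced") ok <- ok + 1
  }
  expect_gte(ok, 7)
  expect_error(nested_model_comparison(
    simulate_dataset(two_way_graph(0.5), 1000, two_way_samples, seed = 1),
    "T", c("S1", "S2"), "O1", c("O1", "O2", "O3", "O4")), "subset")
})

test_that("basal alpha hits the boundary cases exactly", {
  ds <- random_dataset(4000, c(NB = 5, BP = 5, O1 = 5, O2 = 5, O3 = 5),
                       seed = 69)
  # target copies the non-basal source -> alpha ~ 0
  ds0 <- toy_dataset(cbind(ds$geno, ds$geno[, 1:5]),
                     c(ds$ind$population, rep("T", 5)), n_chrom = 4)
  expect_warning(
    a0 <- basal_alpha(ds0, "T", "NB", "BP", c("O1", "O2", "O3")),
    "ridge")
  expect_equal(a0$alpha, 0, tolerance = 1e-8)
  # target copies the proxy -> alpha ~ 1
  ds1 <- toy_dataset(cbind(ds$geno, ds$geno[, 6:10]),
                     c(ds$ind$population, rep("T", 5)), n_chrom = 4)
  expect_warning(
    a1 <- basal_alpha(ds1, "T", "NB", "BP", c("O1", "O2", "O3")),
    "ridge")
  expect_equal(a1$alpha, 1, tolerance = 1e-8)
})

test_that("insufficient outgroups and unknown populations are errors", {
  ds <- random_dataset(500, c(T = 2, S1 = 2, S2 = 2, O1 = 2, O2 = 2),
                       seed = 70)
  expect_error(qpadm(ds, "T", c("S1", "S2"), c("O1", "O2")),
               "insufficient outgroups")
  expect_error(qpadm(ds, "T", c("S1", "S2"), c("O1", "O2", "nope")),
               "not in dataset")
})

test_that("compose_alpha reproduces the delta-method propagation", {
  cp <- compose_alpha(0.258, 0.050, 0.248, 0.055)
  expect_equal(round(100 * cp$estimate, 1), 6.4)
  expect_equal(round(100 * cp$se, 1), 1.9)
  # identity factor passes through unchanged
  id <- compose_alpha(1, 0, 0.37, 0.041)
  expect_equal(id$estimate, 0.37)
  expect_equal(id$se, 0.041)
  # Monte-Carlo oracle: product of independent normals
  set.seed(71)
  n <- 1e6
  prod <- rnorm(n, 0.258, 0.050) * rnorm(n, 0.248, 0.055)
  expect_lt(abs(sd(prod) / cp$se - 1), 0.05)
  expect_error(compose_alpha(0.2, -0.1, 0.3, 0.05), ">= 0")
})
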
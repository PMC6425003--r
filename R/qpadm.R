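#' qpAdm-style admixture-proportion estimation
#'
#' Models a target population as a linear combination of k source
#' populations relative to a set of outgroups. The left set is
#' (target, sources...), giving a k x (n_right - 1) f4 matrix
#' X[i, j] = f4(target, source_i; right_1, right_j). Under the model
#' target = sum w_i source_i the rows satisfy w' X = 0, so X is fitted
#' at rank k - 1 (alternating weighted least squares under the
#' block-jackknife covariance) and the mixture weights are the left
#' null vector of the fitted matrix rescaled to sum to 1. The model-fit
#' chi-square is the rank-(k - 1) test statistic with n_right - k
#' degrees of freedom; its p-value asks whether the admixture model is
#' adequate to explain the target's relationship to the outgroups.
#' Weight standard errors come from re-estimating the weights on each
#' delete-one-block replicate of the f4 matrix. Fits with any weight
#' outside [0, 1] are reported but flagged infeasible.
#'
#' @param data a `genotype_dataset`.
#' @param target target population label.
#' @param sources character vector of k >= 1 source population labels.
#' @param outgroups character vector of more than k outgroup labels
#'   (right populations); they must be able to distinguish the sources
#'   (check with [qpwave_rank_test()] on the sources beforehand).
#' @param blocks a [assign_blocks()] result; computed with defaults
#'   when omitted.
#' @param snp_policy SNP usability policy, see [build_f4_matrix()].
#' @param ridge covariance regularization, see [qpwave_rank_test()].
#' @return Object of class `qpadm` with components `weights` (named,
#'   summing to 1), `se`, `vcov`, `chisq`, `dof`, `p_value`,
#'   `feasible`, `n_snps`, `n_blocks` and the underlying `f4_matrix`.
#' @seealso [qpwave_rank_test()], [nested_model_comparison()],
#'   [basal_alpha()]
#' @export
qpadm <- function(data, target, sources, outgroups, blocks = NULL,
                  snp_policy = "intersection", ridge = 1e-5) {
  sources <- as.character(sources)
  outgroups <- as.character(outgroups)
  k <- length(sources)
  if (k < 1) stop("need at least one source population")
  if (k >= length(outgroups))
    stop("insufficient outgroups: need more outgroups (", length(outgroups),
         ") than sources (", k, ")")
  f4m <- build_f4_matrix(data, left = c(target, sources), right = outgroups,
                         blocks = blocks, snp_policy = snp_policy)
  L <- k
  R <- length(outgroups) - 1L
  Qi <- safe_precision(f4m$cov, ridge)
  r <- k - 1L
  ft <- fit_rank(f4m$est, Qi, L, R, r)
  w <- extract_weights(ft$fitted, k)
  dof <- length(outgroups) - k
  p <- stats::pchisq(ft$chisq, dof, lower.tail = FALSE)

  # weight SEs: full jackknife re-estimation on delete-one-block replicates
  g <- f4m$n_blocks
  if (k == 1) {
    se <- 0
    Vw <- matrix(0, 1, 1)
  } else {
    loo_w <- matrix(NA_real_, g, k)
    init <- list(A = ft$A, B = ft$B)
    for (j in seq_len(g)) {
      fj <- fit_rank(f4m$loo[j, ], Qi, L, R, r, init = init)
      loo_w[j, ] <- extract_weights(fj$fitted, k)
    }
    Vw <- jackknife_cov(w, loo_w, f4m$block_weights)
    se <- sqrt(diag(Vw))
  }
  names(w) <- names(se) <- sources
  dimnames(Vw) <- list(sources, sources)
  structure(list(
    target = target, sources = sources, outgroups = outgroups,
    weights = w, se = se, vcov = Vw,
    chisq = ft$chisq, dof = dof, p_value = p,
    feasible = all(w >= 0 & w <= 1),
    n_snps = f4m$n_snps, n_blocks = g,
    f4m = f4m
  ), class = "qpadm")
}

# Mixture weights = left null vector of the rank-(k-1) fitted matrix,
# rescaled to sum to 1.
extract_weights <- function(fitted, k) {
  if (k == 1) return(1)
  sv <- svd(fitted)
  w <- sv$u[, k]
  s <- sum(w)
  if (abs(s) < 1e-10)
    stop("degenerate null space: outgroups do not distinguish the sources")
  w / s
}

#' @export
print.qpadm <- function(x, ...) {
  cat("qpAdm fit:", x$target, "=",
      paste(sprintf("%.3f %s", x$weights, x$sources), collapse = " + "), "\n")
  cat(sprintf("model fit: chisq = %.3f, dof = %d, p = %.4g%s\n",
              x$chisq, x$dof, x$p_value,
              if (x$feasible) "" else "  [INFEASIBLE weights]"))
  invisible(x)
}

#' @export
summary.qpadm <- function(object, ...) {
  tab <- data.frame(source = object$sources,
                    weight = unname(object$weights),
                    se = unname(object$se),
                    stringsAsFactors = FALSE)
  out <- list(target = object$target, table = tab,
              outgroups = object$outgroups,
              chisq = object$chisq, dof = object$dof,
              p_value = object$p_value, feasible = object$feasible,
              n_snps = object$n_snps, n_blocks = object$n_blocks)
  class(out) <- "summary.qpadm"
  out
}

#' @export
print.summary.qpadm <- function(x, ...) {
  cat("qpAdm admixture model for target:", x$target, "\n")
  cat("outgroups:", paste(x$outgroups, collapse = ", "), "\n\n")
  tab <- x$table
  tab$weight <- sprintf("%.4f", tab$weight)
  tab$se <- sprintf("%.4f", tab$se)
  print(tab, row.names = FALSE)
  cat(sprintf("\nmodel fit: chisq = %.3f on %d dof, p = %.4g\n",
              x$chisq, x$dof, x$p_value))
  cat("feasible:", x$feasible, "|", x$n_snps, "SNPs in", x$n_blocks,
      "blocks\n")
  invisible(x)
}

#' @export
coef.qpadm <- function(object, ...) object$weights

#' @export
vcov.qpadm <- function(object, ...) object$vcov

#' Compare a full admixture model with a nested reduced model
#'
#' Fits the target with the full source set and with a subset of it,
#' and reports whether dropping the extra sources significantly
#' degrades the model fit (reduced-model p below `p_threshold` while
#' the full model remains acceptable). When both models are acceptable
#' the reduced one is preferred by parsimony.
#'
#' @inheritParams qpadm
#' @param full_sources,reduced_sources source sets;
#'   `reduced_sources` must be a proper subset of `full_sources`.
#' @param p_threshold model-fit p-value threshold (default 0.05).
#' @return Object of class `qpadm_comparison` containing both fits and
#'   the verdict.
#' @export
nested_model_comparison <- function(data, target, full_sources,
                                    reduced_sources, outgroups,
                                    blocks = NULL, p_threshold = 0.05, ...) {
  if (!all(reduced_sources %in% full_sources) ||
      length(reduced_sources) >= length(full_sources))
    stop("reduced_sources must be a proper subset of full_sources")
  if (is.null(blocks)) blocks <- assign_blocks(data$snp)
  full <- qpadm(data, target, full_sources, outgroups, blocks = blocks, ...)
  reduced <- qpadm(data, target, reduced_sources, outgroups,
                   blocks = blocks, ...)
  sig <- reduced$p_value < p_threshold && full$p_value >= p_threshold
  preferred <- if (reduced$p_value >= p_threshold) "reduced"
    else if (full$p_value >= p_threshold) "full" else "neither"
  structure(list(full = full, reduced = reduced,
                 p_threshold = p_threshold,
                 significant_reduction = sig, preferred = preferred),
            class = "qpadm_comparison")
}

#' @export
print.qpadm_comparison <- function(x, ...) {
  cat("nested model comparison (threshold p =", x$p_threshold, ")\n")
  cat(sprintf("full    (%s): p = %.4g\n",
              paste(x$full$sources, collapse = " + "), x$full$p_value))
  cat(sprintf("reduced (%s): p = %.4g\n",
              paste(x$reduced$sources, collapse = " + "), x$reduced$p_value))
  if (x$significant_reduction)
    cat("dropping the extra source(s) significantly degrades the fit\n")
  cat("preferred model:", x$preferred, "\n")
  invisible(x)
}

#' Basal Eurasian proxy proportion
#'
#' Estimates the Basal Eurasian ancestry proportion of a west Eurasian
#' target indirectly, as the qpAdm mixture weight on a deeply
#' diverging African proxy (e.g. the ancient Ethiopian Mota genome) in
#' a two-source model (proxy + non-basal source) evaluated against
#' outgroups that are all crown Eurasians without Basal Eurasian
#' ancestry (eastern non-Africans and Upper Paleolithic Eurasians).
#' Because both the proxy and the Basal lineage split from the crown
#' before all such outgroups, the proxy weight identifies the basal
#' fraction.
#'
#' @inheritParams qpadm
#' @param nonbasal_source label of the non-basal source population.
#' @param basal_proxy label of the deeply diverging proxy population.
#' @return Object of class `alpha_estimate`: `alpha`, `se`,
#'   `out_of_range` flag and the underlying `qpadm` fit.
#' @export
basal_alpha <- function(data, target, nonbasal_source, basal_proxy,
                        outgroups, blocks = NULL, ...) {
  fit <- qpadm(data, target, c(basal_proxy, nonbasal_source), outgroups,
               blocks = blocks, ...)
  a <- unname(fit$weights[1])
  structure(list(population = target, alpha = a, se = unname(fit$se[1]),
                 basal_proxy = basal_proxy,
                 nonbasal_source = nonbasal_source,
                 outgroups = outgroups,
                 out_of_range = a < 0 || a > 1,
                 fit = fit),
            class = "alpha_estimate")
}

#' @export
print.alpha_estimate <- function(x, ...) {
  cat(sprintf("Basal proportion (proxy %s) in %s: alpha = %.3f +/- %.3f%s\n",
              x$basal_proxy, x$population, x$alpha, x$se,
              if (x$out_of_range) "  [outside 0..1]" else ""))
  invisible(x)
}

#' Compose an admixture proportion with a source's basal proportion
#'
#' Predicts the basal ancestry fraction of an admixed population as
#' (proportion of the basal-carrying source) x (basal fraction within
#' that source), with a first-order delta-method standard error
#' assuming the two estimates are independent (they come from
#' different fits): se = sqrt(p^2 sd_a^2 + a^2 sd_p^2).
#'
#' @param proportion,proportion_se admixture proportion of the carrier
#'   source in the target, with its standard error (proportion scale).
#' @param alpha,alpha_se basal fraction within the carrier source, with
#'   its standard error.
#' @return Object of class `composed_alpha` with `estimate` and `se`.
#' @export
compose_alpha <- function(proportion, proportion_se, alpha, alpha_se) {
  if (proportion_se < 0 || alpha_se < 0) stop("standard errors must be >= 0")
  est <- proportion * alpha
  se <- sqrt(proportion^2 * alpha_se^2 + alpha^2 * proportion_se^2)
  structure(list(estimate = est, se = se,
                 inputs = c(proportion = proportion,
                            proportion_se = proportion_se,
                            alpha = alpha, alpha_se = alpha_se)),
            class = "composed_alpha")
}

#' @export
print.composed_alpha <- function(x, ...) {
  cat(sprintf("composed prediction: alpha = %.1f%% +/- %.1f%%\n",
              100 * x$estimate, 100 * x$se))
  invisible(x)
}
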
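#' Principal components of a genotype panel
#'
#' Fits principal components on (near-)complete individuals, using the
#' normalization of the reference tool: each SNP is centered by its
#' mean genotype and scaled by sqrt(p(1 - p)) with p = mean/2;
#' monomorphic SNPs are dropped. Residual missingness in the fitting
#' panel is mean-imputed. The loadings are orthonormal SNP vectors and
#' each panel individual gets a score on each of the top K components.
#'
#' @param data a `genotype_dataset`.
#' @param individuals ids of the fitting panel (default: all).
#' @param K number of components.
#' @param completeness_min minimum genotype completeness required of
#'   each fitting individual (default 0.5).
#' @return Object of class `pca_model`: SNP ids, per-SNP center and
#'   scale, loadings (SNPs x K, orthonormal), panel scores and the
#'   eigenvalue share of each component.
#' @export
fit_pca <- function(data, individuals = NULL, K = 2,
                    completeness_min = 0.5) {
  stopifnot(inherits(data, "genotype_dataset"))
  if (is.null(individuals)) individuals <- data$ind$individual_id
  cols <- match(individuals, data$ind$individual_id)
  if (anyNA(cols)) stop("unknown individual id(s) in fitting panel")
  n <- length(cols)
  if (K >= n) stop("K must be smaller than the number of fitting individuals")
  G <- data$geno[, cols, drop = FALSE]
  comp <- colMeans(!is.na(G))
  if (any(comp < completeness_min))
    stop("fitting individuals below completeness threshold: ",
         paste(individuals[comp < completeness_min], collapse = ", "))
  center <- rowMeans(G, na.rm = TRUE)
  p_hat <- center / 2
  keep <- !is.na(p_hat) & p_hat > 0 & p_hat < 1
  if (!any(keep)) stop("no polymorphic SNPs in the fitting panel")
  G <- G[keep, , drop = FALSE]
  center <- center[keep]
  scale <- sqrt(p_hat[keep] * (1 - p_hat[keep]))
  Z <- (G - center) / scale
  Z[is.na(Z)] <- 0  # mean imputation of residual missingness
  if (K > min(dim(Z))) stop("K larger than the available dimensions")
  sv <- svd(Z, nu = K, nv = K)
  loadings <- sv$u[, seq_len(K), drop = FALSE]
  scores <- sv$v[, seq_len(K), drop = FALSE] %*% diag(sv$d[seq_len(K)], K)
  rownames(scores) <- individuals
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(K))
  structure(list(
    snp_id = data$snp$snp_id[keep], center = center, scale = scale,
    loadings = loadings, scores = scores, K = K,
    var_share = sv$d[seq_len(K)]^2 / sum(sv$d^2)
  ), class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("pca_model:", length(x$snp_id), "SNPs,", nrow(x$scores),
      "panel individuals,", x$K, "components\n")
  cat("variance shares:", paste(sprintf("%.1f%%", 100 * x$var_share),
                                collapse = ", "), "\n")
  invisible(x)
}

#' Least-squares projection of missing-data samples onto fitted PCs
#'
#' Projects each sample onto the model's components by solving the
#' least-squares fit of its normalized non-missing genotypes onto the
#' loadings restricted to those SNPs -- the approach used to place
#' low-coverage ancient individuals on a modern PCA without biasing
#' the components. A complete-data member of the fitting panel projects
#' exactly onto its own fitted score.
#'
#' @param model a [fit_pca()] model.
#' @param data a `genotype_dataset` containing the samples.
#' @param individuals ids of the samples to project (default: all).
#' @param min_overlap minimum number of model SNPs with non-missing
#'   genotype required per sample (default 30).
#' @return Matrix of projected coordinates (individuals x K) with an
#'   `n_snps_used` attribute; also returned as a data frame column set
#'   by [as.data.frame()].
#' @export
lsq_project <- function(model, data, individuals = NULL, min_overlap = 30) {
  stopifnot(inherits(model, "pca_model"), inherits(data, "genotype_dataset"))
  if (is.null(individuals)) individuals <- data$ind$individual_id
  cols <- match(individuals, data$ind$individual_id)
  if (anyNA(cols)) stop("unknown individual id(s)")
  rows <- match(model$snp_id, data$snp$snp_id)
  if (all(is.na(rows))) stop("dataset shares no SNPs with the model")
  out <- matrix(NA_real_, length(cols), model$K,
                dimnames = list(individuals, colnames(model$loadings)))
  used <- integer(length(cols))
  for (i in seq_along(cols)) {
    gfull <- rep(NA_integer_, length(model$snp_id))
    ok_row <- !is.na(rows)
    gfull[ok_row] <- data$geno[rows[ok_row], cols[i]]
    ok <- !is.na(gfull)
    used[i] <- sum(ok)
    if (used[i] < min_overlap)
      stop("individual ", individuals[i], " overlaps only ", used[i],
           " model SNPs (minimum ", min_overlap, ")")
    z <- (gfull[ok] - model$center[ok]) / model$scale[ok]
    V <- model$loadings[ok, , drop = FALSE]
    out[i, ] <- solve(crossprod(V), crossprod(V, z))
  }
  attr(out, "n_snps_used") <- used
  out
}

#' Projection results as a table
#'
#' @param projection output of [lsq_project()].
#' @return Data frame with individual, PC coordinates and
#'   `n_snps_used`.
#' @export
projection_table <- function(projection) {
  data.frame(individual = rownames(projection),
             as.data.frame(unclass(projection[, , drop = FALSE])),
             n_snps_used = attr(projection, "n_snps_used"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Serialize a PCA model to a plain-text file
#'
#' Writes the per-SNP center/scale/loadings table preceded by a small
#' header, so a fitted model can be stored and reloaded without
#' refitting.
#'
#' @param model a [fit_pca()] model.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_pca_model <- function(model, path) {
  stopifnot(inherits(model, "pca_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#pca_model K=%d snps=%d", model$K,
                       length(model$snp_id)),
               sprintf("#var_share %s",
                       paste(format(model$var_share, digits = 17),
                             collapse = "\t"))), con)
  tab <- data.frame(snp_id = model$snp_id, center = model$center,
                    scale = model$scale, model$loadings,
                    stringsAsFactors = FALSE)
  utils::write.table(format(tab, digits = 17), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a PCA model written by [write_pca_model()]
#'
#' @param path file path.
#' @return A `pca_model` (without panel scores, which belong to the
#'   fitting run).
#' @export
read_pca_model <- function(path) {
  lines <- readLines(path, n = 2)
  if (!startsWith(lines[1], "#pca_model")) stop("not a pca_model file")
  K <- as.integer(sub(".*K=(\\d+).*", "\\1", lines[1]))
  var_share <- as.numeric(strsplit(sub("^#var_share ", "", lines[2]),
                                   "\t")[[1]])
  tab <- utils::read.table(path, header = TRUE, sep = "\t", skip = 2,
                           stringsAsFactors = FALSE)
  loadings <- as.matrix(tab[, paste0("PC", seq_len(K)), drop = FALSE])
  structure(list(snp_id = as.character(tab$snp_id),
                 center = as.numeric(tab$center),
                 scale = as.numeric(tab$scale),
                 loadings = loadings, scores = NULL, K = K,
                 var_share = var_share),
            class = "pca_model")
}
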
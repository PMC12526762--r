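#' PCA on a complete-data reference panel
#'
#' Genotypes are centered by twice the reference allele frequency and
#' scaled by sqrt(p(1-p)) per SNP, and the top K right singular vectors of
#' the normalized matrix give the loadings. SNPs with any missingness in
#' the reference (logged) or with zero variance are dropped; ancient
#' samples never influence the basis. Loadings follow the sign convention
#' that each vector's largest-magnitude entry is positive.
#'
#' @param x An \code{\link{eigenstrat}} dataset of reference individuals.
#' @param k Number of components (<= min(n_ref, n_snps)).
#' @return Object of class \code{"pca_model"}: SNP ids, means and scale
#'   factors, loadings (SNP x K), eigenvalues, and reference scores.
#' @export
fit_pca <- function(x, k = 10) {
  validate_eigenstrat(x)
  g <- t(x$geno)                       # samples x SNPs
  miss <- colSums(g == 9L) > 0
  if (any(miss))
    message("fit_pca: dropping ", sum(miss),
            " SNPs with missing reference calls")
  keep <- !miss
  g <- g[, keep, drop = FALSE]
  p <- colMeans(g) / 2
  poly <- p > 0 & p < 1
  g <- g[, poly, drop = FALSE]
  p <- p[poly]
  snp_id <- x$snp$snp_id[keep][poly]
  n <- nrow(g); m <- ncol(g)
  if (k > min(n, m)) stop("k must be <= min(n_ref, n_snps) = ", min(n, m))
  sc <- sqrt(p * (1 - p))
  Z <- sweep(sweep(g, 2, 2 * p), 2, sc, "/")
  sv <- svd(Z, nu = k, nv = k)
  V <- sv$v
  flip <- apply(V, 2, function(v) sign(v[which.max(abs(v))]))
  V <- sweep(V, 2, flip, "*")
  scores <- Z %*% V
  rownames(scores) <- x$ind$sample_id
  colnames(scores) <- colnames(V) <- paste0("PC", seq_len(k))
  structure(list(snp_id = snp_id, p = p, scale = sc, loadings = V,
                 eigenvalues = sv$d[seq_len(k)]^2 / (n - 1),
                 total_var = sum(Z^2) / (n - 1),
                 ref_scores = scores, k = k),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("PCA model: ", length(x$snp_id), " SNPs, ", nrow(x$ref_scores),
      " reference samples, K = ", x$k, "\n", sep = "")
  pv <- 100 * x$eigenvalues / x$total_var
  cat("  variance explained (%): ",
      paste(sprintf("%.1f", utils::head(pv, 5)), collapse = " "),
      if (x$k > 5) " ..." else "", "\n", sep = "")
  invisible(x)
}

#' Least-squares projection of samples onto a fitted PCA
#'
#' Each sample's normalized non-missing genotypes are regressed on the
#' loading rows restricted to its observed SNPs (the K x K normal
#' equations), so high-missingness individuals can be placed in the
#' reference PC space without shrinking the basis toward them. A
#' complete-data reference individual projects exactly onto its own
#' \code{\link{fit_pca}} score.
#'
#' @param model A \code{\link{pca_model}}.
#' @param x An \code{\link{eigenstrat}} dataset (any mode) of samples to
#'   project.
#' @return Matrix of PC scores, samples x K.
#' @export
lsq_project <- function(model, x) {
  validate_eigenstrat(x)
  idx <- match(model$snp_id, x$snp$snp_id)
  if (all(is.na(idx))) stop("no model SNPs present in the dataset")
  V <- model$loadings
  k <- model$k
  out <- matrix(NA_real_, nrow(x$ind), k,
                dimnames = list(x$ind$sample_id,
                                colnames(model$loadings)))
  for (s in seq_len(nrow(x$ind))) {
    g <- rep(9L, length(model$snp_id))
    has <- !is.na(idx)
    g[has] <- x$geno[idx[has], s]
    obs <- g != 9L
    if (sum(obs) < k)
      stop("sample ", x$ind$sample_id[s], ": fewer observed SNPs (",
           sum(obs), ") than components (", k, ")")
    z <- (g[obs] - 2 * model$p[obs]) / model$scale[obs]
    Vo <- V[obs, , drop = FALSE]
    G <- crossprod(Vo)
    if (rcond(G) < 1e-12)
      stop("sample ", x$ind$sample_id[s],
           ": restricted loadings are rank deficient")
    out[s, ] <- solve(G, crossprod(Vo, z))
  }
  out
}
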
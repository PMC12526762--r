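# --- admixture dating by ancestry-covariance decay --------------------------
#
# Within an admixed genome, alleles at two loci co-vary around the mixed
# expectation whenever they sit on the same ancestry tract; under a single
# admixture pulse T generations ago the tract process is Markov and that
# covariance decays as exp(-T d) with genetic distance d (Morgans). The
# curve builder below bins SNP pairs by distance using reference-frequency
# weights, and the fitter extracts T as the exponential decay rate.

#' Distance-binned weighted ancestry covariance curve
#'
#' Per SNP the weight is the reference frequency difference
#' w = p_A - p_B; per individual the residual is x = g/2 - mu with
#' mu = alpha p_A + (1 - alpha) p_B and alpha the individual's constrained
#' least-squares ancestry estimate. Pairs of SNPs on the same chromosome
#' are binned by genetic distance (pairs are assigned by the difference of
#' their binsize-grid cell indices, so bin k collects pairs about
#' k * binsize apart) and the bin statistic is
#' sum(w_i w_j x_i x_j) / sum(w_i^2 w_j^2), averaged over individuals.
#'
#' @param x \code{\link{eigenstrat}} dataset holding the admixed target
#'   individuals (optionally restricted via \code{target}), or a genotype
#'   matrix with \code{snp} supplied.
#' @param freq_a,freq_b Reference allele frequencies per SNP for the two
#'   sources.
#' @param target Optional group label selecting the target individuals.
#' @param snp snp table when \code{x} is a bare matrix.
#' @param binsize Distance bin width in Morgans (default 0.001).
#' @param maxdis Maximum pair distance in Morgans (default 0.5).
#' @return Object of class \code{"cov_curve"}: bin centers \code{d},
#'   covariance \code{A}, pair counts, and per-chromosome partial sums for
#'   the leave-one-chromosome-out jackknife.
#' @export
ancestry_cov_curve <- function(x, freq_a, freq_b, target = NULL, snp = NULL,
                               binsize = 0.001, maxdis = 0.5) {
  if (inherits(x, "eigenstrat")) {
    snp <- x$snp
    geno <- x$geno
    if (!is.null(target)) geno <- geno[, x$ind$group == target, drop = FALSE]
  } else geno <- as.matrix(x)
  stopifnot(!is.null(snp), nrow(geno) == nrow(snp),
            length(freq_a) == nrow(snp), length(freq_b) == nrow(snp))
  if (ncol(geno) < 1) stop("target has no individuals")
  w <- freq_a - freq_b
  if (all(w == 0)) stop("references indistinguishable: all weights zero")
  n_ind <- ncol(geno)
  gd <- geno / 2
  called <- geno != 9L
  gd[!called] <- NA_real_

  # constrained least-squares ancestry proportion per individual
  alpha <- vapply(seq_len(n_ind), function(i) {
    ok <- called[, i]
    num <- sum((gd[ok, i] - freq_b[ok]) * w[ok])
    den <- sum(w[ok]^2)
    min(max(num / den, 0), 1)
  }, numeric(1))

  K <- floor(maxdis / binsize + 1e-9)
  chroms <- unique(snp$chrom)
  nc <- length(chroms)
  num <- array(0, c(nc, K)); den <- array(0, c(nc, K))
  cnt <- array(0, c(nc, K))
  for (ci in seq_along(chroms)) {
    idx <- which(snp$chrom == chroms[ci])
    cell <- floor(snp$genetic_pos[idx] / binsize + 1e-12)
    cell <- cell - min(cell) + 1L
    C <- max(cell)
    # per-cell accumulators: S = sum w x (0 where missing), T = sum w^2,
    # per individual; N = count of called SNPs per cell per individual
    wx <- (gd[idx, , drop = FALSE] -
             outer(freq_b[idx], rep(1, n_ind)) -
             outer(w[idx], alpha)) * w[idx]
    wx[!called[idx, , drop = FALSE]] <- 0
    S <- rowsum(wx, cell)
    W2 <- (w[idx]^2) * called[idx, , drop = FALSE]
    T2 <- rowsum(W2, cell)
    N <- rowsum(called[idx, , drop = FALSE] * 1, cell)
    # rowsum drops absent cells; expand to full grid
    rows <- as.integer(rownames(S))
    Sf <- matrix(0, C, n_ind); Sf[rows, ] <- S
    Tf <- matrix(0, C, n_ind); Tf[rows, ] <- T2
    Nf <- matrix(0, C, n_ind); Nf[rows, ] <- N
    kmax <- min(K, C - 1L)
    if (kmax < 1L) next
    # lagged cross-sums sum_c M(c) M(c+k) for all k at once, by FFT
    # autocorrelation of the zero-padded cell series
    M <- cbind(Sf, Tf, Nf)
    pad <- stats::nextn(C + kmax, 2)
    Mp <- rbind(M, matrix(0, pad - C, ncol(M)))
    F <- stats::mvfft(Mp)
    ac <- Re(stats::mvfft(F * Conj(F), inverse = TRUE)) / pad
    lag <- ac[2:(kmax + 1), , drop = FALSE]        # lags 1..kmax
    num[ci, seq_len(kmax)] <- rowSums(lag[, seq_len(n_ind), drop = FALSE])
    den[ci, seq_len(kmax)] <-
      rowSums(lag[, n_ind + seq_len(n_ind), drop = FALSE])
    cnt[ci, seq_len(kmax)] <-
      rowSums(lag[, 2 * n_ind + seq_len(n_ind), drop = FALSE])
  }
  A <- colSums(num) / colSums(den)
  A[colSums(den) == 0] <- NA_real_
  structure(list(d = seq_len(K) * binsize, A = A,
                 count = colSums(cnt), binsize = binsize, maxdis = maxdis,
                 chrom = chroms, num = num, den = den, cnt = cnt,
                 n_ind = n_ind, alpha = alpha),
            class = "cov_curve")
}

#' @export
print.cov_curve <- function(x, ...) {
  cat("ancestry covariance curve: ", length(x$d), " bins (binsize ",
      x$binsize, " M, maxdis ", x$maxdis, " M), ", x$n_ind,
      " individual(s)\n", sep = "")
  cat("  mean fitted ancestry proportion: ",
      round(mean(x$alpha), 3), "\n", sep = "")
  invisible(x)
}

#' @export
plot.cov_curve <- function(x, fit = NULL, ...) {
  graphics::plot(x$d, x$A, xlab = "genetic distance (Morgans)",
                 ylab = "ancestry covariance", pch = 16, cex = 0.4, ...)
  if (!is.null(fit))
    graphics::curve(fit$a * exp(-fit$lambda * x) + fit$c0, add = TRUE,
                    col = 2)
  invisible(x)
}

# internal: single exponential fit on (d, A) points
fit_exp_points <- function(d, A, starts = c(1, 10, 100, 1000)) {
  best <- NULL
  for (l0 in starts) {
    a0 <- max(A[1] - min(A), 1e-6)
    fit <- tryCatch(
      minpack.lm::nlsLM(A ~ a * exp(-l * d) + c0,
                        start = list(a = a0, l = l0, c0 = mean(utils::tail(A, 5))),
                        lower = c(-Inf, 1e-8, -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(coef = stats::coef(fit), rss = rss)
  }
  if (is.null(best)) stop("exponential fit failed from every start")
  best
}

#' Fit an exponential decay to a covariance curve
#'
#' Nonlinear least squares of A(d) = a exp(-lambda d) + c over bins with
#' d >= lovalfit and positive pair count, multi-started over decay rates
#' {1, 10, 100, 1000} per Morgan. The decay rate lambda is the admixture
#' age in generations under the single-pulse model; the affine offset c
#' absorbs finite-sample background covariance.
#'
#' @param curve A \code{\link{ancestry_cov_curve}} result.
#' @param lovalfit Lower fit bound in Morgans (default 0.0045, i.e.
#'   0.45 cM), excluding short-range background LD.
#' @return Object of class \code{"date_fit"}: \code{lambda} (generations),
#'   \code{a}, \code{c0}, \code{rss}, \code{n_bins}, plus \code{se} and
#'   per-chromosome estimates once \code{\link{loco_jackknife}} has run.
#' @export
fit_exponential <- function(curve, lovalfit = 0.0045) {
  stopifnot(inherits(curve, "cov_curve"))
  use <- curve$d >= lovalfit & curve$count > 0 & !is.na(curve$A)
  if (sum(use) < 4) stop("fewer than 4 usable bins above lovalfit")
  best <- fit_exp_points(curve$d[use], curve$A[use])
  structure(list(lambda = unname(best$coef["l"]), a = unname(best$coef["a"]),
                 c0 = unname(best$coef["c0"]), rss = best$rss,
                 n_bins = sum(use), lovalfit = lovalfit,
                 se = NA_real_, lambda_loco = NULL),
            class = "date_fit")
}

#' @export
print.date_fit <- function(x, ...) {
  cat(sprintf("admixture date: lambda = %.2f generations", x$lambda))
  if (is.finite(x$se)) cat(sprintf(" +/- %.2f (LOCO jackknife SE)", x$se))
  cat(sprintf("\n  amplitude = %.4g, offset = %.4g, %d bins (d >= %.4g M)\n",
              x$a, x$c0, x$n_bins, x$lovalfit))
  invisible(x)
}

#' Leave-one-chromosome-out jackknife for the admixture date
#'
#' Refits the exponential with each chromosome's pair contributions
#' removed and returns the weighted delete-one jackknife SE of lambda,
#' weights proportional to per-chromosome pair counts.
#'
#' @param curve A \code{\link{ancestry_cov_curve}} result (holds the
#'   per-chromosome partial sums).
#' @param fit The full-data \code{\link{fit_exponential}} result.
#' @return The \code{date_fit} with \code{se} and \code{lambda_loco}
#'   filled in.
#' @export
loco_jackknife <- function(curve, fit) {
  stopifnot(inherits(curve, "cov_curve"), inherits(fit, "date_fit"))
  nc <- length(curve$chrom)
  if (nc < 2) stop("leave-one-chromosome-out requires >= 2 chromosomes")
  lam <- numeric(nc)
  wts <- numeric(nc)
  for (ci in seq_len(nc)) {
    num <- colSums(curve$num[-ci, , drop = FALSE])
    den <- colSums(curve$den[-ci, , drop = FALSE])
    cnt <- colSums(curve$cnt[-ci, , drop = FALSE])
    A <- num / den
    use <- curve$d >= fit$lovalfit & cnt > 0 & is.finite(A)
    if (sum(use) < 4) stop("chromosome ", curve$chrom[ci],
                           ": too few bins after exclusion")
    lam[ci] <- unname(fit_exp_points(curve$d[use], A[use],
                                     starts = fit$lambda)$coef["l"])
    wts[ci] <- sum(curve$cnt[ci, ])
  }
  n <- sum(wts); g <- nc
  h <- n / wts
  tau <- h * fit$lambda - (h - 1) * lam
  theta_j <- g * fit$lambda - sum((1 - wts / n) * lam)
  fit$se <- sqrt(mean((tau - theta_j)^2 / (h - 1)))
  fit$lambda_loco <- lam
  fit
}

#' One-call admixture dating
#'
#' Builds the covariance curve, fits the exponential and runs the
#' leave-one-chromosome-out jackknife.
#'
#' @inheritParams ancestry_cov_curve
#' @inheritParams fit_exponential
#' @return A \code{\link{fit_exponential}} object with jackknife SE, plus
#'   the curve in \code{attr(, "curve")}.
#' @export
date_admixture <- function(x, freq_a, freq_b, target = NULL, snp = NULL,
                           binsize = 0.001, maxdis = 0.5,
                           lovalfit = 0.0045) {
  curve <- ancestry_cov_curve(x, freq_a, freq_b, target, snp, binsize,
                              maxdis)
  fit <- fit_exponential(curve, lovalfit)
  fit <- loco_jackknife(curve, fit)
  attr(fit, "curve") <- curve
  fit
}

#' Convert an admixture age in generations to a calendar interval
#'
#' The admixture date precedes the sampled individuals by lambda
#' generations of \code{generation_time} years. Interval endpoints come
#' from lambda +/- 2 SE; when an archaeological date range for the samples
#' is supplied, each endpoint is widened by half that range to reflect the
#' dating uncertainty of the samples themselves.
#'
#' @param lambda Admixture age in generations.
#' @param lambda_se Its standard error (0 gives a zero-width statistical
#'   interval).
#' @param sample_date_bce Date of the sampled individuals, years BCE
#'   (negative for CE).
#' @param generation_time Years per generation (default 29).
#' @param arch_range_bce Optional length-2 archaeological date range of the
#'   samples (years BCE, any order).
#' @return List with \code{date_bce} and the interval
#'   \code{older_bce}/\code{younger_bce}.
#' @export
gens_to_years <- function(lambda, lambda_se, sample_date_bce,
                          generation_time = 29, arch_range_bce = NULL) {
  date <- sample_date_bce + lambda * generation_time
  older <- sample_date_bce + (lambda + 2 * lambda_se) * generation_time
  younger <- sample_date_bce + (lambda - 2 * lambda_se) * generation_time
  if (!is.null(arch_range_bce)) {
    half <- abs(diff(range(arch_range_bce))) / 2
    older <- older + half
    younger <- younger - half
  }
  list(date_bce = date, older_bce = older, younger_bce = younger,
       generations = lambda, years_before_sample = lambda * generation_time)
}
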
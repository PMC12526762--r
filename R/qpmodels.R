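# --- f4-matrix machinery shared by qpWave and qpAdm -------------------------
#
# All entries of an f4 matrix are computed on one complete-case SNP set
# (every involved group called) and share the same 5 cM jackknife blocks,
# so the block jackknife yields a joint covariance of vec(X).

# rows_ab: 2-column matrix of (a, b) group names; cols_cd: 2-column matrix
# of (c, d). Entry (i, j) is f4(a_i, b_i; c_j, d_j).
f4_matrix_stats <- function(gf, rows_ab, cols_cd, blocks,
                            bias_correct = TRUE) {
  pops <- unique(c(rows_ab, cols_cd))
  usable <- rep(TRUE, nrow(gf$freq))
  for (pop in pops) usable <- usable & !is.na(gf$freq[, pop])
  p <- nrow(rows_ab); q <- nrow(cols_cd)
  terms <- matrix(NA_real_, sum(usable), p * q)
  kk <- 0
  for (j in seq_len(q)) for (i in seq_len(p)) {   # column-major = vec order
    kk <- kk + 1
    tm <- f4_terms(gf, rows_ab[i, 1], rows_ab[i, 2],
                   cols_cd[j, 1], cols_cd[j, 2], bias_correct)
    terms[, kk] <- tm[usable]
  }
  cc <- stats::complete.cases(terms)
  terms <- terms[cc, , drop = FALSE]
  blk <- blocks$block[usable][cc]
  if (!nrow(terms)) stop("no usable SNPs for the f4 matrix")
  lv <- sort(unique(blk))
  if (length(lv) < 2) stop("insufficient blocks for the jackknife (need >= 2)")
  bf <- factor(blk, levels = lv)
  bs <- rowsum(terms, bf)                  # g x (p*q) block sums
  bn <- as.vector(table(bf))
  n <- sum(bn); g <- length(bn)
  xhat <- colSums(bs) / n
  loo <- (matrix(colSums(bs), g, p * q, byrow = TRUE) - bs) / (n - bn)
  h <- n / bn
  tau <- h * matrix(xhat, g, p * q, byrow = TRUE) - (h - 1) * loo
  theta_j <- g * xhat - colSums((1 - bn / n) * loo)
  dev <- sweep(tau, 2, theta_j)
  Q <- crossprod(dev / sqrt(h - 1)) / g   # (1/g) sum_j dev dev' / (h_j - 1)
  list(xhat = matrix(xhat, p, q), Q = Q,
       block_sums = bs, block_n = bn, n_snps = n, n_blocks = g,
       p = p, q = q)
}

# Invert the jackknife covariance, ridge-regularizing if near-singular.
safe_qinv <- function(Q) {
  eps <- 0
  d <- mean(diag(Q))
  for (k in 0:12) {
    Qr <- Q + diag(eps, nrow(Q))
    ev <- tryCatch(min(eigen(Qr, symmetric = TRUE,
                             only.values = TRUE)$values),
                   error = function(e) -1)
    if (ev > d * 1e-12) {
      if (eps > 0)
        message("qp covariance near-singular; ridge epsilon = ",
                signif(eps, 3))
      return(solve(Qr))
    }
    eps <- if (eps == 0) d * 1e-10 else eps * 10
  }
  stop("jackknife covariance is singular beyond repair")
}

# Rank-r generalized-least-squares fit of a p x q matrix under metric Qinv
# on vec(X), by alternating least squares. Returns the fitted matrix and
# the quadratic-form residual statistic.
als_rank_fit <- function(X, Qinv, r, tol = 1e-10, maxit = 1e4,
                         init = NULL) {
  p <- nrow(X); q <- ncol(X)
  x <- as.vector(X)
  obj <- function(e) { d <- x - e; sum(d * (Qinv %*% d)) }
  if (r == 0) return(list(E = matrix(0, p, q), stat = obj(rep(0, p * q)),
                          iters = 0L))
  if (r >= min(p, q)) return(list(E = X, stat = 0, iters = 0L))
  if (is.null(init)) {
    sv <- svd(X)
    A <- sv$u[, seq_len(r), drop = FALSE] %*%
      diag(sqrt(sv$d[seq_len(r)]), r)
    B <- sv$v[, seq_len(r), drop = FALSE] %*%
      diag(sqrt(sv$d[seq_len(r)]), r)
  } else { A <- init$A; B <- init$B }
  Ip <- diag(p); Iq <- diag(q)
  last <- Inf
  for (it in seq_len(maxit)) {
    M <- kronecker(B, Ip)                       # vec(AB') = M vec(A)
    W <- crossprod(M, Qinv)
    A <- matrix(solve(W %*% M + diag(1e-14, p * r), W %*% x), p, r)
    M2 <- kronecker(Iq, A)                      # vec(AB') = M2 vec(B')
    W2 <- crossprod(M2, Qinv)
    Bt <- matrix(solve(W2 %*% M2 + diag(1e-14, q * r), W2 %*% x), r, q)
    B <- t(Bt)
    cur <- obj(as.vector(A %*% t(B)))
    if (is.finite(last) && abs(last - cur) <= tol * max(1, abs(last))) break
    last <- cur
  }
  list(E = A %*% t(B), stat = cur, iters = it, A = A, B = B)
}

#' qpWave rank test
#'
#' Tests whether the left populations are consistent with descending from
#' \code{rank + 1} independent ancestry streams relative to the right
#' (reference) set. Builds the matrix X[i, j] = f4(left_i, left_1;
#' right_j, right_1), estimates the joint block-jackknife covariance of its
#' entries, fits the best rank-\code{rank} approximation under that metric
#' by alternating least squares, and refers the residual quadratic form to
#' a chi-square with df = (L-1-rank)(R-1-rank). \code{rank = 0} with two
#' left populations is the cladality test.
#'
#' @param x An \code{\link{eigenstrat}} dataset or \code{group_freq} table.
#' @param left Ordered character vector of left populations (length L).
#' @param right Ordered character vector of right populations (length R).
#' @param rank Tested rank r (0 <= r < min(L-1, R-1)).
#' @param blocks Optional \code{\link{make_blocks}} result.
#' @param bias_correct Passed to the f4 kernel.
#' @return Object of class \code{"qpwave_result"}: list with \code{stat},
#'   \code{df}, \code{p}, \code{rank}, the f4 matrix and its covariance.
#' @export
qpwave_test <- function(x, left, right, rank = 0, blocks = NULL,
                        bias_correct = TRUE) {
  gf <- as_group_freq(x)
  if (is.null(blocks)) blocks <- make_blocks(gf$snp)
  L <- length(left); R <- length(right)
  if (length(intersect(left, right)))
    stop("left and right sets must be disjoint")
  if (R < L) stop("need at least as many right as left populations")
  df <- as.integer((L - 1 - rank) * (R - 1 - rank))
  if (df < 1) stop("rank ", rank, " leaves no degrees of freedom (df = ",
                   df, ")")
  rows <- cbind(left[-1], left[1])
  cols <- cbind(right[-1], right[1])
  fm <- f4_matrix_stats(gf, rows, cols, blocks, bias_correct)
  Qinv <- safe_qinv(fm$Q)
  fit <- als_rank_fit(fm$xhat, Qinv, rank)
  p <- stats::pchisq(fit$stat, df, lower.tail = FALSE)
  structure(list(stat = fit$stat, df = df, p = p, rank = rank,
                 left = left, right = right, X = fm$xhat, Q = fm$Q,
                 n_snps = fm$n_snps, n_blocks = fm$n_blocks),
            class = "qpwave_result")
}

#' @export
print.qpwave_result <- function(x, ...) {
  cat(sprintf("qpWave rank-%d test: chi2 = %.3f, df = %d, p = %.4g\n",
              x$rank, x$stat, x$df, x$p))
  cat("  left: ", paste(x$left, collapse = ", "), "\n", sep = "")
  cat("  right:", paste(x$right, collapse = ", "), "\n")
  invisible(x)
}

# Weights from the rank-(k-1) fit of the k x (R-1) matrix with rows
# f4(source_i, target; r_j, r_1): if the target is the alpha-mixture of
# the sources, sum_i alpha_i (p_source_i - p_target) = 0, so the source
# weights are the left null vector of the fitted matrix, normalized to
# sum 1. Equivalent to the rank-deficiency condition on the
# (target+sources) x rights matrix, but exactly invariant under
# right-list reordering.
weights_from_fit <- function(E) {
  if (nrow(E) == 1L) return(1)
  sv <- svd(E)
  v <- sv$u[, nrow(E)]
  if (abs(sum(v)) < 1e-10) stop("degenerate null vector: weights do not sum")
  v / sum(v)
}

#' qpAdm admixture-weight estimation
#'
#' Models \code{target} as a mixture of the \code{sources} relative to the
#' \code{right} reference set. Ancestry weights come from the left null
#' space of the rank-k fitted f4 matrix of (target, sources) against the
#' rights; the model p-value is the qpWave test that the full left set
#' carries only k ancestry streams; per-weight standard errors come from a
#' delete-one-block jackknife of the entire fit. Weights may legitimately
#' be negative (an infeasible but well-fitting model); the
#' \code{feasible} flag records whether all weights lie in [0, 1].
#'
#' @inheritParams qpwave_test
#' @param target Target population.
#' @param sources Character vector of k source populations.
#' @return Object of class \code{"qpadm_fit"}: weights, SEs, model
#'   \code{p}, \code{stat}, \code{df}, \code{feasible}, dimensions.
#' @export
qpadm_fit <- function(x, target, sources, right, blocks = NULL,
                      bias_correct = TRUE) {
  gf <- as_group_freq(x)
  if (is.null(blocks)) blocks <- make_blocks(gf$snp)
  k <- length(sources)
  left <- c(target, sources)
  R <- length(right)
  if (length(intersect(left, right)))
    stop("left and right sets must be disjoint")
  if (R < k + 1) stop("need |right| >= k + 1 for a k-source model")
  rows <- cbind(sources, target)
  cols <- cbind(right[-1], right[1])
  fm <- f4_matrix_stats(gf, rows, cols, blocks, bias_correct)
  Qinv <- safe_qinv(fm$Q)
  fit <- als_rank_fit(fm$xhat, Qinv, k - 1)
  w <- weights_from_fit(if (k == 1) fm$xhat else fit$E)
  df <- as.integer((1) * (R - k))          # (L-1-(k-1)) (R-1-(k-1))
  p <- stats::pchisq(fit$stat, df, lower.tail = FALSE)

  # delete-one-block jackknife of the whole fit, warm-started
  g <- fm$n_blocks
  n <- fm$n_snps
  tot <- colSums(fm$block_sums)
  wjack <- matrix(NA_real_, g, k)
  if (k > 1) {
    for (j in seq_len(g)) {
      xj <- (tot - fm$block_sums[j, ]) / (n - fm$block_n[j])
      fj <- als_rank_fit(matrix(xj, fm$p, fm$q), Qinv, k - 1,
                         init = list(A = fit$A, B = fit$B))
      wjack[j, ] <- weights_from_fit(fj$E)
    }
  } else wjack[] <- 1
  h <- n / fm$block_n
  tau <- h * matrix(w, g, k, byrow = TRUE) - (h - 1) * wjack
  theta_j <- g * w - colSums((1 - fm$block_n / n) * wjack)
  se <- sqrt(colMeans(sweep(tau, 2, theta_j)^2 / (h - 1)))

  structure(list(target = target, sources = sources, right = right,
                 weights = stats::setNames(as.vector(w), sources),
                 se = stats::setNames(se, sources),
                 p = p, stat = fit$stat, df = df,
                 feasible = all(w >= 0 & w <= 1),
                 n_snps = fm$n_snps, n_blocks = fm$n_blocks),
            class = "qpadm_fit")
}

#' @export
print.qpadm_fit <- function(x, ...) {
  cat(sprintf("qpAdm: %s = %s  (p = %.4g%s)\n", x$target,
              paste(x$sources, collapse = " + "), x$p,
              if (x$feasible) "" else ", INFEASIBLE weights"))
  tab <- data.frame(source = x$sources, weight = round(unname(x$weights), 4),
                    se = round(unname(x$se), 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.qpadm_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  chi2 = %.3f on %d df; %d SNPs, %d blocks\n",
              object$stat, object$df, object$n_snps, object$n_blocks))
  invisible(object)
}

#' Nested model comparison between a full and a reduced qpAdm model
#'
#' The reduced model drops one source and moves it into the right set, so
#' the two model chi-squares are comparable; their difference is referred
#' to a chi-square with the difference of the model degrees of freedom. A
#' small p means the dropped source is required.
#'
#' @param full \code{\link{qpadm_fit}} with k sources.
#' @param reduced \code{\link{qpadm_fit}} with k-1 sources and the excluded
#'   source appended to the right set.
#' @return The nested p-value.
#' @export
nested_p <- function(full, reduced) {
  stopifnot(inherits(full, "qpadm_fit"), inherits(reduced, "qpadm_fit"))
  dropped <- setdiff(full$sources, reduced$sources)
  if (length(dropped) != 1 || !all(reduced$sources %in% full$sources))
    stop("reduced model must drop exactly one source of the full model")
  if (!dropped %in% reduced$right)
    stop("the excluded source '", dropped,
         "' must be moved into the reduced model's right set")
  ddf <- reduced$df - full$df
  dstat <- max(reduced$stat - full$stat, 0)
  stats::pchisq(dstat, ddf, lower.tail = FALSE)
}

#' Rotating-outgroup qpAdm model search
#'
#' For each candidate, fits a model with the candidate added to the
#' sources while every other candidate is appended to the right set
#' ("rotated out"), and ranks the resulting models by p-value. This is the
#' standard scheme for picking the best proxy source among several related
#' candidates.
#'
#' @inheritParams qpadm_fit
#' @param sources_core Sources present in every model (may be empty).
#' @param candidates Candidate source populations to rotate.
#' @param base_right Base right set.
#' @return Data frame, one row per candidate, with weights for the
#'   candidate, model p and feasibility, ranked by descending p; the fits
#'   themselves are in \code{attr(, "fits")}.
#' @export
rotate_candidates <- function(x, target, sources_core, candidates,
                              base_right, blocks = NULL,
                              bias_correct = TRUE) {
  if (!length(candidates)) stop("empty candidate list")
  gf <- as_group_freq(x)
  if (is.null(blocks)) blocks <- make_blocks(gf$snp)
  fits <- lapply(candidates, function(cand) {
    qpadm_fit(gf, target, c(sources_core, cand),
              c(base_right, setdiff(candidates, cand)), blocks,
              bias_correct)
  })
  tab <- do.call(rbind, lapply(seq_along(candidates), function(i) {
    f <- fits[[i]]
    data.frame(candidate = candidates[i],
               weight = unname(f$weights[length(f$weights)]),
               se = unname(f$se[length(f$se)]),
               p = f$p, feasible = f$feasible, stringsAsFactors = FALSE)
  }))
  ord <- order(-tab$p)
  tab <- tab[ord, , drop = FALSE]
  attr(tab, "fits") <- fits[ord]
  tab
}
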
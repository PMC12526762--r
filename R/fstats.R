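#' Bin SNPs into genetic-distance blocks for the jackknife
#'
#' SNPs are binned per chromosome into consecutive half-open windows of
#' \code{blgsize} Morgans, anchored at the chromosome's first SNP; empty
#' blocks are dropped and indices renumbered contiguously. Blocks never span
#' chromosomes.
#'
#' @param snp snp table (columns \code{chrom}, \code{genetic_pos}) or an
#'   \code{\link{eigenstrat}} object.
#' @param blgsize Block length in Morgans (default 0.05, i.e. 5 cM).
#' @return An object of class \code{"block_spec"}: list with \code{block}
#'   (per-SNP block index), \code{n_blocks}, \code{counts} (SNPs per
#'   block), \code{chrom} (chromosome of each block) and \code{blgsize}.
#' @export
make_blocks <- function(snp, blgsize = 0.05) {
  if (inherits(snp, "eigenstrat")) snp <- snp$snp
  stopifnot(blgsize > 0)
  chrom <- as.character(snp$chrom)
  idx_in_chrom <- integer(nrow(snp))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    g <- snp$genetic_pos[i]
    idx_in_chrom[i] <- floor((g - min(g)) / blgsize)
  }
  key <- paste(chrom, idx_in_chrom)
  ukey <- unique(key)
  block <- match(key, ukey)
  counts <- tabulate(block, nbins = length(ukey))
  structure(list(block = block, n_blocks = length(ukey), counts = counts,
                 chrom = sub(" .*$", "", ukey), blgsize = blgsize),
            class = "block_spec")
}

# Resolve a group_freq object from an eigenstrat dataset or pass through.
as_group_freq <- function(x) {
  if (inherits(x, "group_freq")) x
  else if (inherits(x, "eigenstrat")) group_allele_stats(x)
  else stop("expected an 'eigenstrat' or 'group_freq' object")
}

# Per-SNP f4 product terms (pa - pb)(pc - pd) with finite-sample bias
# correction. Sampling noise in a group's frequency estimate appears in
# both factors whenever a population repeats across the two differences;
# the unbiased correction subtracts hat(p)(1-hat(p))/(n-1) with the sign
# of the induced covariance. SNPs where any group is uncalled (or where a
# repeated group has < 2 observed alleles, so the correction is undefined)
# are NA.
f4_terms <- function(gf, a, b, c, d, bias_correct = TRUE) {
  for (pop in c(a, b, c, d))
    if (!pop %in% gf$groups) stop("unknown group: ", pop)
  pa <- gf$freq[, a]; pb <- gf$freq[, b]
  pc_ <- gf$freq[, c]; pd_ <- gf$freq[, d]
  term <- (pa - pb) * (pc_ - pd_)
  if (bias_correct) {
    vhat <- function(pop) {
      n <- gf$total[, pop]
      v <- gf$freq[, pop] * (1 - gf$freq[, pop]) / (n - 1)
      v[n < 2] <- NA_real_
      v
    }
    if (a == c) term <- term - vhat(a)
    if (a == d) term <- term + vhat(a)
    if (b == c) term <- term + vhat(b)
    if (b == d) term <- term - vhat(b)
  }
  # a == b or c == d: one factor is identically zero, term must be exact 0
  if (a == b || c == d) {
    term <- rep(0, nrow(gf$freq))
    usable <- !is.na(gf$freq[, a]) & !is.na(gf$freq[, b]) &
      !is.na(gf$freq[, c]) & !is.na(gf$freq[, d])
    term[!usable] <- NA_real_
  }
  term
}

# Weighted delete-one-block jackknife for a ratio-of-sums estimator.
# block_sums/block_n: per-block sums of terms and SNP counts.
weighted_jackknife <- function(block_sums, block_n) {
  use <- block_n > 0
  block_sums <- block_sums[use]; block_n <- block_n[use]
  g <- length(block_n)
  if (g < 2) stop("insufficient blocks for the jackknife (need >= 2)")
  n <- sum(block_n); S <- sum(block_sums)
  est <- S / n
  loo <- (S - block_sums) / (n - block_n)
  h <- n / block_n
  tau <- h * est - (h - 1) * loo
  theta_j <- g * est - sum((1 - block_n / n) * loo)
  var_j <- mean((tau - theta_j)^2 / (h - 1))
  list(est = est, se = sqrt(var_j), n_blocks = g, n_snps = n)
}

fstat_result <- function(kind, pops, jk) {
  structure(list(kind = kind, pops = pops, est = jk$est, se = jk$se,
                 z = if (jk$se > 0) jk$est / jk$se else NA_real_,
                 n_snps = jk$n_snps, n_blocks = jk$n_blocks),
            class = "fstat")
}

#' @export
print.fstat <- function(x, ...) {
  cat(sprintf("%s(%s) = %.6g  SE = %.3g  Z = %.2f  (%d SNPs, %d blocks)\n",
              x$kind, paste(x$pops, collapse = ", "), x$est, x$se, x$z,
              x$n_snps, x$n_blocks))
  invisible(x)
}

fstat_from_terms <- function(kind, pops, term, blocks) {
  usable <- !is.na(term)
  if (!any(usable)) stop("no usable SNPs for ", kind)
  bs <- rowsum(term[usable], blocks$block[usable])
  bn <- as.vector(table(factor(blocks$block[usable],
                               levels = sort(unique(blocks$block[usable])))))
  jk <- weighted_jackknife(as.vector(bs), bn)
  fstat_result(kind, pops, jk)
}

#' f4 statistic with block-jackknife standard error
#'
#' Per-SNP term (p_a - p_b)(p_c - p_d) averaged over SNPs where all four
#' groups have data; the standard error comes from a weighted
#' delete-one-block jackknife over genetic-distance blocks, and Z is the
#' estimate in SE units. A positive f4(a,b;c,d) indicates excess allele
#' sharing between a and c (equivalently b and d).
#'
#' @param x An \code{\link{eigenstrat}} dataset or a \code{group_freq}
#'   table from \code{\link{group_allele_stats}}.
#' @param a,b,c,d Group labels.
#' @param blocks A \code{\link{make_blocks}} result (computed at the 5 cM
#'   default when omitted and \code{x} is a dataset).
#' @param bias_correct Subtract finite-sample sampling-variance terms when
#'   a group repeats across the two differences (needed for unbiased f2/f3
#'   and repeated-outgroup f4 configurations).
#' @return An object of class \code{"fstat"}.
#' @export
f4 <- function(x, a, b, c, d, blocks = NULL, bias_correct = TRUE) {
  gf <- as_group_freq(x)
  if (is.null(blocks)) blocks <- make_blocks(gf$snp)
  term <- f4_terms(gf, a, b, c, d, bias_correct)
  fstat_from_terms("f4", c(a, b, c, d), term, blocks)
}

#' f2 statistic (branch length between two groups)
#'
#' Computed as f4(a,b;a,b) with the finite-sample corrections for both
#' groups, making the estimator unbiased for the squared frequency
#' difference of the true population frequencies.
#'
#' @inheritParams f4
#' @return An object of class \code{"fstat"}.
#' @export
f2 <- function(x, a, b, blocks = NULL, bias_correct = TRUE) {
  gf <- as_group_freq(x)
  if (is.null(blocks)) blocks <- make_blocks(gf$snp)
  term <- f4_terms(gf, a, b, a, b, bias_correct)
  fstat_from_terms("f2", c(a, b), term, blocks)
}

#' f3 statistic (shared drift; admixture test)
#'
#' Per-SNP term (p_o - p_a)(p_o - p_b). With \code{bias_correct} the
#' finite-sample heterozygosity correction p_o(1-p_o)/(n_o - 1) is
#' subtracted for the repeated group o. In outgroup-f3 form, larger values
#' mean more drift shared between a and b relative to the outgroup o.
#'
#' @inheritParams f4
#' @param o Outgroup (or admixture-test target) label.
#' @return An object of class \code{"fstat"}.
#' @export
f3 <- function(x, o, a, b, blocks = NULL, bias_correct = TRUE) {
  gf <- as_group_freq(x)
  if (is.null(blocks)) blocks <- make_blocks(gf$snp)
  term <- f4_terms(gf, o, a, o, b, bias_correct)
  fstat_from_terms("f3", c(o, a, b), term, blocks)
}

#' Outgroup-f3 affinity scan
#'
#' Computes f3(o; target, ref) for every reference and returns the table
#' ranked by descending shared drift with the target.
#'
#' @inheritParams f3
#' @param target Target group.
#' @param refs Character vector of reference groups.
#' @return Data frame with one row per reference (columns \code{ref},
#'   \code{est}, \code{se}, \code{z}, \code{n_snps}, \code{n_blocks}),
#'   sorted by descending estimate.
#' @export
outgroup_f3_scan <- function(x, o, target, refs, blocks = NULL,
                             bias_correct = TRUE) {
  gf <- as_group_freq(x)
  if (is.null(blocks)) blocks <- make_blocks(gf$snp)
  rows <- lapply(refs, function(r) {
    fs <- f3(gf, o, target, r, blocks, bias_correct)
    data.frame(ref = r, est = fs$est, se = fs$se, z = fs$z,
               n_snps = fs$n_snps, n_blocks = fs$n_blocks,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$est), , drop = FALSE]
}
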
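# shared fixture builders (everything is generated in code)

tiny_dataset <- function(n_snps = 50, n_samp = 3, seed = 1,
                         mode = "diploid") {
  set.seed(seed)
  codes <- if (mode == "diploid") c(0L, 1L, 2L, 9L) else c(0L, 2L, 9L)
  g <- matrix(sample(codes, n_snps * n_samp, replace = TRUE),
              n_snps, n_samp)
  ind <- data.frame(sample_id = paste0("s", seq_len(n_samp)), sex = "U",
                    group = rep_len(c("g1", "g2"), n_samp),
                    stringsAsFactors = FALSE)
  eigenstrat(g, synthetic_panel(n_snps, n_chrom = 2), ind, mode = mode)
}

# simple 4-leaf tree: O outgroup to the clade ((A,B),C)
toy_graph <- function() {
  admixture_graph(data.frame(
    from = c("R", "R", "N", "N", "N2", "N2"),
    to = c("O", "N", "C", "N2", "A", "B"),
    f = c(0.10, 0.04, 0.06, 0.03, 0.05, 0.05)))
}

# split one population's samples into two pseudo-groups (null cladality)
split_group <- function(ds, pop, new_label) {
  grp <- ds$ind$group
  idx <- which(grp == pop)
  grp[idx[seq_len(floor(length(idx) / 2))]] <- new_label
  grp
}

# SNP-wise simulator of pseudo-haploid relative pairs (no linkage needed
# for PMR, which is a per-SNP statistic)
simulate_pmr_pair <- function(relation, n_snps, seed) {
  set.seed(seed)
  p <- stats::runif(n_snps, 0.05, 0.95)
  draw <- function() stats::rbinom(n_snps, 1, p)
  pick <- function(a, b) ifelse(stats::rbinom(n_snps, 1, 0.5) == 1, a, b)
  ph <- function(a, b) 2L * pick(a, b)
  f1 <- draw(); f2_ <- draw()
  switch(relation,
    identical = {
      a <- cbind(f1, f2_); list(g1 = ph(a[, 1], a[, 2]),
                                g2 = ph(a[, 1], a[, 2]), p = p)
    },
    first = {  # parent-offspring
      m1 <- draw(); m2 <- draw()
      child <- cbind(pick(f1, f2_), pick(m1, m2))
      list(g1 = ph(f1, f2_), g2 = ph(child[, 1], child[, 2]), p = p)
    },
    second = { # half-siblings via shared father
      m1 <- draw(); m2 <- draw(); m3 <- draw(); m4 <- draw()
      c1 <- cbind(pick(f1, f2_), pick(m1, m2))
      c2 <- cbind(pick(f1, f2_), pick(m3, m4))
      list(g1 = ph(c1[, 1], c1[, 2]), g2 = ph(c2[, 1], c2[, 2]), p = p)
    },
    unrelated = {
      u1 <- draw(); u2 <- draw()
      list(g1 = ph(f1, f2_), g2 = ph(u1, u2), p = p)
    })
}
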
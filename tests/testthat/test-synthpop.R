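test_that("graph constructor enforces structure", {
  expect_error(admixture_graph(data.frame(from = c("R", "S"),
                                          to = c("A", "A"),
                                          f = c(0.1, 0.1))),
               "more than one incoming")
  expect_error(admixture_graph(data.frame(from = c("A", "B"),
                                          to = c("B", "A"),
                                          f = c(0.1, 0.1))),
               "root|cycle")
  expect_error(admixture_graph(data.frame(from = "R", to = "A", f = 0.9)),
               "drift")
})

test_that("zero drift everywhere copies the ancestor exactly", {
  gr <- admixture_graph(data.frame(from = c("R", "R", "N", "N"),
                                   to = c("A", "N", "B", "C"),
                                   f = 0))
  fr <- simulate_frequencies(gr, 500, seed = 3)
  expect_equal(fr[, "A"], fr[, "B"])
  expect_equal(fr[, "A"], fr[, "C"])
})

test_that("Balding-Nichols drift has mean p and variance F p(1-p)", {
  n <- 1e5
  f <- 0.07
  gr <- admixture_graph(data.frame(from = "R", to = "A", f = f))
  fr <- simulate_frequencies(gr, n, seed = 4, keep_internal = TRUE)
  p0 <- fr[, "R"]; p1 <- fr[, "A"]
  d <- p1 - p0
  # conditional mean zero: 3 SE on the average deviation
  se_mean <- stats::sd(d) / sqrt(n)
  expect_lt(abs(mean(d)), 3 * se_mean)
  # conditional variance F p (1-p): compare standardized squares to 1
  r <- d^2 / (f * p0 * (1 - p0))
  expect_lt(abs(mean(r) - 1), 3 * stats::sd(r) / sqrt(n))
})

test_that("an alpha = 1 admixture node copies parent1", {
  gr <- admixture_graph(
    data.frame(from = c("R", "R"), to = c("A", "B"), f = c(0.05, 0.05)),
    data.frame(node = "M", parent1 = "A", parent2 = "B", alpha = 1))
  fr <- simulate_frequencies(gr, 200, seed = 5)
  expect_equal(fr[, "M"], pmin(pmax(fr[, "A"], 0.001), 0.999))
})

test_that("expected f-statistics obey the graph trivials", {
  gr <- toy_graph()
  expect_equal(expected_f2(gr, "A", "A"), 0)
  # (A,B) vs (O,C): the two differences share no drift edge
  expect_equal(expected_f4(gr, "A", "B", "O", "C"), 0)
  expect_equal(expected_f4(gr, "A", "B", "C", "O"), 0)
  # f3(O; A, B) equals the shared drift between O and the (A,B) clade root
  expect_gt(expected_f3(gr, "O", "A", "B"), 0)
})

test_that("expected f3 matches a Monte-Carlo estimate within 3 SE", {
  gr <- toy_graph()
  n <- 2e5
  fr <- simulate_frequencies(gr, n, seed = 6)
  term <- (fr[, "O"] - fr[, "A"]) * (fr[, "O"] - fr[, "B"])
  mc_se <- stats::sd(term) / sqrt(n)
  expect_lt(abs(mean(term) - expected_f3(gr, "O", "A", "B")), 3 * mc_se)
})

test_that("genotype sampling hits its marginal distribution", {
  freq <- cbind(P = rep(0, 100))
  ds <- sample_genotypes(freq, 4, "diploid", seed = 7, n_chrom = 2)
  expect_true(all(ds$geno == 0L))

  freq2 <- cbind(P = runif(100))
  ds2 <- sample_genotypes(freq2, 3, "pseudohaploid", missing_rate = 1,
                          seed = 8, n_chrom = 2)
  expect_true(all(ds2$geno == 9L))

  # empirical frequency within 3 binomial SEs at n = 500 samples
  p <- 0.37
  ds3 <- sample_genotypes(cbind(P = rep(p, 50)), 500, "diploid", seed = 9,
                          n_chrom = 1)
  phat <- mean(ds3$geno) / 2
  se <- sqrt(p * (1 - p) / (2 * 500 * 50))
  expect_lt(abs(phat - p), 3 * se)

  # pseudo-haploid draws never produce heterozygotes
  ds4 <- sample_genotypes(freq2, 5, "pseudohaploid", seed = 10, n_chrom = 2)
  expect_true(all(ds4$geno %in% c(0L, 2L)))
})

test_that("ancestry tracts follow the Markov single-pulse model", {
  t_adm <- 8; alpha <- 0.3
  panel <- synthetic_panel(2000, n_chrom = 2, chrom_length = 1)
  pa <- rep(0.9, 2000); pb <- rep(0.1, 2000)
  sim <- simulate_admixed_haplotypes(panel, pa, pb, t_adm, alpha,
                                     n_hap = 200, seed = 11)
  a <- sim$ancestry
  # stationary mean
  expect_lt(abs(mean(a) - alpha), 3 * sqrt(alpha * (1 - alpha) / 200))
  # autocovariance alpha(1-alpha) e^(-T d) at a few distances
  ch1 <- which(panel$chrom == "1")
  g <- panel$genetic_pos[ch1]
  for (d in c(0.05, 0.1, 0.2)) {
    i <- which.min(abs(g - 0.2)); j <- which.min(abs(g - 0.2 - d))
    prod_dev <- (a[ch1[i], ] - alpha) * (a[ch1[j], ] - alpha)
    expected <- alpha * (1 - alpha) * exp(-t_adm * d)
    se <- stats::sd(prod_dev) / sqrt(ncol(a))
    expect_lt(abs(mean(prod_dev) - expected), 3 * se)
  }
  # switch count per Morgan ~ 2 alpha (1-alpha) T
  nsw <- vapply(seq_len(ncol(a)), function(h)
    sum(diff(a[ch1, h]) != 0), numeric(1))
  exp_sw <- 2 * alpha * (1 - alpha) * t_adm
  expect_lt(abs(mean(nsw) - exp_sw), 3 * stats::sd(nsw) / sqrt(length(nsw)))

  # alpha = 1 is all source A
  sim1 <- simulate_admixed_haplotypes(panel, pa, pb, t_adm, 1, 5, seed = 12)
  expect_true(all(sim1$ancestry == 1L))
  expect_true(all(sim1$tracts$source == "A"))
})

test_that("tract boundaries agree with per-SNP ancestry", {
  panel <- synthetic_panel(500, n_chrom = 1, chrom_length = 1)
  sim <- simulate_admixed_haplotypes(panel, rep(0.8, 500), rep(0.2, 500),
                                     10, 0.5, 3, seed = 13)
  tr <- sim$tracts[sim$tracts$hap == 2, ]
  g <- panel$genetic_pos
  for (r in seq_len(nrow(tr))) {
    inside <- g >= tr$start[r] & g < tr$end[r]
    if (any(inside))
      expect_true(all(sim$ancestry[inside, 2] ==
                        as.integer(tr$source[r] == "A")))
  }
})

test_that("simulated pileups reflect genotypes and damage settings", {
  panel <- synthetic_panel(300, n_chrom = 2)
  panel$ref <- rep(c("C", "A", "G"), 100)
  panel$alt <- rep(c("T", "C", "A"), 100)
  g <- rep(c(0L, 2L, 1L), 100)
  pu <- simulate_pileup(g, panel, depth_mean = 4, seed = 14)
  # damage-free reads at homozygous sites match the genotype allele
  hom <- pu$pos %in% panel$physical_pos[g != 1L]
  site <- match(pu$pos, panel$physical_pos)
  want <- ifelse(g[site] == 2L, panel$alt[site], panel$ref[site])
  expect_true(all(pu$base[hom] == want[hom]))

  # depth 0 -> empty stream
  pu0 <- simulate_pileup(g, panel, depth_mean = 0, seed = 15)
  expect_identical(nrow(pu0), 0L)

  # recovered 5' damage rate within 3 binomial SDs of the input
  rate <- 0.3
  panelC <- synthetic_panel(3000, n_chrom = 2)
  panelC$ref <- "C"; panelC$alt <- "T"
  puC <- simulate_pileup(rep(0L, 3000), panelC, depth_mean = 3,
                         damage_5p = c(rate), read_len = 50, seed = 16)
  at0 <- puC$d5 == 0 & puC$strand == "+"
  n0 <- sum(at0)
  est <- mean(puC$base[at0] == "T")
  expect_lt(abs(est - rate), 3 * sqrt(rate * (1 - rate) / n0))
})

test_that("generators are reproducible from (spec, seed)", {
  gr <- toy_graph()
  expect_identical(simulate_frequencies(gr, 100, seed = 17),
                   simulate_frequencies(gr, 100, seed = 17))
  fr <- simulate_frequencies(gr, 100, seed = 17)
  expect_identical(sample_genotypes(fr, 3, "diploid", seed = 18)$geno,
                   sample_genotypes(fr, 3, "diploid", seed = 18)$geno)
  panel <- synthetic_panel(100, 2)
  s1 <- simulate_admixed_haplotypes(panel, fr[, 1], fr[, 2], 5, 0.4, 4,
                                    seed = 19)
  s2 <- simulate_admixed_haplotypes(panel, fr[, 1], fr[, 2], 5, 0.4, 4,
                                    seed = 19)
  expect_identical(s1$haplotypes, s2$haplotypes)
})

test_that("random graphs are valid and have the requested leaves", {
  for (i in 1:10) {
    gr <- random_admixture_graph(n_leaves = 5 + i %% 4,
                                 n_admix = i %% 3, seed = i)
    expect_s3_class(gr, "admixture_graph")
    expect_gte(length(gr$leaves), 5)
    fr <- simulate_frequencies(gr, 50, seed = i)
    expect_true(all(fr >= 0 & fr <= 1))
  }
})
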
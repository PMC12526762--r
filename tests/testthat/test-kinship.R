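
test_that("PMR trivials: identical vectors, disjoint masks, x0 floor", {
  panel <- synthetic_panel(5000, n_chrom = 4)
  g <- matrix(2L * rbinom(5000 * 4, 1, 0.4), 5000, 4)
  g[, 2] <- g[, 1]                         # identical calls
  g[1:2500, 3] <- 9L; g[2501:5000, 4] <- 9L  # disjoint masks
  ds <- eigenstrat(g, panel,
                   data.frame(sample_id = paste0("s", 1:4), sex = "U",
                              group = "g"), "pseudohaploid")
  tab <- pmr_all_pairs(ds, min_overlap = 100)
  p12 <- tab[tab$id1 == "s1" & tab$id2 == "s2", ]
  expect_identical(p12$n_mismatch, 0)
  expect_equal(p12$pmr, 0)
  p34 <- tab[tab$id1 == "s3" & tab$id2 == "s4", ]
  expect_identical(p34$n_overlap, 0)
  expect_false(p34$reliable)
  expect_true(is.na(p34$pmr))
  # diploid codes are rejected
  expect_error(pmr_all_pairs(tiny_dataset(10, 2)), "pseudo-haploid")
})

test_that("PMR ratios converge to 1/2, 3/4, 7/8 of baseline", {
  n <- 1e5
  pairs <- list(identical = 0.5, first = 0.75, second = 0.875)
  # background level from unrelated draws with the same frequencies
  for (nm in names(pairs)) {
    pr <- simulate_pmr_pair(nm, n, seed = match(nm, names(pairs)) + 60)
    un <- simulate_pmr_pair("unrelated", n, seed = match(nm, names(pairs)) + 60)
    pm <- mean(pr$g1 != pr$g2)
    x0 <- mean(un$g1 != un$g2)
    ratio <- pm / x0
    se <- sqrt(pm * (1 - pm) / n) / x0 * 3  # 3 binomial SDs, plus x0 noise
    se <- se + 3 * sqrt(x0 * (1 - x0) / n) / x0 * pairs[[nm]]
    expect_lt(abs(ratio - pairs[[nm]]), se)
  }
})

test_that("degree classification applies the midpoint cutoffs", {
  tab <- data.frame(id1 = "a", id2 = letters[2:6],
                    n_overlap = 1e5, n_mismatch = 0,
                    pmr = c(0.10, 0.15, 0.175, 0.199, 0.25),
                    reliable = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  out <- classify_degree(tab, x0 = 0.2)
  expect_identical(out$degree,
                   c("identical", "first", "second", "unrelated", NA))
})

test_that("merging follows the alternating-block rule", {
  segs <- data.frame(chrom = "1", start_cm = c(10, 30, 35),
                     end_cm = c(30, 35, 50),
                     type = c("IBD1", "IBD2", "IBD1"),
                     n_snps = c(7000, 1750, 5250))
  m <- merge_adjacent_segments(segs)
  expect_identical(nrow(m), 1L)
  expect_equal(m$start_cm, 10)
  expect_equal(m$end_cm, 50)
  expect_equal(m$n_snps, 14000)
  expect_equal(m$ibd2_cm, 5)

  # single segment unchanged; different chromosomes never merge
  one <- merge_adjacent_segments(segs[1, ])
  expect_equal(one$end_cm - one$start_cm, 20)
  segs2 <- segs; segs2$chrom <- c("1", "2", "2")
  m2 <- merge_adjacent_segments(segs2)
  expect_identical(nrow(m2), 2L)

  # idempotence: merging merged blocks changes nothing
  m_again <- merge_adjacent_segments(
    data.frame(chrom = m$chrom, start_cm = m$start_cm, end_cm = m$end_cm,
               type = "IBD1", n_snps = m$n_snps))
  expect_equal(m_again$start_cm, m$start_cm)
  expect_equal(m_again$end_cm, m$end_cm)
})

test_that("length and density filters keep/drop as specified", {
  blocks <- data.frame(chrom = "1",
                       start_cm = c(0, 100, 200),
                       end_cm = c(10, 120, 220),
                       n_snps = c(3000, 4000, 5000),
                       ibd2_cm = 0)
  f <- filter_segments(blocks)
  # 10 cM (too short), 20 cM at 200/cM (too sparse), 20 cM at 250/cM (kept)
  expect_identical(nrow(f), 1L)
  expect_equal(f$start_cm, 200)
  # filter is idempotent
  expect_identical(nrow(filter_segments(f)), 1L)
})

test_that("crossover count conserves map length for any interference", {
  set.seed(71)
  for (pars in list(c(7.6, 0.1), c(3, 0.5), c(1, 1))) {
    m <- interference_model(nu = pars[1], p_esc = pars[2])
    L <- 2.2
    n <- 4000
    counts <- vapply(seq_len(n), function(i)
      length(crossover_positions(L, m)), numeric(1))
    expect_lt(abs(mean(counts) - L), 3 * stats::sd(counts) / sqrt(n))
  }
})

test_that("nu = 1, p_esc = 1 reduces to a Poisson process", {
  set.seed(72)
  m <- interference_model(nu = 1, p_esc = 1)
  xo <- crossover_positions(1e4, m)
  iv <- diff(xo)
  expect_gt(suppressWarnings(stats::ks.test(iv, "pexp", 1))$p.value, 0.01)
})

test_that("interference tightens the spacing distribution", {
  set.seed(73)
  cv <- function(nu) {
    m <- interference_model(nu = nu, p_esc = 0)
    iv <- diff(crossover_positions(3000, m))
    stats::sd(iv) / mean(iv)
  }
  expect_lt(cv(10), cv(1))   # strong interference -> more regular spacing
})

test_that("relationship envelopes match Mendelian sharing expectations", {
  m <- interference_model()
  envs <- lapply(c("half-siblings", "double first cousins",
                   "grandparent-grandchild"), function(r)
    simulate_relationship_ibd(r, m, n_replicates = 40, seed = 74))
  names(envs) <- c("hs", "dfc", "gp")
  # half-siblings share half the genome IBD1 pre-filter
  expect_lt(abs(mean(envs$hs$summaries$raw_ibd1_frac) - 0.5), 0.02)
  # double first cousins carry ~1/16 IBD2 pre-filter
  expect_lt(abs(mean(envs$dfc$summaries$raw_ibd2_frac) - 1 / 16), 0.015)
  # grandparent pairs: fewer and longer blocks than half-siblings
  expect_lt(mean(envs$gp$summaries$n_blocks),
            mean(envs$hs$summaries$n_blocks))
  expect_gt(mean(envs$gp$summaries$total_cm / envs$gp$summaries$n_blocks),
            mean(envs$hs$summaries$total_cm / envs$hs$summaries$n_blocks))
})

test_that("second-degree classification ranks, excludes and validates", {
  m <- interference_model()
  rels <- c("grandparent-grandchild", "avuncular", "half-siblings",
            "double first cousins")
  envs <- lapply(rels, simulate_relationship_ibd, model = m,
                 n_replicates = 40, seed = 75)
  # an observation equal to an envelope mean has distance ~0 there
  s <- envs[[3]]$summaries
  obs <- list(n_blocks = mean(s$n_blocks), total_cm = mean(s$total_cm),
              ibd2_cm = 1)
  out <- classify_second_degree(obs, envs)
  expect_lt(out$distance[out$relationship == "half-siblings"], 1e-10)

  # zero IBD2 with counts in the avuncular/half-sib overlap excludes DFC
  obs0 <- list(n_blocks = mean(s$n_blocks), total_cm = mean(s$total_cm),
               ibd2_cm = 0)
  out0 <- classify_second_degree(obs0, envs)
  dfc <- out0[out0$relationship == "double first cousins", ]
  expect_true(dfc$excluded)
  expect_identical(dfc$reason, "no IBD2 observed")

  # summaries drawn from an envelope are mostly classified back to it
  fresh <- simulate_relationship_ibd("half-siblings", m,
                                     n_replicates = 25, seed = 76)
  hit <- vapply(seq_len(25), function(i) {
    ss <- fresh$summaries[i, ]
    classify_second_degree(
      list(n_blocks = ss$n_blocks, total_cm = ss$total_cm,
           ibd2_cm = ss$ibd2_cm), envs)$relationship[1]
  }, character(1))
  expect_gte(mean(hit == "half-siblings"), 0.5)
})

test_that("IBD segment TSV reader validates its contract", {
  path <- file.path(withr::local_tempdir(), "ibd.tsv")
  seg <- data.frame(pair_id = "a-b", chrom = "1", start_cm = 10,
                    end_cm = 40, type = "IBD1", n_snps = 9000)
  write.table(seg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  rd <- read_ibd_segments(path)
  expect_equal(rd$end_cm, 40)
  seg$type <- "IBD3"
  write.table(seg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_ibd_segments(path), "IBD1 or IBD2")
})

test_that("pseudohaploidize halves heterozygotes reproducibly", {
  ds <- tiny_dataset(2000, 4, seed = 77)
  ph1 <- pseudohaploidize(ds, seed = 7)
  ph2 <- pseudohaploidize(ds, seed = 7)
  expect_identical(ph1$geno, ph2$geno)
  expect_true(all(ph1$geno %in% c(0L, 2L, 9L)))
  het <- ds$geno == 1L
  expect_lt(abs(mean(ph1$geno[het] == 2L) - 0.5),
            3 * sqrt(0.25 / sum(het)))
})
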
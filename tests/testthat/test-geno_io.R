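test_that("write/read round trip is the identity, including missing codes", {
  ds <- tiny_dataset(5, 3)
  prefix <- file.path(withr::local_tempdir(), "rt")
  write_eigenstrat(ds, prefix)
  ds2 <- read_eigenstrat(prefix)
  expect_identical(unname(ds2$geno), unname(ds$geno))
  expect_equal(ds2$snp$genetic_pos, ds$snp$genetic_pos, tolerance = 1e-7)
  expect_identical(ds2$snp$physical_pos, ds$snp$physical_pos)
  expect_identical(ds2$ind$sample_id, ds$ind$sample_id)
  # "9" preserved literally in the file
  lines <- readLines(paste0(prefix, ".geno"))
  expect_true(any(grepl("9", lines, fixed = TRUE)))
})

test_that("round trip holds on random dataset shapes (property)", {
  dir <- withr::local_tempdir()
  for (i in 1:100) {
    set.seed(i)
    ds <- tiny_dataset(sample(1:40, 1), sample(1:6, 1), seed = i,
                       mode = sample(c("diploid", "pseudohaploid"), 1))
    prefix <- file.path(dir, paste0("p", i))
    write_eigenstrat(ds, prefix)
    ds2 <- read_eigenstrat(prefix)
    expect_identical(unname(ds2$geno), unname(ds$geno))
    expect_equal(ds2$snp$genetic_pos, ds$snp$genetic_pos,
                 tolerance = 1e-6)
  }
})

test_that("geno digits decode positionally and bad input is located", {
  dir <- withr::local_tempdir()
  writeLines(c("029"), file.path(dir, "x.geno"))
  writeLines("rs1\t1\t0.01\t100\tA\tG", file.path(dir, "x.snp"))
  writeLines(c("a\tU\tg", "b\tU\tg", "c\tU\tg"), file.path(dir, "x.ind"))
  ds <- read_eigenstrat(file.path(dir, "x"))
  expect_identical(as.vector(ds$geno), c(0L, 2L, 9L))
  expect_identical(ds$mode, "pseudohaploid")

  # row with wrong length names the row
  writeLines(c("02"), file.path(dir, "x.geno"))
  expect_error(read_eigenstrat(file.path(dir, "x")), "row 1")

  # invalid digit carries coordinates
  writeLines(c("035"), file.path(dir, "x.geno"))
  expect_error(read_eigenstrat(file.path(dir, "x")), "row 1.*column 2")

  # packed dialect recognized and refused
  con <- file(file.path(dir, "x.geno"), "wb")
  writeBin(charToRaw("GENO packed"), con); close(con)
  expect_error(read_eigenstrat(file.path(dir, "x")), "packed")
})

test_that("genetic positions honour the cM unit flag", {
  dir <- withr::local_tempdir()
  writeLines("0", file.path(dir, "u.geno"))
  writeLines("rs1\t1\t1.5\t100\tA\tG", file.path(dir, "u.snp"))
  writeLines("a\tU\tg", file.path(dir, "u.ind"))
  m <- read_eigenstrat(file.path(dir, "u"))
  cm <- read_eigenstrat(file.path(dir, "u"), genetic_unit = "cM")
  expect_equal(m$snp$genetic_pos, 1.5)
  expect_equal(cm$snp$genetic_pos, 0.015)
})

test_that("intersect keeps matched SNPs, flips swapped alleles, drops rest", {
  snp <- data.frame(snp_id = paste0("rs", 1:3), chrom = "1",
                    genetic_pos = c(0.01, 0.02, 0.03),
                    physical_pos = c(100L, 200L, 300L),
                    ref = c("A", "A", "A"), alt = c("G", "G", "G"))
  ind_a <- data.frame(sample_id = "a1", sex = "U", group = "ga")
  ind_b <- data.frame(sample_id = "b1", sex = "U", group = "gb")
  a <- eigenstrat(matrix(c(0L, 1L, 2L), 3), snp, ind_a, "diploid")
  snp_b <- snp
  snp_b$ref[2] <- "G"; snp_b$alt[2] <- "A"      # swapped coding
  snp_b$alt[3] <- "C"                           # inconsistent
  b <- eigenstrat(matrix(c(2L, 2L, 0L), 3), snp_b, ind_b, "diploid")
  expect_message(m <- intersect_datasets(a, b), "dropped 1")
  expect_identical(nrow(m$snp), 2L)
  expect_identical(attr(m, "n_dropped"), 1L)
  # flipped site: B's code 2 becomes 0
  expect_identical(unname(m$geno[2, ]), c(1L, 0L))

  # identical panels: merged panel equals input
  m2 <- intersect_datasets(a, a)
  expect_identical(m2$snp$snp_id, a$snp$snp_id)

  # symmetric SNP content
  m_ab <- intersect_datasets(a, b)
  m_ba <- intersect_datasets(b, a)
  expect_identical(m_ab$snp$physical_pos, m_ba$snp$physical_pos)

  # zero overlap errors
  snp_c <- snp; snp_c$physical_pos <- c(1000L, 2000L, 3000L)
  cc <- eigenstrat(matrix(c(0L, 0L, 0L), 3), snp_c, ind_b, "diploid")
  expect_error(intersect_datasets(a, cc), "no overlapping")
})

test_that("flip preserves missing codes", {
  snp <- data.frame(snp_id = "rs1", chrom = "1", genetic_pos = 0.01,
                    physical_pos = 100L, ref = "A", alt = "G")
  a <- eigenstrat(matrix(0L, 1), snp,
                  data.frame(sample_id = "a", sex = "U", group = "g"),
                  "diploid")
  snp_b <- snp; snp_b$ref <- "G"; snp_b$alt <- "A"
  b <- eigenstrat(matrix(9L, 1), snp_b,
                  data.frame(sample_id = "b", sex = "U", group = "g"),
                  "diploid")
  m <- intersect_datasets(a, b)
  expect_identical(unname(m$geno[1, 2]), 9L)
})

test_that("group allele stats follow the ploidy-aware counting convention", {
  snp <- synthetic_panel(3, n_chrom = 1)
  # one diploid het
  d <- eigenstrat(matrix(c(1L, 0L, 9L), 3),
                  data.frame(sample_id = "a", sex = "U", group = "g"),
                  snp = snp, mode = "diploid")
  gf <- group_allele_stats(d)
  expect_equal(unname(gf$freq[1, "g"]), 0.5)
  expect_equal(unname(gf$total[1, "g"]), 2)
  expect_true(is.na(gf$freq[3, "g"]))   # all missing -> flagged missing

  # two pseudo-haploid samples, codes 0 and 2 -> 1 alt of 2 alleles
  ph <- eigenstrat(matrix(c(0L, 2L), 1, 2), synthetic_panel(1, 1),
                   data.frame(sample_id = c("a", "b"), sex = "U",
                              group = "g"), mode = "pseudohaploid")
  gp <- group_allele_stats(ph)
  expect_equal(unname(gp$alt_count[1, "g"]), 1)
  expect_equal(unname(gp$total[1, "g"]), 2)
  expect_equal(unname(gp$freq[1, "g"]), 0.5)
})

test_that("group totals equal the number of non-missing allele obs exactly", {
  for (i in 1:20) {
    ds <- tiny_dataset(30, 5, seed = 100 + i,
                       mode = sample(c("diploid", "pseudohaploid"), 1))
    gf <- group_allele_stats(ds)
    per <- if (ds$mode == "diploid") 2L else 1L
    for (g in gf$groups) {
      cols <- which(ds$ind$group == g)
      expect_identical(unname(gf$total[, g]),
                       per * rowSums(ds$geno[, cols, drop = FALSE] != 9L))
    }
  }
})

test_that("pseudohaploid mode rejects heterozygote codes", {
  expect_error(
    eigenstrat(matrix(1L, 1), synthetic_panel(1, 1),
               data.frame(sample_id = "a", sex = "U", group = "g"),
               mode = "pseudohaploid"),
    "heterozygote")
})
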
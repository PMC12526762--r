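# --- damage-aware pseudo-haploid calling from pileup data ------------------

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Read a simplified pileup TSV
#'
#' One row per site: \code{chrom}, \code{pos}, \code{ref}, and a
#' comma-separated list of read observations
#' \code{base:strand:baseq:mapq:d5:d3} (base as seen on the reference
#' strand; d5/d3 are the 0-based distances of the site from the read's 5'
#' and 3' ends). A \code{"."} read field marks a coverage-less site.
#'
#' @param path File path.
#' @return Long data frame, one row per read observation, with the site
#'   columns repeated.
#' @export
read_pileup <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "integer",
                                          "character", "character"))
  need <- c("chrom", "pos", "ref", "reads")
  if (!all(need %in% names(tab)))
    stop("pileup file must have columns: ", paste(need, collapse = ", "))
  keep <- tab$reads != "." & nzchar(tab$reads)
  tab <- tab[keep, , drop = FALSE]
  reads <- strsplit(tab$reads, ",", fixed = TRUE)
  n <- lengths(reads)
  flat <- strsplit(unlist(reads), ":", fixed = TRUE)
  if (any(lengths(flat) != 6))
    stop("malformed read tuple; expected base:strand:baseq:mapq:d5:d3")
  m <- matrix(unlist(flat), ncol = 6, byrow = TRUE)
  data.frame(chrom = rep(tab$chrom, n), pos = rep(tab$pos, n),
             ref = rep(tab$ref, n), base = m[, 1], strand = m[, 2],
             baseq = as.integer(m[, 3]), mapq = as.integer(m[, 4]),
             d5 = as.integer(m[, 5]), d3 = as.integer(m[, 6]),
             stringsAsFactors = FALSE)
}

#' Write a long pileup data frame to the simplified TSV
#'
#' @param pileup Long pileup data frame (see \code{\link{read_pileup}}).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_pileup <- function(pileup, path) {
  key <- paste(pileup$chrom, pileup$pos)
  tup <- sprintf("%s:%s:%d:%d:%d:%d", pileup$base, pileup$strand,
                 pileup$baseq, pileup$mapq, pileup$d5, pileup$d3)
  agg <- tapply(tup, key, paste, collapse = ",")
  first <- !duplicated(key)
  out <- data.frame(chrom = pileup$chrom[first], pos = pileup$pos[first],
                    ref = pileup$ref[first],
                    reads = as.vector(agg[key[first]]),
                    stringsAsFactors = FALSE)
  con <- file(path, open = "wb")
  utils::write.table(out, con, quote = FALSE, row.names = FALSE,
                     sep = "\t", eol = "\n")
  close(con)
  invisible(path)
}

#' Damage-aware pseudo-haploid genotype calling
#'
#' Selects one high-quality allele-supporting read per panel site,
#' uniformly at random, and codes the site 0 (reference) or 2
#' (alternative); sites with no eligible read are missing (9). Reads below
#' the base or mapping quality cutoffs are excluded. With
#' \code{single_strand} (the damage-avoidance mode for single-stranded
#' libraries), transversion-unsafe reads are excluded: at C/T SNPs only
#' minus-strand reads are eligible (plus-strand C->T deamination mimics
#' the T allele), and at G/A SNPs only plus-strand reads. Reads whose base
#' matches neither allele are ignored. Reads are canonically sorted
#' (strand, position in read, base, quality) before the seeded draw, so
#' the call depends only on the read set, not its input order.
#'
#' @param pileup Long pileup data frame from \code{\link{read_pileup}} or
#'   \code{\link{simulate_pileup}}.
#' @param panel snp table (\code{chrom}, \code{physical_pos}, \code{ref},
#'   \code{alt}).
#' @param min_base_q,min_map_q Phred cutoffs (default 30/30).
#' @param single_strand Apply the strand-exclusion rule (default TRUE).
#' @param seed Integer seed for the random read choice.
#' @return Integer vector of codes (0/2/9) along the panel, with
#'   attribute \code{"n_offsite_reads"}: reads at positions not in the
#'   panel (skipped, counted).
#' @export
call_pseudohaploid <- function(pileup, panel, min_base_q = 30,
                               min_map_q = 30, single_strand = TRUE,
                               seed = 1) {
  key_panel <- paste(normalize_chrom(panel$chrom), panel$physical_pos)
  key_reads <- paste(normalize_chrom(pileup$chrom), pileup$pos)
  site <- match(key_reads, key_panel)
  n_offsite <- sum(is.na(site))
  ok <- !is.na(site) &
    pileup$baseq >= min_base_q & pileup$mapq >= min_map_q
  ref <- panel$ref[site]; alt <- panel$alt[site]
  pair <- paste(pmin(ref, alt), pmax(ref, alt))
  if (single_strand) {
    ct <- pair == "C T"
    ga <- pair == "A G"
    ok <- ok & !(ct & pileup$strand == "+") & !(ga & pileup$strand == "-")
  }
  ok <- ok & (pileup$base == ref | pileup$base == alt)
  ok[is.na(ok)] <- FALSE
  idx <- which(ok)
  # canonical order: site, then (strand, position in read, base, quality)
  ord <- idx[order(site[idx], pileup$strand[idx], pileup$d5[idx],
                   pileup$base[idx], pileup$baseq[idx])]
  out <- rep(9L, nrow(panel))
  if (length(ord)) {
    gsite <- site[ord]
    r <- rle(gsite)
    starts <- cumsum(c(1L, utils::head(r$lengths, -1)))
    set.seed(seed)
    u <- stats::runif(length(r$values))
    pick <- ord[starts + floor(u * r$lengths)]
    out[r$values] <- ifelse(pileup$base[pick] == panel$alt[r$values], 2L, 0L)
  }
  attr(out, "n_offsite_reads") <- n_offsite
  out
}

#' Terminal deamination damage profile
#'
#' For reads carrying their aligned reference sequence, computes the
#' C-to-T mismatch rate by distance from the 5' read end and the G-to-A
#' analogue from the 3' end (both in read orientation), the classic
#' post-mortem deamination signature used to authenticate ancient DNA.
#'
#' @param reads Data frame with character columns \code{read_seq} and
#'   \code{ref_seq} (aligned, equal length per read, read orientation;
#'   soft-clipped bases already removed).
#' @param k Window: offsets 0..k-1 from each end (default 25).
#' @return Data frame with columns \code{end} ("5p"/"3p"), \code{offset},
#'   \code{n_sites} (reference C for 5p, G for 3p), \code{n_mismatch}
#'   (observed T resp. A) and \code{rate}.
#' @export
damage_profile <- function(reads, k = 25) {
  stopifnot(all(c("read_seq", "ref_seq") %in% names(reads)),
            all(nchar(reads$read_seq) == nchar(reads$ref_seq)))
  c5 <- integer(k); t5 <- integer(k)
  g3 <- integer(k); a3 <- integer(k)
  rs <- strsplit(reads$read_seq, "", fixed = TRUE)
  fs <- strsplit(reads$ref_seq, "", fixed = TRUE)
  for (i in seq_along(rs)) {
    rd <- rs[[i]]; rf <- fs[[i]]
    L <- length(rd)
    m5 <- seq_len(min(k, L))
    isc <- rf[m5] == "C"
    c5[m5] <- c5[m5] + isc
    t5[m5] <- t5[m5] + (isc & rd[m5] == "T")
    m3 <- L - seq_len(min(k, L)) + 1L
    isg <- rf[m3] == "G"
    g3[seq_along(m3)] <- g3[seq_along(m3)] + isg
    a3[seq_along(m3)] <- a3[seq_along(m3)] + (isg & rd[m3] == "A")
  }
  rbind(data.frame(end = "5p", offset = 0:(k - 1), n_sites = c5,
                   n_mismatch = t5,
                   rate = ifelse(c5 > 0, t5 / c5, NA_real_)),
        data.frame(end = "3p", offset = 0:(k - 1), n_sites = g3,
                   n_mismatch = a3,
                   rate = ifelse(g3 > 0, a3 / g3, NA_real_)))
}

#' Coverage-ratio sex determination
#'
#' Y-to-autosomal mean depth ratio above 0.3 calls male, below 0.1 calls
#' female; anything between is undetermined.
#'
#' @param cov_auto,cov_x,cov_y Mean depths on autosomal, X and Y panel
#'   sites (vectors allowed).
#' @return Data frame of class \code{"sex_call"}: depths, X/auto and
#'   Y/auto ratios, and the \code{call}.
#' @export
determine_sex <- function(cov_auto, cov_x, cov_y) {
  stopifnot(all(cov_auto > 0))
  ratio_x <- cov_x / cov_auto
  ratio_y <- cov_y / cov_auto
  call <- ifelse(ratio_y > 0.3, "M", ifelse(ratio_y < 0.1, "F", "U"))
  out <- data.frame(cov_auto = cov_auto, cov_x = cov_x, cov_y = cov_y,
                    ratio_x = ratio_x, ratio_y = ratio_y, call = call,
                    stringsAsFactors = FALSE)
  class(out) <- c("sex_call", "data.frame")
  out
}

#' Simulate a damaged-read pileup from known genotypes
#'
#' Per panel site, Poisson(\code{depth_mean}) reads with uniform strand
#' and uniform position-in-read; the read allele is drawn from the true
#' genotype. Deamination damage follows the single-stranded library
#' chemistry: in read orientation, C becomes T at 5'-end offsets with
#' \code{damage_5p} and at 3'-end offsets with \code{damage_3p}, so on the
#' reference strand plus-strand reads show C->T and minus-strand reads
#' G->A.
#'
#' @param genotypes Integer vector of true genotypes (0/1/2/9) along the
#'   panel.
#' @param panel snp table (\code{chrom}, \code{physical_pos}, \code{ref},
#'   \code{alt}).
#' @param depth_mean Mean coverage per site.
#' @param damage_5p,damage_3p Per-offset read-space C->T rates from the 5'
#'   and 3' read ends (vectors, offset 0 first; empty = no damage at that
#'   end).
#' @param read_len Read length in bp (default 60).
#' @param base_q,map_q Qualities attached to every simulated read
#'   (defaults 40/60, above the calling cutoffs).
#' @param seed Integer seed.
#' @return Long pileup data frame as from \code{\link{read_pileup}}, with
#'   the true genotypes in \code{attr(, "truth")}.
#' @export
simulate_pileup <- function(genotypes, panel, depth_mean = 5,
                            damage_5p = numeric(0),
                            damage_3p = numeric(0), read_len = 60,
                            base_q = 40, map_q = 60, seed = 1) {
  stopifnot(length(genotypes) == nrow(panel))
  set.seed(seed)
  n_reads <- stats::rpois(nrow(panel), depth_mean)
  n_reads[genotypes == 9L] <- 0L
  tot <- sum(n_reads)
  if (tot == 0) {
    out <- data.frame(chrom = character(), pos = integer(),
                      ref = character(), base = character(),
                      strand = character(), baseq = integer(),
                      mapq = integer(), d5 = integer(), d3 = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "truth") <- genotypes
    return(out)
  }
  site <- rep(seq_len(nrow(panel)), n_reads)
  g <- genotypes[site]
  is_alt <- stats::runif(tot) < g / 2
  base <- ifelse(is_alt, panel$alt[site], panel$ref[site])
  strand <- ifelse(stats::runif(tot) < 0.5, "+", "-")
  d5 <- floor(stats::runif(tot) * read_len)
  d3 <- read_len - 1L - d5
  # read-orientation base: complement on the minus strand
  rbase <- ifelse(strand == "+", base, unname(COMPLEMENT[base]))
  r5 <- ifelse(d5 < length(damage_5p), damage_5p[d5 + 1L], 0)
  r3 <- ifelse(d3 < length(damage_3p), damage_3p[d3 + 1L], 0)
  p_deam <- 1 - (1 - r5) * (1 - r3)
  hit <- rbase == "C" & stats::runif(tot) < p_deam
  rbase[hit] <- "T"
  obs <- ifelse(strand == "+", rbase, unname(COMPLEMENT[rbase]))
  out <- data.frame(chrom = panel$chrom[site],
                    pos = panel$physical_pos[site],
                    ref = panel$ref[site], base = obs, strand = strand,
                    baseq = base_q, mapq = map_q, d5 = d5, d3 = d3,
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- genotypes
  out
}
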
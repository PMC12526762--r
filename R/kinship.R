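# --- kinship: pairwise mismatch rate --------------------------------------

#' Randomly haploidize a diploid dataset
#'
#' Samples one allele per called genotype, the standard representation for
#' low-coverage ancient samples: heterozygotes become 0 or 2 with equal
#' probability.
#'
#' @param x An \code{\link{eigenstrat}} dataset.
#' @param seed Integer seed.
#' @return A pseudo-haploid \code{\link{eigenstrat}} dataset.
#' @export
pseudohaploidize <- function(x, seed = 1) {
  validate_eigenstrat(x)
  set.seed(seed)
  g <- x$geno
  het <- g == 1L
  g[het] <- 2L * stats::rbinom(sum(het), 1L, 0.5)
  ind <- x$ind
  ind$ploidy <- 1L
  eigenstrat(g, x$snp, ind, mode = "pseudohaploid")
}

#' Pairwise mismatch rate (PMR) for all sample pairs
#'
#' The fraction of autosomal SNPs called in both members of a pair where
#' the two pseudo-haploid calls disagree. The PMR of a pair scales with
#' kinship: identical genomes sit at half the unrelated ("background")
#' level, first-degree pairs at 3/4, second-degree at 7/8.
#'
#' @param x A pseudo-haploid \code{\link{eigenstrat}} dataset (codes
#'   0/2/9; use \code{\link{pseudohaploidize}} first for diploid data).
#' @param min_overlap Pairs with fewer overlapping SNPs are flagged
#'   unreliable.
#' @return Data frame of class \code{"pmr_table"}: \code{id1}, \code{id2},
#'   \code{n_overlap}, \code{n_mismatch}, \code{pmr}, \code{reliable}.
#' @export
pmr_all_pairs <- function(x, min_overlap = 3000) {
  validate_eigenstrat(x)
  if (any(x$geno == 1L))
    stop("PMR is defined on pseudo-haploid calls; run pseudohaploidize()")
  auto <- is_autosome(x$snp$chrom)
  g <- x$geno[auto, , drop = FALSE]
  called <- g != 9L
  alt <- (g == 2L) & called
  ref <- (g == 0L) & called
  n_overlap <- crossprod(called * 1)
  n_mismatch <- crossprod(alt * 1, ref * 1)
  n_mismatch <- n_mismatch + t(n_mismatch)
  ids <- x$ind$sample_id
  pairs <- which(upper.tri(n_overlap), arr.ind = TRUE)
  out <- data.frame(id1 = ids[pairs[, 1]], id2 = ids[pairs[, 2]],
                    n_overlap = n_overlap[pairs],
                    n_mismatch = n_mismatch[pairs],
                    stringsAsFactors = FALSE)
  out$pmr <- ifelse(out$n_overlap > 0, out$n_mismatch / out$n_overlap,
                    NA_real_)
  out$reliable <- out$n_overlap >= min_overlap
  class(out) <- c("pmr_table", "data.frame")
  out
}

#' Classify relatedness degree from PMR ratios
#'
#' The cohort background level x0 is the median PMR over all reliable
#' pairs (robust to a few relatives); each pair's normalized ratio
#' pmr / x0 is assigned to the nearest of the expected ratios 1/2
#' (identical/twin), 3/4 (first degree), 7/8 (second degree) and 1
#' (unrelated), using midpoint cutoffs 0.625, 0.8125 and 0.9375.
#'
#' @param pmr A \code{\link{pmr_all_pairs]{pmr_table}} (or compatible data
#'   frame).
#' @param x0 Optional background PMR; default the median over reliable
#'   pairs.
#' @return The table with \code{ratio} and \code{degree} columns added;
#'   \code{attr(, "x0")} holds the baseline. Unreliable pairs get
#'   \code{NA} degree.
#' @export
classify_degree <- function(pmr, x0 = NULL) {
  stopifnot(all(c("pmr", "reliable") %in% names(pmr)))
  if (is.null(x0)) x0 <- stats::median(pmr$pmr[pmr$reliable], na.rm = TRUE)
  ratio <- pmr$pmr / x0
  degree <- cut(ratio, c(-Inf, 0.625, 0.8125, 0.9375, Inf),
                labels = c("identical", "first", "second", "unrelated"))
  degree <- as.character(degree)
  degree[!pmr$reliable] <- NA_character_
  pmr$ratio <- ratio
  pmr$degree <- degree
  attr(pmr, "x0") <- x0
  pmr
}

# --- crossover interference and pedigree simulation ------------------------

#' Crossover interference model and sex-specific genetic maps
#'
#' Crossovers per meiosis follow a two-pathway model: chiasmata from a
#' stationary gamma renewal process with interference shape \code{nu}
#' (rate 2 nu (1 - p_esc) per Morgan, thinned 1/2 to a gamete) plus a
#' non-interfering Poisson "escape" pathway carrying a fraction
#' \code{p_esc} of events. The expected crossover count per gamete equals
#' the map length in Morgans for any (nu, p_esc). Meioses use the
#' sex-specific map length of the transmitting parent; coordinates are
#' rescaled to the sex-averaged map so both probands live on one scale.
#'
#' @param nu Gamma interference shape (>= 1; 1 = no interference).
#' @param p_esc Escape fraction of non-interfering crossovers in [0, 1].
#' @param maps Data frame with columns \code{chrom}, \code{male_len},
#'   \code{female_len} (Morgans); default \code{\link{default_genetic_maps}}.
#' @return Object of class \code{"interference_model"}.
#' @export
interference_model <- function(nu = 7.6, p_esc = 0.1,
                               maps = default_genetic_maps()) {
  stopifnot(nu >= 1, p_esc >= 0, p_esc <= 1,
            all(c("chrom", "male_len", "female_len") %in% names(maps)))
  structure(list(nu = nu, p_esc = p_esc, maps = maps),
            class = "interference_model")
}

#' Default sex-specific genetic maps for 22 autosomes
#'
#' Approximate per-chromosome genetic lengths (Morgans) with the female
#' map 1.25x and the male map 0.75x a sex-averaged baseline; totals are
#' near the human sex-averaged ~35 M, female ~44 M and male ~26 M.
#'
#' @return Data frame with \code{chrom}, \code{male_len},
#'   \code{female_len}, \code{avg_len}.
#' @export
default_genetic_maps <- function() {
  base <- c(2.86, 2.69, 2.23, 2.14, 2.04, 1.92, 1.87, 1.70, 1.68, 1.81,
            1.58, 1.75, 1.28, 1.19, 1.41, 1.34, 1.29, 1.17, 1.08, 1.08,
            0.62, 0.74)
  data.frame(chrom = as.character(1:22), male_len = 0.75 * base,
             female_len = 1.25 * base, avg_len = base,
             stringsAsFactors = FALSE)
}

#' Simulate crossover positions for one meiosis
#'
#' @param L Map length in Morgans of the transmitting parent's map.
#' @param model An \code{\link{interference_model}}.
#' @return Sorted crossover positions in (0, L). Uses the current RNG
#'   state (seed at the caller).
#' @export
crossover_positions <- function(L, model) {
  nu <- model$nu; p <- model$p_esc
  xo <- numeric(0)
  if (p < 1) {
    rate <- 2 * nu * (1 - p)           # gamma rate: chiasma rate 2(1-p)/M
    mean_iv <- nu / rate
    burn <- 15 * mean_iv
    n_guess <- ceiling((L + burn) / mean_iv * 1.5) + 20
    pos <- -burn + cumsum(stats::rgamma(n_guess, shape = nu, rate = rate))
    while (length(pos) && pos[length(pos)] < L) {
      pos <- c(pos, pos[length(pos)] +
                 cumsum(stats::rgamma(10, shape = nu, rate = rate)))
    }
    chi <- pos[pos > 0 & pos < L]
    chi <- chi[stats::runif(length(chi)) < 0.5]   # thin to one gamete
    xo <- chi
  }
  if (p > 0) {
    n_e <- stats::rpois(1, p * L)                 # escape pathway, gamete
    xo <- c(xo, stats::runif(n_e, 0, L))
  }
  sort(xo)
}

# haplotype = list(end = ascending segment end positions (last == L),
#                  allele = integer founder-allele labels per segment)
splice_haplotypes <- function(h1, h2, xo, start_hap) {
  if (!length(xo)) return(if (start_hap == 1L) h1 else h2)
  cur <- start_hap
  bounds <- c(0, xo, h1$end[length(h1$end)])
  ends <- numeric(0); alleles <- integer(0)
  for (s in seq_len(length(bounds) - 1)) {
    a <- bounds[s]; b <- bounds[s + 1]
    h <- if (cur == 1L) h1 else h2
    i1 <- findInterval(a, h$end, left.open = FALSE) + 1L
    keep <- which(h$end > a & c(0, h$end[-length(h$end)]) < b)
    for (k in keep) {
      e <- min(h$end[k], b)
      if (length(ends) && alleles[length(alleles)] == h$allele[k])
        ends[length(ends)] <- e
      else { ends <- c(ends, e); alleles <- c(alleles, h$allele[k]) }
    }
    cur <- 3L - cur
  }
  list(end = ends, allele = alleles)
}

# one gamete from a parent (list of per-chromosome haplotype pairs)
make_gamete <- function(parent, model, sex) {
  maps <- model$maps
  lapply(seq_len(nrow(maps)), function(ci) {
    Lsex <- if (sex == "M") maps$male_len[ci] else maps$female_len[ci]
    Lavg <- maps$avg_len[ci]
    xo <- crossover_positions(Lsex, model) * (Lavg / Lsex)
    splice_haplotypes(parent[[ci]]$h1, parent[[ci]]$h2, xo,
                      sample(2L, 1))
  })
}

new_founder <- function(model, next_allele) {
  maps <- model$maps
  haps <- lapply(seq_len(nrow(maps)), function(ci) {
    L <- maps$avg_len[ci]
    list(h1 = list(end = L, allele = next_allele),
         h2 = list(end = L, allele = next_allele + 1L))
  })
  haps
}

# founder-allele identity between two individuals on one chromosome:
# IBD state per interval of the union breakpoint grid
ibd_states_chrom <- function(a, b, L) {
  bks <- sort(unique(c(a$h1$end, a$h2$end, b$h1$end, b$h2$end, L)))
  starts <- c(0, bks[-length(bks)])
  mids <- (starts + bks) / 2
  al1 <- a$h1$allele[findInterval(mids, a$h1$end, left.open = TRUE) + 1L]
  al2 <- a$h2$allele[findInterval(mids, a$h2$end, left.open = TRUE) + 1L]
  bl1 <- b$h1$allele[findInterval(mids, b$h1$end, left.open = TRUE) + 1L]
  bl2 <- b$h2$allele[findInterval(mids, b$h2$end, left.open = TRUE) + 1L]
  shared <- integer(length(mids))
  for (i in seq_along(mids)) {
    av <- c(al1[i], al2[i]); bv <- c(bl1[i], bl2[i])
    s <- 0L
    for (lbl in unique(av))
      s <- s + min(sum(av == lbl), sum(bv == lbl))
    shared[i] <- s
  }
  data.frame(start = starts, end = bks, shared = pmin(shared, 2L))
}

# collapse consecutive same-state intervals, keep IBD1/IBD2 only
ibd_segments_from_states <- function(states, chrom, snps_per_cm) {
  r <- rle(states$shared)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- c(1, utils::head(ends_idx, -1) + 1)
  keep <- r$values > 0L
  if (!any(keep)) return(NULL)
  st <- states$start[starts_idx[keep]] * 100   # cM
  en <- states$end[ends_idx[keep]] * 100
  ty <- ifelse(r$values[keep] == 2L, "IBD2", "IBD1")
  data.frame(chrom = chrom, start_cm = st, end_cm = en, type = ty,
             n_snps = floor((en - st) * snps_per_cm),
             stringsAsFactors = FALSE)
}

# the four second-degree pedigrees (paternal variants, as in a shared
# Y-chromosome male pair); returns the two probands' genomes
second_degree_pedigrees <- c("grandparent-grandchild", "avuncular",
                             "half-siblings", "double first cousins")

drop_one_pedigree <- function(relationship, model) {
  counter <- 0L
  founder <- function() {
    f <- new_founder(model, counter + 1L)
    counter <<- counter + 2L
    f
  }
  child <- function(father, mother) {
    pat <- make_gamete(father, model, "M")
    mat <- make_gamete(mother, model, "F")
    lapply(seq_along(pat), function(ci)
      list(h1 = pat[[ci]], h2 = mat[[ci]]))
  }
  switch(relationship,
    "grandparent-grandchild" = {
      gf <- founder(); gm <- founder(); m <- founder()
      fa <- child(gf, gm)
      list(a = gf, b = child(fa, m))
    },
    "avuncular" = {
      gf <- founder(); gm <- founder(); m2 <- founder()
      uncle <- child(gf, gm)
      fa <- child(gf, gm)
      list(a = uncle, b = child(fa, m2))
    },
    "half-siblings" = {
      fa <- founder(); m1 <- founder(); m2 <- founder()
      list(a = child(fa, m1), b = child(fa, m2))
    },
    "double first cousins" = {
      f1 <- founder(); m1 <- founder(); f2 <- founder(); m2 <- founder()
      a1 <- child(f1, m1); a2 <- child(f1, m1)
      b1 <- child(f2, m2); b2 <- child(f2, m2)
      list(a = child(a1, b1), b = child(a2, b2))
    },
    stop("unknown relationship: ", relationship))
}

#' Simulate IBD sharing for a second-degree relationship
#'
#' Gene-drops founder genomes through the minimal pedigree of the
#' relationship with interference-aware recombination, derives IBD1/IBD2
#' segments between the two probands from founder-allele identity, applies
#' the same merge and filter steps used on observed segment tables, and
#' summarizes each replicate.
#'
#' @param relationship One of \code{"grandparent-grandchild"},
#'   \code{"avuncular"}, \code{"half-siblings"},
#'   \code{"double first cousins"}.
#' @param model An \code{\link{interference_model}}.
#' @param n_replicates Number of simulated proband pairs (default 100).
#' @param seed Integer seed.
#' @param snps_per_cm Marker density used to attach SNP counts to
#'   segments (default 350, a 1240K-like autosomal density).
#' @param min_len_cm,min_snp_per_cm Filter thresholds applied to merged
#'   blocks (defaults 12 cM and 220 SNPs/cM).
#' @return Object of class \code{"rel_envelope"}: per-replicate summaries
#'   (\code{n_blocks}, \code{total_cm}, \code{ibd2_cm}, raw pre-filter
#'   IBD1/IBD2 genome fractions) and the relationship label.
#' @export
simulate_relationship_ibd <- function(relationship, model =
                                        interference_model(),
                                      n_replicates = 100, seed = 1,
                                      snps_per_cm = 350, min_len_cm = 12,
                                      min_snp_per_cm = 220) {
  relationship <- match.arg(relationship, second_degree_pedigrees)
  set.seed(seed)
  maps <- model$maps
  tot_cm <- sum(maps$avg_len) * 100
  out <- vector("list", n_replicates)
  for (rep in seq_len(n_replicates)) {
    pr <- drop_one_pedigree(relationship, model)
    segs <- vector("list", nrow(maps))
    for (ci in seq_len(nrow(maps))) {
      st <- ibd_states_chrom(pr$a[[ci]], pr$b[[ci]], maps$avg_len[ci])
      segs[[ci]] <- ibd_segments_from_states(st, maps$chrom[ci],
                                             snps_per_cm)
    }
    segs <- do.call(rbind, segs[!vapply(segs, is.null, logical(1))])
    raw_ibd1 <- if (is.null(segs)) 0 else
      sum(segs$end_cm[segs$type == "IBD1"] -
            segs$start_cm[segs$type == "IBD1"]) / tot_cm
    raw_ibd2 <- if (is.null(segs)) 0 else
      sum(segs$end_cm[segs$type == "IBD2"] -
            segs$start_cm[segs$type == "IBD2"]) / tot_cm
    if (is.null(segs) || !nrow(segs)) {
      out[[rep]] <- data.frame(n_blocks = 0L, total_cm = 0, ibd2_cm = 0,
                               raw_ibd1_frac = raw_ibd1,
                               raw_ibd2_frac = raw_ibd2)
      next
    }
    blocks <- merge_adjacent_segments(segs)
    blocks <- filter_segments(blocks, min_len_cm, min_snp_per_cm)
    out[[rep]] <- data.frame(
      n_blocks = nrow(blocks),
      total_cm = sum(blocks$end_cm - blocks$start_cm),
      ibd2_cm = sum(blocks$ibd2_cm),
      raw_ibd1_frac = raw_ibd1, raw_ibd2_frac = raw_ibd2)
  }
  structure(list(relationship = relationship,
                 summaries = do.call(rbind, out),
                 n_replicates = n_replicates, model = model),
            class = "rel_envelope")
}

#' @export
print.rel_envelope <- function(x, ...) {
  s <- x$summaries
  cat(sprintf("IBD envelope for %s (%d replicates):\n", x$relationship,
              x$n_replicates))
  cat(sprintf("  blocks: %.1f +/- %.1f; total %.0f +/- %.0f cM; IBD2 %.1f cM\n",
              mean(s$n_blocks), stats::sd(s$n_blocks), mean(s$total_cm),
              stats::sd(s$total_cm), mean(s$ibd2_cm)))
  invisible(x)
}

# --- IBD segment algebra ---------------------------------------------------

#' Merge adjacent and overlapping IBD segments into blocks
#'
#' On each chromosome (and pair, when a \code{pair_id} column is present),
#' maximal runs of abutting or overlapping IBD1/IBD2 segments become one
#' block, so alternating IBD1/IBD2 runs count as a single consecutive
#' block. Block length is the union length, SNP counts are summed, and the
#' IBD2 component length is retained.
#'
#' @param segments Data frame with \code{chrom}, \code{start_cm},
#'   \code{end_cm}, \code{type} (\code{"IBD1"}/\code{"IBD2"}),
#'   \code{n_snps}, optionally \code{pair_id}.
#' @param tol Gap (cM) up to which segments count as abutting (default 0,
#'   with a 1e-9 numeric guard).
#' @return Data frame of merged blocks with \code{ibd2_cm} and
#'   \code{n_members} columns.
#' @export
merge_adjacent_segments <- function(segments, tol = 0) {
  stopifnot(all(c("chrom", "start_cm", "end_cm", "type", "n_snps") %in%
                  names(segments)))
  if (any(segments$end_cm <= segments$start_cm))
    stop("segments must have end_cm > start_cm")
  has_pair <- "pair_id" %in% names(segments)
  keyv <- if (has_pair) paste(segments$pair_id, segments$chrom)
          else as.character(segments$chrom)
  out <- list()
  for (key in unique(keyv)) {
    s <- segments[keyv == key, , drop = FALSE]
    s <- s[order(s$start_cm), , drop = FALSE]
    cur <- s[1, , drop = FALSE]
    cur_ibd2 <- if (s$type[1] == "IBD2") s$end_cm[1] - s$start_cm[1] else 0
    cur_n <- 1L
    flush <- function(cur, ibd2, nm) {
      r <- data.frame(chrom = cur$chrom, start_cm = cur$start_cm,
                      end_cm = cur$end_cm, n_snps = cur$n_snps,
                      ibd2_cm = ibd2, n_members = nm,
                      stringsAsFactors = FALSE)
      if (has_pair) r$pair_id <- cur$pair_id
      r
    }
    for (i in seq_len(nrow(s))[-1]) {
      if (s$start_cm[i] <= cur$end_cm + tol + 1e-9) {
        cur$end_cm <- max(cur$end_cm, s$end_cm[i])
        cur$n_snps <- cur$n_snps + s$n_snps[i]
        if (s$type[i] == "IBD2")
          cur_ibd2 <- cur_ibd2 + s$end_cm[i] - s$start_cm[i]
        cur_n <- cur_n + 1L
      } else {
        out[[length(out) + 1L]] <- flush(cur, cur_ibd2, cur_n)
        cur <- s[i, , drop = FALSE]
        cur_ibd2 <- if (s$type[i] == "IBD2") s$end_cm[i] - s$start_cm[i]
                    else 0
        cur_n <- 1L
      }
    }
    out[[length(out) + 1L]] <- flush(cur, cur_ibd2, cur_n)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Filter merged IBD blocks by length and marker density
#'
#' Keeps blocks at least \code{min_len_cm} long AND with at least
#' \code{min_snp_per_cm} SNPs per cM, the standard filters against false
#' IBD calls on sparse panels.
#'
#' @param blocks Output of \code{\link{merge_adjacent_segments}} (or any
#'   data frame with \code{start_cm}, \code{end_cm}, \code{n_snps}).
#' @param min_len_cm Minimum block length in cM (default 12).
#' @param min_snp_per_cm Minimum SNP density (default 220).
#' @return The surviving rows.
#' @export
filter_segments <- function(blocks, min_len_cm = 12, min_snp_per_cm = 220) {
  len <- blocks$end_cm - blocks$start_cm
  keep <- len >= min_len_cm & blocks$n_snps / len >= min_snp_per_cm
  blocks[keep, , drop = FALSE]
}

#' Summarize merged+filtered IBD blocks for classification
#'
#' @param blocks Output of \code{\link{merge_adjacent_segments}} after
#'   \code{\link{filter_segments}}.
#' @return List of class \code{"ibd_summary"}: \code{n_blocks},
#'   \code{total_cm}, \code{ibd2_cm}.
#' @export
ibd_summary <- function(blocks) {
  structure(list(n_blocks = nrow(blocks),
                 total_cm = if (nrow(blocks))
                   sum(blocks$end_cm - blocks$start_cm) else 0,
                 ibd2_cm = if ("ibd2_cm" %in% names(blocks) && nrow(blocks))
                   sum(blocks$ibd2_cm) else 0),
            class = "ibd_summary")
}

#' Read an IBD segment table (TSV)
#'
#' Expected columns: pair_id, chrom, start_cm, end_cm, type, n_snps.
#'
#' @param path File path.
#' @return Data frame of segments.
#' @export
read_ibd_segments <- function(path) {
  seg <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("pair_id", "chrom", "start_cm", "end_cm", "type", "n_snps")
  if (!all(need %in% names(seg)))
    stop("IBD segment table must have columns: ",
         paste(need, collapse = ", "))
  if (!all(seg$type %in% c("IBD1", "IBD2")))
    stop("segment type must be IBD1 or IBD2")
  seg
}

#' Classify a second-degree relationship from IBD summaries
#'
#' Ranks the four candidate second-degree relationships by the Mahalanobis
#' distance of the observed (block count, total length) summary to each
#' simulated envelope's empirical mean and covariance. Double first
#' cousins are excluded outright when the observation has no IBD2 while
#' the envelope's 5th percentile of IBD2 length is positive; any
#' relationship whose distance exceeds the envelope's own 97.5th
#' percentile self-distance is flagged excluded.
#'
#' @param observed An \code{\link{ibd_summary}} (or list with
#'   \code{n_blocks}, \code{total_cm}, \code{ibd2_cm}).
#' @param envelopes List of \code{\link{simulate_relationship_ibd}}
#'   results, one per candidate relationship.
#' @return Data frame ranked by distance with columns
#'   \code{relationship}, \code{distance} (squared Mahalanobis),
#'   \code{cutoff}, \code{excluded}, \code{reason}.
#' @export
classify_second_degree <- function(observed, envelopes) {
  obs <- c(observed$n_blocks, observed$total_cm)
  rows <- lapply(envelopes, function(env) {
    s <- env$summaries
    mu <- c(mean(s$n_blocks), mean(s$total_cm))
    V <- stats::cov(cbind(s$n_blocks, s$total_cm)) + diag(1e-6, 2)
    d2 <- stats::mahalanobis(matrix(obs, 1), mu, V)
    self <- stats::mahalanobis(cbind(s$n_blocks, s$total_cm), mu, V)
    cutoff <- stats::quantile(self, 0.975, names = FALSE)
    excluded <- d2 > cutoff
    reason <- if (excluded) "outside envelope" else ""
    if (env$relationship == "double first cousins" &&
        observed$ibd2_cm == 0 &&
        stats::quantile(env$summaries$ibd2_cm, 0.05, names = FALSE) > 0) {
      excluded <- TRUE
      reason <- "no IBD2 observed"
    }
    data.frame(relationship = env$relationship, distance = d2,
               cutoff = cutoff, excluded = excluded, reason = reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$excluded, out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}
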
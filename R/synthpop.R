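#' Construct an admixture graph
#'
#' A rooted acyclic graph of populations. Drift edges carry a drift amount
#' \code{F} in [0, 0.5] (the Balding-Nichols differentiation parameter);
#' admixture nodes have exactly two parents and a mixing proportion
#' \code{alpha} giving the weight of \code{parent1}.
#'
#' @param edges Data frame with columns \code{from}, \code{to}, \code{f}
#'   describing drift edges.
#' @param admixtures Optional data frame with columns \code{node},
#'   \code{parent1}, \code{parent2}, \code{alpha} describing admixture
#'   events. An admixture node receives no drift of its own; add a drift
#'   edge below it if needed.
#' @return An object of class \code{"admixture_graph"} with the nodes in
#'   topological order, the leaf set, and per-node parent/weight lists.
#' @export
admixture_graph <- function(edges, admixtures = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("from", "to", "f") %in% names(edges)))
  if (any(edges$f < 0 | edges$f > 0.5))
    stop("drift amounts must be in [0, 0.5]")
  adm <- if (is.null(admixtures)) {
    data.frame(node = character(), parent1 = character(),
               parent2 = character(), alpha = numeric())
  } else as.data.frame(admixtures, stringsAsFactors = FALSE)
  if (nrow(adm)) {
    stopifnot(all(c("node", "parent1", "parent2", "alpha") %in% names(adm)))
    if (any(adm$alpha <= 0 | adm$alpha > 1))
      stop("admixture proportions must be in (0, 1]")
  }
  children <- c(edges$to, adm$node)
  if (anyDuplicated(children))
    stop("node(s) with more than one incoming edge set: ",
         paste(unique(children[duplicated(children)]), collapse = ", "))
  nodes <- unique(c(edges$from, edges$to, adm$node, adm$parent1, adm$parent2))
  roots <- setdiff(nodes, children)
  if (length(roots) != 1)
    stop("graph must have exactly one root, found: ",
         paste(roots, collapse = ", "))
  parents <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges)))
    parents[[edges$to[i]]] <- list(p = edges$from[i], w = 1, f = edges$f[i])
  for (i in seq_len(nrow(adm)))
    parents[[adm$node[i]]] <- list(p = c(adm$parent1[i], adm$parent2[i]),
                                   w = c(adm$alpha[i], 1 - adm$alpha[i]),
                                   f = NA_real_)
  # Kahn topological sort; failure means a cycle
  topo <- roots
  placed <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  placed[roots] <- TRUE
  repeat {
    ready <- nodes[!placed[nodes] & vapply(nodes, function(n) {
      pr <- parents[[n]]
      !is.null(pr) && all(placed[pr$p])
    }, logical(1))]
    if (!length(ready)) break
    topo <- c(topo, ready)
    placed[ready] <- TRUE
  }
  if (!all(placed)) stop("graph contains a cycle involving: ",
                         paste(nodes[!placed], collapse = ", "))
  # a population is samplable (a "leaf") if no drift edge leaves it;
  # being the parent of an admixture node does not disqualify it
  leaves <- setdiff(nodes, edges$from)
  structure(list(nodes = topo, parents = parents, leaves = leaves,
                 root = roots, edges = edges, admixtures = adm),
            class = "admixture_graph")
}

#' @export
print.admixture_graph <- function(x, ...) {
  cat("admixture graph: ", length(x$nodes), " nodes, ",
      nrow(x$admixtures), " admixture event(s)\n", sep = "")
  cat("  leaves: ", paste(x$leaves, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Generate a random admixture graph
#'
#' Builds a random rooted binary tree over \code{n_leaves} populations by
#' sequential attachment, then optionally grafts admixed leaves whose two
#' parents are random pre-existing nodes.
#'
#' @param n_leaves Number of (non-admixed) leaf populations.
#' @param n_admix Number of admixed leaves to add.
#' @param f_range Range drift amounts are drawn from (uniform).
#' @param seed Integer seed.
#' @return An \code{\link{admixture_graph}} with leaves named
#'   \code{P1, P2, ...} (admixed leaves \code{M1, ...}).
#' @export
random_admixture_graph <- function(n_leaves, n_admix = 0,
                                   f_range = c(0.01, 0.15), seed = 1) {
  stopifnot(n_leaves >= 2)
  set.seed(seed)
  rf <- function(n) stats::runif(n, f_range[1], f_range[2])
  # start with root splitting into two leaves; attach remaining leaves by
  # subdividing a random existing edge
  edges <- data.frame(from = c("R", "R"), to = c("P1", "P2"), f = rf(2),
                      stringsAsFactors = FALSE)
  n_int <- 0
  for (i in seq_len(n_leaves - 2)) {
    e <- sample(nrow(edges), 1)
    n_int <- n_int + 1
    mid <- paste0("N", n_int)
    new_leaf <- paste0("P", i + 2)
    f_old <- edges$f[e]
    child <- edges$to[e]
    edges$to[e] <- mid
    edges$f[e] <- f_old / 2
    edges <- rbind(edges,
                   data.frame(from = mid, to = child, f = f_old / 2),
                   data.frame(from = mid, to = new_leaf, f = rf(1)))
  }
  adm <- NULL
  if (n_admix > 0) {
    adm <- data.frame(node = character(), parent1 = character(),
                      parent2 = character(), alpha = numeric())
    for (j in seq_len(n_admix)) {
      cand <- unique(c(edges$from, edges$to))
      pr <- sample(cand, 2)
      node <- paste0("MX", j)
      adm <- rbind(adm, data.frame(node = node, parent1 = pr[1],
                                   parent2 = pr[2],
                                   alpha = stats::runif(1, 0.2, 0.8)))
      edges <- rbind(edges, data.frame(from = node, to = paste0("M", j),
                                       f = rf(1)))
    }
  }
  admixture_graph(edges, adm)
}

#' Canonical admixture-graph topology for admixture-model checks
#'
#' A fixed three-clade topology with six outgroups straddling the source
#' clades, so a rank test or admixture model on it is well powered: deep
#' outgroups O1/O2, one clade carrying source S1 (with related outgroups
#' O3), and a sister pair of clades carrying S2 (with O4) and S3 (with
#' O5), plus O6 on their shared stem. The target T is a mixture of S1 and
#' S2 (two-way) or of S1, S2 and S3 (three-way), with the given weights.
#'
#' @param alpha Numeric vector of source weights (length 2 or 3, summing
#'   to 1, each in (0,1)).
#' @return An \code{\link{admixture_graph}} whose samplable populations
#'   include S1, S2, S3, T and O1..O6.
#' @export
qp_test_graph <- function(alpha = c(0.3, 0.7)) {
  stopifnot(length(alpha) %in% c(2, 3), abs(sum(alpha) - 1) < 1e-12,
            all(alpha > 0), all(alpha < 1))
  edges <- data.frame(
    from = c("R", "R", "N0", "N0", "N1", "N1", "K23", "K23", "K23",
             "K1", "K1", "K2", "K2", "K3", "K3"),
    to   = c("O1", "N0", "O2", "N1", "K1", "K23", "K2", "K3", "O6",
             "O3", "S1", "O4", "S2", "O5", "S3"),
    f    = c(0.10, 0.02, 0.06, 0.02, 0.03, 0.02, 0.03, 0.03, 0.05,
             0.05, 0.04, 0.05, 0.04, 0.05, 0.04),
    stringsAsFactors = FALSE)
  if (length(alpha) == 2) {
    adm <- data.frame(node = "T", parent1 = "S1", parent2 = "S2",
                      alpha = alpha[1])
  } else {
    a1 <- alpha[1] / (alpha[1] + alpha[2])
    adm <- rbind(
      data.frame(node = "M12", parent1 = "S1", parent2 = "S2", alpha = a1),
      data.frame(node = "T", parent1 = "M12", parent2 = "S3",
                 alpha = alpha[1] + alpha[2]))
  }
  admixture_graph(edges, adm)
}

#' Simulate per-population allele frequencies along an admixture graph
#'
#' The ancestral frequency is drawn uniformly; each drift edge applies
#' Balding-Nichols drift (child frequency Beta with mean p and variance
#' F p (1 - p)); admixture nodes take the alpha-weighted average of their
#' parents, clamped to [0.001, 0.999] to avoid degenerate Bernoulli draws.
#'
#' @param graph An \code{\link{admixture_graph}}.
#' @param n_snps Number of independent SNPs.
#' @param seed Integer seed.
#' @param ancestral Range of the uniform ancestral frequency distribution.
#' @param keep_internal Keep internal node frequencies too (default leaves
#'   only).
#' @return A numeric matrix, \code{n_snps} rows by one column per
#'   population.
#' @export
simulate_frequencies <- function(graph, n_snps, seed = 1,
                                 ancestral = c(0.05, 0.95),
                                 keep_internal = FALSE) {
  stopifnot(inherits(graph, "admixture_graph"))
  set.seed(seed)
  p <- matrix(NA_real_, n_snps, length(graph$nodes),
              dimnames = list(NULL, graph$nodes))
  p[, graph$root] <- stats::runif(n_snps, ancestral[1], ancestral[2])
  for (nd in graph$nodes[-1]) {
    pr <- graph$parents[[nd]]
    if (length(pr$p) == 1L) {
      pp <- p[, pr$p]
      if (pr$f == 0) p[, nd] <- pp
      else {
        shape <- (1 - pr$f) / pr$f
        p[, nd] <- stats::rbeta(n_snps, pp * shape, (1 - pp) * shape)
      }
    } else {
      mix <- pr$w[1] * p[, pr$p[1]] + pr$w[2] * p[, pr$p[2]]
      p[, nd] <- pmin(pmax(mix, 0.001), 0.999)
    }
  }
  if (keep_internal) p else p[, graph$leaves, drop = FALSE]
}

# E[p_u p_v] for every node pair, by dynamic programming in topological
# order: drift edges are martingales (E[p_c | p_a] = p_a, E[p_c^2 | p_a] =
# (1-F) p_a^2 + F p_a); admixture nodes are deterministic mixtures.
node_moment_matrix <- function(graph, ancestral = c(0.05, 0.95)) {
  n <- length(graph$nodes)
  M <- matrix(NA_real_, n, n, dimnames = list(graph$nodes, graph$nodes))
  mu <- mean(ancestral)
  M[1, 1] <- mu^2 + diff(ancestral)^2 / 12
  for (i in seq_len(n)[-1]) {
    nd <- graph$nodes[i]
    pr <- graph$parents[[nd]]
    prev <- graph$nodes[seq_len(i - 1)]
    if (length(pr$p) == 1L) {
      M[nd, prev] <- M[prev, nd] <- M[pr$p, prev]
      M[nd, nd] <- (1 - pr$f) * M[pr$p, pr$p] + pr$f * mu
    } else {
      w <- pr$w
      M[nd, prev] <- M[prev, nd] <-
        w[1] * M[pr$p[1], prev] + w[2] * M[pr$p[2], prev]
      M[nd, nd] <- w[1]^2 * M[pr$p[1], pr$p[1]] +
        2 * w[1] * w[2] * M[pr$p[1], pr$p[2]] +
        w[2]^2 * M[pr$p[2], pr$p[2]]
    }
  }
  M
}

#' Expected f-statistics under an admixture graph
#'
#' Closed-form expectations of f2, f3 and f4 under the generative model of
#' \code{\link{simulate_frequencies}} (exactly: second moments of the true
#' population frequencies, ignoring the rare boundary clamp at admixture
#' nodes). Units are squared-frequency units, the same scale on which the
#' empirical estimators operate.
#'
#' @param graph An \code{\link{admixture_graph}}.
#' @param a,b,c,d Population (node) names.
#' @param ancestral Ancestral frequency range used by the simulator.
#' @return The expected value of the statistic.
#' @name expected_f_stats
NULL

#' @rdname expected_f_stats
#' @export
expected_f4 <- function(graph, a, b, c, d, ancestral = c(0.05, 0.95)) {
  M <- node_moment_matrix(graph, ancestral)
  M[a, c] - M[a, d] - M[b, c] + M[b, d]
}

#' @rdname expected_f_stats
#' @export
expected_f2 <- function(graph, a, b, ancestral = c(0.05, 0.95)) {
  M <- node_moment_matrix(graph, ancestral)
  M[a, a] - 2 * M[a, b] + M[b, b]
}

#' @rdname expected_f_stats
#' @export
expected_f3 <- function(graph, o, a, b, ancestral = c(0.05, 0.95)) {
  M <- node_moment_matrix(graph, ancestral)
  M[o, o] - M[o, a] - M[o, b] + M[a, b]
}

#' Build a uniform synthetic SNP panel
#'
#' SNPs are spread evenly over \code{n_chrom} chromosomes of
#' \code{chrom_length} Morgans each, with physical positions on a uniform
#' 1 cM/Mb map.
#'
#' @param n_snps Total number of SNPs.
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Genetic length per chromosome, Morgans. Scalar or
#'   vector of length \code{n_chrom}.
#' @return A snp table as used by \code{\link{eigenstrat}}.
#' @export
synthetic_panel <- function(n_snps, n_chrom = 22, chrom_length = 1) {
  len <- rep_len(chrom_length, n_chrom)
  per <- diff(round(seq(0, n_snps, length.out = n_chrom + 1)))
  chrom <- rep(as.character(seq_len(n_chrom)), per)
  gpos <- unlist(lapply(seq_len(n_chrom), function(c)
    if (per[c] > 0) (seq_len(per[c]) - 0.5) / per[c] * len[c] else numeric()))
  data.frame(snp_id = paste0("snp", seq_len(n_snps)), chrom = chrom,
             genetic_pos = gpos,
             physical_pos = as.integer(round(gpos * 1e8)) + 1L,
             ref = "A", alt = "G", stringsAsFactors = FALSE)
}

#' Sample genotypes from population allele frequencies
#'
#' Diploid genotypes are Binomial(2, p); pseudo-haploid calls are a single
#' Bernoulli(p) allele coded 0/2. Missingness is i.i.d.
#'
#' @param freq Matrix of frequencies, SNPs x populations (as returned by
#'   \code{\link{simulate_frequencies}}).
#' @param n_per_pop Samples per population (scalar or named vector).
#' @param mode \code{"diploid"} or \code{"pseudohaploid"}.
#' @param missing_rate Per-call missing probability.
#' @param seed Integer seed.
#' @param panel Optional snp table; defaults to a
#'   \code{\link{synthetic_panel}} over \code{n_chrom} chromosomes.
#' @param n_chrom,chrom_length Passed to \code{\link{synthetic_panel}} when
#'   \code{panel} is NULL.
#' @return An \code{\link{eigenstrat}} dataset; sample groups are the
#'   population names.
#' @export
sample_genotypes <- function(freq, n_per_pop, mode = c("diploid",
                                                       "pseudohaploid"),
                             missing_rate = 0, seed = 1, panel = NULL,
                             n_chrom = 22, chrom_length = 1) {
  mode <- match.arg(mode)
  set.seed(seed)
  pops <- colnames(freq)
  n_snps <- nrow(freq)
  if (is.null(panel)) panel <- synthetic_panel(n_snps, n_chrom, chrom_length)
  stopifnot(nrow(panel) == n_snps)
  npp <- if (length(n_per_pop) == 1L)
    stats::setNames(rep(n_per_pop, length(pops)), pops)
  else n_per_pop[pops]
  cols <- list(); ids <- character(); grp <- character()
  for (pop in pops) {
    for (s in seq_len(npp[[pop]])) {
      g <- if (mode == "diploid") stats::rbinom(n_snps, 2L, freq[, pop])
           else 2L * stats::rbinom(n_snps, 1L, freq[, pop])
      cols[[length(cols) + 1L]] <- g
      ids <- c(ids, sprintf("%s_%d", pop, s))
      grp <- c(grp, pop)
    }
  }
  geno <- do.call(cbind, cols)
  if (missing_rate > 0)
    geno[stats::runif(length(geno)) < missing_rate] <- 9L
  ind <- data.frame(sample_id = ids, sex = "U", group = grp,
                    stringsAsFactors = FALSE)
  eigenstrat(geno, panel, ind, mode = mode)
}

#' Simulate admixed haplotypes with known local ancestry
#'
#' Local ancestry along each chromosome follows a two-state Markov process
#' on the genetic map with stationary distribution (alpha, 1 - alpha) and
#' relaxation rate \code{t_adm} per Morgan, so the ancestry autocovariance
#' at genetic distance d is alpha (1 - alpha) exp(-t_adm d) -- the
#' single-pulse model that admixture dating fits. Alleles are Bernoulli
#' draws from the local source's frequency.
#'
#' @param panel snp table (needs \code{chrom}, \code{genetic_pos}).
#' @param freq_a,freq_b Source allele frequencies per SNP.
#' @param t_adm Admixture time in generations (the switch rate per Morgan).
#' @param alpha Fraction of ancestry from source A.
#' @param n_hap Number of haplotypes.
#' @param seed Integer seed.
#' @return List with \code{haplotypes} (SNP x haplotype 0/1 allele matrix),
#'   \code{ancestry} (SNP x haplotype, 1 = source A), and \code{tracts}
#'   (data frame of true tract boundaries per haplotype).
#' @export
simulate_admixed_haplotypes <- function(panel, freq_a, freq_b, t_adm, alpha,
                                        n_hap, seed = 1) {
  stopifnot(t_adm >= 1, alpha > 0, alpha <= 1,
            length(freq_a) == nrow(panel), length(freq_b) == nrow(panel))
  set.seed(seed)
  n_snp <- nrow(panel)
  chroms <- unique(panel$chrom)
  anc <- matrix(0L, n_snp, n_hap)
  tracts <- vector("list", 0)
  for (h in seq_len(n_hap)) {
    for (ch in chroms) {
      idx <- which(panel$chrom == ch)
      g <- panel$genetic_pos[idx]
      L <- max(g)
      # jump chain: from A leave at rate t*(1-alpha), from B at rate t*alpha
      s0 <- stats::rbinom(1, 1, alpha)
      pos <- 0; state <- s0
      bks <- numeric()
      repeat {
        rate <- if (state == 1L) t_adm * (1 - alpha) else t_adm * alpha
        if (rate == 0) break                    # absorbing (alpha 0 or 1)
        pos <- pos + stats::rexp(1, rate)
        if (pos >= L) break
        bks <- c(bks, pos); state <- 1L - state
      }
      starts <- c(0, bks)
      # state alternates from s0 across successive tracts
      states <- if (s0 == 1L) rep_len(c(1L, 0L), length(starts))
                else rep_len(c(0L, 1L), length(starts))
      seg <- findInterval(g, starts)
      anc[idx, h] <- states[seg]
      tracts[[length(tracts) + 1L]] <-
        data.frame(hap = h, chrom = ch, start = starts,
                   end = c(bks, L), source = ifelse(states == 1L, "A", "B"))
    }
  }
  p <- matrix(freq_b, n_snp, n_hap)
  p[anc == 1L] <- matrix(freq_a, n_snp, n_hap)[anc == 1L]
  hap <- matrix(stats::rbinom(n_snp * n_hap, 1L, p), n_snp, n_hap)
  list(haplotypes = hap, ancestry = anc,
       tracts = do.call(rbind, tracts))
}
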
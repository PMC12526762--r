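#' Construct an EIGENSTRAT-style genotype dataset
#'
#' Bundles a SNP panel, a sample table and a genotype matrix into a single
#' validated object, the substrate of every statistic in the package.
#'
#' @param geno Integer matrix, one row per SNP and one column per sample.
#'   Entries count alternative alleles: 0, 1, 2, with 9 for missing.
#' @param snp Data frame with columns \code{snp_id}, \code{chrom},
#'   \code{genetic_pos} (Morgans), \code{physical_pos} (1-based bp),
#'   \code{ref}, \code{alt}.
#' @param ind Data frame with columns \code{sample_id}, \code{sex}
#'   (one of \code{"M"}, \code{"F"}, \code{"U"}) and \code{group}.
#' @param mode Either \code{"diploid"} or \code{"pseudohaploid"}. In
#'   pseudo-haploid mode a single allele is sampled per site so genotypes are
#'   coded 0/2 only; heterozygote codes are rejected.
#' @return An object of class \code{"eigenstrat"}: a list with elements
#'   \code{geno}, \code{snp}, \code{ind}, \code{mode}.
#' @export
eigenstrat <- function(geno, snp, ind, mode = c("diploid", "pseudohaploid")) {
  mode <- match.arg(mode)
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  snp <- as.data.frame(snp, stringsAsFactors = FALSE)
  ind <- as.data.frame(ind, stringsAsFactors = FALSE)
  # per-sample ploidy (allele observations per called genotype) so that
  # merged diploid + pseudo-haploid datasets count alleles correctly
  if (is.null(ind$ploidy))
    ind$ploidy <- if (mode == "pseudohaploid") 1L else 2L
  obj <- structure(list(geno = geno, snp = snp, ind = ind, mode = mode),
                   class = "eigenstrat")
  validate_eigenstrat(obj)
  obj
}

validate_eigenstrat <- function(x) {
  stopifnot(inherits(x, "eigenstrat"))
  need_snp <- c("snp_id", "chrom", "genetic_pos", "physical_pos", "ref", "alt")
  if (!all(need_snp %in% names(x$snp)))
    stop("snp table must have columns: ", paste(need_snp, collapse = ", "))
  need_ind <- c("sample_id", "sex", "group")
  if (!all(need_ind %in% names(x$ind)))
    stop("ind table must have columns: ", paste(need_ind, collapse = ", "))
  if (nrow(x$geno) != nrow(x$snp))
    stop("genotype matrix has ", nrow(x$geno), " rows but snp table has ",
         nrow(x$snp), " SNPs")
  if (ncol(x$geno) != nrow(x$ind))
    stop("genotype matrix has ", ncol(x$geno), " columns but ind table has ",
         nrow(x$ind), " samples")
  if (anyDuplicated(x$ind$sample_id))
    stop("duplicate sample_id in ind table")
  bad <- !(x$geno %in% c(0L, 1L, 2L, 9L))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or 9")
  if (x$mode == "pseudohaploid" && any(x$geno == 1L))
    stop("pseudohaploid mode cannot contain heterozygote code 1")
  if (any(x$snp$genetic_pos < 0)) stop("genetic positions must be >= 0")
  if (any(x$snp$physical_pos < 1)) stop("physical positions are 1-based (>= 1)")
  if (any(x$snp$ref == x$snp$alt)) stop("ref and alt alleles must differ")
  ord <- order_snp_canonical(x$snp)
  if (is.unsorted(ord) && !identical(ord, seq_len(nrow(x$snp))))
    for (ch in unique(x$snp$chrom)) {
      pp <- x$snp$physical_pos[x$snp$chrom == ch]
      if (is.unsorted(pp, strictly = FALSE))
        stop("SNPs on chromosome ", ch, " are not sorted by physical position")
      gp <- x$snp$genetic_pos[x$snp$chrom == ch]
      if (is.unsorted(gp, strictly = FALSE))
        stop("genetic positions on chromosome ", ch, " are not non-decreasing")
    }
  invisible(x)
}

order_snp_canonical <- function(snp) order(match(snp$chrom, unique(snp$chrom)),
                                           snp$physical_pos)

#' @export
print.eigenstrat <- function(x, ...) {
  cat("EIGENSTRAT dataset: ", nrow(x$snp), " SNPs x ", nrow(x$ind),
      " samples (", x$mode, ")\n", sep = "")
  cat("  chromosomes: ", paste(unique(x$snp$chrom), collapse = " "), "\n",
      sep = "")
  cat("  groups: ", paste(unique(x$ind$group), collapse = " "), "\n", sep = "")
  invisible(x)
}

# chromosome labels are normalized by stripping a leading "chr";
# 23/24 (X/Y) are accepted but flagged non-autosomal by is_autosome()
normalize_chrom <- function(chrom) sub("^chr", "", as.character(chrom))

is_autosome <- function(chrom) normalize_chrom(chrom) %in% as.character(1:22)

#' Read an unpacked EIGENSTRAT dataset
#'
#' Reads the classic geno/snp/ind triplet. The .snp file has six whitespace
#' separated columns (snp_id, chrom, genetic position in Morgans, physical
#' position, ref, alt); the .geno file is ASCII, one row per SNP with one
#' digit (0/1/2/9) per sample; the .ind file has three columns (sample_id,
#' sex, group). Packed (binary) EIGENSTRAT is recognized and rejected.
#'
#' @param prefix Path prefix; \code{<prefix>.geno}, \code{<prefix>.snp} and
#'   \code{<prefix>.ind} are read, unless the individual paths are given.
#' @param geno,snp,ind Optional explicit file paths overriding \code{prefix}.
#' @param genetic_unit Unit of the genetic position column: \code{"morgan"}
#'   (the panel convention, default) or \code{"cM"}; positions are stored in
#'   Morgans internally.
#' @return An \code{\link{eigenstrat}} object. The mode is inferred:
#'   \code{"pseudohaploid"} if no heterozygote code occurs.
#' @export
read_eigenstrat <- function(prefix = NULL, geno = NULL, snp = NULL, ind = NULL,
                            genetic_unit = c("morgan", "cM")) {
  genetic_unit <- match.arg(genetic_unit)
  if (!is.null(prefix)) {
    if (is.null(geno)) geno <- paste0(prefix, ".geno")
    if (is.null(snp)) snp <- paste0(prefix, ".snp")
    if (is.null(ind)) ind <- paste0(prefix, ".ind")
  }
  for (f in c(geno, snp, ind)) if (!file.exists(f)) stop("file not found: ", f)

  snp_df <- utils::read.table(snp, header = FALSE, stringsAsFactors = FALSE,
                              col.names = c("snp_id", "chrom", "genetic_pos",
                                            "physical_pos", "ref", "alt"))
  if (ncol(snp_df) != 6) stop("snp file ", snp, ": expected 6 columns")
  snp_df$chrom <- normalize_chrom(snp_df$chrom)
  if (genetic_unit == "cM") snp_df$genetic_pos <- snp_df$genetic_pos / 100

  ind_df <- utils::read.table(ind, header = FALSE, stringsAsFactors = FALSE,
                              col.names = c("sample_id", "sex", "group"))

  lines <- readLines(geno, warn = FALSE)
  if (length(lines) >= 1 && startsWith(lines[[1]], "GENO"))
    stop("packed (binary) EIGENSTRAT is not supported; convert to the ",
         "unpacked ASCII dialect first: ", geno)
  if (length(lines) != nrow(snp_df))
    stop("geno file ", geno, ": ", length(lines), " rows but snp file has ",
         nrow(snp_df), " SNPs")
  n_samp <- nrow(ind_df)
  nch <- nchar(lines)
  bad <- which(nch != n_samp)
  if (length(bad))
    stop("geno file ", geno, ": row ", bad[[1]], " has ", nch[bad[[1]]],
         " characters but ", n_samp, " samples are declared")
  codes <- matrix(utf8ToInt(paste(lines, collapse = "")), nrow = n_samp)
  codes <- t(codes) - utf8ToInt("0")
  ok <- array(codes %in% c(0L, 1L, 2L, 9L), dim(codes))
  if (!all(ok)) {
    idx <- which(!ok, arr.ind = TRUE)[1, ]
    stop("geno file ", geno, ": invalid digit at row ", idx[[1]],
         ", sample column ", idx[[2]])
  }
  mode <- if (any(codes == 1L)) "diploid" else "pseudohaploid"
  eigenstrat(codes, snp_df, ind_df, mode = mode)
}

#' Write an unpacked EIGENSTRAT dataset
#'
#' Writers produce ASCII files with LF line endings; genetic positions are
#' written in Morgans with at least six significant digits, so a write/read
#' round trip is the identity.
#'
#' @param x An \code{\link{eigenstrat}} object.
#' @param prefix Output path prefix (\code{.geno}, \code{.snp}, \code{.ind}
#'   are appended).
#' @return Invisibly, the three file paths.
#' @export
write_eigenstrat <- function(x, prefix) {
  validate_eigenstrat(x)
  dir <- dirname(prefix)
  if (!dir.exists(dir)) stop("unwritable path: directory does not exist: ", dir)
  paths <- paste0(prefix, c(".geno", ".snp", ".ind"))
  rows <- vapply(seq_len(nrow(x$geno)), function(i)
    paste(x$geno[i, ], collapse = ""), character(1))
  con <- file(paths[[1]], open = "wb")
  writeLines(rows, con, sep = "\n")
  close(con)
  snp_out <- data.frame(x$snp$snp_id, x$snp$chrom,
                        formatC(x$snp$genetic_pos, format = "g", digits = 8),
                        x$snp$physical_pos, x$snp$ref, x$snp$alt)
  con <- file(paths[[2]], open = "wb")
  utils::write.table(snp_out, con, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = "\t", eol = "\n")
  close(con)
  con <- file(paths[[3]], open = "wb")
  utils::write.table(x$ind[, c("sample_id", "sex", "group")], con,
                     quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = "\t", eol = "\n")
  close(con)
  invisible(paths)
}

#' Intersect two datasets on shared SNPs
#'
#' Keeps SNPs matched on (chromosome, physical position) with consistent
#' alleles. When ref/alt are swapped between the datasets the second
#' dataset's codes are recoded g -> 2 - g (9 stays missing); sites whose
#' allele pairs disagree are dropped and counted.
#'
#' @param a,b \code{\link{eigenstrat}} objects.
#' @return An \code{\link{eigenstrat}} object on the intersected panel with
#'   the samples of both inputs, plus attribute \code{"n_dropped"}: the
#'   number of shared positions discarded for allele mismatch.
#' @export
intersect_datasets <- function(a, b) {
  validate_eigenstrat(a); validate_eigenstrat(b)
  key_a <- paste(normalize_chrom(a$snp$chrom), a$snp$physical_pos)
  key_b <- paste(normalize_chrom(b$snp$chrom), b$snp$physical_pos)
  ia <- which(key_a %in% key_b)
  if (!length(ia)) stop("no overlapping SNPs between the two datasets")
  ib <- match(key_a[ia], key_b)
  same <- a$snp$ref[ia] == b$snp$ref[ib] & a$snp$alt[ia] == b$snp$alt[ib]
  flip <- a$snp$ref[ia] == b$snp$alt[ib] & a$snp$alt[ia] == b$snp$ref[ib]
  keep <- same | flip
  n_dropped <- sum(!keep)
  if (n_dropped)
    message("intersect_datasets: dropped ", n_dropped,
            " SNPs with inconsistent alleles")
  ia <- ia[keep]; ib <- ib[keep]; flip <- flip[keep]
  if (!length(ia)) stop("no overlapping SNPs with consistent alleles")
  gb <- b$geno[ib, , drop = FALSE]
  if (any(flip)) {
    gflip <- gb[flip, , drop = FALSE]
    miss <- gflip == 9L
    gflip <- 2L - gflip
    gflip[miss] <- 9L
    gb[flip, ] <- gflip
  }
  geno <- cbind(a$geno[ia, , drop = FALSE], gb)
  common <- intersect(names(a$ind), names(b$ind))
  ind <- rbind(a$ind[, common, drop = FALSE], b$ind[, common, drop = FALSE])
  ind$sample_id <- make.unique(ind$sample_id)
  mode <- if (a$mode == "diploid" || b$mode == "diploid") "diploid"
          else "pseudohaploid"
  out <- eigenstrat(geno, a$snp[ia, , drop = FALSE], ind, mode = mode)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Per-group allele counts and frequencies
#'
#' A diploid call contributes two allele observations; a pseudo-haploid call
#' contributes one (its single sampled allele: code 0 counts 0 alt of 1,
#' code 2 counts 1 alt of 1). Frequencies are \code{NA} where a group has no
#' observed alleles.
#'
#' @param x An \code{\link{eigenstrat}} object.
#' @param groups Optional character vector assigning each sample to a group;
#'   defaults to \code{x$ind$group}. A two-column data frame
#'   (sample_id, group) is also accepted as an override.
#' @return A list of class \code{"group_freq"}: matrices \code{alt_count},
#'   \code{total} (observed allele count) and \code{freq}, each
#'   SNPs x groups.
#' @export
group_allele_stats <- function(x, groups = NULL) {
  validate_eigenstrat(x)
  if (is.null(groups)) groups <- x$ind$group
  if (is.data.frame(groups)) {
    m <- match(x$ind$sample_id, groups[[1]])
    if (anyNA(m)) stop("group override is missing samples: ",
                       paste(x$ind$sample_id[is.na(m)], collapse = ", "))
    groups <- as.character(groups[[2]][m])
  }
  stopifnot(length(groups) == ncol(x$geno))
  glev <- unique(groups)
  ploidy <- x$ind$ploidy
  g <- x$geno
  called <- g != 9L
  alt <- g
  alt[!called] <- 0L
  # a pseudo-haploid call (ploidy 1) carries one sampled allele: 2 -> 1 alt
  ph <- which(ploidy == 1L)
  if (length(ph)) alt[, ph] <- alt[, ph, drop = FALSE] %/% 2L
  gi <- match(groups, glev)
  n_g <- length(glev)
  alt_count <- matrix(0, nrow(g), n_g)
  total <- matrix(0, nrow(g), n_g)
  for (k in seq_len(n_g)) {
    cols <- which(gi == k)
    if (length(cols) == 0L) stop("group '", glev[[k]], "' is empty")
    alt_count[, k] <- rowSums(alt[, cols, drop = FALSE])
    total[, k] <- rowSums(called[, cols, drop = FALSE] *
                            rep(ploidy[cols], each = nrow(g)))
  }
  freq <- alt_count / total
  freq[total == 0] <- NA_real_
  colnames(alt_count) <- colnames(total) <- colnames(freq) <- glev
  structure(list(alt_count = alt_count, total = total, freq = freq,
                 groups = glev, snp = x$snp),
            class = "group_freq")
}
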
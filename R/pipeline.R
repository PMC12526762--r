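# --- configuration, orchestration and provenance ---------------------------

pipeline_defaults <- list(
  blgsize = 0.05, binsize = 0.001, maxdis = 0.5, lovalfit = 0.0045,
  min_len_cm = 12, min_snp_per_cm = 220, sex_male_ratio = 0.3,
  sex_female_ratio = 0.1, min_base_q = 30, min_map_q = 30,
  generation_time = 29)

known_stage_types <- c("simulate_graph", "fstat", "qpadm", "dates", "pmr")

# counter-based per-stage seed derivation from the global seed, kept
# within 32-bit integer range so stages can be re-run in isolation
stage_seed <- function(global_seed, index) {
  as.integer((as.numeric(global_seed) + 100003 * index) %% 2147483647)
}

validate_config <- function(cfg) {
  allowed_top <- c("seed", "out_dir", "stages")
  extra <- setdiff(names(cfg), allowed_top)
  if (length(extra))
    stop("unknown configuration key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  if (is.null(cfg$stages)) cfg$stages <- list()
  allowed_stage <- c("name", "type", "params", "input")
  for (i in seq_along(cfg$stages)) {
    st <- cfg$stages[[i]]
    extra <- setdiff(names(st), allowed_stage)
    if (length(extra))
      stop("stage ", i, ": unknown key(s): ",
           paste(extra, collapse = ", "), call. = FALSE)
    if (is.null(st$type) || !st$type %in% known_stage_types)
      stop("stage ", i, ": unknown or missing type '", st$type, "'",
           call. = FALSE)
  }
  cfg
}

#' Run a configured analysis pipeline
#'
#' Executes the configured stages in order (simulate, f-statistics,
#' qpAdm, admixture dating, PMR), writing every artifact under the output
#' directory and recording a JSON manifest with the verbatim
#' configuration, the seed, per-stage parameters and the MD5 hash of
#' every artifact, so a run is fully reproducible from (config, seed).
#'
#' @param config Path to a YAML configuration file, or an equivalent
#'   nested list. Top-level keys: \code{seed}, \code{out_dir},
#'   \code{stages} (list of \code{name}/\code{type}/\code{params}/
#'   \code{input}); unknown keys are rejected.
#' @param out_dir Output directory (overrides the config's).
#' @param seed Global seed (overrides the config's); per-stage seeds are
#'   derived by a counter scheme.
#' @return Invisibly, the manifest list (also written to
#'   \code{manifest.json}).
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  cfg_raw <- if (is.character(config)) yaml::read_yaml(config) else config
  cfg <- validate_config(cfg_raw)
  if (is.null(out_dir)) out_dir <- cfg$out_dir
  if (is.null(out_dir)) stop("no output directory configured")
  if (is.null(seed)) seed <- cfg$seed
  if (is.null(seed)) seed <- 1L
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  artifacts <- list()
  stage_log <- list()
  datasets <- list()   # in-memory handoff between stages, keyed by name

  add_artifact <- function(stage, path) {
    artifacts[[length(artifacts) + 1L]] <<-
      list(stage = stage, path = path,
           md5 = unname(tools::md5sum(path)))
  }

  for (i in seq_along(cfg$stages)) {
    st <- cfg$stages[[i]]
    nm <- if (!is.null(st$name)) st$name else paste0("stage", i)
    sseed <- stage_seed(seed, i)
    prm <- if (is.null(st$params)) list() else st$params
    t0 <- Sys.time()
    if (st$type == "simulate_graph") {
      gr <- admixture_graph(do.call(rbind, lapply(prm$edges, as.data.frame)),
                            if (!is.null(prm$admixtures))
                              do.call(rbind, lapply(prm$admixtures,
                                                    as.data.frame)))
      fr <- simulate_frequencies(gr, prm$n_snps, seed = sseed)
      ds <- sample_genotypes(fr, prm$n_per_pop,
                             mode = if (is.null(prm$mode)) "diploid"
                                    else prm$mode,
                             missing_rate = if (is.null(prm$missing_rate)) 0
                                            else prm$missing_rate,
                             seed = sseed,
                             n_chrom = if (is.null(prm$n_chrom)) 22
                                       else prm$n_chrom)
      datasets[[nm]] <- ds
      prefix <- file.path(out_dir, nm)
      paths <- write_eigenstrat(ds, prefix)
      for (p in paths) add_artifact(nm, p)
    } else {
      ds <- datasets[[st$input]]
      if (is.null(ds)) stop("stage ", nm, ": unknown input '", st$input, "'")
      blocks <- make_blocks(ds, blgsize = if (is.null(prm$blgsize))
        pipeline_defaults$blgsize else prm$blgsize)
      out_path <- file.path(out_dir, paste0(nm, ".tsv"))
      if (st$type == "fstat") {
        res <- if (prm$stat == "f3")
          f3(ds, prm$pops[[1]], prm$pops[[2]], prm$pops[[3]], blocks)
        else f4(ds, prm$pops[[1]], prm$pops[[2]], prm$pops[[3]],
                prm$pops[[4]], blocks)
        tab <- data.frame(stat = res$kind,
                          pops = paste(res$pops, collapse = ","),
                          est = res$est, se = res$se, z = res$z,
                          n_snps = res$n_snps, n_blocks = res$n_blocks)
        utils::write.table(tab, out_path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
      } else if (st$type == "qpadm") {
        fit <- qpadm_fit(ds, prm$target, unlist(prm$sources),
                         unlist(prm$right), blocks)
        tab <- data.frame(source = fit$sources,
                          weight = unname(fit$weights),
                          se = unname(fit$se), p = fit$p,
                          feasible = fit$feasible)
        utils::write.table(tab, out_path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
      } else if (st$type == "dates") {
        gf <- group_allele_stats(ds)
        fit <- date_admixture(ds, gf$freq[, prm$ref_a], gf$freq[, prm$ref_b],
                              target = prm$target,
                              binsize = if (is.null(prm$binsize))
                                pipeline_defaults$binsize else prm$binsize,
                              maxdis = if (is.null(prm$maxdis))
                                pipeline_defaults$maxdis else prm$maxdis,
                              lovalfit = if (is.null(prm$lovalfit))
                                pipeline_defaults$lovalfit else prm$lovalfit)
        tab <- data.frame(lambda = fit$lambda, se = fit$se,
                          years = fit$lambda *
                            pipeline_defaults$generation_time)
        utils::write.table(tab, out_path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
      } else if (st$type == "pmr") {
        ph <- if (ds$mode == "diploid") pseudohaploidize(ds, seed = sseed)
              else ds
        tab <- classify_degree(pmr_all_pairs(ph))
        utils::write.table(tab, out_path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
      }
      add_artifact(nm, out_path)
    }
    stage_log[[length(stage_log) + 1L]] <-
      list(name = nm, type = st$type, seed = sseed,
           elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }

  manifest <- list(
    package = "steppekit",
    version = as.character(utils::packageVersion("steppekit")),
    seed = seed,
    config = cfg_raw,
    stages = stage_log,
    artifacts = artifacts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
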
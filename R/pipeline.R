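# Config-driven orchestration of the full chain:
# simulate -> meta -> finemap -> mr, with per-stage manifests (input hashes,
# parameters, seed, row counts) and a machine-readable JSON run report.
# Stages communicate through TSV files in `out_dir`, so any stage can be
# re-run on its own against existing outputs.

pipeline_defaults <- function() {
  list(
    seed = 1,
    out_dir = "metamr_run",
    stages = c("simulate", "meta", "finemap", "mr"),
    log_level = "info",
    simulate = list(n_cohorts = 2, n_per_cohort = c(2741, 15061), n_loci = 20,
                    snps_per_locus = 50, ld_rho = 0.5, causal_fraction = 0.5,
                    causal_z = 8, mr_n_instruments = 200,
                    mr_pleiotropy_fraction = 0, trait = "WBCc"),
    meta = list(maf_threshold = 0.05, genomic_control = TRUE,
                gc_mode = "post_meta"),
    finemap = list(alpha = 5e-9, window = 250000, level = 0.99,
                   reference_loci = NULL),
    mr = list(alpha = 5e-9, r2_max = 0.001, window = 250000,
              proxy_r2_min = 0.8, n_boot = 1000, q_alpha = 0.05,
              exclude_pleiotropy = TRUE))
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Load a pipeline run configuration
#'
#' Reads a YAML config file (one block per stage) and fills unset values
#' with the package defaults. `overrides` (a named list, e.g. from CLI
#' flags) take precedence over file values.
#'
#' @param path path to a YAML file, or `NULL` for pure defaults.
#' @param overrides named list merged on top of the file values.
#' @return full configuration list.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- pipeline_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stopf("config file not found: %s", path)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  merge_config(cfg, overrides)
}

log_msg <- function(level, cfg, fmt, ...) {
  levels <- c(debug = 1, info = 2, warn = 3, error = 4)
  if (levels[[level]] >= levels[[cfg$log_level %||% "info"]])
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}

stage_manifest <- function(out_dir, stage, params, seed, inputs, outputs,
                           counts) {
  hash <- function(paths) {
    paths <- paths[file.exists(paths)]
    setNames(as.list(unname(tools::md5sum(paths))), basename(paths))
  }
  man <- list(stage = stage, seed = seed, parameters = params,
              inputs = hash(inputs), outputs = hash(outputs),
              row_counts = counts)
  path <- file.path(out_dir, sprintf("manifest_%s.json", stage))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  man
}

require_input <- function(path, stage) {
  if (!file.exists(path))
    stopf("stage '%s': required input missing: %s", stage, path)
  path
}

stage_simulate <- function(cfg) {
  p <- cfg$simulate
  scfg <- do.call(sim_config, c(list(seed = cfg$seed), p))
  sim <- simulate_cohort_sumstats(scfg)
  paths <- character()
  for (i in seq_along(sim$cohorts)) {
    f <- file.path(cfg$out_dir, sprintf("cohort_%d.tsv", i))
    write_sumstats(sim$cohorts[[i]], f)
    paths <- c(paths, f)
  }
  truth_f <- file.path(cfg$out_dir, "truth_loci.json")
  jsonlite::write_json(sim$truth, truth_f, auto_unbox = TRUE, digits = NA)
  mr <- simulate_mr_dataset(scfg)
  exp_f <- file.path(cfg$out_dir, "mr_exposure.tsv")
  out_f <- file.path(cfg$out_dir, "mr_outcome.tsv")
  ld_f <- file.path(cfg$out_dir, "mr_ld.tsv")
  mrtruth_f <- file.path(cfg$out_dir, "truth_mr.json")
  write_sumstats(mr$exposure, exp_f)
  write_sumstats(mr$outcome, out_f)
  write_ld_matrix(mr$ld, ld_f)
  jsonlite::write_json(list(theta = mr$truth$theta,
                            valid = as.list(mr$truth$valid),
                            seed = mr$truth$seed),
                       mrtruth_f, auto_unbox = TRUE, digits = NA)
  outs <- c(paths, truth_f, exp_f, out_f, ld_f, mrtruth_f)
  stage_manifest(cfg$out_dir, "simulate", p, cfg$seed, character(), outs,
                 list(n_snps = nrow(sim$cohorts[[1]]),
                      n_instruments = nrow(mr$exposure)))
}

stage_meta <- function(cfg) {
  p <- cfg$meta
  ins <- list.files(cfg$out_dir, "^cohort_\\d+\\.tsv$", full.names = TRUE)
  if (!length(ins)) stopf("stage 'meta': no cohort_*.tsv found in %s", cfg$out_dir)
  tables <- lapply(seq_along(ins), function(i)
    read_sumstats(ins[i], cohort_name = sprintf("cohort_%d", i),
                  trait = cfg$simulate$trait %||% "trait"))
  tables <- lapply(tables, filter_maf, threshold = p$maf_threshold)
  if (identical(p$gc_mode, "per_cohort"))
    tables <- lapply(tables, genomic_control_table)
  tables <- harmonize_alleles(tables, reference = tables[[1]])
  meta <- meta_analyze(tables)
  if (isTRUE(p$genomic_control) && !identical(p$gc_mode, "per_cohort"))
    meta <- genomic_control(meta)
  meta_f <- file.path(cfg$out_dir, "meta.tsv")
  write_meta(meta, meta_f)
  qq <- qq_data(meta)
  qq_f <- file.path(cfg$out_dir, "qq.tsv")
  write.table(qq, qq_f, sep = "\t", quote = FALSE, row.names = FALSE)
  report_f <- file.path(cfg$out_dir, "sample_size_report.tsv")
  write.table(sample_size_report(tables), report_f, sep = "\t", quote = FALSE,
              row.names = FALSE)
  stage_manifest(cfg$out_dir, "meta", p, cfg$seed, ins,
                 c(meta_f, qq_f, report_f),
                 list(n_snps = nrow(meta),
                      lambda_gc = meta$lambda_gc[1]))
}

stage_finemap <- function(cfg) {
  p <- cfg$finemap
  meta_f <- require_input(file.path(cfg$out_dir, "meta.tsv"), "finemap")
  meta <- read_meta(meta_f)
  sig <- select_significant(meta, p$alpha)
  loci <- define_loci(sig, p$window)
  if (!is.null(p$reference_loci)) {
    ref <- read_reference_loci(require_input(p$reference_loci, "finemap"))
    loci <- novelty_check(loci, ref, p$window)
  }
  loci_f <- file.path(cfg$out_dir, "loci.tsv")
  write_loci(loci, loci_f)
  outs <- loci_f
  counts <- list(n_significant = nrow(sig), n_loci = nrow(loci))
  if (nrow(loci)) {
    fm <- finemap_loci(meta, loci, window = p$window, level = p$level)
    snps_f <- file.path(cfg$out_dir, "finemap_snps.tsv")
    sum_f <- file.path(cfg$out_dir, "finemap_summary.tsv")
    write.table(fm$snps, snps_f, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(fm$summary, sum_f, sep = "\t", quote = FALSE,
                row.names = FALSE)
    outs <- c(outs, snps_f, sum_f)
    counts$n_high_confidence <- sum(fm$summary$high_confidence)
  }
  stage_manifest(cfg$out_dir, "finemap", p, cfg$seed, meta_f, outs, counts)
}

stage_mr <- function(cfg) {
  p <- cfg$mr
  exp_f <- require_input(file.path(cfg$out_dir, "mr_exposure.tsv"), "mr")
  out_f <- require_input(file.path(cfg$out_dir, "mr_outcome.tsv"), "mr")
  ld_f <- require_input(file.path(cfg$out_dir, "mr_ld.tsv"), "mr")
  exposure <- read_sumstats(exp_f, cohort_name = "exposure")
  outcome <- read_sumstats(out_f, cohort_name = "outcome")
  ld <- read_ld_matrix(ld_f)
  exp_meta <- meta_analyze(list(exposure))
  iv <- clump_instruments(exp_meta, ld, alpha = p$alpha, r2_max = p$r2_max,
                          window = p$window)
  if (length(iv) < 3)
    stopf("stage 'mr': only %d instrument(s) pass clumping; need >= 3",
          length(iv))
  proxies <- NULL
  if (!is.null(p$proxy_table))
    proxies <- read.delim(require_input(p$proxy_table, "mr"), sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("snp_id", "proxy", "r2"))
  dat <- make_instruments(exp_meta, outcome, iv, proxy_table = proxies,
                          r2_min = p$proxy_r2_min)
  excluded <- character()
  if (isTRUE(p$exclude_pleiotropy) && nrow(dat) >= 3) {
    excl <- exclude_pleiotropic(dat, q_alpha = p$q_alpha)
    dat <- excl$instruments
    excluded <- excl$excluded
  }
  rep_df <- mr_report(dat, n_boot = p$n_boot, seed = child_seed(cfg$seed, 91))
  mr_f <- file.path(cfg$out_dir, "mr_results.tsv")
  write.table(rep_df, mr_f, sep = "\t", quote = FALSE, row.names = FALSE)
  run_f <- file.path(cfg$out_dir, "mr_run_report.json")
  jsonlite::write_json(
    list(n_clumped = length(iv), n_instruments = nrow(dat),
         excluded_pleiotropic = excluded, seed = cfg$seed,
         thresholds = p[c("alpha", "r2_max", "window", "proxy_r2_min",
                          "q_alpha")]),
    run_f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage_manifest(cfg$out_dir, "mr", p, cfg$seed, c(exp_f, out_f, ld_f),
                 c(mr_f, run_f),
                 list(n_clumped = length(iv), n_instruments = nrow(dat)))
}

#' Run the analysis pipeline from a declarative configuration
#'
#' Executes the requested stages in dependency order
#' (simulate, meta, finemap, mr). Each stage writes its outputs and a
#' manifest (parameters, seed, input/output MD5 hashes, row counts) under
#' `out_dir`; the final run report echoes every analysis threshold, so no
#' default is silent. A stage failure raises an error after writing a
#' structured `run_report.json` with the failure recorded.
#'
#' @param config a configuration list (see [load_run_config()]) or a path to
#'   a YAML config file.
#' @param overrides named list applied on top of `config`.
#' @return the run report, invisibly (also written to
#'   `out_dir/run_report.json`).
#' @export
run_pipeline <- function(config = NULL, overrides = list()) {
  cfg <- if (is.character(config)) load_run_config(config, overrides)
         else merge_config(merge_config(pipeline_defaults(), config %||% list()),
                           overrides)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  order <- c("simulate", "meta", "finemap", "mr")
  stages <- order[order %in% cfg$stages]
  runners <- list(simulate = stage_simulate, meta = stage_meta,
                  finemap = stage_finemap, mr = stage_mr)
  manifests <- list()
  status <- "ok"
  err <- NULL
  for (st in stages) {
    log_msg("info", cfg, "running stage '%s'", st)
    res <- tryCatch(runners[[st]](cfg), error = function(e) e)
    if (inherits(res, "error")) {
      status <- "failed"
      err <- list(stage = st, message = conditionMessage(res))
      break
    }
    manifests[[st]] <- res
  }
  report <- list(
    status = status, error = err, stages = stages, seed = cfg$seed,
    thresholds = list(maf_threshold = cfg$meta$maf_threshold,
                      alpha = cfg$finemap$alpha,
                      window = cfg$finemap$window,
                      clump_r2 = cfg$mr$r2_max,
                      credible_level = cfg$finemap$level),
    manifests = manifests)
  jsonlite::write_json(report, file.path(cfg$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (status == "failed")
    stopf("pipeline stage '%s' failed: %s", err$stage, err$message)
  invisible(report)
}
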
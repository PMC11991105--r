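#' Validate and normalize a pipeline configuration
#'
#' Accepts a YAML file path or a nested list. Required input paths are
#' checked for existence, stage blocks are completed with the documented
#' defaults (filter 0.1/0.05 + 50/10/0.1, sweep window 50 at top 0.05%,
#' GEA K = 4 at FDR 1%, environment pruning at |r| 0.8), and unknown keys
#' produce a warning, not an error.
#'
#' @param config YAML path or list.
#' @return normalized `pipeline_config` list, or a stop() carrying all
#'   validation errors.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  known <- c("paths", "seed", "log_level", "filter", "sweep", "gea",
             "env_prune", "rona")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    warning("unknown configuration key(s) ignored: ",
            paste(unknown, collapse = ", "))

  errors <- character()
  paths <- config$paths
  for (field in c("vcf", "pop_map", "env_current", "out_dir")) {
    if (is.null(paths[[field]]))
      errors <- c(errors, paste0("missing required path: paths$", field))
  }
  for (field in c("vcf", "pop_map", "env_current")) {
    p <- paths[[field]]
    if (!is.null(p) && !file.exists(p))
      errors <- c(errors, paste0("paths$", field, " does not exist: ", p))
  }
  futures <- paths$env_future
  if (!is.null(futures)) {
    for (sc in names(futures))
      if (!file.exists(futures[[sc]]))
        errors <- c(errors, paste0("paths$env_future$", sc,
                                   " does not exist: ", futures[[sc]]))
  }
  if (length(errors)) stop(paste(errors, collapse = "\n"))

  take <- function(block, builder) do.call(builder, as.list(block))
  cfg <- list(
    paths = paths,
    seed = if (is.null(config$seed)) 1L else as.integer(config$seed),
    log_level = if (is.null(config$log_level)) "info" else config$log_level,
    filter = take(config$filter, filter_config),
    sweep = take(config$sweep, sweep_config),
    gea = take(config$gea, gea_config),
    env_prune = take(config$env_prune, env_prune_config),
    rona = take(config$rona, rona_config))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full adaptive-genomics pipeline
#'
#' Stage order: SNP filtering (missingness, MAF, LD pruning) -> sweep scan
#' -> environmental-variable pruning -> genotype-environment association ->
#' RONA projection. Each stage writes its outputs into `paths$out_dir` and
#' is skipped on rerun if those outputs already exist (delete a stage's
#' files to recompute it). The global seed spawns a fixed per-stage
#' substream so stage results do not depend on execution order, and the
#' seed is recorded in every output header.
#'
#' @param config a `pipeline_config` from [validate_config()] (or a path /
#'   list, validated on the fly).
#' @return list with `out_dir`, `stages_run` (stages actually recomputed),
#'   `files` (named output paths) and `log` (path of the run log).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  out <- config$paths$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "pipeline.log")
  log_line <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    paste0(...))
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    if (identical(config$log_level, "info")) message(line)
  }
  seed <- config$seed
  files <- list(
    filtered_vcf = file.path(out, "filtered.vcf"),
    filter_report = file.path(out, "filter_report.tsv"),
    sweep_windows = file.path(out, "sweep_windows.tsv"),
    sweep_regions = file.path(out, "sweep_regions.bed"),
    env_retained = file.path(out, "env_retained.tsv"),
    gea_associations = file.path(out, "gea_associations.tsv"),
    gea_candidates = file.path(out, "gea_candidates.tsv"),
    rona_models = file.path(out, "rona_models.tsv"),
    rona_report = file.path(out, "rona_report.tsv"))
  stages_run <- character()

  pop_map <- read_pop_map(config$paths$pop_map)
  env <- read_env_table(config$paths$env_current,
                        unlist(config$paths$env_future))

  # -- stage 1: filter ------------------------------------------------
  if (!all(file.exists(files$filtered_vcf, files$filter_report))) {
    set.seed(seed + 101L)
    log_line("filter: reading ", config$paths$vcf)
    g <- read_vcf(config$paths$vcf, pop_map = pop_map)
    fm <- filter_missing_maf(g, config$filter)
    lp <- ld_prune(fm$genotypes, config$filter)
    report <- rbind(fm$report,
                    data.frame(rule = "ld_prune",
                               threshold = config$filter$ld_r2_threshold,
                               removed = length(lp$pruned)))
    report$retained_after <- c(
      n_snps(g) - cumsum(report$removed))
    write_vcf(lp$genotypes, files$filtered_vcf)
    write_stage_tsv(report, files$filter_report, seed)
    log_line("filter: ", n_snps(lp$genotypes), " SNPs retained")
    stages_run <- c(stages_run, "filter")
  } else log_line("filter: outputs present, skipped")
  g <- read_vcf(files$filtered_vcf, pop_map = pop_map)

  # -- stage 2: sweep scan --------------------------------------------
  # runs on the missingness-filtered but MAF-unfiltered, unpruned SNP set:
  # rare variants carry the SFS signature and LD pruning would erase the
  # flanking-LD pattern the statistic measures
  if (!all(file.exists(files$sweep_windows, files$sweep_regions))) {
    set.seed(seed + 202L)
    g_raw <- read_vcf(config$paths$vcf, pop_map = pop_map)
    cfg_m <- config$filter
    cfg_m$min_maf <- 0
    g_sweep <- filter_missing_maf(g_raw, cfg_m)$genotypes
    scan <- mu_scan(g_sweep, config$sweep)
    write_stage_tsv(scan$windows, files$sweep_windows, seed)
    con <- file(files$sweep_regions, "w")
    writeLines(sprintf("# seed: %d", seed), con)
    close(con)
    if (nrow(scan$regions)) {
      tmp <- tempfile()
      write_regions(scan$regions, tmp)
      file.append(files$sweep_regions, tmp)
      unlink(tmp)
    }
    log_line("sweep: ", nrow(scan$regions), " region(s), ",
             scan$n_snps_in_regions, " SNP(s) inside")
    stages_run <- c(stages_run, "sweep")
  } else log_line("sweep: outputs present, skipped")

  # -- stage 3: environment pruning -----------------------------------
  if (!file.exists(files$env_retained)) {
    pr <- prune_env(env, config$env_prune)
    write_stage_tsv(data.frame(variable = pr$retained),
                    files$env_retained, seed)
    log_line("env_prune: ", length(pr$retained), " variable(s) retained")
    stages_run <- c(stages_run, "env_prune")
  } else log_line("env_prune: outputs present, skipped")
  retained <- read_stage_tsv(files$env_retained)$variable
  env_r <- env_table(lapply(env$values, function(m)
    m[, retained, drop = FALSE]), env$site_ids, retained)

  # -- stage 4: GEA ----------------------------------------------------
  if (!all(file.exists(files$gea_associations, files$gea_candidates))) {
    set.seed(seed + 404L)
    U <- estimate_latent_factors(g, config$gea$K)
    res <- fit_association(g, env_r, U, config$gea)
    write_stage_tsv(res$stats, files$gea_associations, seed)
    cand <- res$stats[res$stats$candidate, c("variable", "snp")]
    cand$chrom <- g$chrom[cand$snp]
    cand$pos <- g$pos[cand$snp]
    write_stage_tsv(cand, files$gea_candidates, seed)
    log_line("gea: ", length(unique(cand$snp)),
             " candidate SNP(s) across variables")
    stages_run <- c(stages_run, "gea")
  } else log_line("gea: outputs present, skipped")
  cand <- read_stage_tsv(files$gea_candidates)

  # -- stage 5: RONA ---------------------------------------------------
  if (!all(file.exists(files$rona_report, files$rona_models))) {
    set.seed(seed + 505L)
    cand_list <- split(cand$snp, cand$variable)
    scenarios <- setdiff(env$scenarios, "current")
    if (nrow(cand) && length(scenarios)) {
      models <- fit_freq_env(g, env_r, cand_list, config$rona)
      reports <- lapply(scenarios, function(sc)
        compute_rona(models, env_r, sc, config$rona)$report)
      write_stage_tsv(models$models, files$rona_models, seed)
      write_stage_tsv(do.call(rbind, reports), files$rona_report, seed)
    } else {
      log_line("rona: no candidates or no future scenario; empty report")
      write_stage_tsv(data.frame(), files$rona_models, seed)
      write_stage_tsv(data.frame(), files$rona_report, seed)
    }
    log_line("rona: ", length(scenarios), " scenario(s) projected")
    stages_run <- c(stages_run, "rona")
  } else log_line("rona: outputs present, skipped")

  list(out_dir = out, stages_run = stages_run, files = files,
       log = log_path)
}

write_stage_tsv <- function(df, path, seed) {
  con <- file(path, "w")
  writeLines(sprintf("# seed: %d", seed), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  close(con)
  invisible(path)
}

read_stage_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE)
}
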
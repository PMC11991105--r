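#' Environmental-variable correlation pruning configuration
#'
#' @param max_abs_corr pairs of variables with absolute Pearson correlation
#'   above this value (over sites) are reduced to one member.
#' @param priority optional named numeric importance scores; the
#'   higher-priority member of an offending pair is kept. Without scores, a
#'   redundancy proxy is used: the variable with the lower mean absolute
#'   correlation to the other variables is kept.
#' @return an `env_prune_config` list.
#' @export
env_prune_config <- function(max_abs_corr = 0.8, priority = NULL) {
  stopifnot(max_abs_corr > 0, max_abs_corr <= 1)
  structure(list(max_abs_corr = max_abs_corr, priority = priority),
            class = "env_prune_config")
}

#' RONA configuration
#'
#' @param unit fit and summarize per `"population"` (allele frequencies at
#'   sites) or per `"individual"` (dosage/2 with site values expanded to
#'   samples).
#' @param weighting per-SNP weights in the RONA average: `"r2"` (fit
#'   quality) or `"uniform"`.
#' @param min_r2 SNP models below this r-squared are excluded from
#'   summaries.
#' @param clip_predictions clip predicted allele frequencies to `[0, 1]`
#'   before differencing.
#' @return a `rona_config` list.
#' @export
rona_config <- function(unit = c("population", "individual"),
                        weighting = c("r2", "uniform"),
                        min_r2 = 0, clip_predictions = TRUE) {
  stopifnot(min_r2 >= 0, min_r2 < 1)
  structure(list(unit = match.arg(unit), weighting = match.arg(weighting),
                 min_r2 = min_r2, clip_predictions = clip_predictions),
            class = "rona_config")
}

#' Greedy correlation pruning of environmental variables
#'
#' While any retained pair has absolute Pearson correlation (over sites)
#' above the threshold, the offending pair with the largest absolute
#' correlation is resolved by dropping its lower-priority member (priority
#' ties drop the lexicographically later name). Deterministic.
#'
#' @param env an [env_table()] (pruned on the current layer).
#' @param cfg an [env_prune_config()].
#' @return list with `retained` (variable names), `dropped` (data.frame of
#'   dropped variable, the partner it clashed with, and their correlation).
#' @export
prune_env <- function(env, cfg = env_prune_config()) {
  cur <- env$values$current
  if (nrow(cur) < 2) stop("need at least two sites")
  vars <- colnames(cur)
  prio <- cfg$priority
  if (is.null(prio)) {
    # redundancy proxy: lower mean |r| with the other variables wins
    cm <- abs(cor(cur))
    diag(cm) <- NA
    prio <- -rowMeans(cm, na.rm = TRUE)
  }
  prio <- prio[vars]
  retained <- vars
  dropped <- data.frame(variable = character(), partner = character(),
                        correlation = numeric())
  repeat {
    if (length(retained) < 2) break
    cm <- cor(cur[, retained, drop = FALSE])
    diag(cm) <- 0
    m <- max(abs(cm))
    if (m <= cfg$max_abs_corr) break
    hit <- which(abs(cm) == m, arr.ind = TRUE)[1, ]
    a <- retained[min(hit)]; b <- retained[max(hit)]
    loser <- if (prio[a] > prio[b]) b
    else if (prio[b] > prio[a]) a
    else max(a, b)  # tie: lexicographically later name dropped
    keeper <- setdiff(c(a, b), loser)
    dropped <- rbind(dropped,
                     data.frame(variable = loser, partner = keeper,
                                correlation = cm[hit[1], hit[2]]))
    retained <- setdiff(retained, loser)
  }
  list(retained = retained, dropped = dropped)
}

#' Per-SNP linear allele-frequency-on-environment models
#'
#' For each candidate SNP of a variable, least-squares fit of allele
#' frequency (per population) or dosage/2 (per individual) on the
#' present-day value of that variable; slope, intercept and r-squared are
#' recorded for the RONA projection.
#'
#' @param g a [genotype_matrix()].
#' @param env an [env_table()] with sites matching the populations.
#' @param candidates named list: variable -> SNP indices (e.g. built from a
#'   `gea_result`).
#' @param cfg a [rona_config()].
#' @return a `rona_models` list: `models` (data.frame: variable, snp,
#'   intercept, slope, r2), plus the fitting unit and config.
#' @export
fit_freq_env <- function(g, env, candidates, cfg = rona_config()) {
  pops <- sort(unique(g$pop_of_sample))
  if (!all(pops %in% env$site_ids))
    stop("populations missing from environmental table")
  cur <- env$values$current

  if (cfg$unit == "population") {
    if (length(pops) < 3) stop("need at least 3 populations")
    freq <- allele_freq(g, by_population = TRUE)   # pops x SNPs
    units <- rownames(freq)
  } else {
    if (n_samples(g) < 3) stop("need at least 3 individuals")
    d <- impute_freq(g$dosages) / 2
    freq <- d
    units <- g$pop_of_sample
  }

  out <- list()
  for (v in names(candidates)) {
    snps <- candidates[[v]]
    if (!length(snps)) next
    e <- if (cfg$unit == "population") cur[units, v]
    else cur[g$pop_of_sample, v]
    if (var(e) == 0) stop("zero environmental variance for ", v)
    Y <- freq[, snps, drop = FALSE]
    fit <- lm.fit(cbind(1, e), Y)
    cf <- fit$coefficients
    if (is.null(dim(cf))) cf <- matrix(cf, ncol = 1)
    pred <- cbind(1, e) %*% cf
    ssr <- colSums((Y - pred)^2)
    sst <- colSums(sweep(Y, 2, colMeans(Y))^2)
    r2 <- ifelse(sst > 0, 1 - ssr / sst, 0)
    out[[v]] <- data.frame(variable = v, snp = snps,
                           intercept = unname(cf[1, ]),
                           slope = unname(cf[2, ]), r2 = unname(r2))
  }
  models <- if (length(out)) do.call(rbind, out)
  else data.frame(variable = character(), snp = integer(),
                  intercept = numeric(), slope = numeric(), r2 = numeric())
  rownames(models) <- NULL
  structure(list(models = models, unit = cfg$unit, config = cfg,
                 populations = pops, pop_of_sample = g$pop_of_sample),
            class = "rona_models")
}

impute_freq <- function(d) {
  cm <- colMeans(d, na.rm = TRUE)
  idx <- which(is.na(d), arr.ind = TRUE)
  if (nrow(idx)) d[idx] <- cm[idx[, 2]]
  d
}

#' Risk of Non-Adaptedness under a future scenario
#'
#' For each unit (population or individual) and variable, RONA is the
#' weighted average over the variable's SNP models of the absolute
#' difference between allele frequencies predicted under the future and the
#' current environment at that unit's site: the allele-frequency
#' displacement the population would need to track the projected climate.
#' Weights are per-SNP r-squared (default) or uniform; predictions are
#' clipped to `[0, 1]` before differencing unless disabled.
#'
#' @param models a `rona_models` from [fit_freq_env()].
#' @param env an [env_table()] containing the scenario layer.
#' @param scenario name of the future layer (e.g. `"ssp585"`).
#' @param cfg a [rona_config()] (should match the one used for fitting).
#' @return a `rona_report` list: `report` (data.frame per population x
#'   variable: rona, n_snps, mean_r2, scenario), `per_snp` (per-SNP current
#'   and projected frequencies and displacement, population-unit fits
#'   only), `scenario`.
#' @export
compute_rona <- function(models, env, scenario, cfg = rona_config()) {
  if (!scenario %in% env$scenarios) stop("unknown scenario: ", scenario)
  cur <- env$values$current
  fut <- env$values[[scenario]]
  mods <- models$models
  mods <- mods[mods$r2 >= cfg$min_r2, , drop = FALSE]
  pops <- models$populations

  rows <- list()
  per_snp <- list()
  for (v in unique(mods$variable)) {
    mv <- mods[mods$variable == v, , drop = FALSE]
    for (p in pops) {
      e0 <- cur[p, v]; e1 <- fut[p, v]
      f0 <- mv$intercept + mv$slope * e0
      f1 <- mv$intercept + mv$slope * e1
      if (cfg$clip_predictions) {
        f0 <- pmin(pmax(f0, 0), 1)
        f1 <- pmin(pmax(f1, 0), 1)
      }
      w <- if (cfg$weighting == "r2") mv$r2 else rep(1, nrow(mv))
      if (sum(w) == 0) w <- rep(1, nrow(mv))
      rona <- sum(w * abs(f1 - f0)) / sum(w)
      rows[[length(rows) + 1]] <-
        data.frame(population = p, variable = v, scenario = scenario,
                   rona = rona, n_snps = nrow(mv), mean_r2 = mean(mv$r2))
      per_snp[[length(per_snp) + 1]] <-
        data.frame(population = p, variable = v, snp = mv$snp,
                   freq_current = f0, freq_future = f1,
                   abs_shift = abs(f1 - f0), r2 = mv$r2)
    }
  }
  missing_vars <- setdiff(unique(models$models$variable),
                          unique(mods$variable))
  for (v in missing_vars)
    message("variable ", v, " has no SNP model above min_r2; ",
            "RONA reported as NA")
  for (v in missing_vars) for (p in pops)
    rows[[length(rows) + 1]] <-
    data.frame(population = p, variable = v, scenario = scenario,
               rona = NA_real_, n_snps = 0L, mean_r2 = NA_real_)

  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  structure(list(report = report,
                 per_snp = do.call(rbind, per_snp),
                 scenario = scenario),
            class = "rona_report")
}

#' @export
print.rona_report <- function(x, ...) {
  cat(sprintf("rona_report (%s):\n", x$scenario))
  print(x$report)
  invisible(x)
}
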
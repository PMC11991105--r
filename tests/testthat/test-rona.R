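make_env <- function(cur, fut = NULL, scenario = "ssp585") {
  layers <- list(current = cur)
  if (!is.null(fut)) layers[[scenario]] <- fut
  env_table(layers, rownames(cur), colnames(cur))
}

test_that("correlation pruning drops the lower-priority member of identical pairs", {
  sites <- sprintf("S%d", 1:6)
  set.seed(81)
  a <- rnorm(6)
  cur <- cbind(V1 = a, V2 = a, V3 = rnorm(6))
  rownames(cur) <- sites
  env <- make_env(cur)
  res <- prune_env(env, env_prune_config(priority = c(V1 = 2, V2 = 1,
                                                      V3 = 0)))
  expect_equal(sort(res$retained), c("V1", "V3"))
  expect_equal(res$dropped$variable, "V2")

  # all pairwise |r| at or below the threshold: nothing dropped
  set.seed(82)
  cur2 <- matrix(rnorm(6 * 100), 100,
                 dimnames = list(NULL, sprintf("W%d", 1:6)))
  env2 <- env_table(list(current = cur2), rownames(cur2, do.NULL = FALSE),
                    colnames(cur2))
  expect_lt(max(abs(cor(cur2)[upper.tri(diag(6))])), 0.8)
  res2 <- prune_env(env2, env_prune_config())
  expect_equal(res2$retained, colnames(cur2))
  expect_equal(nrow(res2$dropped), 0L)

  # equal priorities resolve by dropping the later name
  cur3 <- cbind(AA = a, AB = a)
  rownames(cur3) <- sites
  res3 <- prune_env(make_env(cur3),
                    env_prune_config(priority = c(AA = 1, AB = 1)))
  expect_equal(res3$retained, "AA")
})

test_that("greedy pruning of a planted correlated block matches exhaustive search", {
  # planted block V1~V2~V3 highly correlated; V4, V5 independent
  set.seed(83)
  base <- rnorm(30)
  cur <- cbind(V1 = base + rnorm(30, sd = 0.1),
               V2 = base + rnorm(30, sd = 0.1),
               V3 = base + rnorm(30, sd = 0.1),
               V4 = rnorm(30), V5 = rnorm(30))
  rownames(cur) <- sprintf("S%d", 1:30)
  cfg <- env_prune_config()
  res <- prune_env(make_env(cur), cfg)

  # exhaustive oracle: replay the same deterministic rule by brute force
  diag_adj <- abs(cor(cur)); diag(diag_adj) <- NA
  prio <- -rowMeans(diag_adj, na.rm = TRUE)
  retained <- colnames(cur)
  repeat {
    cm <- cor(cur[, retained, drop = FALSE]); diag(cm) <- 0
    if (max(abs(cm)) <= cfg$max_abs_corr) break
    hit <- which(abs(cm) == max(abs(cm)), arr.ind = TRUE)[1, ]
    pair <- retained[sort(hit)]
    loser <- if (prio[pair[1]] > prio[pair[2]]) pair[2]
    else if (prio[pair[2]] > prio[pair[1]]) pair[1] else max(pair)
    retained <- setdiff(retained, loser)
  }
  expect_equal(sort(res$retained), sort(retained))
  # the planted block is reduced to a single member
  expect_equal(sum(res$retained %in% c("V1", "V2", "V3")), 1L)
  expect_true(all(c("V4", "V5") %in% res$retained))
})

test_that("per-SNP models recover exact lines and flat responses", {
  e <- c(DLS = -2, JFL = -1, QSX = 0, QXL = 1, SMX = 2)
  g <- line_genotypes(e, a = c(0.2, 0.5), b = c(0.05, 0))
  cur <- matrix(e, ncol = 1, dimnames = list(names(e), "BIO18"))
  env <- make_env(cur)
  m <- fit_freq_env(g, env, list(BIO18 = 1:2), rona_config())
  expect_equal(m$models$slope, c(0.05, 0), tolerance = 1e-12)
  expect_equal(m$models$intercept, c(0.2, 0.5), tolerance = 1e-12)
  expect_equal(m$models$r2, c(1, 0), tolerance = 1e-12)
})

test_that("RONA is exact on analytic cases and zero when nothing changes", {
  e <- c(DLS = -2, JFL = -1, QSX = 0, QXL = 1, SMX = 2)
  g <- line_genotypes(e, a = 0.2, b = 0.05)
  cur <- matrix(e, ncol = 1, dimnames = list(names(e), "BIO18"))

  # future identical to current: RONA identically zero
  env_same <- make_env(cur, cur, "ssp126")
  m <- fit_freq_env(g, env_same, list(BIO18 = 1), rona_config())
  r0 <- compute_rona(m, env_same, "ssp126", rona_config())
  expect_equal(r0$report$rona, rep(0, 5))

  # uniform +2 shift on a perfect 0.05-slope line: RONA = 0.1 everywhere
  env_shift <- make_env(cur, cur + 2, "ssp585")
  m2 <- fit_freq_env(g, env_shift, list(BIO18 = 1), rona_config())
  r2 <- compute_rona(m2, env_shift, "ssp585", rona_config())
  expect_equal(r2$report$rona, rep(0.1, 5), tolerance = 1e-12)
  expect_equal(r2$report$n_snps, rep(1L, 5))
  expect_equal(r2$report$mean_r2, rep(1, 5), tolerance = 1e-12)
})

test_that("RONA equals a naive per-SNP per-unit recomputation on synthetic data", {
  g <- sim_structured_genotypes(300, fst = 0.1, seed = 91)
  env <- sim_env(n_sites = 5, n_vars = 3, seed = 92)
  cand <- list()
  set.seed(93)
  for (v in env$variables[1:3]) cand[[v]] <- sort(sample(300, 40))
  cfg <- rona_config()
  m <- fit_freq_env(g, env, cand, cfg)
  rep_ <- compute_rona(m, env, "ssp585", cfg)$report

  freq <- allele_freq(g, by_population = TRUE)
  for (k in seq_len(nrow(rep_))) {
    v <- rep_$variable[k]; p <- rep_$population[k]
    snps <- cand[[v]]
    e0 <- env$values$current[p, v]; e1 <- env$values$ssp585[p, v]
    num <- den <- 0
    for (j in snps) {
      fit <- lm(freq[, j] ~ env$values$current[, v])
      a <- coef(fit)[1]; b <- coef(fit)[2]
      r2 <- summary(fit)$r.squared
      f0 <- min(max(a + b * e0, 0), 1)
      f1 <- min(max(a + b * e1, 0), 1)
      num <- num + r2 * abs(f1 - f0)
      den <- den + r2
    }
    expect_equal(rep_$rona[k], num / den, tolerance = 1e-12)
  }
})

test_that("RONA is invariant to affine transforms of the environmental scale", {
  g <- sim_structured_genotypes(200, fst = 0.1, seed = 94)
  env <- sim_env(n_sites = 5, n_vars = 2, seed = 95)
  cand <- list()
  set.seed(96)
  for (v in env$variables[1:2]) cand[[v]] <- sort(sample(200, 30))
  cfg <- rona_config()
  r1 <- compute_rona(fit_freq_env(g, env, cand, cfg), env, "ssp585",
                     cfg)$report

  aff <- env_table(lapply(env$values, function(m) 3.7 * m - 11),
                   env$site_ids, env$variables)
  r2 <- compute_rona(fit_freq_env(g, aff, cand, cfg), aff, "ssp585",
                     cfg)$report
  expect_equal(r1$rona, r2$rona, tolerance = 1e-10)
})

test_that("single-SNP RONA grows with the shift until clipping saturates it", {
  e <- c(DLS = -2, JFL = -1, QSX = 0, QXL = 1, SMX = 2)
  g <- line_genotypes(e, a = 0.5, b = 0.1)
  cur <- matrix(e, ncol = 1, dimnames = list(names(e), "V"))
  prev <- -1
  for (shift in c(0, 1, 2, 5, 10, 20)) {
    env <- make_env(cur, cur + shift, "f")
    cfg <- rona_config()
    r <- compute_rona(fit_freq_env(g, env, list(V = 1), cfg), env, "f",
                      cfg)$report
    expect_gte(r$rona[1] + 1e-12, prev)
    prev <- r$rona[1]
    expect_lte(r$rona[1], 1)
  }
  expect_lt(prev, 1)  # clipped at the frequency bounds
})

test_that("weighted RONA lies between the extreme per-SNP shifts", {
  g <- sim_structured_genotypes(100, fst = 0.1, seed = 97)
  env <- sim_env(n_sites = 5, n_vars = 1, seed = 98)
  cand <- list(VAR1 = 1:50)
  cfg <- rona_config()
  m <- fit_freq_env(g, env, cand, cfg)
  out <- compute_rona(m, env, "ssp585", cfg)
  for (p in unique(out$per_snp$population)) {
    shifts <- out$per_snp$abs_shift[out$per_snp$population == p]
    rona <- out$report$rona[out$report$population == p]
    expect_gte(rona, min(shifts) - 1e-12)
    expect_lte(rona, max(shifts) + 1e-12)
  }
})

test_that("population and individual units agree on frequency-exact fixtures", {
  e <- c(DLS = -2, JFL = -1, QSX = 0, QXL = 1, SMX = 2)
  g <- line_genotypes(e, a = c(0.3, 0.4), b = c(0.08, -0.05))
  cur <- matrix(e, ncol = 1, dimnames = list(names(e), "V"))
  env <- make_env(cur, cur + 1.5, "f")
  cand <- list(V = 1:2)
  cfg_p <- rona_config(unit = "population", weighting = "uniform")
  cfg_i <- rona_config(unit = "individual", weighting = "uniform")
  mp <- fit_freq_env(g, env, cand, cfg_p)
  mi <- fit_freq_env(g, env, cand, cfg_i)
  expect_equal(mp$models$slope, mi$models$slope, tolerance = 1e-12)
  rp <- compute_rona(mp, env, "f", cfg_p)
  ri <- compute_rona(mi, env, "f", cfg_i)
  expect_equal(rp$report$rona, ri$report$rona, tolerance = 1e-12)
})
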
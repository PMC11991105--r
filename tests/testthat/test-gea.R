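test_that("with K = 0 and no structure the test reduces to simple linear regression", {
  set.seed(61)
  n <- 40
  e <- rnorm(n)
  dos <- matrix(rbinom(n * 30, 2, 0.5), n)
  g <- genotype_matrix(dos, rep("chr1", 30), seq_len(30) * 100L,
                       rep("A", 30), rep("G", 30),
                       sprintf("s%d", 1:n), rep("P", n))
  res <- fit_association(g, matrix(e, ncol = 1,
                                   dimnames = list(NULL, "E1")),
                         U = NULL, cfg = gea_config(K = 0,
                                                    calibrate = FALSE))
  # closed-form slope, SE and t p-value per SNP
  z <- (e - mean(e)) / sd(e)
  for (j in c(1, 7, 30)) {
    y <- dos[, j] - mean(dos[, j])
    b <- sum(z * y) / sum((z - mean(z))^2)
    resid <- y - mean(y) - b * (z - mean(z))
    se <- sqrt(sum(resid^2) / (n - 2) / sum((z - mean(z))^2))
    p <- 2 * pt(abs(b / se), df = n - 2, lower.tail = FALSE)
    row <- res$stats[res$stats$snp == j, ]
    expect_equal(row$effect, b, tolerance = 1e-10)
    expect_equal(row$z, b / se, tolerance = 1e-10)
    expect_equal(row$p_raw, p, tolerance = 1e-10)
  }
})

test_that("a noiseless linear dosage-environment relation gives vanishing p", {
  n <- 30
  e <- seq(-2, 2, length.out = n)
  dos <- matrix(as.integer(round(1 + 0.5 * e)), n, 1)
  g <- genotype_matrix(dos, "chr1", 100L, "A", "G",
                       sprintf("s%d", 1:n), rep("P", n))
  res <- fit_association(g, matrix(e, ncol = 1,
                                   dimnames = list(NULL, "E1")),
                         U = NULL, cfg = gea_config(K = 0,
                                                    calibrate = FALSE))
  expect_lt(res$stats$p[1], 1e-10)
})

test_that("latent factors recover deme structure and respect sample symmetry", {
  g <- sim_structured_genotypes(2000, fst = 0.2, n_pops = 2,
                                n_per_pop = 15, seed = 62)
  U <- estimate_latent_factors(g, 1)
  lab <- as.numeric(factor(g$pop_of_sample))
  expect_gt(abs(cor(U[, 1], lab)), 0.9)

  # duplicating every sample gives identical factor rows for the twins
  idx <- rep(seq_len(n_samples(g)), each = 2)
  gd <- genotype_matrix(g$dosages[idx, ], g$chrom, g$pos, g$ref, g$alt,
                        sprintf("d%d", seq_along(idx)),
                        g$pop_of_sample[idx])
  Ud <- estimate_latent_factors(gd, 2)
  expect_equal(unname(Ud[seq(1, nrow(Ud), 2), ]),
               unname(Ud[seq(2, nrow(Ud), 2), ]), tolerance = 1e-8)

  expect_equal(ncol(estimate_latent_factors(g, 0)), 0L)
  expect_error(estimate_latent_factors(g, 30), "smaller")
})

test_that("q-values reproduce Benjamini-Hochberg under the small-m fallback", {
  expect_equal(qvalues(c(0.01, 0.02, 0.03, 0.9)), c(0.04, 0.04, 0.04, 0.9))
  expect_equal(qvalues(rep(1, 10)), rep(1, 10))
  expect_error(qvalues(numeric(0)), "empty")

  # agreement with p.adjust as an independent reference
  set.seed(63)
  p <- runif(50)
  expect_equal(qvalues(p), p.adjust(p, method = "BH"), tolerance = 1e-12)
})

test_that("q-values are monotone in p and bounded by the BH-scaled pi0", {
  set.seed(64)
  p <- c(runif(900), runif(100, 0, 0.001))  # m >= 100: Storey path
  q <- qvalues(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  expect_true(all(q >= 0 & q <= 1))
  # Storey pi0 shrinks q relative to plain BH
  expect_true(all(q <= p.adjust(p, "BH") + 1e-12))
})

test_that("structured deme-level environments inflate lambda and calibration restores it", {
  g <- sim_structured_genotypes(5000, fst = 0.1, n_pops = 5,
                                n_per_pop = 30, seed = 65)
  env <- sim_env(n_sites = 5, n_vars = 1, seed = 66)  # null: no injection
  U <- estimate_latent_factors(g, 2)
  res <- fit_association(g, env, U, gea_config(K = 2))
  expect_gt(res$lambda[["VAR1"]], 1)
  # the calibrated statistics have unit inflation by construction
  z2 <- qchisq(res$stats$p, df = 1, lower.tail = FALSE)
  expect_lt(abs(median(z2) / qchisq(0.5, 1) - 1), 0.1)
})

test_that("planted environmental associations are recovered with controlled FDR", {
  g <- sim_structured_genotypes(10000, fst = 0.1, n_pops = 5,
                                n_per_pop = 60, seed = 67)
  env <- sim_env(n_sites = 5, n_vars = 2, env_correlation = 0, seed = 68)
  inj <- inject_env_association(g, env, 100, variables = "VAR1", seed = 69)
  U <- estimate_latent_factors(inj$genotypes, 2)
  res <- fit_association(inj$genotypes, env, U, gea_config(K = 2))
  st <- res$stats[res$stats$variable == "VAR1", ]
  called <- st$snp[st$candidate]
  expect_gt(mean(inj$truth$snp %in% called), 0.5)
  expect_lt(mean(!(called %in% inj$truth$snp)), 0.2)
})

test_that("an iid null environment yields calibrated p-values close to uniform", {
  g <- sim_structured_genotypes(10000, fst = 0.1, n_pops = 5,
                                n_per_pop = 30, seed = 70)
  set.seed(71)
  e <- matrix(rnorm(n_samples(g)), ncol = 1,
              dimnames = list(NULL, "NULLVAR"))
  U <- estimate_latent_factors(g, 2)
  res <- fit_association(g, e, U, gea_config(K = 2))
  ks <- suppressWarnings(ks.test(res$stats$p, "punif"))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("constant environments and degenerate SNPs are handled as specified", {
  g <- toy_genotypes()
  env_const <- matrix(c(1, 1, 1, 1), ncol = 1,
                      dimnames = list(NULL, "FLAT"))
  expect_error(fit_association(g, env_const, NULL, gea_config(K = 0)),
               "FLAT")

  # a monomorphic SNP gets p = 1 by convention
  dos <- cbind(rep(1L, 6), rbinom(6, 2, 0.5))
  gm <- genotype_matrix(dos, c("chr1", "chr1"), c(1L, 2L), c("A", "A"),
                        c("T", "T"), sprintf("s%d", 1:6), rep("P", 6))
  e <- matrix(rnorm(6), ncol = 1, dimnames = list(NULL, "E1"))
  res <- fit_association(gm, e, NULL, gea_config(K = 0))
  expect_equal(res$stats$p[res$stats$snp == 1], 1)
})

test_that("candidate union and per-variable counts follow set semantics", {
  fake <- structure(list(
    stats = data.frame(
      variable = rep(c("A", "B"), each = 4),
      snp = c(1:4, 3:6),
      candidate = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE)),
    candidate_counts = c(A = 3L, B = 4L)), class = "gea_result")
  u <- candidate_union(fake)
  expect_equal(u$snps, c(1, 2, 3, 4, 5, 6))
  expect_equal(u$total, 6L)
  expect_equal(u$per_variable, c(A = 3L, B = 4L))

  # identical sets: union equals the per-variable count
  fake$stats$candidate <- rep(c(TRUE, TRUE, FALSE, FALSE), 2)
  fake$stats$snp <- rep(1:4, 2)
  u2 <- candidate_union(fake)
  expect_equal(u2$total, 2L)
})

test_that("hotspot windows match brute-force binning and detect concentration", {
  g <- sim_structured_genotypes(5000, fst = 0.1, n_chroms = 4,
                                chrom_len = 5e6, seed = 72)
  set.seed(73)
  cand <- sort(sample(n_snps(g), 400))
  hw <- hotspot_windows(cand, g, window = 1e6)
  # brute-force binning oracle
  for (k in seq_len(nrow(hw$windows))) {
    row <- hw$windows[k, ]
    expected <- sum(g$chrom[cand] == row$chrom &
                      g$pos[cand] - 1 >= row$start &
                      g$pos[cand] - 1 < row$end)
    expect_equal(row$count, expected)
  }
  expect_equal(sum(hw$windows$count), length(cand))
  expect_equal(sum(hw$per_chromosome$count), length(cand))

  # uniform placement: window counts consistent with a common Poisson mean
  counts <- hw$windows$count
  gof <- suppressWarnings(chisq.test(counts))
  expect_gt(gof$p.value, 0.01)

  # all candidates in one window
  one <- which(g$chrom == "chr2" & g$pos <= 1e6)
  hw1 <- hotspot_windows(one, g, window = 1e6)
  w <- hw1$windows
  expect_equal(w$count[w$chrom == "chr2" & w$start == 0], length(one))
  expect_equal(sum(w$count), length(one))
})
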
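# Independent brute-force oracles and small fixture builders shared by the
# test files. These deliberately use naive loops / base idioms distinct from
# the package's vectorized implementations.

# loop-based ALT allele frequency, optionally per population
naive_freq <- function(g, by_population = FALSE) {
  count_one <- function(d) {
    f <- numeric(ncol(d))
    for (j in seq_len(ncol(d))) {
      x <- d[, j]
      x <- x[!is.na(x)]
      f[j] <- if (length(x)) sum(x) / (2 * length(x)) else NA_real_
    }
    f
  }
  if (!by_population) return(count_one(g$dosages))
  pops <- sort(unique(g$pop_of_sample))
  out <- matrix(NA_real_, length(pops), n_snps(g),
                dimnames = list(pops, NULL))
  for (p in pops)
    out[p, ] <- count_one(g$dosages[g$pop_of_sample == p, , drop = FALSE])
  out
}

# naive per-window LD factor: explicit pair loops on cor()
naive_mu_ld <- function(d, eps = 1e-6) {
  W <- ncol(d)
  h <- W / 2
  r2 <- function(i, j) {
    x <- d[, i]; y <- d[, j]
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    y[is.na(y)] <- mean(y, na.rm = TRUE)
    if (sd(x) == 0 || sd(y) == 0) return(0)
    cor(x, y)^2
  }
  sl <- sr <- sc <- 0
  for (i in 1:(h - 1)) for (j in (i + 1):h) sl <- sl + r2(i, j)
  for (i in (h + 1):(W - 1)) for (j in (i + 1):W) sr <- sr + r2(i, j)
  for (i in 1:h) for (j in (h + 1):W) sc <- sc + r2(i, j)
  np <- h * (h - 1) / 2
  ((sl / np + sr / np) / 2) / (sc / h^2 + eps)
}

# per-window LD factor recomputed from scratch with cor() on the imputed
# window matrix (no sliding-band reuse)
naive_mu_ld_cor <- function(d, eps = 1e-6) {
  W <- ncol(d)
  h <- W / 2
  di <- apply(d, 2, function(x) {
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    x
  })
  r <- suppressWarnings(cor(di))
  r[!is.finite(r)] <- 0
  r2 <- r * r
  iL <- 1:h; iR <- (h + 1):W
  sl <- mean(r2[iL, iL][upper.tri(diag(h))])
  sr <- mean(r2[iR, iR][upper.tri(diag(h))])
  sc <- mean(r2[iL, iR])
  ((sl + sr) / 2) / (sc + eps)
}

# naive full scan of one chromosome: per-window recomputation from scratch
naive_scan <- function(g, cfg) {
  W <- cfg$window_snps
  stopifnot(length(unique(g$chrom)) == 1)
  S <- n_snps(g)
  span <- max(g$pos) - min(g$pos)
  cnt <- colSums(g$dosages, na.rm = TRUE)
  nh <- 2 * colSums(!is.na(g$dosages))
  n_win <- S - W + 1
  mvv <- msv <- mlv <- numeric(n_win)
  for (w in 1:n_win) {
    idx <- w:(w + W - 1)
    mvv[w] <- ((g$pos[idx[W]] - g$pos[idx[1]]) / span) * (S / W)
    msv[w] <- if (cfg$polarized)
      mean(cnt[idx] <= cfg$k_low | cnt[idx] >= nh[idx] - cfg$k_low)
    else mean(pmin(cnt[idx], nh[idx] - cnt[idx]) <= cfg$k_low)
    mlv[w] <- naive_mu_ld_cor(g$dosages[, idx, drop = FALSE],
                              cfg$ld_epsilon)
  }
  data.frame(mu_var = mvv, mu_sfs = msv, mu_ld = mlv,
             mu = mvv * msv * mlv)
}

# deterministic genotype matrix whose population frequencies follow an
# exact line f_j = a_j + b_j * e over the sites
line_genotypes <- function(e, a, b, n_per_pop = 10) {
  pops <- names(e)
  n_snps <- length(a)
  dos <- matrix(0L, length(pops) * n_per_pop, n_snps)
  for (j in seq_len(n_snps)) {
    f <- a[j] + b[j] * e
    stopifnot(all(f >= 0 & f <= 1))
    for (i in seq_along(pops)) {
      rows <- (i - 1) * n_per_pop + seq_len(n_per_pop)
      alt <- round(f[i] * 2 * n_per_pop)
      full <- alt %/% 2
      half <- alt %% 2
      dos[rows, j] <- c(rep(2L, full), rep(1L, half),
                        rep(0L, n_per_pop - full - half))
    }
  }
  genotype_matrix(dos, rep("chr1", n_snps), seq_len(n_snps) * 100L,
                  rep("A", n_snps), rep("G", n_snps),
                  sprintf("s%d", seq_len(nrow(dos))),
                  rep(pops, each = n_per_pop))
}

# nucleotide diversity (mean pairwise difference) of 0/1 haplotypes whose
# positions fall inside [from, to]
pi_in_window <- function(hap, positions, from, to) {
  cols <- which(positions >= from & positions <= to)
  if (!length(cols)) return(0)
  h <- hap[, cols, drop = FALSE]
  n <- nrow(h)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(h[i, ] != h[j, ])
  tot / (n * (n - 1) / 2)
}

# off-diagonal genotype r2 via cor(), NA-safe
dosage_r2_test <- function(d) {
  r <- suppressWarnings(cor(d, use = "pairwise.complete.obs"))
  r[!is.finite(r)] <- 0
  r2 <- r * r
  diag(r2) <- 0
  r2
}

# small deterministic genotype matrix built by hand
toy_genotypes <- function() {
  dos <- rbind(c(0L, 1L, 2L, NA, 1L),
               c(1L, 1L, 2L, 0L, 0L),
               c(2L, 0L, 1L, 0L, NA),
               c(0L, 0L, 2L, 1L, 1L))
  genotype_matrix(dos,
                  chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
                  pos = c(100L, 250L, 900L, 40L, 77L),
                  ref = c("A", "C", "G", "T", "A"),
                  alt = c("G", "T", "A", "C", "C"),
                  sample_ids = c("s1", "s2", "s3", "s4"),
                  pop_of_sample = c("DLS", "DLS", "JFL", "JFL"))
}

# minimal env_table fixture over the five island sites
toy_env <- function() {
  cur <- matrix(c(1, 2, 3, 4, 5,
                  5, 3, 1, 2, 4), ncol = 2,
                dimnames = list(c("DLS", "JFL", "QSX", "QXL", "SMX"),
                                c("BIO2", "BIO18")))
  env_table(list(current = cur, ssp585 = cur + 2),
            c("DLS", "JFL", "QSX", "QXL", "SMX"), c("BIO2", "BIO18"))
}
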
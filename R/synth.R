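#' Simulate structured genotypes under the Balding-Nichols model
#'
#' Per SNP, an ancestral frequency `p0 ~ Uniform(0.05, 0.95)` is drawn;
#' each deme's frequency is Beta-distributed around `p0` with parameter
#' `F = fst` (`Beta(p0(1-F)/F, (1-p0)(1-F)/F)`), and diploid genotypes are
#' binomial draws from the deme frequency. Positions are assigned uniformly
#' over `n_chroms` synthetic chromosomes. The defaults mirror a typical
#' island resequencing design: 5 populations of 6 diploid individuals.
#'
#' @param n_snps number of SNPs.
#' @param fst target differentiation, in (0, 1).
#' @param n_pops number of demes.
#' @param n_per_pop diploid individuals per deme.
#' @param n_chroms number of synthetic chromosomes.
#' @param chrom_len chromosome length in bp.
#' @param pop_names deme labels; defaults to the five island site codes
#'   (DLS, JFL, QSX, QXL, SMX) when `n_pops == 5`.
#' @param seed integer RNG seed; the generator is a pure function of it.
#' @return a [genotype_matrix()] with attributes `p0` (ancestral
#'   frequencies) and `deme_freq` (demes x SNPs frequency matrix).
#' @export
sim_structured_genotypes <- function(n_snps, fst = 0.1, n_pops = 5L,
                                     n_per_pop = 6L, n_chroms = 12L,
                                     chrom_len = 1e7, pop_names = NULL,
                                     seed = 1L) {
  stopifnot(n_pops >= 2, fst > 0, fst < 1, n_snps >= 1)
  if (is.null(pop_names)) {
    pop_names <- if (n_pops == 5) c("DLS", "JFL", "QSX", "QXL", "SMX")
    else sprintf("P%02d", seq_len(n_pops))
  }
  set.seed(seed)
  chrom_of <- sort(sample.int(n_chroms, n_snps, replace = TRUE))
  pos <- integer(n_snps)
  for (ch in unique(chrom_of)) {
    k <- sum(chrom_of == ch)
    pos[chrom_of == ch] <- sort(sample.int(chrom_len, k))
  }
  chrom <- sprintf("chr%d", chrom_of)

  p0 <- runif(n_snps, 0.05, 0.95)
  a <- p0 * (1 - fst) / fst
  b <- (1 - p0) * (1 - fst) / fst
  deme_freq <- matrix(rbeta(n_pops * n_snps, rep(a, each = n_pops),
                            rep(b, each = n_pops)),
                      nrow = n_pops,
                      dimnames = list(pop_names, NULL))
  n <- n_pops * n_per_pop
  pops <- rep(pop_names, each = n_per_pop)
  dos <- matrix(rbinom(n * n_snps, 2L, deme_freq[match(pops, pop_names), ]),
                nrow = n)
  alleles <- sample_alleles(n_snps)
  g <- genotype_matrix(dos, chrom, pos, alleles$ref, alleles$alt,
                       sprintf("%s_%d", pops,
                               sequence(rep(n_per_pop, n_pops))),
                       pops)
  attr(g, "p0") <- p0
  attr(g, "deme_freq") <- deme_freq
  g
}

sample_alleles <- function(n_snps) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_snps, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  list(ref = ref, alt = unname(alt))
}

#' Weir-Cockerham FST estimator
#'
#' Multi-population variance-components estimator for biallelic SNPs
#' (ratio-of-sums across loci). Serves as the independent check on the
#' Balding-Nichols generator.
#'
#' @param g a [genotype_matrix()] with at least two populations.
#' @return the genome-wide FST estimate (a single number).
#' @export
wc_fst <- function(g) {
  pops <- unique(g$pop_of_sample)
  r <- length(pops)
  stopifnot(r >= 2)
  d <- g$dosages
  nk <- matrix(0, r, ncol(d))   # non-missing diploid counts
  pk <- matrix(0, r, ncol(d))   # ALT freqs
  hk <- matrix(0, r, ncol(d))   # observed heterozygote proportion
  for (i in seq_len(r)) {
    di <- d[g$pop_of_sample == pops[i], , drop = FALSE]
    nk[i, ] <- colSums(!is.na(di))
    pk[i, ] <- colSums(di, na.rm = TRUE) / (2 * pmax(nk[i, ], 1))
    hk[i, ] <- colSums(di == 1L, na.rm = TRUE) / pmax(nk[i, ], 1)
  }
  nbar <- colMeans(nk)
  nc <- (colSums(nk) - colSums(nk^2) / colSums(nk)) / (r - 1)
  pbar <- colSums(nk * pk) / colSums(nk)
  s2 <- colSums(nk * sweep(pk, 2, pbar)^2) / ((r - 1) * nbar)
  hbar <- colSums(nk * hk) / colSums(nk)

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 -
       (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  ok <- is.finite(a) & is.finite(b) & is.finite(cc)
  sum(a[ok]) / sum((a + b + cc)[ok])
}

#' Simulate site-level environmental tables
#'
#' The current layer is drawn from a multivariate normal with an
#' equicorrelated inter-variable structure; future layers add deterministic
#' per-variable shifts, emulating low- and high-emission scenario pairs.
#' Variables are on a standardized (zero-mean, unit-variance) scale, so
#' shifts are in units of present-day spatial standard deviations.
#'
#' @param n_sites number of sampling sites.
#' @param n_vars number of environmental variables.
#' @param env_correlation target pairwise correlation among variables.
#' @param shifts named list of scenario -> shift (scalar or per-variable
#'   vector), added to the current layer.
#' @param site_ids site labels (default matches
#'   [sim_structured_genotypes()] population names).
#' @param var_names variable names; defaults to seven commonly used
#'   bioclimatic predictors when `n_vars == 7`.
#' @param seed integer RNG seed.
#' @return an [env_table()].
#' @export
sim_env <- function(n_sites = 5L, n_vars = 7L, env_correlation = 0.3,
                    shifts = list(ssp126 = 0.5, ssp585 = 1.5),
                    site_ids = NULL, var_names = NULL, seed = 1L) {
  stopifnot(n_sites >= 2, n_vars >= 1)
  if (is.null(site_ids)) {
    site_ids <- if (n_sites == 5) c("DLS", "JFL", "QSX", "QXL", "SMX")
    else sprintf("P%02d", seq_len(n_sites))
  }
  if (is.null(var_names)) {
    var_names <- if (n_vars == 7)
      c("BIO2", "BIO3", "BIO7", "BIO8", "BIO9", "BIO14", "BIO18")
    else sprintf("VAR%d", seq_len(n_vars))
  }
  sigma <- matrix(env_correlation, n_vars, n_vars)
  diag(sigma) <- 1
  ch <- tryCatch(chol(sigma),
                 error = function(e)
                   stop("correlation target is not positive definite"))
  set.seed(seed)
  cur <- matrix(rnorm(n_sites * n_vars), n_sites) %*% ch
  dimnames(cur) <- list(site_ids, var_names)
  layers <- list(current = cur)
  for (sc in names(shifts)) {
    sh <- shifts[[sc]]
    stopifnot(length(sh) == 1 || length(sh) == n_vars)
    layers[[sc]] <- sweep(cur, 2, rep(sh, length.out = n_vars), `+`)
  }
  env_table(layers, site_ids, var_names)
}

#' Plant environmentally associated loci into structured genotypes
#'
#' For each chosen locus, deme allele frequencies are regenerated as
#' `clamp(p0 + b * z(e))` where `z(e)` is the standardized value of the
#' locus's environmental variable across demes and `b` is a signed slope
#' drawn from `slope_range`; genotypes at the locus are then redrawn
#' binomially. Returns the ground-truth table for power/FDR evaluation.
#'
#' @param g a [genotype_matrix()] from [sim_structured_genotypes()] (deme
#'   labels must match `env` site ids).
#' @param env an [env_table()].
#' @param n_adaptive_loci number of loci to plant.
#' @param slope_range interval for the slope magnitude, in allele-frequency
#'   units per environmental standard deviation.
#' @param clamp lower/upper bounds applied to regenerated deme frequencies,
#'   keeping planted loci polymorphic.
#' @param variables which environmental variables to use (cycled over
#'   loci); defaults to all.
#' @param seed integer RNG seed.
#' @return list with `genotypes` (modified matrix) and `truth` (data.frame
#'   of snp index, chrom, pos, variable, slope).
#' @export
inject_env_association <- function(g, env, n_adaptive_loci,
                                   slope_range = c(0.35, 0.55),
                                   clamp = c(0.02, 0.98),
                                   variables = NULL, seed = 1L) {
  if (n_adaptive_loci > n_snps(g))
    stop("more adaptive loci requested than SNPs available")
  pops <- unique(g$pop_of_sample)
  if (!all(pops %in% env$site_ids))
    stop("population labels must match environmental site ids")
  if (is.null(variables)) variables <- env$variables
  p0 <- attr(g, "p0")
  if (is.null(p0)) p0 <- allele_freq(g)

  set.seed(seed)
  loci <- sort(sample.int(n_snps(g), n_adaptive_loci))
  vars <- rep(variables, length.out = n_adaptive_loci)
  slopes <- runif(n_adaptive_loci, slope_range[1], slope_range[2]) *
    sample(c(-1, 1), n_adaptive_loci, replace = TRUE)

  cur <- env$values$current
  dos <- g$dosages
  for (k in seq_along(loci)) {
    j <- loci[k]
    e <- cur[pops, vars[k]]
    z <- (e - mean(e)) / sd(e)
    fd <- pmin(pmax(p0[j] + slopes[k] * z, clamp[1]), clamp[2])
    names(fd) <- pops
    dos[, j] <- rbinom(n_samples(g), 2L, fd[g$pop_of_sample])
  }
  g2 <- genotype_matrix(dos, g$chrom, g$pos, g$ref, g$alt,
                        g$sample_ids, g$pop_of_sample)
  attr(g2, "p0") <- p0
  list(genotypes = g2,
       truth = data.frame(snp = loci, chrom = g$chrom[loci],
                          pos = g$pos[loci], variable = vars,
                          slope = slopes))
}

#' Forward Wright-Fisher hard-sweep simulator
#'
#' Discrete-generation forward simulation with infinite-sites mutation,
#' uniform recombination and multiplicative selection at a single site. The
#' beneficial mutation enters as a single copy after a neutral burn-in of
#' `burnin_gens`; runs that lose it restart from the saved burn-in state
#' (rejection conditioning on fixation). At fixation, `n_sample` haplotypes
#' are drawn and paired into diploids. `s = 0` gives the neutral control.
#'
#' Population size and per-bp rates are desk-scale: `n_diploid` stands in
#' for a much larger natural effective size, with the mutation rate scaled
#' up by `mu_scale` so that the population mutation rate (4*N*mu per bp)
#' stays at a realistic magnitude.
#'
#' @param n_diploid population size (diploids).
#' @param seq_len chromosome length in bp.
#' @param mu per-bp per-generation mutation rate before scaling.
#' @param mu_scale factor applied to `mu` (and implicitly to time) for
#'   desk-scale runs.
#' @param rho per-bp per-generation recombination rate (already on the
#'   desk scale).
#' @param s selection coefficient (fitness 1, 1+s, (1+s)^2 by genotype).
#' @param sel_pos position of the beneficial allele, bp.
#' @param n_sample haplotypes sampled at fixation (even).
#' @param burnin_gens neutral burn-in generations (default `10 * n_diploid`).
#' @param max_restarts maximum rejection restarts before erroring.
#' @param chrom_name chromosome label for the output.
#' @param seed integer RNG seed.
#' @return list with `genotypes` (a [genotype_matrix()] of `n_sample / 2`
#'   diploids; derived alleles are ALT), `haplotypes` (0/1 matrix,
#'   `n_sample` x S), `positions` (bp), `sel_pos`, `restarts`,
#'   `sweep_generations`.
#' @export
sim_sweep <- function(n_diploid = 200L, seq_len = 2e5, mu = 8.21e-10,
                      mu_scale = 3400, rho = 6e-7, s = 0.05,
                      sel_pos = seq_len / 2, n_sample = 50L,
                      burnin_gens = 10L * n_diploid, max_restarts = 1000L,
                      chrom_name = "chr1", seed = 1L) {
  stopifnot(s >= 0, sel_pos < seq_len, n_sample %% 2 == 0,
            n_sample <= 2 * n_diploid)
  set.seed(seed)
  sim <- .wf_sweep_sim(as.integer(n_diploid), seq_len, mu * mu_scale, rho,
                       s, sel_pos, as.integer(n_sample),
                       as.integer(burnin_gens), as.integer(max_restarts),
                       as.integer(200L * n_diploid))
  if (length(sim$positions) == 0)
    stop("no segregating sites in the sampled haplotypes")
  # continuous coordinates -> strictly increasing integer bp
  pos <- floor(sim$positions) + 1
  for (i in seq_along(pos)[-1])
    if (pos[i] <= pos[i - 1]) pos[i] <- pos[i - 1] + 1
  hap <- sim$haplotypes
  n_dip <- n_sample / 2L
  dos <- hap[seq(1, n_sample, by = 2), , drop = FALSE] +
    hap[seq(2, n_sample, by = 2), , drop = FALSE]
  alleles <- sample_alleles(length(pos))
  g <- genotype_matrix(dos, rep(chrom_name, length(pos)), pos,
                       alleles$ref, alleles$alt,
                       sprintf("ind_%d", base::seq_len(n_dip)),
                       rep("POP1", n_dip))
  list(genotypes = g, haplotypes = hap, positions = pos,
       sel_pos = sel_pos, restarts = sim$restarts,
       sweep_generations = sim$sweep_generations)
}

#' Watterson's expectation for the number of segregating sites
#'
#' `E[S] = 4 N mu L * a` with `a = sum(1/i, i < n)` at sample size `n`
#' haplotypes; the neutral yardstick for the sweep simulator.
#'
#' @param n_diploid population size used in the simulation.
#' @param mu effective per-bp mutation rate (after scaling).
#' @param seq_len sequence length, bp.
#' @param n_sample number of sampled haplotypes.
#' @return expected segregating-site count.
#' @export
watterson_expected_s <- function(n_diploid, mu, seq_len, n_sample) {
  4 * n_diploid * mu * seq_len * sum(1 / seq(1, n_sample - 1))
}
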
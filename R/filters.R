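#' SNP filter configuration
#'
#' Defaults reproduce a standard resequencing workflow: drop SNPs with a
#' genotype missing rate above 0.1 or a minor allele frequency below 0.05,
#' then prune linkage disequilibrium with a 50-SNP window advanced by 10
#' SNPs at an r-squared threshold of 0.1.
#'
#' @param max_missing_rate maximum per-SNP fraction of missing genotypes.
#' @param min_maf minimum minor allele frequency.
#' @param ld_window_snps LD pruning window size, in SNPs.
#' @param ld_step_snps LD pruning window step, in SNPs.
#' @param ld_r2_threshold maximum tolerated pairwise genotype r-squared.
#' @return a `filter_config` list.
#' @export
filter_config <- function(max_missing_rate = 0.1, min_maf = 0.05,
                          ld_window_snps = 50L, ld_step_snps = 10L,
                          ld_r2_threshold = 0.1) {
  stopifnot(max_missing_rate >= 0, max_missing_rate <= 1,
            min_maf >= 0, min_maf <= 1,
            ld_r2_threshold >= 0, ld_r2_threshold <= 1,
            ld_window_snps >= ld_step_snps, ld_step_snps >= 1)
  structure(list(max_missing_rate = max_missing_rate, min_maf = min_maf,
                 ld_window_snps = as.integer(ld_window_snps),
                 ld_step_snps = as.integer(ld_step_snps),
                 ld_r2_threshold = ld_r2_threshold),
            class = "filter_config")
}

#' ALT allele frequencies
#'
#' Frequency is the ALT-allele count over twice the number of non-missing
#' genotypes, globally or per population.
#'
#' @param g a [genotype_matrix()].
#' @param by_population if `TRUE`, return a populations x SNPs matrix;
#'   otherwise a per-SNP vector. A group whose genotypes are all missing at
#'   a SNP gets frequency `NA`.
#' @return numeric vector (global) or matrix (per population), values in
#'   `[0, 1]` or `NA`.
#' @export
allele_freq <- function(g, by_population = FALSE) {
  freq_of <- function(d) {
    nn <- colSums(!is.na(d))
    f <- colSums(d, na.rm = TRUE) / (2 * nn)
    f[nn == 0] <- NA_real_
    f
  }
  if (!by_population) return(freq_of(g$dosages))
  pops <- sort(unique(g$pop_of_sample))
  fm <- vapply(pops, function(p) {
    freq_of(g$dosages[g$pop_of_sample == p, , drop = FALSE])
  }, numeric(n_snps(g)))
  if (is.null(dim(fm))) fm <- matrix(fm, nrow = 1,
                                     dimnames = list(NULL, pops))
  t(fm)
}

#' Missingness and minor-allele-frequency filter
#'
#' Applies the missingness rule first; MAF is then computed on the retained
#' SNPs from non-missing genotypes. Idempotent.
#'
#' @param g a [genotype_matrix()].
#' @param cfg a [filter_config()].
#' @return list with elements `genotypes` (filtered matrix), `report`
#'   (data.frame of per-rule removal counts) and `kept` (original SNP
#'   indices retained).
#' @export
filter_missing_maf <- function(g, cfg = filter_config()) {
  miss_rate <- colMeans(is.na(g$dosages))
  pass_miss <- miss_rate <= cfg$max_missing_rate
  f <- allele_freq(g)
  maf <- pmin(f, 1 - f)
  pass_maf <- !is.na(maf) & maf >= cfg$min_maf
  kept <- which(pass_miss & pass_maf)
  report <- data.frame(
    rule = c("missing_rate", "maf"),
    threshold = c(cfg$max_missing_rate, cfg$min_maf),
    removed = c(sum(!pass_miss), sum(pass_miss & !pass_maf)))
  list(genotypes = subset_snps(g, kept), report = report, kept = kept)
}

# squared Pearson correlation of dosage columns over pairwise-complete
# samples; monomorphic (zero-variance) columns give r2 = 0
dosage_r2 <- function(d) {
  suppressWarnings(r <- cor(d, use = "pairwise.complete.obs"))
  r[!is.finite(r)] <- 0
  r * r
}

#' Windowed linkage-disequilibrium pruning
#'
#' Sliding windows of `ld_window_snps` SNPs advanced by `ld_step_snps`
#' within each chromosome. While any pair of kept SNPs in the window has
#' genotype r-squared above the threshold, the pair member with the lower
#' MAF is removed (tie: the later-positioned SNP). Offending pairs are
#' resolved highest-r-squared first, which makes the result deterministic.
#' After completion no within-window pair among the kept SNPs exceeds the
#' threshold.
#'
#' @param g a [genotype_matrix()], SNPs sorted by (chrom, pos).
#' @param cfg a [filter_config()].
#' @return list with `genotypes` (pruned matrix), `pruned` (original SNP
#'   indices removed) and `kept` (indices retained).
#' @export
ld_prune <- function(g, cfg = filter_config()) {
  W <- cfg$ld_window_snps
  step <- cfg$ld_step_snps
  thr <- cfg$ld_r2_threshold
  f <- allele_freq(g)
  maf <- pmin(f, 1 - f)
  keep <- rep(TRUE, n_snps(g))

  for (ch in unique(g$chrom)) {
    idx <- which(g$chrom == ch)
    s <- 1L
    while (s <= length(idx)) {
      win <- idx[s:min(s + W - 1L, length(idx))]
      drop <- prune_window(win[keep[win]], g$dosages, maf, thr)
      keep[drop] <- FALSE
      if (s + W - 1L >= length(idx)) break
      s <- s + step
    }
  }
  list(genotypes = subset_snps(g, which(keep)),
       pruned = which(!keep), kept = which(keep))
}

# returns the SNP indices (columns of `dosages`) to drop from one window
prune_window <- function(active, dosages, maf, thr) {
  if (length(active) < 2) return(integer())
  r2 <- dosage_r2(dosages[, active, drop = FALSE])
  diag(r2) <- 0
  drop <- integer()
  repeat {
    m <- max(r2)
    if (m <= thr) break
    hit <- which(r2 == m, arr.ind = TRUE)[1, ]  # first hit = deterministic
    i <- min(hit); j <- max(hit)
    # drop the lower-MAF member; ties drop the later-positioned SNP
    d <- if (maf[active[i]] < maf[active[j]]) i else j
    drop <- c(drop, active[d])
    r2[d, ] <- 0
    r2[, d] <- 0
  }
  drop
}
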
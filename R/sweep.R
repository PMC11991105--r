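#' Sweep-scan configuration
#'
#' @param window_snps window size in SNPs (even; the LD factor splits the
#'   window into two halves).
#' @param k_low maximum derived-allele count for the "low" SFS class (and
#'   `n - k_low` minimum for the "high" class).
#' @param top_quantile fraction of windows called significant (genome-wide
#'   empirical quantile).
#' @param ld_epsilon small positive guard added to the cross-half mean
#'   r-squared, keeping the LD factor finite in degenerate windows.
#' @param polarized if `TRUE`, the SFS factor uses derived-allele counts
#'   (REF treated as ancestral); if `FALSE`, a folded spectrum based on
#'   minor-allele counts.
#' @return a `sweep_config` list.
#' @export
sweep_config <- function(window_snps = 50L, k_low = 1L,
                         top_quantile = 0.0005, ld_epsilon = 1e-6,
                         polarized = TRUE) {
  stopifnot(window_snps >= 4, window_snps %% 2 == 0,
            top_quantile > 0, top_quantile < 1, ld_epsilon > 0,
            k_low >= 1)
  structure(list(window_snps = as.integer(window_snps),
                 k_low = as.integer(k_low),
                 top_quantile = top_quantile, ld_epsilon = ld_epsilon,
                 polarized = polarized),
            class = "sweep_config")
}

#' Polymorphism-deficit factor of the composite sweep statistic
#'
#' `mu_var = ((p_W - p_1) / R) * (S / W)`: the bp span of the window's `W`
#' SNPs relative to the chromosome's analyzed span `R`, scaled by the
#' chromosome's SNP count `S`. Its neutral expectation is ~1; windows whose
#' SNPs stretch over disproportionately many bp (a local deficit of
#' polymorphism) score above 1.
#'
#' @param pos_window positions (bp) of the window's SNPs, non-decreasing.
#' @param chrom_span analyzed chromosome span `R` in bp.
#' @param chrom_snp_count number of SNPs `S` on the chromosome.
#' @return the factor value (non-negative scalar).
#' @export
mu_var <- function(pos_window, chrom_span, chrom_snp_count) {
  W <- length(pos_window)
  if (chrom_span <= 0) stop("chromosome span must be positive")
  if (chrom_snp_count < W) stop("chromosome has fewer SNPs than the window")
  ((pos_window[W] - pos_window[1]) / chrom_span) * (chrom_snp_count / W)
}

#' Site-frequency-spectrum factor of the composite sweep statistic
#'
#' Polarized mode: the fraction of window SNPs whose derived-allele count is
#' at most `k_low` or at least `n - k_low` — hard sweeps push the SFS toward
#' both extremes. Folded mode: the fraction whose minor-allele count is at
#' most `k_low`.
#'
#' @param derived_counts derived (ALT) allele counts of the window's SNPs.
#' @param n_haplotypes total allele count per SNP (scalar or per-SNP
#'   vector); must be at least 4.
#' @param k_low low-frequency class bound.
#' @param polarized polarized or folded spectrum.
#' @return the factor value, in `[0, 1]`.
#' @export
mu_sfs <- function(derived_counts, n_haplotypes, k_low = 1L,
                   polarized = TRUE) {
  if (any(n_haplotypes < 4)) stop("need at least 4 haplotypes")
  n <- rep(n_haplotypes, length.out = length(derived_counts))
  if (polarized) {
    mean(derived_counts <= k_low | derived_counts >= n - k_low)
  } else {
    mean(pmin(derived_counts, n - derived_counts) <= k_low)
  }
}

# r-squared on mean-imputed dosages; monomorphic columns give 0
r2_imputed <- function(d) {
  d <- apply(d, 2, function(x) {
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    x
  })
  suppressWarnings(r <- cor(d))
  r[!is.finite(r)] <- 0
  r * r
}

#' Linkage-disequilibrium factor of the composite sweep statistic
#'
#' The window is split into halves; the factor is the average of the mean
#' pairwise genotype r-squared within each half, divided by the mean
#' r-squared across halves (plus `ld_epsilon`). A completed sweep leaves
#' high LD on each flank of the beneficial site but little LD across it, so
#' the ratio rises sharply at the sweep center.
#'
#' @param dosage_window samples x W dosage matrix (W even). Missing dosages
#'   are mean-imputed; monomorphic pairs contribute r-squared 0.
#' @param ld_epsilon denominator guard.
#' @return the factor value (non-negative scalar).
#' @export
mu_ld <- function(dosage_window, ld_epsilon = 1e-6) {
  W <- ncol(dosage_window)
  stopifnot(W %% 2 == 0, W >= 4)
  h <- W / 2
  r2 <- r2_imputed(dosage_window)
  iL <- seq(1, h)
  iR <- seq(h + 1, W)
  mean_off <- function(m) mean(m[upper.tri(m)])
  rL <- mean_off(r2[iL, iL])
  rR <- mean_off(r2[iR, iR])
  rC <- mean(r2[iL, iR])
  ((rL + rR) / 2) / (rC + ld_epsilon)
}

#' Composite mu-statistic sweep scan
#'
#' Slides a `window_snps`-SNP window one SNP at a time along each
#' chromosome, computes the three factors and their product `mu`, applies a
#' genome-wide empirical-quantile threshold (`1 - top_quantile`) and merges
#' overlapping significant windows into candidate sweep regions.
#'
#' @param g a filtered [genotype_matrix()].
#' @param cfg a [sweep_config()].
#' @return a `sweep_scan` list: `windows` (data.frame with chrom,
#'   first/last SNP positions, center, the three factors and mu),
#'   `threshold`, `regions` (merged significant regions, BED-convention
#'   coordinates, score = peak mu), `n_snps_in_regions`, and `config`.
#' @export
mu_scan <- function(g, cfg = sweep_config()) {
  W <- cfg$window_snps
  h <- W %/% 2
  out <- list()
  for (ch in unique(g$chrom)) {
    idx <- which(g$chrom == ch)
    if (length(idx) < W) {
      warning("chromosome ", ch, " has fewer than ", W, " SNPs; skipped")
      next
    }
    out[[ch]] <- scan_chromosome(g, idx, ch, cfg)
  }
  if (!length(out)) stop("no chromosome has enough SNPs for the window size")
  windows <- do.call(rbind, out)
  rownames(windows) <- NULL
  threshold <- unname(quantile(windows$mu, 1 - cfg$top_quantile))
  sig <- windows[windows$mu > threshold, , drop = FALSE]
  regions <- merge_windows(sig)
  n_in <- 0L
  if (nrow(regions)) {
    for (k in seq_len(nrow(regions))) {
      n_in <- n_in + sum(g$chrom == regions$chrom[k] &
                           g$pos - 1 >= regions$start[k] &
                           g$pos - 1 < regions$end[k])
    }
  }
  structure(list(windows = windows, threshold = threshold,
                 regions = regions, n_snps_in_regions = n_in,
                 config = cfg),
            class = "sweep_scan")
}

#' @export
print.sweep_scan <- function(x, ...) {
  cat(sprintf(
    "sweep_scan: %d windows, threshold %.4g (top %.3g%%), %d region(s), %d SNP(s) inside\n",
    nrow(x$windows), x$threshold, 100 * x$config$top_quantile,
    nrow(x$regions), x$n_snps_in_regions))
  invisible(x)
}

# band-sum implementation of the per-window factors for one chromosome
scan_chromosome <- function(g, idx, ch, cfg) {
  W <- cfg$window_snps
  h <- W %/% 2
  pos <- g$pos[idx]
  d <- g$dosages[, idx, drop = FALSE]
  S <- length(idx)
  n_win <- S - W + 1L
  span <- pos[S] - pos[1]

  # standardized columns: z'z = Pearson r on mean-imputed dosages
  z <- apply(d, 2, function(x) {
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    x <- x - mean(x)
    nrm <- sqrt(sum(x * x))
    if (nrm > 0) x / nrm else x * 0
  })

  # r2 band: B[i, dd] = r2(snp i, snp i + dd)
  B <- matrix(0, S, W - 1L)
  for (dd in seq_len(W - 1L)) {
    i <- seq_len(S - dd)
    B[i, dd] <- colSums(z[, i, drop = FALSE] *
                          z[, i + dd, drop = FALSE])^2
  }
  C <- apply(B, 2, cumsum)

  band_sum <- function(starts, width) {
    # sum of r2 over all pairs within [start, start + width - 1]
    tot <- numeric(length(starts))
    for (dd in seq_len(min(width - 1L, W - 1L))) {
      hi <- starts + width - 1L - dd
      lo <- starts - 1L
      tot <- tot + C[hi, dd] - ifelse(lo >= 1L, C[pmax(lo, 1L), dd], 0)
    }
    tot
  }
  starts <- seq_len(n_win)
  sL <- band_sum(starts, h)
  sR <- band_sum(starts + h, h)
  sT <- band_sum(starts, W)
  sC <- sT - sL - sR
  n_half_pairs <- h * (h - 1) / 2
  mu_ld_v <- ((sL / n_half_pairs + sR / n_half_pairs) / 2) /
    (sC / (h * h) + cfg$ld_epsilon)

  p1 <- pos[starts]
  pW <- pos[starts + W - 1L]
  mu_var_v <- ((pW - p1) / span) * (S / W)

  cnt <- colSums(d, na.rm = TRUE)
  n_hap <- 2 * colSums(!is.na(d))
  extreme <- if (cfg$polarized) {
    cnt <= cfg$k_low | cnt >= n_hap - cfg$k_low
  } else {
    pmin(cnt, n_hap - cnt) <= cfg$k_low
  }
  cs <- cumsum(c(0, extreme))
  mu_sfs_v <- (cs[starts + W] - cs[starts]) / W

  data.frame(chrom = ch, first_pos = p1, last_pos = pW,
             center = (p1 + pW) / 2,
             mu_var = mu_var_v, mu_sfs = mu_sfs_v, mu_ld = mu_ld_v,
             mu = mu_var_v * mu_sfs_v * mu_ld_v)
}

# merge significant windows whose SNP spans overlap into regions
merge_windows <- function(sig) {
  if (!nrow(sig))
    return(region(character(), numeric(), numeric(), numeric())[0, ])
  out <- list()
  for (ch in unique(sig$chrom)) {
    s <- sig[sig$chrom == ch, , drop = FALSE]
    s <- s[order(s$first_pos), , drop = FALSE]
    cur_start <- s$first_pos[1]; cur_end <- s$last_pos[1]
    cur_score <- s$mu[1]
    for (k in seq_len(nrow(s))[-1]) {
      if (s$first_pos[k] <= cur_end) {
        cur_end <- max(cur_end, s$last_pos[k])
        cur_score <- max(cur_score, s$mu[k])
      } else {
        out[[length(out) + 1]] <- region(ch, cur_start - 1, cur_end,
                                         cur_score)
        cur_start <- s$first_pos[k]; cur_end <- s$last_pos[k]
        cur_score <- s$mu[k]
      }
    }
    out[[length(out) + 1]] <- region(ch, cur_start - 1, cur_end, cur_score)
  }
  do.call(rbind, out)
}
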
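#' Genotype-environment association configuration
#'
#' @param K number of latent factors absorbing population structure.
#' @param fdr_threshold q-value cutoff for candidate loci.
#' @param hotspot_window window size (bp) for the genomic-distribution
#'   analysis of candidates.
#' @param calibrate recalibrate p-values with the genomic inflation factor.
#' @return a `gea_config` list.
#' @export
gea_config <- function(K = 4L, fdr_threshold = 0.01,
                       hotspot_window = 1e6, calibrate = TRUE) {
  stopifnot(K >= 0, fdr_threshold > 0, fdr_threshold < 1,
            hotspot_window > 0)
  structure(list(K = as.integer(K), fdr_threshold = fdr_threshold,
                 hotspot_window = hotspot_window, calibrate = calibrate),
            class = "gea_config")
}

#' Estimate latent population-structure factors
#'
#' Columns are the top-K left singular vectors of the column-centered
#' (missing-mean-imputed) dosage matrix, scaled by their singular values.
#' Signs are fixed by making each column's largest-magnitude entry
#' positive, so the result is fully deterministic.
#'
#' @param g a [genotype_matrix()].
#' @param K number of factors; `K = 0` returns a zero-column matrix.
#' @return `n_samples x K` numeric matrix `U`.
#' @export
estimate_latent_factors <- function(g, K) {
  n <- n_samples(g)
  if (K >= n) stop("K must be smaller than the number of samples")
  if (K == 0) return(matrix(numeric(0), n, 0))
  X <- impute_center(g$dosages)
  sv <- svd(X, nu = K, nv = 0)
  U <- sv$u %*% diag(sv$d[seq_len(K)], K, K)
  for (k in seq_len(K)) {
    i <- which.max(abs(U[, k]))
    if (U[i, k] < 0) U[, k] <- -U[, k]
  }
  rownames(U) <- g$sample_ids
  U
}

impute_center <- function(d) {
  cm <- colMeans(d, na.rm = TRUE)
  X <- sweep(d, 2, cm)
  X[is.na(X)] <- 0
  X
}

#' Per-variable latent-factor-corrected association tests
#'
#' For each SNP and environmental variable, ordinary least squares of the
#' (mean-imputed) dosage on an intercept, the standardized variable and the
#' latent factors `U`. The z-score is the variable's effect over its
#' standard error, with raw p-values from the t distribution on
#' `n - K - 2` degrees of freedom. When `calibrate` is on, the genomic
#' inflation factor `lambda = median(z^2) / qchisq(0.5, 1)` is estimated
#' per variable and calibrated p-values are the upper chi-square tail of
#' `z^2 / lambda`. Storey q-values are computed per variable and a SNP is a
#' candidate when its q-value is below `fdr_threshold`.
#'
#' Environmental values are site (population) measurements expanded to the
#' samples through their population labels; alternatively a per-sample
#' matrix can be supplied.
#'
#' @param g a filtered [genotype_matrix()].
#' @param env an [env_table()] whose site ids match the population labels,
#'   or a numeric samples x variables matrix.
#' @param U latent factor matrix from [estimate_latent_factors()] (or
#'   `NULL` for `K = 0`).
#' @param cfg a [gea_config()].
#' @return a `gea_result` list: `stats` (data.frame per SNP x variable:
#'   effect, z, p_raw, p, q, candidate), `lambda` (per-variable inflation),
#'   `candidate_counts` (per variable), `U`, `config`, and the SNP
#'   coordinate table `snps`.
#' @export
fit_association <- function(g, env, U = NULL, cfg = gea_config()) {
  if (is.null(U)) U <- matrix(numeric(0), n_samples(g), 0)
  K <- ncol(U)
  n <- n_samples(g)
  if (n <= K + 2) stop("too few samples for K latent factors")

  E <- expand_env(env, g)
  Y <- impute_center(g$dosages)
  zero_var <- apply(Y, 2, function(x) all(x == 0))

  res <- list()
  lambda <- numeric(0)
  for (v in colnames(E)) {
    e <- E[, v]
    if (sd(e) == 0) stop("environmental variable is constant: ", v)
    e <- (e - mean(e)) / sd(e)
    # Identifiability convention of joint latent-factor estimation: variance
    # shared between the tested variable and the factors is attributed to
    # the variable, so the correction cannot absorb a genuine environmental
    # effect; the inflation calibration then handles the residual
    # confounding this leaves along the environmental axis.
    Uo <- if (K > 0) qr.resid(qr(cbind(1, e)), U) else U
    X <- cbind(intercept = 1, env = e, Uo)
    qrX <- qr(X)
    if (qrX$rank < ncol(X))
      stop("design matrix is rank deficient for variable ", v,
           " (environment collinear with latent factors)")
    coefs <- qr.coef(qrX, Y)
    fitted <- X %*% coefs
    rss <- colSums((Y - fitted)^2)
    df <- n - (K + 2)
    xtx_inv <- solve(crossprod(X))
    se <- sqrt(pmax(rss / df * xtx_inv[2, 2], .Machine$double.xmin))
    z <- coefs[2, ] / se
    z[zero_var] <- 0
    p_raw <- 2 * pt(abs(z), df = df, lower.tail = FALSE)
    p_raw[zero_var] <- 1

    if (cfg$calibrate) {
      lam <- median(z[!zero_var]^2) / qchisq(0.5, df = 1)
      lam <- max(lam, 1e-12)
      p_cal <- pchisq(z^2 / lam, df = 1, lower.tail = FALSE)
      p_cal[zero_var] <- 1
    } else {
      lam <- NA_real_
      p_cal <- p_raw
    }
    q <- qvalues(p_cal)
    lambda[v] <- lam
    res[[v]] <- data.frame(variable = v, snp = seq_len(ncol(Y)),
                           effect = unname(coefs[2, ]), z = unname(z),
                           p_raw = unname(p_raw), p = unname(p_cal),
                           q = unname(q),
                           candidate = unname(q < cfg$fdr_threshold))
  }
  stats <- do.call(rbind, res)
  rownames(stats) <- NULL
  counts <- vapply(res, function(x) sum(x$candidate), integer(1))
  structure(list(stats = stats, lambda = lambda,
                 candidate_counts = counts, U = U, config = cfg,
                 snps = data.frame(snp = seq_len(n_snps(g)),
                                   chrom = g$chrom, pos = g$pos)),
            class = "gea_result")
}

#' @export
print.gea_result <- function(x, ...) {
  cat(sprintf("gea_result: %d SNPs x %d variables (K = %d)\n",
              nrow(x$snps), length(x$lambda), ncol(x$U)))
  for (v in names(x$lambda))
    cat(sprintf("  %s: lambda = %.3f, %d candidate(s)\n", v, x$lambda[v],
                x$candidate_counts[v]))
  invisible(x)
}

expand_env <- function(env, g) {
  if (inherits(env, "env_table")) {
    cur <- env$values$current
    pops <- g$pop_of_sample
    if (!all(pops %in% rownames(cur)))
      stop("population labels missing from the environmental table: ",
           paste(setdiff(pops, rownames(cur)), collapse = ", "))
    cur[pops, , drop = FALSE]
  } else {
    m <- as.matrix(env)
    stopifnot(nrow(m) == n_samples(g))
    if (is.null(colnames(m))) colnames(m) <- sprintf("VAR%d", seq_len(ncol(m)))
    m
  }
}

#' Storey q-values
#'
#' Estimates the null proportion `pi0` on a lambda grid (0.05 to 0.95 by
#' 0.05) with cubic-spline smoothing, then converts sorted p-values with
#' the step-up rule `q_i = pi0 * min_{p_(j) >= p_(i)} (m * p_(j) / j)`.
#' With fewer than 100 p-values the pi0 estimate is unstable, so the
#' procedure falls back to Benjamini-Hochberg (`pi0 = 1`).
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return q-values, same length and order as `p`.
#' @export
qvalues <- function(p) {
  if (!length(p)) stop("empty p-value vector")
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  pi0 <- if (m < 100) 1 else estimate_pi0(p)
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

estimate_pi0 <- function(p) {
  lam <- seq(0.05, 0.95, by = 0.05)
  pi0_lam <- vapply(lam, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- smooth.spline(lam, pi0_lam, df = 3)
  pi0 <- predict(fit, x = max(lam))$y
  min(max(pi0, 1e-8), 1)
}

#' Union of per-variable candidate SNPs
#'
#' A SNP may be significant for several variables; the union counts it
#' once, while the per-variable tallies keep the multiplicity.
#'
#' @param result a `gea_result` from [fit_association()].
#' @return list with `snps` (sorted unique candidate SNP indices), `total`
#'   (union size) and `per_variable` (named counts).
#' @export
candidate_union <- function(result) {
  st <- result$stats
  cand <- st[st$candidate, , drop = FALSE]
  list(snps = sort(unique(cand$snp)),
       total = length(unique(cand$snp)),
       per_variable = result$candidate_counts)
}

#' Genomic distribution of candidate SNPs in fixed windows
#'
#' Bins candidates into non-overlapping windows (`[0, w)`, `[w, 2w)`, ...)
#' per chromosome, tallies per-chromosome totals, and tests whether the
#' candidate count scales with chromosome span (Pearson correlation).
#'
#' @param candidate_snps SNP indices (columns of `g`).
#' @param g the [genotype_matrix()] the indices refer to.
#' @param window window size in bp.
#' @return list with `windows` (chrom, start, end, count), `per_chromosome`
#'   (chrom, span_bp, count), and `size_correlation` (estimate and p-value,
#'   `NA` when fewer than 3 chromosomes).
#' @export
hotspot_windows <- function(candidate_snps, g, window = 1e6) {
  chrom <- g$chrom[candidate_snps]
  pos <- g$pos[candidate_snps]
  chroms <- unique(g$chrom)
  win_list <- list()
  per_chrom <- data.frame(chrom = chroms,
                          span_bp = vapply(chroms, function(ch)
                            max(g$pos[g$chrom == ch]), numeric(1)),
                          count = vapply(chroms, function(ch)
                            sum(chrom == ch), numeric(1)))
  for (ch in chroms) {
    span <- per_chrom$span_bp[per_chrom$chrom == ch]
    n_win <- ceiling(span / window)
    starts <- (seq_len(n_win) - 1) * window
    p <- pos[chrom == ch]
    counts <- tabulate(pmin(floor((p - 1) / window) + 1, n_win), n_win)
    win_list[[ch]] <- data.frame(chrom = ch, start = starts,
                                 end = starts + window, count = counts)
  }
  windows <- do.call(rbind, win_list)
  rownames(windows) <- NULL
  size_cor <- c(estimate = NA_real_, p_value = NA_real_)
  if (nrow(per_chrom) >= 3 && sd(per_chrom$count) > 0) {
    ct <- cor.test(per_chrom$span_bp, per_chrom$count)
    size_cor <- c(estimate = unname(ct$estimate), p_value = ct$p.value)
  }
  list(windows = windows, per_chromosome = per_chrom,
       size_correlation = size_cor)
}
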
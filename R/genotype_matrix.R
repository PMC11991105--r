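#' Genotype matrix container
#'
#' The central data object of the pipeline: an `n_samples x n_snps` integer
#' matrix of ALT-allele dosages (0, 1, 2 or `NA` for a missing call) together
#' with per-SNP coordinates and alleles and per-sample population labels.
#' Positions are 1-based (VCF convention) and strictly increasing within each
#' chromosome. The REF allele is treated as ancestral wherever a
#' derived/ancestral distinction is needed downstream.
#'
#' @param dosages integer matrix, samples in rows, SNPs in columns. Values
#'   must be 0, 1, 2 or `NA`.
#' @param chrom character vector of chromosome labels, one per SNP.
#' @param pos integer vector of 1-based positions, one per SNP; strictly
#'   increasing within each chromosome.
#' @param ref,alt single-base allele strings, one per SNP.
#' @param sample_ids character vector of sample names (unique).
#' @param pop_of_sample character vector of population labels, one per sample.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `chrom`, `pos`, `ref`, `alt`, `sample_ids`, `pop_of_sample`.
#' @export
genotype_matrix <- function(dosages, chrom, pos, ref, alt,
                            sample_ids, pop_of_sample) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  n <- nrow(dosages)
  s <- ncol(dosages)
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  ref <- as.character(ref)
  alt <- as.character(alt)
  sample_ids <- as.character(sample_ids)
  pop_of_sample <- as.character(pop_of_sample)

  stopifnot(length(chrom) == s, length(pos) == s,
            length(ref) == s, length(alt) == s,
            length(sample_ids) == n, length(pop_of_sample) == n)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids")
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("dosages must be 0, 1, 2 or NA")
  if (any(is.na(pop_of_sample)) || !length(pop_of_sample))
    stop("every sample needs a population label")
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (length(p) > 1 && any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  rownames(dosages) <- sample_ids
  structure(list(dosages = dosages, chrom = chrom, pos = pos,
                 ref = ref, alt = alt, sample_ids = sample_ids,
                 pop_of_sample = pop_of_sample),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs\n",
              n_samples(x), n_snps(x)))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$chrom), collapse = ", ")))
  pops <- table(x$pop_of_sample)
  cat(sprintf("  populations: %s\n",
              paste(sprintf("%s (%d)", names(pops), pops), collapse = ", ")))
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing genotypes: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Number of samples / SNPs in a genotype matrix
#' @param g a `genotype_matrix`.
#' @return integer count.
#' @export
n_samples <- function(g) nrow(g$dosages)

#' @rdname n_samples
#' @export
n_snps <- function(g) ncol(g$dosages)

#' Subset a genotype matrix by SNP index
#'
#' Keeps all samples; retains SNP-parallel metadata consistently.
#'
#' @param g a `genotype_matrix`.
#' @param snp_idx integer or logical index over SNP columns.
#' @return a `genotype_matrix` restricted to the selected SNPs.
#' @export
subset_snps <- function(g, snp_idx) {
  genotype_matrix(g$dosages[, snp_idx, drop = FALSE],
                  g$chrom[snp_idx], g$pos[snp_idx],
                  g$ref[snp_idx], g$alt[snp_idx],
                  g$sample_ids, g$pop_of_sample)
}

#' Subset a genotype matrix by sample index
#' @param g a `genotype_matrix`.
#' @param sample_idx integer or logical index over samples.
#' @return a `genotype_matrix` restricted to the selected samples.
#' @export
subset_samples <- function(g, sample_idx) {
  genotype_matrix(g$dosages[sample_idx, , drop = FALSE],
                  g$chrom, g$pos, g$ref, g$alt,
                  g$sample_ids[sample_idx], g$pop_of_sample[sample_idx])
}
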
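#' Environmental table container
#'
#' Site-by-variable matrices of bioclimatic predictors, one layer per
#' climate scenario. All layers share the same site and variable ordering;
#' the `"current"` layer is mandatory. Site ids match the population labels
#' of the genotype data (one sampling site per population).
#'
#' @param values named list of numeric matrices (sites x variables), one per
#'   scenario; must contain `"current"`.
#' @param site_ids character vector of site (population) labels.
#' @param variables character vector of variable names (e.g. `BIO2`).
#' @return An object of class `env_table` with elements `values`, `site_ids`,
#'   `variables`, `scenarios`.
#' @export
env_table <- function(values, site_ids, variables) {
  stopifnot(is.list(values), "current" %in% names(values))
  site_ids <- as.character(site_ids)
  variables <- as.character(variables)
  values <- lapply(values, function(m) {
    m <- as.matrix(m)
    stopifnot(nrow(m) == length(site_ids), ncol(m) == length(variables))
    if (any(!is.finite(m))) stop("environmental table contains missing values")
    dimnames(m) <- list(site_ids, variables)
    m
  })
  structure(list(values = values, site_ids = site_ids,
                 variables = variables, scenarios = names(values)),
            class = "env_table")
}

#' @export
print.env_table <- function(x, ...) {
  cat(sprintf("env_table: %d sites x %d variables; scenarios: %s\n",
              length(x$site_ids), length(x$variables),
              paste(x$scenarios, collapse = ", ")))
  invisible(x)
}

#' Genomic region
#'
#' Lightweight interval carrier (sweep regions, hotspot windows). Intervals
#' are 0-based half-open, matching BED.
#'
#' @param chrom chromosome label.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; must exceed `start`.
#' @param score numeric score (e.g. peak mu value).
#' @return data.frame with columns chrom, start, end, score.
#' @export
region <- function(chrom, start, end, score = NA_real_) {
  if (any(end <= start)) stop("region end must exceed start")
  data.frame(chrom = as.character(chrom), start = as.numeric(start),
             end = as.numeric(end), score = as.numeric(score),
             stringsAsFactors = FALSE)
}

#' Read a VCF file into a genotype matrix
#'
#' Reads diploid GT calls from a VCF v4.x file. Only biallelic SNP records
#' (single-base REF and ALT) are retained; multi-allelic or indel records are
#' skipped and their count reported in the `skipped` attribute. Phase
#' separators `/` and `|` are treated identically; `./.` becomes a missing
#' dosage.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @param pop_map optional named character vector mapping sample id ->
#'   population label (see [read_pop_map()]). Samples absent from the map get
#'   population `"unknown"`.
#' @param region_filter optional single-row region data.frame (see
#'   [region()]); only SNPs whose (1-based) position `p` satisfies
#'   `start < p <= end` on `chrom` are kept.
#' @return a [genotype_matrix()] with attribute `skipped` (number of
#'   non-biallelic/non-SNP records dropped).
#' @export
read_vcf <- function(path, pop_map = NULL, region_filter = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  is_snp <- !is.na(ref) & !is.na(alt) &
    nchar(ref) == 1L & nchar(alt) == 1L &
    !grepl(",", alt, fixed = TRUE) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!is_snp)
  if (n_skipped > 0)
    message(n_skipped, " non-biallelic/non-SNP record(s) skipped")
  if (!any(is_snp)) stop("no biallelic SNP records in ", path)

  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(NULL, names(gt)))
  gt <- gt[is_snp, , drop = FALSE]
  chrom <- chrom[is_snp]; pos <- pos[is_snp]
  ref <- ref[is_snp]; alt <- alt[is_snp]

  if (!is.null(region_filter)) {
    keep <- chrom == region_filter$chrom[1] &
      pos > region_filter$start[1] & pos <= region_filter$end[1]
    if (!any(keep)) stop("no SNPs inside the region filter")
    gt <- gt[keep, , drop = FALSE]
    chrom <- chrom[keep]; pos <- pos[keep]
    ref <- ref[keep]; alt <- alt[keep]
  }

  # dosage = number of ALT alleles in the (unphased) genotype call
  dos <- gt_to_dosage(gt)
  samples <- colnames(gt)
  pops <- if (is.null(pop_map)) rep("unknown", length(samples)) else {
    p <- unname(pop_map[samples])
    p[is.na(p)] <- "unknown"
    p
  }
  g <- genotype_matrix(t(dos), chrom, pos, ref, alt, samples, pops)
  attr(g, "skipped") <- n_skipped
  g
}

gt_to_dosage <- function(gt) {
  d <- matrix(NA_integer_, nrow(gt), ncol(gt))
  norm <- gsub("|", "/", gt, fixed = TRUE)
  d[norm %in% c("0/0")] <- 0L
  d[norm %in% c("0/1", "1/0")] <- 1L
  d[norm %in% c("1/1")] <- 2L
  dimnames(d) <- dimnames(gt)
  d
}

#' Write a genotype matrix as a minimal VCF v4.2 file
#'
#' Emits contig headers, a GT-only FORMAT and unphased genotype calls.
#' `read_vcf(write_vcf(g))` is the identity on dosages, coordinates, alleles
#' and sample ids.
#'
#' @param g a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  if (n_samples(g) == 0) stop("cannot write a VCF with no samples")
  ord <- order(factor(g$chrom, levels = unique(g$chrom)), g$pos)
  if (any(duplicated(paste(g$chrom[ord], g$pos[ord]))))
    stop("duplicate coordinates; cannot produce a sorted VCF")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  for (ch in unique(g$chrom)) {
    len <- max(g$pos[g$chrom == ch])
    writeLines(sprintf("##contig=<ID=%s,length=%d>", ch, len), con)
  }
  writeLines('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", g$sample_ids), collapse = "\t"), con)
  code <- c("0/0", "0/1", "1/1")
  for (j in ord) {
    d <- g$dosages[, j]
    gtcol <- ifelse(is.na(d), "./.", code[d + 1L])
    writeLines(paste(c(g$chrom[j], g$pos[j], ".", g$ref[j], g$alt[j], ".",
                       "PASS", ".", "GT", gtcol), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read current and future environmental tables
#'
#' Each file is a CSV with a `site_id` column and numeric variable columns.
#' Future scenario files must contain the same sites and variables as the
#' current file (any row/column order); layers are realigned to the current
#' layer's ordering.
#'
#' @param path_current CSV for the present-day layer.
#' @param paths_future named character vector of scenario -> CSV path (e.g.
#'   `c(ssp126 = "...", ssp585 = "...")`). May be empty.
#' @return an [env_table()].
#' @export
read_env_table <- function(path_current, paths_future = character()) {
  read_one <- function(p) {
    df <- read.table(p, header = TRUE, sep = ",", stringsAsFactors = FALSE,
                     check.names = FALSE)
    if (!"site_id" %in% names(df)) stop("missing site_id column in ", p)
    vars <- setdiff(names(df), "site_id")
    m <- as.matrix(df[, vars, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric environmental value in ", p)
    rownames(m) <- df$site_id
    m
  }
  cur <- read_one(path_current)
  layers <- list(current = cur)
  for (sc in names(paths_future)) {
    m <- read_one(paths_future[[sc]])
    if (!setequal(rownames(m), rownames(cur)))
      stop("site mismatch between current and ", sc)
    if (!setequal(colnames(m), colnames(cur)))
      stop("variable mismatch between current and ", sc)
    layers[[sc]] <- m[rownames(cur), colnames(cur), drop = FALSE]
  }
  env_table(layers, rownames(cur), colnames(cur))
}

#' Write an environmental layer to CSV
#'
#' @param env an [env_table()].
#' @param scenario which layer to write.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_env_table <- function(env, scenario, path) {
  m <- env$values[[scenario]]
  if (is.null(m)) stop("unknown scenario: ", scenario)
  df <- data.frame(site_id = env$site_ids, m, check.names = FALSE)
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-to-population map
#'
#' Two-column TSV (sample, population), no header.
#'
#' @param path TSV file path.
#' @return named character vector: names are sample ids, values populations.
#' @export
read_pop_map <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE,
                   col.names = c("sample", "population"))
  if (anyDuplicated(df$sample))
    stop("duplicate sample in population map: ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  stats::setNames(df$population, df$sample)
}

#' Write a sample-to-population map
#' @param pop_map named character vector (sample -> population).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_pop_map <- function(pop_map, path) {
  write.table(data.frame(names(pop_map), unname(pop_map)), path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write regions as BED (0-based half-open, with score)
#'
#' @param regions data.frame with chrom/start/end/score (see [region()]).
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  df <- regions[, c("chrom", "start", "end", "score")]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
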
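# iHS preprocessing: from per-SNP raw iHS tables to the per-window response
# and the standardized design matrix of the mixture density regression.
# Everything here is deterministic: no RNG.

#' Read a hapbin-style per-SNP iHS table
#'
#' Reads a tab-delimited score file with one row per SNP. Column names are
#' configurable because different scan tools label position/frequency columns
#' differently (and the frequency may be derived- or minor-allele depending on
#' the upstream run).
#'
#' @param path Tab-delimited file with a header line.
#' @param columns Named character vector mapping the internal names
#'   `chromosome`, `position`, `freq`, `raw_ihs` to the file's column names.
#' @return A data.frame with columns chromosome (character), position
#'   (integer bp), derived_allele_freq, raw_ihs.
#' @export
read_ihs_scores <- function(path,
                            columns = c(chromosome = "chromosome",
                                        position = "position",
                                        freq = "freq", raw_ihs = "raw_ihs")) {
  if (!file.exists(path)) stop("iHS score file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chromosome", "position", "freq", "raw_ihs")
  if (!all(need %in% names(columns))) {
    stop("columns mapping must name: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  miss <- setdiff(unname(columns[need]), names(tab))
  if (length(miss)) {
    stop("iHS file ", path, " lacks column(s): ", paste(miss, collapse = ", "),
         "; has: ", paste(names(tab), collapse = ", "), call. = FALSE)
  }
  out <- data.frame(chromosome = as.character(tab[[columns["chromosome"]]]),
                    position = as.integer(tab[[columns["position"]]]),
                    derived_allele_freq = as.numeric(tab[[columns["freq"]]]),
                    raw_ihs = as.numeric(tab[[columns["raw_ihs"]]]),
                    stringsAsFactors = FALSE)
  bad <- which(!is.finite(out$position) | out$position < 0 |
                 !is.finite(out$derived_allele_freq) |
                 out$derived_allele_freq < 0 | out$derived_allele_freq > 1)
  if (length(bad)) {
    stop("iHS file ", path, ": invalid position or frequency at data line ",
         bad[1L], call. = FALSE)
  }
  out
}

#' Filter SNPs to minor allele frequency > 0.05
#'
#' The minor allele frequency of a biallelic SNP with derived-allele
#' frequency f is min(f, 1 - f); SNPs at MAF <= 0.05 are removed (strict
#' inequality). The comparison carries a 1e-9 guard so a frequency whose
#' decimal MAF is exactly the threshold (e.g. 0.95) is dropped even when
#' 1 - f lands a few ulp above it in binary.
#'
#' @param snps SNP table as from [read_ihs_scores()].
#' @param maf_min MAF threshold; keep SNPs with MAF strictly above it.
#' @return The filtered table, with the number of dropped SNPs in attribute
#'   `n_dropped_maf`.
#' @export
filter_maf <- function(snps, maf_min = 0.05) {
  maf <- pmin(snps$derived_allele_freq, 1 - snps$derived_allele_freq)
  keep <- maf > maf_min + 1e-9
  out <- snps[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped_maf") <- sum(!keep)
  out
}

#' Assign a frequency to its standardization bin
#'
#' Bins are half-open intervals [k/n_bins, (k+1)/n_bins) over [0, 1], except
#' the final bin, which is closed at 1.0. Returned indices are 0-based
#' (0 .. n_bins - 1). Frequencies are decimal fractions, so the boundary
#' comparison carries a 1e-9 guard: a frequency printed exactly at k/n_bins
#' opens bin k even when its binary representation falls a few ulp short.
#'
#' @param freq Frequencies in [0, 1] (vectorized).
#' @param n_bins Number of bins (50 for the standard iHS protocol).
#' @return Integer bin indices.
#' @export
assign_frequency_bin <- function(freq, n_bins = 50L) {
  if (any(!is.finite(freq) | freq < 0 | freq > 1)) {
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  }
  pmin(as.integer(floor(freq * n_bins + 1e-9)), n_bins - 1L)
}

#' Standardize raw iHS within allele-frequency bins
#'
#' Splits retained SNPs into `n_bins` derived-allele-frequency bins computed
#' genome-wide (never per chromosome or window), and standardizes each SNP's
#' raw iHS against its bin: (raw - bin mean) / bin SD, with the sample
#' (n - 1) SD convention. Bins holding fewer than `min_bin_size` SNPs, or
#' with zero SD, are degenerate: their SNPs are dropped and counted.
#'
#' @param snps MAF-filtered SNP table ([filter_maf()]).
#' @param n_bins Number of frequency bins.
#' @param min_bin_size Minimum SNPs for a bin to be retained.
#' @return A list: `snps` (input rows surviving, plus `bin` and
#'   `standardized_ihs` columns), `bin_stats` (data.frame: bin_index,
#'   mean_raw, sd_raw, n_snps over all non-empty bins), `n_dropped_bins`
#'   (SNPs lost to degenerate bins).
#' @export
standardize_ihs <- function(snps, n_bins = 50L, min_bin_size = 2L) {
  if (nrow(snps) == 0L) stop("no SNPs to standardize", call. = FALSE)
  bin <- assign_frequency_bin(snps$derived_allele_freq, n_bins)
  fbin <- factor(bin, levels = sort(unique(bin)))
  mean_raw <- tapply(snps$raw_ihs, fbin, mean)
  sd_raw <- tapply(snps$raw_ihs, fbin, stats::sd)
  n_snps <- as.integer(table(fbin))
  bin_stats <- data.frame(bin_index = as.integer(levels(fbin)),
                          mean_raw = as.numeric(mean_raw),
                          sd_raw = as.numeric(sd_raw), n_snps = n_snps)
  ok_bin <- bin_stats$n_snps >= min_bin_size &
    !is.na(bin_stats$sd_raw) & bin_stats$sd_raw > 0
  if (!any(ok_bin)) stop("all frequency bins are degenerate", call. = FALSE)
  keep <- bin %in% bin_stats$bin_index[ok_bin]
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " SNP(s) dropped from degenerate frequency bins")
  }
  out <- snps[keep, , drop = FALSE]
  bin <- bin[keep]
  idx <- match(bin, bin_stats$bin_index)
  out$bin <- bin
  out$standardized_ihs <- (out$raw_ihs - bin_stats$mean_raw[idx]) /
    bin_stats$sd_raw[idx]
  rownames(out) <- NULL
  list(snps = out, bin_stats = bin_stats, n_dropped_bins = n_dropped)
}

#' Window mean of absolute standardized iHS
#'
#' For each gene-centered window, averages |standardized iHS| over the SNPs
#' whose position falls inside the half-open interval [start, end), and
#' counts them. Windows containing no SNP are omitted from the result.
#'
#' @param snps Standardized SNP table (`$snps` from [standardize_ihs()]).
#' @param windows Window table from [gene_center_windows()] (columns gene_id,
#'   chromosome, start, end).
#' @return data.frame: gene_id, chromosome, start, end, mean_abs_ihs, n_ihs;
#'   rows in the order of `windows`, zero-SNP windows dropped.
#' @export
summarize_windows <- function(snps, windows) {
  stopifnot(all(c("gene_id", "chromosome", "start", "end") %in% names(windows)))
  if (!"standardized_ihs" %in% names(snps)) {
    stop("snps lack standardized_ihs; run standardize_ihs() first", call. = FALSE)
  }
  res <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    sel <- snps$chromosome == w$chromosome &
      snps$position >= w$start & snps$position < w$end
    n <- sum(sel)
    if (n == 0L) return(NULL)
    data.frame(gene_id = w$gene_id, chromosome = w$chromosome,
               start = w$start, end = w$end,
               mean_abs_ihs = mean(abs(snps$standardized_ihs[sel])),
               n_ihs = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), chromosome = character(),
                      start = integer(), end = integer(),
                      mean_abs_ihs = numeric(), n_ihs = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Write a per-window iHS summary table
#'
#' @param summaries Output of [summarize_windows()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_window_summary <- function(summaries, path) {
  utils::write.table(summaries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Response vector: z-scored log window mean |iHS|
#'
#' Takes the natural log of each window's mean absolute standardized iHS and
#' z-scores the result over the analysis set (mean 0, sample-SD 1). Call this
#' on the rows that survive complete-case filtering, so the response is
#' standardized on exactly the data entering the model.
#'
#' @param mean_abs_ihs Positive window means (column `mean_abs_ihs` of
#'   [summarize_windows()] output).
#' @return Numeric response vector with mean 0 and SD 1.
#' @export
transform_response <- function(mean_abs_ihs) {
  if (!length(mean_abs_ihs)) stop("empty response", call. = FALSE)
  if (any(!is.finite(mean_abs_ihs) | mean_abs_ihs <= 0)) {
    stop("mean_abs_ihs must be positive and finite", call. = FALSE)
  }
  y <- log(mean_abs_ihs)
  s <- stats::sd(y)
  if (length(y) < 2L || s == 0) {
    stop("degenerate response: constant mean |iHS| across windows", call. = FALSE)
  }
  (y - mean(y)) / s
}

#' Standardize covariate columns to mean 0, SD 1
#'
#' Centers and scales each column of a complete-case feature matrix with the
#' sample (n - 1) SD, as the regression expects. Zero-variance columns are an
#' error (they carry no information and break scaling), named explicitly.
#'
#' @param features Numeric matrix or data.frame of covariates; column names
#'   required.
#' @return A numeric matrix of standardized covariates.
#' @export
standardize_covariates <- function(features) {
  X <- as.matrix(features)
  if (is.null(colnames(X))) stop("covariates must be named", call. = FALSE)
  if (!is.numeric(X)) stop("covariates must be numeric", call. = FALSE)
  if (any(!is.finite(X))) {
    bad <- colnames(X)[apply(!is.finite(X), 2, any)]
    stop("covariates contain missing/non-finite values: ",
         paste(bad, collapse = ", "), " (complete-case rows required)",
         call. = FALSE)
  }
  sds <- apply(X, 2, stats::sd)
  zero <- sds == 0 | is.na(sds)
  if (any(zero)) {
    stop("zero-variance covariate(s): ",
         paste(colnames(X)[zero], collapse = ", "), call. = FALSE)
  }
  scale(X, center = TRUE, scale = sds)[, , drop = FALSE]
}
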
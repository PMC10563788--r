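# Gene-centered windows and genomic covariates. Coordinates are 0-based
# half-open [start, end) throughout (BED convention); IRanges (1-based
# closed) is used internally for merge/intersect arithmetic via to_iranges().

#' Read a tab-delimited genetic map
#'
#' Expects a header line and columns chromosome, position (bp), cm
#' (cumulative genetic position). Positions must be strictly increasing and
#' genetic positions non-decreasing within each chromosome; violations are
#' reported with their line number. Map positions are interpreted on the same
#' 0-based coordinate axis as all other inputs.
#'
#' @param path Map file path.
#' @return A `genetic_map`: named list (per chromosome) of lists with sorted
#'   numeric vectors `pos` (bp) and `cm`.
#' @export
read_genetic_map <- function(path) {
  if (!file.exists(path)) stop("genetic map not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("chromosome", "position", "cm")
  if (!all(need %in% names(tab))) {
    stop("genetic map ", path, " must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  tab$line <- seq_len(nrow(tab)) + 1L
  by_chrom <- split(tab, tab$chromosome)
  map <- lapply(by_chrom, function(d) {
    d <- d[order(d$position), ]
    if (any(duplicated(d$position))) {
      stop("genetic map ", path, ": duplicated position at line ",
           d$line[duplicated(d$position)][1L], call. = FALSE)
    }
    if (is.unsorted(d$cm)) {
      stop("genetic map ", path, ": genetic position decreases at line ",
           d$line[which(diff(d$cm) < 0)[1L] + 1L], call. = FALSE)
    }
    list(pos = as.numeric(d$position), cm = as.numeric(d$cm))
  })
  structure(map, class = "genetic_map")
}

#' Construct a genetic map from vectors
#'
#' @param chromosome,position,cm Parallel vectors of map points.
#' @return A `genetic_map` object (see [read_genetic_map()]).
#' @export
genetic_map <- function(chromosome, position, cm) {
  d <- data.frame(chromosome = as.character(chromosome),
                  position = as.numeric(position), cm = as.numeric(cm))
  map <- lapply(split(d, d$chromosome), function(x) {
    x <- x[order(x$position), ]
    stopifnot(!anyDuplicated(x$position), !is.unsorted(x$cm))
    list(pos = x$position, cm = x$cm)
  })
  structure(map, class = "genetic_map")
}

#' Read a BED file (3 to 6 columns, no header)
#'
#' Native 0-based half-open intervals. Column 4 is a name and column 5 a
#' numeric score, when present. Malformed lines (start >= end, negative
#' start) are reported with their line number.
#'
#' @param path BED file path.
#' @return data.frame: chromosome, start, end, and score when the file has
#'   >= 5 columns.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("BED file ", path, " has fewer than 3 columns",
                           call. = FALSE)
  out <- data.frame(chromosome = as.character(tab[[1L]]),
                    start = as.integer(tab[[2L]]), end = as.integer(tab[[3L]]),
                    stringsAsFactors = FALSE)
  if (ncol(tab) >= 5L) out$score <- as.numeric(tab[[5L]])
  bad <- which(!is.finite(out$start) | !is.finite(out$end) |
                 out$start < 0 | out$start >= out$end)
  if (length(bad)) {
    stop("BED file ", path, ", line ", bad[1L],
         ": invalid interval (need 0 <= start < end)", call. = FALSE)
  }
  out
}

#' Read a BED-like gene annotation table
#'
#' Tab-delimited with header; columns chromosome, start, end, gene_id
#' (strand optional, ignored). start/end span the most upstream transcription
#' start to the most downstream transcription end, 0-based half-open.
#'
#' @param path Gene table path.
#' @return data.frame: gene_id, chromosome, start, end.
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stop("gene table not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("chromosome", "start", "end", "gene_id")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("gene table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- which(tab$start >= tab$end | tab$start < 0)
  if (length(bad)) {
    stop("gene table ", path, ", data line ", bad[1L],
         ": invalid gene span (need 0 <= start < end)", call. = FALSE)
  }
  if (anyDuplicated(tab$gene_id)) {
    stop("gene table ", path, ": duplicated gene_id ",
         tab$gene_id[duplicated(tab$gene_id)][1L], call. = FALSE)
  }
  data.frame(gene_id = as.character(tab$gene_id),
             chromosome = as.character(tab$chromosome),
             start = as.integer(tab$start), end = as.integer(tab$end),
             stringsAsFactors = FALSE)
}

#' Read a per-gene scalar table (expression, PPI, VIP status)
#'
#' Tab-delimited with header; columns gene_id, tpm_mean, tpm_testis,
#' tpm_immune (transcripts per million, >= 0), ppi_count (integer >= 0),
#' is_vip (0/1).
#'
#' @param path Scalar table path.
#' @return data.frame with the columns above.
#' @export
read_gene_scalars <- function(path) {
  if (!file.exists(path)) stop("gene scalar table not found: ", path,
                               call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("gene_id", "tpm_mean", "tpm_testis", "tpm_immune", "ppi_count",
            "is_vip")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("gene scalar table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(tab$tpm_mean < 0 | tab$tpm_testis < 0 | tab$tpm_immune < 0 |
            tab$ppi_count < 0)) {
    stop("gene scalar table ", path, ": TPM and ppi_count must be >= 0",
         call. = FALSE)
  }
  tab$is_vip <- as.logical(tab$is_vip)
  tab[, need]
}

# 0-based half-open [start, end) -> IRanges (1-based closed)
to_iranges <- function(start, end) IRanges::IRanges(start = start + 1, end = end)

#' Gene-centered fixed-size windows
#'
#' One window per gene, centered at floor((start + end) / 2) and spanning
#' [center - size/2, center + size/2). Windows of different genes may
#' overlap. When chromosome lengths are supplied, windows reaching past a
#' chromosome end are clipped and flagged `truncated` (clipping at 0 happens
#' and is flagged even without lengths).
#'
#' @param genes Gene table ([read_gene_table()]).
#' @param size Window size in bp, even and positive; the standard scan sizes
#'   are 50, 100, 200, 500 and 1,000 kb.
#' @param chrom_lengths Optional named vector of chromosome lengths (bp). If
#'   given, every gene's chromosome must be present.
#' @return data.frame: gene_id, chromosome, start, end, truncated.
#' @export
gene_center_windows <- function(genes, size, chrom_lengths = NULL) {
  stopifnot(size > 0, size %% 2 == 0)
  center <- floor((genes$start + genes$end) / 2)
  start <- center - size / 2
  end <- center + size / 2
  truncated <- start < 0
  start <- pmax(start, 0)
  if (!is.null(chrom_lengths)) {
    miss <- setdiff(unique(genes$chromosome), names(chrom_lengths))
    if (length(miss)) {
      stop("chromosome length unknown for: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    len <- chrom_lengths[genes$chromosome]
    truncated <- truncated | end > len
    end <- pmin(end, len)
  }
  data.frame(gene_id = genes$gene_id, chromosome = genes$chromosome,
             start = as.numeric(start), end = as.numeric(end),
             truncated = truncated, stringsAsFactors = FALSE)
}

#' Interpolated genetic position
#'
#' Genetic (cM) position of physical positions by linear interpolation
#' between the two flanking map points. A position exactly on a map point
#' returns that point's cM. Otherwise both flanking points must lie within
#' `max_search` bp of the query; if either side lacks such a point — in
#' particular beyond the first or last map point, where no extrapolation is
#' done — the result is NA.
#'
#' @param map A `genetic_map`.
#' @param chromosome Chromosome label (single value).
#' @param pos Physical positions (bp), vectorized.
#' @param max_search Maximum distance (bp) to a flanking map point; 50 kb for
#'   window edges, 1,000 kb for SNPs in the standard protocol.
#' @return Numeric vector of cM positions, NA where undefined.
#' @export
genetic_position <- function(map, chromosome, pos, max_search) {
  stopifnot(inherits(map, "genetic_map"), max_search > 0)
  m <- map[[chromosome]]
  if (is.null(m)) return(rep(NA_real_, length(pos)))
  p <- m$pos
  cm <- m$cm
  n <- length(p)
  out <- rep(NA_real_, length(pos))
  exact <- match(pos, p)
  hit <- !is.na(exact)
  out[hit] <- cm[exact[hit]]
  i <- findInterval(pos, p)
  ok <- !hit & i >= 1L & i < n
  ok[ok] <- (pos[ok] - p[i[ok]]) <= max_search &
    (p[i[ok] + 1L] - pos[ok]) <= max_search
  ii <- i[ok]
  out[ok] <- cm[ii] + (pos[ok] - p[ii]) / (p[ii + 1L] - p[ii]) *
    (cm[ii + 1L] - cm[ii])
  out
}

#' Window-wide recombination rate
#'
#' Genetic distance between the window edges divided by their physical
#' distance, in cM/Mb. Edge genetic positions come from
#' [genetic_position()] under the `max_search` rule (50 kb by default); if
#' either edge has no genetic position, the window's rate is NA and the
#' window is later excluded by complete-case filtering.
#'
#' @param map A `genetic_map`.
#' @param windows Window table ([gene_center_windows()]).
#' @param max_search Maximum distance (bp) for edge interpolation.
#' @return Numeric vector of rates (cM/Mb), NA where undefined.
#' @export
window_recombination_rate <- function(map, windows, max_search = 50000) {
  rates <- rep(NA_real_, nrow(windows))
  for (ch in unique(windows$chromosome)) {
    sel <- windows$chromosome == ch
    cm_start <- genetic_position(map, ch, windows$start[sel], max_search)
    cm_end <- genetic_position(map, ch, windows$end[sel], max_search)
    rates[sel] <- (cm_end - cm_start) /
      ((windows$end[sel] - windows$start[sel]) / 1e6)
  }
  rates
}

#' Interval density per window, excluding assembly gaps
#'
#' Fraction of non-gap window bases covered by the (merged) interval set:
#' (bases of merged intervals within the window, excluding gap bases) /
#' (window length - gap bases in the window). NA when the denominator is 0
#' (window entirely gap).
#'
#' @param intervals Interval data.frame (chromosome, start, end), 0-based
#'   half-open; overlapping intervals are merged before measuring.
#' @param windows Window table.
#' @param gaps Optional assembly-gap intervals, same format.
#' @return Numeric densities in [0, 1] (or NA), one per window.
#' @export
interval_density <- function(intervals, windows, gaps = NULL) {
  out <- rep(NA_real_, nrow(windows))
  for (ch in unique(windows$chromosome)) {
    sel <- which(windows$chromosome == ch)
    wir <- to_iranges(windows$start[sel], windows$end[sel])
    iv <- intervals[intervals$chromosome == ch, , drop = FALSE]
    ir <- IRanges::reduce(to_iranges(iv$start, iv$end))
    if (!is.null(gaps)) {
      gv <- gaps[gaps$chromosome == ch, , drop = FALSE]
      gr <- IRanges::reduce(to_iranges(gv$start, gv$end))
      ir <- IRanges::setdiff(ir, gr)
    } else {
      gr <- IRanges::IRanges()
    }
    cov_w <- vapply(seq_along(wir), function(j) {
      sum(IRanges::width(IRanges::intersect(ir, wir[j])))
    }, numeric(1))
    gap_w <- vapply(seq_along(wir), function(j) {
      sum(IRanges::width(IRanges::intersect(gr, wir[j])))
    }, numeric(1))
    denom <- IRanges::width(wir) - gap_w
    out[sel] <- ifelse(denom > 0, cov_w / denom, NA_real_)
  }
  out
}

#' Score threshold capturing a target genome fraction
#'
#' Finds the smallest score t such that the merged bases of intervals with
#' score >= t cover at most `target_fraction` of the genome. Intervals tied
#' on a score are kept or dropped together. If even the highest score class
#' exceeds the target, no finite threshold works: Inf is returned with a
#' warning (empty selection). Used to call, e.g., the top 4.17% of the
#' genome conserved or the top 10% DNaseI-accessible.
#'
#' @param intervals Scored interval data.frame (chromosome, start, end,
#'   score).
#' @param genome_length Total genome length in bp.
#' @param target_fraction Target covered fraction, in (0, 1).
#' @return List of class `score_threshold`: `threshold`,
#'   `achieved_fraction`, `target_fraction`.
#' @export
score_threshold_for_fraction <- function(intervals, genome_length,
                                         target_fraction) {
  stopifnot(target_fraction > 0, target_fraction < 1, genome_length > 0)
  if (is.null(intervals$score)) stop("intervals carry no score", call. = FALSE)
  if (nrow(intervals) == 0L) stop("empty interval set", call. = FALSE)
  scores <- sort(unique(intervals$score), decreasing = TRUE)
  budget <- target_fraction * genome_length
  covered <- function(t) {
    sub <- intervals[intervals$score >= t, , drop = FALSE]
    sum(vapply(split(sub, sub$chromosome), function(d) {
      sum(IRanges::width(IRanges::reduce(to_iranges(d$start, d$end))))
    }, numeric(1)))
  }
  best <- Inf
  best_cov <- 0
  for (t in scores) {           # descending: coverage grows as t drops
    cv <- covered(t)
    if (cv <= budget) {
      best <- t
      best_cov <- cv
    } else break
  }
  if (!is.finite(best)) {
    warning("no finite score threshold keeps coverage at or below ",
            "the target fraction; selection is empty", call. = FALSE)
  }
  res <- structure(list(threshold = best,
                        achieved_fraction = best_cov / genome_length,
                        target_fraction = target_fraction),
                   class = "score_threshold")
  message(sprintf("score threshold %g covers %.4f of the genome (target %.4f)",
                  res$threshold, res$achieved_fraction, res$target_fraction))
  res
}

#' Apply a score threshold to a scored interval set
#'
#' @param intervals Scored interval data.frame.
#' @param threshold Score cut-off (keep score >= threshold), e.g.
#'   `$threshold` from [score_threshold_for_fraction()].
#' @return The subset of intervals at or above the threshold.
#' @export
apply_score_threshold <- function(intervals, threshold) {
  intervals[intervals$score >= threshold, , drop = FALSE]
}

#' GC content per window
#'
#' (G + C) / (A + C + G + T) over the window sequence; ambiguous bases (N
#' etc.) are excluded from the denominator. NA for an all-ambiguous window.
#'
#' @param sequences A [Biostrings::DNAStringSet] named by chromosome (or a
#'   FASTA path, which is read with [Biostrings::readDNAStringSet()]).
#' @param windows Window table.
#' @return Numeric GC fractions in [0, 1] (or NA), one per window.
#' @export
gc_content <- function(sequences, windows) {
  if (is.character(sequences)) {
    sequences <- Biostrings::readDNAStringSet(sequences)
    names(sequences) <- sub("\\s.*$", "", names(sequences))
  }
  miss <- setdiff(unique(windows$chromosome), names(sequences))
  if (length(miss)) {
    stop("no sequence for chromosome(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  vapply(seq_len(nrow(windows)), function(i) {
    s <- sequences[[windows$chromosome[i]]]
    from <- max(windows$start[i] + 1, 1)
    to <- min(windows$end[i], length(s))
    if (from > to) return(NA_real_)
    fr <- Biostrings::alphabetFrequency(Biostrings::subseq(s, from, to))
    acgt <- sum(fr[c("A", "C", "G", "T")])
    if (acgt == 0) NA_real_ else sum(fr[c("G", "C")]) / acgt
  }, numeric(1))
}

#' Distance to the nearest virus-interacting gene
#'
#' Edge-to-edge gap (bp) between each gene and the closest same-chromosome
#' VIP gene: 0 if the spans overlap or the gene is itself a VIP; NA when the
#' chromosome carries no VIP. Optionally center-to-center distances instead.
#'
#' @param genes Gene table.
#' @param is_vip Logical vector marking VIP genes, parallel to `genes`.
#' @param convention "edge" (gap, default) or "center" (distance between
#'   gene centers; 0 only for a VIP gene itself).
#' @return Numeric distances (bp), one per gene.
#' @export
distance_to_nearest_vip <- function(genes, is_vip,
                                    convention = c("edge", "center")) {
  convention <- match.arg(convention)
  stopifnot(length(is_vip) == nrow(genes))
  out <- rep(NA_real_, nrow(genes))
  for (ch in unique(genes$chromosome)) {
    sel <- which(genes$chromosome == ch)
    vsel <- sel[is_vip[sel]]
    if (!length(vsel)) next
    for (i in sel) {
      if (is_vip[i]) {
        out[i] <- 0
        next
      }
      if (convention == "edge") {
        gap <- pmax(0, pmax(genes$start[vsel] - genes$end[i],
                            genes$start[i] - genes$end[vsel]))
      } else {
        ci <- (genes$start[i] + genes$end[i]) / 2
        cv <- (genes$start[vsel] + genes$end[vsel]) / 2
        gap <- abs(cv - ci)
      }
      out[i] <- min(gap)
    }
  }
  out
}

#' Genes overlapping each window
#'
#' Counts genes whose span [start, end) intersects the window by at least
#' one base; the window's own central gene counts.
#'
#' @param genes Gene table.
#' @param windows Window table.
#' @return Integer counts, one per window.
#' @export
gene_number <- function(genes, windows) {
  vapply(seq_len(nrow(windows)), function(i) {
    sel <- genes$chromosome == windows$chromosome[i]
    sum(genes$start[sel] < windows$end[i] & genes$end[sel] > windows$start[i])
  }, integer(1))
}

#' Local recombination around regulatory elements within a window
#'
#' For each window: takes the elements intersecting it, expands each by
#' `flank` bp on both sides, merges and clips the regions to the window,
#' and averages the recombination rate of segments between consecutive map
#' points falling inside a region, weighting by physical span. `n_points`
#' counts the map data points used. The mean is NA when fewer than two map
#' points share a region anywhere in the window.
#'
#' @param map A `genetic_map`.
#' @param elements Interval data.frame of regulatory elements.
#' @param windows Window table.
#' @param flank Flank size in bp (5 kb in the standard protocol).
#' @return data.frame: `local_recomb` (cM/Mb or NA), `local_recomb_n`
#'   (map points used), one row per window.
#' @export
local_recombination_around_elements <- function(map, elements, windows,
                                                flank = 5000) {
  res <- data.frame(local_recomb = rep(NA_real_, nrow(windows)),
                    local_recomb_n = integer(nrow(windows)))
  for (i in seq_len(nrow(windows))) {
    ch <- windows$chromosome[i]
    m <- map[[ch]]
    ev <- elements[elements$chromosome == ch &
                     elements$start < windows$end[i] &
                     elements$end > windows$start[i], , drop = FALSE]
    if (is.null(m) || nrow(ev) == 0L) next
    reg <- IRanges::restrict(
      IRanges::reduce(to_iranges(pmax(ev$start - flank, 0), ev$end + flank)),
      start = windows$start[i] + 1, end = windows$end[i])
    rs <- IRanges::start(reg) - 1   # back to 0-based half-open
    re <- IRanges::end(reg)
    npts <- 0L
    wsum <- 0
    rsum <- 0
    for (j in seq_along(rs)) {
      inside <- which(m$pos >= rs[j] & m$pos < re[j])
      npts <- npts + length(inside)
      if (length(inside) >= 2L) {
        dp <- diff(m$pos[inside])
        dc <- diff(m$cm[inside])
        rsum <- rsum + sum(dc / dp * 1e6 * dp)
        wsum <- wsum + sum(dp)
      }
    }
    res$local_recomb_n[i] <- npts
    if (wsum > 0) res$local_recomb[i] <- rsum / wsum
  }
  res
}

#' Gene-level covariates: length, log2 expression, log2 PPIs
#'
#' gene_length = end - start; expression = log2(TPM + 1) (the pseudocount
#' handles TPM = 0); log2_ppi = log2(ppi_count + 1).
#'
#' @param genes Gene table.
#' @param scalars Per-gene scalar table ([read_gene_scalars()]), matched by
#'   gene_id.
#' @param tpm_pseudocount Pseudocount added to TPM before log2.
#' @return data.frame: gene_id, gene_length, expression_mean,
#'   expression_testis, expression_immune, log2_ppi.
#' @export
derived_gene_covariates <- function(genes, scalars, tpm_pseudocount = 1) {
  idx <- match(genes$gene_id, scalars$gene_id)
  if (anyNA(idx)) {
    stop("no scalar data for gene(s): ",
         paste(utils::head(genes$gene_id[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  s <- scalars[idx, ]
  if (any(s$tpm_mean < 0 | s$tpm_testis < 0 | s$tpm_immune < 0 |
            s$ppi_count < 0)) {
    stop("TPM and ppi_count must be >= 0", call. = FALSE)
  }
  data.frame(gene_id = genes$gene_id,
             gene_length = genes$end - genes$start,
             expression_mean = log2(s$tpm_mean + tpm_pseudocount),
             expression_testis = log2(s$tpm_testis + tpm_pseudocount),
             expression_immune = log2(s$tpm_immune + tpm_pseudocount),
             log2_ppi = log2(s$ppi_count + 1),
             stringsAsFactors = FALSE)
}

#' Greedy non-overlapping window subset
#'
#' Left-to-right greedy selection per chromosome: windows sorted by start;
#' a window is kept when it does not overlap the last kept one. Used for the
#' robustness check on physically non-overlapping windows.
#'
#' @param windows Window table.
#' @return Logical vector: TRUE for retained windows.
#' @export
select_non_overlapping <- function(windows) {
  keep <- logical(nrow(windows))
  for (ch in unique(windows$chromosome)) {
    sel <- which(windows$chromosome == ch)
    sel <- sel[order(windows$start[sel], windows$end[sel])]
    last_end <- -Inf
    for (i in sel) {
      if (windows$start[i] >= last_end) {
        keep[i] <- TRUE
        last_end <- windows$end[i]
      }
    }
  }
  keep
}

#' Assemble the per-window feature table
#'
#' Joins every genomic covariate into one row per gene window: gene length,
#' overlapping-gene count, window recombination rate (50 kb edge rule),
#' interval densities with gap exclusion (one column per supplied track),
#' GC content, log2 expression (mean/testis/immune), log2 PPIs, distance to
#' the nearest VIP, and the window mean |iHS| response with its SNP count.
#' Rows with any missing covariate are excluded (complete case) and counted
#' per reason; an optional greedy filter keeps only physically
#' non-overlapping windows.
#'
#' @param genes Gene table ([read_gene_table()]).
#' @param scalars Per-gene scalar table ([read_gene_scalars()]).
#' @param map A `genetic_map`.
#' @param snps Standardized SNP table (`$snps` from [standardize_ihs()]).
#' @param window_size Window size in bp.
#' @param density_tracks Named list of interval data.frames; each yields a
#'   column `<name>_density`. Scored tracks must be thresholded beforehand
#'   ([apply_score_threshold()]).
#' @param gaps Assembly-gap intervals (or NULL).
#' @param sequences DNAStringSet or FASTA path for GC content.
#' @param chrom_lengths Optional named chromosome lengths for truncation
#'   flagging.
#' @param local_recomb_tracks Optional named list of regulatory interval
#'   sets; each yields `local_recomb_<name>` and `local_recomb_n_<name>`
#'   columns (5 kb flank rule). These columns do NOT enter complete-case
#'   filtering unless `local_recomb_complete_case = TRUE`.
#' @param max_search Edge-interpolation search limit (bp).
#' @param flank Flank for local recombination (bp).
#' @param non_overlapping Keep only a greedy non-overlapping window subset.
#' @param exclude_truncated Drop windows truncated at chromosome ends
#'   (default keeps them, flagged).
#' @param local_recomb_complete_case Include local-recombination columns in
#'   the complete-case filter.
#' @param tpm_pseudocount Pseudocount for log2 expression.
#' @return A list of class `window_feature_table`: `features` (data.frame,
#'   complete-case rows), `exclusions` (named integer vector of per-reason
#'   counts; a window can count under several reasons), `n_input` (gene
#'   count), `window_size`.
#' @export
assemble_feature_table <- function(genes, scalars, map, snps, window_size,
                                   density_tracks = list(), gaps = NULL,
                                   sequences = NULL, chrom_lengths = NULL,
                                   local_recomb_tracks = NULL,
                                   max_search = 50000, flank = 5000,
                                   non_overlapping = FALSE,
                                   exclude_truncated = FALSE,
                                   local_recomb_complete_case = FALSE,
                                   tpm_pseudocount = 1) {
  check_chromosomes(genes, map, snps, density_tracks, gaps, sequences)
  windows <- gene_center_windows(genes, window_size, chrom_lengths)

  feat <- derived_gene_covariates(genes, scalars, tpm_pseudocount)
  feat$chromosome <- windows$chromosome
  feat$window_start <- windows$start
  feat$window_end <- windows$end
  feat$truncated <- windows$truncated
  feat$gene_number <- gene_number(genes, windows)
  feat$recomb_rate <- window_recombination_rate(map, windows, max_search)
  for (nm in names(density_tracks)) {
    feat[[paste0(nm, "_density")]] <-
      interval_density(density_tracks[[nm]], windows, gaps)
  }
  if (!is.null(sequences)) feat$gc_content <- gc_content(sequences, windows)
  sidx <- match(genes$gene_id, scalars$gene_id)
  feat$vip_distance <- distance_to_nearest_vip(genes, scalars$is_vip[sidx])
  if (!is.null(local_recomb_tracks)) {
    for (nm in names(local_recomb_tracks)) {
      lr <- local_recombination_around_elements(map, local_recomb_tracks[[nm]],
                                                windows, flank)
      feat[[paste0("local_recomb_", nm)]] <- lr$local_recomb
      feat[[paste0("local_recomb_n_", nm)]] <- lr$local_recomb_n
    }
  }

  ws <- summarize_windows(snps, windows)
  widx <- match(feat$gene_id, ws$gene_id)
  feat$mean_abs_ihs <- ws$mean_abs_ihs[widx]
  feat$n_ihs <- ws$n_ihs[widx]

  exclusions <- c()
  cc_cols <- setdiff(names(feat),
                     c("gene_id", "chromosome", "truncated",
                       if (!local_recomb_complete_case)
                         grep("^local_recomb", names(feat), value = TRUE)))
  for (cl in cc_cols) {
    nbad <- sum(is.na(feat[[cl]]))
    if (nbad > 0) exclusions[paste0("missing_", cl)] <- nbad
  }
  keep <- stats::complete.cases(feat[cc_cols])
  if (exclude_truncated) {
    exclusions["truncated_window"] <- sum(feat$truncated & keep)
    keep <- keep & !feat$truncated
  }
  feat <- feat[keep, , drop = FALSE]
  if (non_overlapping) {
    wk <- data.frame(chromosome = feat$chromosome, start = feat$window_start,
                     end = feat$window_end)
    nov <- select_non_overlapping(wk)
    exclusions["overlapping_window"] <- sum(!nov)
    feat <- feat[nov, , drop = FALSE]
  }
  rownames(feat) <- NULL
  structure(list(features = feat,
                 exclusions = if (length(exclusions)) exclusions
                              else c(none = 0L),
                 n_input = nrow(genes), window_size = window_size),
            class = "window_feature_table")
}

check_chromosomes <- function(genes, map, snps, density_tracks, gaps,
                              sequences) {
  gch <- unique(genes$chromosome)
  sources <- list(genetic_map = names(map),
                  snps = unique(snps$chromosome))
  for (nm in names(density_tracks)) {
    sources[[nm]] <- unique(density_tracks[[nm]]$chromosome)
  }
  if (!is.null(gaps)) sources$gaps <- unique(gaps$chromosome)
  if (!is.null(sequences) && !is.character(sequences)) {
    sources$sequences <- names(sequences)
  }
  for (nm in names(sources)) {
    extra <- setdiff(sources[[nm]], gch)
    if (length(extra)) {
      stop("chromosome name(s) in ", nm, " not present in gene table: ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.window_feature_table <- function(x, ...) {
  cat(sprintf("Window feature table: %d windows (%d genes in, %s excluded), size %g bp\n",
              nrow(x$features), x$n_input,
              x$n_input - nrow(x$features), x$window_size))
  cat("  exclusion reasons:\n")
  for (nm in names(x$exclusions)) {
    cat(sprintf("    %-28s %d\n", nm, x$exclusions[[nm]]))
  }
  invisible(x)
}

#' Write / read a window feature table as TSV
#'
#' The file starts with a schema-version comment line plus the exclusion
#' counts, so results are self-describing and round-trip losslessly.
#'
#' @param x A `window_feature_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path) {
  stopifnot(inherits(x, "window_feature_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# mdrscan_feature_table v1",
               sprintf("# window_size=%g", x$window_size),
               sprintf("# n_input=%d", x$n_input),
               sprintf("# exclusion:%s=%d", names(x$exclusions),
                       x$exclusions)), con)
  utils::write.table(format(x$features, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "# mdrscan_feature_table")) {
    stop(path, " is not an mdrscan feature table (missing schema header)",
         call. = FALSE)
  }
  lines <- readLines(path)
  hl <- grep("^#", lines, value = TRUE)
  ex <- grep("^# exclusion:", hl, value = TRUE)
  exclusions <- stats::setNames(as.integer(sub(".*=", "", ex)),
                                sub("=.*", "", sub("^# exclusion:", "", ex)))
  ws <- as.numeric(sub(".*=", "", grep("^# window_size=", hl, value = TRUE)))
  ni <- as.integer(sub(".*=", "", grep("^# n_input=", hl, value = TRUE)))
  feat <- utils::read.table(path, header = TRUE, sep = "\t",
                            comment.char = "#", stringsAsFactors = FALSE)
  structure(list(features = feat, exclusions = exclusions, n_input = ni,
                 window_size = ws),
            class = "window_feature_table")
}
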
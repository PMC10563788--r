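# Toy genome: a small, fully seeded fixture (2 chromosomes x 5 Mb, ~55
# genes) written in the exact file dialects the readers consume, together
# with a companion ground-truth feature table computed by construction —
# brute-force, per-base code kept deliberately independent of the pipeline
# (naive loops and per-base occupancy vectors instead of interval algebra
# and vectorized interpolation) so the two can be compared end to end.

TOY_CHROM_LEN <- c(chr1 = 5e6, chr2 = 5e6)

#' Simulate a toy genome with known window features
#'
#' Writes a complete input set for the feature pipeline — FASTA sequence,
#' gene table, per-gene scalars, genetic map, coding/conserved/regulatory/gap
#' interval tracks and a hapbin-style iHS score table — plus a ground-truth
#' feature table computed by construction. Planted structure: chr1 has a
#' piecewise-uniform recombination map (2 cM/Mb then 0.5 cM/Mb), chr2 a
#' uniform 1.5 cM/Mb map with a map desert (no points for 300 kb) that makes
#' some windows lack a recombination rate; one window sits entirely inside
#' an assembly gap (density denominator 0); SNP frequencies span [0, 1]
#' including MAF <= 0.05 rows that the filter must drop.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed; the whole fixture is a deterministic function
#'   of it.
#' @param window_size Window size (bp) used for the ground-truth features.
#' @return A list: `paths` (named file paths), `ground_truth` (data.frame,
#'   one row per gene, NA where the pipeline should report missing),
#'   `chrom_lengths`, `window_size`, `seed`.
#' @export
simulate_toy_genome <- function(dir = tempfile("toygenome"), seed = 1L,
                                window_size = 50000) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lens <- TOY_CHROM_LEN
  with_seed(seed, {
    genes <- toy_genes(lens)
    scalars <- toy_scalars(genes)
    map <- toy_map_table(lens)
    seqs <- toy_sequences(lens)
    tracks <- toy_tracks(genes, lens, window_size)
    snps <- toy_snps(lens)

    paths <- c(
      genome = file.path(dir, "genome.fa"),
      genes = file.path(dir, "genes.tsv"),
      gene_scalars = file.path(dir, "gene_scalars.tsv"),
      map = file.path(dir, "map.tsv"),
      coding = file.path(dir, "coding.bed"),
      conserved = file.path(dir, "conserved.bed"),
      dnase = file.path(dir, "dnase.bed"),
      chip_all = file.path(dir, "chip_all.bed"),
      chip_testis = file.path(dir, "chip_testis.bed"),
      chip_immune = file.path(dir, "chip_immune.bed"),
      gaps = file.path(dir, "gaps.bed"),
      ihs = file.path(dir, "ihs.tsv"),
      ground_truth = file.path(dir, "ground_truth.tsv"))

    dna <- Biostrings::DNAStringSet(vapply(seqs, paste0, character(1),
                                           collapse = ""))
    names(dna) <- names(seqs)
    Biostrings::writeXStringSet(dna, paths["genome"])
    utils::write.table(genes[, c("chromosome", "start", "end", "gene_id")],
                       paths["genes"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(scalars, paths["gene_scalars"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    map_out <- map
    # 17 significant digits so the cumulative cM round-trip is bit exact
    map_out$cm <- format(map_out$cm, digits = 17, trim = TRUE,
                         scientific = FALSE)
    utils::write.table(map_out, paths["map"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_bed <- function(d, p) {
      cols <- if (is.null(d$score)) d[, c("chromosome", "start", "end")]
        else cbind(d[, c("chromosome", "start", "end")], name = ".",
                   score = d$score)
      utils::write.table(cols, p, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    }
    write_bed(tracks$coding, paths["coding"])
    write_bed(tracks$conserved, paths["conserved"])
    write_bed(tracks$dnase, paths["dnase"])
    write_bed(tracks$chip_all, paths["chip_all"])
    write_bed(tracks$chip_testis, paths["chip_testis"])
    write_bed(tracks$chip_immune, paths["chip_immune"])
    write_bed(tracks$gaps, paths["gaps"])
    utils::write.table(
      data.frame(chromosome = snps$chromosome, position = snps$position,
                 freq = snps$derived_allele_freq, raw_ihs = snps$raw_ihs),
      paths["ihs"], sep = "\t", quote = FALSE, row.names = FALSE)

    gt <- toy_ground_truth(genes, scalars, map, seqs, tracks, snps,
                           window_size, lens)
    utils::write.table(format(gt, digits = 17, trim = TRUE,
                              scientific = FALSE),
                       paths["ground_truth"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(paths = paths, ground_truth = gt, chrom_lengths = lens,
         window_size = window_size, seed = seed)
  })
}

toy_genes <- function(lens) {
  rows <- list()
  gi <- 0L
  for (ch in names(lens)) {
    starts <- seq(150000, lens[[ch]] - 400000, by = 180000)
    for (s in starts) {
      gi <- gi + 1L
      len <- sample(2000:40000, 1L)
      rows[[length(rows) + 1L]] <-
        data.frame(gene_id = sprintf("g%03d", gi), chromosome = ch,
                   start = s, end = s + len, stringsAsFactors = FALSE)
      if (gi %% 5L == 0L) {        # a close neighbor: overlapping windows,
        gi <- gi + 1L              # gene_number > 1
        rows[[length(rows) + 1L]] <-
          data.frame(gene_id = sprintf("g%03d", gi), chromosome = ch,
                     start = s + len + 5000, end = s + len + 5000 + 8000,
                     stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

toy_scalars <- function(genes) {
  n <- nrow(genes)
  data.frame(gene_id = genes$gene_id,
             tpm_mean = round(stats::rexp(n, 1 / 20), 3),
             tpm_testis = round(stats::rexp(n, 1 / 30), 3),
             tpm_immune = round(stats::rexp(n, 1 / 15), 3),
             ppi_count = stats::rpois(n, 4),
             is_vip = as.integer(stats::runif(n) < 0.15),
             stringsAsFactors = FALSE)
}

# piecewise-uniform maps; points every 10 kb, desert on chr2 at 3.0-3.3 Mb
toy_map_table <- function(lens) {
  seg_rate <- function(pos, ch) {
    if (ch == "chr1") ifelse(pos < 2.5e6, 2.0, 0.5) else 1.5
  }
  out <- list()
  for (ch in names(lens)) {
    pos <- seq(0, lens[[ch]], by = 10000)
    if (ch == "chr2") pos <- pos[pos < 3.0e6 | pos > 3.3e6]
    rate <- seg_rate(pos, ch)
    cm <- cumsum(c(0, diff(pos) * seg_rate(pos[-length(pos)], ch) / 1e6))
    out[[ch]] <- data.frame(chromosome = ch, position = pos, cm = cm,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

toy_sequences <- function(lens) {
  seqs <- lapply(names(lens), function(ch) {
    s <- sample(c("A", "C", "G", "T"), lens[[ch]], replace = TRUE,
                prob = c(0.3, 0.2, 0.2, 0.3))
    s
  })
  names(seqs) <- names(lens)
  # N-runs so the GC denominator exclusion is exercised
  seqs$chr1[500001:505000] <- "N"
  seqs
}

# disjoint scored tracks (grid placement); coding may overlap itself to
# exercise merging; one gap swallows gene g003's window entirely
toy_tracks <- function(genes, lens, window_size) {
  place <- function(ch, n, wmin, wmax, scores = NULL) {
    slots <- seq(10000, lens[[ch]] - wmax - 10000, length.out = n)
    start <- floor(slots + stats::runif(n, 0, 4000))
    width <- sample(wmin:wmax, n, replace = TRUE)
    d <- data.frame(chromosome = ch, start = start, end = start + width,
                    stringsAsFactors = FALSE)
    if (!is.null(scores)) d$score <- scores
    d
  }
  both <- function(n, wmin, wmax, scored = FALSE) {
    do.call(rbind, lapply(names(lens), function(ch) {
      sc <- if (scored) sample(1:10, n, replace = TRUE) else NULL
      place(ch, n, wmin, wmax, sc)
    }))
  }
  coding <- both(260, 200, 2000)
  # overlapping pair: merged, not double-counted
  coding <- rbind(coding,
                  data.frame(chromosome = "chr1", start = 160000, end = 161000,
                             stringsAsFactors = FALSE),
                  data.frame(chromosome = "chr1", start = 160500, end = 161600,
                             stringsAsFactors = FALSE))
  g3 <- genes[genes$gene_id == "g003", ]
  c3 <- floor((g3$start + g3$end) / 2)
  gaps <- rbind(
    data.frame(chromosome = "chr1", start = c3 - window_size / 2 - 5000,
               end = c3 + window_size / 2 + 5000, stringsAsFactors = FALSE),
    data.frame(chromosome = "chr2", start = 1.2e6, end = 1.23e6,
               stringsAsFactors = FALSE))
  chip_all <- both(220, 300, 1500, scored = TRUE)
  idx <- sample(nrow(chip_all))
  list(coding = coding,
       conserved = both(200, 100, 1200, scored = TRUE),
       dnase = both(200, 200, 1000, scored = TRUE),
       chip_all = chip_all,
       chip_testis = chip_all[sort(idx[1:70]), ],
       chip_immune = chip_all[sort(idx[71:140]), ],
       gaps = gaps)
}

toy_snps <- function(lens) {
  out <- lapply(names(lens), function(ch) {
    n <- 4000L
    pos <- sort(sample.int(lens[[ch]], n))
    freq <- round(stats::runif(n), 4)
    # raw iHS location/scale depend on frequency, so bin standardization
    # actually changes values
    raw <- round(0.8 * sin(freq * pi) +
                   stats::rnorm(n, sd = 0.6 + 0.8 * freq), 4)
    data.frame(chromosome = ch, position = pos, derived_allele_freq = freq,
               raw_ihs = raw, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

## ---- construction-time ground truth (brute force, per base) --------------

# naive O(n) interpolation scan over map rows of one chromosome
bf_genetic_position <- function(mp, pos, max_search) {
  p <- mp$position
  cm <- mp$cm
  for (j in seq_along(p)) if (p[j] == pos) return(cm[j])
  lo <- NA_integer_
  hi <- NA_integer_
  for (j in seq_along(p)) {
    if (p[j] < pos) lo <- j
    if (p[j] > pos) { hi <- j; break }
  }
  if (is.na(lo) || is.na(hi)) return(NA_real_)
  if ((pos - p[lo]) > max_search || (p[hi] - pos) > max_search) {
    return(NA_real_)
  }
  cm[lo] + (pos - p[lo]) / (p[hi] - p[lo]) * (cm[hi] - cm[lo])
}

# per-base occupancy of [start, end) intervals over a window
bf_occupancy <- function(iv, wstart, wend) {
  occ <- logical(wend - wstart)
  for (j in seq_len(nrow(iv))) {
    a <- max(iv$start[j], wstart)
    b <- min(iv$end[j], wend)
    if (a < b) occ[(a - wstart + 1):(b - wstart)] <- TRUE
  }
  occ
}

# sort-and-accumulate threshold oracle on disjoint scored intervals
bf_score_threshold <- function(track, genome_length, target) {
  sc <- sort(unique(track$score), decreasing = TRUE)
  tot <- 0
  best <- Inf
  for (t in sc) {
    tot <- tot + sum(track$end[track$score == t] -
                       track$start[track$score == t])
    if (tot <= target * genome_length) best <- t else break
  }
  best
}

toy_ground_truth <- function(genes, scalars, map, seqs, tracks, snps,
                             window_size, lens) {
  half <- window_size / 2
  n <- nrow(genes)
  genome_length <- sum(lens)

  # iHS: MAF filter, 50-bin stats, standardization — all by naive loops
  maf <- pmin(snps$derived_allele_freq, 1 - snps$derived_allele_freq)
  kept <- snps[maf > 0.05 + 1e-9, ]      # decimal-threshold guard
  bin <- integer(nrow(kept))
  for (j in seq_len(nrow(kept))) {
    b <- floor(kept$derived_allele_freq[j] * 50 + 1e-9)
    if (b > 49) b <- 49
    bin[j] <- b
  }
  z <- rep(NA_real_, nrow(kept))
  for (b in unique(bin)) {
    v <- kept$raw_ihs[bin == b]
    if (length(v) >= 2 && stats::sd(v) > 0) {
      z[bin == b] <- (v - mean(v)) / stats::sd(v)
    }
  }
  kept <- kept[!is.na(z), ]
  z <- z[!is.na(z)]

  # thresholded regulatory/conserved subsets via the accumulate oracle
  thr <- list(conserved = bf_score_threshold(tracks$conserved, genome_length,
                                             0.0417),
              dnase = bf_score_threshold(tracks$dnase, genome_length, 0.10),
              chip = bf_score_threshold(tracks$chip_all, genome_length, 0.10))
  dens_tracks <- list(
    coding = tracks$coding,
    conserved = tracks$conserved[tracks$conserved$score >= thr$conserved, ],
    dnase = tracks$dnase[tracks$dnase$score >= thr$dnase, ],
    chip = tracks$chip_all[tracks$chip_all$score >= thr$chip, ],
    chip_testis = tracks$chip_testis[tracks$chip_testis$score >= thr$chip, ],
    chip_immune = tracks$chip_immune[tracks$chip_immune$score >= thr$chip, ])

  out <- data.frame(gene_id = genes$gene_id, stringsAsFactors = FALSE)
  out$gene_length <- genes$end - genes$start
  out$expression_mean <- log2(scalars$tpm_mean + 1)
  out$expression_testis <- log2(scalars$tpm_testis + 1)
  out$expression_immune <- log2(scalars$tpm_immune + 1)
  out$log2_ppi <- log2(scalars$ppi_count + 1)

  for (cl in c("gene_number", "recomb_rate", "gc_content", "vip_distance",
               "mean_abs_ihs")) out[[cl]] <- NA_real_
  out$n_ihs <- NA_integer_
  for (nm in names(dens_tracks)) out[[paste0(nm, "_density")]] <- NA_real_

  for (i in seq_len(n)) {
    ch <- genes$chromosome[i]
    center <- floor((genes$start[i] + genes$end[i]) / 2)
    ws <- center - half
    we <- center + half
    mp <- map[map$chromosome == ch, ]
    seqv <- seqs[[ch]]

    cnt <- 0L
    for (j in seq_len(n)) {
      if (genes$chromosome[j] == ch && genes$start[j] < we &&
            genes$end[j] > ws) cnt <- cnt + 1L
    }
    out$gene_number[i] <- cnt

    cm_s <- bf_genetic_position(mp, ws, 50000)
    cm_e <- bf_genetic_position(mp, we, 50000)
    out$recomb_rate[i] <- (cm_e - cm_s) / ((we - ws) / 1e6)

    gocc <- bf_occupancy(tracks$gaps[tracks$gaps$chromosome == ch, ], ws, we)
    for (nm in names(dens_tracks)) {
      tocc <- bf_occupancy(
        dens_tracks[[nm]][dens_tracks[[nm]]$chromosome == ch, ], ws, we)
      denom <- sum(!gocc)
      out[[paste0(nm, "_density")]][i] <-
        if (denom > 0) sum(tocc & !gocc) / denom else NA_real_
    }

    bases <- table(factor(seqv[(ws + 1):we],
                          levels = c("A", "C", "G", "T", "N")))
    acgt <- sum(bases[c("A", "C", "G", "T")])
    out$gc_content[i] <- if (acgt > 0) {
      sum(bases[c("G", "C")]) / acgt
    } else NA_real_

    vd <- Inf
    for (j in seq_len(n)) {
      if (genes$chromosome[j] != ch || !scalars$is_vip[j]) next
      if (j == i) { vd <- 0; break }
      g <- max(0, genes$start[j] - genes$end[i], genes$start[i] - genes$end[j])
      if (g < vd) vd <- g
    }
    if (scalars$is_vip[i]) vd <- 0
    out$vip_distance[i] <- if (is.finite(vd)) vd else NA_real_

    sel <- kept$chromosome == ch & kept$position >= ws & kept$position < we
    if (sum(sel) > 0) {
      out$mean_abs_ihs[i] <- mean(abs(z[sel]))
      out$n_ihs[i] <- sum(sel)
    }
  }
  out
}
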
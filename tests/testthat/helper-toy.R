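# the toy genome takes a few seconds to build; memoize one instance for the
# whole suite (seed fixed: the fixture is deterministic)
.toy_cache <- new.env(parent = emptyenv())

get_toy <- function() {
  if (is.null(.toy_cache$toy)) {
    .toy_cache$toy <- simulate_toy_genome(
      dir = file.path(tempdir(), "mdrscan-toy"), seed = 42)
  }
  .toy_cache$toy
}

# run the full feature pipeline over the toy genome files, as a user would
toy_pipeline_features <- function(toy, non_overlapping = FALSE) {
  genes <- read_gene_table(toy$paths[["genes"]])
  scalars <- read_gene_scalars(toy$paths[["gene_scalars"]])
  map <- read_genetic_map(toy$paths[["map"]])
  snp_raw <- read_ihs_scores(toy$paths[["ihs"]])
  gaps <- read_bed(toy$paths[["gaps"]])
  seqs <- Biostrings::readDNAStringSet(toy$paths[["genome"]])
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  G <- sum(Biostrings::width(seqs))
  suppressMessages({
    thr_cons <- score_threshold_for_fraction(
      read_bed(toy$paths[["conserved"]]), G, 0.0417)$threshold
    thr_dnase <- score_threshold_for_fraction(
      read_bed(toy$paths[["dnase"]]), G, 0.10)$threshold
    thr_chip <- score_threshold_for_fraction(
      read_bed(toy$paths[["chip_all"]]), G, 0.10)$threshold
  })
  tracks <- list(
    coding = read_bed(toy$paths[["coding"]]),
    conserved = apply_score_threshold(read_bed(toy$paths[["conserved"]]),
                                      thr_cons),
    dnase = apply_score_threshold(read_bed(toy$paths[["dnase"]]), thr_dnase),
    chip = apply_score_threshold(read_bed(toy$paths[["chip_all"]]), thr_chip),
    chip_testis = apply_score_threshold(read_bed(toy$paths[["chip_testis"]]),
                                        thr_chip),
    chip_immune = apply_score_threshold(read_bed(toy$paths[["chip_immune"]]),
                                        thr_chip))
  snps <- standardize_ihs(filter_maf(snp_raw))$snps
  assemble_feature_table(
    genes, scalars, map, snps, toy$window_size,
    density_tracks = tracks, gaps = gaps, sequences = seqs,
    chrom_lengths = stats::setNames(Biostrings::width(seqs), names(seqs)),
    non_overlapping = non_overlapping)
}
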
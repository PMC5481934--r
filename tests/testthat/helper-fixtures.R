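# In-code fixtures shared across test files.

mk_genome <- function(lengths = c(chr1 = 50000L, chr2 = 30000L)) {
  genome_assembly(names(lengths), lengths)
}

mk_peaks <- function(..., organ = "hypothalamus", replicate = "rep1",
                     genome = NULL) {
  df <- data.frame(matrix(c(...), ncol = 3, byrow = TRUE))
  names(df) <- c("chrom_i", "start", "end")
  df$chrom <- paste0("chr", df$chrom_i)
  peak_set(df[, c("chrom", "start", "end")], organ, replicate, genome)
}

# single-chromosome annotation: one + strand gene with two exons and one
# - strand single-exon gene, comfortably separated
mk_annotation <- function(genome = mk_genome()) {
  gene_annotation(
    genes = data.frame(
      gene_id = c("gA", "gB"),
      chrom = "chr1",
      strand = c("+", "-"),
      start = c(20000L, 40000L),
      end = c(23000L, 42000L)
    ),
    exons = data.frame(
      gene_id = c("gA", "gA"),
      chrom = "chr1",
      start = c(20000L, 22000L),
      end = c(21000L, 23000L)
    ),
    genome = genome
  )
}

# constant-depth track over every chromosome
mk_flat_track <- function(genome, depth = 1) {
  lens <- chrom_lengths(genome)
  out <- lapply(lens, function(l) S4Vectors::Rle(depth, l))
  names(out) <- names(lens)
  out
}

# depth track from (chrom, start, end, score) rows, zero elsewhere
mk_track <- function(genome, regions) {
  lens <- chrom_lengths(genome)
  out <- lapply(names(lens), function(chrom) {
    d <- regions[regions$chrom == chrom, , drop = FALSE]
    IRanges::coverage(
      IRanges::IRanges(d$start + 1L, d$end),
      width = lens[[chrom]],
      weight = if (nrow(d)) d$score else numeric(0)
    )
  })
  names(out) <- names(lens)
  out
}

# run the full differential-methylation path on a generated dataset
run_dmr_recovery <- function(cfg) {
  gen <- generate_genome(cfg)
  ann <- generate_annotation(cfg, gen$genome)
  meth <- generate_methylation(cfg, gen$genome, ann)
  samples <- meth$samples
  regions <- candidate_regions(lapply(samples, `[[`, "peaks"))
  mat <- depth_matrix(regions, lapply(samples, `[[`, "track"), gen$genome)
  dmrs <- call_dmrs(regions, mat,
    groups = vapply(samples, `[[`, "", "organ")
  )
  dmgs <- dmrs_to_dmgs(dmrs, ann)
  list(
    genome = gen$genome, annotation = ann, meth = meth,
    dmrs = dmrs, dmgs = dmgs,
    called_genes = unique(dmgs$genes$gene_id),
    planted_genes = meth$truth$dmrs$gene_id
  )
}

# integration-scale configuration (coordinate-only genome, ~200
# hypo-methylated genes in a 5000-gene universe)
integration_cfg <- function(seed, coupling = 0.6) {
  synthetic_config(
    seed = seed, emit_sequence = FALSE,
    n_chromosomes = 4L, chrom_length = 1.2e7, n_genes = 5000L,
    n_peak_regions = 2000L, n_dmrs = 400L, n_degs = 1000L,
    coupling_fraction = coupling
  )
}

# tiny full dataset for io/pipeline tests
small_cfg <- function(seed = 1) {
  synthetic_config(
    seed = seed, n_chromosomes = 2L, chrom_length = 60000L,
    n_genes = 12L, n_cgis = 2L, cgi_length = 1000L,
    n_peak_regions = 40L, n_dmrs = 4L, n_degs = 6L
  )
}
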
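# Geometry of mk_annotation(): gene gA on chr1 [20000, 23000) on +, exons
# [20000, 21000) and [22000, 23000); gene gB on chr1 [40000, 42000) on -,
# single exon. chr2 is gene-free.

test_that("categorize_bases partitions peak bases by category priority", {
  genome <- mk_genome()
  ann <- mk_annotation()
  cats <- c("promoter", "exon", "intron", "downstream", "distal", "intergenic")

  # gene-free chromosome: everything intergenic
  cb <- categorize_bases(mk_peaks(2, 100, 600), ann, genome)
  expect_equal(cb$intergenic, 500L)
  expect_equal(sum(cb[, cats]), 500L)

  # fully inside the 2 kb upstream flank of the + strand gene
  cb <- categorize_bases(mk_peaks(1, 18500, 18600), ann, genome)
  expect_equal(cb$promoter, 100L)

  # straddles the exon/intron boundary 120 bp into the first exon
  cb <- categorize_bases(mk_peaks(1, 20880, 21080), ann, genome)
  expect_equal(cb$exon, 120L)
  expect_equal(cb$intron, 80L)

  # - strand gene: promoter flank sits to the right of the body
  cb <- categorize_bases(mk_peaks(1, 42000, 42100), ann, genome)
  expect_equal(cb$promoter, 100L)
  cb <- categorize_bases(mk_peaks(1, 39900, 40000), ann, genome)
  expect_equal(cb$downstream, 100L)
})

test_that("category base counts always sum to peak length", {
  genome <- mk_genome()
  ann <- mk_annotation()
  cats <- c("promoter", "exon", "intron", "downstream", "distal", "intergenic")
  set.seed(41)
  starts <- sort(sample(0:25000, 40))
  peaks <- data.frame(
    chrom = sample(c("chr1", "chr2"), 40, TRUE),
    start = starts, end = starts + sample(50:900, 40, TRUE)
  )
  cb <- categorize_bases(peaks, ann, genome)
  expect_equal(rowSums(cb[, cats]), peaks$end - peaks$start,
    ignore_attr = TRUE
  )
})

test_that("region_density follows the published normalization formula", {
  genome <- mk_genome()
  # one gene, two exons of 100 and 200 bp -> mean exon length 150
  ann <- gene_annotation(
    data.frame(
      gene_id = "g", chrom = "chr1", strand = "+",
      start = 20000L, end = 21000L
    ),
    data.frame(
      gene_id = "g", chrom = "chr1",
      start = c(20000L, 20500L), end = c(20100L, 20700L)
    ),
    genome
  )
  # 2 peaks totalling 300 bp inside exons
  ps <- mk_peaks(1, 20000, 20100, 1, 20500, 20700)
  d <- region_density(list(ps), ann, genome)
  expect_equal(d$density[d$category == "exon"], 300 / 150 / 2)
  # doubling total peaks with intergenic ones halves the exon density
  ps2 <- mk_peaks(2, 0, 50, 2, 100, 150, organ = "hypothalamus")
  d2 <- region_density(list(ps, ps2), ann, genome)
  expect_equal(d2$density[d2$category == "exon"], 300 / 150 / 4)
  # a category is 0 iff no peak base falls in it
  expect_equal(d$density[d$category == "intron"], 0)
  expect_gt(d2$density[d2$category == "intergenic"], 0)
})

test_that("zero peaks give zero densities, absent categories give NA", {
  genome <- mk_genome()
  ann <- mk_annotation()
  empty <- peak_set(
    data.frame(chrom = character(), start = integer(), end = integer()),
    "o", "r"
  )
  d <- region_density(list(empty), ann, genome)
  expect_true(all(d$density[!is.na(d$density)] == 0))
  # annotation with only single-exon genes has no introns
  ann1 <- gene_annotation(
    data.frame(
      gene_id = "g", chrom = "chr1", strand = "+",
      start = 20000L, end = 21000L
    ),
    genome = genome
  )
  d1 <- region_density(list(empty), ann1, genome)
  expect_true(is.na(d1$density[d1$category == "intron"]))
})

test_that("chromosome_density applies the per-Mbp, per-total, x10k scaling", {
  g1 <- genome_assembly("chr1", 1e6)
  ps <- peak_set(
    data.frame(chrom = "chr1", start = seq(0, 900, 100), end = seq(50, 950, 100)),
    "o", "r1", g1
  )
  d <- chromosome_density(list(ps), g1)
  expect_equal(d$ratio, 10000)

  g2 <- genome_assembly(c("chrA", "chrB"), c(1e7, 5e6))
  mk <- function(nA, nB) {
    peak_set(
      data.frame(
        chrom = rep(c("chrA", "chrB"), c(nA, nB)),
        start = c(seq_len(nA), seq_len(nB)) * 10L,
        end = c(seq_len(nA), seq_len(nB)) * 10L + 5L
      ),
      "o", "r1", g2
    )
  }
  d <- chromosome_density(list(mk(100, 900)), g2)
  expect_equal(d$ratio[d$chrom == "chrA"], 100 / 10 / 1000 * 1e4)
  # scale invariance: doubling every count leaves ratios unchanged
  d2 <- chromosome_density(list(mk(200, 1800)), g2)
  expect_equal(d$ratio, d2$ratio)
})

test_that("chromosome density comparison recovers a planted organ shift", {
  set.seed(42)
  lens <- stats::setNames(rep(2e6, 6), paste0("chr", 1:6))
  genome <- genome_assembly(names(lens), lens)
  mk_org <- function(organ, chr1_n) {
    lapply(1:3, function(r) {
      counts <- round(c(chr1_n, rep(100, 5)) * stats::runif(6, 0.95, 1.05))
      rows <- do.call(rbind, lapply(seq_along(lens), function(ci) {
        s <- sort(sample(seq(0, 1.9e6, 20), counts[ci]))
        data.frame(chrom = names(lens)[ci], start = s, end = s + 10)
      }))
      peak_set(rows, organ, paste0("rep", r), genome)
    })
  }
  a <- mk_org("hypothalamus", 100)
  b <- mk_org("ovary", 300)
  res <- compare_chromosome_density(a, b, genome)
  expect_lt(res$fdr[res$chrom == "chr1"], 0.05)
  expect_equal(res$direction[res$chrom == "chr1"], "ovary")
  # identical inputs: nothing significant, p = 1 under zero variance
  res0 <- compare_chromosome_density(a, a, genome)
  expect_true(all(res0$p > 0.05))
  expect_true(all(is.na(res0$direction)))
})

test_that("metagene profile is flat under uniform depth", {
  genome <- mk_genome()
  ann <- mk_annotation()
  prof <- metagene_profile(mk_flat_track(genome, 3.5), ann, genome)
  expect_length(prof$values, 80)
  expect_equal(prof$values, rep(3.5, 80))
  expect_equal(prof$n_genes, 2L)
  # scale_factor divides through
  prof2 <- metagene_profile(mk_flat_track(genome, 3.5), ann, genome,
    scale_factor = 7
  )
  expect_equal(prof2$values, rep(0.5, 80))
})

test_that("metagene reproduces a body-only step function", {
  genome <- mk_genome()
  ann <- gene_annotation(
    data.frame(
      gene_id = "g", chrom = "chr1", strand = "+",
      start = 20000L, end = 24000L
    ),
    genome = genome
  )
  track <- mk_track(
    genome,
    data.frame(chrom = "chr1", start = 20000L, end = 24000L, score = 2)
  )
  prof <- metagene_profile(track, ann, genome)
  expect_equal(prof$values, rep(c(0, 2, 0), c(20, 40, 20)))
})

test_that("metagene commutes with strand flip", {
  len <- 30000L
  genome <- genome_assembly("chr1", len)
  set.seed(43)
  regions <- data.frame(
    chrom = "chr1",
    start = seq(0L, 29000L, 500L),
    end = seq(0L, 29000L, 500L) + sample(100:400, 59, TRUE),
    score = stats::runif(59, 0, 5)
  )
  track <- mk_track(genome, regions)
  mirror <- data.frame(
    chrom = "chr1",
    start = len - regions$end, end = len - regions$start,
    score = regions$score
  )
  mtrack <- mk_track(genome, mirror)
  ann_fw <- gene_annotation(
    data.frame(
      gene_id = "g", chrom = "chr1", strand = "+",
      start = 12000L, end = 17000L
    ),
    genome = genome
  )
  ann_rv <- gene_annotation(
    data.frame(
      gene_id = "g", chrom = "chr1", strand = "-",
      start = len - 17000L, end = len - 12000L
    ),
    genome = genome
  )
  expect_equal(
    metagene_profile(track, ann_fw, genome)$values,
    metagene_profile(mtrack, ann_rv, genome)$values
  )
})

test_that("metagene excludes short gene bodies and clips flanks", {
  genome <- mk_genome()
  ann <- gene_annotation(
    data.frame(
      gene_id = c("tiny", "edge"), chrom = "chr1", strand = "+",
      start = c(100L, 500L), end = c(130L, 5000L)
    ),
    genome = genome
  )
  prof <- metagene_profile(mk_flat_track(genome, 1), ann, genome)
  expect_equal(prof$n_genes, 1L) # 30 bp body cannot form 40 windows
  # upstream flank of "edge" runs off the chromosome: in-bounds windows
  # still average 1, fully out-of-bounds windows are undefined
  vals <- prof$values
  expect_true(all(vals[!is.nan(vals)] == 1))
  ann_tiny <- gene_annotation(
    data.frame(
      gene_id = "tiny", chrom = "chr1", strand = "+",
      start = 100L, end = 130L
    ),
    genome = genome
  )
  expect_error(
    metagene_profile(mk_flat_track(genome, 1), ann_tiny, genome),
    "40 body windows"
  )
})
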
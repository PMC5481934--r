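test_that("candidate_regions union-merges peaks, including book-ends", {
  single <- mk_peaks(1, 10, 100)
  expect_equal(candidate_regions(list(single))$start, 10L)
  merged <- candidate_regions(list(
    mk_peaks(1, 0, 100, 1, 150, 200),
    mk_peaks(1, 50, 150, organ = "ovary")
  ))
  expect_equal(nrow(merged), 1L)
  expect_equal(c(merged$start, merged$end), c(0L, 200L))
  disjoint <- candidate_regions(list(mk_peaks(1, 0, 10, 1, 20, 30)))
  expect_equal(nrow(disjoint), 2L)
  empty <- peak_set(
    data.frame(chrom = character(), start = integer(), end = integer()),
    "o", "r"
  )
  expect_error(candidate_regions(list(empty)), "no peaks")
})

test_that("depth_matrix averages per base and normalizes per million", {
  # chr2 filler brings the library total to exactly 1e6 so the normalized
  # entry matches the unnormalized mean
  genome <- genome_assembly(c("chr1", "chr2"), c(1000L, 1000000L))
  track <- mk_track(genome, data.frame(
    chrom = c("chr1", "chr2"),
    start = c(0L, 0L), end = c(50L, 999800L),
    score = c(4, 1)
  ))
  regions <- data.frame(chrom = "chr1", start = 0L, end = 100L)
  expect_equal(total_signal(track), 1e6)
  m <- depth_matrix(regions, list(s1 = track), genome)
  expect_equal(m[1, 1], 2)
  expect_equal(
    depth_matrix(regions, list(s1 = track), genome, normalize = FALSE)[1, 1],
    2
  )
  # all-zero sample stays zero
  zero <- mk_flat_track(genome, 0)
  expect_equal(depth_matrix(regions, list(z = zero), genome)[1, 1], 0)
  # doubling depth everywhere leaves the normalized column unchanged
  track2 <- lapply(track, function(r) r * 2)
  expect_equal(
    depth_matrix(regions, list(s1 = track2), genome)[1, 1],
    m[1, 1]
  )
})

test_that("call_dmrs tests regions and adjusts with Benjamini-Hochberg", {
  set.seed(61)
  n <- 50L
  regions <- data.frame(
    chrom = "chr1", start = seq_len(n) * 100L,
    end = seq_len(n) * 100L + 50L
  )
  mat <- matrix(stats::rlnorm(n * 6, log(10), 0.3), n, 6)
  groups <- rep(c("hpt", "ov"), each = 3)
  # identical group matrices -> no DMR, p = 1 on every row
  same <- call_dmrs(regions, cbind(mat[, 1:3], mat[, 1:3]), groups)
  expect_equal(sum(same$significant), 0L)
  expect_true(all(same$p == 1))
  res <- call_dmrs(regions, mat, groups)
  expect_equal(res$fdr, naive_bh(res$p))
  # swapping group labels flips direction and t, keeps p bit-identical
  flipped <- call_dmrs(regions, mat[, c(4:6, 1:3)],
    groups = rep(c("hpt", "ov"), each = 3)
  )
  expect_identical(res$p, flipped$p)
  expect_equal(res$t, -flipped$t)
  swap <- c(hpt = "ov", ov = "hpt")
  expect_equal(unname(swap[res$direction]), flipped$direction)
})

test_that("call_dmrs recovers a planted depth shift with correct direction", {
  set.seed(62)
  n <- 200L
  planted <- 1:5
  regions <- data.frame(
    chrom = "chr1", start = seq_len(n) * 1000L,
    end = seq_len(n) * 1000L + 500L
  )
  mat <- matrix(stats::rlnorm(n * 6, log(10), 0.2), n, 6)
  mat[planted, 1:3] <- mat[planted, 1:3] * 10
  res <- call_dmrs(regions, mat, rep(c("hpt", "ov"), each = 3))
  # every planted region is called; false calls stay within the FDR budget
  expect_true(all(planted %in% which(res$significant)))
  expect_lte(sum(res$significant) - length(planted), 2L)
  expect_true(all(res$direction[planted] == "hpt"))
})

test_that("matching t statistics come from the classic Student formula", {
  a <- matrix(c(1, 2, 3), 1)
  b <- matrix(c(2, 3, 4), 1)
  tt <- row_t_test(a, b)
  expect_equal(round(tt$t, 4), -1.2247)
  expect_equal(tt$df, 4)
  expect_equal(tt$p, stats::t.test(a, b, var.equal = TRUE)$p.value)
  expect_equal(round(tt$p, 3), 0.288)
  # against stats::t.test on random rows, both pooled and Welch
  set.seed(63)
  for (i in 1:10) {
    x <- matrix(stats::rnorm(8), 1)
    y <- matrix(stats::rnorm(12, 0.5), 1)
    ref <- stats::t.test(x, y, var.equal = TRUE)
    got <- row_t_test(x, y)
    expect_equal(got$t, unname(ref$statistic))
    expect_equal(got$p, ref$p.value)
    refw <- stats::t.test(x, y)
    gotw <- row_t_test(x, y, var_equal = FALSE)
    expect_equal(gotw$t, unname(refw$statistic))
    expect_equal(gotw$df, unname(refw$parameter))
    expect_equal(gotw$p, refw$p.value)
  }
  # zero variance, equal means -> p = 1; unequal means -> p = 0
  cons <- row_t_test(matrix(1, 2, 3), matrix(c(1, 2), 2, 3))
  expect_equal(cons$p, c(1, 0))
})

test_that("dmrs_to_dmgs aggregates by gene-body overlap with majority rule", {
  genome <- mk_genome()
  ann <- mk_annotation() # gA [20000,23000), gB [40000,42000)
  dmr <- function(start, end, dir) {
    data.frame(
      chrom = "chr1", start = start, end = end,
      direction = dir, significant = TRUE, stringsAsFactors = FALSE
    )
  }
  # intergenic DMR contributes nothing
  res <- dmrs_to_dmgs(dmr(1000L, 1200L, "hpt"), ann)
  expect_equal(nrow(res$genes), 0L)
  expect_equal(res$counts[["unique_total"]], 0L)
  # two same-direction DMRs in one gene -> one DMG with 2 supports
  res <- dmrs_to_dmgs(
    rbind(dmr(20100L, 20200L, "hpt"), dmr(22000L, 22100L, "hpt")), ann
  )
  expect_equal(res$genes$gene_id, "gA")
  expect_equal(res$genes$n_support, 2L)
  expect_equal(res$in_body_dmrs, 2L)
  # 1 bp of overlap is enough; majority sets the direction
  res <- dmrs_to_dmgs(
    rbind(
      dmr(19000L, 20001L, "hpt"), dmr(20100L, 20200L, "hpt"),
      dmr(22000L, 22100L, "ov"),
      dmr(41000L, 41100L, "ov")
    ), ann
  )
  gA <- res$genes[res$genes$gene_id == "gA", ]
  expect_equal(gA$direction, "hpt")
  expect_equal(gA$n_support, 3L)
  expect_equal(res$counts[["ov"]], 1L)
  # opposing tie -> listed in both directions, counted as shared
  res <- dmrs_to_dmgs(
    rbind(dmr(20100L, 20200L, "hpt"), dmr(22000L, 22100L, "ov")), ann
  )
  expect_equal(sort(res$genes$direction), c("hpt", "ov"))
  expect_equal(res$counts[["shared"]], 1L)
  expect_equal(res$counts[["unique_total"]], 1L)
})

test_that("directional gene accounting obeys inclusion-exclusion", {
  expect_equal(union_gene_count(1264, 456, 74), 1646)
  expect_error(union_gene_count(10, 5, 6), "n_shared")
  set.seed(64)
  for (i in 1:10) {
    a <- sample(letters, sample(5:20, 1))
    b <- sample(letters, sample(5:20, 1))
    expect_equal(
      union_gene_count(length(a), length(b), length(intersect(a, b))),
      length(union(a, b))
    )
  }
})
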
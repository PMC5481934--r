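# Methylation calls on CpG islands: an island counts as methylated in a
# sample when at least 90% of its length is covered by the union of the
# sample's peaks (bedtools-intersect -f semantics with the island as
# query), and methylated in an organ by a replicate-consensus rule.

#' Fraction of an island covered by peaks
#'
#' bp of each island covered by the *union* of a sample's peaks, divided by
#' island length. Overlapping peaks are not double counted.
#'
#' @param islands data.frame of intervals (`chrom`, `start`, `end`, 0-based
#'   half-open), e.g. from [scan_cgis()].
#' @param peakset A `PeakSet`.
#' @return Numeric vector of fractions in `[0, 1]`, one per island row.
#' @export
covered_fraction <- function(islands, peakset) {
  stopifnot(inherits(peakset, "PeakSet"))
  islands <- as.data.frame(islands)
  .validate_intervals(islands, what = "island")
  out <- numeric(nrow(islands))
  if (nrow(islands) == 0L || nrow(peakset$peaks) == 0L) {
    return(out)
  }
  by_chrom <- split(seq_len(nrow(islands)), islands$chrom)
  for (chrom in names(by_chrom)) {
    idx <- by_chrom[[chrom]]
    isl <- .as_iranges(islands$start[idx], islands$end[idx])
    pk <- peakset$peaks[peakset$peaks$chrom == chrom, , drop = FALSE]
    if (nrow(pk) == 0L) next
    cov <- IRanges::reduce(.as_iranges(pk$start, pk$end))
    ov <- IRanges::findOverlaps(isl, cov)
    if (length(ov) == 0L) next
    pint <- IRanges::pintersect(
      isl[S4Vectors::queryHits(ov)], cov[S4Vectors::subjectHits(ov)]
    )
    bp <- tapply(IRanges::width(pint), S4Vectors::queryHits(ov), sum)
    out[idx[as.integer(names(bp))]] <- as.numeric(bp) /
      IRanges::width(isl)[as.integer(names(bp))]
  }
  out
}

#' Call CpG islands methylated in one organ
#'
#' Per-sample call: covered fraction >= `threshold` (inclusive). Organ
#' call: consensus over replicates -- `"majority"` (default; methylated in
#' at least half of the replicates), `"any"`, or `"all"`.
#'
#' @param cgis data.frame of islands (from [scan_cgis()] or equivalent).
#' @param peaksets List of `PeakSet` of one organ (>= 1 sample).
#' @param threshold Minimum covered fraction, default 0.9.
#' @param rule Replicate-consensus rule.
#' @return List of class `CgiMethylation`: `islands` (the input plus
#'   `methylated` organ call), `fractions` and `calls` (island x replicate
#'   matrices), `organ`, `threshold`, `rule`.
#' @export
call_methylated <- function(cgis, peaksets, threshold = 0.9,
                            rule = c("majority", "any", "all")) {
  rule <- match.arg(rule)
  .check_peaksets(peaksets)
  cgis <- as.data.frame(cgis)
  reps <- vapply(peaksets, `[[`, "", "replicate")
  fr <- vapply(peaksets, function(ps) covered_fraction(cgis, ps),
    numeric(nrow(cgis))
  )
  fr <- matrix(fr, nrow = nrow(cgis), dimnames = list(NULL, reps))
  calls <- fr >= threshold
  n <- length(peaksets)
  organ_call <- switch(rule,
    majority = rowSums(calls) >= n / 2,
    any = rowSums(calls) >= 1L,
    all = rowSums(calls) == n
  )
  islands <- cgis
  islands$methylated <- as.logical(organ_call)
  structure(
    list(
      islands = islands, fractions = fr, calls = calls,
      organ = peaksets[[1]]$organ, threshold = threshold, rule = rule
    ),
    class = "CgiMethylation"
  )
}

#' @export
print.CgiMethylation <- function(x, ...) {
  cat(sprintf(
    "CgiMethylation (%s): %d/%d islands methylated (threshold %.2f, %s rule)\n",
    x$organ, sum(x$islands$methylated), nrow(x$islands), x$threshold, x$rule
  ))
  invisible(x)
}

#' Percentage helper for methylation rates
#'
#' `100 * n_methylated / n_total`, validated. Exposed so summary
#' percentages can be recomputed from published or tabulated counts.
#'
#' @param n_methylated,n_total Non-negative counts, `n_total > 0`,
#'   `n_methylated <= n_total`.
#' @return Percentage in `[0, 100]`.
#' @examples
#' methylation_percentage(32952, 71367) # 46.17...
#' @export
methylation_percentage <- function(n_methylated, n_total) {
  if (any(n_total <= 0)) stop("n_total must be positive", call. = FALSE)
  if (any(n_methylated < 0 | n_methylated > n_total)) {
    stop("need 0 <= n_methylated <= n_total", call. = FALSE)
  }
  100 * n_methylated / n_total
}

#' Methylated-CGI rate
#'
#' Overall: percentage of islands with a positive organ call. Per
#' chromosome: counts and percentages plus counts normalized per Mbp of
#' chromosome (for density-style comparisons); chromosomes carrying no
#' islands are omitted with a warning.
#'
#' @param calls A `CgiMethylation` from [call_methylated()].
#' @param genome A `GenomeAssembly` (needed for `by_chromosome`).
#' @param by_chromosome Report per chromosome instead of overall.
#' @return Overall: a single percentage. Per chromosome: data.frame with
#'   `chrom`, `n_total`, `n_methylated`, `pct_methylated`, `total_per_mbp`,
#'   `methylated_per_mbp`.
#' @export
methylation_rate <- function(calls, genome = NULL, by_chromosome = FALSE) {
  stopifnot(inherits(calls, "CgiMethylation"))
  isl <- calls$islands
  if (nrow(isl) == 0L) stop("no CpG islands in calls", call. = FALSE)
  if (!by_chromosome) {
    return(methylation_percentage(sum(isl$methylated), nrow(isl)))
  }
  if (is.null(genome)) {
    stop("per-chromosome rates need a genome for Mbp normalization",
      call. = FALSE
    )
  }
  lens <- chrom_lengths(genome)
  empty <- setdiff(names(lens), unique(isl$chrom))
  if (length(empty)) {
    warning(sprintf(
      "chromosome(s) without CGIs omitted: %s", paste(empty, collapse = ", ")
    ), call. = FALSE)
  }
  keep <- names(lens)[names(lens) %in% unique(isl$chrom)]
  n_total <- as.integer(table(factor(isl$chrom, levels = keep)))
  n_meth <- as.integer(tapply(
    isl$methylated, factor(isl$chrom, levels = keep), sum
  ))
  mbp <- lens[keep] / 1e6
  data.frame(
    chrom = keep, n_total = n_total, n_methylated = n_meth,
    pct_methylated = methylation_percentage(n_meth, n_total),
    total_per_mbp = n_total / mbp, methylated_per_mbp = n_meth / mbp,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Compare CGI methylation between organs per chromosome
#'
#' Student t-test (BH-adjusted across chromosomes) on the per-replicate,
#' per-chromosome methylated-island counts normalized by chromosome length
#' in Mbp.
#'
#' @param calls_a,calls_b `CgiMethylation` objects for the two organs,
#'   called on the same island set with >= 2 replicates each.
#' @param genome A `GenomeAssembly`.
#' @param var_equal Passed to [row_t_test()].
#' @return data.frame: `chrom`, `mean_a`, `mean_b`, `t`, `p`, `fdr`,
#'   `direction` (organ with the higher methylated-CGI density, `NA` on
#'   ties).
#' @export
compare_cgi_methylation <- function(calls_a, calls_b, genome,
                                    var_equal = TRUE) {
  stopifnot(
    inherits(calls_a, "CgiMethylation"), inherits(calls_b, "CgiMethylation"),
    nrow(calls_a$islands) == nrow(calls_b$islands)
  )
  lens <- chrom_lengths(genome)
  chroms <- names(lens)[names(lens) %in% unique(calls_a$islands$chrom)]
  per_rep <- function(calls) {
    f <- factor(calls$islands$chrom, levels = chroms)
    m <- apply(calls$calls, 2, function(cc) {
      as.integer(tapply(cc, f, sum, default = 0L))
    })
    m <- matrix(m, nrow = length(chroms), dimnames = list(chroms, NULL))
    m / (lens[chroms] / 1e6)
  }
  tt <- row_t_test(per_rep(calls_a), per_rep(calls_b), var_equal = var_equal)
  data.frame(
    chrom = chroms,
    mean_a = tt$mean_a, mean_b = tt$mean_b, t = tt$t, p = tt$p,
    fdr = stats::p.adjust(tt$p, "BH"),
    direction = ifelse(tt$mean_a == tt$mean_b, NA_character_,
      ifelse(tt$mean_a > tt$mean_b, calls_a$organ, calls_b$organ)
    ),
    stringsAsFactors = FALSE
  )
}
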
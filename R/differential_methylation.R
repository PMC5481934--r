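# Differential methylation between two organs from replicate depth (or
# peak-presence) signal: candidate regions are the union-merge of every
# sample's peaks, each region gets a normalized mean depth per sample, and
# regions are tested with a per-region Student t-test + Benjamini-Hochberg.
# Significant regions (DMRs) are then aggregated to differentially
# methylated genes (DMGs) by gene-body overlap.

#' Candidate regions for differential methylation testing
#'
#' Union-merge of all samples' peaks across both organs; book-ended
#' (abutting) intervals are merged. Output is sorted and disjoint.
#'
#' @param peaksets List of `PeakSet` (both organs together).
#' @return data.frame of disjoint intervals (`chrom`, `start`, `end`).
#' @export
candidate_regions <- function(peaksets) {
  .check_peaksets(peaksets, one_organ = FALSE)
  all_peaks <- do.call(rbind, lapply(peaksets, `[[`, "peaks"))
  if (nrow(all_peaks) == 0L) {
    stop("no peaks in any sample", call. = FALSE)
  }
  chroms <- sort(unique(all_peaks$chrom))
  out <- lapply(chroms, function(chrom) {
    p <- all_peaks[all_peaks$chrom == chrom, , drop = FALSE]
    .iranges_to_df(IRanges::reduce(.as_iranges(p$start, p$end)), chrom)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Region x sample matrix of normalized depth
#'
#' Entry = mean per-base depth of the sample's track over the region,
#' divided by (the sample's total signal / 1e6) when `normalize` is on.
#' Doubling a sample's depth everywhere leaves its normalized column
#' unchanged.
#'
#' @param regions data.frame of intervals (`chrom`, `start`, `end`).
#' @param tracks Named list of samples; each a named list of per-chromosome
#'   `Rle` depth tracks (see [depth_from_peaks()], [depth_from_bedgraph()]).
#' @param genome A `GenomeAssembly`.
#' @param normalize Library-size normalize each column (default `TRUE`).
#' @return Numeric matrix (regions x samples), rows named
#'   `chrom:start-end`.
#' @export
depth_matrix <- function(regions, tracks, genome, normalize = TRUE) {
  regions <- as.data.frame(regions)
  .validate_intervals(regions, genome, what = "region")
  out <- matrix(0, nrow(regions), length(tracks),
    dimnames = list(
      sprintf("%s:%d-%d", regions$chrom, regions$start, regions$end),
      names(tracks)
    )
  )
  by_chrom <- split(seq_len(nrow(regions)), regions$chrom)
  for (j in seq_along(tracks)) {
    track <- tracks[[j]]
    for (chrom in names(by_chrom)) {
      idx <- by_chrom[[chrom]]
      rle <- track[[chrom]]
      if (is.null(rle)) {
        stop(sprintf("sample %d has no track for chromosome %s", j, chrom),
          call. = FALSE
        )
      }
      v <- IRanges::Views(rle,
        start = regions$start[idx] + 1L,
        end = regions$end[idx]
      )
      out[idx, j] <- IRanges::viewMeans(v)
    }
    if (normalize) {
      tot <- total_signal(track)
      if (tot > 0) out[, j] <- out[, j] / (tot / 1e6)
    }
  }
  out
}

#' Call differentially methylated regions
#'
#' Per-region two-sample two-sided Student t-test between the two groups'
#' columns, Benjamini-Hochberg adjustment across all tested regions, and a
#' direction label (which group is hyper-methylated). By default depth is
#' log2-transformed (with a pseudocount) before testing, the standard
#' variance-stabilizing choice for enrichment coverage; group means are
#' reported on the original normalized-depth scale.
#'
#' @param regions data.frame of tested intervals, rows matching `mat`.
#' @param mat Numeric matrix regions x samples (see [depth_matrix()]).
#' @param groups Character/factor of length `ncol(mat)` with exactly two
#'   levels (organ labels); >= 2 samples per level.
#' @param alpha Significance threshold on FDR. Default 0.05.
#' @param log2_transform Test on `log2(depth + pseudocount)`. Default TRUE.
#' @param pseudocount Added before log2. Default 0.5.
#' @param var_equal Classic Student test (default) vs Welch.
#' @return data.frame: region coordinates, per-group means (normalized
#'   depth scale), `t`, `p`, `fdr`, `direction` (hyper-methylated group,
#'   `NA` on exact ties), `significant` (`fdr < alpha`).
#' @export
call_dmrs <- function(regions, mat, groups, alpha = 0.05,
                      log2_transform = TRUE, pseudocount = 0.5,
                      var_equal = TRUE) {
  regions <- as.data.frame(regions)
  stopifnot(nrow(regions) == nrow(mat), length(groups) == ncol(mat))
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) {
    stop("'groups' must have exactly two levels", call. = FALSE)
  }
  if (min(table(groups)) < 2L) {
    stop("each group needs >= 2 replicate columns", call. = FALSE)
  }
  la <- levels(groups)[1]
  lb <- levels(groups)[2]
  tm <- if (log2_transform) log2(mat + pseudocount) else mat
  tt <- row_t_test(
    tm[, groups == la, drop = FALSE],
    tm[, groups == lb, drop = FALSE],
    var_equal = var_equal
  )
  out <- data.frame(
    chrom = regions$chrom, start = regions$start, end = regions$end,
    stringsAsFactors = FALSE
  )
  out[[paste0("mean_", la)]] <- rowMeans(mat[, groups == la, drop = FALSE])
  out[[paste0("mean_", lb)]] <- rowMeans(mat[, groups == lb, drop = FALSE])
  out$t <- tt$t
  out$p <- tt$p
  out$fdr <- stats::p.adjust(tt$p, "BH")
  out$direction <- ifelse(tt$mean_a == tt$mean_b, NA_character_,
    ifelse(tt$mean_a > tt$mean_b, la, lb)
  )
  out$significant <- out$fdr < alpha
  attr(out, "groups") <- c(la, lb)
  out
}

#' Aggregate DMRs to differentially methylated genes
#'
#' A significant DMR supports every gene whose body (CDS start to CDS end)
#' it overlaps by at least 1 bp. A gene's direction is the direction of the
#' majority of its supporting DMRs; on a tie the gene is listed in both
#' directions (the "in common" class). The summary applies
#' inclusion-exclusion: `n_unique = n_a + n_b - n_shared`.
#'
#' @param dmrs data.frame from [call_dmrs()] (only rows with
#'   `significant == TRUE` are used; pre-filtered tables work too).
#' @param annotation A `GeneAnnotation`.
#' @return List of class `DmgSummary`: `genes` (data.frame `gene_id`,
#'   `direction`, `n_support`; tie genes appear once per direction),
#'   `in_body_dmrs` (number of significant DMRs overlapping any gene
#'   body), and `counts` (named: one count per direction, `shared`,
#'   `unique_total`).
#' @export
dmrs_to_dmgs <- function(dmrs, annotation) {
  stopifnot(inherits(annotation, "GeneAnnotation"))
  if ("significant" %in% names(dmrs)) {
    dmrs <- dmrs[dmrs$significant %in% TRUE, , drop = FALSE]
  }
  dirs <- attr(dmrs, "groups")
  if (is.null(dirs)) dirs <- sort(unique(stats::na.omit(dmrs$direction)))
  g <- annotation$genes
  empty <- data.frame(
    gene_id = character(), direction = character(), n_support = integer(),
    stringsAsFactors = FALSE
  )
  counts <- stats::setNames(
    rep(0L, length(dirs) + 2L), c(dirs, "shared", "unique_total")
  )
  if (nrow(dmrs) == 0L || nrow(g) == 0L) {
    return(structure(
      list(genes = empty, in_body_dmrs = 0L, counts = counts),
      class = "DmgSummary"
    ))
  }
  dmr_gr <- GenomicRanges::GRanges(
    dmrs$chrom, IRanges::IRanges(dmrs$start + 1L, dmrs$end)
  )
  gene_gr <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$start + 1L, g$end)
  )
  ov <- GenomicRanges::findOverlaps(dmr_gr, gene_gr, minoverlap = 1L)
  if (length(ov) == 0L) {
    return(structure(
      list(genes = empty, in_body_dmrs = 0L, counts = counts),
      class = "DmgSummary"
    ))
  }
  hits <- data.frame(
    gene_id = g$gene_id[S4Vectors::subjectHits(ov)],
    direction = dmrs$direction[S4Vectors::queryHits(ov)],
    stringsAsFactors = FALSE
  )
  hits <- hits[!is.na(hits$direction), , drop = FALSE]
  per_gene <- lapply(split(hits$direction, hits$gene_id), function(d) {
    tab <- table(factor(d, levels = dirs))
    win <- names(tab)[tab == max(tab)] # ties keep both directions
    data.frame(
      direction = win, n_support = length(d),
      stringsAsFactors = FALSE
    )
  })
  genes <- do.call(rbind, Map(
    function(id, df) cbind(gene_id = id, df, stringsAsFactors = FALSE),
    names(per_gene), per_gene
  ))
  rownames(genes) <- NULL
  shared_ids <- names(per_gene)[vapply(per_gene, nrow, 0L) > 1L]
  for (d in dirs) counts[d] <- sum(genes$direction == d)
  counts["shared"] <- length(shared_ids)
  counts["unique_total"] <- sum(counts[dirs]) - counts[["shared"]]
  structure(
    list(
      genes = genes,
      in_body_dmrs = length(unique(S4Vectors::queryHits(ov))),
      counts = counts
    ),
    class = "DmgSummary"
  )
}

#' @export
print.DmgSummary <- function(x, ...) {
  cat("DmgSummary:\n")
  for (nm in names(x$counts)) {
    cat(sprintf("  %s: %d\n", nm, x$counts[[nm]]))
  }
  cat(sprintf("  DMRs in gene bodies: %d\n", x$in_body_dmrs))
  invisible(x)
}

#' Unique gene count of two overlapping lists
#'
#' Inclusion-exclusion accounting for directional gene lists that share
#' members: `n_a + n_b - n_shared`.
#'
#' @param n_a,n_b Sizes of the two lists (each including shared members).
#' @param n_shared Number of genes in both lists.
#' @return The number of distinct genes.
#' @examples
#' union_gene_count(1264, 456, 74) # 1646
#' @export
union_gene_count <- function(n_a, n_b, n_shared) {
  stopifnot(n_shared >= 0, n_shared <= min(n_a, n_b))
  n_a + n_b - n_shared
}
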
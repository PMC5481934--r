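# Assignment of peak bases to genomic region categories (promoter, exon,
# intron, downstream, distal, intergenic) and the three density summaries:
# per-region density, per-chromosome peak density, and the metagene
# coverage profile.

#' Region classification configuration
#'
#' Extents of the gene-anchored flanks. The promoter is anchored at the CDS
#' start (2 kb upstream by default, strand-aware) and the downstream region
#' at the CDS end; the distal region extends `distal_bp` beyond each of
#' those flanks. When a base qualifies for several categories (possibly via
#' different genes) the first category in `priority` wins; anything
#' unclaimed is intergenic.
#'
#' @param promoter_bp,downstream_bp,distal_bp Flank extents in bp (> 0).
#' @param priority Character vector ordering
#'   `c("exon", "intron", "promoter", "downstream", "distal")`.
#' @return A list of class `RegionConfig`.
#' @export
region_config <- function(promoter_bp = 2000L, downstream_bp = 2000L,
                          distal_bp = 10000L,
                          priority = c(
                            "exon", "intron", "promoter",
                            "downstream", "distal"
                          )) {
  stopifnot(
    promoter_bp > 0, downstream_bp > 0, distal_bp > 0,
    setequal(priority, c("exon", "intron", "promoter", "downstream", "distal"))
  )
  structure(
    list(
      promoter_bp = as.integer(promoter_bp),
      downstream_bp = as.integer(downstream_bp),
      distal_bp = as.integer(distal_bp),
      priority = priority
    ),
    class = "RegionConfig"
  )
}

#' Disjoint region masks per chromosome
#'
#' Partitions every base of the genome into exactly one category given the
#' annotation and configuration. Returned as a per-chromosome list of
#' [IRanges::IRanges] per category (plus `intergenic`), used by
#' [categorize_bases()] and [region_density()].
#'
#' @param annotation A `GeneAnnotation`.
#' @param genome A `GenomeAssembly`.
#' @param cfg A `RegionConfig`.
#' @return Named list (by chromosome) of named lists (by category) of
#'   `IRanges`.
#' @export
region_masks <- function(annotation, genome, cfg = region_config()) {
  stopifnot(inherits(annotation, "GeneAnnotation"))
  lens <- chrom_lengths(genome)
  g <- annotation$genes
  e <- annotation$exons
  out <- lapply(names(lens), function(chrom) {
    len <- lens[[chrom]]
    whole <- IRanges::IRanges(1L, len)
    gc <- g[g$chrom == chrom, , drop = FALSE]
    clip <- function(start0, end0) {
      # 0-based half-open -> clipped 1-based IRanges; empty ranges dropped
      s <- pmax(start0, 0L)
      en <- pmin(end0, len)
      keep <- s < en
      IRanges::IRanges(s[keep] + 1L, en[keep])
    }
    if (nrow(gc) == 0L) {
      raw <- list(
        exon = IRanges::IRanges(), intron = IRanges::IRanges(),
        promoter = IRanges::IRanges(), downstream = IRanges::IRanges(),
        distal = IRanges::IRanges()
      )
    } else {
      ec <- e[e$chrom == chrom, , drop = FALSE]
      plus <- gc$strand == "+"
      p <- cfg$promoter_bp
      d <- cfg$downstream_bp
      dd <- cfg$distal_bp
      # strand-aware flank geometry in the 0-based frame
      prom_s <- ifelse(plus, gc$start - p, gc$end)
      prom_e <- ifelse(plus, gc$start, gc$end + p)
      down_s <- ifelse(plus, gc$end, gc$start - d)
      down_e <- ifelse(plus, gc$end + d, gc$start)
      dist_s <- c(
        ifelse(plus, gc$start - p - dd, gc$end + p),
        ifelse(plus, gc$end + d, gc$start - d - dd)
      )
      dist_e <- c(
        ifelse(plus, gc$start - p, gc$end + p + dd),
        ifelse(plus, gc$end + d + dd, gc$start - d)
      )
      exon_u <- IRanges::reduce(clip(ec$start, ec$end))
      gene_u <- IRanges::reduce(clip(gc$start, gc$end))
      raw <- list(
        exon = exon_u,
        intron = IRanges::setdiff(gene_u, exon_u),
        promoter = IRanges::reduce(clip(prom_s, prom_e)),
        downstream = IRanges::reduce(clip(down_s, down_e)),
        distal = IRanges::reduce(clip(dist_s, dist_e))
      )
    }
    masks <- list()
    claimed <- IRanges::IRanges()
    for (cat in cfg$priority) {
      masks[[cat]] <- IRanges::setdiff(raw[[cat]], claimed)
      claimed <- IRanges::union(claimed, raw[[cat]])
    }
    masks$intergenic <- IRanges::setdiff(whole, claimed)
    masks
  })
  names(out) <- names(lens)
  out
}

#' @noRd
.region_categories <- function() {
  c("promoter", "exon", "intron", "downstream", "distal", "intergenic")
}

#' Partition peak bases over region categories
#'
#' For each peak, counts how many of its bases fall in each category under
#' the disjoint genome partition of [region_masks()]. Category counts sum
#' to the peak length for every peak.
#'
#' @param peaks A `PeakSet` or data.frame of intervals (`chrom`, `start`,
#'   `end`, 0-based half-open).
#' @param annotation A `GeneAnnotation`.
#' @param genome A `GenomeAssembly`.
#' @param cfg A `RegionConfig`.
#' @param masks Optional precomputed [region_masks()] (saves recomputation
#'   across peak sets).
#' @return data.frame: one row per peak, columns `chrom`, `start`, `end`
#'   and one bp count per category.
#' @export
categorize_bases <- function(peaks, annotation, genome, cfg = region_config(),
                             masks = NULL) {
  df <- if (inherits(peaks, "PeakSet")) peaks$peaks else as.data.frame(peaks)
  .validate_intervals(df, genome, what = "peak")
  if (is.null(masks)) masks <- region_masks(annotation, genome, cfg)
  cats <- .region_categories()
  counts <- matrix(0L, nrow(df), length(cats), dimnames = list(NULL, cats))
  if (nrow(df)) {
    by_chrom <- split(seq_len(nrow(df)), df$chrom)
    for (chrom in names(by_chrom)) {
      idx <- by_chrom[[chrom]]
      ir <- .as_iranges(df$start[idx], df$end[idx])
      for (cat in cats) {
        m <- masks[[chrom]][[cat]]
        if (length(m) == 0L) next
        ov <- IRanges::findOverlaps(ir, m)
        if (length(ov) == 0L) next
        pint <- IRanges::pintersect(
          ir[S4Vectors::queryHits(ov)], m[S4Vectors::subjectHits(ov)]
        )
        bp <- tapply(IRanges::width(pint), S4Vectors::queryHits(ov), sum)
        counts[idx[as.integer(names(bp))], cat] <-
          counts[idx[as.integer(names(bp))], cat] + as.integer(bp)
      }
    }
  }
  cbind(df[, c("chrom", "start", "end")], as.data.frame(counts))
}

#' Mean region length per category
#'
#' The per-category denominator of [region_density()]: exons and introns
#' use the mean length of the annotated features, promoter/downstream/distal
#' use their fixed configured extents, and intergenic uses the mean length
#' of the intergenic segments of the genome partition. Categories with no
#' regions get `NA`.
#'
#' @inheritParams categorize_bases
#' @return Named numeric vector over the six categories.
#' @export
mean_region_lengths <- function(annotation, genome, cfg = region_config(),
                                masks = NULL) {
  if (is.null(masks)) masks <- region_masks(annotation, genome, cfg)
  ex <- annotation$exons
  intr <- gene_introns(annotation)
  inter_w <- unlist(lapply(masks, function(m) IRanges::width(m$intergenic)))
  c(
    promoter = if (nrow(annotation$genes)) as.numeric(cfg$promoter_bp) else NA_real_,
    exon = if (nrow(ex)) mean(ex$end - ex$start) else NA_real_,
    intron = if (nrow(intr)) mean(intr$end - intr$start) else NA_real_,
    downstream = if (nrow(annotation$genes)) as.numeric(cfg$downstream_bp) else NA_real_,
    distal = if (nrow(annotation$genes)) as.numeric(cfg$distal_bp) else NA_real_,
    intergenic = if (length(inter_w)) mean(inter_w) else NA_real_
  )
}

#' Methylation density per genomic region category
#'
#' For one organ's peak sets: total peak bp assigned to each category
#' (summed over the organ's samples), divided by the mean length of that
#' category's regions in the genome and by the total number of peaks in the
#' organ. Categories without annotated regions are reported as `NA`
#' (undefined), not zero.
#'
#' @param peaksets List of `PeakSet` from one organ.
#' @inheritParams categorize_bases
#' @return data.frame with columns `category`, `peak_bp`, `mean_region_bp`,
#'   `n_peaks`, `density`.
#' @export
region_density <- function(peaksets, annotation, genome, cfg = region_config(),
                           masks = NULL) {
  .check_peaksets(peaksets)
  if (is.null(masks)) masks <- region_masks(annotation, genome, cfg)
  cats <- .region_categories()
  bp <- stats::setNames(numeric(length(cats)), cats)
  n_peaks <- 0L
  for (ps in peaksets) {
    n_peaks <- n_peaks + nrow(ps$peaks)
    cb <- categorize_bases(ps, annotation, genome, cfg, masks = masks)
    bp <- bp + colSums(cb[, cats, drop = FALSE])
  }
  mean_len <- mean_region_lengths(annotation, genome, cfg, masks = masks)[cats]
  density <- if (n_peaks == 0L) {
    ifelse(is.na(mean_len), NA_real_, 0)
  } else {
    bp / mean_len / n_peaks
  }
  data.frame(
    category = cats, peak_bp = as.numeric(bp),
    mean_region_bp = as.numeric(mean_len), n_peaks = n_peaks,
    density = as.numeric(density), stringsAsFactors = FALSE
  )
}

#' Per-chromosome peak density
#'
#' For each replicate: (peaks on the chromosome / chromosome length in Mbp /
#' total peaks in the replicate) x `scale` (10,000 by default, mirroring
#' the usual plotting convention). The ratio is invariant under uniform
#' scaling of a replicate's peak counts.
#'
#' @param peaksets List of `PeakSet` from one organ.
#' @param genome A `GenomeAssembly`.
#' @param scale Multiplier applied to every ratio. Default 1e4.
#' @return data.frame with columns `chrom`, `organ`, `replicate`,
#'   `n_peaks`, `ratio`.
#' @export
chromosome_density <- function(peaksets, genome, scale = 1e4) {
  .check_peaksets(peaksets)
  lens <- chrom_lengths(genome)
  rows <- lapply(peaksets, function(ps) {
    total <- nrow(ps$peaks)
    n <- table(factor(ps$peaks$chrom, levels = names(lens)))
    ratio <- if (total == 0L) {
      rep(0, length(lens))
    } else {
      as.numeric(n) / (lens / 1e6) / total * scale
    }
    data.frame(
      chrom = names(lens), organ = ps$organ, replicate = ps$replicate,
      n_peaks = as.integer(n), ratio = as.numeric(ratio),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare per-chromosome peak density between two organs
#'
#' Two-sample two-sided Student t-test (equal variance by default) on the
#' per-replicate chromosome density ratios, with Benjamini-Hochberg
#' adjustment across chromosomes. Direction is the organ with the larger
#' mean ratio.
#'
#' @param peaksets_a,peaksets_b Lists of `PeakSet`, one organ each, with at
#'   least 2 replicates per organ.
#' @param genome A `GenomeAssembly`.
#' @param scale Passed to [chromosome_density()].
#' @param var_equal Passed to [row_t_test()].
#' @return data.frame: `chrom`, `mean_a`, `mean_b`, `t`, `p`, `fdr`,
#'   `direction` (label of the denser organ, `NA` on exact ties).
#' @export
compare_chromosome_density <- function(peaksets_a, peaksets_b, genome,
                                       scale = 1e4, var_equal = TRUE) {
  .check_peaksets(peaksets_a)
  .check_peaksets(peaksets_b)
  lens <- chrom_lengths(genome)
  mat <- function(peaksets) {
    d <- chromosome_density(peaksets, genome, scale)
    m <- matrix(d$ratio,
      nrow = length(lens),
      dimnames = list(names(lens), NULL)
    )
    m
  }
  ma <- mat(peaksets_a)
  mb <- mat(peaksets_b)
  tt <- row_t_test(ma, mb, var_equal = var_equal)
  organ_a <- peaksets_a[[1]]$organ
  organ_b <- peaksets_b[[1]]$organ
  data.frame(
    chrom = names(lens),
    mean_a = tt$mean_a, mean_b = tt$mean_b, t = tt$t, p = tt$p,
    fdr = stats::p.adjust(tt$p, "BH"),
    direction = ifelse(tt$mean_a == tt$mean_b, NA_character_,
      ifelse(tt$mean_a > tt$mean_b, organ_a, organ_b)
    ),
    stringsAsFactors = FALSE
  )
}

#' Binary peak-presence depth track
#'
#' Per-base 0/1 coverage from a sample's peaks, the peak-derived stand-in
#' for read depth.
#'
#' @param peakset A `PeakSet`.
#' @param genome A `GenomeAssembly`.
#' @return A named [IRanges::RleList]-like list of per-chromosome
#'   [S4Vectors::Rle] tracks spanning each chromosome.
#' @export
depth_from_peaks <- function(peakset, genome) {
  stopifnot(inherits(peakset, "PeakSet"))
  lens <- chrom_lengths(genome)
  by_chrom <- .ranges_by_chrom(peakset$peaks, names(lens))
  out <- lapply(names(lens), function(chrom) {
    cv <- IRanges::coverage(by_chrom[[chrom]], width = lens[[chrom]])
    S4Vectors::runValue(cv) <- pmin(S4Vectors::runValue(cv), 1L)
    cv
  })
  names(out) <- names(lens)
  out
}

#' Depth track from a bedGraph file
#'
#' Reads a 4-column bedGraph (0-based half-open intervals with a numeric
#' value) into per-chromosome run-length tracks; bases not covered by any
#' record are 0.
#'
#' @param path bedGraph file path.
#' @param genome A `GenomeAssembly`.
#' @return Named list of per-chromosome [S4Vectors::Rle] tracks.
#' @export
depth_from_bedgraph <- function(path, genome) {
  lens <- chrom_lengths(genome)
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    score = as.numeric(gr$score),
    stringsAsFactors = FALSE
  )
  .validate_intervals(df, genome, what = "bedGraph record")
  out <- lapply(names(lens), function(chrom) {
    d <- df[df$chrom == chrom, , drop = FALSE]
    IRanges::coverage(
      .as_iranges(d$start, d$end),
      width = lens[[chrom]], weight = d$score
    )
  })
  names(out) <- names(lens)
  out
}

#' Total signal of a depth track
#'
#' @param track Named list of per-chromosome `Rle` tracks.
#' @return Sum of per-base depth over the genome.
#' @export
total_signal <- function(track) {
  sum(vapply(track, function(r) sum(as.numeric(S4Vectors::runValue(r)) *
    S4Vectors::runLength(r)), 0))
}

#' Metagene coverage profile
#'
#' Averages a depth track over genes in normalized gene coordinates: 20
#' fixed-width windows across the upstream flank (`flank_bp` total), 40
#' equal windows across the gene body (CDS start to CDS end), and 20
#' windows across the downstream flank -- 80 values with position 1 always
#' at the 5' end (minus-strand genes are reversed). Genes with a body
#' shorter than 40 bp are excluded; flank windows running off the
#' chromosome contribute only their in-bounds part.
#'
#' @param track Named list of per-chromosome `Rle` depth tracks (e.g. from
#'   [depth_from_peaks()] or [depth_from_bedgraph()]).
#' @param annotation A `GeneAnnotation`.
#' @param genome A `GenomeAssembly`.
#' @param flank_bp Flank extent in bp (default 2000, i.e. 100-bp windows).
#' @param scale_factor Divisor applied to every window mean (e.g. total
#'   signal in Mb for per-million library normalization). Default 1.
#' @return List of class `MetageneProfile`: `values` (80 window means
#'   averaged over genes), `n_genes`.
#' @export
metagene_profile <- function(track, annotation, genome, flank_bp = 2000L,
                             scale_factor = 1) {
  stopifnot(inherits(annotation, "GeneAnnotation"), flank_bp >= 20L)
  lens <- chrom_lengths(genome)
  g <- annotation$genes
  g <- g[(g$end - g$start) >= 40L, , drop = FALSE]
  if (nrow(g) == 0L) {
    stop("no genes with body >= 40 bp; cannot form 40 body windows",
      call. = FALSE
    )
  }
  prof <- matrix(NA_real_, nrow(g), 80L)
  row <- 0L
  for (chrom in unique(g$chrom)) {
    gc <- g[g$chrom == chrom, , drop = FALSE]
    rle <- track[[chrom]]
    if (is.null(rle)) {
      stop(sprintf("depth track has no chromosome %s", chrom), call. = FALSE)
    }
    len <- lens[[chrom]]
    starts <- ends <- matrix(0L, nrow(gc), 80L)
    for (k in seq_len(nrow(gc))) {
      s <- gc$start[k]
      e <- gc$end[k]
      lb <- e - s
      br <- c(
        s - flank_bp + floor((0:20) * flank_bp / 20),
        s + floor((1:40) * lb / 40),
        e + floor((1:20) * flank_bp / 20)
      )
      starts[k, ] <- as.integer(br[1:80])
      ends[k, ] <- as.integer(br[2:81])
    }
    # clip to the chromosome; windows fully off-chromosome become NA
    s1 <- pmax(as.vector(starts) + 1L, 1L)
    e1 <- pmin(as.vector(ends), len)
    ok <- s1 <= e1
    vals <- rep(NA_real_, length(s1))
    if (any(ok)) {
      v <- IRanges::Views(rle, start = s1[ok], end = e1[ok])
      vals[ok] <- IRanges::viewMeans(v)
    }
    m <- matrix(vals, nrow(gc), 80L)
    flip <- gc$strand == "-"
    m[flip, ] <- m[flip, 80:1, drop = FALSE]
    prof[row + seq_len(nrow(gc)), ] <- m
    row <- row + nrow(gc)
  }
  structure(
    list(
      values = colMeans(prof, na.rm = TRUE) / scale_factor,
      n_genes = nrow(g)
    ),
    class = "MetageneProfile"
  )
}

#' @export
print.MetageneProfile <- function(x, ...) {
  cat(sprintf(
    "MetageneProfile over %d genes; mean depth %.4g (flank) / %.4g (body)\n",
    x$n_genes, mean(x$values[c(1:20, 61:80)]), mean(x$values[21:60])
  ))
  invisible(x)
}
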
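# Synthetic study generator: a small multi-chromosome genome with planted
# GC-rich islands, a non-overlapping gene annotation, two organs x 3
# replicates of methylation signal with planted differential regions, and
# an expression table with a planted methylation-expression coupling --
# all with a machine-readable ground truth, so every pipeline stage can be
# tested against what was planted.
#
# Each generator draws from its own stream (a fixed offset of the master
# seed), so regenerating one output never perturbs another.

#' Synthetic study configuration
#'
#' Defaults emulate the study design the pipeline targets -- two organs x
#' three replicates at desk scale: a 4 x 300 kb genome at background GC
#' 0.40 with CpG depletion, 10 planted 2-kb CpG islands (GC ~0.85,
#' obs/exp ~1.3), 120 non-overlapping genes of 1.5-4 kb with >= 4 kb gaps,
#' ~300 shared baseline peak regions at lognormal depth around 10, 20
#' planted differentially methylated regions at an 8x depth effect with
#' lognormal noise sigma 0.2, 60 differentially expressed genes of which a
#' fraction rho = 0.6 of the hypo-methylated genes is forced
#' over-expressed.
#'
#' @param n_chromosomes,chrom_length Genome shape (every chromosome the
#'   same length, bp).
#' @param background_gc Background GC fraction.
#' @param n_genes Number of genes across the genome.
#' @param gene_length Length range of a gene body, bp.
#' @param exon_count Range of exons per gene.
#' @param gene_gap Minimum gap between genes, bp (leaves room for flanks).
#' @param n_cgis,cgi_length,cgi_gap Planted islands: count, length, and
#'   minimum separation (bp).
#' @param organs Two organ labels; the first is the reference frame for
#'   hyper/hypo and over/under directions.
#' @param n_replicates Replicates per organ.
#' @param n_peak_regions Baseline methylated regions shared across samples.
#' @param peak_length Length range of a baseline region, bp.
#' @param base_depth Median depth of a methylated region.
#' @param noise_sd Lognormal sigma of depth noise.
#' @param peak_threshold Depth above which a region is emitted as a peak.
#' @param n_dmrs Planted differential regions (inside gene bodies; half
#'   hyper-methylated in each organ).
#' @param dmr_effect Depth fold-change of a planted region in its hyper
#'   organ.
#' @param dmr_length Maximum planted region length, bp.
#' @param n_degs Planted differentially expressed genes.
#' @param deg_logfc Absolute logFC range of a planted DEG.
#' @param coupling_fraction Fraction rho of hypo-methylated genes (first
#'   organ frame) forced into the over-expressed set of the first organ.
#' @param emit_sequence Generate nucleotide sequence (needed for CpG-island
#'   scanning; turn off for large coordinate-only runs).
#' @param seed Master seed.
#' @return List of class `SyntheticConfig`.
#' @export
synthetic_config <- function(n_chromosomes = 4L, chrom_length = 300000L,
                             background_gc = 0.40,
                             n_genes = 120L, gene_length = c(1500L, 4000L),
                             exon_count = c(1L, 10L), gene_gap = 4000L,
                             n_cgis = 10L, cgi_length = 2000L,
                             cgi_gap = 1000L,
                             organs = c("hypothalamus", "ovary"),
                             n_replicates = 3L,
                             n_peak_regions = 300L,
                             peak_length = c(600L, 1200L),
                             base_depth = 10, noise_sd = 0.2,
                             peak_threshold = 2,
                             n_dmrs = 20L, dmr_effect = 8,
                             dmr_length = 800L,
                             n_degs = 60L, deg_logfc = c(1, 4),
                             coupling_fraction = 0.6,
                             emit_sequence = TRUE, seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    background_gc = background_gc,
    n_genes = as.integer(n_genes),
    gene_length = as.integer(gene_length),
    exon_count = as.integer(exon_count),
    gene_gap = as.integer(gene_gap),
    n_cgis = as.integer(n_cgis),
    cgi_length = as.integer(cgi_length),
    cgi_gap = as.integer(cgi_gap),
    organs = as.character(organs),
    n_replicates = as.integer(n_replicates),
    n_peak_regions = as.integer(n_peak_regions),
    peak_length = as.integer(peak_length),
    base_depth = base_depth,
    noise_sd = noise_sd,
    peak_threshold = peak_threshold,
    n_dmrs = as.integer(n_dmrs),
    dmr_effect = dmr_effect,
    dmr_length = as.integer(dmr_length),
    n_degs = as.integer(n_degs),
    deg_logfc = as.numeric(deg_logfc),
    coupling_fraction = coupling_fraction,
    emit_sequence = isTRUE(emit_sequence),
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_chromosomes > 0, cfg$chrom_length > 0,
    cfg$background_gc > 0, cfg$background_gc < 1,
    cfg$n_genes >= 0, length(cfg$gene_length) == 2L,
    cfg$n_cgis >= 0, cfg$cgi_length > 0,
    length(cfg$organs) == 2L, cfg$n_replicates >= 1,
    cfg$n_dmrs >= 0, cfg$dmr_effect > 0, cfg$noise_sd >= 0,
    cfg$n_degs >= 0,
    cfg$coupling_fraction >= 0, cfg$coupling_fraction <= 1
  )
  structure(cfg, class = "SyntheticConfig")
}

#' @noRd
.chrom_names <- function(cfg) sprintf("chr%d", seq_len(cfg$n_chromosomes))

#' Generate a genome with planted CpG islands
#'
#' Background sequence at `background_gc` with CpG dinucleotides depleted
#' (so spurious islands are rare); planted islands are CG-rich dinucleotide
#' repeats (GC >= 0.7, obs/exp >= 0.8) at recorded coordinates, separated
#' by at least `cgi_gap`.
#'
#' @param cfg A `SyntheticConfig`.
#' @return List: `genome` (a `GenomeAssembly`, with sequence when
#'   `cfg$emit_sequence`), `cgis` (data.frame of planted island
#'   coordinates, 0-based half-open).
#' @export
generate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  set.seed(cfg$seed + 101L)
  chroms <- .chrom_names(cfg)
  len <- cfg$chrom_length
  truth <- data.frame(
    chrom = character(), start = integer(), end = integer(),
    stringsAsFactors = FALSE
  )
  if (!cfg$emit_sequence) {
    return(list(
      genome = genome_assembly(chroms, rep(len, cfg$n_chromosomes)),
      cgis = truth
    ))
  }
  # distribute islands round-robin over chromosomes
  isl_chrom <- rep(chroms, length.out = cfg$n_cgis)
  seqs <- character(cfg$n_chromosomes)
  gc <- cfg$background_gc
  for (ci in seq_along(chroms)) {
    s <- sample(c("A", "C", "G", "T"), len,
      replace = TRUE,
      prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    )
    # CpG depletion: most background CG dinucleotides lose the G
    cg_at <- which(s[-len] == "C" & s[-1] == "G")
    kill <- cg_at[stats::runif(length(cg_at)) < 0.9]
    s[kill + 1L] <- "A"
    k <- sum(isl_chrom == chroms[ci])
    if (k > 0L) {
      need <- k * (cfg$cgi_length + cfg$cgi_gap) + cfg$cgi_gap
      if (need > len) {
        stop(sprintf(
          "%d islands of %d bp do not fit on a %d bp chromosome",
          k, cfg$cgi_length, len
        ), call. = FALSE)
      }
      slot <- len %/% k
      for (j in seq_len(k)) {
        lo <- (j - 1L) * slot + cfg$cgi_gap
        hi <- j * slot - cfg$cgi_length - cfg$cgi_gap
        start <- lo + sample.int(max(hi - lo, 1L), 1L) - 1L
        island <- .island_sequence(cfg$cgi_length)
        s[(start + 1L):(start + cfg$cgi_length)] <- island
        truth <- rbind(truth, data.frame(
          chrom = chroms[ci], start = start,
          end = start + cfg$cgi_length, stringsAsFactors = FALSE
        ))
      }
    }
    seqs[ci] <- paste(s, collapse = "")
  }
  names(seqs) <- chroms
  list(
    genome = genome_assembly(chroms, rep(len, cfg$n_chromosomes), seqs),
    cgis = .sort_intervals(truth)
  )
}

#' @noRd
.island_sequence <- function(n) {
  units <- c("CG", "GC", "CC", "GG", "AT", "TA")
  probs <- c(0.50, 0.15, 0.10, 0.10, 0.075, 0.075)
  pick <- sample(units, ceiling(n / 2), replace = TRUE, prob = probs)
  unlist(strsplit(pick, ""))[seq_len(n)]
}

#' Generate a gene annotation
#'
#' Places non-overlapping genes with 1-10 exons on both strands, separated
#' by at least `gene_gap` (room for promoter/downstream flanks). The
#' emitted structure passes the annotation validators.
#'
#' @param cfg A `SyntheticConfig`.
#' @param genome A `GenomeAssembly` (only lengths are used).
#' @return A `GeneAnnotation`.
#' @export
generate_annotation <- function(cfg, genome) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  set.seed(cfg$seed + 202L)
  lens <- chrom_lengths(genome)
  if (cfg$n_genes == 0L) {
    return(gene_annotation(data.frame(
      gene_id = character(), chrom = character(), strand = character(),
      start = integer(), end = integer()
    ), genome = genome))
  }
  # apportion genes to chromosomes by length
  counts <- diff(round(cumsum(c(0, lens / sum(lens))) * cfg$n_genes))
  genes <- exons <- list()
  gid <- 0L
  for (ci in seq_along(lens)) {
    k <- counts[ci]
    if (k == 0L) next
    glen <- sample(seq(cfg$gene_length[1], cfg$gene_length[2]), k,
      replace = TRUE
    )
    slack <- lens[ci] - sum(glen) - (k + 1L) * cfg$gene_gap
    if (slack < 0) {
      stop(sprintf(
        "cannot place %d genes on chromosome %s: %d bp short",
        k, names(lens)[ci], -slack
      ), call. = FALSE)
    }
    w <- stats::runif(k + 1L)
    gaps <- cfg$gene_gap + floor(slack * w / sum(w))
    starts <- as.integer(cumsum(gaps[seq_len(k)]) + cumsum(c(0L, glen[-k])))
    ids <- sprintf("gene%04d", gid + seq_len(k))
    gid <- gid + k
    genes[[ci]] <- data.frame(
      gene_id = ids, chrom = names(lens)[ci],
      strand = sample(c("+", "-"), k, replace = TRUE),
      start = starts, end = starts + glen, stringsAsFactors = FALSE
    )
    exons[[ci]] <- do.call(rbind, Map(
      .gene_exons, ids, names(lens)[ci], starts, starts + glen,
      MoreArgs = list(cfg = cfg)
    ))
  }
  gene_annotation(do.call(rbind, genes), do.call(rbind, exons),
    genome = genome
  )
}

#' @noRd
.gene_exons <- function(id, chrom, start, end, cfg) {
  len <- end - start
  k <- sample(seq(cfg$exon_count[1], cfg$exon_count[2]), 1L)
  k <- max(1L, min(k, (len + 50L) %/% 100L)) # exons/introns >= 50 bp
  nseg <- 2L * k - 1L
  extra <- len - 50L * nseg
  w <- stats::runif(nseg)
  seg <- 50L + floor(extra * w / sum(w))
  seg[nseg] <- seg[nseg] + (len - sum(seg))
  bounds <- start + cumsum(c(0L, seg))
  idx <- seq(1L, nseg, by = 2L)
  data.frame(
    gene_id = id, chrom = chrom,
    start = as.integer(bounds[idx]), end = as.integer(bounds[idx + 1L]),
    stringsAsFactors = FALSE
  )
}

#' Generate replicate methylation signal with planted DMRs
#'
#' A shared set of baseline methylated regions gets per-sample lognormal
#' depth (`meanlog = log(base_depth)`, `sdlog = noise_sd`). `n_dmrs`
#' regions planted inside randomly chosen gene bodies get their depth
#' multiplied by `dmr_effect` in one organ (half of them per organ). Peaks
#' are emitted wherever depth exceeds `peak_threshold`.
#'
#' @param cfg A `SyntheticConfig`.
#' @param genome A `GenomeAssembly`.
#' @param annotation A `GeneAnnotation`.
#' @return List: `samples` (list with `organ`, `replicate`, `peaks`
#'   (`PeakSet`), `regions` (data.frame with `score` = depth), `track`
#'   (per-chromosome `Rle` list)); `regions` (the shared region set with
#'   `planted` flag); `truth` (list: `dmrs` data.frame with `gene_id`,
#'   coordinates and `hyper_organ`; `hyper`/`hypo` gene lists in the
#'   first-organ frame).
#' @export
generate_methylation <- function(cfg, genome, annotation) {
  stopifnot(
    inherits(cfg, "SyntheticConfig"), inherits(genome, "GenomeAssembly"),
    inherits(annotation, "GeneAnnotation")
  )
  set.seed(cfg$seed + 303L)
  g <- annotation$genes
  if (cfg$n_dmrs > nrow(g)) {
    stop("more planted DMRs than genes", call. = FALSE)
  }
  lens <- chrom_lengths(genome)
  organ_a <- cfg$organs[1]

  # planted DMR intervals inside gene bodies
  dmr <- NULL
  if (cfg$n_dmrs > 0L) {
    pick <- g[sample.int(nrow(g), cfg$n_dmrs), , drop = FALSE]
    dlen <- pmin(pick$end - pick$start, cfg$dmr_length)
    off <- floor((pick$end - pick$start - dlen) *
      stats::runif(cfg$n_dmrs))
    hyper <- sample(rep(cfg$organs, length.out = cfg$n_dmrs))
    dmr <- data.frame(
      gene_id = pick$gene_id, chrom = pick$chrom,
      start = as.integer(pick$start + off),
      end = as.integer(pick$start + off + dlen),
      hyper_organ = hyper, stringsAsFactors = FALSE
    )
  }

  # shared baseline regions anywhere in the genome, kept disjoint from each
  # other and from the planted intervals (1 bp margin stops union-merging)
  base <- data.frame(
    chrom = sample(names(lens), cfg$n_peak_regions,
      replace = TRUE,
      prob = lens / sum(lens)
    ),
    len = sample(
      seq(cfg$peak_length[1], cfg$peak_length[2]),
      cfg$n_peak_regions,
      replace = TRUE
    ),
    stringsAsFactors = FALSE
  )
  base$start <- as.integer(floor(stats::runif(
    cfg$n_peak_regions,
    0, lens[base$chrom] - base$len
  )))
  base$end <- base$start + base$len
  base <- .sort_intervals(base[, c("chrom", "start", "end")])
  keep <- rep(TRUE, nrow(base))
  prev_end <- -Inf
  prev_chrom <- ""
  for (i in seq_len(nrow(base))) {
    if (base$chrom[i] == prev_chrom && base$start[i] <= prev_end) {
      keep[i] <- FALSE
    } else {
      prev_end <- base$end[i] + 1L
      prev_chrom <- base$chrom[i]
    }
  }
  base <- base[keep, , drop = FALSE]
  if (!is.null(dmr)) {
    ov <- logical(nrow(base))
    for (chrom in unique(dmr$chrom)) {
      bi <- base$chrom == chrom
      d <- dmr[dmr$chrom == chrom, , drop = FALSE]
      hits <- IRanges::findOverlaps(
        .as_iranges(base$start[bi] - 1L, base$end[bi] + 1L),
        .as_iranges(d$start, d$end)
      )
      ov[which(bi)[unique(S4Vectors::queryHits(hits))]] <- TRUE
    }
    base <- base[!ov, , drop = FALSE]
  }
  regions <- rbind(
    cbind(base, planted = FALSE),
    if (!is.null(dmr)) {
      cbind(dmr[, c("chrom", "start", "end")], planted = TRUE)
    }
  )
  regions <- .sort_intervals(regions)
  rownames(regions) <- NULL
  planted_idx <- which(regions$planted)
  dmr_key <- if (!is.null(dmr)) {
    match(
      sprintf("%s:%d", regions$chrom[planted_idx], regions$start[planted_idx]),
      sprintf("%s:%d", dmr$chrom, dmr$start)
    )
  }

  samples <- list()
  for (organ in cfg$organs) {
    for (r in seq_len(cfg$n_replicates)) {
      depth <- stats::rlnorm(nrow(regions),
        meanlog = log(cfg$base_depth),
        sdlog = cfg$noise_sd
      )
      if (!is.null(dmr)) {
        boost <- dmr$hyper_organ[dmr_key] == organ
        depth[planted_idx[boost]] <- depth[planted_idx[boost]] * cfg$dmr_effect
      }
      reg <- cbind(regions[, c("chrom", "start", "end")], score = depth)
      is_peak <- depth > cfg$peak_threshold
      track <- lapply(names(lens), function(chrom) {
        d <- reg[reg$chrom == chrom, , drop = FALSE]
        IRanges::coverage(.as_iranges(d$start, d$end),
          width = lens[[chrom]], weight = d$score
        )
      })
      names(track) <- names(lens)
      samples[[sprintf("%s.rep%d", organ, r)]] <- list(
        organ = organ, replicate = sprintf("rep%d", r),
        peaks = peak_set(
          reg[is_peak, c("chrom", "start", "end")],
          organ, sprintf("rep%d", r), genome
        ),
        regions = reg, track = track
      )
    }
  }
  truth <- list(
    dmrs = if (is.null(dmr)) {
      data.frame(
        gene_id = character(), chrom = character(), start = integer(),
        end = integer(), hyper_organ = character(), stringsAsFactors = FALSE
      )
    } else {
      dmr
    },
    hyper = if (is.null(dmr)) character() else dmr$gene_id[dmr$hyper_organ == organ_a],
    hypo = if (is.null(dmr)) character() else dmr$gene_id[dmr$hyper_organ != organ_a]
  )
  list(samples = samples, regions = regions, truth = truth)
}

#' Generate an expression table with planted coupling
#'
#' All annotated genes get a row. `n_degs` genes are significant
#' (FDR < 1e-4) with a signed logFC; a fraction rho of the genes
#' hypo-methylated in the first organ is forced into that organ's
#' over-expressed set (negative logFC under the positive-is-second-organ
#' sign convention); the remaining DEGs are drawn uniformly from the
#' other genes with random sign. Non-DEGs get FDR in [0.2, 1).
#'
#' @param cfg A `SyntheticConfig`.
#' @param annotation A `GeneAnnotation` (the gene universe).
#' @param methylation_truth The `truth` element of
#'   [generate_methylation()].
#' @return List: `deg` (data.frame `gene_id`, `logFC`, `FDR` over the
#'   whole universe), `truth` (list: `degs`, `over`, `under` in the
#'   first-organ frame, `coupled`).
#' @export
generate_expression <- function(cfg, annotation, methylation_truth) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  set.seed(cfg$seed + 404L)
  universe <- annotation$genes$gene_id
  hypo <- intersect(methylation_truth$hypo, universe)
  coupled <- if (length(hypo)) {
    sample(hypo, round(cfg$coupling_fraction * length(hypo)))
  } else {
    character()
  }
  if (length(coupled) > cfg$n_degs) {
    stop("coupled set larger than n_degs; raise n_degs or lower coupling",
      call. = FALSE
    )
  }
  rest <- sample(setdiff(universe, coupled), cfg$n_degs - length(coupled))
  degs <- c(coupled, rest)
  mag <- stats::runif(length(degs), cfg$deg_logfc[1], cfg$deg_logfc[2])
  # positive logFC = over-expressed in the second organ; coupled genes are
  # over-expressed in the first organ
  sign <- c(
    rep(-1, length(coupled)),
    sample(c(-1, 1), length(rest), replace = TRUE)
  )
  logfc <- stats::setNames(rep(0, length(universe)), universe)
  fdr <- stats::setNames(stats::runif(length(universe), 0.2, 1 - 1e-9), universe)
  logfc[degs] <- sign * mag
  fdr[degs] <- 10^stats::runif(length(degs), -8, -4.5)
  deg <- data.frame(
    gene_id = universe, logFC = as.numeric(logfc), FDR = as.numeric(fdr),
    stringsAsFactors = FALSE
  )
  list(
    deg = deg,
    truth = list(
      degs = degs,
      over = degs[sign < 0], # first-organ frame
      under = degs[sign > 0],
      coupled = coupled
    )
  )
}

#' Generate and write a complete synthetic dataset
#'
#' Runs every generator and writes the files a real analysis would start
#' from: `genome.fa` (when sequence is emitted), `genes.gff3`, per-sample
#' `<organ>_<rep>.bed` and `.bedGraph`, `manifest.tsv`, `deg.tsv`, and
#' ground-truth tables (`truth_cgis.tsv`, `truth_dmrs.tsv`,
#' `truth_degs.tsv`). Byte-identical under a fixed seed.
#'
#' @param cfg A `SyntheticConfig`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the in-memory objects (`genome`, `annotation`,
#'   `methylation`, `expression`, `truth`, `paths`).
#' @export
simulate_dataset <- function(cfg, dir) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_genome(cfg)
  ann <- generate_annotation(cfg, gen$genome)
  meth <- generate_methylation(cfg, gen$genome, ann)
  expr <- generate_expression(cfg, ann, meth$truth)
  paths <- list()
  if (!is.null(gen$genome$sequence)) {
    paths$genome <- file.path(dir, "genome.fa")
    write_genome_fasta(gen$genome, paths$genome)
  }
  paths$gff <- file.path(dir, "genes.gff3")
  write_gff(ann, paths$gff)
  manifest <- NULL
  for (nm in names(meth$samples)) {
    smp <- meth$samples[[nm]]
    bed <- file.path(dir, sprintf("%s_%s.bed", smp$organ, smp$replicate))
    bg <- file.path(dir, sprintf("%s_%s.bedGraph", smp$organ, smp$replicate))
    write_bed(smp$peaks, bed)
    writeLines(sprintf(
      "%s\t%d\t%d\t%.6g",
      smp$regions$chrom, smp$regions$start, smp$regions$end,
      smp$regions$score
    ), bg)
    manifest <- rbind(manifest, data.frame(
      path = basename(bed), organ = smp$organ, replicate = smp$replicate,
      bedgraph = basename(bg), stringsAsFactors = FALSE
    ))
  }
  paths$manifest <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, paths$manifest,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  paths$deg <- file.path(dir, "deg.tsv")
  write_deg_table(expr$deg, paths$deg)
  paths$truth_cgis <- file.path(dir, "truth_cgis.tsv")
  utils::write.table(gen$cgis, paths$truth_cgis,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  paths$truth_dmrs <- file.path(dir, "truth_dmrs.tsv")
  utils::write.table(meth$truth$dmrs, paths$truth_dmrs,
    sep = "\t",
    quote = FALSE, row.names = FALSE
  )
  paths$truth_degs <- file.path(dir, "truth_degs.tsv")
  utils::write.table(
    data.frame(
      gene_id = expr$truth$degs,
      direction = ifelse(expr$truth$degs %in% expr$truth$over,
        "over", "under"
      ),
      coupled = expr$truth$degs %in% expr$truth$coupled
    ),
    paths$truth_degs,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(list(
    genome = gen$genome, annotation = ann, methylation = meth,
    expression = expr,
    truth = list(
      cgis = gen$cgis, dmrs = meth$truth$dmrs,
      hyper = meth$truth$hyper, hypo = meth$truth$hypo,
      degs = expr$truth
    ),
    paths = paths
  ))
}
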
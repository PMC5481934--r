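# Readers/writers for the formats the pipeline touches (FASTA, BED, GFF3,
# bedGraph, DEG and manifest TSVs) plus the in-memory containers built on
# them. Internal coordinates are 0-based half-open everywhere; GFF3 (1-based
# inclusive) is converted on read and write so no other module ever handles
# two conventions.

#' Genome assembly container
#'
#' Holds the chromosome coordinate frame for the whole pipeline: ordered
#' chromosome names and lengths, optionally with nucleotide sequence (needed
#' only for CpG-island scanning).
#'
#' @param names Character vector of unique chromosome names.
#' @param lengths Integer vector of chromosome lengths in bp (> 0).
#' @param sequence Optional named [Biostrings::DNAStringSet] (or named
#'   character vector) with one entry per chromosome; widths must equal the
#'   declared lengths.
#' @return An object of class `GenomeAssembly`.
#' @examples
#' genome_assembly(c("chr1", "chr2"), c(1e5, 5e4))
#' @export
genome_assembly <- function(names, lengths, sequence = NULL) {
  names <- as.character(names)
  lengths <- as.integer(lengths)
  if (anyDuplicated(names)) {
    stop("chromosome names must be unique", call. = FALSE)
  }
  if (length(names) != length(lengths) || any(lengths <= 0)) {
    stop("each chromosome needs one positive length", call. = FALSE)
  }
  if (!is.null(sequence)) {
    if (is.character(sequence)) sequence <- Biostrings::DNAStringSet(sequence)
    if (!all(names %in% names(sequence))) {
      stop("sequence must be named by chromosome", call. = FALSE)
    }
    sequence <- sequence[names]
    if (!all(Biostrings::width(sequence) == lengths)) {
      stop("sequence widths must equal declared chromosome lengths",
        call. = FALSE
      )
    }
  }
  structure(
    list(
      chromosomes = data.frame(
        name = names, length = lengths,
        stringsAsFactors = FALSE
      ),
      sequence = sequence
    ),
    class = "GenomeAssembly"
  )
}

#' Chromosome lengths of an assembly
#'
#' @param genome A `GenomeAssembly`.
#' @return Named integer vector of lengths in bp.
#' @export
chrom_lengths <- function(genome) {
  stopifnot(inherits(genome, "GenomeAssembly"))
  stats::setNames(genome$chromosomes$length, genome$chromosomes$name)
}

#' Read a genome from FASTA
#'
#' @param path Path to a (multi-)FASTA file.
#' @return A `GenomeAssembly` with sequence.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  genome_assembly(names(seqs), Biostrings::width(seqs), seqs)
}

#' Write a genome to FASTA
#'
#' @param genome A `GenomeAssembly` with sequence.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  if (is.null(genome$sequence)) {
    stop("assembly carries no sequence", call. = FALSE)
  }
  Biostrings::writeXStringSet(genome$sequence, path)
  invisible(path)
}

#' Methylation peak set for one sample
#'
#' One sample's MBD-seq peaks (methylated regions) as genomic intervals with
#' organ and replicate labels. Peaks are stored sorted by (chrom, start);
#' they may abut or overlap.
#'
#' @param peaks data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param organ,replicate Sample labels.
#' @param genome Optional `GenomeAssembly` used to validate chromosome names
#'   and bounds.
#' @return An object of class `PeakSet`.
#' @export
peak_set <- function(peaks, organ, replicate, genome = NULL) {
  peaks <- as.data.frame(peaks)[, c("chrom", "start", "end")]
  peaks$chrom <- as.character(peaks$chrom)
  peaks$start <- as.integer(peaks$start)
  peaks$end <- as.integer(peaks$end)
  .validate_intervals(peaks, genome, what = "peak")
  peaks <- .sort_intervals(peaks)
  rownames(peaks) <- NULL
  structure(
    list(
      organ = as.character(organ), replicate = as.character(replicate),
      peaks = peaks
    ),
    class = "PeakSet"
  )
}

#' @export
print.PeakSet <- function(x, ...) {
  cat(sprintf(
    "PeakSet: %d peaks (%s, replicate %s)\n",
    nrow(x$peaks), x$organ, x$replicate
  ))
  invisible(x)
}

#' Read methylation peaks from BED
#'
#' Reads a >= 3 column tab-separated BED file of peak calls. BED is already
#' 0-based half-open, so coordinates are stored exactly as printed. Track
#' definition lines, comment lines and blank lines are skipped; every other
#' line must parse, and a malformed line fails with its line number.
#'
#' @inheritParams peak_set
#' @param path BED file path.
#' @return A `PeakSet`.
#' @export
read_bed <- function(path, organ, replicate, genome = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*$|^#|^track\\b|^browser\\b", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(peak_set(
      data.frame(chrom = character(), start = integer(), end = integer()),
      organ, replicate, genome
    ))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 3L)) {
    stop(sprintf(
      "BED parse error at line %d: fewer than 3 tab-separated fields",
      idx[which(n < 3L)[1]]
    ), call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop(sprintf(
      "BED parse error at line %d: non-integer coordinates", idx[bad[1]]
    ), call. = FALSE)
  }
  bad <- which(start >= end | start < 0)
  if (length(bad)) {
    stop(sprintf(
      "BED parse error at line %d: start >= end (%d >= %d)",
      idx[bad[1]], start[bad[1]], end[bad[1]]
    ), call. = FALSE)
  }
  peak_set(
    data.frame(
      chrom = chrom, start = start, end = end,
      stringsAsFactors = FALSE
    ),
    organ, replicate, genome
  )
}

#' Write peaks to BED
#'
#' Writes the bare 3-column layout; `write_bed(read_bed(f))` reproduces the
#' coordinate columns bit-exactly.
#'
#' @param x A `PeakSet` or a data.frame with `chrom`, `start`, `end`.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  df <- if (inherits(x, "PeakSet")) x$peaks else x
  writeLines(sprintf("%s\t%d\t%d", df$chrom, df$start, df$end), path)
  invisible(path)
}

#' Gene annotation container
#'
#' Gene bodies (CDS start to CDS end) with strand and exon structure; the
#' geometry source for promoter/intron/downstream classification and
#' metagene profiling.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`+`/`-`), `start`, `end` (gene body, 0-based half-open).
#' @param exons data.frame with columns `gene_id`, `chrom`, `start`, `end`;
#'   exons must be non-overlapping within a gene and contained in its body.
#'   Genes absent from `exons` get a single exon spanning the body.
#' @param genome Optional `GenomeAssembly` for bounds checking.
#' @return An object of class `GeneAnnotation`.
#' @export
gene_annotation <- function(genes, exons = NULL, genome = NULL) {
  genes <- as.data.frame(genes)[, c("gene_id", "chrom", "strand", "start", "end")]
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  genes$strand <- as.character(genes$strand)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (anyDuplicated(genes$gene_id)) {
    stop(sprintf(
      "duplicate gene_id: %s",
      genes$gene_id[anyDuplicated(genes$gene_id)]
    ), call. = FALSE)
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'", call. = FALSE)
  }
  .validate_intervals(genes, genome, what = "gene")
  if (is.null(exons) || nrow(exons) == 0L) {
    exons <- data.frame(
      gene_id = genes$gene_id, chrom = genes$chrom,
      start = genes$start, end = genes$end, stringsAsFactors = FALSE
    )
  } else {
    exons <- as.data.frame(exons)[, c("gene_id", "chrom", "start", "end")]
    exons$gene_id <- as.character(exons$gene_id)
    exons$chrom <- as.character(exons$chrom)
    exons$start <- as.integer(exons$start)
    exons$end <- as.integer(exons$end)
    .validate_intervals(exons, genome, what = "exon")
    orphan <- setdiff(exons$gene_id, genes$gene_id)
    if (length(orphan)) {
      stop(sprintf(
        "exon refers to unknown gene: %s", orphan[1]
      ), call. = FALSE)
    }
    # genes with no exon rows span their whole body
    missing <- setdiff(genes$gene_id, exons$gene_id)
    if (length(missing)) {
      m <- genes[match(missing, genes$gene_id), ]
      exons <- rbind(exons, data.frame(
        gene_id = m$gene_id, chrom = m$chrom, start = m$start, end = m$end,
        stringsAsFactors = FALSE
      ))
    }
    gi <- match(exons$gene_id, genes$gene_id)
    outside <- which(
      exons$chrom != genes$chrom[gi] |
        exons$start < genes$start[gi] | exons$end > genes$end[gi]
    )
    if (length(outside)) {
      e <- exons[outside[1], ]
      stop(sprintf(
        "exon [%d, %d) of gene %s lies outside the gene body",
        e$start, e$end, e$gene_id
      ), call. = FALSE)
    }
  }
  exons <- exons[order(exons$gene_id, exons$start), ]
  ov <- unlist(lapply(split(exons, exons$gene_id), function(e) {
    any(e$start[-1] < e$end[-nrow(e)])
  }))
  if (any(ov)) {
    stop(sprintf(
      "overlapping exons in gene %s", names(ov)[which(ov)[1]]
    ), call. = FALSE)
  }
  genes <- genes[order(genes$chrom, genes$start), ]
  rownames(genes) <- rownames(exons) <- NULL
  structure(list(genes = genes, exons = exons), class = "GeneAnnotation")
}

#' @export
print.GeneAnnotation <- function(x, ...) {
  cat(sprintf(
    "GeneAnnotation: %d genes, %d exons on %d chromosome(s)\n",
    nrow(x$genes), nrow(x$exons), length(unique(x$genes$chrom))
  ))
  invisible(x)
}

#' Per-gene intron intervals
#'
#' @param annotation A `GeneAnnotation`.
#' @return data.frame of introns (`gene_id`, `chrom`, `start`, `end`),
#'   0-based half-open; empty when every gene is single-exon.
#' @export
gene_introns <- function(annotation) {
  stopifnot(inherits(annotation, "GeneAnnotation"))
  out <- lapply(
    split(annotation$exons, annotation$exons$gene_id),
    function(e) {
      if (nrow(e) < 2L) {
        return(NULL)
      }
      data.frame(
        gene_id = e$gene_id[1], chrom = e$chrom[1],
        start = e$end[-nrow(e)], end = e$start[-1],
        stringsAsFactors = FALSE
      )
    }
  )
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(
      gene_id = character(), chrom = character(),
      start = integer(), end = integer()
    )
  }
  rownames(out) <- NULL
  out
}

#' Read a gene annotation from GFF3
#'
#' Parses `gene` and `exon` features (exons tied to their gene through the
#' `Parent` attribute, following the chain through intermediate features such
#' as mRNA when present). GFF3 1-based inclusive coordinates are converted
#' to the internal 0-based half-open frame (`start - 1`, `end`).
#'
#' @param path GFF3 file path.
#' @param genome Optional `GenomeAssembly` for bounds checking.
#' @return A `GeneAnnotation`.
#' @export
read_gff <- function(path, genome = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("GFF file not found: %s", path), call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parents <- vapply(
    as.list(gr$Parent),
    function(p) if (length(p)) p[[1]] else NA_character_, ""
  )
  is_gene <- type == "gene"
  if (!any(is_gene)) {
    return(gene_annotation(
      data.frame(
        gene_id = character(), chrom = character(), strand = character(),
        start = integer(), end = integer()
      ),
      genome = genome
    ))
  }
  # resolve each feature to its ancestral gene ID (exon -> mRNA -> gene)
  to_gene <- function(id) {
    seen <- character()
    while (!is.na(id) && !(id %in% ids[is_gene])) {
      if (id %in% seen) {
        return(NA_character_)
      }
      seen <- c(seen, id)
      j <- match(id, ids)
      id <- if (is.na(j)) NA_character_ else parents[j]
    }
    id
  }
  gdf <- data.frame(
    gene_id = ids[is_gene],
    chrom = as.character(GenomicRanges::seqnames(gr)[is_gene]),
    strand = as.character(BiocGenerics::strand(gr)[is_gene]),
    start = BiocGenerics::start(gr)[is_gene] - 1L,
    end = BiocGenerics::end(gr)[is_gene],
    stringsAsFactors = FALSE
  )
  gdf$strand[!gdf$strand %in% c("+", "-")] <- "+"
  is_exon <- type == "exon"
  edf <- NULL
  if (any(is_exon)) {
    parent_gene <- vapply(parents[is_exon], to_gene, "")
    if (anyNA(parent_gene)) {
      stop("exon without a resolvable parent gene", call. = FALSE)
    }
    edf <- data.frame(
      gene_id = parent_gene,
      chrom = as.character(GenomicRanges::seqnames(gr)[is_exon]),
      start = BiocGenerics::start(gr)[is_exon] - 1L,
      end = BiocGenerics::end(gr)[is_exon],
      stringsAsFactors = FALSE
    )
  }
  gene_annotation(gdf, edf, genome = genome)
}

#' Write a gene annotation to GFF3
#'
#' Emits gene and exon features, converting back to 1-based inclusive
#' coordinates, so `read_gff(write_gff(x))` preserves the printed
#' coordinates exactly.
#'
#' @param annotation A `GeneAnnotation`.
#' @param path Output path.
#' @param source Value for the GFF source column.
#' @export
write_gff <- function(annotation, path, source = "mbdpipe") {
  stopifnot(inherits(annotation, "GeneAnnotation"))
  g <- annotation$genes
  e <- annotation$exons
  glines <- sprintf(
    "%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
    g$chrom, source, g$start + 1L, g$end, g$strand, g$gene_id
  )
  strand <- g$strand[match(e$gene_id, g$gene_id)]
  elines <- sprintf(
    "%s\t%s\texon\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
    e$chrom, source, e$start + 1L, e$end, strand,
    paste0(e$gene_id, ".exon", stats::ave(e$start, e$gene_id, FUN = seq_along)),
    e$gene_id
  )
  # interleave so each gene precedes its exons
  ord <- order(match(e$gene_id, g$gene_id), e$start)
  writeLines(c("##gff-version 3", as.vector(rbind_interleave(
    glines, elines[ord], match(e$gene_id[ord], g$gene_id)
  ))), path)
  invisible(path)
}

#' @noRd
rbind_interleave <- function(gene_lines, exon_lines, exon_gene_idx) {
  out <- vector("list", length(gene_lines))
  sp <- split(exon_lines, factor(exon_gene_idx, levels = seq_along(gene_lines)))
  for (i in seq_along(gene_lines)) {
    out[[i]] <- c(gene_lines[i], sp[[i]])
  }
  unlist(out)
}

#' Read a differential-expression table
#'
#' Tab-separated with header columns `gene_id`, `logFC`, `FDR`. The sign
#' convention follows the source comparison (here: positive logFC means
#' over-expressed in the second organ, ovary).
#'
#' @param path TSV path.
#' @return data.frame with columns `gene_id`, `logFC`, `FDR`.
#' @export
read_deg_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_id", "logFC", "FDR")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(sprintf(
      "DEG table is missing column(s): %s", paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  df <- df[, need]
  if (anyDuplicated(df$gene_id)) {
    stop(sprintf(
      "duplicate gene_id in DEG table: %s",
      df$gene_id[anyDuplicated(df$gene_id)]
    ), call. = FALSE)
  }
  df$logFC <- as.numeric(df$logFC)
  df$FDR <- as.numeric(df$FDR)
  if (anyNA(df$logFC) || anyNA(df$FDR)) {
    stop("non-numeric logFC/FDR in DEG table", call. = FALSE)
  }
  if (any(df$FDR < 0 | df$FDR > 1)) {
    stop(sprintf(
      "FDR outside [0, 1] for gene %s", df$gene_id[which(df$FDR < 0 | df$FDR > 1)[1]]
    ), call. = FALSE)
  }
  df
}

#' Write a differential-expression table
#'
#' @param deg data.frame with `gene_id`, `logFC`, `FDR`.
#' @param path Output path.
#' @export
write_deg_table <- function(deg, path) {
  utils::write.table(deg[, c("gene_id", "logFC", "FDR")], path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read a sample manifest
#'
#' BED files carry no metadata, so organ/replicate labels come from a
#' manifest: a TSV with header columns `path`, `organ`, `replicate`.
#' Relative paths are resolved against the manifest's directory.
#'
#' @param path Manifest TSV path.
#' @param genome Optional `GenomeAssembly` for validation of each BED.
#' @return Named list of `PeakSet` (names `organ.replicate`).
#' @export
read_sample_manifest <- function(path, genome = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("path", "organ", "replicate")
  if (!all(need %in% names(df))) {
    stop("manifest needs columns path, organ, replicate", call. = FALSE)
  }
  base <- dirname(normalizePath(path))
  out <- lapply(seq_len(nrow(df)), function(i) {
    p <- df$path[i]
    if (!file.exists(p)) p <- file.path(base, df$path[i])
    read_bed(p, df$organ[i], df$replicate[i], genome)
  })
  names(out) <- paste(df$organ, df$replicate, sep = ".")
  out
}

#' @noRd
.check_peaksets <- function(peaksets, one_organ = TRUE) {
  stopifnot(length(peaksets) >= 1L)
  ok <- vapply(peaksets, inherits, TRUE, what = "PeakSet")
  if (!all(ok)) stop("expected a list of PeakSet objects", call. = FALSE)
  if (one_organ) {
    organs <- unique(vapply(peaksets, `[[`, "", "organ"))
    if (length(organs) != 1L) {
      stop("peak sets span multiple organs; pass one organ at a time",
        call. = FALSE
      )
    }
  }
  invisible(peaksets)
}
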
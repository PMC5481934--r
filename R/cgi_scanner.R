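# CpG-island detection from genome sequence. Islands are defined by three
# criteria -- length > 200 bp, GC fraction >= 0.5, observed/expected CpG
# ratio >= 0.6 -- applied through the classic sliding-window
# merge-and-trim scheme (Takai & Jones): mark passing 200-bp windows,
# merge overlapping/adjacent ones, then shrink each merged candidate
# symmetrically until its full extent passes both composition criteria.

#' GC fraction of a sequence
#'
#' `(#C + #G) / length`. `N` bases count in the denominator only, so
#' ambiguity can never certify GC content.
#'
#' @param seq A nucleotide string (character scalar or
#'   [Biostrings::DNAString]) over the alphabet A/C/G/T/N.
#' @return Fraction in `[0, 1]`.
#' @examples
#' gc_fraction("ACGTN") # 0.4
#' @export
gc_fraction <- function(seq) {
  seq <- .as_seq_string(seq)
  if (nchar(seq) == 0L) stop("empty sequence", call. = FALSE)
  counts <- Biostrings::letterFrequency(Biostrings::DNAString(seq), c("C", "G"))
  as.numeric(sum(counts)) / nchar(seq)
}

#' Observed/expected CpG ratio
#'
#' The Gardiner-Garden ratio `(N_CpG * L) / (N_C * N_G)`, where `N_CpG`
#' counts `CG` dinucleotides in the window of length `L`. Returns 0 when the
#' window contains no C or no G.
#'
#' @inheritParams gc_fraction
#' @return Non-negative ratio.
#' @examples
#' obs_exp_cpg("CCCGGG") # (1 * 6) / (3 * 3)
#' @export
obs_exp_cpg <- function(seq) {
  seq <- .as_seq_string(seq)
  if (nchar(seq) < 2L) {
    stop("sequence must have length >= 2", call. = FALSE)
  }
  s <- Biostrings::DNAString(seq)
  counts <- Biostrings::letterFrequency(s, c("C", "G"))
  n_c <- counts[[1]]
  n_g <- counts[[2]]
  if (n_c == 0 || n_g == 0) {
    return(0)
  }
  n_cg <- Biostrings::countPattern("CG", s)
  (as.numeric(n_cg) * nchar(seq)) / (as.numeric(n_c) * n_g)
}

#' @noRd
.as_seq_string <- function(seq) {
  seq <- toupper(as.character(seq))
  if (length(seq) != 1L) stop("expected a single sequence", call. = FALSE)
  if (grepl("[^ACGTN]", seq)) {
    stop("sequence contains characters outside A/C/G/T/N", call. = FALSE)
  }
  seq
}

#' Scan a genome for CpG islands
#'
#' Slides a `window_bp` window in 1-bp steps over each chromosome, marks
#' windows with GC fraction >= `min_gc` and observed/expected CpG >=
#' `min_oe` (windows containing `N` never pass), merges
#' overlapping/adjacent passing windows, trims each merged candidate one
#' base from both ends while its full extent fails either criterion, and
#' reports candidates whose final length is strictly greater than `min_len`
#' and that pass both criteria over their full extent. Output islands are
#' sorted and non-overlapping.
#'
#' @param genome A `GenomeAssembly` with sequence.
#' @param min_len Minimum island length in bp (strict: a `min_len`-bp
#'   region is rejected). Default 200.
#' @param min_gc Minimum GC fraction. Default 0.5.
#' @param min_oe Minimum observed/expected CpG ratio. Default 0.6.
#' @param window_bp Scanning window size; defaults to `min_len`.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `gc_fraction`, `obs_exp`.
#' @export
scan_cgis <- function(genome, min_len = 200L, min_gc = 0.5, min_oe = 0.6,
                      window_bp = min_len) {
  stopifnot(inherits(genome, "GenomeAssembly"))
  if (is.null(genome$sequence)) {
    stop("assembly carries no sequence; CpG islands need nucleotides",
      call. = FALSE
    )
  }
  out <- lapply(genome$chromosomes$name, function(chrom) {
    .scan_chromosome(
      as.character(genome$sequence[[chrom]]), chrom,
      min_len, min_gc, min_oe, window_bp
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @noRd
.scan_chromosome <- function(seq, chrom, min_len, min_gc, min_oe, window_bp) {
  empty <- data.frame(
    chrom = character(), start = integer(), end = integer(),
    gc_fraction = numeric(), obs_exp = numeric(), stringsAsFactors = FALSE
  )
  len <- nchar(seq)
  w <- as.integer(window_bp)
  if (len < w) {
    return(empty)
  }
  r <- charToRaw(toupper(seq))
  is_c <- r == as.raw(67L) # "C"
  is_g <- r == as.raw(71L) # "G"
  is_n <- r == as.raw(78L) # "N"
  cum_c <- c(0, cumsum(is_c))
  cum_g <- c(0, cumsum(is_g))
  cum_n <- c(0, cumsum(is_n))
  cg <- is_c[-len] & is_g[-1L]
  cum_cg <- c(0, cumsum(cg))

  # per-window counts, window starting at 1-based position i covers
  # [i, i + w - 1]; CG dinucleotides must start inside the window
  i <- seq_len(len - w + 1L)
  n_c <- cum_c[i + w] - cum_c[i]
  n_g <- cum_g[i + w] - cum_g[i]
  n_n <- cum_n[i + w] - cum_n[i]
  n_cg <- cum_cg[pmin(i + w - 1L, len)] - cum_cg[i]
  gc <- (n_c + n_g) / w
  oe <- ifelse(n_c > 0 & n_g > 0, n_cg * w / (n_c * n_g), 0)
  pass <- gc >= min_gc & oe >= min_oe & n_n == 0L
  if (!any(pass)) {
    return(empty)
  }

  cand <- IRanges::reduce(IRanges::IRanges(start = i[pass], width = w))
  stat <- function(a, b) {
    cl <- b - a + 1L
    cc <- cum_c[b + 1L] - cum_c[a]
    gg <- cum_g[b + 1L] - cum_g[a]
    ccg <- if (b > a) cum_cg[b] - cum_cg[a] else 0
    list(
      gc = (cc + gg) / cl,
      oe = if (cc > 0 && gg > 0) ccg * cl / (cc * gg) else 0
    )
  }
  rows <- lapply(seq_along(cand), function(k) {
    a <- IRanges::start(cand)[k]
    b <- IRanges::end(cand)[k]
    while (b - a + 1L > min_len) {
      s <- stat(a, b)
      if (s$gc >= min_gc && s$oe >= min_oe) {
        return(data.frame(
          chrom = chrom, start = a - 1L, end = b,
          gc_fraction = s$gc, obs_exp = s$oe, stringsAsFactors = FALSE
        ))
      }
      a <- a + 1L
      b <- b - 1L
    }
    NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) empty else out
}

#' Write CpG islands to TSV
#'
#' BED-like tab-separated table: chrom, start, end, gc_fraction, obs_exp.
#'
#' @param cgis data.frame from [scan_cgis()].
#' @param path Output path.
#' @export
write_cgi_table <- function(cgis, path) {
  utils::write.table(cgis, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}
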
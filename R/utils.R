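# Shared internal helpers: interval conversions and the row-wise t-test used
# by every replicate comparison in the pipeline.

# All user-facing coordinates in this package are 0-based half-open
# ([start, end), BED convention). IRanges is 1-based closed, so the shift
# happens in exactly one place: here.

#' @noRd
.as_iranges <- function(start, end) {
  IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end))
}

#' @noRd
.ranges_by_chrom <- function(df, chrom_names) {
  f <- factor(df$chrom, levels = chrom_names)
  sp <- split(seq_len(nrow(df)), f)
  lapply(sp, function(i) .as_iranges(df$start[i], df$end[i]))
}

#' @noRd
.iranges_to_df <- function(ir, chrom) {
  data.frame(
    chrom = rep(chrom, length(ir)),
    start = IRanges::start(ir) - 1L,
    end = IRanges::end(ir),
    stringsAsFactors = FALSE
  )
}

#' @noRd
.sort_intervals <- function(df) {
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

# Shared validation helper: every module consumes 0-based half-open
# intervals on chromosomes the assembly knows about.
#' @noRd
.validate_intervals <- function(df, genome = NULL, what = "interval") {
  stopifnot(is.data.frame(df), all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0L) {
    return(invisible(df))
  }
  bad <- which(df$start < 0 | df$start >= df$end)
  if (length(bad)) {
    stop(sprintf(
      "%s %d is invalid: start=%s end=%s (need 0 <= start < end)",
      what, bad[1], df$start[bad[1]], df$end[bad[1]]
    ), call. = FALSE)
  }
  if (!is.null(genome)) {
    lens <- chrom_lengths(genome)
    unknown <- setdiff(unique(df$chrom), names(lens))
    if (length(unknown)) {
      stop(sprintf(
        "unknown chromosome(s): %s", paste(unknown, collapse = ", ")
      ), call. = FALSE)
    }
    over <- which(df$end > lens[df$chrom])
    if (length(over)) {
      stop(sprintf(
        "%s %d extends past the end of %s (%d > %d)",
        what, over[1], df$chrom[over[1]], df$end[over[1]],
        lens[df$chrom[over[1]]]
      ), call. = FALSE)
    }
  }
  invisible(df)
}

#' Row-wise two-sample t-tests
#'
#' Computes a two-sided two-sample t-test for every row of two matrices with
#' matched rows (features) and replicate columns. Used for the per-chromosome
#' peak-density comparison, the methylated-CGI comparison and differential
#' methylation calling, which all reduce to the same replicate test.
#'
#' Rows where both groups have zero variance and equal means return `t = 0`,
#' `p = 1` (no evidence of difference rather than an error); zero variance
#' with unequal means returns `p = 0`.
#'
#' @param a,b Numeric matrices with the same number of rows; columns are
#'   replicates of group A and group B. Each group needs at least 2 columns.
#' @param var_equal If `TRUE` (default) the classic Student pooled-variance
#'   statistic is used; otherwise Welch's statistic with Satterthwaite
#'   degrees of freedom.
#' @return A data.frame with columns `mean_a`, `mean_b`, `t`, `df`, `p`.
#' @examples
#' row_t_test(matrix(c(1, 2, 3), 1), matrix(c(2, 3, 4), 1))
#' @export
row_t_test <- function(a, b, var_equal = TRUE) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  if (nrow(a) != nrow(b)) {
    stop("'a' and 'b' must have the same number of rows", call. = FALSE)
  }
  na <- ncol(a)
  nb <- ncol(b)
  if (na < 2L || nb < 2L) {
    stop("each group needs at least 2 replicate columns", call. = FALSE)
  }
  ma <- rowMeans(a)
  mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(se))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tt <- (ma - mb) / se
  p <- 2 * stats::pt(-abs(tt), df)
  degenerate <- se == 0
  if (any(degenerate)) {
    same <- degenerate & (ma == mb)
    tt[same] <- 0
    p[same] <- 1
    df[degenerate & !same] <- na + nb - 2
    p[degenerate & !same] <- 0
  }
  data.frame(mean_a = ma, mean_b = mb, t = tt, df = df, p = p)
}
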
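# Independent oracles: naive character-level reimplementations used to
# cross-check the vectorized production code. These deliberately share no
# code with the package.

.chars <- function(seq) strsplit(seq, "")[[1]]

naive_gc <- function(seq) {
  s <- .chars(seq)
  sum(s %in% c("C", "G")) / length(s)
}

naive_oe <- function(seq) {
  s <- .chars(seq)
  nc <- sum(s == "C")
  ng <- sum(s == "G")
  if (nc == 0 || ng == 0) {
    return(0)
  }
  ncg <- sum(s[-length(s)] == "C" & s[-1] == "G")
  ncg * length(s) / (nc * ng)
}

# Brute-force island scan: enumerate every window with substr, merge runs
# of passing windows, trim symmetrically, apply the strict length filter.
naive_scan <- function(seq, min_len = 200, min_gc = 0.5, min_oe = 0.6,
                       w = 200) {
  L <- nchar(seq)
  empty <- data.frame(start = integer(), end = integer())
  if (L < w) {
    return(empty)
  }
  passes <- function(win) {
    s <- .chars(win)
    !any(s == "N") && naive_gc(win) >= min_gc && naive_oe(win) >= min_oe
  }
  pass <- vapply(seq_len(L - w + 1), function(i) {
    passes(substr(seq, i, i + w - 1))
  }, TRUE)
  if (!any(pass)) {
    return(empty)
  }
  # merge overlapping/adjacent passing windows into candidates
  idx <- which(pass)
  brk <- c(0, which(diff(idx) > w), length(idx))
  out <- list()
  for (k in seq_len(length(brk) - 1)) {
    run <- idx[(brk[k] + 1):brk[k + 1]]
    a <- run[1]
    b <- run[length(run)] + w - 1
    while (b - a + 1 > min_len) {
      if (passes(substr(seq, a, b))) {
        out[[length(out) + 1]] <- data.frame(start = a - 1L, end = b)
        break
      }
      a <- a + 1
      b <- b - 1
    }
  }
  if (length(out)) do.call(rbind, out) else empty
}

# Per-base membership count of island coverage by a peak union.
naive_covered_fraction <- function(island_start, island_end, peaks) {
  covered <- logical(island_end - island_start)
  for (i in seq_len(nrow(peaks))) {
    lo <- max(peaks$start[i], island_start)
    hi <- min(peaks$end[i], island_end)
    if (lo < hi) covered[(lo - island_start + 1):(hi - island_start)] <- TRUE
  }
  mean(covered)
}

# Exhaustive enumeration of the overlap distribution of two uniform random
# subsets: every pair of subsets equally likely; population mean/sd.
enum_overlap_moments <- function(n_universe, n_a, n_b) {
  a <- utils::combn(n_universe, n_a)
  b <- utils::combn(n_universe, n_b)
  ma <- matrix(0L, ncol(a), n_universe)
  ma[cbind(rep(seq_len(ncol(a)), each = n_a), as.vector(a))] <- 1L
  mb <- matrix(0L, ncol(b), n_universe)
  mb[cbind(rep(seq_len(ncol(b)), each = n_b), as.vector(b))] <- 1L
  ov <- ma %*% t(mb)
  m <- mean(ov)
  list(mean = m, sd = sqrt(mean((ov - m)^2)))
}

# Benjamini-Hochberg step-up, written out directly.
naive_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}
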
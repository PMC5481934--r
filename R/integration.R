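# DMG x DEG integration: exact set intersection, the jackknife resampling
# null (repeatedly drawing two random gene subsets of the observed sizes
# from the universe and recording intersection sizes), its closed-form
# hypergeometric twin, and the four-way directional cross (hyper/hypo
# methylation vs over/under expression).

#' Gene universe
#'
#' The pool the jackknife test draws from: either an explicit set of gene
#' ids (e.g. every gene in the annotation) or a bare count when only the
#' universe size is known.
#'
#' @param x Character vector of unique gene ids, or a single positive
#'   integer (the universe size N).
#' @return List of class `GeneUniverse` with `ids` (possibly `NULL`) and
#'   `n`.
#' @export
gene_universe <- function(x) {
  if (is.numeric(x) && length(x) == 1L) {
    n <- as.integer(x)
    if (is.na(n) || n <= 0L) stop("universe size must be > 0", call. = FALSE)
    ids <- NULL
  } else {
    ids <- as.character(x)
    if (anyDuplicated(ids)) {
      stop("duplicate gene ids in universe", call. = FALSE)
    }
    n <- length(ids)
    if (n == 0L) stop("empty gene universe", call. = FALSE)
  }
  structure(list(ids = ids, n = n), class = "GeneUniverse")
}

#' @noRd
.universe <- function(x) {
  if (inherits(x, "GeneUniverse")) x else gene_universe(x)
}

#' Intersect two gene lists
#'
#' Exact set intersection; each list must be free of internal duplicates.
#'
#' @param list_a,list_b Character vectors of gene ids.
#' @return Character vector of shared ids.
#' @export
intersect_genes <- function(list_a, list_b) {
  if (anyDuplicated(list_a)) {
    stop("duplicate ids in first list", call. = FALSE)
  }
  if (anyDuplicated(list_b)) {
    stop("duplicate ids in second list", call. = FALSE)
  }
  intersect(list_a, list_b)
}

#' Closed-form moments of a random two-list overlap
#'
#' For two independent uniform random subsets of sizes `n_a` and `n_b`
#' drawn without replacement from a universe of `n_universe` genes, the
#' intersection size is hypergeometric with mean `n_a * n_b / N` and
#' sd `sqrt(mean * (N - n_a)/N * (N - n_b)/(N - 1))` -- the analytic twin
#' of the jackknife simulation.
#'
#' @param n_a,n_b Subset sizes, `0 <= n_a, n_b <= n_universe`.
#' @param n_universe Universe size N (> 0).
#' @return List with `mean` and `sd`.
#' @examples
#' hypergeometric_oracle(4, 5, 10) # mean 2, sd 0.8165
#' @export
hypergeometric_oracle <- function(n_a, n_b, n_universe) {
  n <- as.numeric(n_universe)
  if (length(n) != 1L || is.na(n) || n <= 0) {
    stop("universe size must be > 0", call. = FALSE)
  }
  if (n_a < 0 || n_b < 0 || n_a > n || n_b > n) {
    stop("need 0 <= n_a, n_b <= n_universe", call. = FALSE)
  }
  m <- n_a * n_b / n
  v <- if (n > 1) m * (n - n_a) / n * (n - n_b) / (n - 1) else 0
  list(mean = m, sd = sqrt(v))
}

#' Jackknife overlap test
#'
#' Each simulation draws two independent uniform random subsets of sizes
#' `n_a` and `n_b` (without replacement) from the universe and records
#' their intersection size. The observed overlap is judged against the
#' simulated distribution: `p_empirical = (1 + #\{sim >= observed\}) /
#' (n_sims + 1)` (one-sided, enrichment) and `p_gauss` the two-sided normal
#' tail of `z = (observed - sim_mean) / sim_sd`. With
#' `method = "hypergeometric"` (default) the intersection sizes are drawn
#' directly from their exact distribution, which is distributionally
#' identical to materializing the two subsets and far faster; `"subset"`
#' materializes the subsets.
#'
#' @param n_a,n_b Sizes of the two gene lists.
#' @param universe A `GeneUniverse`, a gene-id vector, or an integer N.
#' @param observed Observed intersection size, `<= min(n_a, n_b)`.
#' @param n_sims Number of simulations (default 100,000).
#' @param seed Optional integer seed; fixed seed gives a bit-identical
#'   result.
#' @param method Simulation engine, see above.
#' @return List of class `OverlapTestResult`: `n_a`, `n_b`, `n_universe`,
#'   `observed`, `sim_mean`, `sim_sd` (sample SD), `p_empirical`,
#'   `p_gauss`, `z`, `n_sims`, `seed`, `method`.
#' @export
jackknife_test <- function(n_a, n_b, universe, observed, n_sims = 100000L,
                           seed = NULL,
                           method = c("hypergeometric", "subset")) {
  method <- match.arg(method)
  u <- .universe(universe)
  n <- u$n
  if (n_a > n || n_b > n) {
    stop("list size exceeds the universe size", call. = FALSE)
  }
  if (observed > min(n_a, n_b) || observed < 0) {
    stop("observed overlap must lie in [0, min(n_a, n_b)]", call. = FALSE)
  }
  if (n_sims < 1L) stop("n_sims must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  sims <- if (method == "hypergeometric") {
    # conditioned on the first subset, the overlap with the second is
    # exactly hypergeometric; sampling it directly skips materializing the
    # subsets
    stats::rhyper(n_sims, m = n_a, n = n - n_a, k = n_b)
  } else {
    vapply(seq_len(n_sims), function(i) {
      length(intersect(sample.int(n, n_a), sample.int(n, n_b)))
    }, 0L)
  }
  sim_mean <- mean(sims)
  sim_sd <- stats::sd(sims)
  z <- if (sim_sd > 0) (observed - sim_mean) / sim_sd else NA_real_
  p_gauss <- if (is.na(z)) {
    if (observed == sim_mean) 1 else 0
  } else {
    2 * stats::pnorm(-abs(z))
  }
  structure(
    list(
      n_a = n_a, n_b = n_b, n_universe = n, observed = observed,
      sim_mean = sim_mean, sim_sd = sim_sd,
      p_empirical = (1 + sum(sims >= observed)) / (n_sims + 1),
      p_gauss = p_gauss, z = z,
      n_sims = as.integer(n_sims), seed = seed, method = method
    ),
    class = "OverlapTestResult"
  )
}

#' @export
print.OverlapTestResult <- function(x, ...) {
  cat(sprintf(
    paste0(
      "OverlapTestResult: observed %d vs simulated %.2f +/- %.2f ",
      "(n_a=%d, n_b=%d, N=%d, %s sims=%d)\n",
      "  p_empirical=%.3g  p_gauss=%.3g\n"
    ),
    x$observed, x$sim_mean, x$sim_sd, x$n_a, x$n_b, x$n_universe,
    x$method, x$n_sims, x$p_empirical, x$p_gauss
  ))
  invisible(x)
}

#' Split a DEG table into over/under-expressed lists
#'
#' Thresholds on FDR and splits by logFC sign. The table's sign convention
#' is "positive logFC = over-expressed in ovary" (the second organ of the
#' source comparison); `frame` selects which organ's point of view the
#' over/under labels take.
#'
#' @param deg data.frame from [read_deg_table()].
#' @param fdr_threshold Keep genes with `FDR < fdr_threshold`.
#' @param frame `"ovary"` (positive logFC = over) or `"hypothalamus"`
#'   (negative logFC = over).
#' @return List with character vectors `over` and `under`.
#' @export
split_deg_directions <- function(deg, fdr_threshold = 0.001,
                                 frame = c("ovary", "hypothalamus")) {
  frame <- match.arg(frame)
  sig <- deg[deg$FDR < fdr_threshold & deg$logFC != 0, , drop = FALSE]
  pos <- sig$gene_id[sig$logFC > 0]
  neg <- sig$gene_id[sig$logFC < 0]
  if (frame == "ovary") list(over = pos, under = neg) else list(over = neg, under = pos)
}

#' Directional methylation-expression correlation
#'
#' Crosses the hyper/hypo-methylated gene lists with the over/under
#' expressed lists (four pairings) and runs the jackknife overlap test on
#' each. Hyper x over and hypo x under are the positive-correlation
#' pairings; hyper x under and hypo x over the negative-correlation ones.
#' The two methylation lists must be disjoint, as must the two expression
#' lists. A pairing is flagged enriched when `p_empirical < p_flag`, and
#' depleted when the observed overlap falls below the simulated mean with
#' `p_gauss < p_flag`.
#'
#' @param dmg_hyper,dmg_hypo Gene lists by methylation direction.
#' @param deg_over,deg_under Gene lists by expression direction.
#' @param universe A `GeneUniverse`, gene-id vector, or integer N.
#' @param n_sims Simulations per pairing (default 100,000).
#' @param seed Optional master seed; pairing `i` uses `seed + i`.
#' @param method Passed to [jackknife_test()].
#' @param p_flag Flagging threshold. Default 1e-3.
#' @return data.frame with one row per pairing: `pairing`, `correlation`,
#'   `n_dmg`, `n_deg`, `observed`, `sim_mean`, `sim_sd`, `p_empirical`,
#'   `p_gauss`, `z`, `enriched`, `depleted`.
#' @export
directional_correlation <- function(dmg_hyper, dmg_hypo, deg_over, deg_under,
                                    universe, n_sims = 100000L, seed = NULL,
                                    method = c("hypergeometric", "subset"),
                                    p_flag = 1e-3) {
  method <- match.arg(method)
  if (length(intersect(dmg_hyper, dmg_hypo))) {
    stop("hyper- and hypo-methylated lists overlap", call. = FALSE)
  }
  if (length(intersect(deg_over, deg_under))) {
    stop("over- and under-expressed lists overlap", call. = FALSE)
  }
  u <- .universe(universe)
  if (!is.null(u$ids)) {
    all_ids <- c(dmg_hyper, dmg_hypo, deg_over, deg_under)
    stray <- setdiff(all_ids, u$ids)
    if (length(stray)) {
      stop(sprintf(
        "gene(s) outside the universe: %s",
        paste(utils::head(stray, 3), collapse = ", ")
      ), call. = FALSE)
    }
  }
  pairs <- list(
    hyper_over = list(dmg_hyper, deg_over, "positive"),
    hypo_under = list(dmg_hypo, deg_under, "positive"),
    hyper_under = list(dmg_hyper, deg_under, "negative"),
    hypo_over = list(dmg_hypo, deg_over, "negative")
  )
  rows <- lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    obs <- length(intersect_genes(pr[[1]], pr[[2]]))
    res <- jackknife_test(
      length(pr[[1]]), length(pr[[2]]), u, obs,
      n_sims = n_sims,
      seed = if (is.null(seed)) NULL else as.integer(seed) + i,
      method = method
    )
    data.frame(
      pairing = names(pairs)[i], correlation = pr[[3]],
      n_dmg = res$n_a, n_deg = res$n_b, observed = res$observed,
      sim_mean = res$sim_mean, sim_sd = res$sim_sd,
      p_empirical = res$p_empirical, p_gauss = res$p_gauss, z = res$z,
      enriched = res$p_empirical < p_flag,
      depleted = !is.na(res$z) & res$z < 0 & res$p_gauss < p_flag,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
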
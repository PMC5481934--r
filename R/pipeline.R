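# Stage orchestration: runs the analysis stages in order over a single
# config (YAML file or R list), writing one TSV per stage plus a run log
# recording versions, seed and parameters. Stages are pure functions of
# (inputs, parameters, seed) and are independently invocable through the
# exported stage functions.

#' Read a pipeline run configuration
#'
#' YAML with input paths (`genome_fasta`, `gff`, `manifest`, `deg_table`),
#' `out_dir`, and optional `params` overriding stage defaults
#' (`promoter_bp`, `downstream_bp`, `distal_bp`, `cgi_threshold`, `alpha`,
#' `n_sims`, `seed`, `universe_n`, `dmg_fdr`, `deg_fdr`, `frame`).
#'
#' @param path YAML file path.
#' @return Config list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' @noRd
.pipeline_defaults <- function() {
  list(
    promoter_bp = 2000L, downstream_bp = 2000L, distal_bp = 10000L,
    cgi_threshold = 0.9, alpha = 0.05, n_sims = 100000L, seed = 1L,
    universe_n = NULL, deg_fdr = 0.001, frame = "hypothalamus"
  )
}

#' Run the full analysis pipeline
#'
#' Executes scan-cgi, annotate-peaks, chrom-density, metagene, cgi-meth,
#' call-dmrs and integrate over the configured inputs, writing one TSV per
#' stage into `out_dir` plus `run_log.txt`. Any stage failure aborts with
#' the stage name and cause. Identical config + seed gives identical
#' outputs.
#'
#' @param config A config list (see [read_run_config()]) or a YAML path.
#' @param stages Character vector of stages to run (default: all, in
#'   order).
#' @return Invisibly, a named list of per-stage results.
#' @export
run_pipeline <- function(config,
                         stages = c(
                           "scan_cgi", "annotate_peaks", "chrom_density",
                           "metagene", "cgi_meth", "call_dmrs", "integrate"
                         )) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  params <- utils::modifyList(.pipeline_defaults(), config$params %||% list())
  out_dir <- config$out_dir %||% stop("config needs out_dir", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
        call. = FALSE
      )
    })
  }
  log_path <- file.path(out_dir, "run_log.txt")
  cat(
    sprintf("mbdpipe %s | R %s\n", utils::packageVersion("mbdpipe"), getRversion()),
    sprintf("date: %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("seed: %d\n", params$seed),
    "params:\n",
    paste(sprintf(
      "  %s: %s", names(params),
      vapply(params, function(p) paste(format(p), collapse = ","), "")
    ), collapse = "\n"), "\n",
    file = log_path, sep = ""
  )
  results <- list()

  genome <- stage("load_genome", {
    if (is.null(config$genome_fasta)) {
      stop("config needs genome_fasta", call. = FALSE)
    }
    read_genome_fasta(config$genome_fasta)
  })
  annotation <- stage("load_annotation", {
    if (is.null(config$gff)) stop("config needs gff", call. = FALSE)
    read_gff(config$gff, genome)
  })
  samples <- stage("load_samples", {
    if (is.null(config$manifest)) stop("config needs manifest", call. = FALSE)
    read_sample_manifest(config$manifest, genome)
  })
  organs <- unique(vapply(samples, `[[`, "", "organ"))
  if (length(organs) != 2L) {
    stop(sprintf(
      "manifest must cover exactly two organs (found: %s)",
      paste(organs, collapse = ", ")
    ), call. = FALSE)
  }
  by_organ <- lapply(organs, function(o) {
    samples[vapply(samples, function(s) s$organ == o, TRUE)]
  })
  names(by_organ) <- organs
  cfg <- region_config(params$promoter_bp, params$downstream_bp, params$distal_bp)
  masks <- region_masks(annotation, genome, cfg)
  tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }

  if ("scan_cgi" %in% stages) {
    results$cgis <- stage("scan_cgi", scan_cgis(genome))
    tsv(results$cgis, "cgis.tsv")
  }
  if ("annotate_peaks" %in% stages) {
    results$region_density <- stage("annotate_peaks", {
      do.call(rbind, lapply(organs, function(o) {
        cbind(
          organ = o,
          region_density(by_organ[[o]], annotation, genome, cfg, masks)
        )
      }))
    })
    tsv(results$region_density, "region_density.tsv")
  }
  if ("chrom_density" %in% stages) {
    results$chrom_density <- stage("chrom_density", {
      list(
        ratios = do.call(rbind, lapply(organs, function(o) {
          chromosome_density(by_organ[[o]], genome)
        })),
        test = compare_chromosome_density(
          by_organ[[1]], by_organ[[2]], genome
        )
      )
    })
    tsv(results$chrom_density$ratios, "chromosome_density.tsv")
    tsv(results$chrom_density$test, "chromosome_density_test.tsv")
  }
  if ("metagene" %in% stages) {
    results$metagene <- stage("metagene", {
      prof <- lapply(organs, function(o) {
        tracks <- lapply(by_organ[[o]], depth_from_peaks, genome = genome)
        vals <- rowMeans(vapply(
          tracks,
          function(tr) metagene_profile(tr, annotation, genome)$values,
          numeric(80)
        ))
        data.frame(organ = o, window = 1:80, value = vals)
      })
      do.call(rbind, prof)
    })
    tsv(results$metagene, "metagene.tsv")
  }
  if ("cgi_meth" %in% stages) {
    results$cgi_meth <- stage("cgi_meth", {
      if (is.null(results$cgis)) results$cgis <- scan_cgis(genome)
      calls <- lapply(organs, function(o) {
        call_methylated(results$cgis, by_organ[[o]], params$cgi_threshold)
      })
      names(calls) <- organs
      list(
        calls = calls,
        rates = vapply(calls, methylation_rate, 0),
        test = compare_cgi_methylation(calls[[1]], calls[[2]], genome)
      )
    })
    tsv(results$cgi_meth$test, "cgi_methylation_test.tsv")
  }
  if ("call_dmrs" %in% stages || "integrate" %in% stages) {
    results$dmr <- stage("call_dmrs", {
      regions <- candidate_regions(samples)
      tracks <- lapply(samples, depth_from_peaks, genome = genome)
      mat <- depth_matrix(regions, tracks, genome)
      dmrs <- call_dmrs(regions, mat,
        groups = vapply(samples, `[[`, "", "organ"),
        alpha = params$alpha
      )
      list(dmrs = dmrs, dmgs = dmrs_to_dmgs(dmrs, annotation))
    })
    tsv(results$dmr$dmrs, "dmrs.tsv")
    tsv(results$dmr$dmgs$genes, "dmgs.tsv")
  }
  if ("integrate" %in% stages) {
    results$integration <- stage("integrate", {
      if (is.null(config$deg_table)) {
        stop("config needs deg_table for the integrate stage", call. = FALSE)
      }
      deg <- read_deg_table(config$deg_table)
      frame <- params$frame
      degsplit <- split_deg_directions(deg, params$deg_fdr, frame = frame)
      genes <- results$dmr$dmgs$genes
      universe <- if (is.null(params$universe_n)) {
        gene_universe(annotation$genes$gene_id)
      } else {
        gene_universe(params$universe_n)
      }
      hyper <- unique(genes$gene_id[genes$direction == frame])
      hypo <- unique(genes$gene_id[genes$direction != frame])
      shared <- intersect(hyper, hypo) # tie genes carry no usable direction
      hyper <- setdiff(hyper, shared)
      hypo <- setdiff(hypo, shared)
      directional_correlation(
        hyper, hypo, degsplit$over, degsplit$under, universe,
        n_sims = params$n_sims, seed = params$seed
      )
    })
    tsv(results$integration, "integration.tsv")
  }
  cat("status: complete\n", file = log_path, append = TRUE)
  invisible(results)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
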
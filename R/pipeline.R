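#' Run the full pipeline
#'
#' Orchestrates the stages annotate -> count -> filter -> cluster (or
#' simulate -> cluster) -> evaluate, persisting intermediates in a run
#' directory. Every stage is a pure function of its inputs, the
#' configuration and the seed, so re-running with identical inputs gives
#' identical outputs. A structured log line records counts in/out per
#' stage; a failure leaves partial outputs plus a `FAILED` marker file.
#'
#' @param config A list with either `simulate` (a [sim_config()]) or the
#'   file inputs `sv` (path), `bam` (path) and optionally `cn` (path) +
#'   `cn_dialect`; always: `purity` (required), and optionally `ploidy`,
#'   `seed`, `model` (a [model_config()]), `counting` (a
#'   [count_params()]), `filtering` (a [filter_params()]), `meta` (a full
#'   [sample_meta()] overriding purity/ploidy).
#' @param out_dir Run directory (created).
#' @return Invisibly, a list with the fit, the variant table and (when
#'   simulating) the evaluation metrics.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.null(config$purity) && is.null(config$meta) &&
      is.null(config$simulate))
    stop("config validation failed: purity is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "pipeline.log")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "",
                                file = logf, append = TRUE)
  on_fail <- function(e) {
    writeLines(conditionMessage(e), file.path(out_dir, "FAILED"))
    stop(e)
  }
  tryCatch({
    seed <- if (!is.null(config$seed)) config$seed else 1
    mcfg <- if (!is.null(config$model)) config$model else model_config(seed = seed)
    truth <- NULL
    if (!is.null(config$simulate)) {
      sim <- simulate_counts(config$simulate, seed = seed)
      variants <- sim$variants
      truth <- sim$truth
      meta <- sample_meta(purity = config$simulate$purity,
                          ploidy = config$simulate$ploidy,
                          expected_depth = config$simulate$depth,
                          error_rate = config$simulate$eps)
      log_line("stage=simulate n_out=%d seed=%d", nrow(variants), seed)
    } else {
      meta <- if (!is.null(config$meta)) config$meta
      else sample_meta(purity = config$purity,
                       ploidy = if (!is.null(config$ploidy)) config$ploidy else 2)
      bp <- read_sv_input(config$sv)
      log_line("stage=annotate n_in=%d", nrow(bp))
      bp <- resolve_mixed(bp)
      bp <- classify_all(bp)
      log_line("stage=annotate n_out=%d", nrow(bp))
      cparams <- if (!is.null(config$counting)) config$counting else count_params()
      counts <- count_svs(bp, config$bam, meta, cparams)
      counts <- adjust_normals(counts, meta)
      counts <- compute_vaf(counts)
      log_line("stage=count n_out=%d", nrow(counts))
      cn_map <- if (!is.null(config$cn))
        read_cn_input(config$cn,
                      if (!is.null(config$cn_dialect)) config$cn_dialect
                      else "battenberg")
      else NULL
      fparams <- if (!is.null(config$filtering)) config$filtering else filter_params()
      flt <- apply_filters(counts, cn_map, meta, fparams)
      .write_tsv(flt$rejected, file.path(out_dir, "rejected_svs.tsv"))
      variants <- flt$kept
      log_line("stage=filter n_in=%d n_kept=%d n_rejected=%d",
               nrow(counts), nrow(variants), nrow(flt$rejected))
    }
    fit <- fit_ccf_clusters(variants, meta, mcfg)
    log_line("stage=cluster n=%d K=%d elbo=%.4f", nrow(variants), fit$K,
             fit$elbo)
    write_results(fit, out_dir)
    metrics <- NULL
    if (!is.null(truth)) {
      metrics <- evaluate_fit(truth, fit)
      .write_tsv(data.frame(metric = names(metrics)[1:6],
                            value = unlist(metrics[1:6])),
                 file.path(out_dir, "metrics.tsv"))
      log_line("stage=evaluate cluster_number_error=%d",
               metrics$cluster_number_error)
    }
    invisible(list(fit = fit, variants = variants, metrics = metrics))
  }, error = on_fail)
}
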
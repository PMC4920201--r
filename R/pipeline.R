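#' Validate a run configuration
#'
#' Checks paths and numeric ranges, aggregating all problems instead of
#' failing on the first.
#'
#' @param config a named list (see [run_pipeline()] for recognized fields)
#' @return character vector of error messages; empty when the config is valid
#' @export
validate_config <- function(config) {
  errs <- character(0)
  add <- function(msg) errs <<- c(errs, msg)
  if (is.null(config$genes)) add("missing 'genes' path")
  else if (!file.exists(config$genes))
    add(sprintf("genes file not found: %s", config$genes))
  if (is.null(config$samples)) add("missing 'samples' path")
  else if (!file.exists(config$samples))
    add(sprintf("samples file not found: %s", config$samples))
  if (is.null(config$out_dir)) add("missing 'out_dir'")
  num_in <- function(field, lo, hi, lo_open = TRUE) {
    v <- config[[field]]
    if (is.null(v)) return(invisible())
    bad <- !is.numeric(v) || length(v) != 1 || !is.finite(v) ||
      (if (lo_open) v <= lo else v < lo) || v > hi
    if (bad) add(sprintf("%s out of range (%g, %g]: %s", field, lo, hi,
                         paste(v, collapse = ",")))
  }
  num_in("beta", 0, 1 - 1e-12)
  num_in("pseudocount", 0, Inf)
  num_in("cap", 0, Inf)
  num_in("fold", 1, Inf)
  num_in("bin_size", 0, Inf)
  num_in("min_length", 0, Inf, lo_open = FALSE)
  num_in("expressed_threshold", 0, Inf, lo_open = FALSE)
  errs
}

default_config <- function() {
  list(cap = 30000, min_interval = 300, expressed_threshold = 0.5,
       pseudocount = 0.1, fold = 2, bin_size = 1000, min_length = 200000,
       beta = 0.25, noise_floor = 0, test = "wilcoxon", seed = 1L)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: quantification (TSS-proximal RPKM matrix and expressed
#' filter), response classification (log2 fold changes vs starved, temporal
#' pattern calls, heat-map ordering, count summary), and wave-front
#' elongation analysis on long responders. All tabular outputs are TSVs with
#' '#'-prefixed header lines; a provenance block (config echo, config hash,
#' package version, seed) is written alongside.
#'
#' @param config named list: `genes` (BED6), `samples` (sample sheet TSV),
#'   `out_dir`, plus optional stage parameters `cap`, `min_interval`,
#'   `expressed_threshold`, `pseudocount`, `fold`, `bin_size`, `min_length`,
#'   `beta`, `noise_floor`, `round_to`, `test`, `top_n`, `seed`
#' @return invisibly, a list with the in-memory stage results and output
#'   paths
#' @export
run_pipeline <- function(config) {
  config <- utils::modifyList(default_config(), config)
  errs <- validate_config(config)
  if (length(errs))
    stopf("invalid configuration:\n- %s", paste(errs, collapse = "\n- "))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    log[[name]] <<- list(seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }

  genes <- stage("read_genes", read_genes(config$genes))
  covset <- stage("read_coverage", read_coverage_set(config$samples))

  mat <- stage("quantify",
               quantify(genes, covset, cap = config$cap,
                        min_interval = config$min_interval))
  expressed <- expressed_filter(mat, threshold = config$expressed_threshold)
  log$quantify$genes_in <- nrow(genes)
  log$quantify$genes_quantified <- nrow(mat)
  log$quantify$expressed <- length(expressed)
  write_tsv_hash(mat, file.path(out, "expression.tsv"))

  emat <- mat[mat$gene_id %in% expressed, , drop = FALSE]
  calls <- NULL; counts <- NULL
  if (nrow(emat)) {
    fc <- stage("log2fc", log2fc(emat, pseudocount = config$pseudocount))
    calls <- stage("classify",
                   classify_genes(fc, fold = config$fold,
                                  expressed_threshold = config$expressed_threshold))
    counts <- summarize_counts(calls)
    hm <- order_for_heatmap(calls, fc)
    log$classify$responders <- sum(calls$direction != "none")
    write_tsv_hash(calls, file.path(out, "calls.tsv"))
    write_tsv_hash(counts, file.path(out, "counts.tsv"))
    write_tsv_hash(hm, file.path(out, "heatmap_matrix.tsv"))
  } else {
    warnf("no expressed genes; classification and wave-front stages skipped")
  }

  wf <- NULL
  if (!is.null(calls) && any(calls$direction %in% c("induced", "repressed"))) {
    wf <- stage("wavefront",
                wavefront_analysis(covset, genes, calls,
                                   min_length = config$min_length,
                                   bin_size = config$bin_size,
                                   params = front_params(
                                     beta = config$beta,
                                     noise_floor = config$noise_floor),
                                   round_to = config$round_to,
                                   test = config$test,
                                   top_n = config$top_n))
    write_tsv_hash(wf$fronts, file.path(out, "fronts.tsv"))
    write_tsv_hash(wf$estimates, file.path(out, "estimates.tsv"))
    per <- do.call(rbind, lapply(names(wf$stats), function(m)
      cbind(mode = m, wf$stats[[m]]$per_interval)))
    cmp <- do.call(rbind, lapply(names(wf$stats), function(m)
      cbind(mode = m, wf$stats[[m]]$comparisons)))
    if (!is.null(per)) write_tsv_hash(per, file.path(out, "cohort_stats.tsv"))
    if (!is.null(cmp)) write_tsv_hash(cmp, file.path(out, "comparisons.tsv"))
    jsonlite::write_json(wf$stats, file.path(out, "cohort_stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  cfg_path <- file.path(out, "config.json")
  cfg_ser <- config[order(names(config))]
  jsonlite::write_json(cfg_ser, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  prov <- list(config_hash = unname(tools::md5sum(cfg_path)),
               package = "bruwave",
               version = as.character(utils::packageVersion("bruwave")),
               seed = config$seed,
               stages = log)
  jsonlite::write_json(prov, file.path(out, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(expression = mat, expressed = expressed, calls = calls,
                 counts = counts, wavefront = wf, log = log,
                 out_dir = out))
}
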
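#' Build a simulation scenario from a plain-text config
#'
#' The config (JSON) may list genes explicitly under `genes` and/or in
#' `blocks`, a shorthand that lays out `n` genes of one pattern side by side
#' on a dedicated chromosome with a fixed gap. Fields per block: `prefix`,
#' `n`, `pattern`, `length`, `baseline_rate`, `fold`, `onset_time`,
#' `off_time`, `epoch_rates`/`change_times`, `rate_kb_min` (scalar or vector
#' with `seg_lengths`), `strand`, `gap`.
#'
#' @param config path to a JSON file, or an equivalent named list
#' @param seed overrides the config's seed when non-NULL
#' @param noise overrides the config's noise model when non-NULL
#' @return a [sim_scenario()]
#' @export
scenario_from_config <- function(config, seed = NULL, noise = NULL) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = FALSE)
  scheme <- if (!is.null(config$scheme)) {
    labeling_scheme(unlist(config$scheme$starts), unlist(config$scheme$ends),
                    unlist(config$scheme$names))
  } else labeling_scheme()
  genes <- list()
  for (gdef in config$genes %||% list()) genes <- c(genes, list(gene_from_def(gdef)))
  for (b in config$blocks %||% list()) genes <- c(genes, block_genes(b))
  sim_scenario(genes, scheme = scheme,
               bin_size = config$bin_size %||% 1000,
               read_depth = config$read_depth %||% 1,
               noise = noise %||% (config$noise %||% "poisson"),
               seed = seed %||% (config$seed %||% 1L),
               library_size = config$library_size)
}

gene_from_def <- function(g) {
  init <- do.call(init_profile, lapply(g$init, unlist))
  elong <- if (!is.null(g$elong))
    elongation_profile(unlist(g$elong$lengths_bp), unlist(g$elong$rates_kb_min))
  else NULL
  sim_gene(g$gene_id, g$chrom, g$start, g$end, g$strand, init, elong)
}

block_genes <- function(b) {
  n <- b$n %||% 1
  len <- b$length %||% 12000
  gap <- b$gap %||% 10000
  strand <- b$strand %||% "+"
  chrom <- b$chrom %||% paste0("chr_", b$prefix)
  rates <- unlist(b$rate_kb_min %||% 2.0)
  seg_lengths <- unlist(b$seg_lengths %||% len)
  if (length(rates) == 1) seg_lengths <- len
  lapply(seq_len(n), function(i) {
    start <- (i - 1) * (len + gap)
    init <- init_profile(
      baseline_rate = b$baseline_rate %||% 0.5,
      pattern = b$pattern %||% "constant",
      fold = b$fold %||% 3,
      onset_time = b$onset_time %||% 0,
      off_time = b$off_time %||% 30,
      change_times = unlist(b$change_times),
      fold_factors = unlist(b$fold_factors),
      epoch_rates = unlist(b$epoch_rates))
    sim_gene(paste0(b$prefix, "_", i), chrom, start, start + len, strand,
             init, elongation_profile(seg_lengths, rates))
  })
}

#' The shipped default scenario
#'
#' A compact serum-response world: three genes for each of the eight
#' temporal initiation patterns (12-kb genes, baseline 0.5 initiations/min,
#' 3-fold effects, 2 kb/min) for the classification stages, plus three long
#' (300-kb) silent genes switched on at t = 0 and three long active genes
#' shut off at t = 0 (2 initiations/min, 2 kb/min) for the wave-front
#' stage. Poisson noise, read depth 1 (about 60 reads per kb of plateau).
#'
#' @param seed master seed
#' @param noise "poisson" or "none"
#' @return a [sim_scenario()]
#' @export
default_scenario <- function(seed = 1L, noise = "poisson") {
  scenario_from_config(default_scenario_config(), seed = seed, noise = noise)
}

default_scenario_config <- function() {
  pats <- c("constant", "sustained_up", "sustained_down", "transient_up",
            "transient_down", "delayed_up", "delayed_down", "reversal")
  blocks <- lapply(pats, function(p)
    list(prefix = p, n = 3, pattern = p, length = 12000,
         baseline_rate = 0.5, fold = 3,
         onset_time = if (grepl("^delayed", p)) 30 else 0,
         off_time = if (p == "reversal") 60 else 30,
         rate_kb_min = 2.0, strand = if (p == "reversal") "-" else "+"))
  blocks <- c(blocks, list(
    list(prefix = "wave_up", n = 3, pattern = "sustained_up",
         length = 300000, baseline_rate = 0, change_times = 0,
         epoch_rates = 2, rate_kb_min = 2.0, gap = 50000),
    list(prefix = "wave_down", n = 3, pattern = "sustained_down",
         length = 300000, baseline_rate = 2, change_times = 0,
         epoch_rates = 0, rate_kb_min = 2.0, gap = 50000)))
  list(seed = 1, bin_size = 1000, read_depth = 1, noise = "poisson",
       library_size = 1e6, blocks = blocks)
}
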
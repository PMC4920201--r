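# Scenario builders shared by unit and acceptance tests.

# n long genes per mode for wave-front work. mode "advancing": silent genes
# switched on at t = 0; "retreating": active genes shut off at t = 0.
# rates/seg_lengths define the elongation field (recycled per gene).
wave_scenario <- function(n = 21, length_bp = 300000, rates = 2.0,
                          seg_lengths = NULL, mode = "advancing",
                          on_rate = 2, depth = 1, noise = "poisson",
                          seed = 1L, bin_size = 1000) {
  seg_lengths <- seg_lengths %||% length_bp
  stopifnot(sum(seg_lengths) >= length_bp)
  genes <- lapply(seq_len(n), function(i) {
    init <- if (mode == "advancing") {
      init_profile(0, "sustained_up", change_times = 0, epoch_rates = on_rate)
    } else {
      init_profile(on_rate, "sustained_down", change_times = 0,
                   epoch_rates = 0)
    }
    sim_gene(sprintf("%s_%02d", mode, i), paste0("chr", i), 0, length_bp,
             "+", init, elongation_profile(seg_lengths, rates))
  })
  sim_scenario(genes, bin_size = bin_size, read_depth = depth, noise = noise,
               seed = seed)
}

# n genes for each of the eight temporal patterns; short genes so the
# TSS-proximal window covers the whole gene.
pattern_scenario <- function(n_per = 5, fold = 3, length_bp = 12000,
                             baseline = 0.5, depth = 1, noise = "poisson",
                             seed = 1L) {
  pats <- c("constant", "sustained_up", "sustained_down", "transient_up",
            "transient_down", "delayed_up", "delayed_down", "reversal")
  genes <- list()
  for (p in pats) for (i in seq_len(n_per)) {
    init <- init_profile(baseline, p, fold = fold,
                         onset_time = if (grepl("^delayed", p)) 30 else 0,
                         off_time = if (p == "reversal") 60 else 30)
    genes[[paste0(p, "_", i)]] <-
      sim_gene(paste0(p, "_", i), paste0("chr_", p),
               (i - 1) * (length_bp + 10000),
               (i - 1) * (length_bp + 10000) + length_bp,
               "+", init, elongation_profile(length_bp, 2.0))
  }
  sim_scenario(unname(genes), read_depth = depth, noise = noise, seed = seed,
               library_size = 1e6)
}

# simulate, then run quantification + classification, returning everything
run_quant_classify <- function(scenario, dir = withr::local_tempdir(),
                               pseudocount = 0.1, fold = 2) {
  res <- simulate_cohort(scenario, dir)
  covset <- read_coverage_set(res$samples)
  genes <- read_genes(res$genes)
  mat <- quantify(genes, covset)
  expressed <- expressed_filter(mat)
  fc <- log2fc(mat[mat$gene_id %in% expressed, , drop = FALSE],
               pseudocount = pseudocount)
  calls <- classify_genes(fc, fold = fold)
  truth <- bruwave:::read_tsv_hash(res$truth)
  list(paths = res, covset = covset, genes = genes, mat = mat,
       expressed = expressed, fc = fc, calls = calls, truth = truth)
}
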
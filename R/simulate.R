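#' Expected labeled-polymerase passages per bin for one labeling window
#'
#' Kinetic model: point polymerases initiate at the TSS as an inhomogeneous
#' Poisson process with piecewise-constant rate I(t) and move deterministically
#' through the position-dependent speed field. A position x is covered by
#' labeled RNA in window (w0, w1) iff some polymerase transcribes x while
#' label is present, i.e. its initiation time t0 satisfies
#' w0 <= t0 + tau(x) <= w1 where tau is [travel_time()]. The expected signal
#' at x is therefore the integral of I over [w0 - tau(x), w1 - tau(x)],
#' evaluated here in closed form at bin centers.
#'
#' @param gene_length_bp gene length in bp (positions beyond it get 0)
#' @param init an [init_profile()]
#' @param elong an [elongation_profile()] covering at least the gene length
#' @param window numeric length-2 (start, end) of the labeling window in min
#' @param bin_size bin width in bp (default 1000)
#' @return numeric vector of expected passages per bin, bins tiling
#'   [0, gene_length_bp) from the TSS (last bin may be partial)
#' @export
expected_coverage <- function(gene_length_bp, init, elong, window,
                              bin_size = 1000) {
  stopifnot(inherits(init, "init_profile"),
            inherits(elong, "elongation_profile"))
  if (length(window) != 2 || diff(window) <= 0)
    stopf("window must be (start, end) with end > start")
  total <- elong$cum_bp[length(elong$cum_bp)]
  if (total < gene_length_bp)
    stopf("elongation profile (%g bp) shorter than gene (%g bp)",
          total, gene_length_bp)
  nb <- ceiling(gene_length_bp / bin_size)
  bin_start <- (seq_len(nb) - 1) * bin_size
  bin_end <- pmin(bin_start + bin_size, gene_length_bp)
  centers <- (bin_start + bin_end) / 2
  tau <- travel_time(elong, centers)
  vals <- cum_initiation(init, window[[2]] - tau) -
          cum_initiation(init, window[[1]] - tau)
  pmax(vals, 0)
}

#' Sample read counts from expected coverage
#'
#' Counts are independent per bin with mean `read_depth * expected`. With
#' `noise = "poisson"` they are Poisson draws; with `noise = "none"` the
#' rounded expectation is returned (deterministic, used for closed-form
#' checks).
#'
#' @param expected non-negative expected passages per bin
#' @param read_depth expected reads per unit expected coverage (>= 0)
#' @param seed integer seed; required when `noise = "poisson"`
#' @param noise "poisson" or "none"
#' @return integer vector of per-bin counts
#' @export
sample_reads <- function(expected, read_depth, seed = NULL,
                         noise = c("poisson", "none")) {
  noise <- match.arg(noise)
  if (!is.finite(read_depth) || read_depth < 0)
    stopf("read_depth must be >= 0")
  if (any(expected < 0)) stopf("expected values must be >= 0")
  lambda <- read_depth * expected
  if (noise == "none") return(as.integer(round(lambda)))
  if (!is.null(seed)) set.seed(seed)
  as.integer(stats::rpois(length(lambda), lambda))
}

#' Define one simulated gene
#'
#' @param gene_id unique id
#' @param chrom chromosome name
#' @param start,end 0-based half-open genomic interval; TSS = start on "+",
#'   end on "-"
#' @param strand "+" or "-"
#' @param init an [init_profile()]
#' @param elong an [elongation_profile()]; defaults to constant 2 kb/min over
#'   the gene length
#' @return a `sim_gene` list
#' @export
sim_gene <- function(gene_id, chrom, start, end, strand, init,
                     elong = NULL) {
  if (start >= end) stopf("gene %s: start must be < end", gene_id)
  if (!strand %in% c("+", "-")) stopf("gene %s: strand must be + or -", gene_id)
  elong <- elong %||% elongation_profile(end - start, 2.0)
  structure(list(gene_id = gene_id, chrom = chrom, start = start, end = end,
                 strand = strand, init = init, elong = elong),
            class = "sim_gene")
}

#' Simulation scenario
#'
#' @param genes list of [sim_gene()]s
#' @param scheme labeling scheme from [labeling_scheme()]
#' @param bin_size bin width in bp
#' @param read_depth expected reads per unit expected coverage
#' @param noise "poisson" or "none"
#' @param seed master integer seed; per-gene substreams are derived by stable
#'   hashing of the gene id so cohort composition changes do not perturb
#'   other genes
#' @param library_size optional fixed per-window library size written to the
#'   sample sheet. A simulated cohort is a small subset of a transcriptome;
#'   in a real library the responding subset is a negligible mass fraction,
#'   so per-window totals are nearly constant. Summing reads over a few
#'   dozen simulated genes instead would couple every gene's RPKM to the
#'   cohort's net response (composition bias). Default NULL = use the
#'   cohort totals (appropriate when the cohort itself is the library).
#' @return a `sim_scenario` list
#' @export
sim_scenario <- function(genes, scheme = labeling_scheme(), bin_size = 1000,
                         read_depth = 1, noise = c("poisson", "none"),
                         seed = 1L, library_size = NULL) {
  noise <- match.arg(noise)
  if (read_depth < 0) stopf("read_depth must be >= 0")
  ids <- vapply(genes, function(g) g$gene_id, "")
  if (anyDuplicated(ids)) stopf("duplicate gene ids in scenario")
  structure(list(genes = genes, scheme = scheme, bin_size = bin_size,
                 read_depth = read_depth, noise = noise,
                 seed = as.integer(seed), library_size = library_size),
            class = "sim_scenario")
}

# Genomic bin intervals for a gene, ordered from the TSS going downstream.
# Bin i covers distances [(i-1)b, ib) from the TSS, strand-oriented.
gene_bins <- function(gene, bin_size) {
  len <- gene$end - gene$start
  nb <- ceiling(len / bin_size)
  d0 <- (seq_len(nb) - 1) * bin_size
  d1 <- pmin(d0 + bin_size, len)
  if (gene$strand == "+") {
    data.frame(start = gene$start + d0, end = gene$start + d1)
  } else {
    data.frame(start = gene$end - d1, end = gene$end - d0)
  }
}

# Ground-truth wave-front positions and displacements for the manifest.
# The moving edge a detector can see is the labeled-signal edge: for an
# advancing wave (initiation increase at onset) it sits at
# front_position(window_end - onset); for a retreating wave (decrease) the
# clearing boundary sits at front_position(window_start - onset). Constant
# genes have no front (NA).
truth_for_gene <- function(gene, scheme) {
  stim <- scheme[scheme$end > 0, , drop = FALSE]
  len <- gene$end - gene$start
  if (!length(gene$init$times)) {
    fronts <- rep(NA_real_, nrow(stim))
  } else {
    onset <- gene$init$times[[1]]
    going_down <- gene$init$rates[[2]] < gene$init$rates[[1]]
    tref <- if (going_down) stim$start else stim$end
    fronts <- front_position(gene$elong, pmax(tref - onset, 0),
                             cap_bp = len)
  }
  disp <- diff(fronts) / 1000
  labs <- paste0(head(stim$end, -1), "-", tail(stim$end, -1))
  dur <- stim$end - stim$start
  list(fronts = fronts, disp_kb = disp, rate = disp / dur[-1],
       interval = labs)
}

# Direction/pattern/onset labels implied by an init_profile under the default
# scheme; onset window = first stimulated window whose interval contains (or
# follows) the first change time.
truth_labels <- function(init, scheme) {
  stim <- scheme[scheme$end > 0, , drop = FALSE]
  if (init$pattern == "constant")
    return(list(direction = "none", pattern = "none", onset = NA_integer_))
  direction <- switch(init$pattern,
    sustained_up = , transient_up = , delayed_up = "induced",
    sustained_down = , transient_down = , delayed_down = "repressed",
    reversal = "reversal")
  pattern <- switch(init$pattern,
    sustained_up = , sustained_down = "sustained",
    transient_up = , transient_down = "transient",
    delayed_up = , delayed_down = "delayed",
    reversal = "reversal")
  onset <- which(stim$end > init$times[[1]])[1]
  list(direction = direction, pattern = pattern, onset = onset)
}

#' Simulate a cohort: stranded bedGraph coverage, annotation, ground truth
#'
#' Runs the kinetic model for every gene and labeling window of a scenario
#' and writes the artifacts the analysis stages consume: one plus- and one
#' minus-strand bedGraph per window, a BED6 gene annotation, a sample sheet,
#' and a ground-truth manifest (pattern labels, onset windows, per-window
#' front positions and per-interval displacements/rates).
#'
#' Minus-strand genes produce coverage extending leftward (toward lower
#' coordinates) from their TSS at `end`. Overlapping same-strand genes are
#' flagged in the manifest and trigger a warning.
#'
#' @param scenario a [sim_scenario()]
#' @param out_dir output directory (created if needed)
#' @return invisibly, a list with paths: `coverage` (per-window per-strand
#'   bedGraphs), `genes` (BED6), `samples` (sample sheet TSV), `truth`
#'   (manifest TSV), and `library_sizes`
#' @export
simulate_cohort <- function(scenario, out_dir) {
  stopifnot(inherits(scenario, "sim_scenario"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scheme <- scenario$scheme
  nW <- nrow(scheme)
  genes <- scenario$genes

  # per-window, per-strand accumulation of (chrom, start, end, count) rows
  acc <- vector("list", nW)
  for (w in seq_len(nW)) acc[[w]] <- list(`+` = list(), `-` = list())
  truth_rows <- list()
  overlaps <- overlap_flags(genes)

  for (g in genes) {
    len <- g$end - g$start
    bins <- gene_bins(g, scenario$bin_size)
    gseed <- derive_seed(scenario$seed, g$gene_id)
    set.seed(gseed)
    counts_by_window <- vector("list", nW)
    for (w in seq_len(nW)) {
      ev <- expected_coverage(len, g$init, g$elong,
                              c(scheme$start[[w]], scheme$end[[w]]),
                              scenario$bin_size)
      counts_by_window[[w]] <- sample_reads(ev, scenario$read_depth,
                                            seed = NULL,
                                            noise = scenario$noise)
    }
    for (w in seq_len(nW)) {
      cnt <- counts_by_window[[w]]
      keep <- cnt > 0
      if (any(keep)) {
        acc[[w]][[g$strand]][[length(acc[[w]][[g$strand]]) + 1]] <-
          data.frame(chrom = g$chrom, start = bins$start[keep],
                     end = bins$end[keep], count = cnt[keep])
      }
    }
    tr <- truth_for_gene(g, scheme)
    lb <- truth_labels(g$init, scheme)
    truth_rows[[g$gene_id]] <- data.frame(
      gene_id = g$gene_id, pattern = lb$pattern, direction = lb$direction,
      onset_window = lb$onset,
      t(setNames(tr$fronts, paste0("front_", seq_along(tr$fronts)))),
      t(setNames(tr$disp_kb, paste0("disp_kb_", tr$interval))),
      t(setNames(tr$rate, paste0("rate_", tr$interval))),
      overlap = overlaps[[g$gene_id]],
      stringsAsFactors = FALSE, check.names = FALSE)
  }

  cov_paths <- list()
  lib_sizes <- numeric(nW)
  for (w in seq_len(nW)) {
    wn <- scheme$name[[w]]
    cov_paths[[wn]] <- list()
    for (s in c("+", "-")) {
      tag <- if (s == "+") "plus" else "minus"
      path <- file.path(out_dir, paste0(wn, ".", tag, ".bedGraph"))
      rows <- acc[[w]][[s]]
      df <- if (length(rows)) do.call(rbind, rows) else
        data.frame(chrom = character(0), start = numeric(0),
                   end = numeric(0), count = numeric(0))
      df <- df[order(df$chrom, df$start), , drop = FALSE]
      write_bedgraph(df, path)
      cov_paths[[wn]][[tag]] <- path
      lib_sizes[[w]] <- lib_sizes[[w]] + sum(df$count)
    }
  }

  genes_path <- file.path(out_dir, "genes.bed")
  write_bed6(genes, genes_path)

  if (!is.null(scenario$library_size))
    lib_sizes <- rep(scenario$library_size, length.out = nW)
  samples_path <- file.path(out_dir, "samples.tsv")
  write_tsv_hash(data.frame(
    window = scheme$name,
    plus = vapply(scheme$name, function(n) basename(cov_paths[[n]]$plus), ""),
    minus = vapply(scheme$name, function(n) basename(cov_paths[[n]]$minus), ""),
    library_size = lib_sizes, stringsAsFactors = FALSE), samples_path)

  truth_path <- file.path(out_dir, "truth.tsv")
  truth <- do.call(rbind, truth_rows)
  write_tsv_hash(truth, truth_path)

  if (any(unlist(overlaps)))
    warnf("overlapping same-strand genes flagged in manifest")

  invisible(list(coverage = cov_paths, genes = genes_path,
                 samples = samples_path, truth = truth_path,
                 library_sizes = setNames(lib_sizes, scheme$name)))
}

# TRUE for genes whose genomic interval overlaps another same-strand gene.
overlap_flags <- function(genes) {
  flags <- setNames(rep(FALSE, length(genes)),
                    vapply(genes, function(g) g$gene_id, ""))
  if (length(genes) < 2) return(as.list(flags))
  for (i in seq_along(genes)) for (j in seq_along(genes)) {
    if (i >= j) next
    a <- genes[[i]]; b <- genes[[j]]
    if (a$chrom == b$chrom && a$strand == b$strand &&
        a$start < b$end && b$start < a$end) {
      flags[[a$gene_id]] <- TRUE; flags[[b$gene_id]] <- TRUE
    }
  }
  as.list(flags)
}

write_bedgraph <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(df))
    writeLines(paste(df$chrom, format(df$start, scientific = FALSE, trim = TRUE),
                     format(df$end, scientific = FALSE, trim = TRUE),
                     format_field(as.double(df$count)), sep = "\t"),
               con, sep = "\n")
  invisible(path)
}

write_bed6 <- function(genes, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (g in genes)
    writeLines(paste(g$chrom,
                     format(g$start, scientific = FALSE, trim = TRUE),
                     format(g$end, scientific = FALSE, trim = TRUE),
                     g$gene_id, 0, g$strand, sep = "\t"), con, sep = "\n")
  invisible(path)
}
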
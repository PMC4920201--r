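#' Read a BED6 gene annotation
#'
#' Coordinates are 0-based, half-open. The TSS is `start` for plus-strand
#' genes and `end` for minus-strand genes; length = end - start.
#'
#' @param path BED6 file (six tab-separated columns; strand required)
#' @return data.frame with columns gene_id, chrom, start, end, strand, tss,
#'   length
#' @export
read_genes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  if (!length(lines)) stopf("no records in %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- vapply(fields, length, 0L)
  bad <- which(n < 6)
  if (length(bad))
    stopf("malformed BED6 line %d in %s: expected >= 6 columns, got %d",
          bad[[1]], path, n[[bad[[1]]]])
  rec <- function(i, f) {
    start <- suppressWarnings(as.numeric(f[[2]]))
    end <- suppressWarnings(as.numeric(f[[3]]))
    if (is.na(start) || is.na(end))
      stopf("malformed BED6 line %d in %s: non-numeric coordinates", i, path)
    if (start >= end)
      stopf("malformed BED6 line %d in %s: start >= end", i, path)
    if (!f[[6]] %in% c("+", "-"))
      stopf("malformed BED6 line %d in %s: strand must be + or -", i, path)
    data.frame(gene_id = f[[4]], chrom = f[[1]], start = start, end = end,
               strand = f[[6]], stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, Map(rec, seq_along(fields), fields))
  if (anyDuplicated(df$gene_id)) stopf("duplicate gene_id in %s", path)
  df$tss <- ifelse(df$strand == "+", df$start, df$end)
  df$length <- df$end - df$start
  df
}

#' TSS-proximal quantification window of a gene
#'
#' Productive initiation is measured near the TSS so that a polymerase at a
#' typical elongation rate fully traverses the measured interval within one
#' 30-min labeling pulse: genes shorter than `cap` are quantified over the
#' whole gene body; genes of length `cap` and over are quantified over the
#' first `cap` bp downstream of the TSS (strand-oriented).
#'
#' @param gene one row of [read_genes()] output (or a list with start, end,
#'   strand)
#' @param cap window cap in bp (default 30000)
#' @return numeric (start, end) genomic interval
#' @export
quant_window <- function(gene, cap = 30000) {
  len <- gene$end - gene$start
  if (len < cap) return(c(gene$start, gene$end))
  if (gene$strand == "+") c(gene$start, gene$start + cap)
  else c(gene$end - cap, gene$end)
}

#' Read a stranded coverage set from a sample sheet
#'
#' The sample sheet is a TSV (hash-prefixed header) with columns `window`,
#' `plus`, `minus` and optionally `library_size`; each coverage file is a
#' bedGraph (0-based half-open, numeric fourth column; track lines ignored).
#' When `library_size` is absent it defaults to the total reads in that
#' window's two files.
#'
#' @param samples_path sample sheet TSV path
#' @return a `coverage_set`: per window, per strand, a data.table of
#'   (chrom, start, end, count), plus `library_size` and `bin_size`
#' @export
read_coverage_set <- function(samples_path) {
  sheet <- read_tsv_hash(samples_path)
  need <- c("window", "plus", "minus")
  if (!all(need %in% names(sheet)))
    stopf("sample sheet must have columns: %s", paste(need, collapse = ", "))
  base <- dirname(samples_path)
  windows <- list()
  lib <- numeric(nrow(sheet))
  bs <- NULL
  for (i in seq_len(nrow(sheet))) {
    covs <- list()
    for (s in c("plus", "minus")) {
      p <- sheet[[s]][[i]]
      if (!file.exists(file.path(base, p))) {
        if (!file.exists(p))
          stopf("coverage file not found: %s", sheet[[s]][[i]])
      } else {
        p <- file.path(base, p)
      }
      covs[[s]] <- read_bedgraph(p)
    }
    names(covs) <- c("+", "-")
    windows[[sheet$window[[i]]]] <- covs
    tot <- sum(covs[["+"]]$count) + sum(covs[["-"]]$count)
    ls_col <- sheet$library_size
    lib[[i]] <- if (!is.null(ls_col) && is.finite(ls_col[[i]]) &&
                      ls_col[[i]] > 0) ls_col[[i]] else tot
    widths <- c(covs[["+"]]$end - covs[["+"]]$start,
                covs[["-"]]$end - covs[["-"]]$start)
    if (length(widths)) bs <- max(bs %||% 0, max(widths))
  }
  structure(list(windows = windows,
                 library_size = setNames(lib, sheet$window),
                 bin_size = bs %||% 1000),
            class = "coverage_set")
}

read_bedgraph <- function(path) {
  if (!file.exists(path)) stopf("coverage file not found: %s", path)
  if (file.size(path) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), count = numeric(0)))
  first <- readLines(path, n = 1)
  skip <- if (startsWith(first, "track")) 1L else 0L
  data.table::fread(path, sep = "\t", header = FALSE, skip = skip,
                    col.names = c("chrom", "start", "end", "count"),
                    data.table = FALSE, colClasses = list(character = 1))
}

#' Count strand-matched reads overlapping an interval
#'
#' Sums bin counts on the gene's strand over the genomic interval; bins
#' partially overlapping the interval contribute in proportion to their
#' overlap fraction, so results converge as bins shrink.
#'
#' @param covset a `coverage_set` from [read_coverage_set()]
#' @param window window name in the set
#' @param chrom,strand where to count
#' @param interval numeric (start, end), 0-based half-open
#' @return fractional read count
#' @export
count_reads <- function(covset, window, chrom, strand, interval) {
  cov <- covset$windows[[window]][[strand]]
  if (is.null(cov)) stopf("unknown window or strand: %s/%s", window, strand)
  cov <- cov[cov$chrom == chrom, , drop = FALSE]
  if (!nrow(cov)) {
    return(0)
  }
  s <- interval[[1]]; e <- interval[[2]]
  ov <- pmin(cov$end, e) - pmax(cov$start, s)
  sel <- ov > 0
  if (!any(sel)) return(0)
  frac <- ov[sel] / (cov$end[sel] - cov$start[sel])
  sum(cov$count[sel] * frac)
}

#' Reads per kilobase per million mapped reads
#'
#' @param reads read count in the interval
#' @param interval_length interval length in bp (> 0)
#' @param library_size total mapped reads in the sample (> 0)
#' @return RPKM value
#' @export
rpkm <- function(reads, interval_length, library_size) {
  if (any(interval_length <= 0)) stopf("interval_length must be > 0")
  if (any(library_size <= 0)) stopf("library_size must be > 0")
  reads / (interval_length / 1e3) / (library_size / 1e6)
}

#' Build the gene-by-window RPKM expression matrix
#'
#' For each gene, reads on the gene's strand within its TSS-proximal
#' quantification window (see [quant_window()]) are converted to RPKM using
#' each labeling window's library size. Genes whose quantification interval
#' is shorter than `min_interval` bp are skipped with a warning. Chromosomes
#' absent from a coverage window count as zero (with a warning, once per
#' chromosome).
#'
#' @param genes data.frame from [read_genes()]
#' @param covset `coverage_set` from [read_coverage_set()]
#' @param cap TSS-proximal window cap in bp
#' @param min_interval minimum quantification-interval length in bp
#' @return data.frame: gene_id, qstart, qend, overlap flag, then one RPKM
#'   column per labeling window (in sample-sheet order)
#' @export
quantify <- function(genes, covset, cap = 30000, min_interval = 300) {
  wnames <- names(covset$windows)
  seen_chroms <- unique(unlist(lapply(covset$windows, function(w)
    c(w[["+"]]$chrom, w[["-"]]$chrom))))
  missing_chroms <- setdiff(unique(genes$chrom), seen_chroms)
  if (length(missing_chroms))
    warnf("chromosome(s) absent from coverage, counted as 0: %s",
          paste(missing_chroms, collapse = ", "))

  qiv <- t(vapply(seq_len(nrow(genes)), function(i)
    quant_window(genes[i, ], cap), numeric(2)))
  short <- (qiv[, 2] - qiv[, 1]) < min_interval
  if (any(short))
    warnf("%d gene(s) with quantification interval < %d bp skipped",
          sum(short), min_interval)
  keep <- which(!short)

  ov <- quant_overlap_flags(genes, qiv)
  out <- data.frame(gene_id = genes$gene_id[keep],
                    qstart = qiv[keep, 1], qend = qiv[keep, 2],
                    overlap = ov[keep], stringsAsFactors = FALSE)
  for (w in wnames) {
    reads <- vapply(keep, function(i)
      count_reads(covset, w, genes$chrom[[i]], genes$strand[[i]], qiv[i, ]),
      0)
    out[[w]] <- rpkm(reads, qiv[keep, 2] - qiv[keep, 1],
                     covset$library_size[[w]])
  }
  out
}

# same-strand quantification-window overlap flags
quant_overlap_flags <- function(genes, qiv) {
  n <- nrow(genes)
  fl <- rep(FALSE, n)
  if (n < 2) return(fl)
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    if (genes$chrom[[i]] == genes$chrom[[j]] &&
        genes$strand[[i]] == genes$strand[[j]] &&
        qiv[i, 1] < qiv[j, 2] && qiv[j, 1] < qiv[i, 2]) {
      fl[[i]] <- TRUE; fl[[j]] <- TRUE
    }
  }
  fl
}

#' Expressed-gene filter
#'
#' A gene is expressed if its RPKM exceeds `threshold` (strictly) in the
#' starved window or in at least one stimulated window.
#'
#' @param mat expression matrix from [quantify()]
#' @param threshold RPKM cutoff (default 0.5, strict)
#' @param windows window columns to consider; default all RPKM columns
#' @return character vector of expressed gene ids
#' @export
expressed_filter <- function(mat, threshold = 0.5, windows = NULL) {
  wcols <- windows %||% setdiff(names(mat),
                                c("gene_id", "qstart", "qend", "overlap"))
  any_above <- Reduce(`|`, lapply(wcols, function(w) mat[[w]] > threshold))
  mat$gene_id[any_above]
}
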
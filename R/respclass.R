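#' Log2 fold changes versus the starved baseline
#'
#' Elementwise log2((RPKM_w + eps) / (RPKM_starved + eps)) for every
#' stimulated window. The symmetric pseudocount keeps ratios finite at zero
#' and damps fold changes of barely-expressed genes; the default 0.1 RPKM is
#' small relative to the 0.5 expressed floor.
#'
#' @param mat expression matrix from [quantify()]
#' @param starved name of the baseline window column (default "starved")
#' @param pseudocount eps > 0 added to numerator and denominator
#' @return data.frame: gene_id, starved RPKM, then one log2 FC column per
#'   stimulated window (prefixed `fc_`), in matrix column order
#' @export
log2fc <- function(mat, starved = "starved", pseudocount = 0.1) {
  if (pseudocount <= 0) stopf("pseudocount must be > 0")
  if (!starved %in% names(mat)) stopf("no column '%s' in matrix", starved)
  wcols <- setdiff(names(mat), c("gene_id", "qstart", "qend", "overlap",
                                 starved))
  out <- data.frame(gene_id = mat$gene_id, starved_rpkm = mat[[starved]],
                    stringsAsFactors = FALSE)
  for (w in wcols)
    out[[paste0("fc_", w)]] <-
      log2((mat[[w]] + pseudocount) / (mat[[starved]] + pseudocount))
  out
}

#' Classify one gene's temporal response pattern
#'
#' Thresholds are strict: a window "responds" when |log2 FC| exceeds
#' log2(fold). Direction is induced when some window exceeds +log2(fold) and
#' none falls below -log2(fold); repressed is the mirror and additionally
#' requires the gene to be expressed when starved (RPKM > 0.5), since loss of
#' signal can only be read against a detectable baseline; reversal means
#' both thresholds are crossed (order recorded as a sub-flag). The onset
#' window is the first crossing. The pattern is sustained when every window
#' from onset onward stays beyond threshold, transient otherwise; an onset
#' after the first window makes the pattern delayed, with the
#' sustained/transient distinction kept as a sub-flag.
#'
#' @param fc numeric vector of log2 fold changes, one per stimulated window
#'   in temporal order (no NAs)
#' @param starved_rpkm the gene's starved RPKM (for repressed eligibility)
#' @param fold fold-change threshold (default 2, strict)
#' @param expressed_threshold starved-expression floor for repressed calls
#' @return list: direction, pattern, onset (integer or NA), subpattern
#'   (sustained/transient for delayed calls, else NA), reversal_order
#'   (up_down/down_up for reversals, else NA)
#' @export
call_response <- function(fc, starved_rpkm, fold = 2,
                          expressed_threshold = 0.5) {
  if (anyNA(fc)) stopf("fold-change vector has missing windows")
  thr <- log2(fold)
  up <- fc > thr
  dn <- fc < -thr
  none <- list(direction = "none", pattern = "none", onset = NA_integer_,
               subpattern = NA_character_, reversal_order = NA_character_)
  if (any(up) && any(dn)) {
    order_flag <- if (which(up)[[1]] < which(dn)[[1]]) "up_down" else "down_up"
    onset <- min(which(up | dn))
    return(list(direction = "reversal", pattern = "reversal",
                onset = onset, subpattern = NA_character_,
                reversal_order = order_flag))
  }
  if (any(up)) {
    cross <- up
    direction <- "induced"
  } else if (any(dn)) {
    if (!(starved_rpkm > expressed_threshold)) return(none)
    cross <- dn
    direction <- "repressed"
  } else {
    return(none)
  }
  onset <- which(cross)[[1]]
  base <- if (all(cross[onset:length(cross)])) "sustained" else "transient"
  if (onset > 1) {
    list(direction = direction, pattern = "delayed", onset = onset,
         subpattern = base, reversal_order = NA_character_)
  } else {
    list(direction = direction, pattern = base, onset = onset,
         subpattern = NA_character_, reversal_order = NA_character_)
  }
}

#' Classify every gene in a fold-change table
#'
#' @param fc_tab output of [log2fc()]
#' @param fold,expressed_threshold see [call_response()]
#' @return data.frame of response calls, one row per gene
#' @export
classify_genes <- function(fc_tab, fold = 2, expressed_threshold = 0.5) {
  fcols <- grep("^fc_", names(fc_tab), value = TRUE)
  if (!length(fcols)) stopf("no fc_ columns in fold-change table")
  rows <- lapply(seq_len(nrow(fc_tab)), function(i) {
    cl <- call_response(as.numeric(fc_tab[i, fcols]),
                        fc_tab$starved_rpkm[[i]],
                        fold = fold, expressed_threshold = expressed_threshold)
    data.frame(gene_id = fc_tab$gene_id[[i]], direction = cl$direction,
               pattern = cl$pattern, onset = cl$onset,
               subpattern = cl$subpattern,
               reversal_order = cl$reversal_order,
               max_abs_fc = max(abs(as.numeric(fc_tab[i, fcols]))),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Order genes for heat-map export
#'
#' Blocks by direction (induced, repressed, reversal), then pattern
#' (sustained, transient, delayed, reversal), then onset window ascending;
#' within a block genes sort by descending max |log2 FC|, ties broken
#' lexicographically by gene id so the ordering is deterministic.
#'
#' @param calls data.frame from [classify_genes()] (responders only are kept)
#' @param fc_tab matching [log2fc()] table
#' @return the fold-change table subset to responders, in heat-map order,
#'   with direction/pattern/onset columns prepended
#' @export
order_for_heatmap <- function(calls, fc_tab) {
  resp <- calls[calls$direction != "none", , drop = FALSE]
  dir_rank <- match(resp$direction, c("induced", "repressed", "reversal"))
  pat_rank <- match(resp$pattern, c("sustained", "transient", "delayed",
                                    "reversal"))
  o <- order(dir_rank, pat_rank, resp$onset, -resp$max_abs_fc, resp$gene_id)
  resp <- resp[o, , drop = FALSE]
  merged <- cbind(resp[, c("gene_id", "direction", "pattern", "onset")],
                  fc_tab[match(resp$gene_id, fc_tab$gene_id),
                         grep("^fc_", names(fc_tab), value = TRUE),
                         drop = FALSE])
  rownames(merged) <- NULL
  merged
}

#' Tabulate response calls by direction and pattern
#'
#' Reversal genes cross both thresholds; with `count_reversal_both = TRUE`
#' (default) they contribute to both the induced and the repressed direction
#' totals while keeping the reversal pattern, mirroring heat maps that show
#' the reversal panel under both directions.
#'
#' @param calls data.frame from [classify_genes()]
#' @param count_reversal_both logical, see above
#' @return data.frame direction, pattern, n; plus attribute
#'   `direction_totals`
#' @export
summarize_counts <- function(calls, count_reversal_both = TRUE) {
  resp <- calls[calls$direction != "none", , drop = FALSE]
  pats <- c("sustained", "transient", "delayed", "reversal")
  dirs <- c("induced", "repressed")
  rows <- list()
  for (d in dirs) for (p in setdiff(pats, "reversal")) {
    rows[[paste(d, p)]] <- data.frame(
      direction = d, pattern = p,
      n = sum(resp$direction == d & resp$pattern == p),
      stringsAsFactors = FALSE)
  }
  n_rev <- sum(resp$direction == "reversal")
  if (count_reversal_both) {
    for (d in dirs)
      rows[[paste(d, "reversal")]] <- data.frame(
        direction = d, pattern = "reversal", n = n_rev,
        stringsAsFactors = FALSE)
  } else {
    rows[["reversal"]] <- data.frame(direction = "reversal",
                                     pattern = "reversal", n = n_rev,
                                     stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  totals <- tapply(tab$n, tab$direction, sum)
  attr(tab, "direction_totals") <- totals
  tab
}
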
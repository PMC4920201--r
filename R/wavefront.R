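#' Default wave-front detector parameters
#'
#' @param w centered moving-average smoothing width, bins
#' @param beta relative threshold as a fraction of the plateau level
#' @param noise_floor absolute count floor; bins at or below it never count
#'   as signal (set from intergenic background when available)
#' @param gap_tol tolerated run of consecutive below-threshold bins inside a
#'   signal run
#' @param min_run minimum number of above-threshold bins for a detectable
#'   front
#' @export
front_params <- function(w = 5L, beta = 0.25, noise_floor = 0,
                         gap_tol = 2L, min_run = 5L) {
  if (beta <= 0 || beta >= 1) stopf("beta must be in (0, 1)")
  if (w < 1 || min_run < 1 || gap_tol < 0) stopf("invalid detector sizes")
  list(w = as.integer(w), beta = beta, noise_floor = noise_floor,
       gap_tol = as.integer(gap_tol), min_run = as.integer(min_run))
}

# centered moving average, truncated at the edges
smooth_ma <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  half <- (w - 1) %/% 2
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - half, 1)
  hi <- pmin(i + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Detect an advancing transcription wave front
#'
#' For an induced gene, labeled signal in a window forms a plateau anchored
#' at the TSS that tapers to zero at the wave front. The detector (i)
#' smooths the binned profile with a centered moving average, (ii) sets a
#' threshold at `beta` times the plateau level (median of the smoothed first
#' quartile of the covered region), floored at `noise_floor`, (iii) walks
#' from the TSS through the above-threshold run, bridging up to `gap_tol`
#' below-threshold bins, and (iv) refines the front by extending along raw
#' bins that exceed `noise_floor`, again bridging `gap_tol` empty bins —
#' step (iv) recovers the true zero-crossing on clean data, where the taper
#' falls below the relative threshold well before the actual front.
#'
#' @param counts raw binned counts, strand-oriented from the TSS
#' @param bin_size bin width in bp
#' @param gene_length gene length in bp (front is capped here)
#' @param params detector parameters from [front_params()]
#' @return list: `position` (bp downstream of TSS, NA if undetectable),
#'   `flag` ("ok", "saturated", "undetectable")
#' @export
detect_front_advancing <- function(counts, bin_size, gene_length,
                                   params = front_params()) {
  n <- length(counts)
  if (!n || all(counts <= params$noise_floor))
    return(list(position = NA_real_, flag = "undetectable"))
  s <- smooth_ma(counts, params$w)
  covered <- which(s > params$noise_floor)
  cov_ext <- covered[length(covered)]
  plateau <- stats::median(s[seq_len(max(1L, ceiling(cov_ext / 4)))])
  thr <- max(params$noise_floor, params$beta * plateau)
  above <- s > thr

  # TSS-anchored run with gap tolerance (run may start within the first
  # gap_tol + 1 bins)
  run_end <- 0L
  n_above <- 0L
  gap <- 0L
  i <- 1L
  while (i <= n) {
    if (above[[i]]) {
      run_end <- i
      n_above <- n_above + 1L
      gap <- 0L
    } else {
      gap <- gap + 1L
      if (gap > params$gap_tol && run_end > 0L) break
      if (i > params$gap_tol && run_end == 0L) break
    }
    i <- i + 1L
  }
  if (n_above < params$min_run)
    return(list(position = NA_real_, flag = "undetectable"))

  # refinement on raw counts: extend to the contiguous (gap-tolerant) end of
  # positive signal past the threshold crossing
  j <- run_end
  gap <- 0L
  k <- run_end + 1L
  while (k <= n) {
    if (counts[[k]] > params$noise_floor) {
      j <- k
      gap <- 0L
    } else {
      gap <- gap + 1L
      if (gap > params$gap_tol) break
    }
    k <- k + 1L
  }
  while (j > 1L && counts[[j]] <= params$noise_floor) j <- j - 1L

  pos <- min(j * bin_size, gene_length)
  flag <- if (j >= n) "saturated" else "ok"
  list(position = pos, flag = flag)
}

#' Detect a retreating transcription wave front
#'
#' For a repressed gene the 5' region clears first; the boundary between the
#' cleared 5' region and the still-occupied 3' region is the retreating
#' front. Implemented as the exact mirror of [detect_front_advancing()] on
#' the reversed profile, which guarantees advancing/retreating symmetry.
#'
#' @inheritParams detect_front_advancing
#' @return list: `position` (bp downstream of TSS; 0 with flag "full" when
#'   the gene is still fully covered), `flag` ("ok", "full", "undetectable")
#' @export
detect_front_retreating <- function(counts, bin_size, gene_length,
                                    params = front_params()) {
  res <- detect_front_advancing(rev(counts), bin_size, gene_length, params)
  if (is.na(res$position))
    return(list(position = NA_real_, flag = "undetectable"))
  pos <- max(gene_length - res$position, 0)
  flag <- if (res$flag == "saturated") "full" else "ok"
  list(position = pos, flag = flag)
}

#' Eligible genes for elongation-rate estimation
#'
#' Wave fronts are only resolvable in genes long enough that the polymerase
#' stays inside the gene body across the time course: responders strictly
#' longer than `min_length` qualify. Induced genes form the advancing set,
#' repressed genes the retreating set; reversal genes are excluded (their
#' wave direction changes mid-course).
#'
#' @param calls response calls from [classify_genes()]
#' @param genes annotation from [read_genes()]
#' @param min_length strict length cutoff in bp (default 200000)
#' @return list with character vectors `advancing` and `retreating`
#' @export
eligible_genes <- function(calls, genes, min_length = 200000) {
  len <- genes$length[match(calls$gene_id, genes$gene_id)]
  long <- !is.na(len) & len > min_length
  list(advancing = calls$gene_id[long & calls$direction == "induced"],
       retreating = calls$gene_id[long & calls$direction == "repressed"])
}

#' Displacements and rates from a per-window front track
#'
#' The first labeling interval (starved to first window) is excluded: wave
#' positions in the first window are dominated by initiation-timing
#' variability, so displacements are taken between consecutive stimulated
#' windows k-1 and k for k = 2..4 and divided by the labeling duration.
#' An undetectable window voids both adjacent intervals. Negative
#' displacements (detector jitter) are kept but flagged; cohort statistics
#' drop them.
#'
#' @param fronts numeric front positions (bp) for stimulated windows in
#'   temporal order; NA = undetectable
#' @param interval_names names for the k-1 to k intervals; default the
#'   30-min grid
#' @param label_duration minutes per labeling window (default 30)
#' @return data.frame: interval, displacement_kb, rate_kb_min, flag
#' @export
displacements <- function(fronts,
                          interval_names = c("30-60", "60-90", "90-120"),
                          label_duration = 30) {
  k <- seq(2, length(fronts))
  if (length(interval_names) != length(k))
    stopf("need %d interval names", length(k))
  disp <- (fronts[k] - fronts[k - 1]) / 1000
  valid <- !is.na(disp)
  if (!any(valid))
    return(data.frame(interval = character(0), displacement_kb = numeric(0),
                      rate_kb_min = numeric(0), flag = character(0),
                      stringsAsFactors = FALSE))
  data.frame(interval = interval_names[valid],
             displacement_kb = disp[valid],
             rate_kb_min = disp[valid] / label_duration,
             flag = ifelse(disp[valid] < 0, "negative", "ok"),
             stringsAsFactors = FALSE)
}

#' Cohort statistics with paired interval comparisons
#'
#' Per-interval n, mean/SD/median of rates and median displacement over the
#' cohort (negative-displacement estimates excluded), plus paired two-sided
#' tests between consecutive intervals and between the first and last
#' interval, on genes with estimates in both members of a pair. The default
#' test is the Wilcoxon signed-rank (exact when n <= 25 and no ties/zeros);
#' a paired t-test is available.
#'
#' @param estimates data.frame with gene_id, interval, displacement_kb,
#'   rate_kb_min, flag (rows from [displacements()] with gene_id added)
#' @param test "wilcoxon" or "ttest"
#' @return list: `per_interval` data.frame, `comparisons` data.frame
#' @export
cohort_stats <- function(estimates, test = c("wilcoxon", "ttest")) {
  test <- match.arg(test)
  est <- estimates[estimates$flag == "ok", , drop = FALSE]
  ivs <- unique(est$interval)
  per <- do.call(rbind, lapply(ivs, function(iv) {
    e <- est[est$interval == iv, , drop = FALSE]
    data.frame(interval = iv, n = nrow(e),
               mean_rate = mean(e$rate_kb_min),
               sd_rate = if (nrow(e) > 1) stats::sd(e$rate_kb_min) else NA_real_,
               median_displacement_kb = stats::median(e$displacement_kb),
               median_rate = stats::median(e$rate_kb_min),
               stringsAsFactors = FALSE)
  }))
  pairs <- list()
  if (length(ivs) >= 2) {
    idx <- cbind(seq_len(length(ivs) - 1), seq(2, length(ivs)))
    if (length(ivs) > 2) idx <- rbind(idx, c(1, length(ivs)))
    for (r in seq_len(nrow(idx))) {
      a <- ivs[[idx[r, 1]]]; b <- ivs[[idx[r, 2]]]
      ea <- est[est$interval == a, c("gene_id", "rate_kb_min")]
      eb <- est[est$interval == b, c("gene_id", "rate_kb_min")]
      m <- merge(ea, eb, by = "gene_id")
      if (nrow(m) < 2) {
        warnf("comparison %s vs %s omitted: fewer than 2 paired genes", a, b)
        next
      }
      p <- paired_test(m$rate_kb_min.x, m$rate_kb_min.y, test)
      pairs[[paste(a, b)]] <- data.frame(
        interval_a = a, interval_b = b, n_pairs = nrow(m),
        statistic = p$statistic, p_value = p$p.value, test = test,
        stringsAsFactors = FALSE)
    }
  }
  comparisons <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(interval_a = character(0), interval_b = character(0),
               n_pairs = integer(0), statistic = numeric(0),
               p_value = numeric(0), test = character(0))
  rownames(comparisons) <- NULL
  list(per_interval = per, comparisons = comparisons)
}

paired_test <- function(x, y, test) {
  if (test == "ttest") {
    ht <- tryCatch(stats::t.test(x, y, paired = TRUE),
                   error = function(e) NULL)  # constant differences
    if (is.null(ht))
      return(list(statistic = NA_real_,
                  p.value = if (all(x == y)) 1 else NA_real_))
  } else {
    d <- x - y
    if (all(d == 0)) return(list(statistic = 0, p.value = 1))
    exact <- length(d) <= 25 && !any(d == 0) && !anyDuplicated(abs(d))
    ht <- suppressWarnings(
      stats::wilcox.test(x, y, paired = TRUE, exact = exact))
  }
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

# Strand-oriented binned raw counts for one gene in one window. Fast path
# when coverage bins align with the gene's bin grid (always true for
# simulator output); otherwise falls back to fractional per-bin counting.
gene_profile <- function(covset, window, gene, bin_size) {
  cov <- covset$windows[[window]][[gene$strand]]
  if (is.null(cov)) stopf("unknown window %s", window)
  cov <- cov[cov$chrom == gene$chrom & cov$end > gene$start &
               cov$start < gene$end, , drop = FALSE]
  len <- gene$end - gene$start
  nb <- ceiling(len / bin_size)
  out <- numeric(nb)
  if (!nrow(cov)) return(out)
  d0 <- if (gene$strand == "+") cov$start - gene$start else gene$end - cov$end
  aligned <- all(d0 >= 0) && all(d0 %% bin_size == 0) &&
    all(cov$end - cov$start <= bin_size)
  if (aligned) {
    idx <- d0 %/% bin_size + 1
    out[idx] <- out[idx] + cov$count
  } else {
    bins <- gene_bins(gene, bin_size)
    for (i in seq_len(nb)) {
      ov <- pmin(cov$end, bins$end[[i]]) - pmax(cov$start, bins$start[[i]])
      sel <- ov > 0
      if (any(sel))
        out[[i]] <- sum(cov$count[sel] * ov[sel] / (cov$end[sel] - cov$start[sel]))
    }
  }
  out
}

#' Wave-front analysis over a cohort
#'
#' Detects per-window fronts for every eligible gene (advancing mode for
#' induced genes, retreating for repressed), converts them to per-interval
#' displacements and rates, and computes cohort statistics per direction.
#'
#' @param covset coverage set from [read_coverage_set()]
#' @param genes annotation from [read_genes()]
#' @param calls response calls from [classify_genes()]
#' @param min_length eligibility cutoff in bp, strict
#' @param bin_size analysis bin width in bp
#' @param params detector parameters from [front_params()]
#' @param stim_windows stimulated window names in temporal order; default =
#'   all windows except "starved"
#' @param round_to optional granularity (bp) to round front positions to
#' @param test paired test passed to [cohort_stats()]
#' @param top_n optional cohort cap per direction: keep the `top_n` genes
#'   with the largest maximum |log2 FC| (strongest responders), mimicking a
#'   fixed-size cohort
#' @return list: `fronts` (gene x window positions + flags), `estimates`,
#'   `stats` (per direction)
#' @export
wavefront_analysis <- function(covset, genes, calls, min_length = 200000,
                               bin_size = 1000, params = front_params(),
                               stim_windows = NULL, round_to = NULL,
                               test = "wilcoxon", top_n = NULL) {
  stim_windows <- stim_windows %||%
    setdiff(names(covset$windows), "starved")
  elig <- eligible_genes(calls, genes, min_length)
  front_rows <- list()
  est_rows <- list()
  for (mode in c("advancing", "retreating")) {
    ids <- elig[[mode]]
    detect <- if (mode == "advancing") detect_front_advancing else
      detect_front_retreating
    for (gid in ids) {
      g <- as.list(genes[genes$gene_id == gid, ])
      fronts <- numeric(length(stim_windows))
      flags <- character(length(stim_windows))
      for (wi in seq_along(stim_windows)) {
        prof <- gene_profile(covset, stim_windows[[wi]], g, bin_size)
        res <- detect(prof, bin_size, g$length, params)
        pos <- res$position
        if (!is.null(round_to) && !is.na(pos))
          pos <- round(pos / round_to) * round_to
        fronts[[wi]] <- if (is.na(pos)) NA_real_ else pos
        flags[[wi]] <- res$flag
      }
      front_rows[[gid]] <- data.frame(
        gene_id = gid, mode = mode, window = stim_windows,
        position = fronts, flag = flags, stringsAsFactors = FALSE)
      d <- displacements(fronts)
      if (nrow(d)) {
        d <- cbind(gene_id = gid, mode = mode, d, stringsAsFactors = FALSE)
        est_rows[[gid]] <- d
      }
    }
  }
  fronts <- if (length(front_rows)) do.call(rbind, front_rows) else
    data.frame(gene_id = character(0), mode = character(0),
               window = character(0), position = numeric(0),
               flag = character(0))
  estimates <- if (length(est_rows)) do.call(rbind, est_rows) else
    data.frame(gene_id = character(0), mode = character(0),
               interval = character(0), displacement_kb = numeric(0),
               rate_kb_min = numeric(0), flag = character(0))
  rownames(fronts) <- rownames(estimates) <- NULL
  if (!is.null(top_n)) {
    for (mode in c("advancing", "retreating")) {
      ids <- unique(estimates$gene_id[estimates$mode == mode])
      if (length(ids) > top_n) {
        strength <- calls$max_abs_fc[match(ids, calls$gene_id)]
        keep <- ids[order(-strength, ids)][seq_len(top_n)]
        drop <- setdiff(ids, keep)
        estimates <- estimates[!(estimates$gene_id %in% drop), , drop = FALSE]
      }
    }
  }
  stats <- list()
  for (mode in c("advancing", "retreating")) {
    e <- estimates[estimates$mode == mode, , drop = FALSE]
    if (nrow(e)) stats[[mode]] <- cohort_stats(e, test = test)
  }
  list(fronts = fronts, estimates = estimates, stats = stats)
}
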
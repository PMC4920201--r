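test_that("eligible_genes splits long responders by direction, strictly", {
  genes <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                      length = c(200000, 350000, 400000, 250000, 300000))
  calls <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                      direction = c("induced", "induced", "none",
                                    "repressed", "reversal"))
  el <- eligible_genes(calls, genes)
  expect_equal(el$advancing, "b")      # "a" is exactly 200 kb -> excluded
  expect_equal(el$retreating, "d")     # non-responder "c", reversal "e" out
})

test_that("advancing detector handles step, saturated and empty profiles", {
  step <- c(rep(10, 120), rep(0, 80))
  r <- detect_front_advancing(step, 1000, 200000)
  expect_equal(r$position, 120000)
  expect_equal(r$flag, "ok")
  sat <- detect_front_advancing(rep(7, 200), 1000, 200000)
  expect_equal(sat$position, 200000)
  expect_equal(sat$flag, "saturated")
  none <- detect_front_advancing(rep(0, 200), 1000, 200000)
  expect_true(is.na(none$position))
  expect_equal(none$flag, "undetectable")
  # an isolated TSS spike (fewer than min_run signal bins) is not a front
  flick <- c(5, rep(0, 107))
  expect_equal(detect_front_advancing(flick, 1000, 108000)$flag,
               "undetectable")
})

test_that("retreating detector mirrors the advancing one", {
  prof <- c(rep(0, 70), rep(10, 130))
  r <- detect_front_retreating(prof, 1000, 200000)
  expect_equal(r$position, 70000)
  expect_equal(r$flag, "ok")
  full <- detect_front_retreating(rep(10, 200), 1000, 200000)
  expect_equal(full$position, 0)
  expect_equal(full$flag, "full")
  gone <- detect_front_retreating(rep(0, 200), 1000, 200000)
  expect_equal(gone$flag, "undetectable")
  # exact mirror on reversed input
  set.seed(5)
  noisy <- c(rpois(80, 40) + 10, rpois(40, 8), rep(0, 80))
  a <- detect_front_advancing(noisy, 1000, 200000)
  b <- detect_front_retreating(rev(noisy), 1000, 200000)
  expect_equal(b$position, 200000 - a$position)
})

test_that("displacements: arithmetic, voiding, and negative flags", {
  d <- displacements(c(60000, 120000, 210000, 310000))
  expect_equal(d$displacement_kb, c(60, 90, 100))
  expect_equal(d$rate_kb_min, c(2, 3, 100 / 30))
  expect_equal(d$interval, c("30-60", "60-90", "90-120"))
  d2 <- displacements(c(60000, 120000, NA, 310000))
  expect_equal(d2$interval, "30-60")    # both intervals touching w3 voided
  expect_equal(nrow(displacements(c(NA, NA, NA, NA))), 0)
  d3 <- displacements(c(60000, 50000, 90000, 100000))
  expect_equal(d3$flag, c("negative", "ok", "ok"))
})

test_that("cohort_stats: identical rates give p = 1; tiny cohorts degrade", {
  est <- do.call(rbind, lapply(sprintf("g%02d", 1:10), function(g)
    data.frame(gene_id = g, interval = c("30-60", "60-90", "90-120"),
               displacement_kb = c(60, 60, 60), rate_kb_min = c(2, 2, 2),
               flag = "ok")))
  cs <- cohort_stats(est)
  expect_equal(cs$per_interval$mean_rate, rep(2, 3))
  expect_equal(cs$per_interval$sd_rate, rep(0, 3))
  expect_true(all(cs$comparisons$p_value == 1))
  one <- est[est$gene_id == "g01", ]
  expect_warning(cs1 <- suppressWarnings(cohort_stats(one)) , NA)
  expect_equal(cs1$per_interval$n, rep(1, 3))
  expect_equal(nrow(cs1$comparisons), 0)
  two <- one[one$interval != "90-120", ]
  expect_warning(cohort_stats(two), "omitted")
  # negative-flagged estimates are excluded from stats
  est$flag[est$gene_id == "g01"] <- "negative"
  expect_equal(cohort_stats(est)$per_interval$n, rep(9, 3))
})

test_that("paired t-test alternative is available", {
  est <- do.call(rbind, lapply(1:8, function(i)
    data.frame(gene_id = sprintf("g%d", i),
               interval = c("30-60", "60-90"),
               displacement_kb = c(60, 90 + i),
               rate_kb_min = c(60, 90 + i) / 30, flag = "ok")))
  w <- cohort_stats(est, test = "wilcoxon")$comparisons
  t <- cohort_stats(est, test = "ttest")$comparisons
  expect_lt(w$p_value[1], 0.05)
  expect_lt(t$p_value[1], 1e-6)
  expect_equal(t$test[1], "ttest")
})

test_that("noiseless fronts equal the closed form; rates are monotone for
           accelerating genes", {
  sc <- wave_scenario(n = 3, length_bp = 320000,
                      seg_lengths = c(90000, 75000, 200000),
                      rates = c(1.5, 2.5, 3.5), mode = "advancing",
                      noise = "none")
  dir <- withr::local_tempdir()
  out <- simulate_cohort(sc, dir)
  covset <- read_coverage_set(out$samples)
  genes <- read_genes(out$genes)
  calls <- data.frame(gene_id = genes$gene_id, direction = "induced",
                      max_abs_fc = 5)
  wf <- wavefront_analysis(covset, genes, calls)
  truth <- bruwave:::read_tsv_hash(out$truth)
  for (w in 1:4) {
    got <- wf$fronts$position[wf$fronts$window ==
                                paste0("w", (w - 1) * 30, "_", w * 30)]
    expect_true(all(abs(got - truth[[paste0("front_", w)]]) <= 1000))
  }
  per <- wf$stats$advancing$per_interval
  expect_true(all(diff(per$mean_rate) > 0))
  expect_equal(per$mean_rate, c(1.5, 2.5, 3.5), tolerance = 0.05)
})

test_that("round_to reproduces coarse-grained front calls", {
  sc <- wave_scenario(n = 2, length_bp = 300000, mode = "advancing",
                      noise = "none")
  dir <- withr::local_tempdir()
  out <- simulate_cohort(sc, dir)
  covset <- read_coverage_set(out$samples)
  genes <- read_genes(out$genes)
  calls <- data.frame(gene_id = genes$gene_id, direction = "induced",
                      max_abs_fc = 5)
  wf <- wavefront_analysis(covset, genes, calls, round_to = 10000)
  expect_true(all(wf$fronts$position %% 10000 == 0))
})

test_that("top_n keeps the strongest responders", {
  sc <- wave_scenario(n = 5, length_bp = 300000, mode = "advancing",
                      noise = "none")
  dir <- withr::local_tempdir()
  out <- simulate_cohort(sc, dir)
  covset <- read_coverage_set(out$samples)
  genes <- read_genes(out$genes)
  calls <- data.frame(gene_id = genes$gene_id, direction = "induced",
                      max_abs_fc = seq_len(5))
  wf <- wavefront_analysis(covset, genes, calls, top_n = 2)
  expect_equal(sort(unique(wf$estimates$gene_id)),
               c("advancing_04", "advancing_05"))
})
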
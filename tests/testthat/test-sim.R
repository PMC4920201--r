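test_that("travel_time matches linear motion and the stepping oracle", {
  const <- elongation_profile(3e5, 2.0)
  expect_equal(travel_time(const, 60000), 30)
  expect_equal(travel_time(const, 0), 0)

  two <- elongation_profile(c(30000, 200000), c(1, 2))
  expect_equal(travel_time(two, 60000), 45)
  # stepping oracle, dt = 0.01 min: agreement within one step of drift
  for (x in c(12000, 30000, 60000, 151000)) {
    expect_equal(travel_time(two, x),
                 oracle_travel_time(c(30000, 200000), c(1, 2), x),
                 tolerance = 0.002)
  }
  expect_error(travel_time(two, 230001), "out of range")
  expect_error(elongation_profile(1000, -1), "positive")
})

test_that("front_position inverts travel_time and caps at the gene end", {
  const <- elongation_profile(3e5, 2.0)
  expect_equal(front_position(const, 30), 60000)
  expect_equal(front_position(const, 0), 0)
  two <- elongation_profile(c(30000, 200000), c(1, 2))
  expect_equal(front_position(two, 45), 60000)
  expect_equal(front_position(two, 1000), 230000)  # capped at profile end
  expect_equal(front_position(two, 45, cap_bp = 50000), 50000)

  # round-trip property over random piecewise profiles
  set.seed(42)
  for (rep in 1:20) {
    k <- sample(1:4, 1)
    ep <- elongation_profile(runif(k, 5e3, 1e5), runif(k, 0.5, 4))
    t <- runif(5, 0, travel_time(ep, sum(ep$lengths_bp)))
    expect_equal(travel_time(ep, front_position(ep, t)), t,
                 tolerance = 1e-9)
  }
})

test_that("expected_coverage: degenerate and steady-state cases", {
  ep <- elongation_profile(60000, 2)
  expect_equal(expected_coverage(60000, init_profile(0), ep, c(0, 30)),
               rep(0, 60))
  # constant initiation: uniform I0 * duration in every window
  for (w in list(c(-30, 0), c(0, 30), c(60, 90))) {
    ev <- expected_coverage(60000, init_profile(1.5), ep, w)
    expect_equal(ev, rep(45, 60))
  }
})

test_that("expected_coverage: induction wedge and repression clearing", {
  ep <- elongation_profile(100000, 2)
  binc <- seq(500, 99500, by = 1000)
  tau <- binc / 2000
  # switch-on at t=0 to I1 = 3: wedge I1 * (30 - tau), zero beyond front
  up <- init_profile(0, "sustained_up", change_times = 0, epoch_rates = 3)
  ev <- expected_coverage(100000, up, ep, c(0, 30))
  expect_equal(ev, pmax(3 * (30 - tau), 0))
  # shut-off at t=0 from I0 = 2: cleared 5' region, boundary at front(30)
  dn <- init_profile(2, "sustained_down", change_times = 0, epoch_rates = 0)
  ev2 <- expected_coverage(100000, dn, ep, c(0, 30))
  expect_equal(ev2, 2 * pmin(tau, 30))
})

test_that("expected_coverage matches the discrete-event oracle", {
  # piecewise elongation and a transient initiation pulse
  lens <- c(40000, 60000); rates <- c(1.5, 3)
  ep <- elongation_profile(lens, rates)
  ip <- init_profile(1, "transient_up", fold = 4, onset_time = 0,
                     off_time = 20)
  binc <- seq(500, 99500, by = 1000)
  tau <- vapply(binc, function(x) oracle_travel_time(lens, rates, x), 0)
  for (w in list(c(0, 30), c(30, 60))) {
    got <- expected_coverage(100000, ip, ep, w)
    want <- oracle_expected_coverage(oracle_rate_fun(ip$times, ip$rates),
                                     tau, w)
    expect_lt(max(abs(got - want)) / max(want), 0.01)
  }
})

test_that("sample_reads: determinism, rounding, and Poisson mean", {
  expect_equal(sample_reads(c(1.2, 3.7), 0, noise = "none"), c(0L, 0L))
  expect_equal(sample_reads(c(1.2, 3.7), 10, noise = "none"), c(12L, 37L))
  expect_error(sample_reads(c(1), -1), "read_depth")
  expect_error(sample_reads(c(-1), 1), ">= 0")
  a <- sample_reads(rep(2, 100), 5, seed = 11)
  b <- sample_reads(rep(2, 100), 5, seed = 11)
  expect_identical(a, b)
  # law of large numbers: mean of 1e4 draws at lambda = 100 within 3 s.e.
  draws <- sample_reads(rep(2, 1e4), 50, seed = 99)
  se <- sqrt(100 / 1e4)
  expect_lt(abs(mean(draws) - 100), 3 * se)
})

test_that("simulate_cohort: exact counts without noise and conservation", {
  sc <- wave_scenario(n = 2, length_bp = 100000, mode = "advancing",
                      depth = 3, noise = "none")
  dir <- withr::local_tempdir()
  res <- simulate_cohort(sc, dir)
  covset <- read_coverage_set(res$samples)
  g <- sc$genes[[1]]
  prof <- bruwave:::gene_profile(covset, "w0_30", list(
    gene_id = g$gene_id, chrom = g$chrom, start = g$start, end = g$end,
    strand = g$strand, length = g$end - g$start), 1000)
  ev <- expected_coverage(100000, g$init, g$elong, c(0, 30))
  expect_equal(prof, round(3 * ev))
  # conservation: library size = sum of rounded expectations over genes
  expected_total <- sum(vapply(sc$genes, function(g)
    sum(round(3 * expected_coverage(100000, g$init, g$elong, c(0, 30)))), 0))
  expect_equal(unname(res$library_sizes[["w0_30"]]), expected_total)
})

test_that("simulate_cohort is byte-identical under a fixed seed", {
  sc <- pattern_scenario(n_per = 1, seed = 5L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_cohort(sc, d1)
  simulate_cohort(sc, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     label = f)
  }
})

test_that("per-gene seed substreams are unaffected by cohort composition", {
  sc_small <- pattern_scenario(n_per = 1, seed = 3L)
  sc_big <- pattern_scenario(n_per = 2, seed = 3L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_cohort(sc_small, d1)
  simulate_cohort(sc_big, d2)
  c1 <- read_coverage_set(file.path(d1, "samples.tsv"))
  c2 <- read_coverage_set(file.path(d2, "samples.tsv"))
  g <- list(gene_id = "sustained_up_1", chrom = "chr_sustained_up",
            start = 0, end = 12000, strand = "+", length = 12000)
  expect_identical(bruwave:::gene_profile(c1, "w0_30", g, 1000),
                   bruwave:::gene_profile(c2, "w0_30", g, 1000))
})

test_that("minus-strand genes mirror their plus-strand twins", {
  init <- init_profile(0, "sustained_up", change_times = 0, epoch_rates = 2)
  ep <- function() elongation_profile(c(40000, 60000), c(1, 3))
  plus <- sim_gene("gp", "chrA", 0, 100000, "+", init, ep())
  minus <- sim_gene("gm", "chrB", 0, 100000, "-", init, ep())
  sc <- sim_scenario(list(plus, minus), read_depth = 2, noise = "none")
  dir <- withr::local_tempdir()
  res <- simulate_cohort(sc, dir)
  covset <- read_coverage_set(res$samples)
  for (w in c("w0_30", "w60_90")) {
    pp <- bruwave:::gene_profile(covset, w, list(
      gene_id = "gp", chrom = "chrA", start = 0, end = 1e5, strand = "+",
      length = 1e5), 1000)
    pm <- bruwave:::gene_profile(covset, w, list(
      gene_id = "gm", chrom = "chrB", start = 0, end = 1e5, strand = "-",
      length = 1e5), 1000)
    expect_identical(pp, pm)
    # and the minus-strand file really extends leftward from the TSS at end
    raw <- covset$windows[[w]][["-"]]
    expect_true(all(raw$end <= 1e5))
  }
})

test_that("truth manifest fronts are consistent with front_position", {
  sc <- wave_scenario(n = 21, length_bp = 300000, rates = 2.0,
                      mode = "advancing", noise = "none")
  dir <- withr::local_tempdir()
  res <- simulate_cohort(sc, dir)
  truth <- bruwave:::read_tsv_hash(res$truth)
  expect_equal(nrow(truth), 21)
  expect_true(all(truth$front_1 == 60000 & truth$front_4 == 240000))
  disp <- as.matrix(truth[, grep("^disp_kb_", names(truth))])
  expect_true(all(disp == 60))
  rates <- as.matrix(truth[, grep("^rate_", names(truth))])
  expect_true(all(rates == 2))
  # fronts non-decreasing across windows
  fr <- as.matrix(truth[, paste0("front_", 1:4)])
  expect_true(all(diff(t(fr)) >= 0))
})

test_that("overlapping same-strand genes are flagged with a warning", {
  init <- init_profile(1)
  g1 <- sim_gene("a", "chr1", 0, 50000, "+", init)
  g2 <- sim_gene("b", "chr1", 30000, 80000, "+", init)
  sc <- sim_scenario(list(g1, g2), noise = "none")
  dir <- withr::local_tempdir()
  expect_warning(res <- simulate_cohort(sc, dir), "overlap")
  truth <- bruwave:::read_tsv_hash(res$truth)
  expect_true(all(truth$overlap))
})
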
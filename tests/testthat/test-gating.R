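panel <- hn_panel()
params <- generator_params(panel)

test_that("ArcSinh transform matches the closed form and preserves order", {
  ev <- simulate_sample(small_entry(ctc_total = 20L), panel, params,
                        seed = 5)
  tr <- arcsinh_transform(ev, cofactor = 5)
  expect_equal(asinh(0), 0)
  expect_equal(round(asinh(5 / 5), 4), 0.8814)  # asinh(1) = ln(1 + sqrt 2)
  # direct check on a channel
  expect_equal(tr$exprs[, "EpCAM"], asinh(ev$exprs[, "EpCAM"] / 5))
  expect_equal(order(tr$exprs[, "EpCAM"]), order(ev$exprs[, "EpCAM"]))
  # acquisition channels untouched
  for (ch in acquisition_channels(panel))
    expect_identical(tr$exprs[, ch], ev$exprs[, ch])
  # idempotence is forbidden
  expect_error(arcsinh_transform(tr), "already")
  expect_error(arcsinh_transform(ev, cofactor = 0), "positive")
})

test_that("Gaussian clean-up recovers the generated debris fraction", {
  entry <- small_entry(ctc_total = 50L, debris_fraction = 0.05)
  entry$carrier_count <- 4000L
  hits <- vapply(1:5, function(s) {
    ev <- simulate_sample(entry, panel, params, seed = 100 + s)
    cl <- gaussian_cleanup(ev)
    truth_debris <- ev$truth == "debris"
    agree <- mean((cl$labels == "debris") == truth_debris)
    expect_gte(agree, 0.95)
    mean(cl$labels == "debris")
  }, numeric(1))
  n <- 4000 + 300 + 500
  se <- sqrt(0.05 * 0.95 / n)
  expect_lt(abs(mean(hits) - 0.05), 3 * se)
})

test_that("clean-up edge cases: no debris, vacuous windows, missing channel", {
  ev <- simulate_sample(small_entry(ctc_total = 10L, debris_fraction = 0),
                        panel, params, seed = 8)
  cl <- gaussian_cleanup(ev)
  expect_equal(sum(cl$labels == "debris"), 0L)
  # (0, 1) quantile windows remove nothing
  ev2 <- simulate_sample(small_entry(ctc_total = 10L), panel, params,
                         seed = 9)
  cl2 <- gaussian_cleanup(ev2, gate_thresholds(acq_quantiles = c(0, 1)))
  expect_equal(sum(cl2$labels == "debris"), 0L)
  ev3 <- ev
  ev3$exprs <- ev3$exprs[, colnames(ev3$exprs) != "Residual"]
  expect_error(gaussian_cleanup(ev3), "Residual")
})

test_that("deconvolution separates carrier, control and enriched", {
  entry <- small_entry(ctc_total = 40L)
  ev <- arcsinh_transform(
    simulate_sample(entry, panel, params, seed = 21))
  clean <- gaussian_cleanup(ev)
  dec <- deconvolute_populations(clean$events, gate_thresholds())
  truth <- clean$events$truth
  # population fractions recovered within 1% of generated fractions
  for (pop in c("carrier", "control")) {
    expect_lt(abs(mean(dec$labels == pop) - mean(truth == pop)), 0.01)
  }
  # per-event agreement on carriers/controls
  expect_gt(mean((dec$labels == "carrier") == (truth == "carrier")), 0.99)
  # a sample with zero control cells yields no control labels
  entry0 <- entry; entry0$control_count <- 0L
  ev0 <- arcsinh_transform(simulate_sample(entry0, panel, params, seed = 3))
  dec0 <- deconvolute_populations(gaussian_cleanup(ev0)$events)
  expect_equal(sum(dec0$labels == "control"), 0L)
  # untransformed input refused
  expect_error(deconvolute_populations(
    simulate_sample(entry, panel, params, seed = 1)), "transform")
})

test_that("valley-seeking refuses unimodal channels without a fallback", {
  withr::with_seed(1, x <- rnorm(4000))
  expect_error(ctcyto:::find_valley_cut(x, fallback = NA_real_),
               "unimodal")
  expect_equal(ctcyto:::find_valley_cut(x, fallback = 2.5), 2.5)
  withr::with_seed(2, y <- c(rnorm(2000, 0, 0.3), rnorm(2000, 4, 0.3)))
  cut <- ctcyto:::find_valley_cut(y, fallback = NA_real_)
  expect_gt(cut, 1); expect_lt(cut, 3)
})

test_that("CTC rule gates on CD45, lineage exclusion and pan-cytokeratin", {
  entry <- small_entry(ctc_total = 60L)
  ev <- arcsinh_transform(simulate_sample(entry, panel, params, seed = 31))
  enr <- enriched_events(deconvolute_populations(gaussian_cleanup(ev)$events))
  res <- identify_ctcs(enr, panel)
  truth_ctc <- startsWith(enr$truth, "ctc")
  expect_lte(abs(sum(res$labels == "ctc") - sum(truth_ctc)), 2)

  # exclusion dominates: CD45 above cut is a leucocyte whatever panCK is
  x <- enr$exprs[1, , drop = FALSE]
  x[, c("CD45", "Pan-cytokeratin")] <- c(5, 5)
  x[, lineage_exclusion_markers(panel)] <- 0
  one <- enr[1]; one$exprs <- x
  expect_equal(identify_ctcs(one, panel,
                             gate_thresholds(auto_marker_cuts = FALSE))$labels,
               "enriched_leucocyte")
  # rule satisfied: all exclusion markers at 0, panCK above cut
  x[, "CD45"] <- 0
  one$exprs <- x
  expect_equal(identify_ctcs(one, panel,
                             gate_thresholds(auto_marker_cuts = FALSE))$labels,
               "ctc")
  # panel missing an exclusion marker is an error
  broken <- enr
  broken$exprs <- broken$exprs[, colnames(broken$exprs) != "CD14"]
  expect_error(identify_ctcs(broken, panel), "CD14")
})

test_that("positivity scoring and per-ml conversion follow the rules", {
  thr <- gate_thresholds()
  expect_equal(score_positivity(4, thr), "negative")
  expect_equal(score_positivity(18, thr), "positive")
  expect_equal(score_positivity(0, thr), "negative")
  expect_error(score_positivity(-1, thr), "non-negative")

  expect_equal(per_ml(218, 9), 24L)
  expect_equal(per_ml(18, 9), 2L)
  expect_equal(per_ml(0, 9), 0L)
  expect_equal(per_ml(13, 9), 1L)   # 1.44 rounds half-up to 1
  expect_equal(per_ml(14, 9), 2L)   # 1.56 rounds half-up to 2
  expect_error(per_ml(5, 0), "positive")
})

test_that("gate labels partition every event at each stage", {
  run <- default_run()
  g <- run$gates[["P5"]]
  expect_equal(sum(g$tallies), nrow(run$samples[["P5"]]$exprs))
  expect_true(all(g$labels %in% c("debris", "carrier", "control",
                                  "enriched_leucocyte", "ctc")))
  expect_equal(as.vector(table(factor(g$labels, names(g$tallies)))),
               as.vector(g$tallies))
})

test_that("monotone thresholds: stricter cuts never increase tallies", {
  run <- default_run()
  ev <- arcsinh_transform(run$samples[["P4"]])
  enr <- enriched_events(deconvolute_populations(gaussian_cleanup(ev)$events))
  tallies <- vapply(c(1, 2, 3, 4.5), function(pk) {
    thr <- gate_thresholds(panck_min = pk, auto_marker_cuts = FALSE)
    sum(identify_ctcs(enr, run$panel, thr)$labels == "ctc")
  }, numeric(1))
  expect_true(all(diff(tallies) <= 0))

  counts <- run$cohort$patients$ctc_total
  positives <- vapply(c(0, 4, 20, 100), function(bg) {
    thr <- gate_thresholds(background_ctc_threshold = bg)
    sum(vapply(counts, score_positivity, "", thresholds = thr) == "positive")
  }, numeric(1))
  expect_true(all(diff(positives) <= 0))
})
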
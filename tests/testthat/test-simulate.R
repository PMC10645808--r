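panel <- hn_panel()
params <- generator_params(panel)

test_that("simulated samples are deterministic and respect composition", {
  entry <- small_entry(ctc_total = 37L)
  ev1 <- simulate_sample(entry, panel, params, seed = 42)
  ev2 <- simulate_sample(entry, panel, params, seed = 42)
  expect_identical(ev1$exprs, ev2$exprs)
  expect_identical(ev1$truth, ev2$truth)
  ev3 <- simulate_sample(entry, panel, params, seed = 43)
  expect_false(identical(ev1$exprs, ev3$exprs))

  # ctc_* events equal the configured total exactly, before any gating
  expect_equal(sum(startsWith(ev1$truth, "ctc")), 37L)
  expect_equal(length(ev1$truth), nrow(ev1$exprs))
  expect_true(all(ev1$exprs >= 0))

  # zero-count entry has no ctc events
  ev0 <- simulate_sample(small_entry(ctc_total = 0L), panel, params, seed = 1)
  expect_equal(sum(startsWith(ev0$truth, "ctc")), 0L)
})

test_that("generator rejects invalid composition settings", {
  bad <- small_entry()
  bad$mixture <- c(epithelial = 0.6, early_EMT = 0.6, advanced_EMT = -0.2)
  expect_error(simulate_sample(bad, panel, params, seed = 1), "simplex|sum to 1")
  bad2 <- small_entry(ctc_total = -5L)
  expect_error(simulate_sample(bad2, panel, params, seed = 1), "non-negative")
  bad3 <- small_entry(ctc_total = 600L)  # exceeds enriched_count 500
  expect_error(simulate_sample(bad3, panel, params, seed = 1), "enriched_count")
})

test_that("barcode and osmium channels separate carriers and controls", {
  ev <- arcsinh_transform(
    simulate_sample(small_entry(), panel, params, seed = 7))
  bc <- ev$exprs[, barcode_marker(panel)]
  os <- ev$exprs[, control_marker(panel)]
  carriers <- ev$truth == "carrier"
  controls <- ev$truth == "control"
  expect_gt(median(bc[carriers]), 4)
  expect_lt(quantile(bc[!carriers & ev$truth != "debris"], 0.99), 2)
  expect_gt(median(os[controls]), 4)
  expect_lt(quantile(os[!controls & ev$truth != "debris"], 0.99), 2)
})

test_that("simulated intensities match the configured archetype moments", {
  # moment fidelity at n = 10,000: empirical ArcSinh mean within 3
  # standard errors of the integral of the configured model
  n <- 10000L
  cells <- list(c("ctc_epithelial", "EpCAM"),
                c("ctc_early_emt", "Vimentin"),
                c("leucocyte", "CD45"),
                c("ctc_advanced_emt", "pCREB"))
  withr::with_seed(99, {
    for (cell in cells) {
      pop <- cell[1]; mk <- cell[2]
      block <- ctcyto:::draw_population(n, pop, panel, params)
      y <- asinh(block[, mk] / params$cofactor)
      expected <- expected_arcsinh_mean(params, pop, mk)
      se <- sd(y) / sqrt(n)
      expect_lt(abs(mean(y) - expected), 3 * se)
    }
  })
})

test_that("archetype ordering holds empirically at n = 10,000", {
  n <- 10000L
  withr::with_seed(123, {
    med <- function(pop, mk) {
      median(asinh(ctcyto:::draw_population(n, pop, panel, params)[, mk] /
                     params$cofactor))
    }
    epcam <- c(med("ctc_epithelial", "EpCAM"),
               med("ctc_early_emt", "EpCAM"),
               med("ctc_advanced_emt", "EpCAM"))
    expect_true(epcam[1] > epcam[2] && epcam[2] > epcam[3])
    vim <- c(med("ctc_epithelial", "Vimentin"),
             med("ctc_early_emt", "Vimentin"),
             med("ctc_advanced_emt", "Vimentin"))
    expect_true(vim[2] > vim[1] && vim[3] > vim[1])
  })
})

test_that("generator parameter validation catches broken archetypes", {
  bad <- params
  bad$m["EpCAM", "ctc_epithelial"] <- 0.1
  expect_error(ctcyto:::validate_genparams(bad), "EpCAM")
  expect_error(generator_params(panel, sdlog = -1), "positive")
})

test_that("tumour count matrices encode the class design", {
  cm <- simulate_tumour_counts(design = c(3, 3, 4), seed = 2)
  expect_equal(as.integer(table(cm$samples$class)[c("epithelial",
                                                    "mesenchymal", "mixed")]),
               c(3L, 3L, 4L))
  expect_true(all(cm$counts >= 0))
  expect_true(all(cm$counts == round(cm$counts)))
  # disjoint signature sets
  sig <- emt_signature()
  expect_length(intersect(sig$epithelial, sig$mesenchymal), 0)
  # matching signature genes elevated
  epi_idx <- cm$genes$set == "signature_epithelial"
  epi_cols <- cm$samples$class == "epithelial"
  mes_cols <- cm$samples$class == "mesenchymal"
  expect_gt(mean(cm$counts[epi_idx, epi_cols]),
            3 * mean(cm$counts[epi_idx, mes_cols]))
  # degenerate single-class design: mesenchymal genes stay at baseline
  cm1 <- simulate_tumour_counts(design = c(1, 0, 0), seed = 3)
  mes_idx <- cm1$genes$set == "signature_mesenchymal"
  bg_idx <- cm1$genes$set == "background"
  expect_lt(abs(log2(mean(cm1$counts[mes_idx, 1]) /
                       mean(cm1$counts[bg_idx, 1]))), 1)
  expect_error(simulate_tumour_counts(design = c(0, 0, 0)), "empty")
})

test_that("null tumour matrices (fold 1) carry no class signal", {
  ps <- unlist(lapply(1:4, function(s) {
    cm <- simulate_tumour_counts(design = c(4, 4, 0), fold = 1, seed = s,
                                 n_background = 60)
    de <- nb_wald_de(cm, cm$samples$class)
    de$p
  }))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("bulk CTC counts elevate marker genes with expressing cells", {
  coh <- hn_cohort()
  pan <- hn_panel()
  # patient 14: 218 CTCs, half early-EMT: vimentin gene elevated in the
  # enriched sample, on average over seeds
  ov <- list(P14 = c(epithelial = 0.5, early_EMT = 0.5, advanced_EMT = 0))
  lfc <- vapply(1:6, function(s) {
    bulk <- simulate_bulk_ctc_counts(coh, pan, params, patients = "P14",
                                     seed = s, mixture_override = ov)
    vim <- bulk$genes$gene == "VIM"
    enr <- bulk$samples$role == "enriched"
    log2((bulk$counts[vim, enr] + 1) / (bulk$counts[vim, !enr] + 1))
  }, numeric(1))
  expect_gt(mean(lfc), 1)

  # null patient: no epithelial marker gene elevated beyond noise
  bulk0 <- simulate_bulk_ctc_counts(coh, pan, params, patients = "P12",
                                    seed = 1)
  dm <- suppressWarnings(panel_dge_map(paired_bulk_de(bulk0), pan))
  expect_equal(sum(dm[c("EpCAM", "Pan-cytokeratin", "E-cadherin"), 1]), 0)

  # zero effect-size override: paired samples exchangeable
  bulkn <- simulate_bulk_ctc_counts(coh, pan, params, patients = "P14",
                                    gain = 0, seed = 5)
  den <- paired_bulk_de(bulkn)
  expect_equal(sum(den$P14$significant), 0)
})
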
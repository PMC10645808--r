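test_that("median-of-ratios normalization matches its closed forms", {
  withr::with_seed(3, m <- matrix(rnbinom(50 * 4, mu = 50, size = 5), 50, 4))
  rownames(m) <- paste0("g", 1:50)
  # identical columns: all factors 1
  same <- cbind(m[, 1], m[, 1], m[, 1])
  rownames(same) <- rownames(m)
  nz <- same[rowSums(same == 0) == 0, ]
  expect_equal(unname(median_of_ratios_normalize(same)$size_factors),
               rep(1, 3))
  # doubling one column exactly doubles its factor relative to the rest
  dbl <- cbind(m[, 1], m[, 1] * 2)
  res <- median_of_ratios_normalize(dbl)
  expect_equal(unname(res$size_factors[2] / res$size_factors[1]), 2)
  # genes with any zero are excluded from the reference median
  z <- rbind(c(0, 1000), c(10, 10), c(20, 20), c(30, 30))
  rz <- median_of_ratios_normalize(z)
  expect_equal(unname(rz$size_factors), c(1, 1))
  # no all-nonzero gene is an error
  expect_error(median_of_ratios_normalize(rbind(c(0, 5), c(5, 0))),
               "nonzero")
  # idempotence: normalizing a normalized matrix gives factors 1
  norm1 <- median_of_ratios_normalize(m)$normalized
  sf2 <- median_of_ratios_normalize(norm1)$size_factors
  expect_equal(unname(sf2), rep(1, 4), tolerance = 1e-10)
})

test_that("BH adjustment equals the brute-force step-up on small inputs", {
  withr::with_seed(13, {
    for (rep in 1:25) {
      n <- sample(1:20, 1)
      p <- runif(n)^sample(1:3, 1)
      expect_equal(stats::p.adjust(p, "BH"), bh_stepup_oracle(p))
    }
  })
  # the package's DE path uses the same adjustment
  cm <- simulate_tumour_counts(design = c(3, 3, 0), seed = 4,
                               n_background = 0)
  de <- nb_wald_de(cm, cm$samples$class)
  expect_equal(de$p_adj, bh_stepup_oracle(de$p))
})

test_that("NB Wald DE is calibrated under the generator null", {
  ps <- unlist(lapply(1:5, function(s) {
    cm <- simulate_tumour_counts(design = c(5, 5, 0), fold = 1, seed = s,
                                 n_background = 250)
    nb_wald_de(cm, cm$samples$class)$p
  }))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  expect_lte(mean(ps < 0.05), 0.10)   # within 2x nominal
})

test_that("NB Wald DE detects a strong fold change at small n", {
  hits <- vapply(1:20, function(s) {
    withr::with_seed(s, {
      m <- rbind(target = c(rnbinom(3, mu = 100, size = 10),
                            rnbinom(3, mu = 800, size = 10)),
                 matrix(rnbinom(50 * 6, mu = 100, size = 10), 50, 6))
    })
    rownames(m) <- c("target", paste0("g", 1:50))
    # the simulation dispersion is known here, so the normal Wald
    # reference applies
    de <- nb_wald_de(m, rep(c("a", "b"), each = 3), dispersion = 0.1)
    de$significant[de$gene == "target"]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("DE contract: identical columns and degenerate groups", {
  m <- matrix(rep(c(5L, 10L, 20L), 4), 3, 4)
  rownames(m) <- paste0("g", 1:3)
  de <- nb_wald_de(m, c("a", "a", "b", "b"))
  expect_true(all(de$p == 1))
  expect_true(all(!de$significant))
  expect_true(all(de$log2fc == 0))
  expect_error(nb_wald_de(m, rep("a", 4)), "two groups")
  expect_error(nb_wald_de(m[, 1:2], c("a", "b")), "dispersion")
})

test_that("panel DGE map has the mapped-marker by patient shape", {
  run <- default_run()
  bulk <- simulate_bulk_ctc_counts(run$cohort, run$panel, run$params,
                                   patients = c("P1", "P14"), seed = 2)
  de <- paired_bulk_de(bulk)
  expect_warning(dm <- panel_dge_map(de, run$panel), "skipped")
  map <- marker_gene_map(run$panel)
  expect_equal(dim(dm), c(sum(!is.na(map$gene)), 2L))
  expect_true(all(dm %in% c(0L, 1L)))
  # a high-count epithelial-dominant patient shows epithelial transcripts
  expect_gt(sum(dm[c("EpCAM", "Pan-cytokeratin", "E-cadherin"), "P14"]), 0)
  # a patient lacking its matched PBMC sample is rejected
  broken <- bulk
  keep <- !(broken$samples$patient_id == "P1" &
              broken$samples$role == "matched_pbmc")
  broken$samples <- broken$samples[keep, ]
  broken$counts <- broken$counts[, keep]
  expect_error(paired_bulk_de(broken), "matched PBMC")
})

test_that("tumour EMT-signature classification recovers the design", {
  for (s in c(2, 7)) {
    cm <- simulate_tumour_counts(design = c(3, 3, 4), seed = s)
    cls <- emt_signature_cluster(cm)
    expect_equal(unname(cls$class), cm$samples$class)
  }
  # invariance to sample order
  cm <- simulate_tumour_counts(design = c(3, 3, 4), seed = 2)
  perm <- c(7, 2, 9, 1, 5, 10, 3, 8, 4, 6)
  cm2 <- cm
  cm2$counts <- cm$counts[, perm]
  cm2$samples <- cm$samples[perm, ]
  cls2 <- emt_signature_cluster(cm2)
  expect_equal(unname(cls2$class), cm$samples$class[perm])
  # degenerate identical samples are refused
  flat <- cm
  flat$counts <- matrix(rep(cm$counts[, 1], 10), ncol = 10,
                        dimnames = dimnames(cm$counts))
  expect_error(emt_signature_cluster(flat), "degenerate|identical")
  expect_error(emt_signature_cluster(cm$counts[, 1:2]), "3 samples")
})

test_that("concordance report counts agreements and runs the ANOVAs", {
  run <- default_run()
  pats <- paste0("P", 1:10)
  dm <- matrix(0L, 3, 10,
               dimnames = list(c("EpCAM", "Vimentin", "Ki67"), pats))
  dm["EpCAM", 1:9] <- 1L
  dm["Vimentin", 1:3] <- 1L
  cyto <- data.frame(patient_id = pats,
                     positivity = rep("positive", 10),
                     ctc_total = run$cohort$patients$ctc_total[1:10],
                     emt_fraction = c(rep(0.8, 3), rep(0.5, 5), 0.05, 0.02))
  cls <- stats::setNames(rep(c("epithelial", "mesenchymal", "mixed"),
                             c(3, 3, 4)), pats)
  rep <- concordance_report(cyto, dm, tumour_class = cls)
  expect_equal(unname(rep$agreement["positivity"]), 9L)
  # vimentin flagged for 3; cytometry sees EMT in 8 -> 5 disagreements
  expect_equal(unname(rep$agreement["emt"]), 5L)
  expect_true(all(rep$anova[, "p"] > 0 & rep$anova[, "p"] <= 1))
  # identical calls agree n/n
  cyto2 <- cyto
  cyto2$emt_fraction <- c(rep(0.8, 3), rep(0.01, 7))
  dm2 <- dm; dm2["EpCAM", ] <- 1L
  rep2 <- concordance_report(cyto2, dm2, panel = run$panel)
  expect_equal(unname(rep2$agreement["positivity"]), 10L)
  expect_equal(unname(rep2$agreement["emt"]), 10L)
  expect_error(concordance_report(cyto[1:5, ], dm), "unmatched")
})

test_that("tumour-class ANOVA p is uniform when classes are independent", {
  run <- default_run()
  pats <- paste0("P", 1:10)
  dm <- matrix(0L, 2, 10, dimnames = list(c("EpCAM", "Vimentin"), pats))
  cyto <- data.frame(patient_id = pats, positivity = "positive",
                     ctc_total = run$cohort$patients$ctc_total[1:10],
                     emt_fraction = 0.5)
  withr::with_seed(19, {
    ps <- vapply(1:150, function(i) {
      cyto$ctc_total <- rnorm(10, 50, 20)
      cls <- stats::setNames(sample(rep(c("e", "m", "x"), c(3, 3, 4))),
                             pats)
      concordance_report(cyto, dm, tumour_class = cls)$anova["ctc_total", "p"]
    }, numeric(1))
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
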
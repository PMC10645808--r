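test_that("Mann-Whitney U matches its definition and enumeration", {
  t1 <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(t1$U, 0)
  expect_equal(t1$p, 0.1)        # 2 of the 20 label assignments
  expect_equal(t1$method, "exact")
  # identical multisets: U = n^2/2, p = 1
  t2 <- mann_whitney_u(c(1, 2, 2, 7), c(1, 2, 2, 7))
  expect_equal(t2$U, 8)
  expect_equal(t2$p, 1)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
  # refusal: ties with n1+n2 > 12 cannot be enumerated
  expect_error(mann_whitney_u(c(rep(1, 7), 2:7), c(2:8), exact = TRUE),
               "refused")
})

test_that("exact p equals the permutation oracle for all n1+n2 <= 8", {
  withr::with_seed(31, {
    for (rep in 1:30) {
      n1 <- sample(1:6, 1)
      n2 <- sample(seq_len(8 - n1), 1)
      vals <- if (rep %% 2 == 0) sample(1:5, n1 + n2, replace = TRUE)
      else rnorm(n1 + n2)
      a <- vals[seq_len(n1)]; b <- vals[-seq_len(n1)]
      got <- mann_whitney_u(a, b)
      ora <- mwu_enum_oracle(a, b)
      expect_equal(got$U, ora$U)
      expect_equal(got$p, ora$p)
    }
  })
})

test_that("exact tie-free p agrees with the standard library test", {
  withr::with_seed(77, {
    for (rep in 1:10) {
      a <- rnorm(4); b <- rnorm(5)
      got <- mann_whitney_u(a, b)
      ref <- stats::wilcox.test(a, b, exact = TRUE)
      expect_equal(got$p, ref$p.value)
    }
  })
})

test_that("large-sample p values are uniform under the null", {
  # continuous draws from one leucocyte archetype, split at random
  panel <- hn_panel(); params <- generator_params(panel)
  withr::with_seed(55, {
    pool <- asinh(ctcyto:::draw_population(48000, "leucocyte", panel,
                                           params)[, "CD45"] / 5)
    ps <- vapply(1:600, function(i) {
      idx <- ((i - 1) * 80 + 1):(i * 80)
      x <- pool[idx]
      mann_whitney_u(x[1:40], x[41:80])$p
    }, numeric(1))
  })
  # U is discrete, so replicate p values tie; the KS distance is still
  # the right yardstick
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("subgroup contrasts report every pair per marker", {
  run <- default_run()
  st <- compare_subgroups(run$ctcs, run$subgroups$event_label,
                          markers = c("pCREB", "Snail1"))
  expect_equal(nrow(st), 2 * 3)   # 2 markers x 3 subgroup pairs
  expect_true(all(st$p > 0 & st$p <= 1))
  expect_true(all(st$U >= 0 & st$U <= st$n1 * st$n2))
  adj <- compare_subgroups(run$ctcs, run$subgroups$event_label,
                           markers = c("pCREB"), adjust = TRUE)
  expect_true(all(adj$p_adj >= adj$p))
  expect_error(compare_subgroups(run$ctcs,
                                 rep("one", nrow(run$ctcs$exprs))),
               "two subgroups")
})

test_that("composition matrix is row-normalized over positive patients", {
  run <- default_run()
  comp <- composition_matrix(run$ctcs, run$profile)
  expect_equal(nrow(comp$matrix), 13L)   # the CTC-positive patients
  expect_true(all(abs(rowSums(comp$matrix) - 1) < 1e-12))
  expect_true(all(comp$matrix >= 0))
  # a patient whose CTCs sit in one cluster has a unit row
  unit <- structure(list(event_metacluster = rep(2L, 7)),
                    class = "cluster_profile")
  ev <- run$ctcs[1:7]; ev$patient_id <- rep("PX", 7)
  cm <- composition_matrix(ev, unit)
  expect_equal(unname(cm$matrix[1, ]), 1)
})

test_that("composition PCA conserves variance and recovers archetypes", {
  run <- default_run()
  comp <- composition_matrix(run$ctcs, run$profile)
  pca <- pca_composition(comp)
  expect_equal(sum(pca$explained), 1)
  # loadings orthonormal
  ld <- pca$loadings
  expect_equal(unname(crossprod(ld)), diag(ncol(ld)), tolerance = 1e-10)
  # score variance equals centred-input variance
  xc <- scale(comp$matrix, scale = FALSE)
  expect_equal(sum(apply(pca$scores, 2, var)), sum(apply(xc, 2, var)))
  # full reconstruction of the centred matrix
  rec <- pca$scores %*% t(ld[, seq_len(ncol(pca$scores))])
  expect_lt(max(abs(rec - xc)), 1e-10)

  # four constructed composition archetypes are recovered as score groups
  arch <- rbind(c(.7, .1, .1, .05, .05), c(.05, .7, .1, .1, .05),
                c(.05, .1, .7, .1, .05), c(.1, .05, .05, .1, .7))
  withr::with_seed(11, {
    truth <- rep(1:4, length.out = 13)
    m <- t(sapply(truth, function(k) {
      p <- arch[k, ] + runif(5, 0, 0.05); p / sum(p)
    }))
  })
  rownames(m) <- paste0("P", 1:13); colnames(m) <- paste0("c", 1:5)
  pc4 <- pca_composition(structure(list(matrix = m),
                                   class = "patient_composition"),
                         seed = 2)
  expect_gte(ari(truth, pc4$groups), 0.8)
  # identical patients: no variance beyond the first component
  flat <- matrix(rep(c(.5, .5), each = 4), 4, 2)
  rownames(flat) <- paste0("Q", 1:4)
  pcf <- pca_composition(structure(list(matrix = flat),
                                   class = "patient_composition"))
  expect_lt(max(abs(pcf$scores)), 1e-12)
  expect_error(pca_composition(structure(list(matrix = flat),
                                         class = "patient_composition"),
                               n_components = 9), "fewer patients")
})

test_that("clinical associations run the cohort test battery", {
  run <- default_run()
  totals <- stats::setNames(run$cohort$patients$ctc_total,
                            run$cohort$patients$patient_id)
  emt <- withr::with_seed(8, stats::setNames(
    runif(13, 0.5, 0.9),
    setdiff(run$cohort$patients$patient_id, "P12")))
  cls <- stats::setNames(rep(c("epithelial", "mesenchymal", "mixed"),
                             c(3, 3, 4)),
                         run$cohort$patients$patient_id[1:10])
  rep <- clinical_associations(run$cohort, totals, emt_fraction = emt,
                               tumour_class = cls)
  expect_equal(nrow(rep$logistic), 3L)
  expect_true(all(rep$logistic$wald_p > 0 & rep$logistic$wald_p <= 1))
  expect_true(!is.null(rep$t_test))
  expect_true(rep$anova$p > 0 && rep$anova$p <= 1)
  # identical groups in the t-test: t = 0, p = 1
  emt2 <- emt; emt2[] <- 0.5
  rep2 <- clinical_associations(run$cohort, totals, emt_fraction = emt2)
  expect_equal(rep2$t_test$statistic, 0)
  expect_equal(rep2$t_test$p, 1)
  # single tumour class is a degenerate ANOVA design
  expect_error(clinical_associations(run$cohort, totals,
                                     tumour_class = cls[cls == "mixed"]),
               "two tumour classes")
})

test_that("logistic Wald p is uniform when outcome is independent of count", {
  run <- default_run()
  coh <- run$cohort
  totals <- stats::setNames(coh$patients$ctc_total, coh$patients$patient_id)
  withr::with_seed(91, {
    ps <- vapply(1:120, function(i) {
      coh2 <- coh
      coh2$patients$n_stage <- sample(c("0", "1"), 14, replace = TRUE)
      rep <- clinical_associations(coh2, totals)
      rep$logistic$wald_p[rep$logistic$outcome == "node_positive"]
    }, numeric(1))
  })
  ps <- ps[!is.na(ps)]
  # small-sample Wald p is only approximately uniform; check it is not
  # grossly anticonservative
  expect_lt(mean(ps < 0.05), 0.1)
})
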
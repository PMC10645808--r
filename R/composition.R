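#' Per-patient metacluster composition matrix
#'
#' Fractions of each positive patient's CTCs falling in each
#' metacluster.  Rows are patients (positivity-positive only), columns
#' metaclusters; each row sums to 1.
#'
#' @param events Concatenated `ctc_events` (with `patient_id`).
#' @param profile A [cluster_profiles()] object for those events.
#' @return A list of class `patient_composition` with `matrix`
#'   (patients x metaclusters) and `counts`.
#' @export
composition_matrix <- function(events, profile) {
  pid <- events$patient_id
  if (is.null(pid)) stop("events must carry per-event patient identifiers")
  mc <- profile$event_metacluster
  tab <- table(pid, factor(mc, sort(unique(profile$event_metacluster))))
  if (any(rowSums(tab) == 0)) stop("patient with zero CTCs in composition")
  frac <- sweep(unclass(tab), 1, rowSums(tab), "/")
  colnames(frac) <- paste0("c", colnames(frac))
  res <- list(matrix = frac, counts = unclass(tab))
  class(res) <- "patient_composition"
  res
}

#' PCA of the patient composition matrix
#'
#' Centred (uncentred-variance-preserving) principal component analysis
#' of the per-patient metacluster composition, followed by an explicit
#' patient-grouping rule: k-means on the component scores with k chosen
#' by mean silhouette width over `k_grid` (score plots are often grouped
#' visually; this rule makes the grouping reproducible).
#'
#' @param comp A [composition_matrix()] result.
#' @param n_components Number of components to retain in `scores`
#'   (default: all).
#' @param k_grid Candidate numbers of patient groups (default 2:6).
#' @param seed Seed for the k-means restarts.
#' @return A list of class `pca_result`: `scores`, `loadings`,
#'   `explained` (variance fractions over all components), `groups`
#'   (patient -> group), `k`.
#' @export
pca_composition <- function(comp, n_components = NULL, k_grid = 2:6,
                            seed = 1) {
  x <- comp$matrix
  if (nrow(x) < 2) stop("PCA needs at least two patients")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  nc <- if (is.null(n_components)) ncol(pc$x) else n_components
  if (nc > ncol(pc$x)) stop("fewer patients than components requested")
  scores <- pc$x[, seq_len(nc), drop = FALSE]

  k_grid <- k_grid[k_grid < nrow(x)]
  groups <- rep(1L, nrow(x)); best_k <- 1L
  if (length(k_grid) && stats::sd(scores[, 1]) > 0) {
    sil <- rep(-Inf, length(k_grid))
    fits <- vector("list", length(k_grid))
    withr::with_seed(as.integer(seed), {
      for (i in seq_along(k_grid)) {
        km <- stats::kmeans(scores, centers = k_grid[i], nstart = 25)
        fits[[i]] <- km
        if (length(unique(km$cluster)) > 1) {
          sw <- cluster::silhouette(km$cluster, stats::dist(scores))
          sil[i] <- mean(sw[, "sil_width"])
        }
      }
    })
    best <- which.max(sil)
    best_k <- k_grid[best]
    groups <- fits[[best]]$cluster
  }
  names(groups) <- rownames(x)
  res <- list(scores = scores, loadings = pc$rotation,
              explained = explained, groups = groups, k = best_k,
              center = pc$center)
  class(res) <- "pca_result"
  res
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> ", nrow(x$scores), " patients, ", x$k,
      " score groups; PC1 ", round(100 * x$explained[1], 1),
      "% / PC2 ", round(100 * x$explained[2], 1), "%\n", sep = "")
  invisible(x)
}

#' Clinical association tests
#'
#' The descriptive association battery run on the cohort: univariate
#' logistic regressions of each binary clinical outcome (advanced
#' T stage, nodal positivity, advanced overall stage) on total CTC count
#' (maximum-likelihood fit, Wald p); a Welch two-sample t-test of the
#' per-patient EMT CTC fraction by nodal status; and a one-way ANOVA of
#' CTC count across tumour expression classes.  Complete separation in a
#' logistic fit is reported as a flagged non-convergence, not an error.
#'
#' @param cohort A [hn_cohort()] object.
#' @param ctc_totals Named per-patient identified CTC totals.
#' @param emt_fraction Named per-patient fraction of EMT (early +
#'   advanced) CTCs; patients missing from the vector are dropped from
#'   the t-test.
#' @param tumour_class Optional named per-patient tumour expression class
#'   for the ANOVA.
#' @return A list of class `clinical_report` with elements `logistic`
#'   (data frame: outcome, estimate, wald_p, converged), `t_test` and
#'   `anova`.
#' @export
clinical_associations <- function(cohort, ctc_totals, emt_fraction = NULL,
                                  tumour_class = NULL) {
  p <- cohort$patients
  count <- ctc_totals[p$patient_id]
  if (any(is.na(count))) stop("ctc_totals must cover every patient")
  outcomes <- list(
    t_advanced = as.integer(p$t_stage %in% c("3", "4a", "4b")),
    node_positive = as.integer(p$n_stage != "0"),
    stage_advanced = as.integer(p$stage %in% c("III", "IV"))
  )
  logistic <- do.call(rbind, lapply(names(outcomes), function(nm) {
    y <- outcomes[[nm]]
    converged <- TRUE
    fit <- withCallingHandlers(
      stats::glm(y ~ count, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities|did not converge", conditionMessage(w)))
          converged <<- FALSE
        invokeRestart("muffleWarning")
      })
    co <- summary(fit)$coefficients
    est <- if ("count" %in% rownames(co)) co["count", "Estimate"] else NA_real_
    wp <- if ("count" %in% rownames(co)) co["count", "Pr(>|z|)"] else NA_real_
    data.frame(outcome = nm, estimate = est, wald_p = wp,
               converged = converged && fit$converged,
               stringsAsFactors = FALSE)
  }))

  t_test <- NULL
  if (!is.null(emt_fraction)) {
    idx <- p$patient_id %in% names(emt_fraction)
    grp <- outcomes$node_positive[idx]
    val <- emt_fraction[p$patient_id[idx]]
    if (length(unique(grp)) == 2) {
      v1 <- val[grp == 1]; v0 <- val[grp == 0]
      if (stats::sd(v1) == 0 && stats::sd(v0) == 0 &&
            mean(v1) == mean(v0)) {
        t_test <- list(statistic = 0, p = 1,
                       means = c(node_positive = mean(v1),
                                 node_negative = mean(v0)))
      } else {
        tt <- stats::t.test(v1, v0)
        t_test <- list(statistic = unname(tt$statistic), p = tt$p.value,
                       means = c(node_positive = mean(v1),
                                 node_negative = mean(v0)))
      }
    }
  }

  anova <- NULL
  if (!is.null(tumour_class)) {
    idx <- p$patient_id %in% names(tumour_class)
    cls <- factor(tumour_class[p$patient_id[idx]])
    if (nlevels(cls) < 2) stop("ANOVA needs at least two tumour classes")
    fit <- stats::aov(count[idx] ~ cls)
    sm <- summary(fit)[[1]]
    anova <- list(F = sm[["F value"]][1], p = sm[["Pr(>F)"]][1],
                  df = sm[["Df"]])
  }
  structure(list(logistic = logistic, t_test = t_test, anova = anova),
            class = "clinical_report")
}

#' @export
print.clinical_report <- function(x, ...) {
  cat("<clinical_report>\n")
  print(x$logistic, row.names = FALSE)
  if (!is.null(x$t_test))
    cat("EMT fraction by nodal status: t = ", signif(x$t_test$statistic, 3),
        ", p = ", signif(x$t_test$p, 3), "\n", sep = "")
  if (!is.null(x$anova))
    cat("CTC count ~ tumour class: F = ", signif(x$anova$F, 3),
        ", p = ", signif(x$anova$p, 3), "\n", sep = "")
  invisible(x)
}
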
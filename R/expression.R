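#' Median-of-ratios size-factor normalization
#'
#' Per-sample size factor: the median, over genes with nonzero counts in
#' every sample, of the ratio of the sample's count to the gene's
#' geometric mean across samples.  Normalized counts are raw counts
#' divided by the sample's factor.  Genes containing any zero are
#' excluded from the reference median (but still normalized).
#'
#' @param counts A `ctc_counts` object or genes x samples matrix.
#' @return List with `size_factors` (per sample) and `normalized`
#'   (matrix).
#' @export
median_of_ratios_normalize <- function(counts) {
  m <- if (inherits(counts, "ctc_counts")) counts$counts else counts
  stopifnot(is.matrix(m))
  ref <- m[rowSums(m == 0) == 0, , drop = FALSE]
  if (nrow(ref) == 0)
    stop("no gene has nonzero counts in all samples")
  geo <- exp(rowMeans(log(ref)))
  sf <- apply(ref, 2, function(col) stats::median(col / geo))
  # rescale to geometric mean 1 so normalization is idempotent
  sf <- sf / exp(mean(log(sf)))
  list(size_factors = sf, normalized = sweep(m, 2, sf, "/"))
}

#' Negative-binomial Wald differential expression
#'
#' Simplified two-group differential expression on size-factor-normalized
#' counts: per-gene method-of-moments dispersion (pooled within-group
#' excess variance over the squared mean, floored at 1e-8) moderated by
#' equal-weight shrinkage toward the across-gene median (raw per-gene
#' moment estimates are too unstable below ~5 samples per group), log2
#' fold change of normalized group means, a Wald test of the log fold
#' change with the delta-method standard error
#' `sqrt((1/mu1 + alpha)/n1 + (1/mu2 + alpha)/n2)` on the natural-log
#' scale (t reference on `n1 + n2 - 2` df when the dispersion is
#' estimated, normal when supplied), and Benjamini-Hochberg adjustment.  The full
#' empirical-Bayes dispersion machinery and independent filtering of
#' full-featured DE tools are deliberately omitted.  With a single
#' sample per group the dispersion cannot be estimated and `dispersion`
#' must be supplied (a fixed prior, default 0.1, is used for the paired
#' per-patient comparisons).
#'
#' @param counts A `ctc_counts` object or matrix.
#' @param groups Factor/character of length `ncol`, exactly two levels;
#'   the fold change is level2 vs level1 (alphabetical).
#' @param dispersion Optional fixed dispersion overriding the per-gene
#'   estimate (required when either group has a single sample).
#' @param fdr Significance threshold on the adjusted p (default 0.05).
#' @return A data frame of class `de_result`: `gene`, `mean1`, `mean2`,
#'   `log2fc`, `wald`, `p`, `p_adj`, `significant`.
#' @export
nb_wald_de <- function(counts, groups, dispersion = NULL, fdr = 0.05) {
  m <- if (inherits(counts, "ctc_counts")) counts$counts else counts
  groups <- as.character(groups)
  lv <- sort(unique(groups))
  if (length(lv) != 2) stop("exactly two groups are required")
  i1 <- which(groups == lv[1]); i2 <- which(groups == lv[2])
  n1 <- length(i1); n2 <- length(i2)
  if (is.null(dispersion) && (n1 < 2 || n2 < 2))
    stop("single-sample groups need a fixed dispersion")
  norm <- median_of_ratios_normalize(m)$normalized
  mu1 <- rowMeans(norm[, i1, drop = FALSE])
  mu2 <- rowMeans(norm[, i2, drop = FALSE])
  if (is.null(dispersion)) {
    v1 <- apply(norm[, i1, drop = FALSE], 1, stats::var)
    v2 <- apply(norm[, i2, drop = FALSE], 1, stats::var)
    excess <- ((n1 - 1) * (v1 - mu1) + (n2 - 1) * (v2 - mu2)) /
      ((n1 - 1) * mu1^2 + (n2 - 1) * mu2^2)
    alpha <- pmax(excess, 1e-8)
    alpha[!is.finite(alpha)] <- 1e-8
    alpha <- 0.5 * alpha + 0.5 * stats::median(alpha)
  } else {
    alpha <- rep(max(dispersion, 1e-8), nrow(m))
  }
  eps <- 1e-8
  lfc <- log2((mu2 + eps) / (mu1 + eps))
  se_ln <- sqrt((1 / pmax(mu1, eps) + alpha) / n1 +
                  (1 / pmax(mu2, eps) + alpha) / n2)
  wald <- log((mu2 + eps) / (mu1 + eps)) / se_ln
  # estimated dispersions add noise to the SE: absorb it with a t
  # reference on the residual df; a supplied (known/prior) dispersion
  # keeps the plain normal Wald reference
  p <- if (is.null(dispersion))
    2 * stats::pt(-abs(wald), df = n1 + n2 - 2)
  else
    2 * stats::pnorm(-abs(wald))
  p[mu1 < eps & mu2 < eps] <- 1
  p <- pmin(p, 1)
  p_adj <- stats::p.adjust(p, method = "BH")
  out <- data.frame(gene = rownames(m), mean1 = mu1, mean2 = mu2,
                    log2fc = lfc, dispersion = alpha, wald = wald, p = p,
                    p_adj = p_adj, significant = p_adj < fdr,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "groups") <- lv
  attr(out, "fdr") <- fdr
  class(out) <- c("de_result", "data.frame")
  out
}

#' Per-patient differential expression of enriched vs matched PBMC
#'
#' Runs [nb_wald_de()] separately for every patient pair in a
#' [simulate_bulk_ctc_counts()]-style matrix (one `enriched` and one
#' `matched_pbmc` sample each, fixed prior dispersion).  The fold change
#' is enriched over PBMC.
#'
#' @param counts A paired `ctc_counts` object.
#' @param dispersion Fixed dispersion for the single-sample pairs.
#' @param fdr FDR threshold.
#' @return Named list of `de_result`, one per patient.
#' @export
paired_bulk_de <- function(counts, dispersion = 0.1, fdr = 0.05) {
  stopifnot(inherits(counts, "ctc_counts"),
            all(c("patient_id", "role") %in% names(counts$samples)))
  pats <- unique(counts$samples$patient_id)
  out <- lapply(pats, function(pid) {
    idx <- which(counts$samples$patient_id == pid)
    roles <- counts$samples$role[idx]
    if (!all(c("enriched", "matched_pbmc") %in% roles))
      stop("patient ", pid, " lacks a matched PBMC sample")
    sub <- counts$counts[, idx, drop = FALSE]
    # alphabetical levels: enriched < matched_pbmc, so flip the sign to
    # report enriched over PBMC
    de <- nb_wald_de(sub, roles, dispersion = dispersion, fdr = fdr)
    de$log2fc <- -de$log2fc
    de$wald <- -de$wald
    tmp <- de$mean1; de$mean1 <- de$mean2; de$mean2 <- tmp
    de
  })
  names(out) <- pats
  out
}

#' Map differential expression onto the antibody panel
#'
#' Builds the binary marker x patient detection table of the bulk
#' comparator: for each panel marker with a mapped gene, 1 iff that gene
#' is significantly *elevated* in the patient's enriched sample versus
#' the matched PBMC control.  Markers without a mapped gene are skipped
#' with a warning.
#'
#' @param de_list Named list of per-patient `de_result`s
#'   ([paired_bulk_de()]).
#' @param panel The antibody panel.
#' @return Binary matrix, mapped markers x patients.
#' @export
panel_dge_map <- function(de_list, panel = hn_panel()) {
  map <- marker_gene_map(panel)
  unmapped <- map$marker[is.na(map$gene)]
  if (length(unmapped))
    warning("markers without a mapped gene skipped: ",
            paste(unmapped, collapse = ", "))
  map <- map[!is.na(map$gene), ]
  out <- vapply(de_list, function(de) {
    hit <- de$significant & de$log2fc > 0
    as.integer(map$gene %in% de$gene[hit])
  }, integer(nrow(map)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(map))
  rownames(out) <- map$marker
  colnames(out) <- names(de_list)
  out
}

#' EMT-signature tumour classification
#'
#' Classifies tumour samples as epithelial, mesenchymal or mixed: the
#' log-normalized signature submatrix is gene-wise z-scored, samples are
#' joined by an agglomerative tree (euclidean distance, complete linkage
#' by default) cut into three branches, and the branches are named by
#' their mean epithelial-minus-mesenchymal signature z-score contrast:
#' the highest-contrast branch is `epithelial`, the lowest is
#' `mesenchymal`, and the intermediate branch -- expressing both gene
#' sets relative to those extremes -- is `mixed`.  (A fixed zero
#' threshold on the branch z-scores is degenerate here: after gene-wise
#' centering, samples expressing both programmes sit at z of about 0 by
#' construction.)
#'
#' @param counts A `ctc_counts` tumour matrix (>= 3 samples).
#' @param signature List with `epithelial` and `mesenchymal` gene sets
#'   (default [emt_signature()]).
#' @param linkage Linkage method (default `"complete"`).
#' @return A list of class `tumour_classes`: `class` (named per sample),
#'   `scores` (per-sample epithelial/mesenchymal mean z), `hclust`.
#' @export
emt_signature_cluster <- function(counts, signature = emt_signature(),
                                  linkage = "complete") {
  m <- if (inherits(counts, "ctc_counts")) counts$counts else counts
  if (ncol(m) < 3) stop("tumour classification needs at least 3 samples")
  sig_genes <- c(signature$epithelial, signature$mesenchymal)
  missing <- setdiff(sig_genes, rownames(m))
  if (length(missing))
    stop("signature genes missing from the matrix: ",
         paste(utils::head(missing, 3), collapse = ", "), " ...")
  norm <- median_of_ratios_normalize(m)$normalized
  lg <- log2(norm[sig_genes, , drop = FALSE] + 1)
  sds <- apply(lg, 1, stats::sd)
  if (all(sds == 0)) stop("degenerate distances: all samples identical")
  z <- t(scale(t(lg)))
  z[!is.finite(z)] <- 0
  d <- stats::dist(t(z))
  if (all(d == 0)) stop("degenerate distances: all samples identical")
  hc <- stats::hclust(d, method = linkage)
  branch <- stats::cutree(hc, 3)
  epi_score <- colMeans(z[signature$epithelial, , drop = FALSE])
  mes_score <- colMeans(z[signature$mesenchymal, , drop = FALSE])
  bids <- sort(unique(branch))
  contrast <- vapply(bids, function(b)
    mean(epi_score[branch == b]) - mean(mes_score[branch == b]), numeric(1))
  cls <- character(length(bids))
  cls[which.max(contrast)] <- "epithelial"
  cls[which.min(contrast)] <- "mesenchymal"
  cls[cls == ""] <- "mixed"
  class_per_sample <- cls[match(branch, bids)]
  names(class_per_sample) <- colnames(m)
  res <- list(class = class_per_sample,
              scores = data.frame(sample_id = colnames(m),
                                  epithelial = epi_score,
                                  mesenchymal = mes_score,
                                  branch = branch,
                                  stringsAsFactors = FALSE),
              hclust = hc)
  class(res) <- "tumour_classes"
  res
}

#' @export
print.tumour_classes <- function(x, ...) {
  cat("<tumour_classes>\n"); print(table(x$class)); invisible(x)
}

#' Concordance of cytometry calls with the bulk comparators
#'
#' Descriptive per-patient agreement between mass-cytometry calls and the
#' bulk gene-expression comparator, plus ANOVAs of the CTC metrics across
#' tumour expression classes:
#'
#' * CTC positivity: cytometry-positive vs any epithelial-lineage marker
#'   gene flagged in the patient's DGE map.
#' * EMT detectability: cytometry EMT fraction above `emt_floor` vs the
#'   vimentin gene flagged.
#' * Proliferation: Ki-67.
#'
#' @param cyto Data frame with columns `patient_id`, `positivity`,
#'   `emt_fraction` and optionally `ki67_present` (logical).
#' @param dge_map Binary marker x patient matrix ([panel_dge_map()]).
#' @param tumour_class Optional named per-patient tumour class; enables
#'   the ANOVAs of total CTC count and EMT fractions across classes
#'   (requires `cyto$ctc_total`).
#' @param panel The antibody panel.
#' @param emt_floor Cytometry EMT-presence floor (default 0.1).
#' @return A list of class `concordance_report` with `per_patient`,
#'   `agreement` counts and `anova` results.
#' @export
concordance_report <- function(cyto, dge_map, tumour_class = NULL,
                               panel = hn_panel(), emt_floor = 0.1) {
  pats <- colnames(dge_map)
  if (!all(pats %in% cyto$patient_id))
    stop("unmatched patient identifiers between cytometry and DGE inputs")
  cyto <- cyto[match(pats, cyto$patient_id), ]
  epi_markers <- intersect(
    panel$marker[panel$category == "epithelial_lineage"], rownames(dge_map))
  per <- data.frame(
    patient_id = pats,
    cyto_positive = cyto$positivity == "positive",
    bulk_positive = colSums(dge_map[epi_markers, , drop = FALSE]) > 0,
    cyto_emt = cyto$emt_fraction > emt_floor,
    bulk_emt = dge_map["Vimentin", ] > 0,
    stringsAsFactors = FALSE
  )
  if ("ki67_present" %in% names(cyto)) {
    per$cyto_ki67 <- cyto$ki67_present
    per$bulk_ki67 <- dge_map["Ki67", ] > 0
  }
  agreement <- c(
    positivity = sum(per$cyto_positive == per$bulk_positive),
    emt = sum(per$cyto_emt == per$bulk_emt),
    ki67 = if ("cyto_ki67" %in% names(per))
      sum(per$cyto_ki67 == per$bulk_ki67) else NA_integer_,
    n = length(pats)
  )
  anova <- NULL
  if (!is.null(tumour_class)) {
    cls <- factor(tumour_class[pats])
    if (nlevels(cls) >= 2 && "ctc_total" %in% names(cyto)) {
      run_aov <- function(y) {
        sm <- summary(stats::aov(y ~ cls))[[1]]
        c(F = sm[["F value"]][1], p = sm[["Pr(>F)"]][1])
      }
      anova <- rbind(ctc_total = run_aov(cyto$ctc_total),
                     emt_fraction = run_aov(cyto$emt_fraction))
    }
  }
  structure(list(per_patient = per, agreement = agreement, anova = anova),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  a <- x$agreement
  cat("<concordance_report> positivity agreement ", a["positivity"], "/",
      a["n"], ", EMT ", a["emt"], "/", a["n"], "\n", sep = "")
  invisible(x)
}
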
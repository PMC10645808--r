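#' Marker-to-gene mapping table
#'
#' Editable table mapping each antibody-panel marker to a representative
#' gene symbol for the bulk gene-expression comparator.  Pan-cytokeratin
#' maps to a representative keratin gene (KRT19) and is flagged
#' `representative`; phospho-epitopes have no meaningful transcript and
#' are unmapped (`NA`) by default.
#'
#' @param panel A [hn_panel()] panel.
#' @return Data frame with columns `marker`, `gene`, `representative`.
#' @export
marker_gene_map <- function(panel = hn_panel()) {
  map <- c(
    "EpCAM" = "EPCAM", "Pan-cytokeratin" = "KRT19", "E-cadherin" = "CDH1",
    "EGFR" = "EGFR", "CD3" = "CD3E", "CD4" = "CD4", "CD8" = "CD8A",
    "CD25" = "IL2RA", "CD14" = "CD14", "CD86" = "CD86", "CD163" = "CD163",
    "CD19" = "CD19", "CD56" = "NCAM1", "CD66b" = "CEACAM8",
    "HLA-ABC" = "HLA-A", "HLA-DR" = "HLA-DRA", "CD45" = "PTPRC",
    "CD31" = "PECAM1", "Vimentin" = "VIM", "Snail1" = "SNAI1",
    "Twist" = "TWIST1", "CD133" = "PROM1", "CD24" = "CD24", "CD44" = "CD44",
    "Ki67" = "MKI67", "CD47" = "CD47", "PD-1" = "PDCD1", "PD-L1" = "CD274",
    "PD-L2" = "PDCD1LG2", "CTLA4" = "CTLA4", "CD39" = "ENTPD1",
    "CD73" = "NT5E"
  )
  mk <- panel_markers(panel)$marker
  data.frame(
    marker = mk,
    gene = unname(map[mk]),
    representative = mk %in% c("Pan-cytokeratin", "HLA-ABC"),
    stringsAsFactors = FALSE
  )
}

#' Synthetic EMT gene signature
#'
#' The tumour classifier targets a validated HNSCC EMT signature whose
#' gene list is not bundled here; a synthetic stand-in of 25 epithelial
#' and 25 mesenchymal placeholder gene identifiers is used instead.
#'
#' @return List with `epithelial` and `mesenchymal` character vectors
#'   (disjoint).
#' @export
emt_signature <- function() {
  list(epithelial = sprintf("EPI_SIG_%02d", 1:25),
       mesenchymal = sprintf("MES_SIG_%02d", 1:25))
}

new_counts <- function(counts, samples, genes) {
  stopifnot(is.matrix(counts), all(counts >= 0),
            nrow(samples) == ncol(counts), nrow(genes) == nrow(counts))
  res <- list(counts = counts, samples = samples, genes = genes)
  class(res) <- "ctc_counts"
  res
}

#' @export
print.ctc_counts <- function(x, ...) {
  cat("<ctc_counts> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples\n", sep = "")
  if ("class" %in% names(x$samples)) print(table(x$samples$class))
  if ("role" %in% names(x$samples)) print(table(x$samples$role))
  invisible(x)
}

#' Simulate tumour gene-expression counts
#'
#' Negative-binomial count matrix for the tumour comparator: epithelial
#' signature genes are elevated (`fold`) in epithelial-class tumours,
#' mesenchymal signature genes in mesenchymal-class tumours, and both at
#' the intermediate level `sqrt(fold)` in mixed-class tumours.  The true
#' class is stored per sample.
#'
#' @param design `c(n_epithelial, n_mesenchymal, n_mixed)` sample counts
#'   (default `c(3, 3, 4)`, the comparator's tumour design).
#' @param fold Fold elevation of matching signature genes (default 6;
#'   set to 1 for a null matrix).
#' @param dispersion NB dispersion (default 0.1).
#' @param n_background Unregulated background genes (default 400).
#' @param base_mu Median baseline mean count (default 100; per-gene
#'   baselines are lognormal around it).
#' @param seed Integer seed.
#' @return A `ctc_counts` object; `samples$class` holds the truth.
#' @export
simulate_tumour_counts <- function(design = c(3, 3, 4), fold = 6,
                                   dispersion = 0.1, n_background = 400,
                                   base_mu = 100, seed = 1) {
  if (length(design) != 3 || any(design < 0))
    stop("design must be c(n_epithelial, n_mesenchymal, n_mixed) >= 0")
  if (sum(design) == 0) stop("empty design")
  sig <- emt_signature()
  genes <- data.frame(
    gene = c(sig$epithelial, sig$mesenchymal,
             sprintf("BG_%03d", seq_len(n_background))),
    set = c(rep("signature_epithelial", length(sig$epithelial)),
            rep("signature_mesenchymal", length(sig$mesenchymal)),
            rep("background", n_background)),
    stringsAsFactors = FALSE
  )
  classes <- rep(c("epithelial", "mesenchymal", "mixed"), design)
  withr::with_seed(as.integer(seed), {
    base <- stats::rlnorm(nrow(genes), log(base_mu), 1)
    mu <- matrix(base, nrow(genes), length(classes))
    for (j in seq_along(classes)) {
      f_epi <- switch(classes[j], epithelial = fold, mixed = sqrt(fold), 1)
      f_mes <- switch(classes[j], mesenchymal = fold, mixed = sqrt(fold), 1)
      mu[genes$set == "signature_epithelial", j] <-
        mu[genes$set == "signature_epithelial", j] * f_epi
      mu[genes$set == "signature_mesenchymal", j] <-
        mu[genes$set == "signature_mesenchymal", j] * f_mes
    }
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / dispersion),
                     nrow(mu), ncol(mu))
  })
  rownames(counts) <- genes$gene
  colnames(counts) <- sprintf("T%02d", seq_along(classes))
  samples <- data.frame(sample_id = colnames(counts), class = classes,
                        stringsAsFactors = FALSE)
  new_counts(counts, samples, genes)
}

# relative per-cell transcript contribution of a population for one
# marker: detection probability times intensity relative to a bright
# channel
marker_cell_weight <- function(params, population, marker) {
  m <- params$m[marker, population]
  zp <- params$zero_prob[marker, population]
  (1 - zp) * min(1, sinh(m) / sinh(4.5))
}

#' Simulate paired bulk CTC / PBMC count matrices
#'
#' For each requested patient, generates a Parsortix-enriched bulk RNA
#' sample and a matched PBMC negative-control sample.  Counts for genes
#' mapped to panel markers are elevated in the enriched sample in
#' proportion to the abundance of cells expressing the corresponding
#' protein (subgroup composition times per-cell detection weight), so
#' low-frequency subpopulations (e.g. a handful of EMT CTCs) can fall
#' below differential-expression detectability -- the sensitivity gap of
#' bulk profiling.
#'
#' @param cohort A [hn_cohort()] object.
#' @param panel,params Panel and generator parameters (the per-cell
#'   weights reuse the event generator's archetypes).
#' @param patients Patient ids to simulate (default: first 10).
#' @param gain Relative transcript abundance of a marker-positive cell
#'   over the baseline pool (default 1000, so an expressing-cell
#'   fraction of 0.01 elevates the gene ~10-fold; 0 gives an
#'   exchangeable null pair).
#' @param dispersion NB dispersion (default 0.1).
#' @param n_background Background genes.
#' @param base_mu Median baseline mean count.
#' @param seed Integer seed.
#' @param mixture_override Optional named list patient -> 3-vector
#'   replacing the cohort subgroup mixture (used to probe the
#'   sensitivity gap at fixed total count).
#' @return A `ctc_counts` object with `samples$role` in
#'   `{enriched, matched_pbmc}` and `samples$patient_id`.
#' @export
simulate_bulk_ctc_counts <- function(cohort, panel = hn_panel(),
                                     params = generator_params(panel),
                                     patients = cohort$patients$patient_id[1:10],
                                     gain = 1000, dispersion = 0.1,
                                     n_background = 200, base_mu = 100,
                                     seed = 1,
                                     mixture_override = NULL) {
  stopifnot(all(patients %in% cohort$patients$patient_id))
  map <- marker_gene_map(panel)
  map <- map[!is.na(map$gene), ]
  genes <- data.frame(
    gene = c(map$gene, sprintf("BG_%03d", seq_len(n_background))),
    set = c(rep("panel_marker", nrow(map)), rep("background", n_background)),
    marker = c(map$marker, rep(NA_character_, n_background)),
    stringsAsFactors = FALSE
  )
  pops <- c("ctc_epithelial", "ctc_early_emt", "ctc_advanced_emt", "leucocyte")
  withr::with_seed(as.integer(seed), {
    base <- stats::rlnorm(nrow(genes), log(base_mu), 1)
    cols <- list(); samp <- list()
    for (pid in patients) {
      entry <- cohort_entry(cohort, pid)
      mix <- if (!is.null(mixture_override) && pid %in% names(mixture_override))
        mixture_override[[pid]] else entry$mixture
      ncell <- c(mix * entry$ctc_total,
                 entry$enriched_count - entry$ctc_total)
      names(ncell) <- pops
      total <- entry$enriched_count
      for (role in c("enriched", "matched_pbmc")) {
        comp <- if (role == "enriched") ncell else
          c(ctc_epithelial = 0, ctc_early_emt = 0, ctc_advanced_emt = 0,
            leucocyte = total)
        mu <- base
        for (i in which(genes$set == "panel_marker")) {
          w <- vapply(pops, marker_cell_weight, numeric(1),
                      params = params, marker = genes$marker[i])
          expressing <- sum(comp * w)
          mu[i] <- base[i] * (1 + gain * expressing / total)
        }
        cols[[length(cols) + 1L]] <-
          stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
        samp[[length(samp) + 1L]] <-
          data.frame(sample_id = paste0(pid, "_", role), patient_id = pid,
                     role = role, stringsAsFactors = FALSE)
      }
    }
  })
  counts <- do.call(cbind, cols)
  samples <- do.call(rbind, samp)
  rownames(counts) <- genes$gene
  colnames(counts) <- samples$sample_id
  new_counts(counts, samples, genes)
}
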
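#' Default study cohort configuration
#'
#' Returns the cohort emulated by the synthetic-data module: 14
#' treatment-naive HNSCC patients with their clinical-pathological fields
#' and total CTC count per 9 ml blood draw, plus six healthy donors of
#' whom two carry background-level CTC-like cells (2 and 3 cells per
#' draw).  Per-patient subgroup mixtures (epithelial / early-EMT /
#' advanced-EMT simplex weights) and the scaled-down population sizes used
#' by the event generator are attached.
#'
#' The per-patient totals sum to 1144; the stage-I patient (patient 12)
#' is listed with a total of 0.  An alternate reading treats that
#' patient as carrying 4 background-level cells (giving a concatenated
#' total of 1150); set `patient12_alt = TRUE` to generate it instead.
#'
#' @param patient12_alt Logical; if `TRUE`, patient 12 is configured with
#'   4 CTC-like background cells rather than 0.
#' @param carrier_count,control_count,enriched_count Scaled-down
#'   population sizes per sample (defaults 9000 / 1000 / 2000; the assay
#'   pools ~900,000 barcoded carrier PBMCs, ~100,000 osmium-labelled
#'   control cells and 20,000-50,000 enriched cells, preserved here at
#'   1:100 / 1:100 / ~1:10-25 scale).
#' @param debris_fraction Expected fraction of debris/doublet events in
#'   each acquired file (default 0.05).
#' @return A list of class `ctc_cohort` with elements `patients` (data
#'   frame), `donors` (data frame), `mixtures` (patients x 3 matrix of
#'   subgroup weights), and the scalar settings above plus
#'   `draw_volume_ml = 9`.
#' @examples
#' coh <- hn_cohort()
#' coh$patients$ctc_total
#' @export
hn_cohort <- function(patient12_alt = FALSE,
                      carrier_count = 9000L,
                      control_count = 1000L,
                      enriched_count = 2000L,
                      debris_fraction = 0.05) {
  patients <- data.frame(
    patient_id = paste0("P", 1:14),
    age    = c(77, 65, 73, 75, 53, 63, 43, 66, 57, 52, 73, 76, 61, 62),
    sex    = c("M", "M", "M", "M", "M", "M", "F", "F", "M", "F", "M", "F",
               "M", "M"),
    t_stage = c("4a", "4a", "3", "3", "3", "4a", "4a", "4a", "3", "2",
                "4a", "1", "4a", "4a"),
    n_stage = c("1", "0", "2b", "2b", "0", "0", "2b", "2b", "0", "0", "0",
                "0", "0", "2b"),
    m_stage = rep("0", 14),
    stage  = c("IV", "IV", "IV", "IV", "III", "IV", "IV", "IV", "III",
               "II", "IV", "I", "IV", "IV"),
    site   = c("Oral", "Larynx", "Oral", "Oral", "Oral", "Oral", "Oral",
               "Oral", "Oral", "Oral", "Oral", "Oral", "Oral", "Oral"),
    treatment = c("S+CRT", "S", "S+RT", "S+RT", "S+CRT", "S+RT", "S+CRT",
                  "S+RT", "S", "S", "S+RT", "S", "S+RT", "S+RT"),
    ctc_total = c(97L, 40L, 54L, 98L, 58L, 167L, 86L, 18L, 39L, 25L,
                  183L, 0L, 61L, 218L),
    stringsAsFactors = FALSE
  )
  if (patient12_alt) patients$ctc_total[12] <- 4L

  donors <- data.frame(
    donor_id = paste0("HD", 1:6),
    ctc_total = c(0L, 0L, 2L, 0L, 3L, 0L),
    stringsAsFactors = FALSE
  )

  # Per-patient subgroup simplex weights (epithelial, early_EMT,
  # advanced_EMT).  Most patients carry all three subgroups with an
  # early-EMT majority; two patients lack one subgroup each, mirroring
  # the cohort-level pattern that all but two patients possessed all
  # three groups.
  mixtures <- rbind(
    c(0.20, 0.50, 0.30),  # P1
    c(0.25, 0.45, 0.30),  # P2
    c(0.15, 0.55, 0.30),  # P3
    c(0.20, 0.45, 0.35),  # P4
    c(0.30, 0.40, 0.30),  # P5
    c(0.15, 0.55, 0.30),  # P6
    c(0.20, 0.50, 0.30),  # P7
    c(0.25, 0.45, 0.30),  # P8
    c(0.20, 0.55, 0.25),  # P9
    c(0.00, 0.60, 0.40),  # P10 (no epithelial CTCs)
    c(0.30, 0.70, 0.00),  # P11 (no advanced-EMT CTCs)
    c(0.34, 0.33, 0.33),  # P12
    c(0.15, 0.50, 0.35),  # P13
    c(0.15, 0.50, 0.35)   # P14
  )
  rownames(mixtures) <- patients$patient_id
  colnames(mixtures) <- c("epithelial", "early_EMT", "advanced_EMT")

  cohort <- list(
    patients = patients,
    donors = donors,
    mixtures = mixtures,
    carrier_count = as.integer(carrier_count),
    control_count = as.integer(control_count),
    enriched_count = as.integer(enriched_count),
    debris_fraction = debris_fraction,
    draw_volume_ml = 9
  )
  class(cohort) <- "ctc_cohort"
  validate_cohort(cohort)
  cohort
}

validate_cohort <- function(cohort) {
  p <- cohort$patients
  stopifnot(is.data.frame(p), all(p$ctc_total >= 0))
  if (cohort$draw_volume_ml <= 0) stop("draw_volume_ml must be positive")
  if (cohort$enriched_count < max(p$ctc_total))
    stop("enriched_count must be >= the largest per-patient CTC total")
  if (any(cohort$carrier_count < 0, cohort$control_count < 0))
    stop("population counts must be non-negative")
  mx <- cohort$mixtures
  if (!all(abs(rowSums(mx) - 1) < 1e-8) || any(mx < 0))
    stop("subgroup mixture weights must be a simplex per patient")
  if (cohort$debris_fraction < 0 || cohort$debris_fraction >= 1)
    stop("debris_fraction must lie in [0, 1)")
  invisible(cohort)
}

#' @export
print.ctc_cohort <- function(x, ...) {
  cat("<ctc_cohort> ", nrow(x$patients), " patients, ",
      nrow(x$donors), " healthy donors\n", sep = "")
  cat("  CTC totals: ", paste(x$patients$ctc_total, collapse = ", "),
      " (per ", x$draw_volume_ml, " ml)\n", sep = "")
  cat("  per sample: ", x$carrier_count, " carrier / ", x$control_count,
      " control / ", x$enriched_count, " enriched cells, debris fraction ",
      x$debris_fraction, "\n", sep = "")
  invisible(x)
}

#' Look up one cohort entry
#'
#' @param cohort A [hn_cohort()] object.
#' @param id Patient or donor identifier.
#' @return A list with `id`, `ctc_total`, `mixture`, `is_donor` and the
#'   cohort-level population sizes, suitable for [simulate_sample()].
#' @export
cohort_entry <- function(cohort, id) {
  if (id %in% cohort$patients$patient_id) {
    row <- cohort$patients[cohort$patients$patient_id == id, ]
    list(id = id, ctc_total = row$ctc_total,
         mixture = cohort$mixtures[id, ],
         is_donor = FALSE,
         carrier_count = cohort$carrier_count,
         control_count = cohort$control_count,
         enriched_count = cohort$enriched_count,
         debris_fraction = cohort$debris_fraction)
  } else if (id %in% cohort$donors$donor_id) {
    row <- cohort$donors[cohort$donors$donor_id == id, ]
    list(id = id, ctc_total = row$ctc_total,
         mixture = c(epithelial = 1, early_EMT = 0, advanced_EMT = 0),
         is_donor = TRUE,
         carrier_count = cohort$carrier_count,
         control_count = cohort$control_count,
         enriched_count = cohort$enriched_count,
         debris_fraction = cohort$debris_fraction)
  } else {
    stop("unknown cohort id: ", id)
  }
}
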
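#' Simulate one acquired mass-cytometry sample
#'
#' Generates the event table for a single patient or healthy-donor sample
#' as it would be acquired after pooled staining: barcoded carrier PBMCs,
#' osmium-labelled phospho-control cells, the enriched fraction (CTCs of
#' the configured subgroup mixture plus carried-over leucocytes) and a
#' configurable proportion of debris/doublet events with aberrant
#' acquisition Gaussian parameters.  Each event carries a ground-truth
#' population label.
#'
#' The number of `ctc_*` events equals the entry's `ctc_total` exactly
#' (the multinomial subgroup split preserves the total); gating stages
#' downstream are what lose or mislabel cells, never the generator.
#'
#' @param entry A [cohort_entry()] list (or any list with `id`,
#'   `ctc_total`, `mixture`, `is_donor` and the population sizes).
#' @param panel A [hn_panel()] panel.
#' @param params A [generator_params()] object.
#' @param seed Integer seed; identical seeds give bit-identical tables.
#' @return A `ctc_events` object: list with `exprs` (events x channels
#'   numeric matrix of raw intensities, marker-named columns plus the
#'   acquisition channels and `Time`), `panel`, `sample_id`, `truth`
#'   (per-event population label), `transformed = FALSE`.
#' @examples
#' coh <- hn_cohort(); pan <- hn_panel(); par <- generator_params(pan)
#' ev <- simulate_sample(cohort_entry(coh, "P8"), pan, par, seed = 1)
#' table(ev$truth)["ctc_early_emt"]
#' @export
simulate_sample <- function(entry, panel, params, seed) {
  stopifnot(inherits(params, "ctc_genparams"))
  if (entry$ctc_total < 0 || entry$carrier_count < 0 ||
      entry$control_count < 0 || entry$enriched_count < 0)
    stop("population counts must be non-negative")
  mix <- entry$mixture
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8)
    stop("subgroup mixture weights must be non-negative and sum to 1")
  if (entry$enriched_count < entry$ctc_total)
    stop("enriched_count must be >= ctc_total")

  withr::with_seed(as.integer(seed), {
    if (entry$is_donor) {
      ctc_counts <- c(ctc_background = entry$ctc_total)
    } else {
      split <- as.vector(stats::rmultinom(1, entry$ctc_total, mix))
      ctc_counts <- c(ctc_epithelial = split[1], ctc_early_emt = split[2],
                      ctc_advanced_emt = split[3])
    }
    n_core <- entry$carrier_count + entry$control_count + entry$enriched_count
    n_debris <- round(entry$debris_fraction / (1 - entry$debris_fraction) *
                        n_core)
    counts <- c(carrier = entry$carrier_count,
                control = entry$control_count,
                leucocyte = entry$enriched_count - entry$ctc_total,
                ctc_counts,
                debris = n_debris)
    counts <- counts[counts > 0]

    blocks <- lapply(names(counts), function(pop) {
      draw_population(counts[[pop]], pop, panel, params)
    })
    exprs <- do.call(rbind, blocks)
    truth <- rep(names(counts), counts)

    # interleave populations as they would arrive at the detector
    ord <- sample.int(nrow(exprs))
    exprs <- exprs[ord, , drop = FALSE]
    truth <- truth[ord]
    exprs <- cbind(exprs, Time = seq_len(nrow(exprs)) / 500)
    rownames(exprs) <- NULL

    new_events(exprs, panel, sample_id = entry$id, truth = truth)
  })
}

# Draw a block of n events for one population: zero-inflated lognormal
# intensities for antibody/barcode/control channels, Gaussian acquisition
# parameters (truncated at zero).
draw_population <- function(n, pop, panel, params) {
  markers <- rownames(params$m)
  cf <- params$cofactor
  intens <- vapply(markers, function(mk) {
    m <- params$m[mk, pop]
    zp <- params$zero_prob[mk, pop]
    x <- stats::rlnorm(n, meanlog = log(cf * sinh(max(m, 1e-6))),
                       sdlog = params$sdlog)
    x[stats::runif(n) < zp] <- 0
    x
  }, numeric(n))
  if (n == 1L) intens <- matrix(intens, nrow = 1, dimnames = list(NULL, markers))

  acq_par <- if (pop == "debris") params$acquisition$debris else
    params$acquisition$intact
  acq <- vapply(names(acq_par), function(ch) {
    pmax(stats::rnorm(n, acq_par[[ch]][1], acq_par[[ch]][2]), 1)
  }, numeric(n))
  if (n == 1L) acq <- matrix(acq, nrow = 1, dimnames = list(NULL, names(acq_par)))
  cbind(intens, acq)
}

new_events <- function(exprs, panel, sample_id, truth = NULL,
                       transformed = FALSE, cofactor = NA_real_) {
  stopifnot(is.matrix(exprs), !is.null(colnames(exprs)))
  if (any(!transformed & exprs[, setdiff(colnames(exprs), "Time"), drop = FALSE] < 0))
    stop("raw intensities must be non-negative")
  if (!is.null(truth) && length(truth) != nrow(exprs))
    stop("truth labels, when present, must cover every event")
  ev <- list(exprs = exprs, panel = panel, sample_id = sample_id,
             truth = truth, transformed = transformed, cofactor = cofactor)
  class(ev) <- "ctc_events"
  ev
}

#' @export
print.ctc_events <- function(x, ...) {
  cat("<ctc_events> sample ", x$sample_id, ": ", nrow(x$exprs), " events x ",
      ncol(x$exprs), " channels",
      if (x$transformed) paste0(" (ArcSinh, cofactor ", x$cofactor, ")"),
      "\n", sep = "")
  if (!is.null(x$truth)) print(table(x$truth))
  invisible(x)
}

#' @export
`[.ctc_events` <- function(x, i, ...) {
  new_events(x$exprs[i, , drop = FALSE], x$panel, x$sample_id,
             truth = if (!is.null(x$truth)) x$truth[i],
             transformed = x$transformed, cofactor = x$cofactor)
}

#' @export
dim.ctc_events <- function(x) dim(x$exprs)

#' Simulate the full default cohort
#'
#' Calls [simulate_sample()] for every patient and healthy donor in the
#' cohort, deriving one sub-seed per sample from the global seed.
#'
#' @param cohort A [hn_cohort()] object.
#' @param panel,params Panel and generator parameters.
#' @param seed Global integer seed.
#' @param include_donors Simulate the healthy donors as well.
#' @return Named list of `ctc_events`, one per sample.
#' @export
simulate_cohort <- function(cohort, panel = hn_panel(),
                            params = generator_params(panel), seed = 1,
                            include_donors = TRUE) {
  ids <- cohort$patients$patient_id
  if (include_donors) ids <- c(ids, cohort$donors$donor_id)
  samples <- lapply(seq_along(ids), function(i) {
    simulate_sample(cohort_entry(cohort, ids[i]), panel, params,
                    seed = (as.integer(seed) * 1000L + i) %% .Machine$integer.max)
  })
  names(samples) <- ids
  samples
}
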
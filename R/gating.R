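#' ArcSinh variance-stabilizing transform
#'
#' Replaces each antibody-channel intensity x by `asinh(x / cofactor)`.
#' The transform is monotone per channel, so event rank order is
#' preserved.  Acquisition channels (Event_length, Center, Offset, Width,
#' Residual, Time) are never transformed.  Re-applying the transform is
#' refused: the events object carries a `transformed` flag.
#'
#' @param events A `ctc_events` object with raw intensities.
#' @param cofactor Positive ArcSinh cofactor (default 5, conventional for
#'   mass cytometry).
#' @return The events object with transformed antibody channels and
#'   `transformed = TRUE`.
#' @examples
#' asinh(5 / 5)  # 0.8814, the transform of a raw intensity equal to the cofactor
#' @export
arcsinh_transform <- function(events, cofactor = 5) {
  stopifnot(inherits(events, "ctc_events"))
  if (cofactor <= 0) stop("cofactor must be positive")
  if (isTRUE(events$transformed))
    stop("events are already ArcSinh transformed")
  skip <- c(acquisition_channels(events$panel), "Time")
  chans <- setdiff(colnames(events$exprs), skip)
  events$exprs[, chans] <- asinh(events$exprs[, chans, drop = FALSE] / cofactor)
  events$transformed <- TRUE
  events$cofactor <- cofactor
  events
}

#' Gate thresholds
#'
#' Container for every cut point used by the gating stages.  By default
#' all cut points are data-driven: acquisition retention windows are
#' robust windows (median +/- `acq_nmad` scaled MADs per channel, unless
#' explicit quantile windows or fixed bounds are given) and the
#' barcode/osmium/CD45/lineage/pan-cytokeratin cuts are found by
#' valley-seeking between the two modes of the ArcSinh distribution, with
#' the fixed values below as fallback when no clear bimodality exists.
#'
#' @param acq_nmad Number of scaled MADs for the default robust
#'   acquisition windows.
#' @param acq_quantiles Optional `c(lower, upper)` quantile pair applied
#'   to every acquisition channel instead of the MAD windows.
#' @param acq_fixed Optional named list of fixed `c(lower, upper)` bounds
#'   per acquisition channel (overrides everything else for that channel).
#' @param barcode_cut,osmium_cut Fixed ArcSinh cuts; `NULL` means
#'   valley-seeking with no fallback (an error if the channel is
#'   unimodal), a number is used as the valley fallback and direct cut.
#' @param cd45_low,lineage_low,panck_min Fallback ArcSinh cuts for the
#'   CTC identification rule (used when valley-seeking finds no
#'   bimodality, or directly when `auto_marker_cuts = FALSE`).
#' @param auto_marker_cuts Use valley-seeking for the CTC rule cuts.
#' @param background_ctc_threshold Healthy-donor background count; a
#'   patient with at most this many CTCs per draw is scored negative
#'   (default 4).
#' @return A list of class `gate_thresholds`.
#' @export
gate_thresholds <- function(acq_nmad = 5,
                            acq_quantiles = NULL,
                            acq_fixed = NULL,
                            barcode_cut = 2,
                            osmium_cut = 2,
                            cd45_low = 2,
                            lineage_low = 1.5,
                            panck_min = 2,
                            auto_marker_cuts = TRUE,
                            background_ctc_threshold = 4) {
  if (background_ctc_threshold < 0)
    stop("background_ctc_threshold must be >= 0")
  if (!is.null(acq_quantiles) &&
      (length(acq_quantiles) != 2 || diff(acq_quantiles) <= 0))
    stop("acq_quantiles must be c(lower, upper) with lower < upper")
  structure(list(acq_nmad = acq_nmad, acq_quantiles = acq_quantiles,
                 acq_fixed = acq_fixed, barcode_cut = barcode_cut,
                 osmium_cut = osmium_cut, cd45_low = cd45_low,
                 lineage_low = lineage_low, panck_min = panck_min,
                 auto_marker_cuts = auto_marker_cuts,
                 background_ctc_threshold = background_ctc_threshold),
            class = "gate_thresholds")
}

resolve_acq_window <- function(x, channel, thr) {
  if (!is.null(thr$acq_fixed) && channel %in% names(thr$acq_fixed))
    return(thr$acq_fixed[[channel]])
  if (!is.null(thr$acq_quantiles))
    return(unname(stats::quantile(x, thr$acq_quantiles)))
  med <- stats::median(x)
  s <- stats::mad(x)
  c(med - thr$acq_nmad * s, med + thr$acq_nmad * s)
}

#' Gaussian acquisition-parameter clean-up
#'
#' Removes debris and fused (doublet) events using the per-event
#' acquisition quality metrics recorded by the instrument (Event_length,
#' Center, Offset, Width, Residual).  An event falling outside the
#' retention window of any acquisition channel is labelled `debris`; all
#' other events are retained.  The resolved windows are recorded in the
#' result.
#'
#' @param events A `ctc_events` object (raw or transformed; acquisition
#'   channels are never transformed).
#' @param thresholds A [gate_thresholds()] object.
#' @return A list of class `cleanup_result` with `labels` (`"debris"` /
#'   `"intact"` per event), `events` (the retained subset), `windows`
#'   and `tallies`.
#' @export
gaussian_cleanup <- function(events, thresholds = gate_thresholds()) {
  stopifnot(inherits(events, "ctc_events"))
  acq <- acquisition_channels(events$panel)
  missing <- setdiff(acq, colnames(events$exprs))
  if (length(missing))
    stop("missing acquisition channel(s): ", paste(missing, collapse = ", "))
  windows <- lapply(acq, function(ch)
    resolve_acq_window(events$exprs[, ch], ch, thresholds))
  names(windows) <- acq
  ok <- rep(TRUE, nrow(events$exprs))
  for (ch in acq) {
    w <- windows[[ch]]
    ok <- ok & events$exprs[, ch] >= w[1] & events$exprs[, ch] <= w[2]
  }
  labels <- ifelse(ok, "intact", "debris")
  res <- list(labels = labels, events = events[ok], windows = windows,
              tallies = c(intact = sum(ok), debris = sum(!ok)))
  class(res) <- "cleanup_result"
  res
}

# Valley-seeking cut between the two dominant modes of a 1-D ArcSinh
# distribution.  Returns the x position of minimum density between the
# two highest well-separated peaks, or `fallback` (NA => error) when the
# distribution is effectively unimodal or one mode carries less than
# `min_mass` of the events.
find_valley_cut <- function(x, fallback = NA_real_, min_mass = 0.02) {
  if (length(unique(x)) < 3) {
    if (is.na(fallback)) stop("degenerate distribution and no fallback cut")
    return(fallback)
  }
  d <- stats::density(x, n = 512)
  y <- d$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(peaks) >= 2) {
    ord <- peaks[order(y[peaks], decreasing = TRUE)]
    # two strongest peaks that are separated on the x axis
    p1 <- ord[1]
    p2 <- ord[which(abs(d$x[ord] - d$x[p1]) > 0.5)[1]]
    if (!is.na(p2)) {
      lo <- min(p1, p2); hi <- max(p1, p2)
      valley <- lo + which.min(y[lo:hi]) - 1L
      cut <- d$x[valley]
      mass_lo <- mean(x < cut)
      if (mass_lo >= min_mass && mass_lo <= 1 - min_mass) return(cut)
    }
  }
  if (is.na(fallback))
    stop("distribution is unimodal and no fallback cut is configured")
  fallback
}

#' Deconvolute carrier / control / enriched populations
#'
#' Top-level gating after clean-up: barcode(Cd-106)-high events are
#' carrier PBMCs, osmium-high events are phospho-control cells, and
#' double-negative events form the enriched (Parsortix) fraction.  Cut
#' points are found by valley-seeking between the two modes of each
#' channel's ArcSinh distribution, falling back to the configured fixed
#' cut when a channel is unimodal (e.g. a sample with no control cells).
#'
#' @param events ArcSinh-transformed, cleaned `ctc_events`.
#' @param thresholds A [gate_thresholds()] object.
#' @return A list of class `deconv_result` with `labels` (`carrier` /
#'   `control` / `enriched`), `events` (unchanged input), `cuts` and
#'   `tallies`.
#' @export
deconvolute_populations <- function(events, thresholds = gate_thresholds()) {
  stopifnot(inherits(events, "ctc_events"))
  if (!isTRUE(events$transformed))
    stop("deconvolution expects ArcSinh-transformed events")
  bc <- barcode_marker(events$panel)
  os <- control_marker(events$panel)
  missing <- setdiff(c(bc, os), colnames(events$exprs))
  if (length(missing))
    stop("missing channel(s): ", paste(missing, collapse = ", "))
  bc_cut <- find_valley_cut(events$exprs[, bc], thresholds$barcode_cut)
  os_cut <- find_valley_cut(events$exprs[, os], thresholds$osmium_cut)
  labels <- rep("enriched", nrow(events$exprs))
  labels[events$exprs[, os] >= os_cut] <- "control"
  labels[events$exprs[, bc] >= bc_cut] <- "carrier"
  res <- list(labels = labels, events = events,
              cuts = c(barcode = bc_cut, osmium = os_cut),
              tallies = table(factor(labels,
                                     c("carrier", "control", "enriched"))))
  class(res) <- "deconv_result"
  res
}

#' Extract the enriched fraction from a deconvolution result
#' @param deconv A `deconv_result`.
#' @return `ctc_events` restricted to enriched-labelled events.
#' @export
enriched_events <- function(deconv) {
  stopifnot(inherits(deconv, "deconv_result"))
  deconv$events[deconv$labels == "enriched"]
}

#' Identify CTCs within the enriched fraction
#'
#' Applies the marker rule: a cell is a CTC iff it has low CD45, low
#' expression of every immune-lineage exclusion marker (CD3, CD4, CD8,
#' CD19, CD14, CD56, CD66b) and intermediate-to-high pan-cytokeratin.
#' All other enriched events are labelled `enriched_leucocyte`.  Cut
#' points default to valley-seeking on each marker's ArcSinh distribution
#' (anchored by the leucocytes present in the fraction), with the
#' configured fixed cuts as fallback; set `auto_marker_cuts = FALSE` in
#' the thresholds to use the fixed cuts directly.
#'
#' @param events Enriched-fraction `ctc_events` (ArcSinh transformed).
#' @param panel The antibody panel.
#' @param thresholds A [gate_thresholds()] object.
#' @return A list of class `ctc_gate_result` with `labels` (`ctc` /
#'   `enriched_leucocyte`), `events`, `cuts` and `tallies`.
#' @export
identify_ctcs <- function(events, panel = events$panel,
                          thresholds = gate_thresholds()) {
  stopifnot(inherits(events, "ctc_events"))
  if (!isTRUE(events$transformed))
    stop("CTC identification expects ArcSinh-transformed events")
  lineage <- lineage_exclusion_markers(panel)
  need <- c("CD45", "Pan-cytokeratin", lineage)
  missing <- setdiff(need, colnames(events$exprs))
  if (length(missing))
    stop("panel/events missing required marker(s): ",
         paste(missing, collapse = ", "))
  cut_for <- function(marker, fallback) {
    if (!isTRUE(thresholds$auto_marker_cuts)) return(fallback)
    tryCatch(find_valley_cut(events$exprs[, marker], fallback),
             error = function(e) fallback)
  }
  cd45_cut <- cut_for("CD45", thresholds$cd45_low)
  panck_cut <- cut_for("Pan-cytokeratin", thresholds$panck_min)
  lin_cuts <- vapply(lineage, cut_for, numeric(1),
                     fallback = thresholds$lineage_low)
  is_ctc <- events$exprs[, "CD45"] < cd45_cut &
    events$exprs[, "Pan-cytokeratin"] >= panck_cut
  for (mk in lineage) is_ctc <- is_ctc & events$exprs[, mk] < lin_cuts[mk]
  labels <- unname(ifelse(is_ctc, "ctc", "enriched_leucocyte"))
  res <- list(labels = labels, events = events,
              cuts = c(CD45 = cd45_cut, `Pan-cytokeratin` = panck_cut,
                       lin_cuts),
              tallies = c(ctc = sum(is_ctc),
                          enriched_leucocyte = sum(!is_ctc)))
  class(res) <- "ctc_gate_result"
  res
}

#' Score a patient's CTC positivity
#'
#' A patient is scored `negative` when the identified CTC total is at or
#' below the healthy-donor background threshold (default 4 cells per
#' draw), `positive` otherwise.
#'
#' @param ctc_total Non-negative CTC count for the draw.
#' @param thresholds A [gate_thresholds()] object.
#' @return `"positive"` or `"negative"`.
#' @export
score_positivity <- function(ctc_total, thresholds = gate_thresholds()) {
  if (ctc_total < 0) stop("ctc_total must be non-negative")
  if (ctc_total <= thresholds$background_ctc_threshold) "negative" else "positive"
}

#' CTCs per millilitre of blood
#'
#' Converts a per-draw CTC total to a cells/ml concentration, rounded
#' half-up to an integer (218 cells in a 9 ml draw gives 24 cells/ml).
#'
#' @param ctc_total Non-negative count.
#' @param volume_ml Draw volume in ml (default 9).
#' @return Integer concentration.
#' @export
per_ml <- function(ctc_total, volume_ml = 9) {
  if (volume_ml <= 0) stop("volume_ml must be positive")
  if (any(ctc_total < 0)) stop("ctc_total must be non-negative")
  as.integer(floor(ctc_total / volume_ml + 0.5))
}

#' Gate one sample end to end
#'
#' Convenience wrapper running ArcSinh transformation (if needed),
#' Gaussian clean-up, population deconvolution and CTC identification,
#' returning one exhaustive per-event label partition
#' (`debris` / `carrier` / `control` / `enriched_leucocyte` / `ctc`)
#' together with the tallies, the positivity call and every threshold
#' used.
#'
#' @param events Raw or transformed `ctc_events` for one sample.
#' @param thresholds A [gate_thresholds()] object.
#' @param cofactor ArcSinh cofactor applied when the input is raw.
#' @return A list of class `sample_gate` with `labels`, `tallies`,
#'   `positivity`, `ctc_events` (the transformed CTC subset), `cuts`
#'   and `windows`.
#' @export
gate_sample <- function(events, thresholds = gate_thresholds(), cofactor = 5) {
  if (!isTRUE(events$transformed))
    events <- arcsinh_transform(events, cofactor)
  clean <- gaussian_cleanup(events, thresholds)
  deconv <- deconvolute_populations(clean$events, thresholds)
  enr <- enriched_events(deconv)
  idres <- identify_ctcs(enr, events$panel, thresholds)

  labels <- character(nrow(events$exprs))
  labels[clean$labels == "debris"] <- "debris"
  intact_idx <- which(clean$labels == "intact")
  labels[intact_idx] <- deconv$labels
  enr_idx <- intact_idx[deconv$labels == "enriched"]
  labels[enr_idx] <- idres$labels

  tallies <- table(factor(labels, c("debris", "carrier", "control",
                                    "enriched_leucocyte", "ctc")))
  res <- list(labels = labels,
              tallies = tallies,
              positivity = score_positivity(sum(labels == "ctc"), thresholds),
              ctc_events = idres$events[idres$labels == "ctc"],
              cuts = c(deconv$cuts, idres$cuts),
              windows = clean$windows,
              sample_id = events$sample_id)
  class(res) <- "sample_gate"
  res
}

#' @export
print.sample_gate <- function(x, ...) {
  cat("<sample_gate> ", x$sample_id, ": ", sum(x$tallies), " events, ",
      x$tallies[["ctc"]], " CTCs (", x$positivity, ")\n", sep = "")
  print(x$tallies)
  invisible(x)
}
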
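#' Antibody panel for CTC mass cytometry
#'
#' Builds the default 41-antibody panel used throughout the pipeline: 40
#' analytical markers covering immune-cell lineage, epithelial lineage,
#' epithelial-mesenchymal transition (EMT), stemness/proliferation, immune
#' evasion and phosphorylated signalling proteins, plus the cadmium-106
#' B2M/CD298 barcode used to tag carrier PBMCs.  Osmium (the control-cell
#' label) and the acquisition Gaussian parameters (Event_length, Center,
#' Offset, Width, Residual) are carried as non-antibody channels.
#'
#' Each analytical marker is assigned a metal channel identifier in the
#' conventional `<Metal><Mass>Di` form.  Channel assignments are stable
#' across calls.
#'
#' @return A data frame of class `ctc_panel` with columns `marker`,
#'   `channel` and `category`.  Categories are one of
#'   `epithelial_lineage`, `immune_lineage`, `emt`,
#'   `stemness_proliferation`, `immune_evasion`, `phospho` (the analytical
#'   categories), `barcode`, `control_label` or `acquisition`.
#' @examples
#' pan <- hn_panel()
#' nrow(panel_markers(pan))   # 40 analytical markers
#' @export
hn_panel <- function() {
  analytical <- list(
    # marker, category
    c("EpCAM",           "epithelial_lineage"),
    c("Pan-cytokeratin", "epithelial_lineage"),
    c("E-cadherin",      "epithelial_lineage"),
    c("EGFR",            "epithelial_lineage"),
    c("CD3",             "immune_lineage"),
    c("CD4",             "immune_lineage"),
    c("CD8",             "immune_lineage"),
    c("CD25",            "immune_lineage"),
    c("CD14",            "immune_lineage"),
    c("CD86",            "immune_lineage"),
    c("CD163",           "immune_lineage"),
    c("CD19",            "immune_lineage"),
    c("CD56",            "immune_lineage"),
    c("CD66b",           "immune_lineage"),
    c("HLA-ABC",         "immune_lineage"),
    c("HLA-DR",          "immune_lineage"),
    c("CD45",            "immune_lineage"),
    c("CD31",            "immune_lineage"),
    c("Vimentin",        "emt"),
    c("Snail1",          "emt"),
    c("Twist",           "emt"),
    c("CD133",           "stemness_proliferation"),
    c("CD24",            "stemness_proliferation"),
    c("CD44",            "stemness_proliferation"),
    c("Ki67",            "stemness_proliferation"),
    c("CD47",            "immune_evasion"),
    c("PD-1",            "immune_evasion"),
    c("PD-L1",           "immune_evasion"),
    c("PD-L2",           "immune_evasion"),
    c("CTLA4",           "immune_evasion"),
    c("CD39",            "immune_evasion"),
    c("CD73",            "immune_evasion"),
    c("pSTAT1",          "phospho"),
    c("pSTAT3",          "phospho"),
    c("pSTAT5",          "phospho"),
    c("pPARP",           "phospho"),
    c("pAKT",            "phospho"),
    c("pERK",            "phospho"),
    c("pCREB",           "phospho"),
    c("p38",             "phospho")
  )
  metals <- c(
    "Y89", "In113", "In115", "Pr141", "Nd142", "Nd143", "Nd144", "Nd145",
    "Nd146", "Sm147", "Nd148", "Sm149", "Nd150", "Eu151", "Sm152", "Eu153",
    "Sm154", "Gd155", "Gd156", "Gd158", "Tb159", "Gd160", "Dy161", "Dy162",
    "Dy163", "Dy164", "Ho165", "Er166", "Er167", "Er168", "Tm169", "Er170",
    "Yb171", "Yb172", "Yb173", "Yb174", "Lu175", "Yb176", "Pt195", "Bi209"
  )
  stopifnot(length(analytical) == length(metals))
  df <- data.frame(
    marker   = vapply(analytical, `[`, "", 1L),
    channel  = paste0(metals, "Di"),
    category = vapply(analytical, `[`, "", 2L),
    stringsAsFactors = FALSE
  )
  extra <- data.frame(
    marker  = c("B2M_ATPase", "Osmium",
                "Event_length", "Center", "Offset", "Width", "Residual"),
    channel = c("Cd106Di", "Os189Di",
                "Event_length", "Center", "Offset", "Width", "Residual"),
    category = c("barcode", "control_label", rep("acquisition", 5L)),
    stringsAsFactors = FALSE
  )
  panel <- rbind(df, extra)
  validate_panel(panel)
  class(panel) <- c("ctc_panel", "data.frame")
  panel
}

validate_panel <- function(panel) {
  stopifnot(is.data.frame(panel),
            all(c("marker", "channel", "category") %in% names(panel)))
  if (anyDuplicated(panel$marker))
    stop("panel marker names must be unique")
  if (sum(panel$category == "barcode") != 1L)
    stop("panel must contain exactly one barcode channel")
  if (sum(panel$category == "control_label") != 1L)
    stop("panel must contain exactly one control-label channel")
  invisible(panel)
}

#' Panel category groups
#'
#' Convenience accessors over a [hn_panel()]-style panel.
#' `panel_markers()` returns the analytical marker rows (antibodies other
#' than the carrier barcode); `barcode_marker()`, `control_marker()` and
#' `acquisition_channels()` return the respective marker names;
#' `lineage_exclusion_markers()` returns the immune-lineage markers used
#' (besides CD45) to exclude leucocytes from the CTC gate.
#'
#' @param panel A `ctc_panel` data frame.
#' @return For `panel_markers()` a data frame; character vectors otherwise.
#' @export
panel_markers <- function(panel) {
  panel[panel$category %in% c("epithelial_lineage", "immune_lineage", "emt",
                              "stemness_proliferation", "immune_evasion",
                              "phospho"), , drop = FALSE]
}

#' @rdname panel_markers
#' @export
barcode_marker <- function(panel) panel$marker[panel$category == "barcode"]

#' @rdname panel_markers
#' @export
control_marker <- function(panel) panel$marker[panel$category == "control_label"]

#' @rdname panel_markers
#' @export
acquisition_channels <- function(panel) {
  panel$marker[panel$category == "acquisition"]
}

#' @rdname panel_markers
#' @export
lineage_exclusion_markers <- function(panel) {
  want <- c("CD3", "CD4", "CD8", "CD19", "CD14", "CD56", "CD66b")
  missing <- setdiff(want, panel$marker)
  if (length(missing))
    stop("panel is missing exclusion markers: ", paste(missing, collapse = ", "))
  want
}

#' @export
print.ctc_panel <- function(x, ...) {
  cat("<ctc_panel> ", nrow(panel_markers(x)), " analytical markers, ",
      sum(x$category == "acquisition"), " acquisition channels\n", sep = "")
  print(table(x$category))
  invisible(x)
}
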
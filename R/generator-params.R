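#' Intensity-model parameters for the synthetic event generator
#'
#' Per (population, marker) the generator draws raw metal intensities from
#' a zero-inflated lognormal: with probability `zero_prob` the intensity
#' is 0, otherwise lognormal with log-scale standard deviation `sdlog`
#' (default 0.35) and a location chosen so that the typical ArcSinh value
#' (cofactor 5) equals the configured archetype level `m`.  Archetype
#' tables encode the qualitative marker co-patterns of the three CTC
#' subgroups:
#'
#' * `ctc_epithelial`: pan-cytokeratin/EpCAM/E-cadherin high, vimentin
#'   low, CD133/CD24 and immune-checkpoint markers elevated,
#'   pSTAT1/3/5, pPARP, pAKT elevated, Ki-67 intermediate.
#' * `ctc_early_emt`: vimentin high, EpCAM/E-cadherin moderate,
#'   Twist/CD44/pERK/pCREB elevated, Ki-67 elevated in part.
#' * `ctc_advanced_emt`: vimentin high, EpCAM/E-cadherin low, Snail1
#'   elevated, Ki-67 and pSTAT1 low, pCREB elevated.
#'
#' Carrier PBMCs are barcode(Cd-106)-positive, osmium-labelled control
#' cells are osmium-positive with uniformly activated phospho-markers,
#' enriched leucocytes are CD45-high/pan-cytokeratin-negative, and
#' healthy-donor background cells (`ctc_background`) are
#' pan-cytokeratin-moderate / CD45-low.  Debris and doublets carry
#' shifted acquisition Gaussian parameters (Residual and Offset inflated,
#' Width broadened).
#'
#' @param panel A [hn_panel()] panel.
#' @param sdlog Log-scale dispersion of the intensity model (default 0.35).
#' @param cofactor ArcSinh cofactor the archetype levels refer to.
#' @return A list of class `ctc_genparams` with archetype matrices `m`
#'   and `zero_prob` (markers x populations), `sdlog`, `cofactor` and
#'   `acquisition` distributions.
#' @export
generator_params <- function(panel = hn_panel(), sdlog = 0.35, cofactor = 5) {
  markers <- c(panel_markers(panel)$marker, barcode_marker(panel),
               control_marker(panel))
  pops <- c("carrier", "control", "leucocyte", "ctc_epithelial",
            "ctc_early_emt", "ctc_advanced_emt", "ctc_background", "debris")

  m  <- matrix(0.4, nrow = length(markers), ncol = length(pops),
               dimnames = list(markers, pops))
  zp <- matrix(0.85, nrow = length(markers), ncol = length(pops),
               dimnames = list(markers, pops))

  set <- function(pop, marker, level, zero) {
    m[marker, pop] <<- level
    zp[marker, pop] <<- zero
  }
  bc <- barcode_marker(panel)   # "B2M_ATPase"
  os <- control_marker(panel)   # "Osmium"
  phospho <- panel$marker[panel$category == "phospho"]
  checkpoints <- panel$marker[panel$category == "immune_evasion"]

  # barcode / osmium are negative everywhere unless set below
  zp[bc, ] <- 0.98; m[bc, ] <- 0.3
  zp[os, ] <- 0.98; m[os, ] <- 0.3

  ## carrier PBMCs: barcoded, CD45-high, mixed immune subsets
  pbmc <- function(pop) {
    set(pop, "CD45", 4.5, 0); set(pop, "HLA-ABC", 4.0, 0)
    set(pop, "CD3", 4.0, 0.40); set(pop, "CD4", 3.5, 0.60)
    set(pop, "CD8", 3.5, 0.75); set(pop, "CD14", 4.0, 0.80)
    set(pop, "CD19", 3.5, 0.88); set(pop, "CD56", 3.5, 0.88)
    set(pop, "CD66b", 3.0, 0.95); set(pop, "HLA-DR", 3.5, 0.60)
    set(pop, "Vimentin", 1.0, 0.70)
  }
  pbmc("carrier")
  set("carrier", bc, 4.5, 0)

  ## osmium-labelled activated control PBMCs
  pbmc("control")
  set("control", os, 4.5, 0)
  for (p in phospho) set("control", p, 4.0, 0.05)

  ## enriched leucocytes (Parsortix carry-over, unbarcoded)
  pbmc("leucocyte")

  ## CTC archetypes: all are CD45/immune-lineage negative (baseline) and
  ## pan-cytokeratin positive.
  ctc_common <- function(pop, panck) {
    set(pop, "Pan-cytokeratin", panck, 0)
    set(pop, "EGFR", 3.0, 0.15)
  }
  ctc_common("ctc_epithelial", 4.5)
  set("ctc_epithelial", "EpCAM", 4.5, 0)
  set("ctc_epithelial", "E-cadherin", 4.2, 0)
  set("ctc_epithelial", "Vimentin", 0.5, 0.80)
  set("ctc_epithelial", "CD133", 3.0, 0.20)
  set("ctc_epithelial", "CD24", 3.0, 0.20)
  for (ck in checkpoints) set("ctc_epithelial", ck, 3.0, 0.25)
  set("ctc_epithelial", "CD47", 1.5, 0.50)  # inversely related to stemness
  set("ctc_epithelial", "pSTAT1", 3.2, 0.10)
  set("ctc_epithelial", "pSTAT3", 3.2, 0.10)
  set("ctc_epithelial", "pSTAT5", 3.2, 0.10)
  set("ctc_epithelial", "pPARP", 3.0, 0.10)
  set("ctc_epithelial", "pAKT", 3.0, 0.10)
  set("ctc_epithelial", "pERK", 1.5, 0.40)
  set("ctc_epithelial", "pCREB", 1.0, 0.50)
  set("ctc_epithelial", "Ki67", 2.5, 0.30)
  set("ctc_epithelial", "CD44", 1.5, 0.40)

  ctc_common("ctc_early_emt", 4.2)
  set("ctc_early_emt", "EpCAM", 2.5, 0.05)
  set("ctc_early_emt", "E-cadherin", 2.5, 0.05)
  set("ctc_early_emt", "Vimentin", 4.2, 0)
  set("ctc_early_emt", "Twist", 3.5, 0.10)
  set("ctc_early_emt", "Snail1", 3.0, 0.15)
  set("ctc_early_emt", "CD44", 3.8, 0.05)
  set("ctc_early_emt", "pERK", 4.0, 0.05)
  set("ctc_early_emt", "pCREB", 3.8, 0.05)
  set("ctc_early_emt", "pSTAT1", 3.0, 0.15)
  set("ctc_early_emt", "Ki67", 3.0, 0.25)

  ctc_common("ctc_advanced_emt", 4.2)
  set("ctc_advanced_emt", "EpCAM", 0.8, 0.50)
  set("ctc_advanced_emt", "E-cadherin", 0.8, 0.50)
  set("ctc_advanced_emt", "Vimentin", 4.3, 0)
  set("ctc_advanced_emt", "Snail1", 3.8, 0.05)
  set("ctc_advanced_emt", "Twist", 2.0, 0.30)
  set("ctc_advanced_emt", "CD44", 3.5, 0.05)
  set("ctc_advanced_emt", "pERK", 2.0, 0.35)
  set("ctc_advanced_emt", "pCREB", 3.8, 0.05)
  set("ctc_advanced_emt", "pSTAT1", 0.6, 0.70)
  set("ctc_advanced_emt", "Ki67", 0.8, 0.70)

  ## healthy-donor background cells: panCK-moderate, CD45-low
  set("ctc_background", "Pan-cytokeratin", 2.5, 0)
  set("ctc_background", "EpCAM", 1.5, 0.30)
  set("ctc_background", "CD45", 0.4, 0.70)

  ## debris: dim on every channel
  m[, "debris"] <- 0.3
  zp[, "debris"] <- 0.70

  params <- list(
    m = m, zero_prob = zp, sdlog = sdlog, cofactor = cofactor,
    acquisition = list(
      intact = list(Event_length = c(25, 4),  Center = c(600, 50),
                    Offset = c(80, 15),       Width = c(120, 15),
                    Residual = c(70, 20)),
      debris = list(Event_length = c(45, 12), Center = c(600, 80),
                    Offset = c(300, 60),      Width = c(300, 60),
                    Residual = c(400, 80))
    )
  )
  class(params) <- "ctc_genparams"
  validate_genparams(params)
  params
}

validate_genparams <- function(params) {
  if (params$sdlog <= 0) stop("sdlog dispersion must be positive")
  if (params$cofactor <= 0) stop("cofactor must be positive")
  zp <- params$zero_prob
  if (any(zp < 0 | zp > 1)) stop("zero-inflation probabilities must lie in [0,1]")
  m <- params$m
  ord <- function(mk, a, b) m[mk, a] > m[mk, b]
  if (!(ord("EpCAM", "ctc_epithelial", "ctc_early_emt") &&
        ord("EpCAM", "ctc_early_emt", "ctc_advanced_emt")))
    stop("archetype ordering violated: EpCAM must decrease along the EMT axis")
  if (!(ord("Vimentin", "ctc_early_emt", "ctc_epithelial") &&
        ord("Vimentin", "ctc_advanced_emt", "ctc_epithelial")))
    stop("archetype ordering violated: vimentin must be higher in EMT subgroups")
  invisible(params)
}

#' Expected ArcSinh mean of a configured archetype
#'
#' The generator's configured level for a (population, marker) pair is an
#' ArcSinh-scale location; because intensities are zero-inflated
#' lognormal, the population mean of `asinh(x / cofactor)` differs
#' slightly from that location.  This helper computes the exact expected
#' value by numerical integration over the lognormal, for use in
#' moment-fidelity checks.
#'
#' @param params A [generator_params()] object.
#' @param population,marker Archetype cell.
#' @return Expected value of the ArcSinh-transformed intensity.
#' @export
expected_arcsinh_mean <- function(params, population, marker) {
  m <- params$m[marker, population]
  zp <- params$zero_prob[marker, population]
  cf <- params$cofactor
  meanlog <- log(cf * sinh(max(m, 1e-6)))
  f <- function(z) asinh(exp(z) / cf) * stats::dnorm(z, meanlog, params$sdlog)
  nonzero <- stats::integrate(f, meanlog - 8 * params$sdlog,
                              meanlog + 8 * params$sdlog)$value
  (1 - zp) * nonzero
}
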
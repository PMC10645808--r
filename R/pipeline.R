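#' Pipeline configuration
#'
#' Collects every setting of the end-to-end run.  The configuration can
#' be round-tripped through YAML with [read_pipeline_config()] /
#' [write_pipeline_config()].
#'
#' @param out_dir Output directory for the run.
#' @param seed Global integer seed.
#' @param cofactor ArcSinh cofactor.
#' @param som_grid,som_epochs SOM settings.
#' @param k_range Metacluster search range.
#' @param elbow_frac Elbow relative-decrease threshold.
#' @param simulate Generate the synthetic cohort (`TRUE`) or read event
#'   files from `input_files` (named list id -> FCS path).
#' @param input_files Named FCS paths when `simulate = FALSE`.
#' @param patient12_alt Alternate reading for the stage-I patient.
#' @param include_donors Simulate healthy donors as well.
#' @param run_expression Run the gene-expression comparators.
#' @param thresholds A [gate_thresholds()] object.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("ctc_run_"), seed = 1,
                            cofactor = 5, som_grid = c(10, 10),
                            som_epochs = 10, k_range = 2:20,
                            elbow_frac = 0.05, simulate = TRUE,
                            input_files = NULL, patient12_alt = FALSE,
                            include_donors = FALSE, run_expression = TRUE,
                            thresholds = gate_thresholds()) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              cofactor = cofactor, som_grid = som_grid,
              som_epochs = som_epochs, k_range = k_range,
              elbow_frac = elbow_frac, simulate = simulate,
              input_files = input_files, patient12_alt = patient12_alt,
              include_donors = include_donors,
              run_expression = run_expression, thresholds = thresholds)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  thr <- do.call(gate_thresholds, raw$thresholds %||% list())
  raw$thresholds <- thr
  cfg <- do.call(pipeline_config, raw)
  cfg
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  out <- unclass(config)
  out$thresholds <- unclass(config$thresholds)
  out$thresholds$acq_fixed <- NULL
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

provenance <- function(config) {
  list(tool = "ctcyto",
       version = as.character(utils::packageVersion("ctcyto")),
       seed = config$seed,
       config_hash = substr(config_hash(config), 1, 12))
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(unclass(config)[setdiff(names(config), "out_dir")], file = tmp)
  unname(tools::md5sum(tmp))
}

write_provenance_csv <- function(df, path, prov) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s %s | seed %d | config %s", prov$tool,
                     prov$version, prov$seed, prov$config_hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> ArcSinh -> Gaussian clean-up ->
#' population deconvolution -> CTC gate -> positivity -> concatenation ->
#' SOM + elbow metaclustering -> hierarchical EMT subgrouping -> subgroup
#' statistics, composition PCA and clinical associations -> (optionally)
#' the gene-expression comparators.  Every stage's outputs are written to
#' the run directory together with the resolved configuration and seed;
#' re-running with the same configuration is bit-identical for the
#' deterministic stages.  A stage failure aborts with the stage name;
#' partial outputs are retained.
#'
#' @param config A [pipeline_config()].
#' @param dry_run Validate the configuration and return without
#'   computing.
#' @return Invisibly, a list with the per-stage results (`gates`,
#'   `ctcs`, `som`, `map`, `profile`, `subgroups`, `stats`,
#'   `composition`, `pca`, `clinical`, `expression`) and `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), dry_run = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!config$simulate && is.null(config$input_files))
    stop("configuration error: no input files and simulation disabled")
  if (dry_run) return(invisible(list(config = config, out_dir = config$out_dir)))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- provenance(config)
  jsonlite::write_json(c(prov, list(config = "pipeline_config.yaml")),
                       file.path(config$out_dir, "run_info.json"),
                       auto_unbox = TRUE)
  write_pipeline_config(config, file.path(config$out_dir,
                                          "pipeline_config.yaml"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  panel <- hn_panel()
  cohort <- hn_cohort(patient12_alt = config$patient12_alt)
  params <- generator_params(panel, cofactor = config$cofactor)

  samples <- stage("input", {
    if (config$simulate) {
      simulate_cohort(cohort, panel, params, seed = config$seed,
                      include_donors = config$include_donors)
    } else {
      lapply(config$input_files, read_fcs, panel = panel)
    }
  })

  gates <- stage("gate", lapply(samples, gate_sample,
                                thresholds = config$thresholds,
                                cofactor = config$cofactor))
  tally <- data.frame(
    sample_id = names(gates),
    ctc = vapply(gates, function(g) unname(g$tallies[["ctc"]]), 0L),
    positivity = vapply(gates, function(g) g$positivity, ""),
    stringsAsFactors = FALSE)
  tally$ctc_per_ml <- per_ml(tally$ctc, cohort$draw_volume_ml)
  write_provenance_csv(tally, file.path(config$out_dir, "gate_tallies.csv"),
                       prov)
  jsonlite::write_json(
    c(prov, list(tallies = tally)),
    file.path(config$out_dir, "gate_tallies.json"), auto_unbox = TRUE)

  patient_gates <- gates[names(gates) %in% cohort$patients$patient_id]
  ctcs <- stage("concatenate", concatenate_ctcs(patient_gates))
  if (nrow(ctcs$exprs) == 0)
    stop("pipeline stage 'concatenate' produced no CTCs; ",
         "downstream clustering refused")

  som <- stage("cluster", train_som(ctcs, grid = config$som_grid,
                                    epochs = config$som_epochs,
                                    seed = config$seed))
  map <- stage("metacluster",
               elbow_metacluster(som, k_range = config$k_range,
                                 frac = config$elbow_frac))
  profile <- stage("profile", cluster_profiles(ctcs, som, map))
  prof_df <- data.frame(cluster = rep(rownames(profile$medians),
                                      ncol(profile$medians)),
                        marker = rep(colnames(profile$medians),
                                     each = nrow(profile$medians)),
                        median = as.vector(profile$medians),
                        stringsAsFactors = FALSE)
  write_provenance_csv(prof_df,
                       file.path(config$out_dir, "cluster_profiles.csv"),
                       prov)

  subgroups <- stage("subgroup", {
    sg <- hierarchical_subgroups(profile)
    label_emt_subgroups(sg, profile)
  })
  write_dendrogram(subgroups, file.path(config$out_dir,
                                        "subgroup_dendrogram.nwk"))
  write_provenance_csv(
    data.frame(metacluster = names(subgroups$metacluster_label),
               subgroup = unname(subgroups$metacluster_label)),
    file.path(config$out_dir, "subgroup_assignment.csv"), prov)

  stats_tab <- stage("stats", {
    compare_subgroups(ctcs, subgroups$event_label,
                      markers = c("EpCAM", "E-cadherin", "Vimentin",
                                  "Snail1", "Twist", "CD44", "Ki67",
                                  "pCREB", "pERK", "pSTAT1"))
  })
  write_provenance_csv(stats_tab,
                       file.path(config$out_dir, "subgroup_tests.csv"), prov)

  comp <- stage("composition", composition_matrix(ctcs, profile))
  write_provenance_csv(
    data.frame(patient_id = rownames(comp$matrix), comp$matrix,
               check.names = FALSE),
    file.path(config$out_dir, "composition.csv"), prov)
  pca <- stage("pca", pca_composition(comp, seed = config$seed))

  emt_frac <- vapply(rownames(comp$matrix), function(pid) {
    lab <- subgroups$event_label[ctcs$patient_id == pid]
    mean(lab != "epithelial")
  }, numeric(1))
  clinical <- NULL
  if (all(cohort$patients$patient_id %in% tally$sample_id)) {
    clinical <- stage("clinical", {
      totals <- stats::setNames(tally$ctc, tally$sample_id)
      clinical_associations(cohort,
                            totals[cohort$patients$patient_id],
                            emt_fraction = emt_frac)
    })
  }

  expression <- NULL
  if (config$run_expression) {
    expression <- stage("expression", {
      tum <- simulate_tumour_counts(seed = config$seed)
      classes <- emt_signature_cluster(tum)
      bulk <- simulate_bulk_ctc_counts(cohort, panel, params,
                                       seed = config$seed)
      de <- paired_bulk_de(bulk)
      dmap <- suppressWarnings(panel_dge_map(de, panel))
      cyto <- data.frame(patient_id = colnames(dmap),
                         positivity = tally$positivity[
                           match(colnames(dmap), tally$sample_id)],
                         ctc_total = tally$ctc[
                           match(colnames(dmap), tally$sample_id)],
                         emt_fraction = emt_frac[colnames(dmap)],
                         stringsAsFactors = FALSE)
      cyto$emt_fraction[is.na(cyto$emt_fraction)] <- 0
      tumour_class <- stats::setNames(
        classes$class, cohort$patients$patient_id[seq_along(classes$class)])
      conc <- concordance_report(cyto, dmap, tumour_class = tumour_class,
                                 panel = panel)
      write_provenance_csv(as.data.frame(dmap) ,
                           file.path(config$out_dir, "panel_dge_map.csv"),
                           prov)
      list(tumour_classes = classes, dge_map = dmap, concordance = conc)
    })
  }

  summary_json <- list(
    positive_patients = sum(tally$positivity[
      tally$sample_id %in% cohort$patients$patient_id] == "positive"),
    n_patients = nrow(cohort$patients),
    k_metaclusters = map$k,
    subgroup_counts = as.list(subgroups$counts))
  jsonlite::write_json(c(prov, summary_json),
                       file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE)

  invisible(list(config = config, out_dir = config$out_dir, gates = gates,
                 tally = tally, ctcs = ctcs, som = som, map = map,
                 profile = profile, subgroups = subgroups,
                 stats = stats_tab, composition = comp, pca = pca,
                 clinical = clinical, expression = expression))
}
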
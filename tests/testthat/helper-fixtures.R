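# Shared fixtures, lazily built once per test run, plus independent
# oracles used across test files.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Full default cohort: simulated samples, per-sample gates, concatenated
# CTCs, SOM, metaclusters, profiles, labelled subgroups.
default_run <- function() {
  fixture("default_run", function() {
    panel <- hn_panel()
    cohort <- hn_cohort()
    params <- generator_params(panel)
    samples <- simulate_cohort(cohort, panel, params, seed = 1,
                               include_donors = TRUE)
    gates <- lapply(samples, gate_sample)
    patient_gates <- gates[cohort$patients$patient_id]
    ctcs <- concatenate_ctcs(patient_gates)
    som <- train_som(ctcs, seed = 1)
    map <- elbow_metacluster(som)
    profile <- cluster_profiles(ctcs, som, map)
    subgroups <- label_emt_subgroups(hierarchical_subgroups(profile))
    list(panel = panel, cohort = cohort, params = params,
         samples = samples, gates = gates, patient_gates = patient_gates,
         ctcs = ctcs, som = som, map = map, profile = profile,
         subgroups = subgroups)
  })
}

# a small sample for fast per-operation tests
small_entry <- function(id = "S1", ctc_total = 60L,
                        mixture = c(epithelial = 0.3, early_EMT = 0.4,
                                    advanced_EMT = 0.3),
                        debris_fraction = 0.05) {
  list(id = id, ctc_total = ctc_total, mixture = mixture, is_donor = FALSE,
       carrier_count = 1500L, control_count = 300L, enriched_count = 500L,
       debris_fraction = debris_fraction)
}

truth_subgroup <- function(truth) {
  c(ctc_epithelial = "epithelial", ctc_early_emt = "early_EMT",
    ctc_advanced_emt = "advanced_EMT")[truth]
}

# Adjusted Rand index (mclust is the independent implementation)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Brute-force two-sided Mann-Whitney p: enumerate every assignment of
# group labels to the pooled values and recompute U from the pair
# definition each time.
mwu_enum_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  u_of <- function(av, bv) {
    sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  }
  u_obs <- u_of(a, b)
  lo_obs <- min(u_obs, n1 * n2 - u_obs)
  combs <- utils::combn(n1 + n2, n1)
  stats <- apply(combs, 2, function(idx) {
    u_of(pooled[idx], pooled[-idx])
  })
  lo <- pmin(stats, n1 * n2 - stats)
  list(U = u_obs, p = mean(lo <= lo_obs + 1e-9))
}

# Benjamini-Hochberg by the literal step-up definition
bh_stepup_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- Inf
  for (i in n:1) {
    running <- min(running, n * p[o[i]] / i)
    adj[o[i]] <- min(running, 1)
  }
  adj
}

# Independent byte-level FCS reader: parses HEADER offsets and the TEXT
# dictionary directly, without any package code path.
fcs_bytes_oracle <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  header <- rawToChar(bytes[1:58])
  version <- substr(header, 1, 6)
  off <- as.integer(vapply(0:5, function(i)
    substr(header, 11 + 8 * i, 18 + 8 * i), ""))
  text <- rawToChar(bytes[(off[1] + 1):(off[2] + 1)])
  delim <- substr(text, 1, 1)
  toks <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  kv <- stats::setNames(toks[seq(2, length(toks), 2)],
                        toks[seq(1, length(toks), 2)])
  n_tot <- as.integer(kv[["$TOT"]])
  n_par <- as.integer(kv[["$PAR"]])
  data_start <- as.integer(kv[["$BEGINDATA"]])
  vals <- readBin(bytes[(data_start + 1):length(bytes)], "numeric",
                  n = n_tot * n_par, size = 4, endian = "little")
  list(version = version, n_tot = n_tot, n_par = n_par,
       pnn = vapply(seq_len(n_par), function(i) kv[[paste0("$P", i, "N")]], ""),
       data = matrix(vals, n_tot, n_par, byrow = TRUE))
}
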
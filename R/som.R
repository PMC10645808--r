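#' Concatenate CTC events from positive patients
#'
#' Builds the single cross-patient dataset used for clustering by
#' stacking the CTC-labelled events of every CTC-positive sample.  The
#' patient identifier is retained per event; events from
#' positivity-negative patients are refused.
#'
#' @param gates Named list of [gate_sample()] results (one per patient).
#' @return A `ctc_events` object whose `patient_id` field holds the
#'   per-event source patient and whose row count equals the sum of the
#'   positive patients' CTC tallies.
#' @export
concatenate_ctcs <- function(gates) {
  stopifnot(length(gates) > 0)
  pos <- Filter(function(g) g$positivity == "positive", gates)
  neg <- Filter(function(g) g$positivity == "negative" &&
                  g$tallies[["ctc"]] > 0, gates)
  if (length(pos) == 0) {
    tmpl <- gates[[1]]$ctc_events
    out <- new_events(tmpl$exprs[0, , drop = FALSE], tmpl$panel,
                      sample_id = "concatenated", transformed = TRUE,
                      cofactor = tmpl$cofactor)
    out$patient_id <- character(0)
    return(out)
  }
  blocks <- lapply(pos, function(g) g$ctc_events$exprs)
  exprs <- do.call(rbind, blocks)
  patient <- rep(vapply(pos, function(g) g$sample_id, ""),
                 vapply(blocks, nrow, 0L))
  truths <- lapply(pos, function(g) g$ctc_events$truth)
  truth <- if (!any(vapply(truths, is.null, TRUE))) unlist(truths, use.names = FALSE)
  ev <- new_events(exprs, pos[[1]]$ctc_events$panel,
                   sample_id = "concatenated", truth = truth,
                   transformed = TRUE, cofactor = pos[[1]]$ctc_events$cofactor)
  ev$patient_id <- unname(patient)
  ev
}

clustering_matrix <- function(events, markers = NULL, z_scale = FALSE) {
  if (is.null(markers)) markers <- panel_markers(events$panel)$marker
  x <- events$exprs[, markers, drop = FALSE]
  if (z_scale) x <- scale(x)
  x
}

#' Train a batch self-organizing map on CTC events
#'
#' FlowSOM-style quantization: a rectangular SOM grid is fitted to the
#' ArcSinh intensities of the analytical markers by batch updates with a
#' Gaussian neighbourhood whose radius shrinks linearly across epochs.
#' The codebook is initialized from a seeded sample of the events, so the
#' fit is fully reproducible.
#'
#' @param events Concatenated, transformed `ctc_events` (all events must
#'   be finite).
#' @param grid `c(rows, cols)` grid dimensions (default 10 x 10).
#' @param epochs Number of batch epochs (default 10).
#' @param seed Integer seed.
#' @param markers Markers to cluster on (default: all analytical markers).
#' @param z_scale Optional per-marker z-scaling before training (default
#'   `FALSE`; ArcSinh is the only scaling, matching cytometry convention).
#' @return A list of class `som_model` with `codebook` (nodes x markers),
#'   `grid`, `qe` (quantization error per epoch), `markers`, `seed`.
#' @export
train_som <- function(events, grid = c(10, 10), epochs = 10, seed = 1,
                      markers = NULL, z_scale = FALSE) {
  x <- clustering_matrix(events, markers, z_scale)
  if (nrow(x) == 0) stop("cannot train a SOM on an empty event table")
  if (!all(is.finite(x))) stop("non-finite intensities in clustering markers")
  n_nodes <- prod(grid)
  gx <- rep(seq_len(grid[1]), times = grid[2])
  gy <- rep(seq_len(grid[2]), each = grid[1])
  grid_d2 <- outer(gx, gx, "-")^2 + outer(gy, gy, "-")^2

  withr::with_seed(as.integer(seed), {
    # PCA-grid initialization: nodes start on the plane of the first two
    # principal components, so early epochs only refine an ordered map
    ctr <- colMeans(x)
    xc <- sweep(x, 2, ctr)
    sv <- svd(xc, nu = 0, nv = 2)
    ax1 <- sv$v[, 1] * sv$d[1] / sqrt(max(nrow(x) - 1, 1))
    ax2 <- if (ncol(sv$v) > 1) sv$v[, 2] * sv$d[2] / sqrt(max(nrow(x) - 1, 1)) else 0 * ax1
    s1 <- seq(-2, 2, length.out = grid[1])[gx]
    s2 <- seq(-2, 2, length.out = grid[2])[gy]
    codebook <- matrix(ctr, n_nodes, ncol(x), byrow = TRUE) +
      outer(s1, ax1) + outer(s2, ax2) +
      matrix(stats::rnorm(n_nodes * ncol(x), 0, 1e-4), n_nodes)
    colnames(codebook) <- colnames(x)
    radii <- seq(max(grid) / 2, 0.5, length.out = epochs)
    qe <- numeric(epochs)
    for (e in seq_len(epochs)) {
      d2 <- cross_dist2(x, codebook)
      bmu <- max.col(-d2, ties.method = "first")
      qe[e] <- mean(sqrt(d2[cbind(seq_len(nrow(x)), bmu)]))
      h <- exp(-grid_d2 / (2 * radii[e]^2))     # nodes x nodes
      w <- h[, bmu, drop = FALSE]               # nodes x events
      denom <- rowSums(w)
      codebook <- sweep(w %*% x, 1, pmax(denom, 1e-12), "/")
    }
  })
  rownames(codebook) <- paste0("node", seq_len(n_nodes))
  res <- list(codebook = codebook, grid = grid, qe = qe,
              markers = colnames(x), epochs = epochs, seed = seed,
              z_scale = z_scale)
  class(res) <- "som_model"
  res
}

# squared euclidean cross-distances, events x nodes
cross_dist2 <- function(x, w) {
  d2 <- outer(rowSums(x^2), rowSums(w^2), "+") - 2 * tcrossprod(x, w)
  pmax(d2, 0)
}

#' Best-matching node per event
#'
#' Nearest-centroid assignment of events to SOM codebook nodes.
#'
#' @param model A [train_som()] model.
#' @param events `ctc_events` with the model's markers.
#' @return Integer vector of node indices.
#' @export
map_events <- function(model, events) {
  x <- clustering_matrix(events, model$markers, model$z_scale)
  max.col(-cross_dist2(x, model$codebook), ties.method = "first")
}

#' @export
print.som_model <- function(x, ...) {
  cat("<som_model> ", x$grid[1], "x", x$grid[2], " grid, ",
      length(x$markers), " markers, ", x$epochs,
      " epochs (QE ", signif(x$qe[1], 3), " -> ",
      signif(x$qe[length(x$qe)], 3), ")\n", sep = "")
  invisible(x)
}

#' Elbow metaclustering of SOM nodes
#'
#' Agglomerative (Ward) clustering of the codebook vectors, with the
#' number of metaclusters chosen by an explicit elbow rule: walking k
#' upward through `k_range`, k is accepted as soon as the decrease in
#' within-metacluster sum of squares gained by moving to k + 1 clusters
#' falls below `frac` (default 0.05) of the total decrease across the
#' whole curve.  A flat curve therefore yields the smallest k in range.
#' The full elbow curve (k versus within-cluster sum of squares) is
#' returned; because the agglomerative partitions are nested, the curve
#' is monotone non-increasing.
#'
#' @param model A [train_som()] model.
#' @param k_range Candidate metacluster counts (default 2:20).
#' @param frac Relative-decrease threshold of the elbow rule.
#' @param linkage Linkage for the codebook tree (default `"ward.D2"`).
#' @return A list of class `metacluster_map` with `k`, `assignment`
#'   (node -> metacluster), `curve` (data frame k, wss) and `hclust`.
#' @export
elbow_metacluster <- function(model, k_range = 2:20, frac = 0.05,
                              linkage = "ward.D2") {
  cb <- model$codebook
  k_range <- sort(unique(as.integer(k_range)))
  if (max(k_range) >= nrow(cb))
    stop("k_range must not reach the node count")
  hc <- stats::hclust(stats::dist(cb), method = linkage)
  ks <- 1:(max(k_range) + 1L)
  wss <- vapply(ks, function(k) {
    cl <- stats::cutree(hc, k)
    sum(vapply(split(seq_len(nrow(cb)), cl), function(idx) {
      sub <- cb[idx, , drop = FALSE]
      sum(sweep(sub, 2, colMeans(sub))^2)
    }, numeric(1)))
  }, numeric(1))
  total <- wss[1] - wss[length(wss)]
  k <- max(k_range)
  if (total > 0) {
    for (kk in k_range) {
      if ((wss[kk] - wss[kk + 1L]) / total < frac) { k <- kk; break }
    }
  } else {
    k <- min(k_range)
  }
  res <- list(k = k, assignment = stats::cutree(hc, k),
              curve = data.frame(k = ks, wss = wss), hclust = hc,
              k_range = k_range, frac = frac)
  class(res) <- "metacluster_map"
  res
}

#' @export
print.metacluster_map <- function(x, ...) {
  cat("<metacluster_map> k = ", x$k, " metaclusters over ",
      length(x$assignment), " nodes\n", sep = "")
  invisible(x)
}

#' Per-metacluster median profiles
#'
#' Assigns every event to a metacluster (via its best-matching node) and
#' summarizes each metacluster by its per-marker median ArcSinh
#' intensity, cell count and fraction of the concatenated dataset.
#'
#' @param events Concatenated `ctc_events`.
#' @param model A [train_som()] model.
#' @param map A [elbow_metacluster()] map.
#' @return A list of class `cluster_profile` with `medians`
#'   (metaclusters x markers), `counts`, `fractions` and
#'   `event_metacluster` (per-event assignment).
#' @export
cluster_profiles <- function(events, model, map) {
  bmu <- map_events(model, events)
  mc <- map$assignment[bmu]
  x <- clustering_matrix(events, model$markers, model$z_scale)
  # metaclusters whose nodes attract no event carry no phenotype and are
  # dropped from the profile
  ks <- sort(unique(mc))
  medians <- t(vapply(ks, function(k) {
    apply(x[mc == k, , drop = FALSE], 2, stats::median)
  }, numeric(ncol(x))))
  rownames(medians) <- paste0("c", ks)
  counts <- vapply(ks, function(k) sum(mc == k), 0L)
  names(counts) <- rownames(medians)
  res <- list(medians = medians, counts = counts,
              fractions = counts / sum(counts),
              event_metacluster = mc, ids = ks, k = length(ks))
  class(res) <- "cluster_profile"
  res
}

#' @export
print.cluster_profile <- function(x, ...) {
  cat("<cluster_profile> ", x$k, " metaclusters, ",
      sum(x$counts), " cells\n", sep = "")
  print(round(x$fractions, 3))
  invisible(x)
}

#' Two-dimensional embedding of events
#'
#' Seeded 2-D layout of the clustered events for visual inspection,
#' computed by principal components of jittered ArcSinh intensities.  No
#' downstream stage consumes the embedding.
#'
#' @param events `ctc_events` with at least 10 events.
#' @param seed Integer seed (controls the jitter).
#' @param markers Markers to embed on (default: analytical markers).
#' @return Matrix events x 2 of coordinates.
#' @export
embed_events <- function(events, seed = 1, markers = NULL) {
  x <- clustering_matrix(events, markers)
  if (nrow(x) < 10) stop("embedding needs at least 10 events")
  withr::with_seed(as.integer(seed), {
    xj <- x + matrix(stats::rnorm(length(x), 0, 1e-6), nrow(x))
    sc <- stats::prcomp(xj, center = TRUE)$x[, 1:2, drop = FALSE]
  })
  colnames(sc) <- c("dim1", "dim2")
  sc
}
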
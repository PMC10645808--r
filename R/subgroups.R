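#' Hierarchical parent grouping of metaclusters
#'
#' Builds an agglomerative tree over the metacluster median profiles
#' (euclidean distance, average linkage by default) and cuts it into
#' exactly `k` parent groups (default 3, the number of CTC subgroups the
#' analysis targets).
#'
#' @param profile A [cluster_profiles()] object with at least `k`
#'   metaclusters.
#' @param k Number of parent groups (default 3).
#' @param linkage Agglomeration method (default `"average"`).
#' @return A list of class `subgroup_assignment` with `group`
#'   (metacluster -> parent-group id), `hclust`, `profile` and, until
#'   [label_emt_subgroups()] is applied, `labels = NULL`.
#' @export
hierarchical_subgroups <- function(profile, k = 3, linkage = "average") {
  stopifnot(inherits(profile, "cluster_profile"))
  if (profile$k < k)
    stop("need at least ", k, " metaclusters to form ", k, " parent groups")
  hc <- stats::hclust(stats::dist(profile$medians), method = linkage)
  group <- stats::cutree(hc, k)
  res <- list(group = group, hclust = hc, profile = profile, k = k,
              labels = NULL)
  class(res) <- "subgroup_assignment"
  res
}

#' Label parent groups along the epithelial-EMT axis
#'
#' Applies the labelling rule used to name the three CTC subgroups: the
#' parent group with the lowest mean vimentin median is `epithelial`; of
#' the remaining two (vimentin-expressing) groups, the one with the
#' higher mean of the EpCAM and E-cadherin medians is `early_EMT`
#' (moderate residual epithelial expression) and the other is
#' `advanced_EMT`.  Exact ties on a deciding statistic are reported as an
#' error rather than silently broken.
#'
#' @param assignment A [hierarchical_subgroups()] result with 3 groups.
#' @param profile The matching [cluster_profiles()] object.
#' @return The assignment with `labels` filled in: a named character
#'   vector parent-group id -> label, plus `metacluster_label` and
#'   per-subgroup `counts` and `fractions`.
#' @export
label_emt_subgroups <- function(assignment, profile = assignment$profile) {
  stopifnot(inherits(assignment, "subgroup_assignment"))
  if (assignment$k != 3)
    stop("EMT labelling is defined for exactly 3 parent groups")
  med <- profile$medians
  need <- c("Vimentin", "EpCAM", "E-cadherin")
  if (!all(need %in% colnames(med)))
    stop("profiles must include Vimentin, EpCAM and E-cadherin medians")
  gids <- sort(unique(assignment$group))
  vim <- vapply(gids, function(g)
    mean(med[assignment$group == g, "Vimentin"]), numeric(1))
  if (anyDuplicated(vim))
    stop("tie on mean vimentin median between parent groups")
  epi <- gids[which.min(vim)]
  rest <- setdiff(gids, epi)
  ecad <- vapply(rest, function(g)
    mean((med[assignment$group == g, "EpCAM"] +
            med[assignment$group == g, "E-cadherin"]) / 2), numeric(1))
  if (ecad[1] == ecad[2])
    stop("tie on mean EpCAM/E-cadherin median between EMT groups")
  early <- rest[which.max(ecad)]
  advanced <- rest[which.min(ecad)]
  labels <- c("epithelial", "early_EMT", "advanced_EMT")
  names(labels) <- c(epi, early, advanced)
  labels <- labels[as.character(gids)]

  mc_label <- labels[as.character(assignment$group)]
  names(mc_label) <- names(assignment$group)
  ids <- if (!is.null(profile$ids)) profile$ids
  else seq_along(mc_label)
  ev_label <- mc_label[match(profile$event_metacluster, ids)]
  counts <- table(factor(ev_label,
                         c("epithelial", "early_EMT", "advanced_EMT")))
  assignment$labels <- labels
  assignment$metacluster_label <- mc_label
  assignment$event_label <- unname(ev_label)
  assignment$counts <- counts
  assignment$fractions <- counts / sum(counts)
  assignment
}

#' @export
print.subgroup_assignment <- function(x, ...) {
  cat("<subgroup_assignment> ", length(x$group), " metaclusters -> ",
      x$k, " parent groups\n", sep = "")
  if (!is.null(x$labels)) {
    print(x$counts)
    cat("fractions: ",
        paste(sprintf("%s %.1f%%", names(x$fractions), 100 * x$fractions),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Export a subgroup dendrogram as Newick text
#'
#' @param assignment A `subgroup_assignment` (or any result carrying an
#'   `hclust` element).
#' @param path File to write.
#' @return The path, invisibly.
#' @export
write_dendrogram <- function(assignment, path) {
  phy <- ape::as.phylo(assignment$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}
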
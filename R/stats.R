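#' Mann-Whitney U test
#'
#' Rank-sum test with the U statistic defined over pairs:
#' `U = sum_ij [a_i > b_j] + 0.5 * [a_i == b_j]` (computed via midranks).
#' For small samples (`n1 + n2 <= 12`) the two-sided p value is exact,
#' by full enumeration of all group-label assignments of the pooled
#' values: `p = P(min(U*, n1 n2 - U*) <= min(u, n1 n2 - u))`.  For larger
#' samples a tie-corrected normal approximation is used.  Exact
#' enumeration with ties present and `n1 + n2 > 12` is refused.
#'
#' @param a,b Non-empty numeric samples.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) enumeration; default
#'   `NULL` enumerates iff `n1 + n2 <= 12`.
#' @return A list of class `mwu_test`: `U`, `p`, `method` (`"exact"` or
#'   `"normal_approx"`), `medians`, `n`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(a, b, exact = NULL) {
  if (length(a) == 0 || length(b) == 0)
    stop("both samples must be non-empty")
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  if (is.null(exact)) exact <- n <= 12
  if (exact && n > 12 && ties)
    stop("exact enumeration refused: ties present and n1 + n2 > 12")
  if (exact) {
    if (n > 22) stop("exact enumeration limited to n1 + n2 <= 22")
    combs <- utils::combn(n, n1)
    stat <- apply(combs, 2, function(idx) {
      sum(r[idx]) - n1 * (n1 + 1) / 2
    })
    lo_obs <- min(u, n1 * n2 - u)
    lo <- pmin(stat, n1 * n2 - stat)
    p <- mean(lo <= lo_obs + 1e-9)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    sigma2 <- n1 * n2 / 12 *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal_approx"
  }
  structure(list(U = u, p = p, method = method,
                 medians = c(stats::median(a), stats::median(b)),
                 n = c(n1 = n1, n2 = n2)),
            class = "mwu_test")
}

#' @export
print.mwu_test <- function(x, ...) {
  cat("Mann-Whitney U = ", x$U, ", p = ", signif(x$p, 4),
      " (", x$method, "; n = ", x$n[1], ", ", x$n[2], ")\n", sep = "")
  invisible(x)
}

#' Per-marker contrasts between EMT subgroups
#'
#' For every marker and every pair of subgroups, runs [mann_whitney_u()]
#' on the ArcSinh intensities of the cells in each subgroup (default), or
#' on the per-metacluster median profiles when `level =
#' "cluster_median"`.  No multiple-testing correction is applied by
#' default; set `adjust = TRUE` to add a Benjamini-Hochberg column.
#'
#' @param events Concatenated `ctc_events`.
#' @param labels Per-event subgroup label (e.g.
#'   `subgroup$event_label`); at least two subgroups must be present.
#' @param markers Markers to test (default: all analytical markers).
#' @param level `"cell"` or `"cluster_median"`.
#' @param profile Required for `level = "cluster_median"`: a
#'   [cluster_profiles()] object (the metacluster labels are then taken
#'   from `metacluster_labels`).
#' @param metacluster_labels Metacluster -> subgroup label vector for the
#'   cluster-median level.
#' @param adjust Add a BH-adjusted p column.
#' @return Data frame with one row per (marker, group pair): medians per
#'   group, `U`, `p`, `method`, and optionally `p_adj`.
#' @export
compare_subgroups <- function(events, labels, markers = NULL,
                              level = c("cell", "cluster_median"),
                              profile = NULL, metacluster_labels = NULL,
                              adjust = FALSE) {
  level <- match.arg(level)
  if (level == "cell") {
    if (length(labels) != nrow(events$exprs))
      stop("every event must carry a subgroup label")
    x <- clustering_matrix(events, markers)
    grp <- labels
  } else {
    if (is.null(profile) || is.null(metacluster_labels))
      stop("cluster_median level needs a profile and metacluster labels")
    x <- profile$medians
    if (!is.null(markers)) x <- x[, markers, drop = FALSE]
    grp <- metacluster_labels
  }
  groups <- sort(unique(grp))
  if (length(groups) < 2)
    stop("at least two subgroups are required")
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  rows <- list()
  for (mk in colnames(x)) {
    for (pr in pairs) {
      a <- x[grp == pr[1], mk]
      b <- x[grp == pr[2], mk]
      tst <- mann_whitney_u(a, b, exact = NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        marker = mk, group1 = pr[1], group2 = pr[2],
        median1 = tst$medians[1], median2 = tst$medians[2],
        n1 = tst$n[1], n2 = tst$n[2],
        U = tst$U, p = tst$p, method = tst$method,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
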
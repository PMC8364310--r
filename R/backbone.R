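# Group-common binary "backbone" connectivity: per-subject streamline counts
# are normalized for whole-brain count and ROI size, averaged over subjects,
# and thresholded at a fraction of the maximum mean entry. Only strong
# connections shared across the group survive, suppressing false-positive
# streamlines from imaging noise.

#' Normalize a subject's streamline-count matrix
#'
#' Removes variation driven by individual brain size (whole-brain streamline
#' count) and by ROI size: entry (i, j) becomes
#' `counts[i,j] / total / f(size_i, size_j)` where `f` is the mean of the two
#' endpoint sizes by default. Units: streamline fraction per unit ROI size.
#'
#' @param conn_counts symmetric nonnegative ROI x ROI matrix.
#' @param total_streamlines the subject's whole-brain streamline count (> 0).
#' @param roi_sizes positive per-ROI sizes.
#' @param size_correction `"mean"` (default), `"sum"`, or `"none"`.
#' @return normalized symmetric matrix with zero diagonal.
#' @export
normalize_connectivity <- function(conn_counts, total_streamlines, roi_sizes,
                                   size_correction = c("mean", "sum", "none")) {
  size_correction <- match.arg(size_correction)
  if (!isTRUE(total_streamlines > 0))
    stop("total_streamlines must be positive")
  if (any(roi_sizes <= 0)) stop("roi_sizes must be positive")
  n <- nrow(conn_counts)
  stopifnot(length(roi_sizes) == n, ncol(conn_counts) == n)
  denom <- switch(size_correction,
                  mean = outer(roi_sizes, roi_sizes, function(a, b) (a + b) / 2),
                  sum  = outer(roi_sizes, roi_sizes, `+`),
                  none = matrix(1, n, n))
  out <- conn_counts / total_streamlines / denom
  diag(out) <- 0
  out
}

#' Element-wise mean of normalized connectivity matrices
#'
#' @param mats non-empty list of identically shaped matrices.
#' @return their element-wise arithmetic mean.
#' @export
group_mean_connectivity <- function(mats) {
  if (length(mats) == 0) stop("need at least one matrix")
  dims <- lapply(mats, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("matrices have mismatched shapes")
  Reduce(`+`, mats) / length(mats)
}

#' Binarize the group-mean connectivity into a backbone
#'
#' An edge is kept iff its group-mean value is at least
#' `threshold_fraction * max(group_mean)` (inclusive comparator, so the
#' maximal edge always survives). The threshold is relative to the maximum of
#' the group-mean matrix, making the backbone invariant to uniform rescaling
#' of all subjects' normalized matrices.
#'
#' @param group_mean symmetric nonnegative matrix with some positive entry.
#' @param threshold_fraction fraction of the maximum entry (default 0.10).
#' @return object of class `ddis_backbone`: binary `adjacency`, the
#'   `group_mean` matrix kept for provenance, `threshold_fraction`, and
#'   `edges` (data.frame of unordered kept pairs, i < j).
#' @export
binarize_backbone <- function(group_mean, threshold_fraction = 0.10) {
  if (!isTRUE(threshold_fraction > 0 && threshold_fraction < 1))
    stop("threshold_fraction must be in (0, 1)")
  m <- group_mean
  diag(m) <- 0
  if (max(m) <= 0) stop("all-zero connectivity matrix: no maximum to scale by")
  if (!isTRUE(all.equal(m, t(m))))
    stop("group_mean must be symmetric")
  adj <- (m >= threshold_fraction * max(m)) * 1L
  diag(adj) <- 0L
  idx <- which(upper.tri(adj) & adj == 1L, arr.ind = TRUE)
  structure(list(adjacency = adj,
                 group_mean = group_mean,
                 threshold_fraction = threshold_fraction,
                 edges = data.frame(i = idx[, 1], j = idx[, 2])),
            class = "ddis_backbone")
}

#' @export
print.ddis_backbone <- function(x, ...) {
  cat("ddis_backbone:", nrow(x$edges), "edges at threshold fraction",
      x$threshold_fraction, "\n")
  invisible(x)
}

#' Sweep the binarization threshold
#'
#' Recomputes the backbone at each requested fraction of the maximum
#' group-mean entry and reports edge and connected-component counts (isolated
#' ROIs count as their own components). Edge counts are non-increasing in the
#' fraction.
#'
#' @param group_mean symmetric group-mean connectivity matrix.
#' @param fractions fractions in (0, 1); default 0.04 to 0.11 in steps of 0.01.
#' @return `data.frame` with `fraction`, `n_edges`, `n_components`.
#' @export
backbone_sweep <- function(group_mean, fractions = seq(0.04, 0.11, by = 0.01)) {
  if (any(fractions <= 0 | fractions >= 1))
    stop("fractions must be in (0, 1)")
  n <- nrow(group_mean)
  rows <- lapply(fractions, function(f) {
    bb <- binarize_backbone(group_mean, f)
    g <- igraph::graph_from_adjacency_matrix(bb$adjacency, mode = "undirected")
    data.frame(fraction = f, n_edges = nrow(bb$edges),
               n_components = igraph::components(g)$no)
  })
  do.call(rbind, rows)
}

#' Build the backbone directly from a cohort
#'
#' Convenience wrapper: normalizes each subject's counts, averages across
#' subjects, and binarizes.
#'
#' @param cohort a `ddis_cohort`.
#' @param threshold_fraction see [binarize_backbone()].
#' @param size_correction see [normalize_connectivity()].
#' @return a `ddis_backbone`.
#' @export
build_backbone <- function(cohort, threshold_fraction = 0.10,
                           size_correction = "mean") {
  mats <- lapply(seq_len(n_subjects(cohort)), function(s)
    normalize_connectivity(cohort$conn_counts[, , s],
                           cohort$total_streamlines[s],
                           cohort$parcellation$size,
                           size_correction = size_correction))
  binarize_backbone(group_mean_connectivity(mats), threshold_fraction)
}

#' Write the backbone edge table
#'
#' All pairs with positive group-mean connectivity, flagged by whether they
#' survived the threshold.
#'
#' @param backbone a `ddis_backbone`.
#' @param parcellation the cohort's parcellation table.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_backbone_table <- function(backbone, parcellation, path) {
  gm <- backbone$group_mean
  idx <- which(upper.tri(gm) & gm > 0, arr.ind = TRUE)
  out <- data.frame(roi_i = parcellation$name[idx[, 1]],
                    hemi_i = parcellation$hemisphere[idx[, 1]],
                    roi_j = parcellation$name[idx[, 2]],
                    hemi_j = parcellation$hemisphere[idx[, 2]],
                    group_mean_value = gm[idx],
                    kept = backbone$adjacency[idx])
  out <- out[order(idx[, 1], idx[, 2]), , drop = FALSE]
  .write_tsv(out, path)
}
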
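# Data model and tabular I/O for the pathway-search pipeline.
#
# A cohort bundles a parcellation (the ROI universe), per-subject covariates,
# per-ROI node signals (tau SUVR, amyloid centiloid), per-subject ROI x ROI
# streamline-count matrices, and per-edge diffusion metrics. Node signals are
# stored as subject x ROI matrices and connectivity/metrics as
# ROI x ROI x subject arrays so that per-connection vectors can be sliced
# directly into the regression engine.

#' Diffusion metric channels carried by a cohort
#'
#' Fractional anisotropy (fa), mean diffusivity (md), axial (da) and radial
#' (dr) diffusivity from the tensor model, plus intracellular volume fraction
#' (icvf) and orientation dispersion (od) from the NODDI compartment model.
#' @export
DIFFUSION_METRICS <- c("fa", "md", "da", "dr", "icvf", "od")

#' Node signal channels carried by a cohort
#' @export
NODE_SIGNALS <- c("tau_suvr", "amyloid_centiloid")

#' Construct a parcellation table
#'
#' The parcellation defines the ROI universe: one row per region with its
#' hemisphere, size (voxel count or mm^3) and an off-target flag marking
#' regions whose tau-PET signal is known to reflect off-target tracer binding
#' (basal ganglia) rather than tau tangles; such regions participate in the
#' analysis unchanged and act as negative controls.
#'
#' @param name character vector of ROI names.
#' @param hemisphere character vector, `"left"` or `"right"`.
#' @param size positive numeric vector of ROI sizes.
#' @param off_target logical vector.
#' @return A `data.frame` with columns `roi_id` (1-based, contiguous),
#'   `name`, `hemisphere`, `size`, `off_target`.
#' @export
parcellation <- function(name, hemisphere, size, off_target = FALSE) {
  n <- length(name)
  hemisphere <- rep_len(as.character(hemisphere), n)
  size <- rep_len(as.numeric(size), n)
  off_target <- rep_len(as.logical(off_target), n)
  if (!all(hemisphere %in% c("left", "right")))
    stop("hemisphere must be 'left' or 'right'")
  if (any(!is.finite(size)) || any(size <= 0))
    stop("ROI sizes must be positive and finite")
  key <- paste(name, hemisphere)
  if (anyDuplicated(key))
    stop("duplicate ROI identity (name, hemisphere): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  data.frame(roi_id = seq_len(n), name = as.character(name),
             hemisphere = hemisphere, size = size, off_target = off_target,
             stringsAsFactors = FALSE)
}

#' Construct a cohort object
#'
#' @param parcellation parcellation table from [parcellation()].
#' @param subjects `data.frame` with `subject_id`, `age`, `sex` (0/1), `group`
#'   (`CN`/`SCD`/`MCI`; carried as metadata only, never used by the search).
#' @param node_signal named list of subject x ROI matrices (at least
#'   `tau_suvr`).
#' @param conn_counts ROI x ROI x subject array of streamline counts
#'   (symmetric slices, zero diagonal, nonnegative).
#' @param edge_metric named list of ROI x ROI x subject arrays, one per
#'   diffusion metric; `NA` where a metric is not defined (unconnected pairs).
#' @return An object of class `ddis_cohort`. Whole-brain streamline totals are
#'   derived as the sum of each subject's upper-triangle counts.
#' @seealso [validate_cohort()], [load_cohort()], [write_cohort()]
#' @export
new_cohort <- function(parcellation, subjects, node_signal, conn_counts,
                       edge_metric) {
  n_roi <- nrow(parcellation)
  n_sub <- nrow(subjects)
  stopifnot(is.list(node_signal), is.list(edge_metric))
  if (!identical(dim(conn_counts), c(n_roi, n_roi, n_sub)))
    stop("conn_counts must be an ROI x ROI x subject array")
  total <- vapply(seq_len(n_sub), function(s) {
    m <- conn_counts[, , s, drop = FALSE][, , 1]
    sum(m[upper.tri(m)])
  }, numeric(1))
  structure(list(parcellation = parcellation,
                 subjects = subjects,
                 node_signal = node_signal,
                 conn_counts = conn_counts,
                 total_streamlines = total,
                 edge_metric = edge_metric),
            class = "ddis_cohort")
}

#' @export
print.ddis_cohort <- function(x, ...) {
  cat("ddis_cohort:", nrow(x$subjects), "subjects,",
      nrow(x$parcellation), "ROIs,",
      sum(x$parcellation$hemisphere == "left"), "left /",
      sum(x$parcellation$hemisphere == "right"), "right\n")
  cat("  node signals:", paste(names(x$node_signal), collapse = ", "), "\n")
  cat("  edge metrics:", paste(names(x$edge_metric), collapse = ", "), "\n")
  invisible(x)
}

#' Number of subjects / ROIs
#' @param cohort a `ddis_cohort`.
#' @return integer count.
#' @export
n_subjects <- function(cohort) nrow(cohort$subjects)

#' @rdname n_subjects
#' @export
n_rois <- function(cohort) nrow(cohort$parcellation)

#' Subset a cohort by subject index
#'
#' Used by the bootstrap: `idx` may contain repeats (sampling with
#' replacement); repeated subjects are carried as independent observations.
#'
#' @param cohort a `ddis_cohort`.
#' @param idx integer subject indices.
#' @return a `ddis_cohort` with `length(idx)` subjects.
#' @export
cohort_subset <- function(cohort, idx) {
  idx <- as.integer(idx)
  stopifnot(all(idx >= 1), all(idx <= n_subjects(cohort)))
  new_cohort(cohort$parcellation,
             cohort$subjects[idx, , drop = FALSE],
             lapply(cohort$node_signal, function(m) m[idx, , drop = FALSE]),
             cohort$conn_counts[, , idx, drop = FALSE],
             lapply(cohort$edge_metric, function(a) a[, , idx, drop = FALSE]))
}

#' Validate a cohort against its structural invariants
#'
#' Checks every invariant of the data model and reports all violations rather
#' than stopping at the first: symmetry, zero diagonal and nonnegativity of
#' streamline counts; node-signal completeness and dimensions; diffusion
#' metrics defined only on connected pairs; positive ROI sizes; sample size
#' large enough for the covariate-adjusted regressions.
#'
#' @param cohort a `ddis_cohort`.
#' @return character vector of violation messages; `character(0)` if valid.
#' @export
validate_cohort <- function(cohort) {
  v <- character(0)
  p <- cohort$parcellation
  if (any(p$size <= 0)) v <- c(v, "parcellation: non-positive ROI size")
  if (!identical(p$roi_id, seq_len(nrow(p))))
    v <- c(v, "parcellation: roi_id not contiguous from 1")
  if (!all(p$hemisphere %in% c("left", "right")))
    v <- c(v, "parcellation: hemisphere must be left/right")
  n_roi <- nrow(p); n_sub <- nrow(cohort$subjects)
  if (n_sub < 5)
    v <- c(v, sprintf("cohort: %d subjects; need at least covariates + 3", n_sub))
  ids <- cohort$subjects$subject_id
  for (sig in names(cohort$node_signal)) {
    m <- cohort$node_signal[[sig]]
    if (!identical(dim(m), c(n_sub, n_roi)))
      v <- c(v, sprintf("node_signal '%s': wrong dimensions", sig))
    else if (anyNA(m))
      v <- c(v, sprintf("node_signal '%s': missing values (node signals must be complete)", sig))
  }
  for (s in seq_len(n_sub)) {
    cc <- cohort$conn_counts[, , s]
    if (any(cc < 0, na.rm = TRUE))
      v <- c(v, sprintf("subject %s: negative streamline count", ids[s]))
    if (any(diag(cc) != 0))
      v <- c(v, sprintf("subject %s: nonzero diagonal (self-connection)", ids[s]))
    asym <- which(cc != t(cc), arr.ind = TRUE)
    if (nrow(asym) > 0)
      v <- c(v, sprintf("subject %s: asymmetric conn_counts at (%d,%d)",
                        ids[s], asym[1, 1], asym[1, 2]))
    for (met in names(cohort$edge_metric)) {
      em <- cohort$edge_metric[[met]][, , s]
      bad <- !is.na(em) & cc == 0
      diag(bad) <- FALSE
      if (any(bad))
        v <- c(v, sprintf("subject %s: metric '%s' defined on unconnected pair",
                          ids[s], met))
    }
  }
  v
}

# canonical unordered pair: i < j
.pair_canon <- function(i, j) {
  cbind(pmin(i, j), pmax(i, j))
}

.read_tsv <- function(path, required) {
  if (!file.exists(path)) stop("input file not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  miss <- setdiff(required, names(d))
  if (length(miss) > 0)
    stop("file ", basename(path), " missing columns: ",
         paste(miss, collapse = ", "))
  d
}

#' Load a cohort from its four tab-separated input tables
#'
#' ROI identity is the pair (name, hemisphere); integer ids are assigned from
#' the row order of the parcellation table. The edge table is long format (one
#' row per subject and connected ROI pair) and is mirrored into symmetric
#' matrices on load. Empty metric fields become `NA` ("missing"; handled
#' downstream by listwise deletion per connection).
#'
#' @param subjects_table,nodes_table,edges_table,parcellation_table file paths.
#' @return a validated `ddis_cohort`.
#' @export
load_cohort <- function(subjects_table, nodes_table, edges_table,
                        parcellation_table) {
  parc_raw <- .read_tsv(parcellation_table,
                        c("roi_name", "hemisphere", "size", "off_target"))
  parc <- parcellation(parc_raw$roi_name, parc_raw$hemisphere,
                       parc_raw$size, as.logical(parc_raw$off_target))
  key <- paste(parc$name, parc$hemisphere)
  roi_of <- stats::setNames(parc$roi_id, key)
  n_roi <- nrow(parc)

  subj <- .read_tsv(subjects_table, c("subject_id", "age", "sex", "group"))
  subj$subject_id <- as.character(subj$subject_id)
  if (anyDuplicated(subj$subject_id))
    stop("duplicate subject_id in subjects table")
  n_sub <- nrow(subj)
  sub_of <- stats::setNames(seq_len(n_sub), subj$subject_id)

  nodes <- .read_tsv(nodes_table, c("subject_id", "roi_name", "hemisphere",
                                    "tau_suvr", "amyloid_centiloid"))
  nkey <- paste(nodes$roi_name, nodes$hemisphere)
  if (!all(nkey %in% names(roi_of)))
    stop("nodes table references ROIs absent from the parcellation: ",
         paste(unique(nkey[!nkey %in% names(roi_of)]), collapse = ", "))
  if (!all(nodes$subject_id %in% names(sub_of)))
    stop("nodes table references unknown subjects")
  if (anyDuplicated(paste(nodes$subject_id, nkey)))
    stop("duplicate (subject, roi) rows in nodes table")
  node_signal <- lapply(c(tau_suvr = "tau_suvr",
                          amyloid_centiloid = "amyloid_centiloid"),
                        function(col) {
    m <- matrix(NA_real_, n_sub, n_roi,
                dimnames = list(subj$subject_id, key))
    m[cbind(sub_of[nodes$subject_id], roi_of[nkey])] <- nodes[[col]]
    gaps <- which(is.na(m), arr.ind = TRUE)
    if (nrow(gaps) > 0)
      stop("nodes table incomplete for '", col, "': missing (subject, roi) pairs: ",
           paste(utils::head(paste0(subj$subject_id[gaps[, 1]], "/",
                                    key[gaps[, 2]]), 5), collapse = ", "),
           if (nrow(gaps) > 5) sprintf(" ... and %d more", nrow(gaps) - 5) else "")
    m
  })

  edges <- .read_tsv(edges_table, c("subject_id", "roi_i", "hemi_i", "roi_j",
                                    "hemi_j", "streamline_count",
                                    DIFFUSION_METRICS))
  ikey <- paste(edges$roi_i, edges$hemi_i)
  jkey <- paste(edges$roi_j, edges$hemi_j)
  if (!all(c(ikey, jkey) %in% names(roi_of)))
    stop("edges table references ROIs absent from the parcellation")
  if (!all(edges$subject_id %in% names(sub_of)))
    stop("edges table references unknown subjects")
  ii <- roi_of[ikey]; jj <- roi_of[jkey]
  if (any(ii == jj))
    stop("edges table contains a self-connection (roi_i == roi_j): ",
         ikey[which(ii == jj)[1]])
  pc <- .pair_canon(ii, jj)
  if (anyDuplicated(paste(edges$subject_id, pc[, 1], pc[, 2])))
    stop("duplicate (subject, roi_i, roi_j) rows in edges table")
  if (any(edges$streamline_count < 0))
    stop("negative streamline_count in edges table")

  ss <- sub_of[edges$subject_id]
  conn <- array(0, dim = c(n_roi, n_roi, n_sub))
  conn[cbind(pc[, 1], pc[, 2], ss)] <- edges$streamline_count
  conn[cbind(pc[, 2], pc[, 1], ss)] <- edges$streamline_count
  edge_metric <- lapply(stats::setNames(DIFFUSION_METRICS, DIFFUSION_METRICS),
                        function(met) {
    a <- array(NA_real_, dim = c(n_roi, n_roi, n_sub))
    a[cbind(pc[, 1], pc[, 2], ss)] <- edges[[met]]
    a[cbind(pc[, 2], pc[, 1], ss)] <- edges[[met]]
    a
  })

  cohort <- new_cohort(parc, subj, node_signal, conn, edge_metric)
  viol <- validate_cohort(cohort)
  if (length(viol) > 0)
    stop("loaded cohort fails validation:\n  ", paste(viol, collapse = "\n  "))
  cohort
}

.write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write a cohort to the four tab-separated input tables
#'
#' Inverse of [load_cohort()]: `load_cohort` on the written files reproduces
#' the cohort (round-trip identity, up to numeric printing precision).
#'
#' @param cohort a `ddis_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the four file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- cohort$parcellation
  .write_tsv(data.frame(roi_name = p$name, hemisphere = p$hemisphere,
                        size = p$size, off_target = p$off_target),
             file.path(dir, "parcellation.tsv"))
  .write_tsv(cohort$subjects[, c("subject_id", "age", "sex", "group")],
             file.path(dir, "subjects.tsv"))

  n_sub <- n_subjects(cohort); n_roi <- n_rois(cohort)
  nodes <- data.frame(
    subject_id = rep(cohort$subjects$subject_id, each = n_roi),
    roi_name = rep(p$name, n_sub),
    hemisphere = rep(p$hemisphere, n_sub),
    tau_suvr = as.vector(t(cohort$node_signal$tau_suvr)),
    amyloid_centiloid = as.vector(t(cohort$node_signal$amyloid_centiloid)))
  .write_tsv(nodes, file.path(dir, "nodes.tsv"))

  rows <- list()
  ut <- upper.tri(matrix(0, n_roi, n_roi))
  for (s in seq_len(n_sub)) {
    cc <- cohort$conn_counts[, , s]
    idx <- which(ut & cc > 0, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    d <- data.frame(subject_id = cohort$subjects$subject_id[s],
                    roi_i = p$name[idx[, 1]], hemi_i = p$hemisphere[idx[, 1]],
                    roi_j = p$name[idx[, 2]], hemi_j = p$hemisphere[idx[, 2]],
                    streamline_count = cc[idx])
    for (met in DIFFUSION_METRICS)
      d[[met]] <- cohort$edge_metric[[met]][, , s][idx]
    rows[[length(rows) + 1L]] <- d
  }
  edges <- if (length(rows) > 0) do.call(rbind, rows) else
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = 6 + length(DIFFUSION_METRICS))),
                    c("subject_id", "roi_i", "hemi_i", "roi_j", "hemi_j",
                      "streamline_count", DIFFUSION_METRICS))
  .write_tsv(edges, file.path(dir, "edges.tsv"))
  invisible(file.path(dir, c("parcellation.tsv", "subjects.tsv",
                             "nodes.tsv", "edges.tsv")))
}

#' Write the discovered pathways as a tab-separated table
#'
#' One row per accepted pathway, ordered deterministically by iteration, then
#' up-ROI id, then down-ROI id. Columns carry both regressions' coefficient,
#' p-value and incremental adjusted R^2 (`r2_diff`: variance explained beyond
#' the age+sex covariate model); `r2_diff` of the edge-to-destination model is
#' the headline value.
#'
#' @param pattern a `ddis_pattern` from [run_ddis()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_pathway_table <- function(pattern, path) {
  pw <- pattern$pathways
  cols <- c("hemisphere", "up_roi", "down_roi", "metric", "iteration",
            "coef_up", "p_up", "sign_up", "r2_diff_up",
            "coef_down", "p_down", "sign_down", "r2_diff", "n_used")
  if (nrow(pw) == 0) {
    out <- stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(cols))),
                           cols)
  } else {
    ord <- order(pw$iteration, pw$up_id, pw$down_id)
    pw <- pw[ord, , drop = FALSE]
    out <- data.frame(hemisphere = pw$hemisphere, up_roi = pw$up_name,
                      down_roi = pw$down_name, metric = pw$metric,
                      iteration = pw$iteration,
                      coef_up = pw$coef_up, p_up = pw$p_up,
                      sign_up = pw$sign_up, r2_diff_up = pw$r2_diff_up,
                      coef_down = pw$coef_down, p_down = pw$p_down,
                      sign_down = pw$sign_down, r2_diff = pw$r2_diff,
                      n_used = pw$n_used)
  }
  .write_tsv(out, path)
}
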
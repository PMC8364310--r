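# Regional positivity calling, prevalence, and seed selection.
#
# Tau positivity follows the conventional SUVR cutoff (1.23 for flortaucipir);
# prevalence is the fraction of subjects positive in an ROI, and the search is
# seeded from ROIs whose prevalence exceeds a threshold (default 80%),
# hemisphere by hemisphere.

#' Call per-subject, per-ROI signal positivity
#'
#' @param values subject x ROI numeric matrix of a node signal (e.g. tau SUVR).
#' @param cutoff positivity cutoff in signal units (default 1.23, the
#'   flortaucipir tau SUVR cutoff).
#' @param comparator `"gt"` (strict `>`, default) or `"ge"` (`>=`). The strict
#'   comparator is the default; the boundary has measure zero for a continuous
#'   signal, but the choice is exposed.
#' @return logical subject x ROI matrix.
#' @export
call_positivity <- function(values, cutoff = 1.23, comparator = c("gt", "ge")) {
  comparator <- match.arg(comparator)
  if (!is.finite(cutoff)) stop("cutoff must be finite")
  if (anyNA(values))
    stop("missing node-signal values: node signals must be complete")
  if (comparator == "gt") values > cutoff else values >= cutoff
}

#' Per-ROI positivity prevalence
#'
#' The fraction of subjects positive in each ROI. Raising the cutoff can never
#' raise any ROI's prevalence.
#'
#' @param positivity logical subject x ROI matrix from [call_positivity()].
#' @param signal optional signal name recorded for provenance.
#' @param cutoff optional cutoff recorded for provenance.
#' @return object of class `ddis_prevalence`: numeric per-ROI vector in
#'   \[0, 1\] with attributes `signal`, `cutoff`, `n_subjects`.
#' @export
compute_prevalence <- function(positivity, signal = NA_character_,
                               cutoff = NA_real_) {
  if (nrow(positivity) < 1) stop("need at least one subject")
  prev <- colMeans(positivity)
  structure(prev, signal = signal, cutoff = cutoff,
            n_subjects = nrow(positivity), class = "ddis_prevalence")
}

#' @export
print.ddis_prevalence <- function(x, ...) {
  cat("ddis_prevalence over", attr(x, "n_subjects"), "subjects (signal:",
      attr(x, "signal"), ", cutoff:", attr(x, "cutoff"), ")\n")
  print(unclass(x)[order(-unclass(x))][seq_len(min(10, length(x)))])
  invisible(x)
}

#' Select seed ROIs for the iterative search
#'
#' ROIs whose positivity prevalence strictly exceeds `threshold` become
#' seeds. Left and right ROIs are selected independently from their own
#' prevalence values (each ROI belongs to one hemisphere). An explicit
#' `seed_list` bypasses the prevalence rule, e.g. for the amyloid variant
#' where seeds are given by name.
#'
#' @param prevalence per-ROI prevalence (vector or `ddis_prevalence`), aligned
#'   with `parcellation` rows.
#' @param parcellation the parcellation table.
#' @param threshold prevalence threshold (default 0.80).
#' @param seed_list optional explicit seeds: integer roi_ids, or a
#'   `data.frame` with `name` and `hemisphere` columns, or a character vector
#'   of ROI names (matched in both hemispheres).
#' @return object of class `ddis_seeds`: sorted integer `roi_ids`, plus
#'   `threshold` and `provenance`.
#' @export
select_seeds <- function(prevalence, parcellation, threshold = 0.80,
                         seed_list = NULL) {
  if (is.null(seed_list)) {
    if (!isTRUE(threshold > 0 && threshold < 1))
      stop("threshold must be in (0, 1)")
    stopifnot(length(prevalence) == nrow(parcellation))
    ids <- parcellation$roi_id[as.numeric(prevalence) > threshold]
    prov <- "prevalence"
  } else {
    if (is.data.frame(seed_list)) {
      key <- paste(seed_list$name, seed_list$hemisphere)
      all_key <- paste(parcellation$name, parcellation$hemisphere)
      if (!all(key %in% all_key))
        stop("seed_list names absent from parcellation: ",
             paste(setdiff(key, all_key), collapse = ", "))
      ids <- parcellation$roi_id[match(key, all_key)]
    } else if (is.character(seed_list)) {
      if (!all(seed_list %in% parcellation$name))
        stop("seed_list names absent from parcellation: ",
             paste(setdiff(seed_list, parcellation$name), collapse = ", "))
      ids <- parcellation$roi_id[parcellation$name %in% seed_list]
    } else {
      ids <- as.integer(seed_list)
      if (!all(ids %in% parcellation$roi_id))
        stop("seed_list ids absent from parcellation")
    }
    prov <- "explicit"
  }
  if (length(ids) == 0)
    warning("empty seed set: the search will return an empty pattern")
  structure(list(roi_ids = sort(unique(ids)), threshold = threshold,
                 provenance = prov),
            class = "ddis_seeds")
}

#' @export
print.ddis_seeds <- function(x, ...) {
  cat("ddis_seeds:", length(x$roi_ids), "seed ROIs (", x$provenance, ")\n")
  invisible(x)
}

#' Write the per-ROI prevalence table
#'
#' @param prevalence a `ddis_prevalence` (aligned with `parcellation` rows).
#' @param parcellation the parcellation table.
#' @param seeds a `ddis_seeds` (for the `is_seed` flag).
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_prevalence_table <- function(prevalence, parcellation, seeds, path) {
  out <- data.frame(roi_name = parcellation$name,
                    hemisphere = parcellation$hemisphere,
                    prevalence = as.numeric(prevalence),
                    is_seed = as.integer(parcellation$roi_id %in% seeds$roi_ids))
  .write_tsv(out, path)
}
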
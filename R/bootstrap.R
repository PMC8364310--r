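# Bootstrap stability of the discovered association pattern.
#
# Subjects are resampled with replacement at fixed sample size; for each
# replicate the seed-selection stage (positivity -> prevalence -> seeds) and
# the search are re-run, and each discovered pathway identity receives one
# vote. The backbone is, by default, the one-time construction from the full
# sample; a flag enables per-replicate rebuilds.

.pathway_keys <- function(pathways, directed = TRUE) {
  if (nrow(pathways) == 0) return(character(0))
  if (directed) {
    paste(pathways$hemisphere, pathways$up_name, pathways$down_name,
          pathways$metric, sep = "|")
  } else {
    a <- pmin(pathways$up_name, pathways$down_name)
    b <- pmax(pathways$up_name, pathways$down_name)
    paste(pathways$hemisphere, a, b, pathways$metric, sep = "|")
  }
}

.stability_from_votes <- function(keys, n_boot, per_replicate_counts,
                                  rng_seed = NA_integer_) {
  tab <- if (length(keys) > 0) table(keys) else
    table(factor(character(0)))
  parts <- if (length(tab) > 0)
    do.call(rbind, strsplit(names(tab), "|", fixed = TRUE)) else
    matrix(character(0), 0, 4)
  out <- data.frame(hemisphere = parts[, 1], up_roi = parts[, 2],
                    down_roi = parts[, 3], metric = parts[, 4],
                    votes = as.integer(tab),
                    frequency = as.integer(tab) / n_boot,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, out$hemisphere, out$up_roi, out$down_roi),
             , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_boot = n_boot, rng_seed = rng_seed,
            per_replicate_counts = per_replicate_counts,
            class = c("ddis_stability", "data.frame"))
}

#' Combine patterns from resamples into a voting summary
#'
#' Each pattern casts one vote per pathway identity. Identity is
#' (hemisphere, up ROI, down ROI, metric), directed up -> down by default;
#' iteration labels are ignored (they vary across resamples). Within one
#' pattern each connection is tested at most once, so per-replicate votes are
#' 0 or 1.
#'
#' @param patterns non-empty list of `ddis_pattern` objects.
#' @param directed treat up -> down and down -> up as distinct identities
#'   (default `TRUE`); `FALSE` aggregates undirected for display.
#' @return a `ddis_stability` data.frame: `hemisphere`, `up_roi`, `down_roi`,
#'   `metric`, `votes`, `frequency`, with attributes `n_boot` and
#'   `per_replicate_counts`.
#' @export
vote_summary <- function(patterns, directed = TRUE) {
  if (length(patterns) == 0) stop("need at least one pattern")
  keys <- unlist(lapply(patterns, function(p)
    unique(.pathway_keys(p$pathways, directed))))
  counts <- vapply(patterns, function(p) nrow(p$pathways), integer(1))
  .stability_from_votes(keys, length(patterns), counts)
}

#' Bootstrap the whole search pipeline
#'
#' Each of `n_boot` replicates draws `n` subjects with replacement (`n` = the
#' cohort size), recomputes positivity, prevalence and seeds, re-runs
#' [run_ddis()], and casts one vote per discovered pathway identity.
#' Replicates with an empty seed set contribute zero votes but still count in
#' the denominator. Replicate `r` uses RNG seed `rng_seed + r`, so the result
#' is a pure function of (cohort, config, n_boot, rng_seed) and independent
#' of execution order.
#'
#' @param cohort a `ddis_cohort`.
#' @param config a `ddis_config`.
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param rng_seed integer seed.
#' @param resample_backbone rebuild the thresholded backbone inside each
#'   replicate (default `FALSE`: the backbone is a one-time construction from
#'   the full sample).
#' @param directed see [vote_summary()].
#' @return a `ddis_stability` data.frame (see [vote_summary()]).
#' @export
bootstrap_ddis <- function(cohort, config = ddis_config(), n_boot = 1000,
                           rng_seed = 1L, resample_backbone = FALSE,
                           directed = TRUE) {
  stopifnot(n_boot >= 1)
  n <- n_subjects(cohort)
  full_backbone <- if (!resample_backbone)
    build_backbone(cohort, config$backbone_fraction, config$size_correction)
  keys <- character(0)
  counts <- integer(n_boot)
  for (r in seq_len(n_boot)) {
    set.seed(rng_seed + r)
    idx <- sample.int(n, n, replace = TRUE)
    boot <- cohort_subset(cohort, idx)
    bb <- if (resample_backbone)
      build_backbone(boot, config$backbone_fraction, config$size_correction)
    else full_backbone
    pos <- call_positivity(boot$node_signal[[config$signal]],
                           config$positivity_cutoff,
                           config$positivity_comparator)
    prev <- compute_prevalence(pos, config$signal, config$positivity_cutoff)
    seeds <- suppressWarnings(
      select_seeds(prev, boot$parcellation, config$seed_prevalence,
                   config$seed_list))
    if (length(seeds$roi_ids) == 0) next
    pat <- suppressWarnings(run_ddis(boot, bb, seeds, config))
    counts[r] <- nrow(pat$pathways)
    keys <- c(keys, unique(.pathway_keys(pat$pathways, directed)))
  }
  .stability_from_votes(keys, n_boot, counts, rng_seed)
}

#' Filter a stability map by voting frequency
#'
#' Retains pathways whose bootstrap frequency is at least `min_frequency`
#' (default 0.30, the display cutoff).
#'
#' @param map a `ddis_stability`.
#' @param min_frequency frequency cutoff in \[0, 1\].
#' @return the filtered `ddis_stability`.
#' @export
filter_stability <- function(map, min_frequency = 0.30) {
  stopifnot(min_frequency >= 0, min_frequency <= 1)
  out <- map[map$frequency >= min_frequency, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("n_boot", "rng_seed", "per_replicate_counts")] <-
    attributes(map)[c("n_boot", "rng_seed", "per_replicate_counts")]
  class(out) <- class(map)
  out
}

#' Write a stability map as a tab-separated table
#'
#' @param map a `ddis_stability`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_stability_table <- function(map, path) {
  .write_tsv(as.data.frame(map)[, c("hemisphere", "up_roi", "down_roi",
                                    "metric", "votes", "frequency")], path)
}
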
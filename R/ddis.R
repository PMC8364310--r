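# The iterative dual-regression pathway search.
#
# From a set of seed ROIs, every backbone connection leaving the seed set is
# tested with two covariate-adjusted linear models:
#   (a) metric_edge ~ tau_up   + age + sex   (seed tau -> edge diffusion)
#   (b) tau_down    ~ metric_edge + age + sex (edge diffusion -> destination tau)
# A connection is an association pathway iff both models are significant at
# alpha. Accepted destinations join the seed set and the search repeats until
# an iteration finds nothing. Hemispheres are searched independently by
# default; connections among current seeds are never tested (no circulation),
# and a connection is tested at most once per direction (identical data would
# give an identical p-value).

#' Configuration for a pathway-search run
#'
#' @param metric diffusion metric channel tested along edges (one of
#'   [DIFFUSION_METRICS]; default `"md"`).
#' @param signal node signal regressed at both ends (default `"tau_suvr"`;
#'   `"amyloid_centiloid"` for the amyloid variant).
#' @param alpha per-model significance level (default 0.05).
#' @param positivity_cutoff signal-units cutoff for positivity (default 1.23,
#'   the tau SUVR cutoff; set e.g. 20 for centiloid).
#' @param positivity_comparator `"gt"` or `"ge"` (see [call_positivity()]).
#' @param seed_prevalence prevalence threshold for seed selection
#'   (default 0.80).
#' @param seed_list optional explicit seed list overriding the prevalence rule
#'   (see [select_seeds()]).
#' @param backbone_fraction backbone binarization threshold (default 0.10).
#' @param size_correction ROI-size correction in the normalization
#'   (`"mean"`, `"sum"`, `"none"`).
#' @param covariates covariate columns of the subjects table entered in every
#'   model (default `c("age", "sex")`).
#' @param hemisphere_mode `"separate"` (default; drops inter-hemispheric
#'   backbone edges from the candidate set and searches each hemisphere
#'   independently) or `"pooled"`.
#' @param min_n minimum subjects after listwise deletion for a model fit.
#' @param p_adjust optional per-iteration multiple-testing correction method
#'   (any [stats::p.adjust] method); `"none"` by default — the bootstrap,
#'   not a correction inside the search, serves as the stability check.
#' @param rng_seed integer seed recorded for provenance (the search itself is
#'   deterministic; randomness enters only in simulation and bootstrap).
#' @return a validated list of class `ddis_config`.
#' @export
ddis_config <- function(metric = "md", signal = "tau_suvr", alpha = 0.05,
                        positivity_cutoff = 1.23,
                        positivity_comparator = "gt",
                        seed_prevalence = 0.80, seed_list = NULL,
                        backbone_fraction = 0.10, size_correction = "mean",
                        covariates = c("age", "sex"),
                        hemisphere_mode = c("separate", "pooled"),
                        min_n = 5, p_adjust = "none", rng_seed = 1L) {
  hemisphere_mode <- match.arg(hemisphere_mode)
  if (!metric %in% DIFFUSION_METRICS)
    stop("metric must be one of: ", paste(DIFFUSION_METRICS, collapse = ", "))
  if (!isTRUE(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (!isTRUE(seed_prevalence > 0 && seed_prevalence < 1))
    stop("seed_prevalence must be in (0, 1)")
  if (!isTRUE(backbone_fraction > 0 && backbone_fraction < 1))
    stop("backbone_fraction must be in (0, 1)")
  structure(list(metric = metric, signal = signal, alpha = alpha,
                 positivity_cutoff = positivity_cutoff,
                 positivity_comparator = positivity_comparator,
                 seed_prevalence = seed_prevalence, seed_list = seed_list,
                 backbone_fraction = backbone_fraction,
                 size_correction = size_correction,
                 covariates = covariates, hemisphere_mode = hemisphere_mode,
                 min_n = min_n, p_adjust = p_adjust,
                 rng_seed = as.integer(rng_seed)),
            class = "ddis_config")
}

#' Covariate-adjusted linear association test
#'
#' Ordinary least squares with intercept: `response ~ predictor + covariates`,
#' with a two-sided t-test on the predictor's coefficient. The incremental
#' adjusted R^2 (`r2_diff`) is the full model's adjusted R^2 minus that of
#' the covariates-only model fitted on the same subjects (after listwise
#' deletion).
#'
#' @param response,predictor per-subject numeric vectors.
#' @param covariates per-subject `data.frame` (or matrix) of covariates;
#'   may have zero columns.
#' @param min_n minimum subjects after listwise deletion (default 5).
#' @return list of class `ddis_glm`: `coefficient`, `se`, `t`, `p`, `n_used`,
#'   `adj_r2_full`, `adj_r2_covariates_only`, `r2_diff`, `sign`.
#' @export
fit_glm <- function(response, predictor, covariates = NULL, min_n = 5) {
  covariates <- if (is.null(covariates))
    data.frame(row.names = seq_along(response))
  else as.data.frame(covariates)
  keep <- if (ncol(covariates) == 0)
    stats::complete.cases(response, predictor)
  else stats::complete.cases(response, predictor, covariates)
  y <- response[keep]; x <- predictor[keep]
  cv <- covariates[keep, , drop = FALSE]
  n <- length(y)
  if (n < max(min_n, ncol(cv) + 3))
    stop(sprintf("too few complete observations (%d) for the model", n))
  if (stats::sd(x) == 0) stop("degenerate predictor (constant)")
  dat <- cbind(data.frame(.y = y, .x = x), cv)
  full <- stats::lm(.y ~ ., data = dat)
  if (full$rank < ncol(dat))
    stop("rank-deficient design")
  sm <- summary(full)
  co <- sm$coefficients[".x", ]
  red <- stats::lm(.y ~ ., data = dat[, -2, drop = FALSE])
  adj_red <- summary(red)$adj.r.squared
  structure(list(coefficient = unname(co[1]), se = unname(co[2]),
                 t = unname(co[3]), p = unname(co[4]), n_used = n,
                 adj_r2_full = sm$adj.r.squared,
                 adj_r2_covariates_only = adj_red,
                 r2_diff = sm$adj.r.squared - adj_red,
                 sign = if (co[1] >= 0) "+" else "-"),
            class = "ddis_glm")
}

#' @export
print.ddis_glm <- function(x, ...) {
  cat(sprintf("ddis_glm: coef %.4g (se %.3g), t = %.3g, p = %.3g, n = %d, r2_diff = %.3g\n",
              x$coefficient, x$se, x$t, x$p, x$n_used, x$r2_diff))
  invisible(x)
}

.cov_frame <- function(cohort, covariates) {
  cohort$subjects[, covariates, drop = FALSE]
}

#' Test one backbone connection for a dual association
#'
#' Model (a): edge diffusion metric on seed tau; model (b): destination tau on
#' edge diffusion metric, both adjusted for the configured covariates. The
#' connection is accepted iff both p-values are below `alpha`. Degenerate fits
#' (too few complete observations, constant predictor, rank deficiency) abort
#' this connection only, returning `accepted = FALSE` with the reason.
#'
#' @param cohort a `ddis_cohort`.
#' @param up_roi,down_roi roi_ids of the seed and destination end.
#' @param metric diffusion metric name.
#' @param signal node signal name.
#' @param alpha significance level.
#' @param covariates covariate column names.
#' @param min_n minimum complete observations per fit.
#' @return list: `test_up`, `test_down` (`ddis_glm` or `NULL`), `accepted`,
#'   `reason` (`NA` unless a fit failed).
#' @export
test_connection <- function(cohort, up_roi, down_roi, metric,
                            signal = "tau_suvr", alpha = 0.05,
                            covariates = c("age", "sex"), min_n = 5) {
  tau_up <- cohort$node_signal[[signal]][, up_roi]
  tau_down <- cohort$node_signal[[signal]][, down_roi]
  dif <- cohort$edge_metric[[metric]][up_roi, down_roi, ]
  cv <- .cov_frame(cohort, covariates)
  res <- tryCatch({
    a <- fit_glm(dif, tau_up, cv, min_n = min_n)
    b <- fit_glm(tau_down, dif, cv, min_n = min_n)
    list(test_up = a, test_down = b,
         accepted = isTRUE(a$p < alpha) && isTRUE(b$p < alpha),
         reason = NA_character_)
  }, error = function(e) {
    list(test_up = NULL, test_down = NULL, accepted = FALSE,
         reason = conditionMessage(e))
  })
  res
}

# directed candidate connections leaving the seed set, deterministic order
.candidates <- function(backbone, seeds, parcellation, hemisphere_mode,
                        tested_keys) {
  e <- backbone$edges
  cand <- rbind(data.frame(up = e$i, down = e$j),
                data.frame(up = e$j, down = e$i))
  cand <- cand[cand$up %in% seeds & !(cand$down %in% seeds), , drop = FALSE]
  if (hemisphere_mode == "separate") {
    h <- parcellation$hemisphere
    cand <- cand[h[cand$up] == h[cand$down], , drop = FALSE]
  }
  key <- paste(cand$up, cand$down, sep = "->")
  cand <- cand[!key %in% tested_keys, , drop = FALSE]
  cand[order(cand$up, cand$down), , drop = FALSE]
}

#' One iteration of the pathway search
#'
#' Enumerates untested backbone connections whose up endpoint is a current
#' seed and whose down endpoint is not (seed-seed connections are excluded;
#' inter-hemispheric edges are excluded under `hemisphere_mode = "separate"`),
#' tests each once, and returns the accepted pathways together with the
#' deduplicated set of newly seeded destination ROIs.
#'
#' @param cohort a `ddis_cohort`.
#' @param backbone a `ddis_backbone`.
#' @param current_seeds integer roi_ids of the current seed set.
#' @param tested_keys character keys `"up->down"` of connections already
#'   tested in this run (never re-tested).
#' @param config a `ddis_config`.
#' @return list: `pathways` (data.frame rows for accepted connections),
#'   `tested` (log rows for every candidate), `new_seeds` (integer ids).
#' @export
run_iteration <- function(cohort, backbone, current_seeds, tested_keys,
                          config) {
  parc <- cohort$parcellation
  cand <- .candidates(backbone, current_seeds, parc,
                      config$hemisphere_mode, tested_keys)
  empty <- list(pathways = .empty_pathways(), tested = .empty_tested(),
                new_seeds = integer(0))
  if (nrow(cand) == 0) return(empty)
  tests <- lapply(seq_len(nrow(cand)), function(k)
    test_connection(cohort, cand$up[k], cand$down[k], config$metric,
                    config$signal, config$alpha, config$covariates,
                    config$min_n))
  p_a <- vapply(tests, function(t) if (is.null(t$test_up)) NA_real_ else t$test_up$p, 0)
  p_b <- vapply(tests, function(t) if (is.null(t$test_down)) NA_real_ else t$test_down$p, 0)
  accepted <- vapply(tests, `[[`, logical(1), "accepted")
  if (config$p_adjust != "none") {
    ok <- !is.na(p_a)
    pa <- stats::p.adjust(p_a[ok], method = config$p_adjust)
    pb <- stats::p.adjust(p_b[ok], method = config$p_adjust)
    accepted[ok] <- (pa < config$alpha) & (pb < config$alpha)
  }
  hemi <- ifelse(parc$hemisphere[cand$up] == parc$hemisphere[cand$down],
                 parc$hemisphere[cand$up], "inter")
  tested <- data.frame(hemisphere = hemi, up_id = cand$up, down_id = cand$down,
                       up_name = parc$name[cand$up],
                       down_name = parc$name[cand$down],
                       p_up = p_a, p_down = p_b, accepted = accepted,
                       reason = vapply(tests, `[[`, character(1), "reason"))
  acc <- which(accepted)
  pw <- if (length(acc) == 0) .empty_pathways() else do.call(rbind, lapply(acc, function(k) {
    a <- tests[[k]]$test_up; b <- tests[[k]]$test_down
    data.frame(hemisphere = hemi[k], iteration = NA_integer_,
               up_id = cand$up[k], down_id = cand$down[k],
               up_name = parc$name[cand$up[k]],
               down_name = parc$name[cand$down[k]],
               metric = config$metric,
               coef_up = a$coefficient, se_up = a$se, p_up = a$p,
               sign_up = a$sign, r2_diff_up = a$r2_diff,
               coef_down = b$coefficient, se_down = b$se, p_down = b$p,
               sign_down = b$sign, r2_diff = b$r2_diff,
               n_used = b$n_used)
  }))
  list(pathways = pw, tested = tested,
       new_seeds = sort(unique(cand$down[acc])))
}

.empty_pathways <- function() {
  data.frame(hemisphere = character(0), iteration = integer(0),
             up_id = integer(0), down_id = integer(0),
             up_name = character(0), down_name = character(0),
             metric = character(0), coef_up = numeric(0), se_up = numeric(0),
             p_up = numeric(0), sign_up = character(0),
             r2_diff_up = numeric(0), coef_down = numeric(0),
             se_down = numeric(0), p_down = numeric(0),
             sign_down = character(0), r2_diff = numeric(0),
             n_used = integer(0))
}

.empty_tested <- function() {
  data.frame(hemisphere = character(0), up_id = integer(0),
             down_id = integer(0), up_name = character(0),
             down_name = character(0), p_up = numeric(0), p_down = numeric(0),
             accepted = logical(0), reason = character(0),
             iteration = integer(0))
}

# search one hemisphere (or the pooled brain): iterate until nothing new
.search_from <- function(cohort, backbone, seeds, config) {
  pathways <- .empty_pathways()
  tested <- .empty_tested()
  seed_history <- list()
  current <- sort(unique(seeds))
  tested_keys <- character(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    seed_history[[iter]] <- current
    step <- run_iteration(cohort, backbone, current, tested_keys, config)
    if (nrow(step$tested) > 0) {
      step$tested$iteration <- iter
      tested <- rbind(tested, step$tested)
      tested_keys <- c(tested_keys,
                       paste(step$tested$up_id, step$tested$down_id, sep = "->"))
    }
    if (nrow(step$pathways) == 0) break
    step$pathways$iteration <- iter
    pathways <- rbind(pathways, step$pathways)
    current <- sort(unique(c(current, step$new_seeds)))
  }
  list(pathways = pathways, tested = tested, seed_history = seed_history)
}

#' Run the full iterative pathway search
#'
#' Iterates [run_iteration()] from the seed set, labeling each accepted
#' pathway with the iteration at which it was found, until an iteration
#' detects no further pathways. Under `hemisphere_mode = "separate"` the left
#' and right hemispheres are searched independently (each with its own
#' iteration counter starting at 1) and merged into one pattern with
#' hemisphere tags.
#'
#' @param cohort a validated `ddis_cohort`.
#' @param backbone a `ddis_backbone`.
#' @param seeds a `ddis_seeds` or integer vector of seed roi_ids.
#' @param config a `ddis_config`.
#' @return object of class `ddis_pattern`: `pathways` (one row per accepted
#'   pathway with both regressions' statistics), `tested` (log of every
#'   tested connection), `seed_history` (per-hemisphere, per-iteration seed
#'   sets), `config`.
#' @export
run_ddis <- function(cohort, backbone, seeds, config = ddis_config()) {
  seed_ids <- if (inherits(seeds, "ddis_seeds")) seeds$roi_ids else
    sort(unique(as.integer(seeds)))
  if (!all(seed_ids %in% cohort$parcellation$roi_id))
    stop("seed ids outside the parcellation")
  if (length(seed_ids) == 0) {
    warning("empty seed set: returning an empty pattern")
    return(structure(list(pathways = .empty_pathways(),
                          tested = .empty_tested(),
                          seed_history = list(), config = config),
                     class = "ddis_pattern"))
  }
  parc <- cohort$parcellation
  if (config$hemisphere_mode == "separate") {
    runs <- lapply(c("left", "right"), function(h) {
      s <- seed_ids[parc$hemisphere[seed_ids] == h]
      if (length(s) == 0)
        return(list(pathways = .empty_pathways(), tested = .empty_tested(),
                    seed_history = list()))
      .search_from(cohort, backbone, s, config)
    })
    names(runs) <- c("left", "right")
    pathways <- rbind(runs$left$pathways, runs$right$pathways)
    tested <- rbind(runs$left$tested, runs$right$tested)
    seed_history <- list(left = runs$left$seed_history,
                         right = runs$right$seed_history)
  } else {
    r <- .search_from(cohort, backbone, seed_ids, config)
    pathways <- r$pathways; tested <- r$tested
    seed_history <- list(pooled = r$seed_history)
  }
  structure(list(pathways = pathways, tested = tested,
                 seed_history = seed_history, config = config),
            class = "ddis_pattern")
}

#' @export
print.ddis_pattern <- function(x, ...) {
  cat("ddis_pattern:", nrow(x$pathways), "pathways over",
      nrow(x$tested), "tested connections (metric:", x$config$metric, ")\n")
  if (nrow(x$pathways) > 0) {
    tab <- table(x$pathways$hemisphere, x$pathways$iteration)
    print(tab)
  }
  invisible(x)
}

#' Summarize a pattern by iteration
#'
#' Per-iteration pathway counts (pooled over hemispheres), the mean and range
#' of the incremental adjusted R^2 of the edge-to-destination model, and the
#' tally of the metric's direction of change as tau increases (the sign of
#' the seed-tau model's coefficient). A `total` row closes the table.
#'
#' @param pattern a `ddis_pattern`.
#' @return `data.frame` with columns `iteration`, `n_pathways`,
#'   `mean_r2_diff`, `min_r2_diff`, `max_r2_diff`, `n_increase`, `n_decrease`.
#' @export
summarize_pattern <- function(pattern) {
  pw <- pattern$pathways
  row_for <- function(label, d) {
    data.frame(iteration = label, n_pathways = nrow(d),
               mean_r2_diff = if (nrow(d)) mean(d$r2_diff) else NA_real_,
               min_r2_diff = if (nrow(d)) min(d$r2_diff) else NA_real_,
               max_r2_diff = if (nrow(d)) max(d$r2_diff) else NA_real_,
               n_increase = sum(d$sign_up == "+"),
               n_decrease = sum(d$sign_up == "-"))
  }
  if (nrow(pw) == 0) return(row_for("total", pw))
  iters <- sort(unique(pw$iteration))
  out <- do.call(rbind, lapply(iters, function(it)
    row_for(as.character(it), pw[pw$iteration == it, , drop = FALSE])))
  rbind(out, row_for("total", pw))
}
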
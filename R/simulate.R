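# Synthetic cohorts with the statistical structure the pathway search
# assumes: a two-hemisphere parcellation graph, planted node -> edge -> node
# association chains with configurable standardized effect sizes, age/sex
# confounding of both tau and the diffusion metrics, heterogeneous tau
# severity producing a prevalence gradient, and low-count spurious streamline
# connections that exercise the backbone threshold.
#
# Effect sizes are parameterized on the correlation scale: every planted
# variable is built from a unit-variance "signal part", so the partial
# correlation between adjacent chain variables (given the covariates) equals
# the stated effect size and power is interpretable in n.

#' Build a two-hemisphere template graph and parcellation
#'
#' Each hemisphere is a connected random geometric graph (nodes at uniform
#' 3-D coordinates, edges within a distance radius chosen to hit
#' `target_degree`, completed by a minimum spanning tree so the hemisphere is
#' connected), plus a few homotopic inter-hemispheric edges. The
#' `"desikan84"` model uses the shipped 84-region Desikan-Killiany name table
#' (34 cortical + 8 subcortical regions per hemisphere; basal-ganglia regions
#' flagged off-target) with the same edge generator. ROI sizes are drawn from
#' a lognormal (meanlog `log(3000)`, sdlog 0.4). Each edge carries a "true"
#' mean streamline count, uniform on \[200, 400\] scaled by the mean endpoint
#' size, so that after size normalization all true edges are comparable and
#' survive a 10% relative threshold.
#'
#' @param nodes_per_hemisphere node count per hemisphere (>= 3; ignored for
#'   `"desikan84"`, which has 42).
#' @param model `"random_geometric"` or `"desikan84"`.
#' @param rng_seed integer seed; the same seed reproduces the graph exactly.
#' @param target_degree desired mean intra-hemisphere degree (default 4).
#' @param n_interhemi number of homotopic inter-hemispheric edges (default 3).
#' @return object of class `ddis_template`: `parcellation` table and `edges`
#'   data.frame (`i`, `j`, `mean_count`, with `i < j`).
#' @export
make_template_graph <- function(nodes_per_hemisphere = 8,
                                model = c("random_geometric", "desikan84"),
                                rng_seed = 1L, target_degree = 4,
                                n_interhemi = 3) {
  model <- match.arg(model)
  set.seed(rng_seed)
  if (model == "desikan84") {
    dk <- utils::read.delim(system.file("extdata", "desikan84.tsv",
                                        package = "ddis"),
                            stringsAsFactors = FALSE)
    nh <- nrow(dk) / 2
    parc <- parcellation(dk$roi_name, dk$hemisphere,
                         stats::rlnorm(nrow(dk), log(3000), 0.4),
                         dk$off_target)
  } else {
    nh <- as.integer(nodes_per_hemisphere)
    if (nh < 3) stop("nodes_per_hemisphere must be >= 3")
    parc <- parcellation(rep(sprintf("roi%02d", seq_len(nh)), 2),
                         rep(c("left", "right"), each = nh),
                         stats::rlnorm(2 * nh, log(3000), 0.4),
                         FALSE)
  }
  hemi_edges <- function(ids) {
    n <- length(ids)
    xyz <- matrix(stats::runif(n * 3), n, 3)
    d <- as.matrix(stats::dist(xyz))
    dv <- d[upper.tri(d)]
    radius <- stats::quantile(dv, min(1, (target_degree * n / 2) / length(dv)))
    adj <- d <= radius
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                             weighted = TRUE)
    mst <- igraph::as_edgelist(igraph::mst(g))
    adj[cbind(as.integer(mst[, 1]), as.integer(mst[, 2]))] <- TRUE
    adj <- adj | t(adj)
    idx <- which(upper.tri(adj) & adj, arr.ind = TRUE)
    data.frame(i = ids[idx[, 1]], j = ids[idx[, 2]])
  }
  left <- parc$roi_id[parc$hemisphere == "left"]
  right <- parc$roi_id[parc$hemisphere == "right"]
  edges <- rbind(hemi_edges(left), hemi_edges(right))
  k <- min(n_interhemi, length(left))
  if (k > 0)
    edges <- rbind(edges, data.frame(i = left[seq_len(k)],
                                     j = right[seq_len(k)]))
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  msize <- (parc$size[edges$i] + parc$size[edges$j]) / 2
  edges$mean_count <- round(stats::runif(nrow(edges), 200, 400) * msize / 3000)
  structure(list(parcellation = parc, edges = edges, model = model,
                 rng_seed = as.integer(rng_seed)),
            class = "ddis_template")
}

#' @export
print.ddis_template <- function(x, ...) {
  cat("ddis_template (", x$model, "):", nrow(x$parcellation), "ROIs,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

# default planted chains: the first `len` non-off-target ROIs of each
# hemisphere, in id order (chain edges are added to the template if absent)
.default_chains <- function(template, len = 6) {
  parc <- template$parcellation
  lapply(c("left", "right"), function(h) {
    ids <- parc$roi_id[parc$hemisphere == h & !parc$off_target]
    ids[seq_len(min(len, length(ids)))]
  })
}

#' Ground truth for a simulated cohort
#'
#' Fixes the planted association chains and all generative parameters. A chain
#' is an ordered ROI path; each consecutive link plants a tau -> metric effect
#' of standardized size `beta1` and a metric -> tau effect of size `alpha1`
#' (partial correlations given age and sex). Chain roots and off-target ROIs
#' receive elevated tau severity (baseline 1.0 plus a Gamma draw), so chain
#' roots become high-prevalence seeds; off-target ROIs have elevated tau but
#' no planted downstream effects and act as negative controls. Missing chain
#' edges are added to the template.
#'
#' @param template a `ddis_template`.
#' @param chains list of integer roi_id paths (default: the first 6
#'   non-off-target ROIs of each hemisphere).
#' @param beta1 standardized tau -> metric effect per link (default 0.5).
#' @param alpha1 standardized metric -> tau effect per link (default 0.5).
#' @param metric channel carrying the planted signal (default `"md"`; other
#'   channels are covariates-plus-noise).
#' @param tau_seed_shape,tau_seed_scale Gamma severity parameters for chain
#'   roots and off-target ROIs (defaults 3 and 0.2: mean severity 0.6 SUVR
#'   above the 1.0 baseline, giving tau+ prevalence near 0.9 at cutoff 1.23).
#' @param tau_down_mu,tau_down_sd tau mean and SD for planted downstream ROIs
#'   (defaults 1.12, 0.15).
#' @param tau_bg_mu,tau_bg_sd background tau mean and SD (defaults 1.05, 0.10).
#' @param gamma_age_tau,gamma_sex_tau covariate effects on tau (SUVR per year;
#'   SUVR for male sex).
#' @param age_slope_sd,sex_slope_sd covariate effects on every diffusion
#'   channel, in units of the channel's SD (per year; for male sex).
#' @param spurious_rate per-subject probability that a non-edge ROI pair gets
#'   a spurious streamline count (default 0.08).
#' @param spurious_mu mean spurious count (default 6; two orders of magnitude
#'   below true edges, so spurious connections stay under the backbone
#'   threshold).
#' @param nb_size negative-binomial dispersion of true-edge counts
#'   (default 50).
#' @return object of class `ddis_ground_truth`.
#' @export
ground_truth <- function(template, chains = NULL, beta1 = 0.5, alpha1 = 0.5,
                         metric = "md",
                         tau_seed_shape = 3, tau_seed_scale = 0.2,
                         tau_down_mu = 1.12, tau_down_sd = 0.15,
                         tau_bg_mu = 1.05, tau_bg_sd = 0.10,
                         gamma_age_tau = 0.004, gamma_sex_tau = 0.03,
                         age_slope_sd = 0.01, sex_slope_sd = 0.2,
                         spurious_rate = 0.08, spurious_mu = 6,
                         nb_size = 50) {
  stopifnot(inherits(template, "ddis_template"))
  if (!metric %in% DIFFUSION_METRICS) stop("unknown metric: ", metric)
  if (!all(is.finite(c(beta1, alpha1))) || abs(beta1) > 1 || abs(alpha1) > 1)
    stop("effect sizes must be finite correlations in [-1, 1]")
  if (tau_seed_shape <= 0 || tau_seed_scale <= 0)
    stop("invalid severity distribution parameters")
  if (is.null(chains)) chains <- .default_chains(template)
  parc <- template$parcellation
  edges <- template$edges
  ekey <- paste(edges$i, edges$j)
  for (ch in chains) {
    ch <- as.integer(ch)
    if (!all(ch %in% parc$roi_id)) stop("chain node outside the parcellation")
    if (length(ch) < 2) stop("a chain needs at least two nodes")
    if (length(unique(parc$hemisphere[ch])) != 1)
      stop("a chain must stay within one hemisphere")
    for (k in seq_len(length(ch) - 1)) {
      a <- min(ch[k], ch[k + 1]); b <- max(ch[k], ch[k + 1])
      if (!paste(a, b) %in% ekey) {
        msize <- (parc$size[a] + parc$size[b]) / 2
        edges <- rbind(edges, data.frame(i = a, j = b,
                                         mean_count = round(300 * msize / 3000)))
        ekey <- c(ekey, paste(a, b))
      }
    }
  }
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  template$edges <- edges
  structure(list(template = template, chains = lapply(chains, as.integer),
                 beta1 = beta1, alpha1 = alpha1, metric = metric,
                 tau_seed_shape = tau_seed_shape,
                 tau_seed_scale = tau_seed_scale,
                 tau_down_mu = tau_down_mu, tau_down_sd = tau_down_sd,
                 tau_bg_mu = tau_bg_mu, tau_bg_sd = tau_bg_sd,
                 gamma_age_tau = gamma_age_tau, gamma_sex_tau = gamma_sex_tau,
                 age_slope_sd = age_slope_sd, sex_slope_sd = sex_slope_sd,
                 spurious_rate = spurious_rate, spurious_mu = spurious_mu,
                 nb_size = nb_size),
            class = "ddis_ground_truth")
}

# typical natural-unit scales per diffusion channel (MD/Da/Dr in 1e-3 mm^2/s)
# and the direction tau-related degeneration moves each one
.metric_scales <- data.frame(
  metric = c("fa", "md", "da", "dr", "icvf", "od"),
  mu = c(0.45, 0.85, 1.25, 0.65, 0.55, 0.25),
  sd = c(0.05, 0.06, 0.08, 0.06, 0.05, 0.04),
  planted_sign = c(-1, 1, 1, 1, -1, 1),
  stringsAsFactors = FALSE)

#' The pathways a generator plants, as an expected-pattern table
#'
#' One row per chain link: the pathway the search should recover, with the
#' iteration at which it should appear (the link's position in its chain).
#'
#' @param gt a `ddis_ground_truth`.
#' @return `data.frame`: `hemisphere`, `up_id`, `down_id`, `up_name`,
#'   `down_name`, `metric`, `iteration`.
#' @export
planted_pathways <- function(gt) {
  parc <- gt$template$parcellation
  rows <- lapply(gt$chains, function(ch) {
    if (length(ch) < 2) return(NULL)
    up <- ch[-length(ch)]; down <- ch[-1]
    data.frame(hemisphere = parc$hemisphere[up], up_id = up, down_id = down,
               up_name = parc$name[up], down_name = parc$name[down],
               metric = gt$metric, iteration = seq_along(up))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a cohort from a ground truth
#'
#' Per subject: age ~ Normal(70, 8^2) years, sex ~ Bernoulli(0.5), group label
#' (CN/SCD/MCI, metadata only) drawn with probabilities 22:22:18. Chain-root
#' and off-target ROIs get tau = 1.0 + Gamma severity; each planted link then
#' builds the edge metric from the upstream tau signal part and the
#' downstream tau from the edge signal part, at the standardized effect
#' sizes, on top of covariate effects. Non-planted ROIs and edges carry
#' covariate effects plus independent noise. Streamline counts are
#' negative-binomial around each true edge's mean count, with low-count
#' spurious entries on a random fraction of non-edges; diffusion metrics
#' exist only on true edges. All six channels are generated; the planted
#' signal goes into `gt$metric` only.
#'
#' @param gt a `ddis_ground_truth`.
#' @param n_subjects cohort size (>= 10; default 62).
#' @param rng_seed integer seed; the same seed reproduces the cohort exactly.
#' @return a `ddis_cohort` passing [validate_cohort()].
#' @export
simulate_cohort <- function(gt, n_subjects = 62, rng_seed = 1L) {
  stopifnot(inherits(gt, "ddis_ground_truth"))
  n <- as.integer(n_subjects)
  if (n < 10) stop("n_subjects must be >= 10")
  set.seed(rng_seed)
  parc <- gt$template$parcellation
  edges <- gt$template$edges
  n_roi <- nrow(parc)

  age <- stats::rnorm(n, 70, 8)
  sex <- stats::rbinom(n, 1, 0.5)
  zage <- age - 70
  subjects <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                         age = age, sex = sex,
                         group = sample(c("CN", "SCD", "MCI"), n,
                                        replace = TRUE,
                                        prob = c(22, 22, 18) / 62),
                         stringsAsFactors = FALSE)

  # tau: background everywhere, Gamma-elevated on chain roots and off-target
  tau <- matrix(gt$tau_bg_mu + gt$tau_bg_sd * stats::rnorm(n * n_roi),
                n, n_roi)
  roots <- vapply(gt$chains, `[`, integer(1), 1)
  elevated <- sort(unique(c(roots, parc$roi_id[parc$off_target])))
  sev_mu <- gt$tau_seed_shape * gt$tau_seed_scale
  sev_sd <- sqrt(gt$tau_seed_shape) * gt$tau_seed_scale
  sig <- matrix(NA_real_, n, n_roi)  # unit-variance signal parts
  for (r in elevated) {
    sev <- stats::rgamma(n, shape = gt$tau_seed_shape,
                         scale = gt$tau_seed_scale)
    tau[, r] <- 1.0 + sev
    sig[, r] <- (sev - sev_mu) / sev_sd
  }

  # planted chains: propagate unit-variance signal parts link by link
  edge_signal <- list()  # key "i|j" -> per-subject unit-variance edge signal
  for (ch in gt$chains) {
    s_up <- sig[, ch[1]]
    for (k in seq_len(length(ch) - 1)) {
      up <- ch[k]; down <- ch[k + 1]
      s_diff <- gt$beta1 * s_up +
        sqrt(max(0, 1 - gt$beta1^2)) * stats::rnorm(n)
      edge_signal[[paste(min(up, down), max(up, down), sep = "|")]] <- s_diff
      s_down <- gt$alpha1 * s_diff +
        sqrt(max(0, 1 - gt$alpha1^2)) * stats::rnorm(n)
      tau[, down] <- gt$tau_down_mu + gt$tau_down_sd * s_down
      sig[, down] <- s_down
      s_up <- s_down
    }
  }
  tau <- tau + outer(zage, rep(gt$gamma_age_tau, n_roi)) +
    outer(sex, rep(gt$gamma_sex_tau, n_roi))

  amyloid <- matrix(15 + 20 * stats::rnorm(n * n_roi), n, n_roi) + 0.5 * zage

  # streamline counts and diffusion metrics
  conn <- array(0, dim = c(n_roi, n_roi, n))
  metric_arrays <- lapply(stats::setNames(DIFFUSION_METRICS,
                                          DIFFUSION_METRICS),
                          function(m) array(NA_real_, dim = c(n_roi, n_roi, n)))
  m_edges <- nrow(edges)
  all_pairs <- which(upper.tri(matrix(0, n_roi, n_roi)), arr.ind = TRUE)
  pair_key <- paste(all_pairs[, 1], all_pairs[, 2], sep = "|")
  true_key <- paste(edges$i, edges$j, sep = "|")
  non_edge <- all_pairs[!pair_key %in% true_key, , drop = FALSE]

  for (s in seq_len(n)) {
    counts <- pmax(1, stats::rnbinom(m_edges, mu = edges$mean_count,
                                     size = gt$nb_size))
    conn[cbind(edges$i, edges$j, s)] <- counts
    conn[cbind(edges$j, edges$i, s)] <- counts
    if (nrow(non_edge) > 0 && gt$spurious_rate > 0) {
      hit <- which(stats::rbinom(nrow(non_edge), 1, gt$spurious_rate) == 1)
      if (length(hit) > 0) {
        sc <- 1 + stats::rpois(length(hit), gt$spurious_mu)
        conn[cbind(non_edge[hit, 1], non_edge[hit, 2], s)] <- sc
        conn[cbind(non_edge[hit, 2], non_edge[hit, 1], s)] <- sc
      }
    }
  }
  for (m in DIFFUSION_METRICS) {
    sc <- .metric_scales[.metric_scales$metric == m, ]
    covm <- sc$sd * (gt$age_slope_sd * zage + gt$sex_slope_sd * sex)
    for (e in seq_len(m_edges)) {
      key <- true_key[e]
      base <- if (m == gt$metric && !is.null(edge_signal[[key]]))
        sc$mu + sc$planted_sign * sc$sd * edge_signal[[key]]
      else sc$mu + sc$sd * stats::rnorm(n)
      vals <- base + covm
      metric_arrays[[m]][cbind(edges$i[e], edges$j[e], seq_len(n))] <- vals
      metric_arrays[[m]][cbind(edges$j[e], edges$i[e], seq_len(n))] <- vals
    }
  }

  new_cohort(parc, subjects,
             list(tau_suvr = tau, amyloid_centiloid = amyloid),
             conn, metric_arrays)
}

#' Simulate a matched null cohort
#'
#' Identical generative process with all planted effects set to zero: chain
#' roots and off-target ROIs keep their elevated tau severity (so seeds are
#' still selected and connections still tested), but no tau -> metric or
#' metric -> tau association exists anywhere.
#'
#' @param template a `ddis_template`.
#' @param n_subjects cohort size.
#' @param rng_seed integer seed.
#' @param chains,metric,... passed to [ground_truth()].
#' @return a `ddis_cohort`.
#' @export
simulate_null_cohort <- function(template, n_subjects = 62, rng_seed = 1L,
                                 chains = NULL, metric = "md", ...) {
  gt <- ground_truth(template, chains = chains, beta1 = 0, alpha1 = 0,
                     metric = metric, ...)
  simulate_cohort(gt, n_subjects, rng_seed)
}
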
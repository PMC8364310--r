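# Hand-built miniature cohorts for unit tests: node tau values and per-edge
# md values are supplied directly; other channels are flat noise-free
# placeholders defined on the same edges.

tiny_cohort <- function(tau, edges, md_values, hemisphere = NULL,
                        age = NULL, sex = NULL, count = 100) {
  n <- nrow(tau); n_roi <- ncol(tau)
  if (is.null(hemisphere)) hemisphere <- rep("left", n_roi)
  parc <- parcellation(sprintf("r%02d", seq_len(n_roi)), hemisphere,
                       size = 1000)
  if (is.null(age)) age <- seq(60, 80, length.out = n)
  if (is.null(sex)) sex <- rep_len(c(0, 1), n)
  subjects <- data.frame(subject_id = sprintf("S%02d", seq_len(n)),
                         age = age, sex = sex, group = "CN",
                         stringsAsFactors = FALSE)
  conn <- array(0, dim = c(n_roi, n_roi, n))
  mets <- lapply(stats::setNames(DIFFUSION_METRICS, DIFFUSION_METRICS),
                 function(m) array(NA_real_, dim = c(n_roi, n_roi, n)))
  for (r in seq_len(nrow(edges))) {
    i <- edges$i[r]; j <- edges$j[r]
    conn[cbind(i, j, seq_len(n))] <- count
    conn[cbind(j, i, seq_len(n))] <- count
    v <- md_values[[paste(min(i, j), max(i, j), sep = "|")]]
    if (is.null(v)) v <- rep(0.8, n)
    for (m in DIFFUSION_METRICS) {
      vv <- if (m == "md") v else rep(0.5, n)
      mets[[m]][cbind(i, j, seq_len(n))] <- vv
      mets[[m]][cbind(j, i, seq_len(n))] <- vv
    }
  }
  new_cohort(parc, subjects,
             list(tau_suvr = tau,
                  amyloid_centiloid = matrix(10, n, n_roi)),
             conn, mets)
}

# a random small simulated cohort for oracle-equivalence loops
random_small_cohort <- function(rep_seed) {
  set.seed(rep_seed)
  nh <- sample(3:4, 1)
  tpl <- make_template_graph(nh, "random_geometric",
                             rng_seed = rep_seed + 1000)
  len <- sample(2:nh, 1)
  b <- sample(c(0, 0.4, 0.7), 1)
  a <- sample(c(0, 0.4, 0.7), 1)
  gt <- ground_truth(tpl, chains = ddis:::.default_chains(tpl, len),
                     beta1 = b, alpha1 = a)
  list(gt = gt, cohort = simulate_cohort(gt, 60, rng_seed = rep_seed + 2000))
}
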
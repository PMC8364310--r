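# Synthetic-cohort generator: templates, determinism, planted structure

test_that("template graphs are reproducible, connected, two-hemisphere", {
  tpl <- make_template_graph(8, rng_seed = 5)
  expect_equal(nrow(tpl$parcellation), 16)
  expect_equal(sum(tpl$parcellation$hemisphere == "left"), 8)
  tpl2 <- make_template_graph(8, rng_seed = 5)
  expect_identical(tpl, tpl2)

  # each intra-hemisphere subgraph is connected
  for (h in c("left", "right")) {
    ids <- tpl$parcellation$roi_id[tpl$parcellation$hemisphere == h]
    e <- tpl$edges[tpl$edges$i %in% ids & tpl$edges$j %in% ids, ]
    g <- igraph::graph_from_data_frame(e, directed = FALSE,
                                       vertices = data.frame(name = ids))
    expect_equal(igraph::components(g)$no, 1)
  }
  tpl3 <- make_template_graph(3, rng_seed = 6)
  expect_equal(nrow(tpl3$parcellation), 6)
  expect_error(make_template_graph(2), ">= 3")
})

test_that("the 84-region atlas template matches its fixture", {
  tpl <- make_template_graph(model = "desikan84", rng_seed = 1)
  p <- tpl$parcellation
  expect_equal(nrow(p), 84)
  expect_equal(sum(p$hemisphere == "left"), 42)
  expect_setequal(p$name[p$off_target & p$hemisphere == "left"],
                  c("pallidum", "caudate", "putamen", "thalamus"))
  expect_true(all(c("fusiform", "inferiorparietal", "entorhinal",
                    "hippocampus") %in% p$name))
  expect_true(all(p$size > 0))
})

test_that("simulation is deterministic in the seed and passes validation", {
  tpl <- make_template_graph(5, rng_seed = 8)
  gt <- ground_truth(tpl, beta1 = 0.5, alpha1 = 0.5)
  c1 <- simulate_cohort(gt, 30, rng_seed = 9)
  c2 <- simulate_cohort(gt, 30, rng_seed = 9)
  expect_identical(c1, c2)
  c3 <- simulate_cohort(gt, 30, rng_seed = 10)
  expect_false(identical(c1$node_signal$tau_suvr, c3$node_signal$tau_suvr))
  expect_length(validate_cohort(c1), 0)
  expect_length(validate_cohort(simulate_null_cohort(tpl, 30, 9)), 0)
  expect_error(simulate_cohort(gt, 5), ">= 10")
  expect_error(ground_truth(tpl, beta1 = 1.5), "correlations")
  expect_error(ground_truth(tpl, tau_seed_shape = -1), "distribution")
})

test_that("null construction has no tau-metric correlation on planted edges", {
  tpl <- make_template_graph(6, rng_seed = 12)
  n <- 2000
  co <- simulate_null_cohort(tpl, n, rng_seed = 13)
  gt0 <- ground_truth(tpl, beta1 = 0, alpha1 = 0)
  pp <- planted_pathways(gt0)
  for (k in seq_len(nrow(pp))) {
    r <- cor(co$node_signal$tau_suvr[, pp$up_id[k]],
             co$edge_metric$md[pp$up_id[k], pp$down_id[k], ])
    expect_lt(abs(r), 3 / sqrt(n))
  }
})

test_that("fit_glm CI covers the planted raw slope at nominal rate", {
  tpl <- make_template_graph(4, rng_seed = 14)
  gt <- ground_truth(tpl, beta1 = 0.5, alpha1 = 0.5)
  # raw slope implied by the standardized effect: the metric moves
  # planted_sign * sd_m * beta1 per unit of the root's standardized severity,
  # and root tau moves sev_sd per standardized unit
  sev_sd <- sqrt(gt$tau_seed_shape) * gt$tau_seed_scale
  true_slope <- 1 * 0.06 * gt$beta1 / sev_sd   # md: sign +1, sd 0.06
  up <- gt$chains[[1]][1]; down <- gt$chains[[1]][2]
  covered <- 0
  for (rep in 1:100) {
    co <- simulate_cohort(gt, 200, rng_seed = 10000 + rep)
    f <- fit_glm(co$edge_metric$md[up, down, ],
                 co$node_signal$tau_suvr[, up],
                 co$subjects[, c("age", "sex")])
    ci <- f$coefficient + c(-1, 1) * qt(0.975, f$n_used - 4) * f$se
    if (ci[1] <= true_slope && true_slope <= ci[2]) covered <- covered + 1
  }
  expect_gte(covered, 93)
})
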
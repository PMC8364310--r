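# Regression engine and the iterative pathway search

test_that("fit_glm recovers a noise-free linear relation exactly", {
  x <- 1:10
  fit <- suppressWarnings(fit_glm(2 * x, x))  # zero-residual fit warns
  expect_equal(fit$coefficient, 2.0, tolerance = 1e-10)
  expect_equal(fit$adj_r2_full, 1.0, tolerance = 1e-10)
  expect_lt(fit$p, 1e-12)
  expect_equal(fit$sign, "+")
})

test_that("fit_glm matches the normal-equations oracle on a fixed dataset", {
  # fixed 8-row design with two covariates
  y <- c(2.1, 3.9, 1.2, 5.5, 4.1, 0.7, 6.2, 3.3)
  x <- c(0.5, 1.1, 0.2, 2.0, 1.4, 0.1, 2.4, 1.0)
  age <- c(61, 72, 65, 80, 70, 58, 77, 69)
  sex <- c(0, 1, 0, 1, 1, 0, 0, 1)
  cv <- data.frame(age = age, sex = sex)
  fit <- fit_glm(y, x, cv)
  orc <- oracle_glm(y, x, cv)
  expect_equal(fit$coefficient, orc$coefficient, tolerance = 1e-10)
  expect_equal(fit$se, orc$se, tolerance = 1e-10)
  expect_equal(fit$t, orc$t, tolerance = 1e-10)
  expect_equal(fit$p, orc$p, tolerance = 1e-10)
  expect_equal(fit$adj_r2_full, orc$adj_r2_full, tolerance = 1e-10)
  expect_equal(fit$r2_diff, orc$r2_diff, tolerance = 1e-10)
})

test_that("fit_glm rejects degenerate designs and tiny samples", {
  expect_error(fit_glm(rnorm(10), rep(1, 10)), "degenerate predictor")
  expect_error(fit_glm(rnorm(3), rnorm(3)), "too few")
  # missing values removed listwise, n_used reflects it
  y <- c(rnorm(9), NA)
  fit <- fit_glm(y, 1:10)
  expect_equal(fit$n_used, 9)
  # r2_diff never exceeds the full model's adjusted R^2 + reduced >= 0 check
  set.seed(5)
  for (k in 1:20) {
    n <- sample(10:40, 1)
    f <- fit_glm(rnorm(n), rnorm(n),
                 data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5)))
    expect_equal(f$r2_diff, f$adj_r2_full - f$adj_r2_covariates_only)
    # the increment is bounded by the full model's fit whenever the
    # covariates-only baseline explains anything (its adjusted R^2 can be
    # negative on pure noise, where the bound does not apply)
    if (f$adj_r2_covariates_only >= 0)
      expect_lte(f$r2_diff, f$adj_r2_full + 1e-12)
    expect_gte(f$p, 0); expect_lte(f$p, 1)
  }
})

test_that("connection acceptance requires both models significant", {
  set.seed(8)
  n <- 60
  s <- rnorm(n)
  tau <- cbind(1.2 + 0.3 * s, rnorm(n, 1.05, 0.1))  # down end: pure noise
  md <- list("1|2" = 0.85 + 0.06 * (0.9 * s + sqrt(1 - 0.81) * rnorm(n)))
  co <- tiny_cohort(tau, data.frame(i = 1, j = 2), md)
  res <- test_connection(co, 1, 2, "md")
  expect_lt(res$test_up$p, 0.05)     # model (a) strongly significant
  expect_gt(res$test_down$p, 0.05)   # model (b) noise
  expect_false(res$accepted)

  # reverse direction: both ends associated -> accepted
  tau2 <- cbind(tau[, 1],
                1.1 + 0.15 * (0.8 * md[["1|2"]] / 0.06 * 0.9 +
                                0.05 * rnorm(n)))
  co2 <- tiny_cohort(tau2, data.frame(i = 1, j = 2), md)
  res2 <- test_connection(co2, 1, 2, "md")
  expect_true(res2$accepted)
  # conjunction at vanishing alpha always rejects
  expect_false(test_connection(co2, 1, 2, "md", alpha = 1e-300)$accepted)
  # degenerate fit aborts only this connection, with a reason
  co3 <- co2
  co3$edge_metric$md[1, 2, ] <- 0.8
  co3$edge_metric$md[2, 1, ] <- 0.8
  res3 <- suppressWarnings(test_connection(co3, 2, 1, "md"))
  expect_false(res3$accepted)
  expect_match(res3$reason, "degenerate")
})

test_that("one iteration on a seeded star finds all planted spokes once", {
  set.seed(9)
  n <- 80
  s <- rnorm(n)
  tau <- matrix(rnorm(n * 4, 1.05, 0.1), n, 4)
  tau[, 1] <- 1.3 + 0.3 * s
  md <- list()
  for (k in 2:4) {
    es <- 0.8 * s + 0.6 * rnorm(n)
    md[[paste(1, k, sep = "|")]] <- 0.85 + 0.06 * es
    tau[, k] <- 1.12 + 0.15 * (0.8 * es + 0.6 * rnorm(n))
  }
  edges <- data.frame(i = c(1, 1, 1), j = 2:4)
  co <- tiny_cohort(tau, edges, md)
  bb <- build_backbone(co)
  cfg <- ddis_config()
  step <- run_iteration(co, bb, 1L, character(0), cfg)
  expect_equal(nrow(step$pathways), 3)
  expect_equal(step$new_seeds, 2:4)

  # both endpoints already seeds: seed-seed connections excluded
  step2 <- run_iteration(co, bb, 1:4, character(0), cfg)
  expect_equal(nrow(step2$tested), 0)

  # destination reachable from two seeds: two pathways, seeded once
  edges2 <- data.frame(i = c(1, 2), j = c(3, 3))
  md2 <- list("1|3" = md[["1|3"]], "2|3" = md[["1|3"]])
  tau2 <- tau[, 1:3]; tau2[, 2] <- tau2[, 1]
  co2 <- tiny_cohort(tau2, edges2, md2)
  step3 <- run_iteration(co2, build_backbone(co2), c(1L, 2L),
                         character(0), cfg)
  expect_equal(nrow(step3$pathways), 2)
  expect_equal(step3$new_seeds, 3L)
})

test_that("run_ddis recovers a planted chain in order and matches the oracle", {
  tpl <- make_template_graph(6, rng_seed = 41)
  gt <- ground_truth(tpl, beta1 = 0.7, alpha1 = 0.7)
  co <- simulate_cohort(gt, 200, rng_seed = 42)
  bb <- build_backbone(co)
  roots <- vapply(gt$chains, `[`, integer(1), 1)
  pat <- run_ddis(co, bb, roots, ddis_config())
  planted <- planted_pathways(gt)
  got <- pattern_tuples(pat)
  want <- planted[order(planted$up_id, planted$down_id),
                  c("hemisphere", "iteration", "up_id", "down_id")]
  rownames(want) <- NULL
  expect_equal(got, want)

  orc <- ddis_oracle(co, bb, roots, "md")
  rownames(orc) <- NULL
  expect_equal(got, orc)
})

test_that("search bookkeeping invariants hold", {
  tpl <- make_template_graph(5, rng_seed = 51)
  gt <- ground_truth(tpl, beta1 = 0.6, alpha1 = 0.6,
                     chains = ddis:::.default_chains(tpl, 4))
  co <- simulate_cohort(gt, 120, rng_seed = 52)
  bb <- build_backbone(co)
  roots <- vapply(gt$chains, `[`, integer(1), 1)
  pat <- run_ddis(co, bb, roots, ddis_config())

  # no connection tested twice
  keys <- paste(pat$tested$up_id, pat$tested$down_id)
  expect_equal(anyDuplicated(keys), 0)
  # iteration labels contiguous from 1 within each hemisphere
  for (h in unique(pat$pathways$hemisphere)) {
    it <- pat$pathways$iteration[pat$pathways$hemisphere == h]
    expect_equal(sort(unique(it)), seq_len(max(it)))
  }
  # iteration count bounded by non-seed ROI count
  expect_lte(max(pat$pathways$iteration),
             n_rois(co) - length(roots))
  # subject-order invariance
  set.seed(2)
  perm <- sample(n_subjects(co))
  pat2 <- run_ddis(cohort_subset(co, perm), bb, roots, ddis_config())
  expect_equal(pattern_tuples(pat), pattern_tuples(pat2))

  # empty seed set: warning and empty pattern
  expect_warning(p0 <- run_ddis(co, bb, integer(0), ddis_config()), "empty")
  expect_equal(nrow(p0$pathways), 0)
})

test_that("shrinking alpha never adds a pathway on fixed data", {
  tpl <- make_template_graph(6, rng_seed = 61)
  gt <- ground_truth(tpl, beta1 = 0.45, alpha1 = 0.45)
  co <- simulate_cohort(gt, 90, rng_seed = 62)
  bb <- build_backbone(co)
  roots <- vapply(gt$chains, `[`, integer(1), 1)
  keyset <- function(alpha) {
    pw <- run_ddis(co, bb, roots, ddis_config(alpha = alpha))$pathways
    paste(pw$up_id, pw$down_id)
  }
  k01 <- keyset(0.01); k05 <- keyset(0.05)
  expect_true(all(k01 %in% k05))
})

test_that("pattern summary conserves counts and tallies directions", {
  tpl <- make_template_graph(5, rng_seed = 71)
  gt <- ground_truth(tpl, beta1 = 0.7, alpha1 = 0.7)
  co <- simulate_cohort(gt, 150, rng_seed = 72)
  pat <- run_ddis(co, build_backbone(co),
                  vapply(gt$chains, `[`, integer(1), 1), ddis_config())
  sm <- summarize_pattern(pat)
  tot <- sm[sm$iteration == "total", ]
  expect_equal(sum(sm$n_pathways[sm$iteration != "total"]), tot$n_pathways)
  expect_equal(tot$n_pathways, nrow(pat$pathways))
  expect_equal(tot$n_increase + tot$n_decrease, tot$n_pathways)
  # md is planted with a positive sign: all pathways tally as increase
  expect_equal(tot$n_increase, tot$n_pathways)

  empty <- structure(list(pathways = ddis:::.empty_pathways()),
                     class = "ddis_pattern")
  sm0 <- summarize_pattern(empty)
  expect_equal(sm0$n_pathways, 0)
  expect_equal(sm0$iteration, "total")
})
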
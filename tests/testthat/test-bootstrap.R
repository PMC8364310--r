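# Bootstrap resampling, voting and stability filtering

fake_pattern <- function(pairs) {
  pw <- if (length(pairs) == 0) ddis:::.empty_pathways() else
    data.frame(hemisphere = "left",
               up_name = vapply(pairs, `[`, character(1), 1),
               down_name = vapply(pairs, `[`, character(1), 2),
               metric = "md")
  structure(list(pathways = pw), class = "ddis_pattern")
}

test_that("voting counts pathway identities across patterns", {
  pats <- c(replicate(7, fake_pattern(list(c("a", "b"))), simplify = FALSE),
            replicate(3, fake_pattern(list()), simplify = FALSE))
  st <- vote_summary(pats)
  expect_equal(st$votes, 7L)
  expect_equal(st$frequency, 0.7)
  expect_equal(attr(st, "n_boot"), 10)

  # disjoint patterns: every identity 1/n
  pats2 <- list(fake_pattern(list(c("a", "b"))),
                fake_pattern(list(c("c", "d"))),
                fake_pattern(list(c("e", "f"))))
  st2 <- vote_summary(pats2)
  expect_equal(st2$frequency, rep(1 / 3, 3))

  # undirected aggregation merges the two directions
  pats3 <- list(fake_pattern(list(c("a", "b"))),
                fake_pattern(list(c("b", "a"))))
  expect_equal(nrow(vote_summary(pats3, directed = TRUE)), 2)
  un <- vote_summary(pats3, directed = FALSE)
  expect_equal(nrow(un), 1)
  expect_equal(un$frequency, 1)
  expect_error(vote_summary(list()), "at least one")
})

test_that("frequency filter is inclusive at the cutoff", {
  pats <- c(replicate(5, fake_pattern(list(c("a", "b"), c("c", "d"))),
                      simplify = FALSE),
            replicate(1, fake_pattern(list(c("a", "b"))), simplify = FALSE),
            replicate(14, fake_pattern(list()), simplify = FALSE))
  st <- vote_summary(pats)   # a->b: 6/20 = 0.30; c->d: 5/20 = 0.25
  kept <- filter_stability(st, 0.30)
  expect_equal(kept$up_roi, "a")        # 0.30 retained, 0.25 removed
  expect_equal(nrow(filter_stability(st, 0)), 2)
  expect_equal(nrow(filter_stability(st, 1)), 0)
})

test_that("bootstrap is a pure function of cohort, config and seed", {
  tpl <- make_template_graph(4, rng_seed = 81)
  gt <- ground_truth(tpl, beta1 = 0.8, alpha1 = 0.8,
                     chains = ddis:::.default_chains(tpl, 3))
  co <- simulate_cohort(gt, 60, rng_seed = 82)
  s1 <- bootstrap_ddis(co, ddis_config(), n_boot = 15, rng_seed = 7)
  s2 <- bootstrap_ddis(co, ddis_config(), n_boot = 15, rng_seed = 7)
  expect_identical(s1, s2)
  s3 <- bootstrap_ddis(co, ddis_config(), n_boot = 15, rng_seed = 8)
  expect_false(identical(s1, s3))
  expect_equal(attr(s1, "n_boot"), 15)
  expect_length(attr(s1, "per_replicate_counts"), 15)
})

test_that("near-deterministic planted pathways are unanimous; empty-seed replicates count", {
  # hand-built 3-node chain per hemisphere, chain edges only (no shortcuts),
  # root always positive, links essentially noise-free
  set.seed(91)
  n <- 60
  s <- rnorm(n)
  link <- function(x) 0.995 * x + sqrt(1 - 0.995^2) * rnorm(n)
  tau <- matrix(rnorm(n * 6, 1.05, 0.05), n, 6)
  md <- list()
  for (off in c(0, 3)) {  # left nodes 1:3, right nodes 4:6
    tau[, off + 1] <- 1.40 + 0.05 * s
    e1 <- link(s)
    md[[paste(off + 1, off + 2, sep = "|")]] <- 0.85 + 0.06 * e1
    tau[, off + 2] <- 1.10 + 0.10 * link(e1)
    e2 <- link(link(e1))
    md[[paste(off + 2, off + 3, sep = "|")]] <- 0.85 + 0.06 * e2
    tau[, off + 3] <- 1.05 + 0.10 * link(e2)
  }
  edges <- data.frame(i = c(1, 2, 4, 5), j = c(2, 3, 5, 6))
  co <- tiny_cohort(tau, edges, md,
                    hemisphere = rep(c("left", "right"), each = 3))
  st <- bootstrap_ddis(co, ddis_config(), n_boot = 20, rng_seed = 93)
  keys <- paste(rep(c("left", "right"), each = 2),
                c("r01", "r02", "r04", "r05"),
                c("r02", "r03", "r05", "r06"), "md", sep = "|")
  got <- paste(st$hemisphere, st$up_roi, st$down_roi, st$metric, sep = "|")
  expect_true(all(keys %in% got))
  expect_equal(st$frequency[match(keys, got)], rep(1, length(keys)))

  # an unreachable positivity cutoff yields no seeds in any replicate:
  # zero votes, but every replicate stays in the denominator
  st0 <- bootstrap_ddis(co, ddis_config(positivity_cutoff = 99),
                        n_boot = 10, rng_seed = 94)
  expect_equal(nrow(st0), 0)
  expect_equal(attr(st0, "n_boot"), 10)
  expect_equal(attr(st0, "per_replicate_counts"), rep(0L, 10))
})
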
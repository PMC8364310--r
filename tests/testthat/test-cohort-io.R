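# I/O, data-model invariants and validation reporting

sim_small <- function(seed = 11) {
  tpl <- make_template_graph(3, rng_seed = seed)
  simulate_cohort(ground_truth(tpl, beta1 = 0.4, alpha1 = 0.4), 12,
                  rng_seed = seed)
}

test_that("write/load round-trips a synthetic cohort", {
  co <- sim_small()
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- load_cohort(file.path(dir, "subjects.tsv"),
                      file.path(dir, "nodes.tsv"),
                      file.path(dir, "edges.tsv"),
                      file.path(dir, "parcellation.tsv"))
  expect_equal(back$parcellation, co$parcellation, tolerance = 1e-12)
  expect_equal(back$subjects, co$subjects, tolerance = 1e-12)
  expect_equal(unname(back$node_signal$tau_suvr),
               unname(co$node_signal$tau_suvr), tolerance = 1e-12)
  expect_equal(back$conn_counts, co$conn_counts)
  expect_equal(back$total_streamlines, co$total_streamlines)
  for (m in DIFFUSION_METRICS)
    expect_equal(back$edge_metric[[m]], co$edge_metric[[m]],
                 tolerance = 1e-12)
})

test_that("loader rejects malformed tables with descriptive errors", {
  co <- sim_small(12)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  args <- function(d) list(file.path(d, "subjects.tsv"),
                           file.path(d, "nodes.tsv"),
                           file.path(d, "edges.tsv"),
                           file.path(d, "parcellation.tsv"))

  # self-connection
  e <- read.delim(file.path(dir, "edges.tsv"))
  e2 <- e
  e2$roi_j[1] <- e2$roi_i[1]; e2$hemi_j[1] <- e2$hemi_i[1]
  write.table(e2, file.path(dir, "edges.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  expect_error(do.call(load_cohort, args(dir)), "self-connection")

  # duplicate edge row
  e2 <- rbind(e, e[1, ])
  write.table(e2, file.path(dir, "edges.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  expect_error(do.call(load_cohort, args(dir)), "duplicate")
  write.table(e, file.path(dir, "edges.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")

  # missing (subject, roi) node row
  nd <- read.delim(file.path(dir, "nodes.tsv"))
  write.table(nd[-3, ], file.path(dir, "nodes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")
  expect_error(do.call(load_cohort, args(dir)), "incomplete")
  write.table(nd, file.path(dir, "nodes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")

  # missing column
  s <- read.delim(file.path(dir, "subjects.tsv"))
  write.table(s[, -2], file.path(dir, "subjects.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")
  expect_error(do.call(load_cohort, args(dir)), "missing columns")
})

test_that("validate_cohort flags exactly the injected violations", {
  co <- sim_small(13)
  expect_length(validate_cohort(co), 0)

  bad <- co
  bad$conn_counts[1, 2, 1] <- bad$conn_counts[1, 2, 1] + 5  # symmetry break
  v <- validate_cohort(bad)
  expect_length(grep("asymmetric", v), 1)
  expect_match(v[grepl("asymmetric", v)], bad$subjects$subject_id[1])

  bad <- co
  bad$conn_counts[2, 3, 2] <- -1; bad$conn_counts[3, 2, 2] <- -1
  expect_length(grep("negative", validate_cohort(bad)), 1)

  bad <- co
  bad$conn_counts[1, 1, 1] <- 4
  expect_length(grep("self-connection", validate_cohort(bad)), 1)

  bad <- co
  bad$node_signal$tau_suvr[2, 2] <- NA
  expect_length(grep("missing", validate_cohort(bad)), 1)

  bad <- co
  free <- which(bad$conn_counts[, , 1] == 0 &
                  upper.tri(bad$conn_counts[, , 1]), arr.ind = TRUE)[1, ]
  bad$edge_metric$md[free[1], free[2], 1] <- 0.9
  expect_length(grep("unconnected", validate_cohort(bad)), 1)
})

test_that("pathway table is deterministic, ordered, and handles empties", {
  dir <- withr::local_tempdir()
  empty <- structure(list(pathways = ddis:::.empty_pathways()),
                     class = "ddis_pattern")
  f1 <- file.path(dir, "empty.tsv")
  write_pathway_table(empty, f1)
  lines <- readLines(f1)
  expect_length(lines, 1)  # header only
  expect_match(lines, "^hemisphere\tup_roi\tdown_roi")

  tpl <- make_template_graph(4, rng_seed = 3)
  gt <- ground_truth(tpl, beta1 = 0.8, alpha1 = 0.8)
  co <- simulate_cohort(gt, 80, rng_seed = 3)
  pat <- run_ddis(co, build_backbone(co),
                  select_seeds(NULL, co$parcellation,
                               seed_list = vapply(gt$chains, `[`, integer(1), 1)))
  expect_gt(nrow(pat$pathways), 1)
  f2 <- file.path(dir, "p1.tsv"); f3 <- file.path(dir, "p2.tsv")
  write_pathway_table(pat, f2)
  write_pathway_table(pat, f3)
  expect_identical(readLines(f2), readLines(f3))
  tab <- read.delim(f2)
  ord <- order(tab$iteration)
  expect_identical(tab$iteration, tab$iteration[ord])
})
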
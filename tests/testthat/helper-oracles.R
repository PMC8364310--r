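# Independent oracles, coded against the statistics textbook rather than the
# package: an OLS fit via the normal equations with t-distribution p-values,
# and a brute-force fixed-point rescan version of the iterative pathway
# search built on that oracle.

# OLS with intercept by normal equations; two-sided t test per coefficient
ols_oracle <- function(y, X) {
  X <- cbind(`(Intercept)` = 1, as.matrix(X))
  n <- length(y); p <- ncol(X)
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  resid <- y - X %*% beta
  rss <- sum(resid^2)
  df <- n - p
  sigma2 <- rss / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / df
  list(beta = drop(beta), se = drop(se), t = drop(tval), p = drop(pval),
       r2 = r2, adj_r2 = adj_r2, df = df)
}

# mirror of fit_glm built on ols_oracle (predictor in column 1 of X)
oracle_glm <- function(response, predictor, covariates = NULL) {
  cv <- if (is.null(covariates)) NULL else as.matrix(covariates)
  keep <- stats::complete.cases(response, predictor,
                                if (is.null(cv)) rep(TRUE, length(response)) else cv)
  y <- response[keep]; x <- predictor[keep]
  cv <- if (is.null(cv)) NULL else cv[keep, , drop = FALSE]
  full <- ols_oracle(y, cbind(x = x, cv))
  red_adj <- if (is.null(cv) || ncol(cv) == 0) 0 else ols_oracle(y, cv)$adj_r2
  list(coefficient = unname(full$beta["x"]), se = unname(full$se["x"]),
       t = unname(full$t["x"]), p = unname(full$p["x"]),
       n_used = length(y), adj_r2_full = full$adj_r2,
       r2_diff = full$adj_r2 - red_adj)
}

# brute-force reference search: repeatedly rescan ALL backbone edges against
# the current seed set until a fixed point, per hemisphere, caching tested
# directed connections; returns the accepted (hemisphere, iteration, up, down)
ddis_oracle <- function(cohort, backbone, seed_ids, metric, alpha = 0.05,
                        covariates = c("age", "sex"),
                        hemisphere_mode = "separate", min_n = 5) {
  parc <- cohort$parcellation
  cv <- cohort$subjects[, covariates, drop = FALSE]
  sig <- cohort$node_signal$tau_suvr
  test_dir <- function(u, d) {
    met <- cohort$edge_metric[[metric]][u, d, ]
    ok <- tryCatch({
      a <- oracle_glm(met, sig[, u], cv)
      b <- oracle_glm(sig[, d], met, cv)
      keep_a <- sum(stats::complete.cases(met, sig[, u], cv))
      if (keep_a < max(min_n, ncol(cv) + 3)) FALSE
      else if (stats::sd(sig[stats::complete.cases(met, sig[, u], cv), u]) == 0 ||
               stats::sd(met[stats::complete.cases(sig[, d], met, cv)]) == 0) FALSE
      else a$p < alpha && b$p < alpha
    }, error = function(e) FALSE)
    isTRUE(ok)
  }
  search_hemi <- function(seeds_h) {
    S <- sort(seeds_h)
    tested <- character(0)
    out <- NULL
    iter <- 0L
    repeat {
      iter <- iter + 1L
      accepted <- NULL
      for (r in seq_len(nrow(backbone$edges))) {
        for (dirn in 1:2) {
          u <- if (dirn == 1) backbone$edges$i[r] else backbone$edges$j[r]
          d <- if (dirn == 1) backbone$edges$j[r] else backbone$edges$i[r]
          if (!(u %in% S) || d %in% S) next
          if (hemisphere_mode == "separate" &&
              parc$hemisphere[u] != parc$hemisphere[d]) next
          key <- paste(u, d, sep = "->")
          if (key %in% tested) next
          tested <- c(tested, key)
          if (test_dir(u, d))
            accepted <- rbind(accepted,
                              data.frame(hemisphere = parc$hemisphere[u],
                                         iteration = iter, up_id = u,
                                         down_id = d))
        }
      }
      if (is.null(accepted)) break
      out <- rbind(out, accepted)
      S <- sort(unique(c(S, accepted$down_id)))
    }
    out
  }
  if (hemisphere_mode == "separate") {
    res <- NULL
    for (h in c("left", "right")) {
      sh <- seed_ids[parc$hemisphere[seed_ids] == h]
      if (length(sh) > 0) res <- rbind(res, search_hemi(sh))
    }
  } else res <- search_hemi(seed_ids)
  if (is.null(res))
    res <- data.frame(hemisphere = character(0), iteration = integer(0),
                      up_id = integer(0), down_id = integer(0))
  res[order(res$up_id, res$down_id), , drop = FALSE]
}

# sorted pathway tuple table from a ddis_pattern, for set comparisons
pattern_tuples <- function(pattern) {
  pw <- pattern$pathways
  out <- data.frame(hemisphere = pw$hemisphere, iteration = pw$iteration,
                    up_id = pw$up_id, down_id = pw$down_id)
  out <- out[order(out$up_id, out$down_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
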
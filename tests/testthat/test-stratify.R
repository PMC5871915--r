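make_tables <- function(p_lists) {
  lapply(p_lists, function(p) {
    data.frame(pathway = sprintf("PW%02d", seq_along(p)),
               n_genes = 10L, n_in_network = 10L, score = 1,
               p_empirical = p, n_null = 1000L)
  })
}

test_that("feature matrix is -log10(p) with the add-one floor as cap", {
  tabs <- make_tables(list(S1 = c(1.0, 1 / 10001), S2 = c(0.5, 1.0)))
  F <- build_feature_matrix(tabs)
  expect_equal(F["S1", "PW01"], 0)
  expect_equal(F["S1", "PW02"], log10(10001))
  expect_equal(F["S2", "PW01"], -log10(0.5))
  expect_identical(dim(build_feature_matrix(tabs["S1"])), c(1L, 2L))
  bad <- tabs
  bad$S2$pathway <- c("PW01", "OTHER")
  expect_error(build_feature_matrix(bad), "mismatch.*S2")
})

test_that("hierarchical clustering recovers well-separated blobs and stabilizes labels", {
  withr::with_seed(99, {
    high <- matrix(rnorm(20 * 4, mean = 10, sd = 1), 20)
    low <- matrix(rnorm(20 * 4, mean = 0, sd = 1), 20)
  })
  F <- rbind(high, low)
  rownames(F) <- sprintf("S%02d", 1:40)
  labels <- hierarchical_cluster(F, k = 2)
  planted <- rep(1:2, each = 20)
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(labels, planted), 1.0)
  # the high-mean blob must carry label 1 (stable labeling rule)
  expect_true(all(labels[1:20] == 1))
  expect_true(all(labels[21:40] == 2))
})

test_that("clustering edge cases behave: k = n, duplicates, k > n", {
  F <- matrix(c(0, 0, 5, 5, 9, 9), 3, 2, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), NULL))
  expect_identical(sort(unique(hierarchical_cluster(F, k = 3))), 1:3)
  Fd <- F[c(1, 1, 2, 3), ]
  rownames(Fd) <- c("a1", "a2", "b", "c")
  lab <- hierarchical_cluster(Fd, k = 2)
  expect_identical(lab[["a1"]], lab[["a2"]])
  expect_error(hierarchical_cluster(F, k = 4), "exceeds")
  # correlation metric accepted
  F2 <- matrix(rnorm(40), 8, 5, dimnames = list(letters[1:8], NULL))
  expect_identical(sort(unique(hierarchical_cluster(F2, k = 2,
                                                    metric = "correlation"))),
                   1:2)
})

test_that("log-rank statistic is zero for mirror-image groups", {
  time <- c(1, 2, 3, 4, 1, 2, 3, 4)
  event <- c(1, 1, 0, 1, 1, 1, 0, 1)
  grp <- rep(c("A", "B"), each = 4)
  r <- logrank_test(time, event, grp, "A", "B")
  expect_equal(r$chi_square, 0)
  expect_equal(r$p_value, 1)
})

test_that("log-rank statistic matches the hand-derived at-risk computation", {
  # A: events at 1, 2; B: censored at 10, 10
  # t=1: O-E = 1 - 2/4, V = (2/4)(2/4);  t=2: O-E = 1 - 1/3, V = (1/3)(2/3)
  # chi^2 = (7/6)^2 / (17/36) = 49/17
  r <- logrank_test(c(1, 2, 10, 10), c(1, 1, 0, 0),
                    c("A", "A", "B", "B"), "A", "B")
  expect_equal(r$chi_square, 49 / 17, tolerance = 1e-12)
  # swapping the group labels leaves the statistic unchanged
  r2 <- logrank_test(c(1, 2, 10, 10), c(1, 1, 0, 0),
                     c("A", "A", "B", "B"), "B", "A")
  expect_equal(r2$chi_square, r$chi_square)
  # the observed labeling is the most extreme of all 6 relabelings
  perm <- logrank_perm_stats(c(1, 2, 10, 10), c(1, 1, 0, 0), 2)
  expect_equal(max(perm), r$chi_square, tolerance = 1e-12)
  expect_equal(mean(perm >= r$chi_square - 1e-9), 2 / 6)
})

test_that("log-rank agrees with survival::survdiff on random data", {
  skip_if_not_installed("survival")
  for (s in 1:10) {
    withr::with_seed(700 + s, {
      n <- 40
      time <- rexp(n, rate = rep(c(1, 2), each = n / 2))
      event <- rbinom(n, 1, 0.8)
      grp <- rep(c("A", "B"), each = n / 2)
    })
    ours <- logrank_test(time, event, grp, "A", "B")
    ref <- survival::survdiff(survival::Surv(time, event) ~ grp)
    expect_equal(ours$chi_square, unname(ref$chisq), tolerance = 1e-8)
  }
})

test_that("pooled comparisons and degenerate groups are handled", {
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 1, 1, 1, 0, 0)
  grp <- c(1, 1, 2, 2, 3, 3)
  pooled <- logrank_test(time, event, grp, c(1, 2), 3)
  expect_s3_class(pooled, "logrank_result")
  expect_equal(pooled$df, 1L)
  # censoring-only arm contributes zero observed events, statistic finite
  expect_equal(logrank_test(time, event, grp, 3, c(1, 2))$observed_a, 0)
  expect_true(is.finite(pooled$chi_square))
  expect_error(logrank_test(time, event, grp, 4, 3), "non-empty")
  expect_error(logrank_test(time, rep(0, 6), grp, c(1, 2), 3), "no events")
})

test_that("Kaplan-Meier curves start at 1, are non-increasing, and match survfit", {
  withr::with_seed(88, {
    time <- rexp(30); event <- rbinom(30, 1, 0.7)
    grp <- rep(c("A", "B"), 15)
  })
  km <- km_curves(time, event, grp)
  for (g in c("A", "B")) {
    cur <- km[km$group == g, ]
    expect_equal(cur$survival[1], 1)
    expect_equal(cur$time[1], 0)
    expect_true(all(diff(cur$survival) <= 0))
  }
  skip_if_not_installed("survival")
  fit <- survival::survfit(survival::Surv(time, event) ~ grp)
  ours <- km[km$group == "A" & km$time > 0, ]
  ref <- summary(fit)
  ref_a <- ref$surv[ref$strata == "grp=A"]
  expect_equal(ours$survival, ref_a, tolerance = 1e-12)
})

test_that("case study bundle emits k labels, KM data and pooled tests deterministically", {
  sc <- generate_scenario(mini_cfg())
  res <- suppressWarnings(
    run_case_study(sc$cohort, sc$network, sc$pathways, sc$survival,
                   k = 2, n_null = 100, rng_seed = 4, min_size = 2))
  expect_identical(sort(unique(unname(res$labels))), 1:2)
  expect_identical(length(res$logrank_pooled), 2L)
  expect_true(all(res$km$survival <= 1))
  res2 <- suppressWarnings(
    run_case_study(sc$cohort, sc$network, sc$pathways, sc$survival,
                   k = 2, n_null = 100, rng_seed = 4, min_size = 2))
  expect_identical(res$feature_matrix, res2$feature_matrix)
  expect_identical(res$labels, res2$labels)
  expect_equal(res$logrank_pooled[[1]]$p_value,
               res2$logrank_pooled[[1]]$p_value)
})
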
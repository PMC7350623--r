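# Marker discovery: quantile normalization, variance filtering, the
# resampled t statistic, ranking and external-list intersection.

test_that("quantile normalization matches its definition and is idempotent", {
  # hand-computed: row-sorted means of [[1,4],[2,5],[3,6]] are 2.5/3.5/4.5
  x <- tibble::tibble(probe_id = c("p1", "p2", "p3"),
                      s1 = c(1, 2, 3), s2 = c(4, 5, 6))
  qn <- quantile_normalize(x)
  expect_equal(qn$s1, c(2.5, 3.5, 4.5))
  expect_equal(qn$s2, c(2.5, 3.5, 4.5))

  set.seed(41)
  y <- matrix_tbl(matrix(rlnorm(300, 4, 1), nrow = 50))
  q1 <- quantile_normalize(y)
  # all columns share the same sorted value vector
  sorted <- apply(expr_to_mat(q1), 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  # fixed point: identical columns and repeated application
  expect_equal(quantile_normalize(q1), q1, tolerance = 1e-12)
  same <- tibble::tibble(probe_id = c("a", "b"), s1 = c(1, 7), s2 = c(1, 7))
  expect_equal(quantile_normalize(same), same)
  expect_error(quantile_normalize(same[, 1:2]), ">= 2 samples")
})

test_that("log2 variance filter removes only probes strictly below threshold", {
  # probe at exactly variance 0.25 (log2 values -0.5/0.5 -> var 0.5^2*2/1... )
  # use two samples: values 2^c(-0.25, 0.75) have log2 var = 0.5 -> kept;
  # constant probe var 0 -> dropped; craft exact 0.25: log2 values c(0, canon)
  exact <- 2^c(0, sqrt(0.25 * 2))     # var of the two log2 values = 0.25
  x <- tibble::tibble(
    probe_id = c("const", "exact", "wide"),
    s1 = c(5, exact[1], 1),
    s2 = c(5, exact[2], 16)
  )
  out <- log2_variance_filter(x, 0.25)
  expect_setequal(out$probe_id, c("exact", "wide"))
  expect_equal(unlist(out[out$probe_id == "wide", c("s1", "s2")]),
               c(s1 = 0, s2 = 4))
  # all-above-threshold input passes through unchanged (as log2)
  allw <- x[x$probe_id == "wide", ]
  expect_equal(log2_variance_filter(allw, 0.25)$probe_id, "wide")
  bad <- x
  bad$s1[1] <- 0
  expect_error(log2_variance_filter(bad), "non-positive intensity.*const")
})

test_that("n_reps = 1 reduces to a direct Student t-test (oracle, 1e-10)", {
  set.seed(7)
  m <- matrix(rnorm(40 * 12, 8, 1), nrow = 40,
              dimnames = list(sprintf("g%02d", 1:40), sprintf("s%02d", 1:12)))
  labels <- tibble::tibble(
    sample_id = colnames(m), class = rep(c("T", "O"), each = 6)
  )
  params <- discovery_params(n_reps = 1L, seed = 99L)
  stats <- resampled_marker_stats(matrix_tbl(m), labels, "T", params)
  # reproduce the single seeded draw from the non-target pool
  idx_pool <- which(labels$class != "T")
  drawn <- withr::with_seed(params$seed, sample(idx_pool, 6))
  for (g in rownames(m)) {
    tt <- t.test(m[g, 1:6], m[g, drawn], var.equal = TRUE)
    row <- stats[stats$probe_id == g, ]
    expect_equal(row$mean_p, tt$p.value, tolerance = 1e-10)
    expect_equal(row$mean_log2fc, unname(diff(rev(tt$estimate))),
                 tolerance = 1e-10)
  }
})

test_that("null data gives uniform mean p-values and planted effects recover", {
  # no-signal: mean over probes of mean_p ~ 0.5
  cfg <- discovery_config(classes = c(T = 20L, O = 20L), n_probes = 1000L,
                          seed = 17L)
  sim <- simulate_discovery(cfg)
  lg <- matrix_tbl(log2(expr_to_mat(sim$intensities)))
  stats <- resampled_marker_stats(
    lg, sim$labels, "T", discovery_params(n_reps = 25L, seed = 5L)
  )
  expect_gt(mean(stats$mean_p), 0.45)
  expect_lt(mean(stats$mean_p), 0.55)

  # planted log2 effect 4 at 20 vs 20 on the log2 matrix
  cfg2 <- discovery_config(
    classes = c(T = 20L, O = 20L), n_probes = 200L,
    planted_markers = tibble::tibble(
      class = "T", probe_id = "P0007", log2_effect = 4
    ),
    seed = 23L
  )
  sim2 <- simulate_discovery(cfg2)
  lg2 <- matrix_tbl(log2(expr_to_mat(sim2$intensities)))
  stats2 <- resampled_marker_stats(
    lg2, sim2$labels, "T", discovery_params(n_reps = 25L, seed = 5L)
  )
  hit <- stats2[stats2$probe_id == "P0007", ]
  expect_gt(hit$mean_log2fc, 3.5)
  expect_lt(hit$mean_log2fc, 4.5)
  expect_lt(hit$mean_p, 1e-3)
  expect_equal(hit$rank, 1L)
})

test_that("zero-variance probes get the declared degenerate p-values", {
  m <- rbind(
    flat_same = rep(5, 8),
    flat_diff = rep(c(5, 7), each = 4),
    noisy = rnorm(8)
  )
  colnames(m) <- sprintf("s%d", 1:8)
  labels <- tibble::tibble(sample_id = colnames(m),
                           class = rep(c("T", "O"), each = 4))
  stats <- resampled_marker_stats(
    matrix_tbl(m), labels, "T", discovery_params(n_reps = 3L, seed = 1L)
  )
  expect_equal(stats$mean_p[stats$probe_id == "flat_same"], 1)
  expect_equal(stats$mean_p[stats$probe_id == "flat_diff"], 0)
})

test_that("a pool smaller than the target class is reused with a warning", {
  set.seed(2)
  m <- matrix(rnorm(20 * 9), nrow = 20,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:9)))
  labels <- tibble::tibble(sample_id = colnames(m),
                           class = rep(c("T", "O"), c(6, 3)))
  expect_warning(
    resampled_marker_stats(matrix_tbl(m), labels, "T",
                           discovery_params(n_reps = 2L, seed = 1L)),
    "whole pool"
  )
})

test_that("higher planted effects never raise the marker's mean p (median over seeds)", {
  diffs <- vapply(1:10, function(s) {
    p_at <- function(effect) {
      cfg <- discovery_config(
        classes = c(T = 6L, O = 10L), n_probes = 50L,
        planted_markers = tibble::tibble(
          class = "T", probe_id = "P0001", log2_effect = effect
        ),
        seed = s
      )
      sim <- simulate_discovery(cfg)
      lg <- matrix_tbl(log2(expr_to_mat(sim$intensities)))
      stats <- resampled_marker_stats(
        lg, sim$labels, "T", discovery_params(n_reps = 10L, seed = s)
      )
      stats$mean_p[stats$probe_id == "P0001"]
    }
    p_at(0.5) - p_at(1.5)
  }, numeric(1))
  expect_gte(median(diffs), 0)
})

test_that("label shuffling destroys planted markers", {
  cfg <- discovery_config(
    classes = c(T = 10L, O = 30L), n_probes = 200L,
    planted_markers = tibble::tibble(
      class = "T", probe_id = sprintf("P%04d", 1:3), log2_effect = 5
    ),
    seed = 31L
  )
  sim <- simulate_discovery(cfg)
  lg <- matrix_tbl(log2(expr_to_mat(sim$intensities)))
  hits <- vapply(1:10, function(s) {
    shuffled <- sim$labels
    shuffled$class <- withr::with_seed(s, sample(shuffled$class))
    stats <- resampled_marker_stats(
      lg, shuffled, "T", discovery_params(n_reps = 10L, seed = s)
    )
    any(stats$mean_linear_fold >= 10 & stats$mean_p < 1e-3)
  }, logical(1))
  expect_lte(sum(hits), 1L)
})

test_that("ranking excludes sub-threshold folds and truncates to top_n", {
  stats <- tibble::tibble(
    probe_id = c("a", "b", "c", "d"),
    target_class = "T",
    mean_p = c(1e-9, 1e-8, 1e-7, 0.5),
    mean_log2fc = log2(c(50, 9.9, 20, 30)),
    mean_linear_fold = c(50, 9.9, 20, 30),
    rank = 1:4
  )
  sel <- rank_markers(stats, discovery_params(fold_threshold = 10, top_n = 3L))
  # b is excluded despite its p; d is cut by top_n
  expect_equal(sel$probe_id, c("a", "c"))
  expect_lte(nrow(rank_markers(stats, discovery_params(top_n = 1L))), 1L)
})

test_that("strong planted markers outrank every null probe end-to-end", {
  cfg <- discovery_config(
    classes = c(T = 10L, O = 30L), n_probes = 300L,
    planted_markers = tibble::tibble(
      class = "T", probe_id = sprintf("P%04d", 1:4), log2_effect = c(5, 5.5, 6, 6.5)
    ),
    seed = 13L
  )
  sim <- simulate_discovery(cfg)
  md <- discover_markers(sim$intensities, sim$labels, "T",
                         discovery_params(n_reps = 25L, seed = 2L))
  stats <- attr(md, "stats")
  planted_ranks <- stats$rank[stats$probe_id %in% sprintf("P%04d", 1:4)]
  expect_setequal(planted_ranks, 1:4)
  expect_true(all(sprintf("P%04d", 1:4) %in% md$probe_id))
})

test_that("external-list intersection annotates ranks and forced probes", {
  panel <- tibble::tibble(probe_id = c("a", "b", "c"), rank = 1:3)
  expect_equal(nrow(intersect_markers(panel, c("x", "y"))), 0L)
  same <- intersect_markers(panel, c("a", "b", "c"))
  expect_equal(same$probe_id, panel$probe_id)
  expect_equal(same$rank_internal, same$rank_external)
  forced <- intersect_markers(panel, c("b", "z"), forced = "z")
  expect_equal(
    forced$provenance[forced$probe_id == "z"], "external-only"
  )
  expect_true(is.na(forced$rank_internal[forced$probe_id == "z"]))
  expect_equal(forced$rank_external[forced$probe_id == "z"], 2L)
})
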
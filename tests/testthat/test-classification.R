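# Reference-anchored diagnosis: clustering, signature scores, group calls
# and the glioma-contrast analysis.

test_that("average-linkage merge heights match the brute-force oracle", {
  set.seed(55)
  for (rep in 1:50) {
    n <- sample(3:7, 1)
    pts <- matrix(rnorm(n * 4), nrow = n)
    hc <- hclust(dist(pts), method = "average")
    expect_equal(sort(hc$height), sort(upgma_oracle_heights(pts)),
                 tolerance = 1e-10)
  }
  # the same holds through the package's clustering entry point
  co <- simulate_cohort(cohort_config(
    "supratentorial", c(HGG = 4L), c(`HGNET-BCOR` = 2L),
    list(`HGNET-BCOR` = "HGNET-BCOR_01"), seed = 2
  ))
  norm <- normalize_cohort(co)
  hc <- cluster_samples(norm, compartment = "supratentorial")
  pts <- t(expr_to_mat(norm$log2)[attr(hc, "probes"), ])
  expect_equal(sort(hc$height), sort(upgma_oracle_heights(pts)),
               tolerance = 1e-10)
})

test_that("identical samples merge at height zero; heights are monotone", {
  m <- log2_tbl(
    A1 = c(5, 5, 1, 2), A2 = c(4, 4, 2, 1),
    B1 = c(1, 1, 3, 3), B2 = c(2, 2, 3, 3),
    G1 = c(1, 1, 1, 1), G2 = c(1, 1, 1, 1), G3 = c(0, 0, 0, 0)
  )
  m$S02 <- m$S01  # duplicate sample
  hc <- cluster_samples(m, toy_codeset(), "supratentorial")
  expect_equal(min(hc$height), 0)
  expect_true(all(diff(hc$height) >= -1e-12))
  expect_error(cluster_samples(m[, 1:2], toy_codeset(), "supratentorial"),
               ">= 2 samples")
})

test_that("cutting a strongly planted two-entity tree recovers the partition", {
  cfg <- cohort_config(
    "supratentorial", c(HGG = 10L),
    c(`HGNET-BCOR` = 3L, `HGNET-MN1` = 3L),
    reference_samples = list(`HGNET-BCOR` = "HGNET-BCOR_01",
                             `HGNET-MN1` = "HGNET-MN1_01"),
    marker_fold_range = c(30, 60), seed = 6
  )
  co <- simulate_cohort(cfg)
  norm <- normalize_cohort(co)
  hc <- cluster_samples(norm, compartment = "supratentorial")
  k3 <- cutree(structure(hc, class = "hclust"), k = 3)
  grp <- split(names(k3), k3)
  truth_grp <- split(co$truth$sample_id, dplyr::coalesce(co$truth$entity, "bg"))
  canon <- function(groups) {
    sort(unname(vapply(groups, function(g) paste(sort(g), collapse = ","), "")))
  }
  expect_equal(canon(grp), canon(truth_grp))
})

test_that("newick export carries every leaf", {
  co <- simulate_cohort(default_infratentorial_config(3))
  norm <- normalize_cohort(co)
  hc <- cluster_samples(norm, compartment = "infratentorial")
  tree <- ape::read.tree(text = as_newick(hc))
  expect_setequal(tree$tip.label, co$truth$sample_id)
})

test_that("signature z-scores standardize and detect a single planted sample", {
  # homogeneous cohort: sd 0 -> all z = 0
  flat <- log2_tbl(
    A1 = rep(4, 6), A2 = rep(4, 6), B1 = rep(4, 6), B2 = rep(4, 6)
  )
  sc <- signature_scores(flat, toy_codeset(), "supratentorial")
  expect_true(all(sc$z == 0))

  # one planted sample among 99 nulls: its z must exceed 3
  set.seed(12)
  m <- matrix(rnorm(4 * 100, 4, 0.4), nrow = 4,
              dimnames = list(c("A1", "A2", "B1", "B2"), NULL))
  m[c("A1", "A2"), 100] <- m[c("A1", "A2"), 100] + 6
  tbl <- matrix_tbl(m)
  sc2 <- signature_scores(tbl, toy_codeset(), "supratentorial")
  planted_id <- cnssig:::sample_ids_of(tbl)[100]
  expect_gt(sc2$z[sc2$entity == "E1" & sc2$sample_id == planted_id], 3)
  # standardization: mean 0, sd 1 per entity
  by_e <- split(sc2$z, sc2$entity)
  for (z in by_e) {
    expect_equal(mean(z), 0, tolerance = 1e-12)
    expect_equal(sd(z), 1, tolerance = 1e-12)
  }
})

test_that("a cohort with no planted entities yields zero calls", {
  cfg <- cohort_config(
    "supratentorial",
    background_diagnoses = c(HGG = 20L, PNET = 20L, EPN = 20L),
    planted_entities = c(`HGNET-BCOR` = 0L),
    seed = 19
  )
  co <- simulate_cohort(cfg)
  norm <- normalize_cohort(co)
  calls <- call_groups(norm, compartment = "supratentorial")
  expect_equal(sum(!is.na(calls$called_entity)), 0L)
})

test_that("an exact two-entity tie yields no call with an ambiguity flag", {
  set.seed(3)
  noise <- matrix(rnorm(7 * 12, 3, 0.2), nrow = 7)
  m <- matrix(0, nrow = 7, ncol = 12,
              dimnames = list(c("A1", "A2", "B1", "B2", "G1", "G2", "G3"), NULL))
  m[] <- noise
  # sample 1: identical elevation in both entity panels, built symmetric
  m[c("A1", "B1"), 1] <- 9
  m[c("A2", "B2"), 1] <- 8
  tbl <- matrix_tbl(m)
  # force exact score symmetry between panels
  tbl[tbl$probe_id == "B1", -1] <- tbl[tbl$probe_id == "A1", -1]
  tbl[tbl$probe_id == "B2", -1] <- tbl[tbl$probe_id == "A2", -1]
  calls <- call_groups(tbl, toy_codeset(), compartment = "supratentorial")
  first <- calls[calls$sample_id == cnssig:::sample_ids_of(tbl)[1], ]
  expect_true(is.na(first$called_entity))
  expect_true(first$ambiguous)
})

test_that("calling is permutation-equivariant", {
  co <- simulate_cohort(default_supratentorial_config(8))
  norm <- normalize_cohort(co)
  refs <- split(
    co$truth$sample_id[co$truth$reference],
    co$truth$entity[co$truth$reference]
  )
  calls <- call_groups(norm, references = refs,
                       compartment = "supratentorial")
  perm <- withr::with_seed(1, sample(seq_len(nrow(co$truth))))
  norm_p <- norm
  norm_p$log2 <- norm$log2[, c(1L, perm + 1L)]
  norm_p$linear <- norm$linear[, c(1L, perm + 1L)]
  calls_p <- call_groups(norm_p, norm$codeset, references = refs,
                         compartment = "supratentorial")
  merged <- dplyr::left_join(
    as_tibble(calls), as_tibble(calls_p), by = "sample_id"
  )
  expect_equal(merged$called_entity.x, merged$called_entity.y)
})

test_that("raising tau never increases the number of calls", {
  co <- simulate_cohort(default_supratentorial_config(12))
  norm <- normalize_cohort(co)
  n_calls <- vapply(c(1.5, 2, 3, 4.5), function(tau) {
    calls <- call_groups(norm, compartment = "supratentorial", tau = tau)
    sum(!is.na(calls$called_entity))
  }, numeric(1))
  expect_true(all(diff(n_calls) <= 0))
})

test_that("entity calls recover planted truth with references self-called", {
  # aggregate sensitivity/specificity over 20 seeded cohorts
  tp <- fn <- fp <- tn <- 0L
  for (s in 1:20) {
    cfgs <- default_cohort_configs(s)
    co_s <- simulate_cohort(cfgs$supratentorial)
    co_i <- simulate_cohort(cfgs$infratentorial)
    norm <- normalize_cohort(c(co_s$samples, co_i$samples),
                             co_s$codeset)
    truth <- dplyr::bind_rows(co_s$truth, co_i$truth)
    calls <- classify_cohort(norm, truth)  # errors if a reference miscalls
    j <- dplyr::left_join(calls, truth, by = c("sample_id", "compartment"))
    hit <- !is.na(j$called_entity) & !is.na(j$entity) &
      j$called_entity == j$entity
    tp <- tp + sum(hit)
    fn <- fn + sum(!is.na(j$entity) & !hit)
    fp <- fp + sum(!is.na(j$called_entity) & is.na(j$entity))
    tn <- tn + sum(is.na(j$called_entity) & is.na(j$entity))
  }
  expect_gte(tp / (tp + fn), 0.95)
  expect_gte(tn / (tn + fp), 0.95)
})

test_that("a reference that fails its own call raises an integrity error", {
  cfg <- cohort_config(
    "supratentorial", c(HGG = 15L, PNET = 15L),
    planted_entities = c(`HGNET-BCOR` = 0L), seed = 33
  )
  co <- simulate_cohort(cfg)
  norm <- normalize_cohort(co)
  expect_error(
    call_groups(
      norm, references = list(`HGNET-BCOR` = co$truth$sample_id[1]),
      compartment = "supratentorial"
    ),
    "classification-integrity"
  )
})

test_that("entities cannot be forced into a compartment without a panel", {
  co <- simulate_cohort(default_infratentorial_config(2))
  norm <- normalize_cohort(co)
  expect_error(
    call_groups(norm, compartment = "infratentorial",
                entities = c("HGNET-BCOR", "NB-FOXR2")),
    "not callable"
  )
})

test_that("the glioma contrast reproduces the planted dual/outlier structure", {
  # 28 samples: 21 glioma-high, 6 planted entity samples (2 dual), 1 outlier
  cfg <- cohort_config(
    "supratentorial", c(HGG = 21L, PNET = 1L), c(`HGNET-BCOR` = 6L),
    reference_samples = list(`HGNET-BCOR` = "HGNET-BCOR_01"),
    dual_glioma = c(`HGNET-BCOR` = 2L), glioma_fold = 8, seed = 44
  )
  co <- simulate_cohort(cfg)
  norm <- normalize_cohort(co)
  gc <- glioma_contrast(norm)
  j <- dplyr::left_join(gc, co$truth, by = "sample_id")
  expect_equal(sum(j$label %in% c("signature", "dual")), 6L)
  expect_equal(j$sample_id[j$label == "dual"],
               j$sample_id[j$dual_glioma])
  expect_equal(sum(j$label == "glioma"), 21L)
  expect_equal(j$sample_id[j$label == "outlier"], "ST_PNET_01")
})
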
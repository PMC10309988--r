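test_that("ordinal recoding maps levels deterministically and errors on unknowns", {
  farms <- dplyr::bind_rows(
    make_farm(farm_id = "A", technology = "non", education = "primary"),
    make_farm(farm_id = "B", technology = "semi", education = "high_school"),
    make_farm(farm_id = "C", technology = "technified", education = "university")
  )
  mat <- ordinal_recode(farms)
  expect_identical(unname(mat[, "technology"]), c(0, 1, 2))
  expect_identical(unname(mat[, "education"]), c(0, 1, 2))
  expect_identical(rownames(mat), c("A", "B", "C"))
  expect_false(anyNA(mat))

  bad <- make_farm(farm_id = "X", technology = "industrial")
  expect_error(ordinal_recode(bad), "industrial",
               class = "acarecon_recode_error")
  expect_error(ordinal_recode(bad), "X", class = "acarecon_recode_error")
})

test_that("z-scoring leaves constant columns at zero", {
  farms <- dplyr::bind_rows(make_farm(farm_id = "A"), make_farm(farm_id = "B"))
  mat <- ordinal_recode(farms, scale = "z-score")
  expect_true(all(abs(colMeans(mat)) < 1e-12))
})

test_that("the WSS curve is zero on identical points and non-increasing", {
  same <- dplyr::bind_rows(lapply(1:8, function(i) make_farm(farm_id = paste0("F", i))))
  mat <- ordinal_recode(same)
  curve <- wss_curve(mat, k_max = 4, seed = 1)
  expect_equal(curve$wss, rep(0, 4))

  cohort <- generate_cohort(synth_config(seed = 13))
  curve2 <- wss_curve(ordinal_recode(cohort$farms), seed = 13)
  expect_true(all(diff(curve2$wss) <= 1e-8 * curve2$wss[1]))
  expect_error(wss_curve(mat, k_max = 8), class = "acarecon_input_error")
})

test_that("two well-separated blobs drop sharply at k = 2", {
  set.seed(4)
  mat <- rbind(matrix(rnorm(60, 0, 0.1), ncol = 2),
               matrix(rnorm(60, 10, 0.1), ncol = 2))
  curve <- wss_curve(mat, k_max = 5, seed = 4)
  drop12 <- curve$wss[1] - curve$wss[2]
  drop23 <- curve$wss[2] - curve$wss[3]
  expect_gt(drop12, 100 * max(drop23, 1e-12))
  expect_identical(choose_k_elbow(curve)$k, 2L)
})

test_that("the elbow rule reproduces worked curves and flags flat ones", {
  expect_identical(
    choose_k_elbow(tibble::tibble(k = 1:5, wss = c(100, 40, 35, 33, 32)))$k, 2L
  )
  expect_identical(
    choose_k_elbow(tibble::tibble(k = 1:5, wss = c(100, 40, 35, 33, 32)),
                   method = "raw")$k, 2L
  )
  flat <- choose_k_elbow(tibble::tibble(k = 1:6, wss = c(100, 90, 80, 70, 60, 50)))
  expect_true(flat$low_confidence)
  expect_error(
    choose_k_elbow(tibble::tibble(k = 1:4, wss = c(100, 50, 60, 40))),
    class = "acarecon_input_error"
  )
  expect_error(choose_k_elbow(tibble::tibble(k = 1:2, wss = c(10, 5))),
               class = "acarecon_input_error")
})

test_that("k-means recovers constructed blobs exactly and is seeded", {
  set.seed(5)
  mat <- rbind(matrix(rnorm(40, 0, 0.2), ncol = 2),
               matrix(rnorm(40, 8, 0.2), ncol = 2))
  rownames(mat) <- paste0("F", 1:40)
  res <- cluster_farms(mat, 2, seed = 5)
  truth <- rep(1:2, each = 20)
  expect_equal(ari_oracle(res$assignments, truth), 1)
  res2 <- cluster_farms(mat, 2, seed = 5)
  expect_identical(res$assignments, res2$assignments)
  # k = 1 equals the closed-form total sum of squares
  res1 <- cluster_farms(mat, 1, seed = 5)
  expect_equal(res1$wss, sum(sweep(mat, 2, colMeans(mat))^2))
})

test_that("cluster profiles reproduce templates and conserve shares", {
  cohort <- generate_cohort(synth_config(seed = 17))
  prof <- profile_clusters(cohort$farms, cohort$truth)
  expect_equal(sum(prof$share_pct), 100)
  expect_identical(prof$n, c(21L, 17L, 27L, 23L, 17L))
  tmpl <- default_group_templates()
  expect_identical(prof$technology, tmpl$technology)
  expect_identical(prof$education, tmpl$education)
  expect_identical(prof$milk_destination, tmpl$milk_destination)
  # single cluster profiles equal the whole-sample summary
  one <- profile_clusters(cohort$farms, rep(1L, nrow(cohort$farms)))
  expect_identical(nrow(one), 1L)
  expect_equal(one$farm_area_ha, mean(cohort$farms$farm_area_ha))
})

test_that("relabelling clusters changes neither WSS nor profiles", {
  cohort <- generate_cohort(synth_config(seed = 19))
  mat <- ordinal_recode(cohort$farms)
  res <- cluster_farms(mat, 5, seed = 19)
  relabel <- c(3L, 5L, 1L, 2L, 4L)[res$assignments]
  p1 <- profile_clusters(cohort$farms, res$assignments)
  p2 <- profile_clusters(cohort$farms, relabel)
  cols <- setdiff(names(p1), "cluster")
  expect_equal(
    as.data.frame(p1[order(p1$n, p1$farm_area_ha), cols]),
    as.data.frame(p2[order(p2$n, p2$farm_area_ha), cols]),
    ignore_attr = TRUE
  )
  wss_manual <- sum(vapply(split(seq_len(nrow(mat)), relabel), function(i) {
    sum(sweep(mat[i, , drop = FALSE], 2, colMeans(mat[i, , drop = FALSE]))^2)
  }, numeric(1)))
  expect_equal(wss_manual, res$wss, tolerance = 1e-9)
})

test_that("k-means agrees with the external ARI cross-check", {
  skip_if_not_installed("mclust")
  cohort <- generate_cohort(synth_config(seed = 23))
  mat <- ordinal_recode(cohort$farms)
  res <- cluster_farms(mat, 5, seed = 23)
  expect_equal(ari_oracle(res$assignments, cohort$truth),
               mclust::adjustedRandIndex(res$assignments, cohort$truth),
               tolerance = 1e-12)
})
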
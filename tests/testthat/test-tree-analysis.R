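two_group_data <- function(n = 40, hi = 10, lo = 0, noise = 0) {
  set.seed(1)
  tech <- factor(rep(c("technified", "non"), each = n / 2),
                 levels = c("non", "semi", "technified"))
  tibble::tibble(
    technology = tech,
    y = ifelse(tech == "technified", hi, lo) + rnorm(n, 0, noise)
  )
}

test_that("a constant response yields a single-node tree", {
  d <- tibble::tibble(technology = factor(rep(c("non", "semi"), 20)), y = 7)
  fit <- fit_cart(d, "y", "technology")
  expect_identical(sum(fit$rpart$frame$var == "<leaf>"), 1L)
  expect_equal(unique(predict_tree(fit, d)), 7)
  expect_error(fit_cart(d[0, ], "y", "technology"),
               class = "acarecon_input_error")
})

test_that("a clean one-predictor signal is recovered with exact leaf means", {
  d <- two_group_data()
  fit <- fit_cart(d, "y", "technology")
  expect_identical(sum(fit$rpart$frame$var == "<leaf>"), 2L)
  expect_identical(as.character(fit$rpart$frame$var[1]), "technology")
  pred <- predict_tree(fit, d)
  expect_equal(sort(unique(pred)), c(0, 10))
  expect_equal(pred, d$y)
})

test_that("no leaf is smaller than the minimum leaf size", {
  farms <- generate_cohort(synth_config(seed = 8))$farms
  td <- tree_data(farms)
  spec <- tree_spec("model1")
  fit <- fit_cart(td, spec$response, spec$predictors,
                  control = tree_control(min_leaf = 7))
  leaf_sizes <- fit$rpart$frame$n[fit$rpart$frame$var == "<leaf>"]
  expect_true(all(leaf_sizes >= 7))
})

test_that("predictions are deterministic leaf values, stable under permutation", {
  farms <- generate_cohort(synth_config(seed = 12))$farms
  td <- tree_data(farms)
  spec <- tree_spec("model3")
  fit <- fit_cart(td, spec$response, spec$predictors)
  pred <- predict_tree(fit, td)
  # routing agrees with the fitted partition on training rows
  expect_identical(acarecon:::route_tree(fit$rpart, td),
                   unname(fit$rpart$where))
  expect_equal(pred, unname(predict(fit$rpart, td)))
  set.seed(2)
  perm <- sample(nrow(td))
  expect_equal(predict_tree(fit, td[perm, ]), pred[perm])
})

test_that("unseen factor levels are routed to the majority side with a warning", {
  # unbalanced groups so the majority side is unambiguous
  set.seed(1)
  tech <- factor(rep(c("technified", "non"), c(10, 30)),
                 levels = c("non", "semi", "technified"))
  d <- tibble::tibble(technology = tech,
                      y = ifelse(tech == "technified", 10, 0))
  fit <- fit_cart(d, "y", "technology",
                  control = tree_control(min_split = 10, min_leaf = 5))
  new <- tibble::tibble(technology = factor("industrial"))
  expect_warning(p <- predict_tree(fit, new), "majority")
  expect_equal(unname(p), 0)
})

test_that("split search agrees with exhaustive partition enumeration", {
  set.seed(33)
  for (rep in 1:20) {
    lev <- c("a", "b", "c", "d")
    x <- factor(sample(lev, 80, replace = TRUE), levels = lev)
    means <- setNames(rnorm(4, 0, 3), lev)
    d <- tibble::tibble(x = x, y = means[as.character(x)] + rnorm(80, 0, 0.3))
    fit <- fit_cart(d, "y", "x",
                    control = tree_control(min_split = 10, min_leaf = 5,
                                           max_depth = 1, complexity = 1e-9))
    if (sum(fit$rpart$frame$var == "<leaf>") != 2) next
    got <- extract_rpart_split(fit)
    oracle <- best_split_oracle(as.character(d$x), d$y)$left
    same <- identical(got, oracle) ||
      identical(got, sort(setdiff(lev, oracle)))
    expect_true(same)
  }
})

test_that("training MSE does not increase with depth and beats the mean model", {
  farms <- generate_cohort(synth_config(seed = 14))$farms
  td <- tree_data(farms)
  spec <- tree_spec("model2")
  mses <- vapply(1:5, function(depth) {
    fit <- fit_cart(td, spec$response, spec$predictors,
                    control = tree_control(max_depth = depth,
                                           complexity = 1e-9))
    mean((td[[spec$response]] - predict_tree(fit, td))^2)
  }, numeric(1))
  expect_true(all(diff(mses) <= 1e-9))
  base <- mean((td[[spec$response]] - mean(td[[spec$response]]))^2)
  expect_true(all(mses <= base + 1e-9))
})

test_that("the concordance screen passes identity and rejects shifts and scalings", {
  set.seed(44)
  pred <- rnorm(200)
  exact <- concordance_screen(pred, pred)
  expect_true(exact$pass)
  expect_equal(exact$slope, 1)
  expect_equal(exact$intercept, 0)

  noisy <- concordance_screen(pred, pred + rnorm(200, 0, 0.05))
  expect_true(noisy$pass)

  shifted <- concordance_screen(pred, pred + 10)
  expect_false(shifted$pass)
  expect_true(shifted$intercept_ci[1] > 0)

  scaled <- concordance_screen(pred, 2 * pred + rnorm(200, 0, 0.01))
  expect_false(scaled$pass)
  expect_true(scaled$slope_ci[1] > 1)

  degenerate <- concordance_screen(rep(1, 10), rnorm(10))
  expect_true(degenerate$degenerate)
  expect_false(degenerate$pass)
  expect_error(concordance_screen(1:2, 1:2), class = "acarecon_input_error")
})

test_that("Bland-Altman statistics handle exact, shifted and degenerate cases", {
  x <- c(1.2, 3.4, 5.6, 7.8)
  same <- bland_altman(x, x)
  expect_equal(same$mean_diff, 0)
  expect_equal(same$loa_low, 0)
  expect_equal(same$loa_high, 0)
  expect_equal(same$p_diff_zero, 1)

  shifted <- bland_altman(x + 3, x)
  expect_equal(shifted$mean_diff, 3)
  expect_equal(shifted$sd_diff, 0)
  expect_equal(shifted$p_diff_zero, 0)

  set.seed(55)
  d <- rnorm(100)
  ba <- bland_altman(d + rnorm(100), d)
  expect_equal(ba$loa_high - ba$loa_low, 2 * 1.96 * ba$sd_diff)
  expect_error(bland_altman(1:3, 1:4), class = "acarecon_input_error")
})

test_that("repeated-split selection is seeded and recovers strong signals", {
  set.seed(66)
  n <- 80
  tech <- factor(sample(c("non", "semi", "technified"), n, replace = TRUE),
                 levels = c("non", "semi", "technified"))
  d <- tibble::tibble(
    technology = tech,
    other = factor(sample(c("x", "y"), n, replace = TRUE)),
    y = c(non = 20, semi = 12, technified = 6)[as.character(tech)] +
      rnorm(n, 0, 2)
  )
  sel <- repeated_split_select(d, "y", c("technology", "other"),
                               n_runs = 50, seed = 3)
  expect_identical(nrow(sel$run_log), 50L)
  expect_true(sel$run_log$pass[sel$run])
  expect_true(sel$metrics$slope_ci[1] <= 1 && 1 <= sel$metrics$slope_ci[2])
  expect_identical(as.character(sel$model$rpart$frame$var[1]), "technology")
  sel2 <- repeated_split_select(d, "y", c("technology", "other"),
                                n_runs = 50, seed = 3)
  expect_identical(sel$run, sel2$run)
  expect_identical(sel$run_log, sel2$run_log)
})

test_that("pure-noise responses are not certified as predictive", {
  set.seed(77)
  n <- 80
  d <- tibble::tibble(
    technology = factor(sample(c("non", "semi", "technified"), n, TRUE)),
    other = factor(sample(c("x", "y"), n, TRUE)),
    y = rnorm(n)
  )
  out <- tryCatch(
    repeated_split_select(d, "y", c("technology", "other"),
                          n_runs = 50, seed = 5),
    acarecon_no_model = function(e) e
  )
  if (rlang::is_condition(out)) {
    expect_s3_class(out, "acarecon_no_model")
    expect_identical(nrow(out$run_log), 50L)
  } else {
    expect_lt(out$metrics$r2_test, 0.3)
  }
})

test_that("AUC equals the pairwise concordance probability", {
  expect_equal(auc_roc(c(0.9, 0.8, 0.85, 0.7), c(TRUE, TRUE, FALSE, FALSE))$auc,
               0.75)
  expect_equal(auc_roc(c(1, 2, 3, 10, 11, 12), rep(c(FALSE, TRUE), each = 3))$auc,
               1)
  expect_equal(auc_roc(rep(0.5, 10), rep(c(FALSE, TRUE), 5))$auc, 0.5)
  set.seed(88)
  for (rep in 1:50) {
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), 30, replace = TRUE))
    scores <- round(rnorm(32), 1)  # rounding forces ties
    expect_equal(auc_roc(scores, labels)$auc, auc_oracle(scores, labels),
                 tolerance = 1e-12)
  }
  ci <- auc_roc(c(0.9, 0.8, 0.85, 0.7), c(TRUE, TRUE, FALSE, FALSE))
  expect_true(ci$ci_low <= ci$auc && ci$auc <= ci$ci_high)
  expect_error(auc_roc(1:4, rep(TRUE, 4)), class = "acarecon_input_error")
})

test_that("node profiles conserve farms and reproduce leaf means", {
  d <- two_group_data()
  fit <- fit_cart(d, "y", "technology")
  prof <- profile_nodes(fit, d, attributes = "technology")
  expect_identical(sum(prof$n), nrow(d))
  expect_equal(sum(prof$pct), 100)
  expect_equal(sort(prof$avg), c(0, 10))
  comp <- prof$composition[[which(prof$avg == 10)]]
  expect_equal(unname(comp[["technology_technified_pct"]]), 100)

  # a single-node tree profiles the whole sample
  const <- tibble::tibble(technology = factor(rep("non", 30)), y = rnorm(30))
  cfit <- fit_cart(const, "y", "technology")
  cprof <- profile_nodes(cfit, const)
  expect_identical(nrow(cprof), 1L)
  expect_equal(cprof$avg, mean(const$y))
  expect_true(cprof$ci_low <= cprof$avg && cprof$avg <= cprof$ci_high)
})

test_that("classification trees profile the infested proportion per leaf", {
  farms <- generate_cohort(synth_config(seed = 16))$farms
  td <- tree_data(farms)
  spec <- tree_spec("infestation")
  fit <- fit_cart(td, spec$response, spec$predictors, task = spec$task)
  prof <- profile_nodes(fit, td)
  expect_identical(sum(prof$n), nrow(td))
  expect_true(all(prof$avg >= 0 & prof$avg <= 1))
  expect_true(all(prof$ci_low >= 0 & prof$ci_high <= 1))
  pred <- predict_tree(fit, td)
  for (i in seq_len(nrow(prof))) {
    expect_true(any(abs(pred - prof$avg[i]) < 1e-9))
  }
})
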
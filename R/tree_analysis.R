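# CART trees for the infestation classifier and the four acaricide-cost
# regression models, plus the repeated 75/25-split model selection: fit on
# the training split, screen the test predictions for concordance (slope CI
# covering 1 and intercept CI covering 0) and Bland-Altman agreement, then
# keep the passing run with minimum test MSE.

#' Tree growth and pruning controls
#'
#' Defaults sized to give 5-7 terminal nodes on cohorts of about a hundred
#' farms: minimum 20 rows to attempt a split, minimum 7 rows per leaf, depth
#' at most 5, and pruning of splits improving relative error by less than the
#' complexity threshold.
#'
#' @param min_split Minimum rows in a node for a split attempt (default 20).
#' @param min_leaf Minimum rows in any leaf (default 7).
#' @param max_depth Maximum tree depth (default 5).
#' @param complexity Complexity (cp) pruning threshold (default 0.01).
#' @return A list of class `tree_control`.
#' @export
tree_control <- function(min_split = 20, min_leaf = 7, max_depth = 5,
                         complexity = 0.01) {
  vals <- c(min_split, min_leaf, max_depth, complexity)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("tree control values must be positive", class = "acarecon_input_error")
  }
  structure(list(min_split = min_split, min_leaf = min_leaf,
                 max_depth = max_depth, complexity = complexity),
            class = "tree_control")
}

#' Fit a CART model
#'
#' Greedy binary recursive partitioning: regression splits maximise variance
#' reduction, classification splits minimise Gini impurity; growth stops at
#' the [tree_control()] limits and weak splits are pruned at the complexity
#' threshold. A constant response yields a valid single-node tree.
#'
#' @param data A data frame with complete predictor columns.
#' @param response Name of the response column (numeric for regression, a
#'   two-level factor for classification).
#' @param predictors Character vector of predictor column names.
#' @param task `"auto"` (from the response type), `"regression"` or
#'   `"classification"`.
#' @param control A [tree_control()].
#' @return An object of class `cart_fit` wrapping the fitted partition with
#'   its metadata.
#' @export
fit_cart <- function(data, response, predictors,
                     task = c("auto", "regression", "classification"),
                     control = tree_control()) {
  task <- match.arg(task)
  if (nrow(data) == 0) abort("empty data", class = "acarecon_input_error")
  if (length(predictors) == 0) {
    abort("predictors must be non-empty", class = "acarecon_input_error")
  }
  cols <- c(response, predictors)
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(paste0("data is missing column(s): ", paste(missing, collapse = ", ")),
          class = "acarecon_schema_error")
  }
  if (!all(complete.cases(data[, cols]))) {
    abort("predictor and response values must be complete",
          class = "acarecon_input_error")
  }
  y <- data[[response]]
  if (task == "auto") {
    task <- if (is.numeric(y)) "regression" else "classification"
  }
  if (task == "classification") {
    if (!is.factor(y)) y <- factor(y)
    if (nlevels(droplevels(y)) > 2) {
      abort("classification supports two-level responses",
            class = "acarecon_input_error")
    }
    data[[response]] <- y
  }
  form <- stats::as.formula(
    paste(response, "~", paste(predictors, collapse = " + "))
  )
  fit <- rpart::rpart(
    form, data = data,
    method = if (task == "regression") "anova" else "class",
    control = rpart::rpart.control(
      minsplit = control$min_split, minbucket = control$min_leaf,
      maxdepth = control$max_depth, cp = control$complexity,
      xval = 0, maxcompete = 0, maxsurrogate = 0
    )
  )
  structure(
    list(rpart = fit, response = response, predictors = predictors,
         task = task, control = control, n_train = nrow(data),
         positive = if (task == "classification") levels(y)[nlevels(y)] else NULL),
    class = "cart_fit"
  )
}

#' @export
print.cart_fit <- function(x, ...) {
  cat("<cart_fit> ", x$task, " tree for '", x$response, "' (",
      sum(x$rpart$frame$var == "<leaf>"), " leaves, n = ", x$n_train, ")\n",
      sep = "")
  print(x$rpart)
  invisible(x)
}

# Primary-split row index (into fit$splits) for every frame row of an rpart
# object. Each splitting node stores 1 primary + ncompete + nsurrogate rows.
primary_split_index <- function(frame) {
  idx <- integer(nrow(frame))
  pos <- 1L
  for (i in seq_len(nrow(frame))) {
    if (frame$var[i] == "<leaf>") next
    idx[i] <- pos
    pos <- pos + 1L + frame$ncompete[i] + frame$nsurrogate[i]
  }
  idx
}

# Route rows of `newdata` down an rpart tree, returning the frame row index
# of the leaf each row lands in (same convention as fit$where). Missing
# values and unseen categorical levels are sent to the majority side (the
# child with more training rows), with a warning for unseen levels.
route_tree <- function(fit, newdata) {
  frame <- fit$frame
  node_ids <- as.numeric(rownames(frame))
  prim <- primary_split_index(frame)
  xlev <- attr(fit, "xlevels")
  unseen <- character(0)

  leaf_of <- function(j) {
    row <- 1L
    while (frame$var[row] != "<leaf>") {
      var <- as.character(frame$var[row])
      s <- fit$splits[prim[row], ]
      val <- newdata[[var]][j]
      go_left <- NA
      if (abs(s[["ncat"]]) == 1) {              # continuous split
        v <- suppressWarnings(as.numeric(val))
        if (is.finite(v)) {
          go_left <- if (s[["ncat"]] < 0) v < s[["index"]] else v >= s[["index"]]
        }
      } else {                                   # categorical split
        lev <- match(as.character(val), xlev[[var]])
        if (!is.na(lev)) {
          side <- fit$csplit[s[["index"]], lev]
          if (side == 1) go_left <- TRUE
          if (side == 3) go_left <- FALSE
        } else if (!is.na(val)) {
          unseen <<- union(unseen, paste0(var, "=", as.character(val)))
        }
      }
      left_row <- match(2 * node_ids[row], node_ids)
      right_row <- match(2 * node_ids[row] + 1, node_ids)
      if (is.na(go_left)) {                      # majority-side routing
        go_left <- frame$n[left_row] >= frame$n[right_row]
      }
      row <- if (go_left) left_row else right_row
    }
    row
  }

  out <- vapply(seq_len(nrow(newdata)), leaf_of, integer(1))
  if (length(unseen) > 0) {
    warn(paste0("unseen level(s) routed to the majority side: ",
                paste(unseen, collapse = ", ")))
  }
  out
}

leaf_values <- function(model) {
  fit <- model$rpart
  if (model$task == "regression") {
    fit$frame$yval
  } else {
    nclass <- length(attr(fit, "ylevels"))
    probs <- fit$frame$yval2[, 1 + nclass + seq_len(nclass), drop = FALSE]
    probs[, match(model$positive, attr(fit, "ylevels"))]
  }
}

#' Predict from a fitted CART model
#'
#' Returns the leaf prediction per row: the leaf mean for regression, the
#' leaf proportion of the positive class for classification. Rows with an
#' unseen categorical level at a split are routed to the majority side with
#' a warning.
#'
#' @param model A `cart_fit`.
#' @param newdata A data frame with the split variables.
#' @return A numeric vector of predictions.
#' @export
predict_tree <- function(model, newdata) {
  where <- route_tree(model$rpart, newdata)
  leaf_values(model)[where]
}

#' Concordance screen of observed against predicted values
#'
#' Least-squares regression of observed on predicted; the model passes when
#' the slope confidence interval contains 1 and the intercept interval
#' contains 0 at level `1 - alpha`. Constant predictions make the screen
#' degenerate (automatic fail).
#'
#' @param pred Predicted values (>= 3 pairs).
#' @param obs Observed values.
#' @param alpha Screening level (default 0.05, i.e. 95% intervals).
#' @return A list with `slope`, `intercept`, `slope_ci`, `intercept_ci`,
#'   `pass`, `degenerate`.
#' @export
concordance_screen <- function(pred, obs, alpha = 0.05) {
  if (length(pred) != length(obs)) {
    abort("pred and obs must have equal length", class = "acarecon_input_error")
  }
  if (length(pred) < 3) {
    abort("at least 3 pairs are required", class = "acarecon_input_error")
  }
  if (sd(pred) == 0) {
    return(list(slope = NA_real_, intercept = NA_real_,
                slope_ci = c(NA_real_, NA_real_),
                intercept_ci = c(NA_real_, NA_real_),
                pass = FALSE, degenerate = TRUE))
  }
  fit <- lm(obs ~ pred)
  res_ss <- sum(stats::residuals(fit)^2)
  scale_ss <- sum((obs - mean(obs))^2) + 1
  if (res_ss < 1e-12 * scale_ss) {
    # an exact linear relation defeats confint: zero-width intervals
    slope <- unname(coef(fit)["pred"])
    intercept <- unname(coef(fit)["(Intercept)"])
    tol <- 1e-8
    return(list(slope = slope, intercept = intercept,
                slope_ci = c(slope, slope),
                intercept_ci = c(intercept, intercept),
                pass = abs(slope - 1) < tol && abs(intercept) < tol,
                degenerate = FALSE))
  }
  ci <- suppressWarnings(confint(fit, level = 1 - alpha))
  slope_ci <- ci["pred", ]
  intercept_ci <- ci["(Intercept)", ]
  pass <- slope_ci[1] <= 1 && 1 <= slope_ci[2] &&
    intercept_ci[1] <= 0 && 0 <= intercept_ci[2]
  list(slope = unname(coef(fit)["pred"]),
       intercept = unname(coef(fit)["(Intercept)"]),
       slope_ci = unname(slope_ci), intercept_ci = unname(intercept_ci),
       pass = isTRUE(pass), degenerate = FALSE)
}

#' Bland-Altman agreement between predictions and observations
#'
#' Differences `d = pred - obs`: mean difference, limits of agreement
#' `mean(d) +/- 1.96 sd(d)`, and a one-sample t-test of mean zero. With
#' zero-variance differences the p-value is 1 when the mean is 0 (perfect
#' agreement) and 0 otherwise (a pure shift).
#'
#' @param pred,obs Equal-length numeric vectors (>= 2 pairs).
#' @param alpha Test level stored for reference (default 0.05).
#' @return A list with `mean_diff`, `sd_diff`, `loa_low`, `loa_high`,
#'   `p_diff_zero`, `alpha`.
#' @export
bland_altman <- function(pred, obs, alpha = 0.05) {
  if (length(pred) != length(obs)) {
    abort("pred and obs must have equal length", class = "acarecon_input_error")
  }
  if (length(pred) < 2) {
    abort("at least 2 pairs are required", class = "acarecon_input_error")
  }
  d <- pred - obs
  m <- mean(d)
  s <- sd(d)
  if (s <= 1e-12 * (abs(m) + 1)) {
    # numerically constant differences: perfect agreement or a pure shift
    s <- 0
    p <- if (abs(m) < 1e-12) 1 else 0
  } else {
    p <- t.test(d)$p.value
  }
  list(mean_diff = m, sd_diff = s, loa_low = m - 1.96 * s,
       loa_high = m + 1.96 * s, p_diff_zero = p, alpha = alpha)
}

r_squared <- function(obs, pred) {
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) return(NA_real_)
  1 - sum((obs - pred)^2) / sst
}

#' Repeated train/test split model selection
#'
#' Runs the split-fit-screen cycle `n_runs` times: draw a random
#' `train_frac` training split, fit the tree on it, predict the held-out
#' rows, apply the [concordance_screen()] and [bland_altman()] agreement
#' checks on the test predictions, and among the runs passing both retain
#' the one with minimum test mean squared error. Deterministic given `seed`.
#'
#' @inheritParams fit_cart
#' @param n_runs Number of random splits (default 100).
#' @param train_frac Training fraction (default 0.75; the test split must
#'   keep at least 10 rows).
#' @param seed Seed for the split draws.
#' @param alpha Level for the concordance screen and the Bland-Altman test.
#' @return A list with `model` (the selected `cart_fit`), `run` (index of the
#'   selected run), `metrics` (train/test R2 and MSE, slope/intercept with
#'   CIs, Bland-Altman stats, and AUC for classification) and `run_log` (one
#'   row per run). If no run passes both screens, an error of class
#'   `acarecon_no_model` carrying the run log is raised.
#' @export
repeated_split_select <- function(data, response, predictors,
                                  task = c("auto", "regression", "classification"),
                                  n_runs = 100, train_frac = 0.75, seed = 1,
                                  alpha = 0.05, control = tree_control()) {
  task <- match.arg(task)
  n <- nrow(data)
  n_train <- round(train_frac * n)
  if (n - n_train < 10) {
    abort("the test split must keep at least 10 rows",
          class = "acarecon_input_error")
  }
  if (task == "auto") {
    task <- if (is.numeric(data[[response]])) "regression" else "classification"
  }
  obs_numeric <- function(y, positive) {
    if (task == "regression") as.numeric(y) else as.numeric(y == positive)
  }

  set.seed(seed)
  log_rows <- vector("list", n_runs)
  best <- NULL
  for (run in seq_len(n_runs)) {
    idx <- sample.int(n, n_train)
    fit <- fit_cart(data[idx, ], response, predictors, task = task,
                    control = control)
    pred_test <- predict_tree(fit, data[-idx, ])
    pred_train <- predict_tree(fit, data[idx, ])
    y_test <- obs_numeric(data[[response]][-idx], fit$positive)
    y_train <- obs_numeric(data[[response]][idx], fit$positive)

    screen <- concordance_screen(pred_test, y_test, alpha)
    ba <- bland_altman(pred_test, y_test, alpha)
    mse_test <- mean((y_test - pred_test)^2)
    mse_train <- mean((y_train - pred_train)^2)
    auc <- if (task == "classification" && length(unique(y_test)) == 2) {
      auc_roc(pred_test, y_test == 1)$auc
    } else {
      NA_real_
    }
    pass <- screen$pass && ba$p_diff_zero > alpha
    log_rows[[run]] <- tibble::tibble(
      run = run, pass = pass,
      mse_train = mse_train, mse_test = mse_test,
      r2_train = r_squared(y_train, pred_train),
      r2_test = r_squared(y_test, pred_test),
      slope = screen$slope, intercept = screen$intercept,
      ba_mean_diff = ba$mean_diff, ba_p = ba$p_diff_zero,
      auc_test = auc, n_leaves = sum(fit$rpart$frame$var == "<leaf>")
    )
    if (pass && (is.null(best) || mse_test < best$mse_test)) {
      best <- list(model = fit, run = run, mse_test = mse_test,
                   screen = screen, ba = ba, auc = auc,
                   mse_train = mse_train,
                   r2_train = r_squared(y_train, pred_train),
                   r2_test = r_squared(y_test, pred_test))
    }
  }
  run_log <- dplyr::bind_rows(log_rows)
  if (is.null(best)) {
    abort("no run passed the concordance and agreement screens",
          class = "acarecon_no_model", run_log = run_log)
  }
  metrics <- list(
    r2_train = best$r2_train, r2_test = best$r2_test,
    mse_train = best$mse_train, mse_test = best$mse_test,
    slope = best$screen$slope, intercept = best$screen$intercept,
    slope_ci = best$screen$slope_ci, intercept_ci = best$screen$intercept_ci,
    bland_altman = best$ba, auc = best$auc
  )
  list(model = best$model, run = best$run, metrics = metrics,
       run_log = run_log)
}

#' AUC of the ROC curve with confidence interval
#'
#' AUC as the Mann-Whitney concordance probability (ties counted 1/2), with
#' a 95% interval by the DeLong variance (default) or by bootstrap.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Logical (or two-level) class labels; both classes must be
#'   present.
#' @param ci_method `"delong"` or `"bootstrap"`.
#' @param boot_n Bootstrap resamples (default 2000).
#' @return A list with `auc`, `ci_low`, `ci_high`, `ci_method`.
#' @export
#' @examples
#' auc_roc(c(0.9, 0.8, 0.85, 0.7), c(TRUE, TRUE, FALSE, FALSE))  # 0.75
auc_roc <- function(scores, labels, ci_method = c("delong", "bootstrap"),
                    boot_n = 2000) {
  ci_method <- match.arg(ci_method)
  labels <- if (is.logical(labels)) labels else {
    f <- factor(labels)
    if (nlevels(f) != 2) {
      abort("labels must have exactly two classes", class = "acarecon_input_error")
    }
    f == levels(f)[2]
  }
  if (length(unique(labels)) < 2) {
    abort("both classes must be present", class = "acarecon_input_error")
  }
  roc <- pROC::roc(response = labels, predictor = as.numeric(scores),
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  ci <- suppressWarnings(pROC::ci.auc(
    roc,
    method = if (ci_method == "delong") "delong" else "bootstrap",
    boot.n = boot_n, progress = "none"
  ))
  list(auc = as.numeric(pROC::auc(roc)), ci_low = as.numeric(ci[1]),
       ci_high = as.numeric(ci[3]), ci_method = ci_method)
}

#' Profile the terminal nodes of a fitted tree
#'
#' Routes `data` down the tree and describes every terminal node: size and
#' share of farms, the mean response ("Avg") with a 95% interval (t-based
#' for regression, exact binomial for classification), and the composition
#' of the node over the requested attribute columns (percentage per level
#' for categorical/logical attributes, mean for numeric ones).
#'
#' @param model A `cart_fit`.
#' @param data A data frame holding the response, split variables and
#'   attribute columns (typically the training data).
#' @param attributes Character vector of composition columns (default none).
#' @return A tibble with one row per terminal node: `node`, `n`, `pct`,
#'   `avg`, `ci_low`, `ci_high`, and a `composition` list column of named
#'   percentage/mean vectors.
#' @export
profile_nodes <- function(model, data, attributes = character(0)) {
  where <- route_tree(model$rpart, data)
  frame <- model$rpart$frame
  node_ids <- as.numeric(rownames(frame))
  leaves <- sort(unique(where))
  y_all <- if (model$task == "regression") {
    as.numeric(data[[model$response]])
  } else {
    as.numeric(data[[model$response]] == model$positive)
  }

  purrr::map_dfr(leaves, function(leaf_row) {
    in_node <- where == leaf_row
    y <- y_all[in_node]
    n <- sum(in_node)
    avg <- mean(y)
    if (model$task == "regression") {
      se <- if (n > 1) sd(y) / sqrt(n) else NA_real_
      half <- if (n > 1) qt(0.975, n - 1) * se else NA_real_
      ci <- c(avg - half, avg + half)
    } else {
      ci <- binom.test(sum(y), n)$conf.int
    }
    comp <- list()
    for (a in attributes) {
      v <- data[[a]][in_node]
      if (is.numeric(v)) {
        comp[[paste0(a, "_mean")]] <- mean(v)
      } else {
        tab <- 100 * table(as.character(v)) / n
        for (lv in names(tab)) comp[[paste0(a, "_", lv, "_pct")]] <- as.numeric(tab[[lv]])
      }
    }
    tibble::tibble(
      node = node_ids[leaf_row], n = n, pct = 100 * n / nrow(data),
      avg = avg, ci_low = ci[1], ci_high = ci[2],
      composition = list(unlist(comp) %||% numeric(0))
    )
  })
}

#' Assemble the decision-tree analysis frame from farm records
#'
#' Builds the predictor factors used by the trees (technology, herd-size
#' class at 20 and 70 animals, external paddocks, manual tick removal, study
#' area, high infestation, and the three resistance flags) together with the
#' four economic responses.
#'
#' @param farms A farm-record tibble.
#' @param metrics Optional precomputed [acaricide_cost_metrics()].
#' @param profiles Optional precomputed [resistance_profiles()].
#' @return A tibble ready for [fit_cart()] / [repeated_split_select()].
#' @export
tree_data <- function(farms, metrics = NULL, profiles = NULL) {
  metrics <- metrics %||% acaricide_cost_metrics(farms)
  profiles <- profiles %||% resistance_profiles(farms)
  yn <- function(x) factor(ifelse(x, "yes", "no"), levels = c("no", "yes"))
  tibble::tibble(
    farm_id = farms$farm_id,
    technology = factor(farms$technology, levels = c("non", "semi", "technified")),
    herd_size_class = cut(farms$herd_size_adults, c(0, 20, 70, Inf),
                          labels = c("1-20", "21-70", ">71")),
    external_paddocks = yn(farms$external_paddocks),
    manual_tick_removal = yn(farms$manual_tick_removal),
    zone = factor(farms$zone, levels = c("area1_quijos", "area2_pichincha")),
    high_infestation = yn(farms$high_infestation),
    am_resistant = yn(profiles$amitraz_resistant),
    cy_resistant = yn(profiles$cypermethrin_resistant),
    iv_resistant = yn(profiles$ivermectin_resistant),
    model1_pct = metrics$model1_pct_of_tc,
    model2_usd = metrics$model2_usd_per_adult,
    model3_pct = metrics$model3_pct_of_e6,
    model4_pct = metrics$model4_pct_of_sanitary
  )
}

#' Predictor sets for the five tree models
#'
#' Models 1-4 use the management predictors (technology, herd size class,
#' external paddocks, manual tick removal, study area, infestation and the
#' three resistance flags); the infestation classifier uses technology and
#' the resistance flags only.
#'
#' @param model One of `"model1"`, `"model2"`, `"model3"`, `"model4"`,
#'   `"infestation"`.
#' @return A list with `response`, `predictors` and `task`.
#' @export
tree_spec <- function(model = c("model1", "model2", "model3", "model4",
                                "infestation")) {
  model <- match.arg(model)
  mgmt <- c("technology", "herd_size_class", "external_paddocks",
            "manual_tick_removal", "zone", "high_infestation",
            "am_resistant", "cy_resistant", "iv_resistant")
  if (model == "infestation") {
    list(response = "high_infestation",
         predictors = c("technology", "am_resistant", "cy_resistant",
                        "iv_resistant"),
         task = "classification")
  } else {
    list(response = c(model1 = "model1_pct", model2 = "model2_usd",
                      model3 = "model3_pct", model4 = "model4_pct")[[model]],
         predictors = mgmt, task = "regression")
  }
}
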
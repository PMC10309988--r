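# Farm typology: the twelve management variables are recoded to small ordinal
# integer scales, k-means is run across k with multiple restarts, and the
# number of groups is chosen by the elbow of the within-cluster
# sum-of-squares curve (maximum discrete second difference).

#' Default ordinal recoding map for the typology variables
#'
#' One entry per typology variable. Categorical variables map each level to
#' an integer code in its natural order; numeric variables are binned
#' (farm area into the small/medium/large classes at 20 and 45 ha, owner
#' hours at 2 and 4 h/day, milk price at the 0.42 USD/litre regulatory
#' reference).
#'
#' @return A named list of recoding specs, each with a `source` column name
#'   and either `codes` (named integer vector) or `breaks` + `codes`.
#' @export
default_ordinal_map <- function() {
  lgl <- c("FALSE" = 0L, "TRUE" = 1L)
  list(
    technology = list(source = "technology",
                      codes = c(non = 0L, semi = 1L, technified = 2L)),
    veterinary_control = list(source = "veterinary_control", codes = lgl),
    farm_size = list(source = "farm_area_ha",
                     breaks = c(0, 20, 45, Inf), codes = 0:2),
    external_paddocks = list(source = "external_paddocks", codes = lgl),
    education = list(source = "education",
                     codes = c(primary = 0L, high_school = 1L, university = 2L)),
    owner_hours = list(source = "owner_hours_per_day",
                       breaks = c(-Inf, 2, 4, Inf), codes = 0:2),
    milk_destination = list(source = "milk_destination",
                            codes = c(local = 0L, cheese = 1L, regional = 2L)),
    milk_price = list(source = "milk_price",
                      breaks = c(-Inf, 0.42, Inf), codes = 0:1),
    permanent_paid_labor = list(source = "permanent_paid_labor", codes = lgl),
    crops_for_sale = list(source = "crops_for_sale", codes = lgl),
    concentrate_supplementation = list(source = "concentrate_supplementation",
                                       codes = lgl),
    grass_cut = list(source = "grass_cut", codes = lgl)
  )
}

#' Recode farm records into an ordinal matrix
#'
#' Applies [default_ordinal_map()] (or a user map of the same shape) to the
#' farm table, producing a deterministic integer matrix with one row per farm
#' and one column per typology variable; the map is attached as the
#' `"mapping"` attribute. An unmapped categorical level raises an error
#' naming the farm and the variable.
#'
#' @param farms A farm-record tibble.
#' @param mapping A recoding map (see [default_ordinal_map()]).
#' @param scale `"none"` (default; all codes share small ranges) or
#'   `"z-score"`.
#' @return A numeric matrix with farms as (named) rows.
#' @export
ordinal_recode <- function(farms, mapping = default_ordinal_map(),
                           scale = c("none", "z-score")) {
  scale <- match.arg(scale)
  n <- nrow(farms)
  out <- matrix(NA_real_, nrow = n, ncol = length(mapping),
                dimnames = list(farms$farm_id, names(mapping)))
  for (var in names(mapping)) {
    spec <- mapping[[var]]
    src <- farms[[spec$source]]
    if (is.null(src)) {
      abort(paste0("typology variable '", var, "' needs missing column '",
                   spec$source, "'"), class = "acarecon_schema_error")
    }
    if (!is.null(spec$breaks)) {
      bins <- cut(as.numeric(src), breaks = spec$breaks, right = TRUE,
                  include.lowest = TRUE, labels = FALSE)
      code <- spec$codes[bins]
    } else {
      key <- as.character(src)
      code <- spec$codes[key]
      bad <- which(is.na(code) & !is.na(key))
      if (length(bad) > 0) {
        abort(paste0("unmapped level '", key[bad[1]], "' of variable '", var,
                     "' for farm ", farms$farm_id[bad[1]]),
              class = "acarecon_recode_error")
      }
    }
    if (anyNA(code)) {
      abort(paste0("variable '", var, "' has missing values after recoding"),
            class = "acarecon_recode_error")
    }
    out[, var] <- as.numeric(code)
  }
  if (scale == "z-score") {
    out <- apply(out, 2, function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0)
  }
  attr(out, "mapping") <- mapping
  out
}

total_ss <- function(mat) {
  sum(sweep(mat, 2, colMeans(mat))^2)
}

best_kmeans <- function(mat, k, restarts) {
  n_distinct <- nrow(unique(as.data.frame(mat)))
  if (k >= n_distinct) {
    # every distinct point can hold its own centre
    centre_id <- match(
      do.call(paste, as.data.frame(mat)),
      do.call(paste, as.data.frame(unique(as.data.frame(mat))))
    )
    return(list(cluster = centre_id, tot.withinss = 0,
                centers = unique(as.data.frame(mat))))
  }
  # heavily tied ordinal codes make Hartigan-Wong grumble about its
  # Quick-TRANSfer stage; the best-of-restarts result is still valid
  withCallingHandlers(
    kmeans(mat, centers = k, nstart = restarts, iter.max = 100),
    warning = function(w) {
      if (grepl("Quick-TRANSfer|did not converge", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

#' Within-cluster sum-of-squares curve over k
#'
#' For each `k` in `1:k_max`, the minimum total within-cluster sum of squares
#' over `restarts` seeded initialisations (`k = 1` is the closed-form total
#' sum of squares about the grand centroid).
#'
#' @param mat Ordinal matrix from [ordinal_recode()].
#' @param k_max Largest k (must be < number of farms; default 10).
#' @param restarts Random initialisations per k (default 25).
#' @param seed Seed for the initialisations.
#' @return A tibble with columns `k` and `wss`.
#' @export
wss_curve <- function(mat, k_max = 10, restarts = 25, seed = 1) {
  if (k_max >= nrow(mat)) {
    abort("k_max must be smaller than the number of farms",
          class = "acarecon_input_error")
  }
  set.seed(seed)
  wss <- vapply(seq_len(k_max), function(k) {
    if (k == 1) total_ss(mat) else best_kmeans(mat, k, restarts)$tot.withinss
  }, numeric(1))
  tibble::tibble(k = seq_len(k_max), wss = wss)
}

#' Choose the number of clusters by the elbow rule
#'
#' Selects the k where the within-cluster sum-of-squares curve bends
#' hardest, measured by the discrete second difference of the curve. By
#' default the curvature is taken on the log scale,
#' `log WSS(k-1) - 2 log WSS(k) + log WSS(k+1)`, i.e. the ratio of
#' successive proportional drops; this keeps the rule invariant to the
#' overall scale of the data and stops one unusually distant group from
#' pulling the elbow to k = 2 when several comparable groups exist.
#' `method = "raw"` uses the plain second difference
#' `WSS(k-1) - 2 WSS(k) + WSS(k+1)` instead (also the fallback when the
#' curve touches zero, where the log is undefined).
#'
#' A near-linear curve has no clear elbow: the choice is flagged
#' low-confidence when the maximum curvature falls below a 10% threshold
#' (of `WSS(1)` for the raw rule; a successive-drop ratio of 1.1 for the
#' log rule). A curve with a genuinely increasing segment is invalid.
#'
#' @param curve A tibble from [wss_curve()] (columns `k`, `wss`) over at
#'   least 3 values of k.
#' @param method `"log"` (default) or `"raw"` curvature.
#' @return A list with `k`, `second_differences` (tibble), and
#'   `low_confidence` (logical).
#' @export
#' @examples
#' choose_k_elbow(tibble::tibble(k = 1:5, wss = c(100, 40, 35, 33, 32)))$k
choose_k_elbow <- function(curve, method = c("log", "raw")) {
  method <- match.arg(method)
  k <- curve$k
  wss <- curve$wss
  if (length(k) < 3) {
    abort("the elbow rule needs the curve over at least 3 values of k",
          class = "acarecon_input_error")
  }
  tol <- 1e-8 * max(wss[1], 1)
  if (any(diff(wss) > tol)) {
    abort("invalid curve: within-cluster SS increases with k",
          class = "acarecon_input_error")
  }
  if (method == "log" && any(wss <= 0)) method <- "raw"
  inner <- 2:(length(k) - 1)
  f <- if (method == "log") log(wss) else wss
  d2 <- f[inner - 1] - 2 * f[inner] + f[inner + 1]
  threshold <- if (method == "log") log(1.1) else 0.10 * wss[1]
  best <- inner[which.max(d2)]
  list(
    k = k[best],
    second_differences = tibble::tibble(k = k[inner], second_difference = d2),
    low_confidence = max(d2) < threshold,
    method = method
  )
}

#' Cluster farms with k-means
#'
#' Runs k-means (best of `restarts` seeded initialisations by total
#' within-cluster sum of squares) on the ordinal matrix.
#'
#' @inheritParams wss_curve
#' @param k Number of clusters (`1 <= k <` number of farms).
#' @return An object of class `typology_result`: list with `k`,
#'   `assignments` (integer per farm, named by farm id), `wss`, `centers`
#'   and `seed`.
#' @export
cluster_farms <- function(mat, k, restarts = 25, seed = 1) {
  if (k < 1 || k >= nrow(mat)) {
    abort("k must satisfy 1 <= k < number of farms",
          class = "acarecon_input_error")
  }
  set.seed(seed)
  if (k == 1) {
    assignments <- rep(1L, nrow(mat))
    wss <- total_ss(mat)
    centers <- matrix(colMeans(mat), nrow = 1,
                      dimnames = list(NULL, colnames(mat)))
  } else {
    km <- best_kmeans(mat, k, restarts)
    assignments <- as.integer(km$cluster)
    wss <- km$tot.withinss
    centers <- km$centers
  }
  names(assignments) <- rownames(mat)
  structure(list(k = as.integer(k), assignments = assignments, wss = wss,
                 centers = centers, seed = seed),
            class = "typology_result")
}

#' @export
print.typology_result <- function(x, ...) {
  cat("<typology_result> k =", x$k, " WSS =", format(x$wss), "\n")
  print(table(cluster = x$assignments))
  invisible(x)
}

#' Profile clusters by modal and mean attributes
#'
#' Per cluster: the modal category of every categorical/logical typology
#' variable, the mean of the numeric ones, the cluster size and its share of
#' all farms (shares sum to 100).
#'
#' @param farms A farm-record tibble.
#' @param assignments Cluster id per farm (from [cluster_farms()] or latent
#'   truth labels).
#' @return A tibble with one row per cluster.
#' @export
profile_clusters <- function(farms, assignments) {
  if (length(assignments) != nrow(farms)) {
    abort("assignments must cover all records", class = "acarecon_input_error")
  }
  modal <- function(x) names(sort(table(as.character(x)), decreasing = TRUE))[1]
  farms |>
    dplyr::mutate(.cluster = as.integer(assignments)) |>
    dplyr::group_by(.data$.cluster) |>
    dplyr::summarise(
      n = dplyr::n(),
      share_pct = 100 * dplyr::n() / nrow(farms),
      technology = modal(.data$technology),
      veterinary_control = modal(.data$veterinary_control),
      external_paddocks = modal(.data$external_paddocks),
      permanent_paid_labor = modal(.data$permanent_paid_labor),
      crops_for_sale = modal(.data$crops_for_sale),
      concentrate_supplementation = modal(.data$concentrate_supplementation),
      grass_cut = modal(.data$grass_cut),
      milk_destination = modal(.data$milk_destination),
      education = modal(.data$education),
      farm_area_ha = mean(.data$farm_area_ha),
      owner_hours_per_day = mean(.data$owner_hours_per_day),
      milk_price = mean(.data$milk_price),
      .groups = "drop"
    ) |>
    dplyr::rename(cluster = ".cluster")
}
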
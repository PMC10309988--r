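# Independent oracles used across the suite, kept free of the package's own
# computational paths.

# Two-sided Fisher exact p by full hypergeometric enumeration over all 2x2
# tables with the observed margins (probability-mass rule).
fisher_oracle <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  a_range <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(a_range, function(a) dhyper(a, r1, r2, c1), numeric(1))
  p_obs <- dhyper(m[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# AUC by enumeration of all positive/negative pairs, ties counted 1/2.
auc_oracle <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  grid <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(grid)
}

# Adjusted Rand index from the contingency table (chance-corrected).
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  sij <- sum(choose(tab, 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Best binary partition of a categorical predictor by exhaustive search:
# maximises the between-group sum of squares of a numeric response.
best_split_oracle <- function(x, y) {
  levs <- levels(factor(x))
  best <- NULL
  for (mask in 1:(2^length(levs) - 2)) {
    left <- levs[as.logical(bitwAnd(mask, 2^(seq_along(levs) - 1)))]
    in_left <- x %in% left
    if (!any(in_left) || all(in_left)) next
    ssb <- sum(in_left) * (mean(y[in_left]) - mean(y))^2 +
      sum(!in_left) * (mean(y[!in_left]) - mean(y))^2
    if (is.null(best) || ssb > best$ssb + 1e-12) {
      best <- list(left = sort(left), ssb = ssb)
    }
  }
  best
}

# A single fully valid hand-built farm record (one-row tibble).
make_farm <- function(...) {
  base <- list(
    farm_id = "T001", zone = "area1_quijos", technology = "non",
    herd_size_adults = 12L, cows_in_production = 8L, milking_type = "manual",
    farm_area_ha = 10, external_paddocks = TRUE, manual_tick_removal = FALSE,
    veterinary_control = TRUE, education = "primary",
    owner_hours_per_day = 3, milk_price = 0.37,
    daily_litres_dry = 10, daily_litres_rainy = 12,
    milk_destination = "local", permanent_paid_labor = FALSE,
    crops_for_sale = FALSE, concentrate_supplementation = TRUE,
    grass_cut = FALSE, insemination_by_professional = FALSE,
    high_infestation = FALSE, treatment_interval_days = 21,
    e1 = 1000, e2 = 150, e3 = 1200, e4 = 3000, e5_real = 50,
    e5_opportunity = 150, e6 = 700, e7 = 50, e8 = 30, e9 = 280, e10 = 120,
    e11 = 400, e12 = 290, e13 = 36, e14 = 150, e15 = 100, e16 = 50,
    e17 = 200, e18 = 90, r1 = 11000, r2 = 700, r3 = 1800,
    acaricide_drug_cost = 220, treatment_labor_cost = 60,
    hemo_repellent_drug_cost = 25,
    am_rep1_mortality = 90, am_rep2_mortality = 92, am_control_mortality = 3,
    cy_rep1_mortality = 50, cy_rep2_mortality = 55, cy_control_mortality = 2,
    iv_rep1_mortality = 95, iv_rep2_mortality = 97, iv_control_mortality = 4
  )
  tibble::as_tibble(utils::modifyList(base, list(...)))
}

# Random non-negative ledgers for the cost-identity properties.
random_ledgers <- function(n, seed = 1) {
  set.seed(seed)
  cols <- c(paste0("e", 1:4), "e5_real", "e5_opportunity", paste0("e", 6:18))
  out <- tibble::as_tibble(
    setNames(lapply(cols, function(c) runif(n, 0, 5000)), cols)
  )
  out
}

extract_rpart_split <- function(fit) {
  # levels sent left by the first (categorical) split of a cart_fit
  rp <- fit$rpart
  var <- as.character(rp$frame$var[1])
  s <- rp$splits[1, ]
  lev <- attr(rp, "xlevels")[[var]]
  sort(lev[rp$csplit[s[["index"]], seq_along(lev)] == 1])
}
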
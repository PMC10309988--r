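# Contingency analysis of high tick infestation against acaricide resistance:
# 2x2 tables (rows = infestation no/yes, columns = resistance no/yes),
# two-sided Fisher exact tests and Clopper-Pearson prevalence intervals.

#' Build a 2x2 contingency table from two flag vectors
#'
#' Rows are the first flag (`FALSE` then `TRUE`), columns the second; cell
#' percentages are of the total count.
#'
#' @param flag_rows,flag_cols Equal-length logical vectors (e.g. high
#'   infestation and a resistance flag).
#' @param row_label,col_label Labels for reporting.
#' @return An object of class `table2x2`: list with `counts` (2x2 integer
#'   matrix), `pct` (cell percentages of total), `n`, and the labels.
#' @export
#' @examples
#' crosstab(c(FALSE, FALSE, TRUE, TRUE), c(FALSE, TRUE, FALSE, TRUE))
crosstab <- function(flag_rows, flag_cols,
                     row_label = "high_infestation", col_label = "resistance") {
  if (length(flag_rows) != length(flag_cols)) {
    abort("flag vectors must have equal length", class = "acarecon_input_error")
  }
  counts <- table(factor(flag_rows, levels = c(FALSE, TRUE), labels = c("no", "yes")),
                  factor(flag_cols, levels = c(FALSE, TRUE), labels = c("no", "yes")))
  counts <- matrix(as.integer(counts), 2, 2,
                   dimnames = list(c("no", "yes"), c("no", "yes")))
  as_table2x2(counts, row_label, col_label)
}

#' Construct a `table2x2` from counts
#'
#' @param counts A 2x2 matrix of non-negative integer counts with rows =
#'   infestation (no, yes) and columns = resistance (no, yes).
#' @param row_label,col_label Labels for reporting.
#' @return A `table2x2`.
#' @export
as_table2x2 <- function(counts, row_label = "rows", col_label = "cols") {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2)) || any(counts < 0) ||
      any(counts != round(counts))) {
    abort("counts must be a 2x2 matrix of non-negative integers",
          class = "acarecon_input_error")
  }
  n <- sum(counts)
  if (n == 0) {
    abort("the table must contain at least one observation",
          class = "acarecon_input_error")
  }
  structure(list(counts = counts, pct = 100 * counts / n, n = n,
                 row_label = row_label, col_label = col_label),
            class = "table2x2")
}

#' @export
print.table2x2 <- function(x, ...) {
  cat("<table2x2> ", x$row_label, " x ", x$col_label, " (n = ", x$n, ")\n",
      sep = "")
  print(x$counts)
  invisible(x)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact p-value by the probability-mass rule: the sum of hypergeometric
#' probabilities, over all tables with the observed margins, of tables no
#' more probable than the observed one. A table with a zero margin is
#' degenerate and returns p = 1 with a warning.
#'
#' @param t A `table2x2` (or a 2x2 count matrix).
#' @return The two-sided p-value in (0, 1].
#' @export
#' @examples
#' fisher_exact_2x2(as_table2x2(matrix(c(28, 25, 29, 23), 2)))
fisher_exact_2x2 <- function(t) {
  if (!inherits(t, "table2x2")) t <- as_table2x2(t)
  counts <- t$counts
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    warn("degenerate table (zero margin); p = 1")
    return(1)
  }
  stats::fisher.test(counts)$p.value
}

#' Prevalence with exact binomial confidence interval
#'
#' @param flags Logical vector (at least one value).
#' @param conf_level Confidence level (default 0.95, Clopper-Pearson).
#' @return A tibble with `pct`, `lower_pct`, `upper_pct`, `n_true`, `n`.
#' @export
#' @examples
#' prevalence(rep(c(TRUE, FALSE), c(48, 57)))  # 45.71%
prevalence <- function(flags, conf_level = 0.95) {
  if (length(flags) == 0) {
    abort("at least one flag is required", class = "acarecon_input_error")
  }
  x <- sum(flags)
  n <- length(flags)
  ci <- binom.test(x, n, conf.level = conf_level)$conf.int
  tibble::tibble(pct = 100 * x / n, lower_pct = 100 * ci[1],
                 upper_pct = 100 * ci[2], n_true = as.integer(x),
                 n = as.integer(n))
}

#' Contingency tables for combined resistances
#'
#' Builds one `table2x2` (with its Fisher p-value) per combined-resistance
#' flag: amitraz & alpha-cypermethrin, amitraz & ivermectin,
#' alpha-cypermethrin & ivermectin, and the triple.
#'
#' @param profiles A tibble from [resistance_profiles()].
#' @param infestation Logical high-infestation flag per farm.
#' @return A named list (`am_cy`, `am_iv`, `cy_iv`, `am_cy_iv`) of lists with
#'   `table` and `p_value`.
#' @export
combined_tables <- function(profiles, infestation) {
  if (nrow(profiles) != length(infestation)) {
    abort("profiles and infestation must have equal length",
          class = "acarecon_input_error")
  }
  combos <- c("am_cy", "am_iv", "cy_iv", "am_cy_iv")
  out <- lapply(combos, function(cmb) {
    tab <- crosstab(infestation, profiles[[cmb]], col_label = cmb)
    list(table = tab, p_value = fisher_exact_2x2(tab))
  })
  setNames(out, combos)
}

#' Full association report of infestation against resistance
#'
#' One row per single acaricide and per combination: the 2x2 cell counts and
#' percentages of total, the Fisher exact p-value, and the resistance
#' prevalence.
#'
#' @inheritParams combined_tables
#' @return A tibble with columns `resistance`, cell counts
#'   `n_no_inf_no_res` .. `n_inf_res`, matching `pct_*` columns, `p_value`
#'   and `resistance_prev_pct`.
#' @export
association_report <- function(profiles, infestation) {
  flags <- list(
    amitraz = profiles$amitraz_resistant,
    cypermethrin = profiles$cypermethrin_resistant,
    ivermectin = profiles$ivermectin_resistant,
    am_cy = profiles$am_cy, am_iv = profiles$am_iv,
    cy_iv = profiles$cy_iv, am_cy_iv = profiles$am_cy_iv
  )
  purrr::map_dfr(names(flags), function(nm) {
    tab <- crosstab(infestation, flags[[nm]], col_label = nm)
    tibble::tibble(
      resistance = nm,
      n_no_inf_no_res = tab$counts[1, 1], n_no_inf_res = tab$counts[1, 2],
      n_inf_no_res = tab$counts[2, 1], n_inf_res = tab$counts[2, 2],
      pct_no_inf_no_res = tab$pct[1, 1], pct_no_inf_res = tab$pct[1, 2],
      pct_inf_no_res = tab$pct[2, 1], pct_inf_res = tab$pct[2, 2],
      p_value = fisher_exact_2x2(tab),
      resistance_prev_pct = prevalence(flags[[nm]])$pct
    )
  })
}
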
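#' Reconstruct a 2x2 exposure-by-outcome table from printed percentages
#'
#' Published summary tables often report only group sizes and exposure
#' percentages. This rebuilds the underlying counts: `a = round(n_case *
#' pct_case / 100)` exposed cases, `c = round(n_control * pct_control / 100)`
#' exposed controls, `b` and `d` by complement. Rounding is R's round half
#' to even (relevant because e.g. 19.8% of 364 is 72.07).
#'
#' @param n_case,n_control group sizes (non-negative integers).
#' @param pct_case,pct_control exposure percentages in `[0, 100]`.
#' @return object of class `two_by_two`: list with counts `a` (exposed
#'   cases), `b` (unexposed cases), `c` (exposed controls), `d` (unexposed
#'   controls).
#' @examples
#' reconstruct_table(364, 19.8, 3566, 12.9)  # living alone
#' @export
reconstruct_table <- function(n_case, pct_case, n_control, pct_control) {
  if (n_case < 0 || n_control < 0) stop("group sizes must be non-negative")
  if (any(c(pct_case, pct_control) < 0) || any(c(pct_case, pct_control) > 100))
    stop("percentages must lie in [0, 100]")
  a <- round(n_case * pct_case / 100)
  c_ <- round(n_control * pct_control / 100)
  two_by_two(a = a, b = n_case - a, c = c_, d = n_control - c_)
}

#' Construct a 2x2 table from counts
#'
#' @param a exposed cases; @param b unexposed cases; @param c exposed
#'   controls; @param d unexposed controls.
#' @return object of class `two_by_two`.
#' @export
two_by_two <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  structure(as.list(cells), class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("case", "control"),
                              c("exposed", "unexposed")))
  print(m)
  invisible(x)
}

#' Crude odds ratio with 95 percent Wald confidence interval
#'
#' `OR = ad / bc`; the interval is Woolf's, `exp(log OR +/- 1.96 *
#' sqrt(1/a + 1/b + 1/c + 1/d))`. All four cells must be positive; no
#' continuity correction is applied — a zero cell is an error naming the
#' cell, so the caller decides how to handle sparse tables.
#'
#' @param table a [two_by_two()] table.
#' @return a one-row `or_table` data.frame (`term = "exposure"`), unrounded;
#'   round only at presentation.
#' @examples
#' crude_or(reconstruct_table(364, 19.8, 3566, 12.9))
#' @export
crude_or <- function(table) {
  if (!inherits(table, "two_by_two")) stop("`table` must be a two_by_two")
  zero <- names(which(unlist(table) == 0))
  if (length(zero))
    stop("zero cell(s) in 2x2 table: ", paste(zero, collapse = ", "),
         "; crude OR undefined (no continuity correction applied)")
  or <- (table$a * table$d) / (table$b * table$c)
  se <- sqrt(1 / table$a + 1 / table$b + 1 / table$c + 1 / table$d)
  z <- stats::qnorm(0.975)
  or_table(term = "exposure", or = or, ci_low = exp(log(or) - z * se),
           ci_high = exp(log(or) + z * se))
}

#' Case-control group comparison by Welch's t-test
#'
#' Two-sample t-test with unequal variances, as used for the descriptive
#' case/control comparisons; binary indicators are treated as 0/1 numeric
#' (a t-test on proportions). The degenerate case of zero variance in both
#' groups returns `t = 0, p = 1` when the means are equal.
#'
#' @param case_values,control_values numeric vectors (length >= 2 each).
#' @return list with `t`, `p_value`, `df`, `mean_case`, `mean_control`.
#' @export
group_compare <- function(case_values, control_values) {
  case_values <- as.numeric(case_values)
  control_values <- as.numeric(control_values)
  if (length(case_values) < 2L || length(control_values) < 2L)
    stop("need at least 2 values per group")
  m1 <- mean(case_values); m2 <- mean(control_values)
  if (stats::sd(case_values) == 0 && stats::sd(control_values) == 0) {
    if (m1 == m2)
      return(list(t = 0, p_value = 1, df = NA_real_,
                  mean_case = m1, mean_control = m2))
    return(list(t = sign(m1 - m2) * Inf, p_value = 0, df = NA_real_,
                mean_case = m1, mean_control = m2))
  }
  tt <- stats::t.test(case_values, control_values, var.equal = FALSE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean_case = m1, mean_control = m2)
}

#' Pearson correlation matrix of the analytic dataset
#'
#' @param data data.frame of numeric (or 0/1) analysis columns; at least 3
#'   complete rows required. Constant columns yield `NA` entries with a
#'   warning rather than an error.
#' @return symmetric matrix of Pearson r with unit diagonal.
#' @export
correlation_matrix <- function(data) {
  data <- as.data.frame(data)
  num <- as.data.frame(lapply(data, as.numeric))
  cc <- stats::complete.cases(num)
  if (sum(cc) < 3L) stop("need at least 3 complete rows")
  num <- num[cc, , drop = FALSE]
  const <- vapply(num, function(v) stats::sd(v) == 0, logical(1))
  if (any(const))
    warning("constant column(s), correlations undefined: ",
            paste(names(num)[const], collapse = ", "))
  suppressWarnings(r <- stats::cor(num))
  diag(r) <- ifelse(const, NA_real_, 1)
  r
}

#' Complete-case filter
#'
#' Drops every row with a missing value in any of the analysis columns,
#' mirroring the cross-sectional model's exclusion of records with missing
#' values.
#'
#' @param table data.frame.
#' @param columns columns to require complete (default: all).
#' @return list with `data` (filtered), `n_removed`.
#' @export
complete_case_filter <- function(table, columns = names(table)) {
  stopifnot(all(columns %in% names(table)))
  keep <- stats::complete.cases(table[columns])
  if (!any(keep)) stop("all rows removed by complete-case filtering")
  list(data = table[keep, , drop = FALSE], n_removed = sum(!keep))
}
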
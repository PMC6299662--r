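#' Two-group comparison of a cohort metric
#'
#' Two-tailed t test (Welch by default; pooled-variance on request) of one
#' metric between the two diet groups, reported as the field does:
#' group means plus/minus standard error of the mean, t and p. Missing
#' values are dropped per group with an explicit count, never silently.
#'
#' @param table cohort data.frame with a `group` column
#' @param metric name of the numeric column to compare
#' @param group_col name of the group column (default `"group"`)
#' @param pooled if `TRUE` use the pooled-variance (classic Student) test
#' @return list of class `group_test`: `statistic`, `p_value`, `df`,
#'   per-group `means`, `sems`, `n`, `n_missing`, `method`
#' @export
two_group_test <- function(table, metric, group_col = "group",
                           pooled = FALSE) {
  stopifnot(is.data.frame(table), metric %in% names(table),
            group_col %in% names(table))
  g <- factor(table[[group_col]])
  if (nlevels(g) != 2)
    stop("exactly two groups required, found ", nlevels(g), call. = FALSE)
  x <- table[[metric]]
  miss <- tapply(is.na(x), g, sum)
  ns <- tapply(!is.na(x), g, sum)
  if (any(ns < 2))
    stop("need >= 2 non-missing subjects per group for '", metric, "'",
         call. = FALSE)
  vars <- tapply(x, g, stats::var, na.rm = TRUE)
  if (all(vars == 0))
    stop("zero variance in both groups; t test undefined", call. = FALSE)
  ht <- stats::t.test(x ~ g, var.equal = pooled)
  means <- tapply(x, g, mean, na.rm = TRUE)
  sems <- sqrt(vars / ns)
  structure(list(metric = metric, statistic = unname(ht$statistic),
                 p_value = ht$p.value, df = unname(ht$parameter),
                 means = means, sems = sems, n = ns, n_missing = miss,
                 method = if (pooled) "Student (pooled)" else "Welch"),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("%s: %s t = %.3f, df = %.2f, p = %.4g\n", x$metric, x$method,
              x$statistic, x$df, x$p_value))
  for (g in names(x$means))
    cat(sprintf("  %s: %.4g +/- %.3g SEM (n = %d, missing %d)\n", g,
                x$means[[g]], x$sems[[g]], x$n[[g]], x$n_missing[[g]]))
  invisible(x)
}

#' Pearson correlation between two cohort metrics
#'
#' Pearson's r with a two-sided p value over complete pairs; the number of
#' pairs used is always reported, and incomplete pairs are counted.
#'
#' @param table cohort data.frame
#' @param metric_x,metric_y names of numeric columns
#' @return list: `r`, `p_value`, `n`, `n_dropped`
#' @export
pearson_correlation <- function(table, metric_x, metric_y) {
  stopifnot(is.data.frame(table), metric_x %in% names(table),
            metric_y %in% names(table))
  x <- table[[metric_x]]; y <- table[[metric_y]]
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 3)
    stop("need >= 3 complete pairs, found ", sum(ok), call. = FALSE)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    stop("constant input; correlation undefined", call. = FALSE)
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok),
       n_dropped = sum(!ok))
}

#' Object-location behavior indices
#'
#' From the exploration times of the displaced (novel-location) and familiar
#' objects: preference = 100 * t_novel / (t_novel + t_familiar) percent, and
#' discrimination index DI = (t_novel - t_familiar) / (t_novel + t_familiar),
#' which lies in [-1, 1] and is 0 at chance.
#'
#' @param t_novel,t_familiar exploration times in seconds (vectorized;
#'   both nonnegative, not both zero)
#' @return data.frame with columns `preference_pct` and `discrimination_index`
#' @examples
#' behavior_indices(30, 10)  # preference 75%, DI 0.5
#' @export
behavior_indices <- function(t_novel, t_familiar) {
  if (length(t_novel) != length(t_familiar))
    stop("t_novel and t_familiar must have equal length", call. = FALSE)
  if (any(t_novel < 0 | t_familiar < 0))
    stop("exploration times must be nonnegative", call. = FALSE)
  tot <- t_novel + t_familiar
  if (any(tot == 0))
    stop("t_novel and t_familiar are both zero for at least one subject",
         call. = FALSE)
  data.frame(preference_pct = 100 * t_novel / tot,
             discrimination_index = (t_novel - t_familiar) / tot)
}
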
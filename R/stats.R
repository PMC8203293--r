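#' Two-group comparison
#'
#' Two-sided comparison of two value vectors with either the classical
#' pooled-variance two-sample Student's t-test (`test = "t"`; set
#' `welch = TRUE` for the unequal-variance form) or the non-parametric
#' Mann-Whitney/Wilcoxon rank-sum test. The rank-sum test uses exact
#' enumeration for small tie-free samples (both n <= 8) and the normal
#' approximation with tie correction otherwise.
#'
#' @param a,b Numeric vectors, each with >= 2 values.
#' @param test `"t"` or `"mann-whitney"`.
#' @param welch Use the Welch (unequal variance) t-test instead of the
#'   pooled-variance form.
#' @return One-row tibble: `test_name`, `statistic`, `p_value`, `n1`, `n2`.
#' @export
compare_two_groups <- function(a, b, test = c("t", "mann-whitney"),
                               welch = FALSE) {
  test <- match.arg(test)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) abort("Each group needs >= 2 values.")
  if (test == "t") {
    if (var(a) == 0 && var(b) == 0) {
      abort("Zero variance in both groups: the t statistic is undefined.")
    }
    ht <- t.test(a, b, var.equal = !welch)
    name <- if (welch) "welch_t" else "student_t"
  } else {
    exact <- length(a) <= 8L && length(b) <= 8L
    ht <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = !exact))
    name <- "mann_whitney"
  }
  tibble(test_name = name,
         statistic = unname(ht$statistic),
         p_value = ht$p.value,
         n1 = length(a), n2 = length(b))
}

#' Multi-group comparison
#'
#' Omnibus comparison of three or more groups with one-way ANOVA (F statistic,
#' equal-variance form) or the Kruskal-Wallis rank test (H statistic). The
#' two are independent omnibus tests, not an omnibus/post-hoc pair; for
#' pairwise follow-up after a significant omnibus result use
#' [compare_two_groups()] per pair (with a multiplicity correction such as
#' `p.adjust(method = "holm")`).
#'
#' @param groups List of numeric vectors (>= 3 groups, each >= 2 values for
#'   ANOVA).
#' @param mode `"anova"` or `"kruskal-wallis"`.
#' @return One-row tibble: `test_name`, `statistic`, `df1`, `df2`, `p_value`,
#'   `n_groups`, `n_total`.
#' @export
compare_multi_groups <- function(groups, mode = c("anova", "kruskal-wallis")) {
  mode <- match.arg(mode)
  if (!is.list(groups) || length(groups) < 3L) abort("Need >= 3 groups.")
  sizes <- lengths(groups)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), sizes))
  if (mode == "anova") {
    if (any(sizes < 2L)) abort("ANOVA requires >= 2 values in every group.")
    ht <- oneway.test(values ~ g, var.equal = TRUE)
    tibble(test_name = "anova_F", statistic = unname(ht$statistic),
           df1 = unname(ht$parameter[1]), df2 = unname(ht$parameter[2]),
           p_value = ht$p.value, n_groups = length(groups),
           n_total = length(values))
  } else {
    ht <- kruskal.test(values, g)
    tibble(test_name = "kruskal_wallis_H", statistic = unname(ht$statistic),
           df1 = unname(ht$parameter), df2 = NA_real_,
           p_value = ht$p.value, n_groups = length(groups),
           n_total = length(values))
  }
}

#' Percent change relative to a reference value
#'
#' `100 * (reference - value) / reference`: positive when `value` is a
#' reduction relative to the reference (e.g. the mean fiber width of a
#' treated group versus its control).
#'
#' @param reference Reference (e.g. control) value; must be nonzero.
#' @param value Comparison (e.g. treated) value. Vectorised.
#' @return Percent change (positive = reduction).
#' @examples
#' percent_change(7.4, 6.7) # ~9.46% reduction
#' @export
percent_change <- function(reference, value) {
  if (any(reference == 0)) abort("`reference` must be nonzero.")
  100 * (reference - value) / reference
}

#' Per-group linear fit of motility against stiffness
#'
#' Ordinary least-squares fit of a motility statistic (e.g. mean T-cell
#' speed) against mean tumor stiffness across subjects, with the Pearson
#' correlation, fitted separately per treatment group when `by_group` is set.
#' Two-point groups are fitted but flagged as degenerate (r is ±1 by
#' construction).
#'
#' @param table Study table: one row per subject with numeric columns for
#'   `x_field` and `y_field` and (if `by_group`) a `group` column.
#' @param y_field Name of the motility column (e.g.
#'   `"mean_speed_um_per_min"`).
#' @param x_field Name of the stiffness column.
#' @param by_group Fit per treatment group rather than pooled.
#' @return A `stiffness_motility_fit` object; see [tidy()] and [glance()].
#' @export
stiffness_motility_fit <- function(table, y_field = "mean_speed_um_per_min",
                                   x_field = "mean_stiffness_kPa",
                                   by_group = TRUE) {
  table <- as_tibble(table)
  for (f in c(x_field, y_field)) {
    if (!f %in% names(table)) abort(paste("Missing column:", f))
  }
  if (by_group && !"group" %in% names(table)) {
    abort("`by_group = TRUE` needs a `group` column.")
  }
  groups <- if (by_group) split(table, table$group) else list(all = table)
  fits <- imap(groups, function(df, grp) {
    x <- df[[x_field]]; y <- df[[y_field]]
    ok <- complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 2L) abort(paste("Group", grp, "has < 2 subjects."))
    if (var(x) == 0) {
      abort(paste("Constant stiffness in group", grp, ": slope is undefined."))
    }
    fit <- lm(y ~ x)
    s <- summary(fit)
    tibble(
      group = grp,
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      pearson_r = cor(x, y),
      r_squared = s$r.squared,
      p_value = if (length(x) > 2L) s$coefficients[2, 4] else NA_real_,
      n = length(x),
      degenerate = length(x) == 2L
    )
  })
  structure(
    list(results = list_rbind(unname(fits)), table = table,
         x_field = x_field, y_field = y_field, by_group = by_group),
    class = "stiffness_motility_fit"
  )
}

#' @export
print.stiffness_motility_fit <- function(x, ...) {
  cat(sprintf("<stiffness_motility_fit> %s ~ %s%s\n", x$y_field, x$x_field,
              if (x$by_group) " by group" else ""))
  print(x$results)
  invisible(x)
}

#' @rdname stiffness_motility_fit
#' @param x A `stiffness_motility_fit`.
#' @param ... Unused.
#' @export
tidy.stiffness_motility_fit <- function(x, ...) x$results

#' @rdname stiffness_motility_fit
#' @export
glance.stiffness_motility_fit <- function(x, ...) {
  tibble(
    n_groups = nrow(x$results),
    n_subjects = sum(x$results$n),
    all_negative_slope = all(x$results$slope < 0),
    min_abs_r = min(abs(x$results$pearson_r))
  )
}

#' @rdname stiffness_motility_fit
#' @param object A `stiffness_motility_fit`.
#' @export
autoplot.stiffness_motility_fit <- function(object, ...) {
  tb <- object$table
  tb$x <- tb[[object$x_field]]
  tb$y <- tb[[object$y_field]]
  if (!object$by_group) tb$group <- "all"
  ggplot(tb, aes(.data$x, .data$y, colour = .data$group)) +
    geom_point() +
    geom_abline(data = object$results,
                aes(slope = .data$slope, intercept = .data$intercept,
                    colour = .data$group)) +
    labs(x = object$x_field, y = object$y_field, colour = "group") +
    theme_minimal()
}
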
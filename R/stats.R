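#' Significance mark for a p-value
#'
#' `ns` for p >= 0.05, `*` for p < 0.05, `**` for p < 0.01, `***` for
#' p < 0.001.
#'
#' @param p p-value in (0, 1].
#' @return Character mark.
#' @export
significance_mark <- function(p) {
  stop_if(!is.numeric(p) || any(p <= 0 | p > 1, na.rm = TRUE),
          "p must lie in (0, 1]")
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Compare two experimental groups with assumption-gated test selection
#'
#' Implements the study's statistical logic: normality of each group is
#' checked with the Shapiro-Wilk test and homogeneity of variance across
#' groups with the Brown-Forsythe test (Levene's test with median
#' centring); if all three pass at `alpha`, a two-sided equal-variance
#' t-test for independent groups is used, otherwise the two-sided
#' Mann-Whitney U-test. Group summaries are reported as mean and SD.
#' No multiple-testing correction is applied.
#'
#' @param a,b numeric samples of the two groups (each n >= 3).
#' @param alpha significance level for the assumption checks and the mark
#'   thresholds base (default 0.05).
#' @param labels length-2 character vector of group names.
#' @return Object of class `"group_comparison"`: list with `test_used`
#'   (`"t"` or `"mann_whitney"`), `p_value`, `normality_p` (per group),
#'   `variance_homogeneity_p`, `mean_sd` (data.frame group/n/mean/sd),
#'   `significance_mark`, `alpha`.
#' @export
#' @examples
#' compare_groups(rnorm(8), rnorm(8) + 3)
compare_groups <- function(a, b, alpha = 0.05,
                           labels = c("control", "hfd")) {
  a <- as.numeric(a); b <- as.numeric(b)
  stop_if(length(a) < 3L || length(b) < 3L, "each group needs n >= 3")
  stop_if(anyNA(a) || anyNA(b), "missing values are not allowed")
  check_number(alpha, "alpha", lower = 0, upper = 1)

  sw <- function(x) {
    # constant samples have no normality test; route to the nonparametric arm
    if (diff(range(x)) == 0) return(0)
    shapiro.test(x)$p.value
  }
  norm_p <- c(sw(a), sw(b))
  names(norm_p) <- labels
  g <- factor(rep(labels, c(length(a), length(b))), levels = labels)
  bf <- car::leveneTest(c(a, b) ~ g, center = median)
  bf_p <- bf[["Pr(>F)"]][1]
  if (is.na(bf_p)) bf_p <- 0

  parametric <- all(norm_p > alpha) && bf_p > alpha
  if (parametric) {
    p <- t.test(a, b, var.equal = TRUE)$p.value
    test_used <- "t"
  } else {
    p <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))$p.value
    test_used <- "mann_whitney"
  }
  structure(list(
    test_used = test_used, p_value = p, normality_p = norm_p,
    variance_homogeneity_p = bf_p,
    mean_sd = data.frame(group = labels, n = c(length(a), length(b)),
                         mean = c(mean(a), mean(b)), sd = c(sd(a), sd(b))),
    significance_mark = significance_mark(p), alpha = alpha),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  ms <- x$mean_sd
  cat(sprintf("%s: %.3g +/- %.3g (n = %d)  vs  %s: %.3g +/- %.3g (n = %d)\n",
              ms$group[1], ms$mean[1], ms$sd[1], ms$n[1],
              ms$group[2], ms$mean[2], ms$sd[2], ms$n[2]))
  cat(sprintf("%s test: p = %.4g  [%s]\n",
              if (x$test_used == "t") "Equal-variance t" else "Mann-Whitney U",
              x$p_value, x$significance_mark))
  invisible(x)
}

#' Assemble a cohort report of per-endpoint group comparisons
#'
#' Runs [compare_groups()] on every endpoint of a study (e.g. cumulative
#' delta-T1, EF, ER, strain indices, flow reserve, GTT AUC) and collects
#' the results into one table.
#'
#' @param endpoints named list; each element is itself a named list of two
#'   numeric vectors (the per-animal values of the two groups). Group
#'   names must agree across endpoints.
#' @param alpha significance level passed to [compare_groups()].
#' @return Object of class `"cohort_report"`: list with `table`
#'   (data.frame: endpoint, per-group n/mean/sd, test, p, mark) and
#'   `comparisons` (the full `group_comparison` objects).
#' @export
build_report <- function(endpoints, alpha = 0.05) {
  stop_if(!is.list(endpoints) || length(endpoints) == 0L ||
            is.null(names(endpoints)) || any(names(endpoints) == ""),
          "'endpoints' must be a nonempty named list")
  labels <- names(endpoints[[1]])
  stop_if(length(labels) != 2L, "each endpoint needs exactly two groups")
  comparisons <- vector("list", length(endpoints))
  names(comparisons) <- names(endpoints)
  rows <- vector("list", length(endpoints))
  for (i in seq_along(endpoints)) {
    e <- endpoints[[i]]
    stop_if(!identical(names(e), labels),
            sprintf("endpoint '%s': group labels do not match '%s'",
                    names(endpoints)[i], paste(labels, collapse = "', '")))
    cmp <- compare_groups(e[[1]], e[[2]], alpha = alpha, labels = labels)
    comparisons[[i]] <- cmp
    ms <- cmp$mean_sd
    rows[[i]] <- data.frame(
      endpoint = names(endpoints)[i],
      n_1 = ms$n[1], mean_1 = ms$mean[1], sd_1 = ms$sd[1],
      n_2 = ms$n[2], mean_2 = ms$mean[2], sd_2 = ms$sd[2],
      test = cmp$test_used, p_value = cmp$p_value,
      mark = cmp$significance_mark)
  }
  tab <- do.call(rbind, rows)
  names(tab) <- sub("_1$", paste0("_", labels[1]), names(tab))
  names(tab) <- sub("_2$", paste0("_", labels[2]), names(tab))
  structure(list(table = tab, comparisons = comparisons,
                 groups = labels, alpha = alpha),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Cohort report (", paste(x$groups, collapse = " vs "), ")\n", sep = "")
  tab <- x$table
  tab$p_value <- signif(tab$p_value, 3)
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(v) signif(v, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.cohort_report <- function(x, ...) x$table
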
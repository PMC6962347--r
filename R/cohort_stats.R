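#' Aggregate acquisitions of one plaque and view to mean, SD, n
#'
#' Per-plaque SWE summaries used in all cohort-pooled analysis: the
#' arithmetic mean and sample standard deviation (n - 1 denominator; 0
#' when n = 1) over the passing acquisitions only.
#'
#' @param values Numeric vector of per-acquisition velocities (m/s) that
#'   passed quality control; must be non-empty.
#' @return List with `mean`, `sd`, `n`.
#' @examples
#' aggregate_plaque(c(4, 6)) # mean 5, sd sqrt(2), n 2
#' @export
aggregate_plaque <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0) {
    stop("no passing acquisitions; metric undefined for this plaque",
      call. = FALSE
    )
  }
  list(
    mean = mean(values),
    sd = if (length(values) == 1) 0 else stats::sd(values),
    n = length(values)
  )
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact p-value by full enumeration of rank-sum assignments when the
#' combined sample size is at most `exact_limit` and there are no ties
#' (the regime of small AHA groups, 4-8 plaques each); otherwise the
#' normal approximation with tie correction and continuity correction.
#' The two-sided exact p is `2 * min(P(W <= w), P(W >= w))`, capped at 1.
#'
#' @param x,y Non-empty numeric samples.
#' @param exact_limit Largest combined n for the enumeration branch.
#' @return List with `p_value`, `statistic` (rank sum of `x`) and
#'   `method` (`"exact"` or `"normal_approx"`).
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value # exactly 0.1
#' @export
wilcoxon_rank_sum <- function(x, y, exact_limit = 12L) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  m <- length(x)
  n_all <- m + length(y)
  combined <- c(x, y)
  ranks <- rank(combined)
  w <- sum(ranks[seq_len(m)])
  has_ties <- anyDuplicated(combined) > 0

  if (!has_ties && n_all <= exact_limit) {
    sums <- rank_sum_enumeration(m, n_all)
    p <- 2 * min(mean(sums <= w), mean(sums >= w))
    return(list(p_value = min(p, 1), statistic = w, method = "exact"))
  }
  mu <- m * (n_all + 1) / 2
  ties <- table(combined)
  tie_corr <- sum(ties^3 - ties) / (n_all * (n_all - 1))
  v <- m * length(y) / 12 * ((n_all + 1) - tie_corr)
  if (v <= 0) {
    return(list(p_value = 1, statistic = w, method = "normal_approx"))
  }
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(v)
  list(
    p_value = min(1, max(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)),
    statistic = w, method = "normal_approx"
  )
}

# All C(n_all, m) rank sums of an m-subset of ranks 1..n_all (the exact
# null distribution support); memoised, as the same small group sizes
# recur across metrics and replicates.
.rank_sum_cache <- new.env(parent = emptyenv())
rank_sum_enumeration <- function(m, n_all) {
  key <- paste(m, n_all)
  if (is.null(.rank_sum_cache[[key]])) {
    .rank_sum_cache[[key]] <- utils::combn(seq_len(n_all), m, sum)
  }
  .rank_sum_cache[[key]]
}

#' Compare type VI plaques against every other AHA type
#'
#' Pairwise two-sided Wilcoxon rank-sum tests of the per-plaque means of
#' one velocity metric and view: type VI against each of III, V and VII.
#' The metric "differentiates type VI from all other types" when every
#' pairwise p is below 0.05 (strictly, below 0.01).
#'
#' @param cohort A `cohort_table` (see [simulate_cohort()]).
#' @param metric One of `"gv"`, `"pv200"`, `"pv300"`, `"pv400"`.
#' @param view `"L"` or `"T"`.
#' @return List with `metric`, `view`, `p_values` (named by compared
#'   type, `NA` where a group is empty), `significant_all`,
#'   `significant_all_strict`.
#' @export
compare_aha_groups <- function(cohort, metric, view) {
  col <- paste0(metric, "_mean")
  stopifnot(col %in% names(cohort))
  sub <- cohort[cohort$view == view, c("aha_type", col)]
  vi <- sub[[col]][sub$aha_type == "VI"]
  vi <- vi[is.finite(vi)]
  others <- c("III", "V", "VII")
  p <- stats::setNames(rep(NA_real_, 3), others)
  for (g in others) {
    og <- sub[[col]][sub$aha_type == g]
    og <- og[is.finite(og)]
    if (length(vi) > 0 && length(og) > 0) {
      p[g] <- wilcoxon_rank_sum(vi, og)$p_value
    }
  }
  list(
    metric = metric, view = view, p_values = p,
    significant_all = all(is.finite(p)) && all(p < 0.05),
    significant_all_strict = all(is.finite(p)) && all(p < 0.01)
  )
}

#' Correlate a velocity metric with a plaque covariate
#'
#' Pearson (product-moment, p from the t distribution with n - 2 df) and
#' Spearman (average-rank transform then product-moment, p by the same
#' t approximation) correlations over pairwise-complete plaques: any
#' plaque missing the covariate or the metric is excluded from this
#' particular analysis. A coefficient is flagged when |R| >= 0.5 and
#' p < 0.05.
#'
#' @param cohort A `cohort_table`.
#' @param metric Velocity metric name (`"gv"`, `"pv200"`, ...).
#' @param view `"L"` or `"T"`.
#' @param covariate Covariate column name.
#' @return List with `metric`, `view`, `covariate`, `n_used`,
#'   `pearson_r`, `pearson_p`, `spearman_r`, `spearman_p`,
#'   `flagged_pearson`, `flagged_spearman`, `flagged`, `defined`.
#' @export
correlate <- function(cohort, metric, view, covariate) {
  col <- paste0(metric, "_mean")
  stopifnot(col %in% names(cohort), covariate %in% names(cohort))
  sub <- cohort[cohort$view == view, ]
  xv <- sub[[col]]
  yv <- sub[[covariate]]
  ok <- is.finite(xv) & is.finite(yv)
  res <- list(
    metric = metric, view = view, covariate = covariate,
    n_used = sum(ok), pearson_r = NA_real_, pearson_p = NA_real_,
    spearman_r = NA_real_, spearman_p = NA_real_,
    flagged_pearson = FALSE, flagged_spearman = FALSE, flagged = FALSE,
    defined = FALSE
  )
  if (sum(ok) < 3) return(res)
  xv <- xv[ok]
  yv <- yv[ok]
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) return(res)
  pe <- product_moment_test(xv, yv)
  sp <- product_moment_test(rank(xv), rank(yv))
  res$pearson_r <- pe$r
  res$pearson_p <- pe$p
  res$spearman_r <- sp$r
  res$spearman_p <- sp$p
  res$flagged_pearson <- abs(pe$r) >= 0.5 && pe$p < 0.05
  res$flagged_spearman <- abs(sp$r) >= 0.5 && sp$p < 0.05
  res$flagged <- res$flagged_pearson || res$flagged_spearman
  res$defined <- TRUE
  res
}

product_moment_test <- function(x, y) {
  n <- length(x)
  r <- stats::cor(x, y)
  r <- max(min(r, 1), -1)
  if (abs(r) == 1) return(list(r = r, p = 0))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

#' Run the full cohort statistical evaluation
#'
#' For every velocity metric (group velocity and the three phase-velocity
#' bands) and imaging view: the AHA type VI group comparison and the
#' correlation screen against every covariate column present in the
#' cohort. No multiple-testing correction is applied; the report states
#' the number of tests performed instead.
#'
#' @param cohort A `cohort_table`; validated against the fixed schema.
#' @param metrics,views Metrics and views to evaluate.
#' @return List of class `cohort_evaluation`: `group_comparisons` and
#'   `correlations` data.frames plus `n_tests`.
#' @export
run_full_evaluation <- function(cohort,
                                metrics = c("gv", "pv200", "pv300", "pv400"),
                                views = c("L", "T")) {
  validate_cohort(cohort, metrics)
  id_cols <- c("plaque_id", "subject_id", "view", "aha_type")
  metric_cols <- as.vector(outer(metrics, c("_mean", "_sd", "_n"), paste0))
  covariates <- setdiff(names(cohort), c(id_cols, metric_cols))

  gc_rows <- list()
  for (m in metrics) {
    for (v in views) {
      g <- compare_aha_groups(cohort, m, v)
      gc_rows[[paste(m, v)]] <- data.frame(
        metric = m, view = v,
        p_vs_III = g$p_values[["III"]], p_vs_V = g$p_values[["V"]],
        p_vs_VII = g$p_values[["VII"]],
        significant_all = g$significant_all,
        significant_all_strict = g$significant_all_strict
      )
    }
  }
  cr_rows <- list()
  for (m in metrics) {
    for (v in views) {
      for (cv in covariates) {
        r <- correlate(cohort, m, v, cv)
        cr_rows[[paste(m, v, cv)]] <- data.frame(
          metric = m, view = v, covariate = cv, n_used = r$n_used,
          pearson_r = r$pearson_r, pearson_p = r$pearson_p,
          spearman_r = r$spearman_r, spearman_p = r$spearman_p,
          flagged = r$flagged, defined = r$defined
        )
      }
    }
  }
  gc <- do.call(rbind, gc_rows)
  cr <- do.call(rbind, cr_rows)
  rownames(gc) <- rownames(cr) <- NULL
  structure(
    list(
      group_comparisons = gc, correlations = cr,
      n_tests = nrow(gc) * 3 + sum(cr$defined) * 2
    ),
    class = "cohort_evaluation"
  )
}

validate_cohort <- function(cohort, metrics) {
  required <- c(
    "plaque_id", "view", "aha_type",
    paste0(rep(metrics, each = 3), c("_mean", "_sd", "_n"))
  )
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort table is missing column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  bad_view <- setdiff(unique(cohort$view), c("L", "T"))
  if (length(bad_view) > 0) {
    stop("cohort column 'view' contains unknown level(s): ",
      paste(bad_view, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(TRUE)
}
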
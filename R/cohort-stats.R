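#' Kaplan-Meier survival curve
#'
#' Product-limit estimator via [survival::survfit()].
#'
#' @param times Follow-up times in months (> 0).
#' @param events Event indicators (1 = event, 0 = censored).
#' @return A `survival_curve`: data frame of `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv` (S(0) = 1 implicitly; `surv` is non-increasing).
#' @export
km_fit <- function(times, events) {
  if (length(times) == 0) stopf("empty survival input")
  if (length(times) != length(events)) stopf("times and events differ in length")
  if (any(times <= 0)) stopf("survival times must be > 0")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  structure(data.frame(time = fit$time, n_risk = fit$n.risk,
                       n_event = fit$n.event, n_censor = fit$n.censor,
                       surv = fit$surv),
            class = c("survival_curve", "data.frame"))
}

#' Log-rank test between survival curves
#'
#' Standard (unweighted) log-rank chi-square with k - 1 degrees of freedom,
#' via [survival::survdiff()].
#'
#' @param times,events Survival data.
#' @param group Group labels (>= 2 non-empty groups).
#' @return A `test_result`: list with `statistic`, `df`, `p_value`, `test`,
#'   `group_sizes`.
#' @export
logrank_test <- function(times, events, group) {
  group <- as.factor(group)
  sizes <- table(group)
  if (nlevels(group) < 2) stopf("log-rank needs at least two groups")
  if (any(sizes == 0)) stopf("empty group in log-rank test: %s",
                             paste(names(sizes)[sizes == 0], collapse = ", "))
  if (sum(events) < 1) stopf("log-rank needs at least one event")
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ group)
  df <- nlevels(group) - 1L
  structure(list(statistic = unname(sd_$chisq), df = df,
                 p_value = pchisq(sd_$chisq, df, lower.tail = FALSE),
                 test = "log-rank", group_sizes = as.integer(sizes)),
            class = "test_result")
}

#' Cox proportional-hazards fit
#'
#' Maximizes the partial likelihood via [survival::coxph()] (Efron ties by
#' default, Breslow optional) and reports per-covariate hazard ratios with
#' Wald 95% confidence intervals, the reference level of each categorical
#' covariate, and listwise-deletion counts. A descriptive
#' proportional-hazards check (scaled Schoenfeld residual trend test,
#' [survival::cox.zph()]) is attached but never gates the fit.
#'
#' @param data Data frame with survival columns and covariates.
#' @param time_col,event_col Column names of time and event.
#' @param covariates Character vector of covariate column names.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return A `cox_fit`: list with `table` (term, level, beta, hr, ci_lower,
#'   ci_upper, p_value; reference levels shown as "Ref."), `loglik`,
#'   `n_used`, `n_missing`, `ties`, `zph`, and the underlying `fit`.
#' @export
cox_fit <- function(data, time_col, event_col, covariates,
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(all(c(time_col, event_col, covariates) %in% names(data)))
  used <- complete.cases(data[, c(time_col, event_col, covariates)])
  d <- data[used, , drop = FALSE]
  for (v in covariates) {
    x <- d[[v]]
    if (length(unique(x)) < 2)
      stopf("covariate '%s' is constant in the analysed rows", v)
    if (is.character(x)) d[[v]] <- factor(x)
  }
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time_col, ", ", event_col, ") ~ ",
    paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = d, ties = ties,
                         control = survival::coxph.control(eps = 1e-9,
                                                           iter.max = 50))
  if (any(!is.finite(coef(fit))) || fit$iter >= 50)
    stopf("Cox fit did not converge (monotone likelihood or separation)")
  s <- summary(fit)
  rows <- list()
  for (v in covariates) {
    x <- d[[v]]
    if (is.factor(x)) {
      rows[[length(rows) + 1L]] <- data.frame(
        term = v, level = levels(x)[1], beta = NA_real_, hr = NA_real_,
        ci_lower = NA_real_, ci_upper = NA_real_, p_value = NA_real_,
        ref = TRUE, stringsAsFactors = FALSE)
      for (lv in levels(x)[-1]) {
        cf <- paste0(v, lv)
        rows[[length(rows) + 1L]] <- data.frame(
          term = v, level = lv, beta = s$coefficients[cf, "coef"],
          hr = s$coefficients[cf, "exp(coef)"],
          ci_lower = s$conf.int[cf, "lower .95"],
          ci_upper = s$conf.int[cf, "upper .95"],
          p_value = s$coefficients[cf, "Pr(>|z|)"], ref = FALSE,
          stringsAsFactors = FALSE)
      }
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        term = v, level = "", beta = s$coefficients[v, "coef"],
        hr = s$coefficients[v, "exp(coef)"],
        ci_lower = s$conf.int[v, "lower .95"],
        ci_upper = s$conf.int[v, "upper .95"],
        p_value = s$coefficients[v, "Pr(>|z|)"], ref = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  zph <- tryCatch(survival::cox.zph(fit), error = function(e) NULL)
  structure(list(table = do.call(rbind, rows),
                 loglik = fit$loglik[2],
                 score_test = unname(summary(fit)$sctest["test"]),
                 n_used = sum(used), n_missing = sum(!used),
                 ties = ties, zph = zph, fit = fit),
            class = "cox_fit")
}

#' Progression counts at a fixed horizon with a chi-square test
#'
#' Per stratum, subjects are counted as progressed (event at or before the
#' horizon) or not progressed (followed beyond the horizon without an event
#' by then). Subjects censored before the horizon without progression are
#' excluded from the table by default (`censored_as_nonprogressed = TRUE`
#' counts them as not progressed instead). Pearson chi-square without
#' continuity correction; Yates' correction available by flag.
#'
#' @param strata Factor of group labels.
#' @param times,events Survival data.
#' @param horizon Horizon in months (> 0), e.g. 12 or 24.
#' @param censored_as_nonprogressed Denominator policy flag.
#' @param correct Apply Yates continuity correction (default FALSE).
#' @return List: `table` (2 x k progressed / not-progressed counts),
#'   `excluded` (count), and `test` (a `test_result`).
#' @export
progression_table <- function(strata, times, events, horizon,
                              censored_as_nonprogressed = FALSE,
                              correct = FALSE) {
  if (horizon <= 0) stopf("horizon must be > 0")
  strata <- droplevels(as.factor(strata))
  keep <- !is.na(strata)
  strata <- strata[keep]; times <- times[keep]; events <- events[keep]
  if (any(table(strata) == 0)) stopf("empty stratum in progression table")
  progressed <- events == 1 & times <= horizon
  beyond <- times > horizon
  include <- progressed | beyond
  if (censored_as_nonprogressed) include <- rep(TRUE, length(times))
  tab <- rbind(progressed = tapply(progressed & include, strata, sum),
               not_progressed = tapply(!progressed & include, strata, sum))
  tab[is.na(tab)] <- 0
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  structure(list(table = tab, excluded = sum(!include),
                 test = structure(list(statistic = unname(ct$statistic),
                                       df = unname(ct$parameter),
                                       p_value = ct$p.value,
                                       test = "chi-square",
                                       group_sizes = colSums(tab)),
                                  class = "test_result")),
            class = "progression_table")
}

#' Two-group rank test (Mann-Whitney U)
#'
#' Exact two-sided p-value by enumeration when the combined sample size is at
#' most 20 and there are no ties; otherwise the normal approximation with tie
#' correction (without continuity correction).
#'
#' @param a,b Numeric samples (both non-empty).
#' @return A `test_result` with the U statistic for the first group.
#' @export
rank_test <- function(a, b) {
  if (!length(a) || !length(b)) stopf("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b)) <= 20 && !ties
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = FALSE))
  structure(list(statistic = unname(wt$statistic), df = NA_integer_,
                 p_value = wt$p.value,
                 test = if (exact) "Mann-Whitney (exact)" else
                   "Mann-Whitney (normal approximation)",
                 group_sizes = c(length(a), length(b))),
            class = "test_result")
}

#' Association between two numeric variables
#'
#' Pearson or Spearman correlation (via [stats::cor.test()]) or simple linear
#' regression (slope, intercept, R squared), each with a two-sided p-value.
#'
#' @param x,y Numeric vectors, equal length >= 3.
#' @param method `"pearson"`, `"spearman"` or `"linear_regression"`.
#' @return A `test_result` with `coefficient` (r, rho, or slope),
#'   and for regression also `intercept` and `r_squared`.
#' @export
association <- function(x, y,
                        method = c("pearson", "spearman", "linear_regression")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3)
    stopf("x and y must have equal length >= 3")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (var(x) == 0 || var(y) == 0) stopf("zero variance in x or y")
  if (method == "linear_regression") {
    fit <- lm(y ~ x)
    s <- summary(fit)
    return(structure(list(statistic = s$coefficients["x", "t value"],
                          df = fit$df.residual,
                          p_value = s$coefficients["x", "Pr(>|t|)"],
                          test = "linear regression",
                          coefficient = unname(coef(fit)["x"]),
                          intercept = unname(coef(fit)["(Intercept)"]),
                          r_squared = s$r.squared,
                          group_sizes = length(x)),
                     class = "test_result"))
  }
  ct <- suppressWarnings(cor.test(x, y, method = method))
  structure(list(statistic = unname(ct$statistic), df = NA_integer_,
                 p_value = ct$p.value, test = paste(method, "correlation"),
                 coefficient = unname(ct$estimate),
                 group_sizes = length(x)),
            class = "test_result")
}

#' Differential immune-gene testing between score strata
#'
#' Per gene, a two-sided Welch t-test between the high (Q4) and low (Q1)
#' strata, the difference of group means (log fold change when the matrix is
#' on a log scale) and the Bonferroni-adjusted p-value
#' `min(1, m * p)`; a gene is significant when the adjusted p-value is below
#' `alpha`. Genes with zero variance in both groups are reported with p = 1
#' and flagged.
#'
#' @param expr Numeric genes x patients matrix with gene rownames.
#' @param strata Factor per patient with levels including `Q1` and `Q4`.
#' @param alpha Significance level on the adjusted p (default 0.05).
#' @return Data frame per gene: `gene`, `mean_high`, `mean_low`, `lfc`,
#'   `statistic`, `p_value`, `adjusted_p`, `significant`, `degenerate`.
#' @export
diff_immune_genes <- function(expr, strata, alpha = 0.05) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)),
            ncol(expr) == length(strata))
  hi <- strata == "Q4" & !is.na(strata)
  lo <- strata == "Q1" & !is.na(strata)
  if (sum(hi) < 2 || sum(lo) < 2)
    stopf("need at least two patients in each of Q4 and Q1")
  m <- nrow(expr)
  res <- lapply(seq_len(m), function(g) {
    xh <- expr[g, hi]; xl <- expr[g, lo]
    degen <- var(xh) < 1e-300 && var(xl) < 1e-300
    if (degen) {
      data.frame(gene = rownames(expr)[g], mean_high = mean(xh),
                 mean_low = mean(xl), lfc = mean(xh) - mean(xl),
                 statistic = 0, p_value = 1, degenerate = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      tt <- t.test(xh, xl)
      data.frame(gene = rownames(expr)[g], mean_high = mean(xh),
                 mean_low = mean(xl), lfc = mean(xh) - mean(xl),
                 statistic = unname(tt$statistic), p_value = tt$p.value,
                 degenerate = FALSE, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, res)
  out$adjusted_p <- p.adjust(out$p_value, method = "bonferroni")
  out$significant <- out$adjusted_p < alpha
  out[, c("gene", "mean_high", "mean_low", "lfc", "statistic", "p_value",
          "adjusted_p", "significant", "degenerate")]
}

#' Survival analysis within HRD subgroups
#'
#' Partitions patients by HRD score at the validated cut-off (positive when
#' `hrd_score >= cutoff`, default 42) and reruns the Kaplan-Meier / log-rank
#' comparison of the retained full-cohort Q4 vs Q1 strata within each
#' subgroup (strata are NOT recomputed within subgroups). A subgroup with no
#' events among its Q1/Q4 patients is skipped with a logged reason.
#'
#' @param patients Data frame with `hrd_score`, a stratum column and survival
#'   columns.
#' @param time_col,event_col Survival column names.
#' @param stratum_col Column holding full-cohort strata (default
#'   `"stratum"`).
#' @param cutoff HRD positivity cut-off (default 42).
#' @return Named list (`positive`, `negative`); each element has `n`,
#'   `km` (per-stratum curves), `logrank`, or `skipped` with a reason.
#' @export
hrd_subgroup <- function(patients, time_col, event_col,
                         stratum_col = "stratum", cutoff = 42) {
  stopifnot(all(c("hrd_score", time_col, event_col, stratum_col) %in%
                  names(patients)))
  run <- function(d) {
    d <- d[d[[stratum_col]] %in% c("Q1", "Q4") & !is.na(d[[stratum_col]]), ]
    if (nrow(d) == 0 || sum(d[[event_col]]) == 0 ||
        length(unique(d[[stratum_col]])) < 2)
      return(list(skipped = TRUE,
                  reason = "no events or missing stratum in subgroup",
                  n = nrow(d)))
    g <- droplevels(factor(d[[stratum_col]]))
    km <- lapply(split(d, g), function(s) km_fit(s[[time_col]], s[[event_col]]))
    list(skipped = FALSE, n = nrow(d), km = km,
         logrank = logrank_test(d[[time_col]], d[[event_col]], g))
  }
  ok <- !is.na(patients$hrd_score)
  list(positive = run(patients[ok & patients$hrd_score >= cutoff, ]),
       negative = run(patients[ok & patients$hrd_score < cutoff, ]))
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s)\n", x$test,
              x$statistic, x$p_value, paste(x$group_sizes, collapse = "/")))
  invisible(x)
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH fit (%s ties), n = %d used, %d missing\n",
              x$ties, x$n_used, x$n_missing))
  tab <- x$table
  hr <- ifelse(tab$ref, "Ref.",
               sprintf("%.3f (%.3f-%.3f)", tab$hr, tab$ci_lower, tab$ci_upper))
  print(data.frame(term = tab$term, level = tab$level, `HR (95% CI)` = hr,
                   p = signif(tab$p_value, 3), check.names = FALSE),
        row.names = FALSE)
  invisible(x)
}
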
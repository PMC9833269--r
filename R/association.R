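#' Assign score tertiles or quartiles
#'
#' Cut points are the `k - 1` empirical quantiles under the standard
#' linear-interpolation definition (`stats::quantile` type 7). A subject
#' whose score falls exactly on a cut point is assigned to the lower group.
#' Labels run 1 (lowest scores) to `k`.
#'
#' @param scores numeric vector of scores
#' @param k number of quantile groups, 3 (tertiles) or 4 (quartiles)
#' @return integer vector of group labels in `1..k`
#' @examples
#' assignQuantiles(1:9, 3)  # 1 1 1 2 2 2 3 3 3
#' @export
assignQuantiles <- function(scores, k = c(3, 4)) {
  k <- as.integer(k[1])
  if (!(k %in% c(3L, 4L)))
    stop("k must be 3 (tertiles) or 4 (quartiles)", call. = FALSE)
  if (anyNA(scores))
    stop("scores contain NA; stratify complete data only", call. = FALSE)
  if (length(unique(scores)) < k)
    stop(sprintf("need at least %d distinct score values, found %d",
                 k, length(unique(scores))), call. = FALSE)
  cuts <- stats::quantile(scores, probs = seq_len(k - 1) / k, type = 7,
                          names = FALSE)
  # values equal to a cut point belong to the lower group (right-closed)
  as.integer(cut(scores, breaks = c(-Inf, cuts, Inf), right = TRUE,
                 labels = FALSE))
}

#' Linear association between LDL-C and a polygenic score
#'
#' Ordinary least squares of the response on the score, optionally with
#' additional covariate columns. Reports the score slope, intercept, R^2 and
#' adjusted R^2 (`1 - (1 - R^2)(n - 1)/(n - p - 1)` with `p` predictors),
#' and the two-sided slope p-value.
#'
#' @param response numeric response (LDL-C, mg/dL)
#' @param predictor numeric score
#' @param covariates optional data.frame of extra predictors
#' @return object of class `ldlprs_linear`: list with `slope`, `intercept`,
#'   `r2`, `adjusted_r2`, `n`, `p_value`, and the underlying `fit`
#' @examples
#' r <- linearAssoc(2 * (1:20) + 1, 1:20)
#' r$slope   # 2
#' @export
linearAssoc <- function(response, predictor, covariates = NULL) {
  if (length(response) != length(predictor))
    stop("response and predictor lengths differ", call. = FALSE)
  df <- data.frame(.y = response, .score = predictor)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(response))
      stop("covariates row count differs from response length", call. = FALSE)
    df <- cbind(df, covariates)
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  p <- ncol(df) - 1L
  if (nrow(df) <= p + 1L)
    stop("too few complete observations for the model size", call. = FALSE)
  fit <- stats::lm(.y ~ ., data = df)
  if (anyNA(stats::coef(fit)))
    stop("singular (rank-deficient) design", call. = FALSE)
  sm <- summary(fit)
  structure(list(
    slope = unname(stats::coef(fit)[".score"]),
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    r2 = sm$r.squared,
    adjusted_r2 = sm$adj.r.squared,
    n = nrow(df),
    p_value = sm$coefficients[".score", "Pr(>|t|)"],
    fit = fit
  ), class = "ldlprs_linear")
}

#' @export
print.ldlprs_linear <- function(x, ...) {
  cat(sprintf("Linear score association (n = %d)\n", x$n))
  cat(sprintf("  slope %.4f mg/dL per score unit (p = %.3g)\n",
              x$slope, x$p_value))
  cat(sprintf("  R2 %.4f, adjusted R2 %.4f\n", x$r2, x$adjusted_r2))
  invisible(x)
}

#' Quartile logistic model for high coronary calcium burden
#'
#' Maximum-likelihood logistic regression of a binary outcome (canonically
#' `cac >= 100`) on score quartile indicators (quartile 1 reference) with
#' age and sex as covariates, as in age- and sex-adjusted calcium-burden
#' analyses. Wald 95% CIs (`exp(estimate +/- 1.96 SE)`). A second fit with
#' quartile as an ordinal numeric gives the trend odds ratio.
#'
#' @param outcome logical (or 0/1) outcome vector
#' @param quartile integer labels 1-4 from [assignQuantiles()]
#' @param age numeric, years
#' @param sex character `"F"`/`"M"` (or factor); F is the reference
#' @return object of class `ldlprs_logistic`: list with `quartile_or`
#'   (data.frame: quartile, or, ci_lo, ci_hi, p_value; quartile 1 has OR 1),
#'   `trend_or`, `covariates` (age and sex rows), `n`, and both `fit`s
#' @export
logisticQuartileOr <- function(outcome, quartile, age = NULL, sex = NULL) {
  outcome <- as.logical(outcome)
  n <- length(outcome)
  if (length(quartile) != n)
    stop("outcome and quartile lengths differ", call. = FALSE)
  if (!all(quartile %in% 1:4))
    stop("quartile labels must be integers 1..4", call. = FALSE)
  df <- data.frame(.y = outcome, .q = factor(quartile, levels = 1:4),
                   .qnum = as.numeric(quartile))
  if (!is.null(age)) df$.age <- age
  if (!is.null(sex)) df$.sex <- factor(as.character(sex), levels = c("F", "M"))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (length(unique(df$.y)) < 2L)
    stop("outcome is constant; both classes must be present", call. = FALSE)
  rhs <- c(".q", if (!is.null(age)) ".age", if (!is.null(sex)) ".sex")
  form <- stats::reformulate(rhs, response = ".y")
  fit <- stats::glm(form, family = stats::binomial(), data = df)
  if (!fit$converged)
    stop("logistic fit did not converge", call. = FALSE)
  sm <- summary(fit)$coefficients
  if (any(sm[, "Std. Error"] > 50))
    stop(sprintf("(quasi-)separation suspected: unstable estimates for %s",
                 paste(rownames(sm)[sm[, "Std. Error"] > 50], collapse = ", ")),
         call. = FALSE)
  wald <- function(rows) {
    est <- sm[rows, "Estimate"]
    se <- sm[rows, "Std. Error"]
    data.frame(term = rows, or = exp(est),
               ci_lo = exp(est - 1.96 * se), ci_hi = exp(est + 1.96 * se),
               p_value = sm[rows, "Pr(>|z|)"], row.names = NULL)
  }
  qrows <- paste0(".q", 2:4)
  qtab <- rbind(data.frame(term = ".q1", or = 1, ci_lo = NA, ci_hi = NA,
                           p_value = NA),
                wald(qrows[qrows %in% rownames(sm)]))
  qtab$quartile <- as.integer(sub("^\\.q", "", qtab$term))
  qtab <- qtab[, c("quartile", "or", "ci_lo", "ci_hi", "p_value")]
  form_tr <- stats::reformulate(c(".qnum", setdiff(rhs, ".q")),
                                response = ".y")
  fit_tr <- stats::glm(form_tr, family = stats::binomial(), data = df)
  sm_tr <- summary(fit_tr)$coefficients
  trend <- wald_from(sm_tr, ".qnum")
  cov_rows <- intersect(c(".age", ".sexM"), rownames(sm))
  covs <- if (length(cov_rows) > 0) wald(cov_rows) else NULL
  structure(list(quartile_or = qtab, trend_or = trend, covariates = covs,
                 n = nrow(df), fit = fit, trend_fit = fit_tr),
            class = "ldlprs_logistic")
}

wald_from <- function(sm, row) {
  est <- sm[row, "Estimate"]
  se <- sm[row, "Std. Error"]
  data.frame(term = row, or = exp(est), ci_lo = exp(est - 1.96 * se),
             ci_hi = exp(est + 1.96 * se), p_value = sm[row, "Pr(>|z|)"],
             row.names = NULL)
}

#' @export
print.ldlprs_logistic <- function(x, ...) {
  cat(sprintf("Quartile logistic model (n = %d), reference: quartile 1\n",
              x$n))
  print(transform(x$quartile_or, or = round(or, 2), ci_lo = round(ci_lo, 2),
                  ci_hi = round(ci_hi, 2), p_value = signif(p_value, 2)),
        row.names = FALSE)
  cat(sprintf("  trend OR %.2f (%.2f, %.2f), p = %.3g\n", x$trend_or$or,
              x$trend_or$ci_lo, x$trend_or$ci_hi, x$trend_or$p_value))
  invisible(x)
}

#' Nonparametric and contingency-table group comparisons
#'
#' The comparison toolkit used for cohort tables: chi-square for
#' categorical contingency tables (with Yates continuity correction for
#' 2x2), Mann-Whitney U for two-group continuous comparisons,
#' Kruskal-Wallis for three or more groups with pairwise Mann-Whitney
#' post-hoc tests under Bonferroni adjustment when significant at 0.05.
#'
#' @param values for continuous tests a numeric vector; for `chi2` either a
#'   contingency matrix of counts (then `groups` is ignored) or a
#'   categorical vector
#' @param groups group labels aligned with `values` (ignored for a matrix)
#' @param test `"auto"` (default), `"chi2"`, `"mannwhitney"` or `"kruskal"`
#' @return object of class `ldlprs_groupcomp`: list with `test`,
#'   `statistic`, `p_value`, `summaries` (per-group medians/quartiles or
#'   counts), and `posthoc` (pairwise Bonferroni-adjusted p-values, or NULL)
#' @examples
#' mi <- matrix(c(75, 416, 46, 147), nrow = 2, byrow = TRUE)
#' groupCompare(mi, test = "chi2")$p_value  # ~0.011
#' @export
groupCompare <- function(values, groups = NULL,
                         test = c("auto", "chi2", "mannwhitney", "kruskal")) {
  test <- match.arg(test)
  if (is.matrix(values)) {
    if (test %in% c("mannwhitney", "kruskal"))
      stop("rank tests need raw values, not a contingency matrix",
           call. = FALSE)
    test <- "chi2"
  } else if (test == "auto") {
    if (is.character(values) || is.factor(values) || is.logical(values)) {
      test <- "chi2"
    } else {
      ng <- length(unique(groups))
      test <- if (ng == 2L) "mannwhitney" else "kruskal"
    }
  }
  if (test == "chi2") {
    tab <- if (is.matrix(values)) values else table(groups, values)
    if (any(tab < 0)) stop("counts must be nonnegative", call. = FALSE)
    correct <- all(dim(tab) == c(2L, 2L))
    ht <- stats::chisq.test(tab, correct = correct)
    return(structure(list(test = "chi-square",
                          statistic = unname(ht$statistic),
                          p_value = ht$p.value, summaries = tab,
                          posthoc = NULL), class = "ldlprs_groupcomp"))
  }
  g <- factor(groups)
  if (any(tabulate(g[!is.na(values)]) == 0) || nlevels(g) < 2L)
    stop("each group must be non-empty", call. = FALSE)
  summaries <- do.call(rbind, lapply(levels(g), function(lv) {
    x <- values[g == lv]
    data.frame(group = lv, n = length(x), median = stats::median(x),
               q1 = unname(stats::quantile(x, 0.25)),
               q3 = unname(stats::quantile(x, 0.75)))
  }))
  if (length(unique(values)) == 1L) {
    # fully tied data: the normal approximation degenerates (0/0); the
    # distributions are identical by construction, so report p = 1
    return(structure(list(test = if (test == "mannwhitney") "Mann-Whitney"
                                 else "Kruskal-Wallis",
                          statistic = 0, p_value = 1, summaries = summaries,
                          posthoc = NULL), class = "ldlprs_groupcomp"))
  }
  if (test == "mannwhitney") {
    if (nlevels(g) != 2L)
      stop("Mann-Whitney requires exactly 2 groups", call. = FALSE)
    ht <- stats::wilcox.test(values ~ g, exact = FALSE, correct = TRUE)
    return(structure(list(test = "Mann-Whitney", statistic = unname(ht$statistic),
                          p_value = ht$p.value, summaries = summaries,
                          posthoc = NULL), class = "ldlprs_groupcomp"))
  }
  ht <- stats::kruskal.test(values, g)
  posthoc <- NULL
  if (!is.na(ht$p.value) && ht$p.value < 0.05) {
    pw <- stats::pairwise.wilcox.test(values, g, p.adjust.method = "bonferroni",
                                      exact = FALSE)
    posthoc <- pw$p.value
  }
  structure(list(test = "Kruskal-Wallis", statistic = unname(ht$statistic),
                 p_value = ht$p.value, summaries = summaries,
                 posthoc = posthoc), class = "ldlprs_groupcomp")
}

#' @export
print.ldlprs_groupcomp <- function(x, ...) {
  cat(sprintf("%s test: statistic %.3f, p = %.4g\n", x$test, x$statistic,
              x$p_value))
  print(x$summaries)
  if (!is.null(x$posthoc)) {
    cat("Pairwise post-hoc (Bonferroni-adjusted):\n")
    print(signif(x$posthoc, 3))
  }
  invisible(x)
}
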
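#' Group-wise quantile summary of log SEM burdens
#'
#' Median, Q1 and Q3 of the natural-log burden per group, using linear
#' interpolation between order statistics (position `1 + (n - 1) * q`).
#' Samples with a zero count in the requested direction have no defined log
#' burden and are excluded (their number is reported in `n_zero`).
#'
#' @param burden `sem_burden` table (or any data.frame with `sample_id`,
#'   `n_<direction>`, `ln_<direction>`).
#' @param samples `sample_sheet`.
#' @param direction "hypo" or "hyper".
#' @param groups Group labels to summarise. Default `c("case", "control")`.
#' @return data.frame with one row per group: `group`, `n`, `n_zero`,
#'   `median`, `q1`, `q3` (natural-log units).
#' @export
summarize_burden <- function(burden, samples, direction = c("hypo", "hyper"),
                             groups = c("case", "control")) {
  direction <- match.arg(direction)
  lncol <- paste0("ln_", direction)
  grp <- samples$group[match(burden$sample_id, samples$sample_id)]
  out <- lapply(groups, function(g) {
    v <- burden[[lncol]][!is.na(grp) & grp == g]
    if (length(v) == 0L) stop("no samples in group '", g, "'")
    nz <- sum(is.na(v))
    v <- v[!is.na(v)]
    if (length(v) == 0L) stop("group '", g, "' has no positive ", direction, " counts")
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(group = g, n = length(v), n_zero = nz,
               median = q[2L], q1 = q[1L], q3 = q[3L], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Mixed-effects comparison of log SEM burdens between groups
#'
#' Fits a linear mixed model of the natural-log SEM burden on a case/control
#' indicator plus covariates, with a family-level random intercept, by
#' restricted maximum likelihood, and reports a Wald test on the group
#' coefficient (z reference distribution). If the random-effect variance
#' estimate hits the zero boundary the model degenerates to ordinary least
#' squares; in that case the fit falls back, with a warning, to OLS with
#' family-cluster-robust (CR0 sandwich) standard errors.
#'
#' Samples with a zero count in the chosen direction are dropped with a
#' warning (ln(0) is undefined; no pseudo-count offset is applied so that
#' quantile summaries stay on the exact ln(count) scale).
#'
#' @param burden `sem_burden` table.
#' @param samples `sample_sheet`.
#' @param direction "hypo" or "hyper".
#' @param covariates Character vector of sample-sheet columns used as fixed
#'   covariates. Default `"sex"`.
#' @return Object of class `sem_burden_fit` with elements `estimate`, `se`,
#'   `statistic`, `p_value`, `direction`, `covariates`, `n_obs`, `n_families`,
#'   `method` ("lmm-reml" or "ols-cluster"), `model` (the underlying fit).
#' @export
compare_burden_mixed <- function(burden, samples, direction = c("hypo", "hyper"),
                                 covariates = "sex") {
  direction <- match.arg(direction)
  lncol <- paste0("ln_", direction)
  idx <- match(burden$sample_id, samples$sample_id)
  if (anyNA(idx)) stop("burden contains samples absent from the sample sheet")
  d <- data.frame(ln = burden[[lncol]],
                  group = samples$group[idx],
                  family = factor(samples$family_id[idx]),
                  stringsAsFactors = FALSE)
  for (cv in covariates) d[[cv]] <- samples[[cv]][idx]
  d <- d[d$group %in% c("case", "control"), , drop = FALSE]
  nz <- sum(is.na(d$ln))
  if (nz > 0L) {
    warning(nz, " sample(s) with zero ", direction,
            " count excluded from the log-scale model")
    d <- d[!is.na(d$ln), , drop = FALSE]
  }
  if (sum(d$group == "case") < 4L || sum(d$group == "control") < 4L)
    stop("need at least 4 positive-count samples per group for direction '",
         direction, "'")
  d$is_case <- as.integer(d$group == "case")
  # drop covariates that are constant in the analysis subset
  covariates <- covariates[vapply(covariates,
                                  function(cv) length(unique(d[[cv]])) > 1L,
                                  logical(1L))]
  fml <- stats::reformulate(c("is_case", covariates, "(1 | family)"),
                            response = "ln")
  fit <- suppressMessages(lme4::lmer(fml, data = d, REML = TRUE))
  re_var <- as.data.frame(lme4::VarCorr(fit))$vcov[1L]
  singular <- lme4::isSingular(fit, tol = 1e-6) && re_var < 1e-8
  if (singular) {
    warning("family random-effect variance at zero boundary; ",
            "falling back to OLS with family-cluster-robust errors")
    ofml <- stats::reformulate(c("is_case", covariates), response = "ln")
    ofit <- stats::lm(ofml, data = d)
    vc <- sandwich::vcovCL(ofit, cluster = d$family, type = "HC0")
    ct <- lmtest::coeftest(ofit, vcov. = vc)
    est <- ct["is_case", "Estimate"]; se <- ct["is_case", "Std. Error"]
    z <- est / se
    method <- "ols-cluster"; model <- ofit
  } else {
    co <- summary(fit)$coefficients
    est <- co["is_case", "Estimate"]; se <- co["is_case", "Std. Error"]
    z <- est / se
    method <- "lmm-reml"; model <- fit
  }
  structure(list(estimate = unname(est), se = unname(se),
                 statistic = unname(z),
                 p_value = 2 * stats::pnorm(-abs(z)),
                 direction = direction, covariates = covariates,
                 n_obs = nrow(d), n_families = length(unique(d$family)),
                 n_zero_excluded = nz, method = method, model = model),
            class = "sem_burden_fit")
}

#' @export
print.sem_burden_fit <- function(x, ...) {
  cat(sprintf("Mixed-effects SEM burden comparison (%s-methylated)\n", x$direction))
  cat(sprintf("  ln(burden) ~ case + %s + (1 | family)   [%s]\n",
              paste(x$covariates, collapse = " + "), x$method))
  cat(sprintf("  group effect (case - control): %.4f (SE %.4f), z = %.3f, p = %.4g\n",
              x$estimate, x$se, x$statistic, x$p_value))
  cat(sprintf("  %d samples in %d families", x$n_obs, x$n_families))
  if (x$n_zero_excluded > 0L)
    cat(sprintf(" (%d zero-count sample(s) excluded)", x$n_zero_excluded))
  cat("\n")
  invisible(x)
}

#' @export
summary.sem_burden_fit <- function(object, ...) {
  print(object)
  cat("\nUnderlying model summary:\n")
  print(summary(object$model))
  invisible(object)
}

#' @export
coef.sem_burden_fit <- function(object, ...) {
  c(is_case = object$estimate)
}

#' Wilcoxon signed-rank test on within-pair log burden differences
#'
#' Nonparametric companion to [compare_burden_mixed()], restricted to
#' complete discordant twin pairs (one case, one control). Differences are
#' case minus control on the natural-log scale; the exact signed-rank null
#' distribution is used for up to 25 pairs (no ties), the normal
#' approximation otherwise.
#'
#' @param burden `sem_burden` table.
#' @param samples `sample_sheet`.
#' @param direction "hypo" or "hyper".
#' @param alternative "two.sided" (default), "greater" (cases exceed
#'   controls) or "less".
#' @return list with `statistic` (signed-rank V), `p_value`, `n_pairs`,
#'   `differences`.
#' @export
paired_signed_rank <- function(burden, samples, direction = c("hypo", "hyper"),
                               alternative = c("two.sided", "greater", "less")) {
  direction <- match.arg(direction)
  alternative <- match.arg(alternative)
  lncol <- paste0("ln_", direction)
  idx <- match(burden$sample_id, samples$sample_id)
  d <- data.frame(ln = burden[[lncol]], group = samples$group[idx],
                  pair = samples$pair_id[idx], stringsAsFactors = FALSE)
  d <- d[!is.na(d$ln) & d$group %in% c("case", "control"), , drop = FALSE]
  case_ln <- tapply(ifelse(d$group == "case", d$ln, NA_real_), d$pair,
                    function(v) if (sum(!is.na(v)) == 1L) v[!is.na(v)] else NA_real_)
  ctrl_ln <- tapply(ifelse(d$group == "control", d$ln, NA_real_), d$pair,
                    function(v) if (sum(!is.na(v)) == 1L) v[!is.na(v)] else NA_real_)
  keep <- !is.na(case_ln) & !is.na(ctrl_ln)
  diffs <- case_ln[keep] - ctrl_ln[keep]
  n <- length(diffs)
  if (n < 5L) stop("fewer than 5 complete discordant pairs (", n, ")")
  if (all(diffs == 0)) {
    warning("all within-pair differences are zero")
    return(list(statistic = 0, p_value = 1, n_pairs = n, differences = diffs))
  }
  wt <- stats::wilcox.test(diffs, alternative = alternative,
                           exact = n <= 25L, correct = FALSE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_pairs = n, differences = unname(diffs))
}
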
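#' Downsample minute-resolution values for statistics
#'
#' Short spans (< 3 days) are reduced to hourly means, longer spans (>= 3
#' days, including exactly 3 as the documented tie-break) to daily means, so
#' that rank tests are not inflated by the 1-minute sampling rate.
#'
#' @param values numeric vector on a uniform 1-minute grid (`NA`s are ignored
#'   within each bin).
#' @param span_days span of the data in days (default `length(values) / 1440`).
#' @return Vector of bin means (48 values for a 2-day span, one per day for
#'   longer spans).
#' @export
downsample_for_stats <- function(values, span_days = length(values) / 1440) {
  if (length(values) == 0) stop("empty span")
  width <- if (span_days < 3) 60L else 1440L
  bin <- (seq_along(values) - 1L) %/% width
  as.numeric(tapply(values, bin, mean, na.rm = TRUE))
}

#' Two-group Mann-Whitney rank sum test
#'
#' @param a,b numeric vectors, each with at least 3 values.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"` (the
#'   alternative refers to `a` relative to `b`).
#' @return A list of class `comparison_result`: `test = "mann_whitney"`,
#'   `statistic` (U for group `a`), `p_value`, `group_ns`.
#' @export
rank_test_two <- function(a, b, alternative = "two.sided") {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 3 || length(b) < 3) stop("each group needs at least 3 values")
  if (length(unique(c(a, b))) == 1) stop("all values tied across both groups")
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = alternative))
  structure(list(test = "mann_whitney", statistic = unname(wt$statistic),
                 p_value = wt$p.value, group_ns = c(length(a), length(b)),
                 pairwise = NULL),
            class = "comparison_result")
}

# Dunn z statistics on pooled mean ranks after a Kruskal-Wallis test,
# with tie correction
dunn_independent <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  n <- lengths(groups); N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  k <- length(groups)
  z <- matrix(NA_real_, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[i] + 1 / n[j]))
    z[i, j] <- z[j, i] <- (rbar[i] - rbar[j]) / se
  }
  z
}

# Dunn z statistics on within-block mean ranks after a Friedman test
dunn_repeated <- function(m) {
  k <- ncol(m); n <- nrow(m)
  rbar <- colMeans(t(apply(m, 1, rank)))
  se <- sqrt(k * (k + 1) / (6 * n))
  z <- matrix(NA_real_, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    z[i, j] <- z[j, i] <- (rbar[i] - rbar[j]) / se
  }
  z
}

#' Omnibus rank test with Dunn's post hoc comparisons
#'
#' Independent designs use a Kruskal-Wallis chi-squared omnibus test; repeated
#' designs (conditions measured within blocks) use a Friedman test with
#' within-block ranking. Pairwise Dunn z statistics on mean ranks are computed
#' with the stated multiplicity adjustment (Holm step-down by default,
#' Bonferroni available); post hoc results are reported as significant only
#' when the omnibus p-value is below `alpha`.
#'
#' @param groups for `design = "independent"`, a list of numeric vectors; for
#'   `design = "repeated"`, a blocks-by-conditions numeric matrix.
#' @param design `"independent"` or `"repeated"`.
#' @param alpha omnibus gate for the post hoc flags (default 0.05).
#' @param adjust `"holm"` (default) or `"bonferroni"`.
#' @return A list of class `comparison_result`: `test`, `statistic`
#'   (chi-squared), `df`, `p_value`, `group_ns`, `pairwise` (symmetric matrix
#'   of adjusted p-values), `pairwise_z`, `omnibus_significant`.
#' @export
omnibus_with_dunn <- function(groups, design = c("independent", "repeated"),
                              alpha = 0.05, adjust = c("holm", "bonferroni")) {
  design <- match.arg(design); adjust <- match.arg(adjust)
  if (design == "independent") {
    stopifnot(is.list(groups), length(groups) >= 3)
    kt <- stats::kruskal.test(groups)
    stat <- unname(kt$statistic); df <- unname(kt$parameter); p <- kt$p.value
    z <- dunn_independent(groups)
    ns <- lengths(groups)
    k <- length(groups)
  } else {
    m <- as.matrix(groups)
    if (ncol(m) < 3 || nrow(m) < 2) stop("repeated design needs >= 3 conditions and >= 2 blocks")
    if (anyNA(m)) stop("unequal block structure: missing cells in the block matrix")
    ft <- stats::friedman.test(m)
    stat <- unname(ft$statistic); df <- unname(ft$parameter); p <- ft$p.value
    if (!is.finite(stat)) { stat <- 0; p <- 1 }   # fully tied blocks carry no signal
    z <- dunn_repeated(m)
    ns <- rep(nrow(m), ncol(m))
    k <- ncol(m)
  }
  raw <- 2 * stats::pnorm(-abs(z[upper.tri(z)]))
  adj <- stats::p.adjust(raw, method = adjust)
  pw <- matrix(NA_real_, k, k)
  pw[upper.tri(pw)] <- adj
  pw[lower.tri(pw)] <- t(pw)[lower.tri(pw)]
  structure(list(test = if (design == "independent") "kruskal_wallis" else "friedman",
                 statistic = stat, df = df, p_value = p, group_ns = ns,
                 pairwise = pw, pairwise_z = z,
                 omnibus_significant = is.finite(p) && p < alpha),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: statistic = %.4g, p = %.4g\n",
              x$test, x$statistic, x$p_value))
  if (!is.null(x$pairwise)) {
    cat("Dunn-adjusted pairwise p-values:\n")
    print(round(x$pairwise, 4))
  }
  invisible(x)
}

#' Mann-Kendall trend test
#'
#' Computes the Mann-Kendall score `S = sum_{i<j} sign(x_j - x_i)`, Kendall's
#' tau (tie-corrected), and a normal-approximation p-value with tie and
#' continuity corrections.
#'
#' @param values numeric vector, at least 4 values.
#' @return A list of class `trend_result`: `S`, `tau`, `p_value`, `direction`
#'   (`sign(S)`), `var_s`, `n`.
#' @export
mann_kendall <- function(values) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 4) stop("need at least 4 values")
  d <- sign(outer(x, x, "-"))
  S <- sum(d[lower.tri(d)])                  # sign(x_j - x_i) for j > i
  ties <- table(x)
  var_s <- (n * (n - 1) * (2 * n + 5) - sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  denom <- sqrt((n * (n - 1) / 2 - sum(ties * (ties - 1)) / 2) * (n * (n - 1) / 2))
  tau <- if (denom > 0) S / denom else 0
  if (var_s > 0 && S != 0) {
    z <- (S - sign(S)) / sqrt(var_s)
    p <- 2 * stats::pnorm(-abs(z))
  } else {
    p <- 1
  }
  structure(list(S = as.integer(S), tau = tau, p_value = p,
                 direction = sign(S), var_s = var_s, n = n),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("<trend_result> S = %d, tau = %.3f, p = %.4g (n = %d)\n",
              x$S, x$tau, x$p_value, x$n))
  invisible(x)
}

#' Mixed-effects regression of daily circadian power on fE2
#'
#' Fits `power ~ 1 + fe2 + (1 + fe2 | id)` by maximum likelihood (so AIC is
#' comparable across fixed-effect structures). If the correlated
#' random-slope fit is singular or fails, the model falls back to a random
#' intercept only and the result is flagged. "R squared" is the marginal
#' (fixed-effects) variance fraction, `var(X beta) / var(y)`.
#'
#' @param daily data frame with columns `power` (daily circadian power,
#'   normalized per animal), `fe2` and `id` (animal); at least 2 animals with
#'   3 paired days each.
#' @return A list of class `mixed_model_result`: `intercept`, `slope`,
#'   `random_variances` (intercept, slope, residual), `r2_marginal`, `AIC`,
#'   `fallback` (TRUE when the random-slope fit was abandoned), `fit`.
#' @export
mixed_cr_fe2 <- function(daily) {
  stopifnot(all(c("power", "fe2", "id") %in% names(daily)))
  d <- daily[stats::complete.cases(daily[, c("power", "fe2", "id")]), ]
  per_id <- table(d$id)
  if (length(per_id) < 2 || any(per_id < 3)) {
    stop("need >= 2 animals with >= 3 paired days each")
  }
  fallback <- FALSE
  fit <- tryCatch(
    suppressWarnings(suppressMessages(
      lme4::lmer(power ~ fe2 + (1 + fe2 | id), data = d, REML = FALSE))),
    error = function(e) NULL)
  if (is.null(fit) || lme4::isSingular(fit, tol = 1e-5)) {
    fallback <- TRUE
    fit2 <- tryCatch(
      suppressWarnings(suppressMessages(
        lme4::lmer(power ~ fe2 + (1 | id), data = d, REML = FALSE))),
      error = function(e) NULL)
    if (!is.null(fit2)) fit <- fit2
  }
  if (is.null(fit)) stop("mixed model could not be fitted")
  fe <- lme4::fixef(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_int <- vc$vcov[vc$grp == "id" & vc$var1 == "(Intercept)" & is.na(vc$var2)]
  var_slp <- vc$vcov[vc$grp == "id" & !is.na(vc$var1) & vc$var1 == "fe2" & is.na(vc$var2)]
  sigma2 <- vc$vcov[vc$grp == "Residual"]
  fitted_fixed <- fe[1] + fe[2] * d$fe2
  vy <- stats::var(d$power)
  r2 <- if (vy > 0) min(stats::var(fitted_fixed) / vy, 1) else 1
  structure(list(intercept = unname(fe[1]), slope = unname(fe[2]),
                 random_variances = c(intercept = if (length(var_int)) var_int else 0,
                                      slope = if (length(var_slp)) var_slp else 0,
                                      residual = sigma2),
                 r2_marginal = r2, AIC = stats::AIC(fit),
                 fallback = fallback, fit = fit),
            class = "mixed_model_result")
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat(sprintf("<mixed_model_result> slope = %.4g, intercept = %.4g, marginal R2 = %.3f, AIC = %.1f%s\n",
              x$slope, x$intercept, x$r2_marginal, x$AIC,
              if (x$fallback) " (random-intercept fallback)" else ""))
  invisible(x)
}
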
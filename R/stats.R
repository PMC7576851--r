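#' Normality- and variance-screened two-group comparison
#'
#' Implements the statistical decision procedure of the pipeline: both
#' groups are screened with the Shapiro-Wilk normality test and the F test
#' of equality of variances; if all three screens pass at `alpha`, the
#' parametric branch (Student's two-sample t test, pooled variance) is
#' taken, otherwise the nonparametric branch (Mann-Whitney test). Degenerate
#' zero-variance samples, on which Shapiro-Wilk is undefined, route to the
#' nonparametric branch.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 3.
#' @param alpha Screening and significance level.
#' @return A `test_report` list: `test`, `branch`, `statistic`, `p_value`,
#'   screening p-values, and per-group mean +/- sample SD.
#' @export
choose_and_compare <- function(group_a, group_b, alpha = 0.05) {
  if (length(group_a) < 3L || length(group_b) < 3L) {
    stop_histoflow("each group needs n >= 3 (normality screening is undefined below that)")
  }
  safe_shapiro <- function(x) {
    tryCatch(stats::shapiro.test(x)$p.value, error = function(e) NA_real_)
  }
  sw_a <- safe_shapiro(group_a)
  sw_b <- safe_shapiro(group_b)
  fv <- tryCatch(stats::var.test(group_a, group_b)$p.value, error = function(e) NA_real_)
  screens <- c(shapiro_a = sw_a, shapiro_b = sw_b, f_variance = fv)
  parametric <- all(!is.na(screens)) && all(screens > alpha)
  if (parametric) {
    ht <- stats::t.test(group_a, group_b, var.equal = TRUE)
    test <- "Student's t"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(group_a, group_b))
    test <- "Mann-Whitney"
  }
  structure(
    list(
      test = test,
      branch = if (parametric) "parametric" else "nonparametric",
      statistic = unname(ht$statistic),
      p_value = ht$p.value,
      significant = ht$p.value <= alpha,
      alpha = alpha,
      screening = screens,
      summary = data.frame(
        group = c("a", "b"),
        n = c(length(group_a), length(group_b)),
        mean = c(mean(group_a), mean(group_b)),
        sd = c(stats::sd(group_a), stats::sd(group_b))
      )
    ),
    class = "test_report"
  )
}

#' @export
print.test_report <- function(x, ...) {
  cat(sprintf("<test_report> %s (%s branch): statistic %.4g, p = %.4g%s\n",
              x$test, x$branch, x$statistic, x$p_value,
              if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}

#' Correlation with pathology load, with strength classification
#'
#' Pearson correlation on the parametric branch, Spearman on the
#' nonparametric branch, with the correlation-strength convention used for
#' marker-abundance vs pathology-load relationships: strong if r >= 0.8,
#' moderate if 0.7 <= r < 0.8, otherwise weak/none. By default the rule is
#' applied to the signed r; set `strength_on = "absolute"` to classify |r|.
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @param branch `"parametric"` (Pearson) or `"nonparametric"` (Spearman).
#' @param alpha Significance level.
#' @param strength_on Classify the signed r or |r|.
#' @return List with `r`, `p_value`, `strength`, `significant`, `method`.
#' @export
correlate <- function(x, y, branch = c("parametric", "nonparametric"),
                      alpha = 0.05, strength_on = c("signed", "absolute")) {
  branch <- match.arg(branch)
  strength_on <- match.arg(strength_on)
  if (length(x) != length(y)) stop_histoflow("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop_histoflow("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_histoflow("correlation is undefined for constant input")
  }
  method <- if (branch == "parametric") "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  cls <- classify_correlation(unname(ct$estimate), ct$p.value, alpha, strength_on)
  c(list(method = method, n = length(x)), cls)
}

#' Classify a correlation coefficient's strength and significance
#'
#' @param r Correlation coefficient.
#' @param p Its p-value (NA if unknown).
#' @param alpha Significance level.
#' @param strength_on Apply the rule to the signed r or to |r|.
#' @return List with `r`, `p_value`, `strength` (`"strong"`, `"moderate"`,
#'   `"weak/none"`) and `significant`.
#' @export
classify_correlation <- function(r, p = NA_real_, alpha = 0.05,
                                 strength_on = c("signed", "absolute")) {
  strength_on <- match.arg(strength_on)
  v <- if (strength_on == "absolute") abs(r) else r
  strength <- if (v >= 0.8) "strong" else if (v >= 0.7) "moderate" else "weak/none"
  list(r = r, p_value = p, strength = strength,
       significant = !is.na(p) && p <= alpha)
}

#' Read a case-metadata table
#'
#' CSV with columns `case_id, group, age, sex, pmd, staging` (or the
#' long-form names `age_years` / `pmd_hours`); `group` must be `normal` or
#' `AD`; `age`/`pmd` may be missing (NA), other fields may not.
#'
#' @param path CSV path.
#' @return data.frame with canonical columns `case_id, group, age_years,
#'   sex, pmd_hours, staging`.
#' @export
read_case_metadata <- function(path) {
  if (!file.exists(path)) stop_histoflow(sprintf("no such metadata file: '%s'", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ren <- c(age = "age_years", pmd = "pmd_hours")
  for (nm in names(ren)) {
    if (nm %in% names(df) && !ren[[nm]] %in% names(df)) {
      names(df)[names(df) == nm] <- ren[[nm]]
    }
  }
  need <- c("case_id", "group", "age_years", "sex", "pmd_hours", "staging")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop_histoflow(sprintf("metadata is missing columns: %s", paste(missing, collapse = ", ")))
  }
  bad <- setdiff(unique(df$group), c("normal", "AD"))
  if (length(bad)) {
    stop_histoflow(sprintf("group must be 'normal' or 'AD' (found: %s)",
                           paste(bad, collapse = ", ")))
  }
  df[need]
}

#' Per-group cohort summaries (mean and sample SD)
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of age
#' and post-mortem delay per group, with missing values excluded pairwise.
#' A single non-missing value yields a mean but an NA standard deviation.
#'
#' @param meta Metadata data.frame (see [read_case_metadata()]).
#' @return data.frame, one row per group, with n, mean and SD of age and
#'   post-mortem delay.
#' @export
summarise_cohort <- function(meta) {
  need <- c("group", "age_years", "pmd_hours")
  missing <- setdiff(need, names(meta))
  if (length(missing)) {
    stop_histoflow(sprintf("metadata is missing columns: %s", paste(missing, collapse = ", ")))
  }
  one <- function(g) {
    sub <- meta[meta$group == g, ]
    age <- sub$age_years[!is.na(sub$age_years)]
    pmd <- sub$pmd_hours[!is.na(sub$pmd_hours)]
    if (!length(age) && !length(pmd)) {
      stop_histoflow(sprintf("group '%s' has no non-missing age or pmd values", g))
    }
    data.frame(
      group = g, n_cases = nrow(sub),
      n_age = length(age),
      age_mean = if (length(age)) mean(age) else NA_real_,
      age_sd = if (length(age) >= 2L) stats::sd(age) else NA_real_,
      n_pmd = length(pmd),
      pmd_mean = if (length(pmd)) mean(pmd) else NA_real_,
      pmd_sd = if (length(pmd) >= 2L) stats::sd(pmd) else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, lapply(unique(meta$group), one))
}

# ---- multi-group designs ----------------------------------------------------

#' Two-way ANOVA (population x group) with Tukey contrasts
#'
#' Between-subjects two-factor ANOVA of, e.g., mean population intensity by
#' myeloid population and disease group, with Tukey-adjusted pairwise
#' contrasts on the interaction cells. Degenerate all-equal data report
#' F = 0 and adjusted p = 1 rather than NaN.
#'
#' @param df data.frame with columns `value`, `population`, `group`.
#' @return List with the ANOVA table (`anova`) and Tukey contrasts
#'   (`tukey`).
#' @export
two_way_anova_tukey <- function(df) {
  need <- c("value", "population", "group")
  if (!all(need %in% names(df))) {
    stop_histoflow("need columns value, population, group")
  }
  df$population <- factor(df$population)
  df$group <- factor(df$group)
  cells <- table(df$population, df$group)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    stop_histoflow(sprintf(
      "empty design cells: %s",
      paste(sprintf("%s:%s", rownames(cells)[empty[, 1]],
                    colnames(cells)[empty[, 2]]), collapse = ", ")
    ))
  }
  fit <- stats::aov(value ~ population * group, data = df)
  an <- as.data.frame(summary(fit)[[1]])
  names(an) <- c("df", "sum_sq", "mean_sq", "F", "p")
  an$term <- trimws(rownames(an))
  rownames(an) <- NULL
  # all-equal data: zero effect and zero residual SS -> no evidence of effect
  zero <- !is.na(an$sum_sq) & an$sum_sq < 1e-12
  an$F[zero & an$term != "Residuals"] <- 0
  an$p[zero & an$term != "Residuals"] <- 1
  tk <- stats::TukeyHSD(fit, "population:group")[[1]]
  tk <- data.frame(contrast = rownames(tk), tk, row.names = NULL)
  names(tk) <- c("contrast", "diff", "lwr", "upr", "p_adj")
  tk$p_adj[abs(tk$diff) < 1e-12 & !is.finite(tk$p_adj)] <- 1
  tk$p_adj[is.nan(tk$p_adj) & abs(tk$diff) < 1e-12] <- 1
  list(anova = an[, c("term", "df", "sum_sq", "mean_sq", "F", "p")], tukey = tk)
}

#' Greenhouse-Geisser (Box) sphericity correction factor
#'
#' Computed from the sample covariance of the within-subject measures; equals
#' 1 under compound symmetry and 1/(k-1) at maximal sphericity violation.
#'
#' @param Y n x k matrix: one row per subject, one column per
#'   within-subject condition.
#' @return Epsilon in `[1/(k-1), 1]`.
#' @export
gg_epsilon <- function(Y) {
  Y <- as.matrix(Y)
  k <- ncol(Y)
  if (k < 2L || nrow(Y) < 2L) stop_histoflow("need >= 2 subjects and >= 2 conditions")
  S <- stats::cov(Y)
  C <- diag(k) - matrix(1 / k, k, k)
  D <- C %*% S %*% C
  eps <- sum(diag(D))^2 / ((k - 1) * sum(D^2))
  min(max(eps, 1 / (k - 1)), 1)
}

#' Repeated-measures one-within-factor ANOVA with Geisser-Greenhouse
#' correction and Tukey contrasts
#'
#' The design of the plaque-proximity abundance analysis: each case
#' (subject) contributes one value per spatial location, the location effect
#' is tested with the F ratio of the location to the subject-by-location
#' error stratum, the p-value is Geisser-Greenhouse corrected via
#' [gg_epsilon()], and locations are compared pairwise with Tukey's
#' studentized range on the within-subject error.
#'
#' @param df data.frame with columns `value`, `location` (within factor)
#'   and `subject`.
#' @return List with `F`, `df1`, `df2`, `epsilon`, corrected and
#'   uncorrected p-values, and Tukey pairwise contrasts.
#' @export
rm_anova_gg <- function(df) {
  need <- c("value", "location", "subject")
  if (!all(need %in% names(df))) {
    stop_histoflow("need columns value, location, subject")
  }
  df$location <- factor(df$location)
  df$subject <- factor(df$subject)
  tab <- table(df$subject, df$location)
  if (any(tab != 1)) {
    bad <- which(tab != 1, arr.ind = TRUE)
    stop_histoflow(sprintf(
      "repeated-measures design needs exactly one value per subject x location; offending cells: %s",
      paste(sprintf("%s:%s", rownames(tab)[bad[, 1]], colnames(tab)[bad[, 2]]),
            collapse = ", ")
    ))
  }
  Y <- matrix(NA_real_, nlevels(df$subject), nlevels(df$location),
              dimnames = list(levels(df$subject), levels(df$location)))
  Y[cbind(as.integer(df$subject), as.integer(df$location))] <- df$value
  n <- nrow(Y); k <- ncol(Y)
  grand <- mean(Y)
  ss_loc <- n * sum((colMeans(Y) - grand)^2)
  ss_sub <- k * sum((rowMeans(Y) - grand)^2)
  ss_tot <- sum((Y - grand)^2)
  ss_err <- ss_tot - ss_loc - ss_sub
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  ms_loc <- ss_loc / df1; ms_err <- ss_err / df2
  if (ss_loc < 1e-12 && ss_err < 1e-12) {
    Fv <- 0; p_unc <- 1; p_gg <- 1; eps <- 1
  } else {
    Fv <- ms_loc / ms_err
    eps <- gg_epsilon(Y)
    p_unc <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
    p_gg <- stats::pf(Fv, eps * df1, eps * df2, lower.tail = FALSE)
  }
  cm <- colMeans(Y)
  prs <- utils::combn(k, 2)
  tukey <- data.frame(
    contrast = paste(colnames(Y)[prs[2, ]], colnames(Y)[prs[1, ]], sep = "-"),
    diff = cm[prs[2, ]] - cm[prs[1, ]],
    row.names = NULL
  )
  if (ms_err > 1e-12) {
    q <- abs(tukey$diff) / sqrt(ms_err / n)
    tukey$p_adj <- stats::ptukey(q, k, df2, lower.tail = FALSE)
  } else {
    tukey$p_adj <- ifelse(abs(tukey$diff) < 1e-12, 1, 0)
  }
  list(F = Fv, df1 = df1, df2 = df2, epsilon = eps,
       p_uncorrected = p_unc, p_gg = p_gg, tukey = tukey,
       location_means = cm)
}

#' Multi-group tests for population x group layouts
#'
#' Dispatches to the between-subjects two-way ANOVA with Tukey contrasts
#' (`design = "between"`; columns `value`, `population`, `group`) or the
#' repeated-measures variant with the Geisser-Greenhouse correction
#' (`design = "repeated"`; columns `value`, `location`, `subject`).
#'
#' @param df Long-format data.frame (see the two designs above).
#' @param design `"between"` or `"repeated"`.
#' @return See [two_way_anova_tukey()] / [rm_anova_gg()].
#' @export
multi_group_tests <- function(df, design = c("between", "repeated")) {
  design <- match.arg(design)
  if (design == "between") two_way_anova_tukey(df) else rm_anova_gg(df)
}

#' Effect-of-sex screening comparisons
#'
#' Thin wrappers for the covariate screens: one-way ANOVA with step-down
#' Sidak (Holm-Sidak) adjusted pairwise t tests on the parametric branch,
#' Kruskal-Wallis with Dunn's rank-based pairwise z tests on the
#' nonparametric branch.
#'
#' @param values Numeric response.
#' @param groups Factor (e.g. sex).
#' @param branch `"parametric"` or `"nonparametric"`.
#' @return List with the omnibus `p_value`, `method`, and `pairwise`
#'   adjusted comparisons.
#' @export
compare_by_sex <- function(values, groups, branch = c("parametric", "nonparametric")) {
  branch <- match.arg(branch)
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop_histoflow("need at least two groups")
  holm_sidak <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    run <- 0
    for (i in seq_len(m)) {
      run <- max(run, 1 - (1 - p[o[i]])^(m - i + 1))
      adj[o[i]] <- min(run, 1)
    }
    adj
  }
  prs <- utils::combn(levels(groups), 2)
  if (branch == "parametric") {
    fit <- stats::aov(values ~ groups)
    omni <- summary(fit)[[1]][["Pr(>F)"]][1]
    p <- apply(prs, 2, function(g) {
      stats::t.test(values[groups == g[1]], values[groups == g[2]],
                    var.equal = TRUE)$p.value
    })
    method <- "one-way ANOVA + Holm-Sidak t tests"
  } else {
    omni <- stats::kruskal.test(values, groups)$p.value
    r <- rank(values)
    N <- length(values)
    ties <- table(values)
    tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
    p <- apply(prs, 2, function(g) {
      i <- groups == g[1]; j <- groups == g[2]
      z <- (mean(r[i]) - mean(r[j])) /
        sqrt((N * (N + 1) / 12 - tie_corr) * (1 / sum(i) + 1 / sum(j)))
      2 * stats::pnorm(-abs(z))
    })
    method <- "Kruskal-Wallis + Dunn's tests"
  }
  list(
    method = method, p_value = omni,
    pairwise = data.frame(
      contrast = paste(prs[1, ], prs[2, ], sep = "-"),
      p = p, p_adj = holm_sidak(p)
    )
  )
}
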
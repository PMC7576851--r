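test_that("normal samples take the parametric branch with the closed-form t statistic", {
  set.seed(123)
  a <- rnorm(20, 10, 2)
  b <- rnorm(20, 11, 2)
  rep <- choose_and_compare(a, b)
  expect_equal(rep$branch, "parametric")
  expect_equal(rep$test, "Student's t")
  # pooled-variance t by hand
  sp2 <- ((19 * var(a)) + (19 * var(b))) / 38
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 20 + 1 / 20))
  expect_equal(rep$statistic, t_hand)
})

test_that("normality or variance violations force the nonparametric branch", {
  set.seed(7)
  a <- c(rnorm(15), 40)   # gross outlier
  b <- rnorm(16)
  expect_lt(shapiro.test(a)$p.value, 0.05)  # construction check
  rep <- choose_and_compare(a, b)
  expect_equal(rep$branch, "nonparametric")
  expect_equal(rep$test, "Mann-Whitney")

  # normal but heteroscedastic: F test fails, so Mann-Whitney
  set.seed(8)
  c1 <- rnorm(25, 0, 1)
  c2 <- rnorm(25, 0, 8)
  expect_lt(var.test(c1, c2)$p.value, 0.05)
  expect_equal(choose_and_compare(c1, c2)$branch, "nonparametric")
})

test_that("identical groups never report a difference", {
  x <- c(3, 5, 7, 9, 11)
  rep <- choose_and_compare(x, x)
  expect_gt(rep$p_value, 0.05)
  expect_false(rep$significant)
  expect_error(choose_and_compare(c(1, 2), c(1, 2, 3)), "n >= 3")
})

test_that("branch choice is a pure function of the samples", {
  set.seed(11)
  a <- rnorm(12); b <- rnorm(12)
  r1 <- choose_and_compare(a, b)
  r2 <- choose_and_compare(a, b)
  expect_identical(r1$branch, r2$branch)
  expect_identical(r1$p_value, r2$p_value)
})

test_that("correlations are classified by the strength rule", {
  x <- 1:10
  r <- correlate(x, x, "parametric")
  expect_equal(r$r, 1)
  expect_equal(r$strength, "strong")
  # r = 0.905, p = 0.005: strong and significant
  cls <- classify_correlation(0.905, 0.005)
  expect_equal(cls$strength, "strong")
  expect_true(cls$significant)
  expect_equal(classify_correlation(0.75)$strength, "moderate")
  expect_equal(classify_correlation(0.5)$strength, "weak/none")
  # signed convention: r = -1 is unclassified unless |r| is requested
  neg <- correlate(x, -x, "parametric")
  expect_equal(neg$r, -1)
  expect_equal(neg$strength, "weak/none")
  expect_equal(correlate(x, -x, "parametric", strength_on = "absolute")$strength,
               "strong")
  expect_error(correlate(rep(1, 5), 1:5, "parametric"), "constant")
})

test_that("Pearson r is affine-invariant; Spearman r is monotone-invariant", {
  set.seed(21)
  x <- rnorm(15); y <- x + rnorm(15, 0, 0.5)
  expect_equal(correlate(2 * x + 3, y, "parametric")$r,
               correlate(x, y, "parametric")$r)
  expect_equal(correlate(exp(x), y, "nonparametric")$r,
               correlate(x, y, "nonparametric")$r)
})

test_that("cohort summaries reproduce the packaged cohort table", {
  meta <- read_case_metadata(system.file("extdata", "cohort_mtg.csv",
                                         package = "histoflow"))
  s <- summarise_cohort(meta)
  normal <- s[s$group == "normal", ]
  ad <- s[s$group == "AD", ]
  expect_equal(normal$age_mean, 83.5)
  expect_equal(ad$age_mean, 87.5)
  expect_equal(round(ad$age_sd, 1), 5.6)
  expect_equal(round(ad$pmd_mean, 1), 12.7)
  expect_equal(round(ad$pmd_sd, 1), 9.2)
  expect_equal(ad$n_pmd, 7L)  # one missing value excluded pairwise
})

test_that("degenerate cohort fields are handled", {
  meta <- data.frame(case_id = "x", group = "normal", age_years = 70,
                     sex = "male", pmd_hours = NA_real_, staging = "-")
  s <- summarise_cohort(meta)
  expect_equal(s$age_mean, 70)
  expect_true(is.na(s$age_sd))
  meta2 <- data.frame(case_id = "x", group = "AD", age_years = NA_real_,
                      sex = "male", pmd_hours = NA_real_, staging = "-")
  expect_error(summarise_cohort(meta2), "non-missing")
})

test_that("two-way ANOVA matches a hand sums-of-squares computation", {
  set.seed(31)
  d <- expand.grid(population = c("low", "high"), group = c("normal", "AD"),
                   rep = 1:6)
  effect <- ifelse(d$population == "low", 2, 0) + ifelse(d$group == "AD", 3, 0)
  d$value <- effect + rnorm(nrow(d))
  res <- two_way_anova_tukey(d)
  # oracle: balanced-design sums of squares from first principles
  grand <- mean(d$value)
  n_per <- 12
  ss_pop <- n_per * sum((tapply(d$value, d$population, mean) - grand)^2)
  ss_grp <- n_per * sum((tapply(d$value, d$group, mean) - grand)^2)
  cellm <- tapply(d$value, list(d$population, d$group), mean)
  ss_cells <- 6 * sum((cellm - grand)^2)
  ss_int <- ss_cells - ss_pop - ss_grp
  ss_res <- sum((d$value - cellm[cbind(as.character(d$population), as.character(d$group))])^2)
  an <- res$anova
  expect_equal(an$sum_sq[an$term == "population"], ss_pop)
  expect_equal(an$sum_sq[an$term == "group"], ss_grp)
  expect_equal(an$sum_sq[an$term == "population:group"], ss_int, tolerance = 1e-8)
  expect_equal(an$F[an$term == "population"], (ss_pop / 1) / (ss_res / 20))
  expect_true(all(c("contrast", "diff", "p_adj") %in% names(res$tukey)))
})

test_that("all-equal observations give F = 0 and adjusted p = 1", {
  d <- expand.grid(population = c("a", "b"), group = c("g1", "g2"), rep = 1:4)
  d$value <- 5
  res <- two_way_anova_tukey(d)
  expect_true(all(res$anova$F[res$anova$term != "Residuals"] == 0))
  expect_true(all(res$anova$p[res$anova$term != "Residuals"] == 1))
  expect_true(all(res$tukey$p_adj == 1))

  rm <- data.frame(value = 2, location = rep(c("p", "adj", "non"), each = 5),
                   subject = rep(1:5, 3))
  r <- rm_anova_gg(rm)
  expect_equal(r$F, 0)
  expect_equal(r$p_gg, 1)
})

test_that("empty design cells are reported by name", {
  d <- data.frame(population = c("a", "a", "b"), group = c("g1", "g2", "g1"),
                  value = 1:3)
  expect_error(two_way_anova_tukey(d), "b:g2")
})

test_that("repeated-measures F agrees with aov and GG epsilon is 1 under compound symmetry", {
  set.seed(41)
  n <- 8; k <- 4
  d <- expand.grid(subject = factor(1:n), location = factor(1:k))
  d$value <- rnorm(n)[d$subject] + c(0, 1, 2, 1.5)[d$location] + rnorm(n * k)
  res <- rm_anova_gg(d)
  fit <- summary(aov(value ~ location + Error(subject), data = d))
  F_aov <- fit[["Error: Within"]][[1]]$`F value`[1]
  expect_equal(res$F, F_aov, tolerance = 1e-10)
  expect_true(res$epsilon >= 1 / (k - 1) && res$epsilon <= 1)
  expect_true(res$p_gg >= res$p_uncorrected)

  # construct data whose sample covariance is exactly compound symmetric
  set.seed(42)
  W <- matrix(rnorm(n * k), n, k)
  Wc <- scale(W, scale = FALSE)
  Y0 <- Wc %*% solve(chol(cov(Wc)))          # sample cov = I
  target <- 0.4 * diag(k) + 0.6              # a*I + b*J
  Y <- Y0 %*% chol(target)                   # sample cov = target, exactly
  expect_equal(cov(Y), target, ignore_attr = TRUE)
  expect_equal(gg_epsilon(Y), 1, tolerance = 1e-10)
})

test_that("the repeated-measures design must be complete", {
  d <- data.frame(value = 1:5, location = c("a", "a", "b", "b", "b"),
                  subject = c(1, 2, 1, 2, 3))
  expect_error(rm_anova_gg(d), "one value per subject")
})

test_that("sex-effect screens return coherent adjusted p-values", {
  set.seed(51)
  v <- rnorm(30)
  g <- rep(c("m", "f", "x"), each = 10)
  for (br in c("parametric", "nonparametric")) {
    r <- compare_by_sex(v, g, br)
    expect_true(r$p_value >= 0 && r$p_value <= 1)
    expect_true(all(r$pairwise$p_adj >= r$pairwise$p - 1e-12))
    expect_true(all(r$pairwise$p_adj <= 1))
  }
  # Kruskal-Wallis omnibus matches base R directly
  expect_equal(compare_by_sex(v, g, "nonparametric")$p_value,
               kruskal.test(v, factor(g))$p.value)
})
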
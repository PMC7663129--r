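worked_matrix <- function() matrix(c(1, 3, 5, 2, 4, 6), 3, 2)

test_that("the worked 3x2 matrix gives the hand-computed mean squares and ICCs", {
  an <- two_way_anova(worked_matrix())
  expect_equal(an$MSR, 8)
  expect_equal(an$MSC, 1.5)
  expect_equal(an$MSE, 0, tolerance = 1e-12)
  expect_equal(icc_2_1(an$MSR, an$MSC, an$MSE, 3, 2)$est, 8 / 9,
               tolerance = 1e-9)
  expect_equal(icc_2_k(an$MSR, an$MSC, an$MSE, 3), 16 / 17,
               tolerance = 1e-9)
})

test_that("aov-based mean squares equal the brute-force sums of squares", {
  set.seed(14)
  for (i in 1:8) {
    M <- rnorm(10, 10, 3) + matrix(rnorm(70, 0, 2), 10, 7)
    an <- two_way_anova(M)
    bf <- anova_bruteforce(M)
    expect_equal(an$MSR, bf$MSR, tolerance = 1e-10)
    expect_equal(an$MSC, bf$MSC, tolerance = 1e-10)
    expect_equal(an$MSE, bf$MSE, tolerance = 1e-10)
    expect_equal(bf$SST, bf$SSR + bf$SSC + bf$SSE, tolerance = 1e-9)
    # ICC(2,k) is algebraically the Spearman-Brown prophecy of ICC(2,1)
    i1 <- icc_2_1(an$MSR, an$MSC, an$MSE, 10, 7)$est
    ik <- icc_2_k(an$MSR, an$MSC, an$MSE, 10)
    expect_equal(ik, spearman_brown(i1, 7), tolerance = 1e-12)
  }
})

test_that("a constant matrix reports its F statistic as missing", {
  an <- two_way_anova(matrix(5, 4, 3))
  expect_true(is.na(an$F_columns))
  expect_true(is.na(an$p))
})

test_that("ICC confidence interval matches an external absolute-agreement oracle", {
  # frozen oracle values computed once with pingouin (ICC(A,1)) on the
  # matrix regenerated below
  set.seed(9)
  M <- matrix(rnorm(70, 10, 2), 10, 7)
  an <- two_way_anova(M)
  i1 <- icc_2_1(an$MSR, an$MSC, an$MSE, 10, 7)
  expect_equal(i1$est, 0.0366664, tolerance = 1e-5)
  expect_equal(round(i1$lower, 2), -0.07)
  expect_equal(round(i1$upper, 2), 0.32)
  expect_equal(i1$F, 1.275460, tolerance = 1e-4)
  expect_equal(i1$p, 0.271525, tolerance = 1e-4)
})

test_that("perfect agreement yields ICC 1 and degenerate cases go missing", {
  M <- matrix(rep(c(3, 7, 11, 2), 3), 4, 3)  # rows constant across columns
  an <- two_way_anova(M)
  expect_equal(icc_2_1(an$MSR, an$MSC, an$MSE, 4, 3)$est, 1)
  expect_equal(icc_2_k(an$MSR, an$MSC, an$MSE, 4), 1)
})

test_that("Spearman-Brown reproduces the printed seven-footfall ICCs", {
  expect_equal(round(spearman_brown(0.79, 7), 2), 0.96)
  expect_equal(round(spearman_brown(0.46, 7), 2), 0.86)
  expect_equal(spearman_brown(0.5, 1), 0.5)
  expect_equal(spearman_brown(1, 10), 1)
  expect_error(spearman_brown(-0.1, 7), "below 0")
  # strictly increasing in R and in k
  r <- seq(0.05, 0.95, by = 0.1)
  expect_true(all(diff(spearman_brown(r, 7)) > 0))
  expect_true(all(diff(spearman_brown(0.3, 1:20)) > 0))
})

test_that("required_k inverts the prophecy with whole footfalls", {
  expect_equal(required_k(0.13, 0.5), 7L)     # ceil(6.69)
  expect_equal(required_k(0.5, 0.5), 1L)
  expect_equal(required_k(0.2, 0.9), 36L)
  expect_equal(spearman_brown(0.2, 36), 0.9, tolerance = 1e-12)
  expect_error(required_k(0, 0.5), "non-positive")
  # consistency: k replicates of reliability R reach at least the target
  set.seed(2)
  for (R in runif(20, 0.05, 0.9)) {
    k <- required_k(R, 0.7)
    expect_gte(spearman_brown(R, k), 0.7 - 1e-12)
    expect_lte(required_k(spearman_brown(R, k), 0.7), k)
  }
})

test_that("within-subject CV averages per-subject variation", {
  expect_equal(cv_within(matrix(c(2, 4), 1, 2)), 100 * sqrt(2) / 3,
               tolerance = 1e-12)
  M <- rbind(c(10, 10, 10), c(2, 4, 6))
  expect_equal(cv_within(M), mean(c(0, 100 * 2 / 4)))
  expect_true(is.na(cv_within(M, location = TRUE)))
  expect_true(is.na(cv_within(rbind(c(-1, 1), c(2, 2)))))  # zero mean row
  expect_gte(cv_within(M, pooled = TRUE), 0)
})

test_that("SEM and MDC follow their closed forms", {
  expect_equal(sem(10, 0.75), 5)
  expect_equal(sem(10, 1), 0)
  expect_equal(sem(10, 0), 10)
  expect_error(sem(10, 1.2), "exceed 1")
  expect_equal(round(mdc(3.84), 2), 8.91)
  expect_equal(round(mdc(1.64), 2), 3.80)
  expect_equal(mdc(0), 0)
  # the MDC/SEM ratio is the constant sqrt(2) * 1.64
  s <- runif(10, 0.1, 9)
  expect_equal(mdc(s) / s, rep(sqrt(2) * 1.64, 10))
})

test_that("the ICC sample-size formula lands near the study design point", {
  n <- sample_size_icc(0.5, 0.6, alpha = 0.05, power = 0.80, k = 16)
  expect_gte(n, 89)
  expect_lte(n, 92)
  # monotone: a larger true reliability needs fewer subjects
  ns <- vapply(c(0.6, 0.7, 0.8, 0.9),
               function(r1) sample_size_icc(0.5, r1, k = 16), 0L)
  expect_true(all(diff(ns) < 0))
  expect_error(sample_size_icc(0.6, 0.5, k = 16), "exceed")
})

test_that("ICC confidence intervals cover the true value at nominal rate", {
  set.seed(31)
  hits <- replicate(200, {
    gm <- generate_parameter_matrix(90, 7, mu = 50, sigma_between = sqrt(0.6),
                                    sigma_within = sqrt(0.4))
    an <- two_way_anova(gm$M)
    ci <- icc_2_1(an$MSR, an$MSC, an$MSE, an$n, an$k)
    ci$lower <= 0.6 && 0.6 <= ci$upper
  })
  expect_gte(mean(hits), 0.93)
})

test_that("reliability_report summarizes a parameter table like the study tables", {
  set.seed(6)
  # build a small parameter table directly from variance-component draws
  subj <- sprintf("S%02d", 1:8)
  tab <- expand.grid(subject = subj, footfall = 1:7,
                     side = c("right", "left"),
                     condition = "comfortable",
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  b <- stats::setNames(rnorm(8, 0, 2), subj)
  tab$stance_ms <- 600 + b[tab$subject] + rnorm(nrow(tab), 0, 2)
  tab$ICP_mlocAP_pct <- -7 + 0.5 * b[tab$subject] + rnorm(nrow(tab), 0, 0.5)
  rep <- reliability_report(tab, k = 7,
                            parameters = c("stance_ms", "ICP_mlocAP_pct"))
  expect_equal(nrow(rep), 2)
  expect_equal(rep$n, c(8, 8))
  st <- rep[rep$parameter == "stance_ms", ]
  expect_true(st$icc21 > 0 && st$icc21 <= st$icc2k)
  expect_equal(st$mdc, st$sem * sqrt(2) * 1.64)
  expect_true(is.na(rep$cv_dom[rep$parameter == "ICP_mlocAP_pct"]))
  expect_false(is.na(st$cv_dom))
  expect_false(is.na(st$cv_nondom))
})

test_that("a perfect-replication cohort reports ICC 1 with zero error indices", {
  subj <- sprintf("S%02d", 1:5)
  tab <- expand.grid(subject = subj, footfall = 1:7, side = "right",
                     condition = "comfortable",
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  vals <- stats::setNames(c(10, 20, 30, 40, 50), subj)
  tab$stance_ms <- vals[tab$subject]
  rep <- reliability_report(tab, k = 7, parameters = "stance_ms")
  expect_equal(rep$icc21, 1)
  expect_equal(rep$icc2k, 1)
  expect_equal(rep$sem, 0)
  expect_equal(rep$mdc, 0)
  expect_equal(rep$cv_dom, 0)
  expect_equal(rep$required_k, 1L)
})

test_that("incomplete subjects are dropped before the unreplicated ANOVA", {
  tab <- expand.grid(subject = c("A", "B", "C"), footfall = 1:7,
                     side = "right", condition = "c",
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  set.seed(1)
  tab$v <- rnorm(nrow(tab))
  tab$v[tab$subject == "C" & tab$footfall == 4] <- NA
  M <- build_measurement_matrix(tab, "v", k = 7)
  expect_equal(nrow(M), 2)
  expect_false("C" %in% rownames(M))
})
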
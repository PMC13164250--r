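test_that("cluster signatures localize a planted one-cluster shift", {
  set.seed(21)
  x <- matrix(rnorm(60 * 5), 60, 5,
              dimnames = list(sprintf("s%02d", 1:60), sprintf("pr%d", 1:5)))
  cl <- stats::setNames(rep(1:3, each = 20), rownames(x))
  x[cl == 2, "pr3"] <- x[cl == 2, "pr3"] + 1.0
  sig <- cluster_signature(x, cl)
  expect_equal(unname(which.max(sig$scaled["pr3", ])), 2L)
  # no-signal proteins have near-zero raw log2FC everywhere
  expect_lt(max(abs(sig$log2fc["pr1", ])), 0.5)
  # scaled rows are z-scores across clusters
  expect_equal(unname(rowMeans(sig$scaled)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(sig$scaled, 1, sd)), rep(1, 5), tolerance = 1e-12)
  expect_error(cluster_signature(x, cl[cl == 1]), "at least 2")
})

test_that("signature of cluster c is unchanged by merging the other clusters", {
  set.seed(22)
  x <- matrix(rnorm(45 * 4), 45, 4,
              dimnames = list(sprintf("s%02d", 1:45), sprintf("pr%d", 1:4)))
  cl <- stats::setNames(rep(1:3, each = 15), rownames(x))
  merged <- ifelse(cl == 2, 2L, 1L)
  names(merged) <- names(cl)
  s3 <- cluster_signature(x, cl)
  s2 <- cluster_signature(x, merged)
  expect_equal(s3$log2fc[, "cl2"], s2$log2fc[, "cl2"], tolerance = 1e-12)
})

test_that("the printed cluster-by-class contingency table gives p near 0.036", {
  counts <- rbind(noDM = c(27, 5, 6, 11, 8, 11, 1),
                  PreDM = c(3, 2, 7, 2, 4, 3, 4),
                  T2DM = c(18, 1, 9, 5, 3, 5, 7))
  p <- suppressWarnings(stats::chisq.test(counts, correct = FALSE)$p.value)
  expect_lt(abs(p - 0.036), 0.002)
})

test_that("D'Agostino-Pearson omnibus matches the frozen reference values", {
  normal50 <- c(0.00123,0.298746,-0.274138,-0.890592,-0.454671,-0.991647,0.060144,
    1.340215,-0.492207,-0.620475,0.489842,0.356887,0.105414,-0.930468,-0.029252,
    0.695303,-1.344215,-0.457616,-1.901223,-1.289538,-1.841735,-0.235091,-1.267446,
    0.271264,0.156751,-0.186931,-2.51676,-0.538693,-0.048501,0.113309,-1.530136,
    -0.477753,-0.978519,-0.808837,1.060899,-0.807535,-0.032522,0.88439,-0.5836,
    -0.111702,0.110464,0.063782,-1.225056,0.07614,1.358823,-1.547145,0.859383,
    0.119354,-0.64147,2.000417)
  r <- dagostino_pearson(normal50)
  expect_equal(r$statistic, 0.5119238063, tolerance = 1e-8)
  expect_equal(r$p.value, 0.7741714617, tolerance = 1e-8)
  expo40 <- c(0.127217,0.383855,1.067887,0.068701,0.098201,0.871409,1.874,2.696352,
    0.706095,1.306072,0.763546,0.937058,0.144847,2.494997,0.884279,0.875212,
    0.026353,1.085041,1.061857,1.064204,0.568831,1.363631,1.573667,0.650021,
    0.35114,1.699883,0.672579,0.750772,0.111447,0.24509,2.047488,0.727852,
    0.024791,1.326697,0.491553,2.951864,0.842607,0.976582,0.433996,0.019379)
  r2 <- dagostino_pearson(expo40)
  expect_equal(r2$statistic, 9.0704906861, tolerance = 1e-8)
  expect_equal(r2$p.value, 0.0107242758, tolerance = 1e-8)
  # strongly platykurtic (bimodal) sample: negative base in the kurtosis
  # cube root must be handled
  bimodal30 <- c(-2.012072,-1.665809,-2.169935,-1.473937,-2.0027,-1.708309,
    -2.645447,-1.82666,-2.844102,-3.017664,-2.152238,-2.449964,-1.917974,
    -0.877622,-2.415862,1.688028,2.102702,2.246507,1.911797,1.897035,2.351231,
    2.259954,1.483162,1.960409,2.017643,1.472758,2.12992,1.571022,2.486033,
    2.096373)
  r3 <- dagostino_pearson(bimodal30)
  expect_equal(r3$statistic, 72.0355433446, tolerance = 1e-8)
  expect_error(dagostino_pearson(rnorm(5)), "n >= 8")
})

test_that("Dunn test reproduces an independently computed oracle", {
  x <- c(0.03,1.36,1.22,-0.51,-0.3,-0.53,0.57,-0.06,0.75,-1.85,2.57,0.9,1.68,
         0.86,0.62,1.46,1.82,0.8,0.85,1.69,-0.57,-1.21,0.69,-0.37,-1.62,-0.51,
         -0.17,-0.89,-1.19,0.34)
  g <- rep(c("a", "b", "c"), each = 10)
  dn <- dunn_test(x, g)
  # frozen values from an independent rank-based implementation
  expect_equal(dn$z[dn$group1 == "a" & dn$group2 == "b"], -2.6545979541, tolerance = 1e-8)
  expect_equal(dn$p[dn$group1 == "a" & dn$group2 == "b"], 0.0079402982, tolerance = 1e-8)
  expect_equal(dn$z[dn$group1 == "a" & dn$group2 == "c"], 1.3971568180, tolerance = 1e-8)
  expect_equal(dn$z[dn$group1 == "b" & dn$group2 == "c"], 4.0517547721, tolerance = 1e-8)
  expect_equal(dn$p.adj, bh_bruteforce(dn$p), tolerance = 1e-12)
})

test_that("cluster clinical tests route variables to the right procedures", {
  co <- generate_cohort(small_spec(seed = 23))
  cl <- stats::setNames(rep(1:3, length.out = nrow(co$clinical)),
                        co$clinical$sample_id)
  res <- cluster_clinical_tests(co$clinical, cl,
                                variables = c("age", "glycemic_class", "WBC"))
  expect_equal(res$overall$type[res$overall$variable == "age"], "continuous")
  expect_equal(res$overall$type[res$overall$variable == "glycemic_class"], "categorical")
  expect_true("age" %in% names(res$posthoc))
  expect_equal(res$overall$n_missing[res$overall$variable == "WBC"],
               sum(is.na(co$clinical$WBC)))
  # identical groups: zero statistic
  clinical0 <- data.frame(sample_id = sprintf("s%d", 1:30), v = rep(1:10, 3))
  cl0 <- stats::setNames(rep(1:3, each = 10), clinical0$sample_id)
  r0 <- cluster_clinical_tests(clinical0, cl0, variables = "v")
  expect_lt(r0$overall$statistic[1], 1e-10)
  # constant variable is reported untested
  clinical1 <- data.frame(sample_id = sprintf("s%d", 1:30), v = rep(1, 30))
  r1 <- cluster_clinical_tests(clinical1, cl0, variables = "v")
  expect_false(r1$overall$tested[1])
  expect_equal(r1$overall$type[1], "constant")
})

test_that("cohort summary has one row per variable and three contrasts", {
  co <- generate_cohort(small_spec(seed = 24))
  s <- cohort_summary(co$clinical, variables = c("age", "BMI", "sex"))
  expect_equal(nrow(s), 3)
  pcols <- grep("^p_", names(s), value = TRUE)
  expect_length(setdiff(pcols, "p_overall"), 3)
  # planted huge difference -> tiny p; identical groups -> p near 1
  clin <- data.frame(sample_id = sprintf("s%d", 1:60),
                     glycemic_class = rep(c("noDM", "T2DM"), each = 30),
                     big = c(rnorm(30, 0), rnorm(30, 10)),
                     same = rnorm(60))
  s2 <- cohort_summary(as_clinical_table(clin), variables = c("big", "same"))
  expect_lt(s2$p_overall[s2$variable == "big"], 0.001)
  expect_gt(s2$p_overall[s2$variable == "same"], 0.05)
})

test_that("OLS coefficients match the normal-equation solution", {
  set.seed(25)
  for (rep in 1:5) {
    n <- 40; k <- 4
    X <- cbind(1, matrix(rnorm(n * k), n, k))
    beta <- rnorm(k + 1)
    y <- X %*% beta + rnorm(n)
    df <- data.frame(y = y, X[, -1])
    fit <- lm(y ~ ., data = df)
    oracle <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(unname(coef(fit)), as.vector(oracle), tolerance = 1e-8)
  }
})

test_that("regressions recover planted slopes with honest uncertainty", {
  co <- generate_cohort(cohort_spec(seed = 26))
  pp <- preprocess_cohort(co)
  r <- fit_protein_regression(pp$npx, "FLT3L", co$clinical)
  age <- r$coefficients[r$coefficients$term == "age", ]
  expect_lt(abs(age$estimate - 0.033), 4 * age$se)
  expect_true(all(r$vif >= 1))
  expect_true(all(r$coefficients$ci_lo <= r$coefficients$estimate &
                    r$coefficients$estimate <= r$coefficients$ci_hi))
  expect_true("med_burden" %in% r$term_tests$term)
  expect_equal(nrow(r$normality), 3)
  # FPG slope on CDCP1, class-adjusted: matches the generating model
  r2 <- fit_protein_regression(pp$npx, "CDCP1", co$clinical, predictor = "FPG",
                               covariates = c("glycemic_class", "age", "sex", "BMI",
                                              "MASLD_stage", "antidiabetic", "med_burden"))
  fpg <- r2$coefficients[r2$coefficients$term == "FPG", ]
  expect_lt(abs(fpg$estimate - 0.010), 4 * fpg$se)
})

test_that("VIF is 1 for orthogonal predictors and matches car on real fits", {
  n <- 64
  x1 <- rep(c(-1, 1), each = n / 2)
  x2 <- rep(c(-1, 1), times = n / 2)
  set.seed(27)
  y <- rnorm(n)
  df <- data.frame(sample_id = sprintf("s%d", 1:n), y = y, x1 = x1, x2 = x2)
  m <- matrix(y, ncol = 1, dimnames = list(df$sample_id, "pr"))
  r <- fit_protein_regression(m, "pr", df, predictor = "x1", covariates = "x2")
  expect_equal(unname(r$vif), c(1, 1), tolerance = 1e-12)
  # agreement with car::vif on a multi-predictor continuous design
  co <- generate_cohort(small_spec(seed = 28))
  pp <- preprocess_cohort(co)
  rr <- fit_protein_regression(pp$npx, "IL6", co$clinical,
                               predictor = "FPG", covariates = c("age", "BMI"))
  cv <- car::vif(rr$model)
  expect_equal(unname(rr$vif[c("FPG", "age", "BMI")]), unname(cv[c("FPG", "age", "BMI")]),
               tolerance = 1e-10)
})

test_that("a duplicated predictor raises a rank-deficiency error", {
  n <- 30
  set.seed(29)
  df <- data.frame(sample_id = sprintf("s%d", 1:n), x1 = rnorm(n))
  df$x2 <- df$x1
  m <- matrix(rnorm(n), ncol = 1, dimnames = list(df$sample_id, "pr"))
  expect_error(fit_protein_regression(m, "pr", df, predictor = "x1",
                                      covariates = "x2"),
               "rank-deficient")
})

test_that("rescaling FPG rescales its coefficient exactly inversely", {
  co <- generate_cohort(small_spec(seed = 30))
  pp <- preprocess_cohort(co)
  clin <- co$clinical
  r1 <- fpg_sensitivity(pp$npx, "IL8", clin)
  clin2 <- clin
  clin2$FPG <- clin2$FPG / 50
  r2 <- fpg_sensitivity(pp$npx, "IL8", clin2)
  b1 <- r1$coefficients$estimate[r1$coefficients$term == "FPG"]
  b2 <- r2$coefficients$estimate[r2$coefficients$term == "FPG"]
  expect_equal(b2, 50 * b1, tolerance = 1e-8)
})

test_that("a planted null FPG effect is rejected at the nominal rate", {
  # no FPG effect planted on a background protein; alpha = 0.05
  rej <- vapply(1:120, function(s) {
    co <- generate_cohort(small_spec(seed = 3000 + s))
    pp <- preprocess_cohort(co)
    r <- fpg_sensitivity(pp$npx, "VEGFA", co$clinical)
    r$coefficients$p[r$coefficients$term == "FPG"] < 0.05
  }, logical(1))
  expect_lt(mean(rej), 0.12)  # 0.05 nominal + binomial noise at 120 reps
})
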
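test_that("two-group comparison matches hand-evaluated pooled t", {
  idn <- compare_groups(c(1, 2, 3), c(1, 2, 3), var_equal = TRUE)
  expect_equal(idn$t_statistic, 0)
  expect_equal(idn$p_value, 1)

  # a = {1,2,3}, b = {11,12,13}: pooled s^2 = 1, t = -10 / sqrt(2/3)
  sh <- compare_groups(c(1, 2, 3), c(11, 12, 13), var_equal = TRUE)
  t_hand <- -10 / sqrt(2 / 3)
  expect_equal(sh$t_statistic, t_hand)
  expect_equal(sh$p_value, 2 * pt(t_hand, df = 4))

  expect_error(compare_groups(1, c(1, 2)), "n >= 2")
})

test_that("simulated study cohorts separate with the reported direction", {
  co <- generate_cohort(cohort_sim_params(seed = 22))  # study sizes 358/363
  ca <- co[co$group == "cancer", ]; no <- co[co$group == "normal", ]
  cmp <- compare_groups(ca$avg_intensity, no$avg_intensity)
  expect_gt(cmp$t_statistic, 0)
  expect_lt(cmp$p_value, 1e-4)
})

test_that("squared correlation matches direct covariance arithmetic", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlation_r2(x, 2 * x + 1), 1)

  y <- c(2.1, 3.9, 6.2, 7.8, 10.4)
  r2_hand <- (sum((x - mean(x)) * (y - mean(y))))^2 /
    (sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(correlation_r2(x, y), r2_hand)

  expect_error(correlation_r2(rep(1, 5), y), "variance")
  set.seed(33)
  expect_lt(correlation_r2(rnorm(5000), rnorm(5000)), 0.01)
})

test_that("ROC AUC equals brute-force pairwise concordance", {
  sep <- roc_curve(c(1, 2, 3, 10, 11, 12), c(F, F, F, T, T, T))
  expect_equal(sep$auc, 1)

  set.seed(44)
  for (i in 1:10) {
    n <- sample(10:50, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) > 0.5)
    scores <- round(rnorm(n, mean = labels), 1)  # ties likely
    r <- roc_curve(scores, labels)
    expect_equal(r$auc, concordance_auc(scores, labels), tolerance = 1e-12)
  }

  set.seed(45)
  null <- roc_curve(rnorm(4000), rep(c(TRUE, FALSE), 2000))
  expect_lt(abs(null$auc - 0.5), 0.03)

  expect_error(roc_curve(1:5, rep(TRUE, 5)), "both classes")
})

test_that("ROC agrees with an independent implementation", {
  set.seed(46)
  labels <- rep(c(TRUE, FALSE), each = 30)
  scores <- rnorm(60, mean = labels)
  r <- roc_curve(scores, labels)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(r$auc, ref, tolerance = 1e-10)
})

test_that("quadrant rule is positive-inclusive with only Q3 negative", {
  B <- stau2_cutoffs()$B  # (90.28, 53.34)
  expect_true(quadrant_classify(200, 0, B))    # high intensity alone
  expect_true(quadrant_classify(0, 90, B))     # high percentage alone
  expect_false(quadrant_classify(0, 0, B))     # Q3
  expect_true(quadrant_classify(90.28, 53.34, B))  # exact boundary
  expect_false(quadrant_classify(90.279, 53.339, B))
  expect_error(quadrant_classify(NA, 1, B), "undefined")
})

test_that("quadrant rule with y = Inf degenerates to the intensity ROC point", {
  set.seed(47)
  co <- generate_cohort(cohort_sim_params(n_cancer = 150, n_normal = 150,
                                          seed = 47))
  cut <- cutoff_point(90.28, Inf)
  pos <- quadrant_classify(co$avg_intensity, co$pct_positive, cut)
  dis <- co$group == "cancer"
  r <- roc_curve(co$avg_intensity, dis)
  # the generated intensities are continuous; pick the smallest observed
  # score >= 90.28 as the matching ROC threshold
  thr <- min(co$avg_intensity[co$avg_intensity >= 90.28])
  row <- r$points[r$points$threshold == thr, ]
  expect_equal(sum(pos & dis) / sum(dis), row$sensitivity)
  expect_equal(sum(!pos & !dis) / sum(!dis), row$specificity)
})

test_that("2x2 reconstruction from printed rates uses round-half-up", {
  perfect <- confusion_from_rates(1, 1, 358, 363)
  expect_equal(unclass(perfect)[c("tp", "fn", "tn", "fp")],
               list(tp = 358, fn = 0, tn = 363, fp = 0))

  b <- confusion_from_rates(0.8296, 0.8347, 358, 363)
  expect_equal(c(b$tp, b$fn, b$tn, b$fp), c(297, 61, 303, 60))

  c_ <- confusion_from_rates(0.3715, 0.9917, 358, 363)
  expect_equal(c(c_$tp, c_$fn, c_$tn, c_$fp), c(133, 225, 360, 3))
})

test_that("screening metrics reproduce the published worked examples", {
  m <- screening_metrics(confusion_table(297, 61, 303, 60))
  expect_equal(round(m$odds_ratio, 2), 24.59)
  expect_equal(round(unname(m$or_ci_95), 2), c(16.64, 36.34))
  expect_equal(round(100 * m$accuracy, 2), 83.22)
  expect_equal(round(m$npv, 4), 0.8324)
  expect_equal(round(m$ppv, 4), 0.8319)
  expect_false(m$haldane_corrected)

  hi_spec <- screening_metrics(confusion_table(133, 225, 360, 3))
  expect_equal(round(hi_spec$npv, 4), 0.6154)
  expect_equal(round(hi_spec$ppv, 4), 0.9779)
})

test_that("screening metrics obey structural identities", {
  set.seed(55)
  for (i in 1:20) {
    cells <- rpois(4, 40) + 1
    tab <- confusion_table(cells[1], cells[2], cells[3], cells[4])
    m <- screening_metrics(tab)
    # prevalence-weighted accuracy identity
    pi_d <- (tab$tp + tab$fn) / (tab$tp + tab$fn + tab$tn + tab$fp)
    expect_equal(m$accuracy,
                 m$sensitivity * pi_d + m$specificity * (1 - pi_d))
    # Woolf CI contains the point estimate
    expect_lte(m$or_ci_95[["low"]], m$odds_ratio)
    expect_gte(m$or_ci_95[["high"]], m$odds_ratio)
    # odds ratio is transpose-invariant
    mt <- screening_metrics(confusion_table(tab$tp, tab$fp, tab$tn, tab$fn))
    expect_equal(mt$odds_ratio, m$odds_ratio)
    # rates survive the reconstruction round trip to within rounding
    rec <- confusion_from_rates(m$sensitivity, m$specificity,
                                tab$tp + tab$fn, tab$tn + tab$fp)
    expect_lte(abs(rec$tp - tab$tp), 0.5)
    expect_lte(abs(rec$tn - tab$tn), 0.5)
  }
})

test_that("zero cells trigger the Haldane correction and flag", {
  m <- screening_metrics(confusion_table(10, 0, 12, 3))
  expect_true(m$haldane_corrected)
  expect_true(is.finite(m$odds_ratio))
  expect_error(screening_metrics(confusion_table(0, 0, 10, 5)), "zero row")
})

test_that("cut-off evaluation is exact on separable cohorts and scale-invariant", {
  co <- data.frame(
    sample_id = sprintf("s%02d", 1:40),
    group = rep(c("cancer", "normal"), each = 20),
    avg_intensity = rep(c(150, 20), each = 20),
    pct_positive = rep(c(90, 5), each = 20))
  ev <- evaluate_cutoffs(co, stau2_cutoffs())
  expect_equal(ev$sensitivity, rep(1, 3))
  expect_equal(ev$specificity, rep(1, 3))

  doubled <- evaluate_cutoffs(rbind(co, co), stau2_cutoffs())
  expect_equal(doubled$sensitivity, ev$sensitivity)
  expect_equal(doubled$accuracy, ev$accuracy)

  co$replicate_set <- rep_len(1:2, nrow(co))
  by_rep <- attr(evaluate_cutoffs(co, stau2_cutoffs()), "by_replicate")
  expect_equal(sort(unique(by_rep$replicate_set)), 1:2)
  expect_equal(nrow(by_rep), 6)  # 2 sets x 3 cuts
})
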
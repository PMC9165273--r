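# Published threshold-analysis rows (visual assessment and SUV cut-offs per
# stratum): counts tp/fp/tn/fn and the printed point estimates / CI bounds.
table2_rows <- list(
  list(
    stratum = "all_visual", tp = 31, fp = 53, tn = 37, fn = 2,
    sens = c(93.9, 79.8, 99.3), spec = c(41.1, 30.8, 52.0),
    npv = c(94.9, 82.7, 99.4), ppv = c(36.9, 26.6, 48.1),
    bcr = c(31.7, 23.6, 40.7)
  ),
  list(
    stratum = "nonhurthle_visual", tp = 22, fp = 34, tn = 36, fn = 2,
    sens = c(91.7, 73.0, 99.0), spec = c(51.4, 39.2, 63.6),
    npv = c(94.7, 82.3, 99.4), ppv = c(39.3, 26.5, 53.2),
    bcr = c(40.4, 30.4, 51.0)
  ),
  list(
    stratum = "hurthle_visual", tp = 9, fp = 19, tn = 1, fn = 0,
    sens = c(100, 66.4, 100), spec = c(5.0, 0.1, 24.9),
    npv = c(100, 2.5, 100), ppv = c(32.1, 15.9, 52.4),
    bcr = c(3.4, 0.1, 17.8)
  ),
  list(
    stratum = "all_suvmax_2.1", tp = 32, fp = 73, tn = 17, fn = 1,
    sens = c(97.0, 84.2, 99.9), spec = c(18.9, 11.4, 28.5),
    npv = c(94.4, 72.7, 99.9), ppv = c(30.5, 21.9, 40.2),
    bcr = c(14.6, 8.9, 22.1)
  ),
  list(
    stratum = "all_suvpeak_1.6", tp = 32, fp = 80, tn = 10, fn = 1,
    sens = c(97.0, 84.2, 99.9), spec = c(11.1, 5.5, 19.5),
    npv = c(90.9, 58.7, 99.8), ppv = c(28.6, 20.4, 37.9),
    bcr = c(8.9, 4.5, 15.4)
  ),
  list(
    stratum = "all_suvmaxratio_1.2", tp = 32, fp = 56, tn = 34, fn = 1,
    sens = c(97.0, 84.2, 99.9), spec = c(37.8, 27.8, 48.6),
    npv = c(97.1, 85.1, 99.9), ppv = c(36.4, 26.4, 47.3),
    bcr = c(28.5, 20.7, 37.3)
  ),
  list(
    stratum = "all_suvpeakratio_0.9", tp = 32, fp = 75, tn = 15, fn = 1,
    sens = c(97.0, 84.2, 99.9), spec = c(16.7, 9.6, 26.0),
    npv = c(93.8, 69.8, 99.8), ppv = c(29.9, 21.4, 39.5),
    bcr = c(13.0, 7.6, 20.3)
  ),
  list(
    stratum = "nonhurthle_suvmax_2.1", tp = 23, fp = 54, tn = 16, fn = 1,
    sens = c(95.8, 78.9, 99.9), spec = c(22.9, 13.7, 34.4),
    npv = c(94.1, 71.3, 99.9), ppv = c(29.9, 20.0, 41.4),
    bcr = c(18.1, 10.9, 27.4)
  ),
  list(
    stratum = "hurthle_suvmax_5.2", tp = 9, fp = 15, tn = 5, fn = 0,
    sens = c(100, 66.4, 100), spec = c(25.0, 8.7, 49.1),
    npv = c(100, 47.8, 100), ppv = c(37.5, 18.8, 59.4),
    bcr = c(17.2, 5.8, 35.8)
  ),
  list(
    stratum = "hurthle_suvpeak_4.7", tp = 9, fp = 13, tn = 7, fn = 0,
    sens = c(100, 66.4, 100), spec = c(35.0, 15.4, 59.2),
    npv = c(100, 59.0, 100), ppv = c(40.9, 20.7, 63.6),
    bcr = c(24.1, 10.3, 43.5)
  )
)

test_that("Clopper-Pearson intervals reproduce published bounds and conventions", {
  expect_equal(round(clopper_pearson(9, 9), 1), c(low = 66.4, high = 100))
  expect_equal(round(clopper_pearson(23, 24)[["low"]], 1), 78.9)
  ci0 <- clopper_pearson(0, 10)
  expect_equal(ci0[["low"]], 0)
  expect_equal(ci0[["high"]], 100 * qbeta(0.975, 1, 10))
  ci_full <- clopper_pearson(10, 10)
  expect_equal(ci_full[["high"]], 100)
  expect_error(clopper_pearson(1, 0), "at least 1")
  expect_error(clopper_pearson(5, 4), "out of range")
})

test_that("every published threshold-analysis cell is reproduced to one decimal", {
  key <- c(
    sens = "sensitivity", spec = "specificity", npv = "npv",
    ppv = "ppv", bcr = "benign_call_rate"
  )
  for (row in table2_rows) {
    tab <- diagnostic_table_from_counts(row$tp, row$fp, row$tn, row$fn,
      stratum = row$stratum
    )
    for (short in names(key)) {
      got <- tab[tab$metric == key[[short]], ]
      expect_equal(round(got$estimate, 1), row[[short]][1],
        info = paste(row$stratum, short)
      )
      expect_equal(round(got$ci_low, 1), row[[short]][2],
        info = paste(row$stratum, short, "low")
      )
      expect_equal(round(got$ci_high, 1), row[[short]][3],
        info = paste(row$stratum, short, "high")
      )
    }
  }
})

test_that("labels + test results produce the same table as raw counts", {
  co <- make_cohort_from_counts(31, 53, 37, 2)
  a <- diagnostic_table(co$label, co$test_positive)
  b <- diagnostic_table_from_counts(31, 53, 37, 2)
  expect_equal(a, b)
  # degenerate: all test-negative, all benign
  tab <- diagnostic_table_from_counts(0, 0, 12, 0)
  expect_equal(tab$estimate[tab$metric == "specificity"], 100)
  expect_equal(tab$estimate[tab$metric == "benign_call_rate"], 100)
  expect_true(is.na(tab$estimate[tab$metric == "ppv"]))
  expect_true(is.na(tab$estimate[tab$metric == "sensitivity"]))
})

test_that("cut-off selection honours the sensitivity floor and maximises specificity", {
  v <- c(10, 8, 1, 2)
  y <- c(1, 1, 0, 0)
  co <- find_cutoff(v, y, 0.95)
  expect_equal(co, 8)
  expect_equal(mean(v[y == 1] >= co), 1)
  expect_equal(mean(v[y == 0] < co), 1)
  # a single low-valued malignant drags the cut-off down
  v2 <- c(10, 0.5, 1, 2)
  expect_equal(find_cutoff(v2, c(1, 1, 0, 0), 0.95), 0.5)
  # brute-force scan: no larger observed threshold attains the floor
  set.seed(121)
  for (rep in 1:25) {
    n <- 40
    y <- rbinom(n, 1, 0.3)
    if (length(unique(y)) < 2) next
    v <- round(rlnorm(n, 1, 0.7), 2)
    co <- find_cutoff(v, y, 0.95)
    sens_at <- function(t) mean(v[y == 1] >= t)
    expect_gte(sens_at(co), 0.95)
    larger <- sort(unique(v))[sort(unique(v)) > co]
    if (length(larger) > 0) expect_true(all(sapply(larger, sens_at) < 0.95))
  }
  # lowering the floor never lowers the cut-off
  set.seed(122)
  y <- rbinom(60, 1, 0.3)
  v <- rlnorm(60, 1, 0.8)
  cuts <- sapply(c(0.99, 0.95, 0.9, 0.8), function(ms) find_cutoff(v, y, ms))
  expect_true(all(diff(cuts) >= 0))
})

test_that("trapezoid ROC AUC equals the rank AUC and separable data hit 1", {
  sep <- roc_with_auc(c(1, 2, 9, 10), c(0, 0, 1, 1))
  expect_equal(sep$auc, 1)
  set.seed(131)
  for (rep in 1:30) {
    n <- sample(15:40, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.35))
    v <- round(rlnorm(n, 1, 0.6), 1)
    r <- roc_with_auc(v, y)
    expect_equal(r$auc, compute_auc(v, y), tolerance = 1e-12)
    expect_true(all(diff(r$curve$sensitivity) <= 1e-12)) # non-increasing
  }
  expect_error(roc_with_auc(1:5, rep(1, 5)), "both classes")
})

test_that("DeLong interval agrees with a bootstrap percentile interval", {
  set.seed(141)
  n <- 60
  y <- rep(c(0, 1), c(40, 20))
  v <- rnorm(n, mean = y) # moderate separation
  r <- roc_with_auc(v, y)
  boots <- replicate(10000, {
    i0 <- sample(which(y == 0), 40, replace = TRUE)
    i1 <- sample(which(y == 1), 20, replace = TRUE)
    compute_auc(v[c(i0, i1)], y[c(i0, i1)])
  })
  bq <- quantile(boots, c(0.025, 0.975), names = FALSE)
  expect_lt(abs(r$auc_ci[["low"]] - bq[1]), 0.02)
  expect_lt(abs(r$auc_ci[["high"]] - bq[2]), 0.02)
})

test_that("stratified analysis partitions the cohort and filters correctly", {
  co <- generate_cohort(cohort_config(n_total = 123, seed = 151))
  res <- stratified_analysis(co)
  tabs <- res$tables
  # Hurthle + non-Hurthle counts add to the full-cohort counts per metric
  pick <- function(s, m) {
    r <- tabs[tabs$stratum == paste0(s, "/suv_max") & tabs$metric == m, ]
    c(r$tp, r$fp, r$tn, r$fn)
  }
  all_counts <- pick("all", "sensitivity")
  expect_equal(sum(all_counts), 123)
  nh <- tabs[tabs$stratum == "non_hurthle/visual" & tabs$metric == "sensitivity", ]
  hu <- tabs[tabs$stratum == "hurthle/visual" & tabs$metric == "sensitivity", ]
  av <- tabs[tabs$stratum == "all/visual" & tabs$metric == "sensitivity", ]
  expect_equal(nh$tp + hu$tp, av$tp)
  expect_equal(nh$tn + hu$tn, av$tn)
  expect_equal(hu$tp + hu$fp + hu$tn + hu$fn, sum(co$hurthle))
  # selected cut-offs meet the sensitivity floor in every stratum
  suv_rows <- tabs[tabs$metric == "sensitivity" & !is.na(tabs$cut_off), ]
  expect_true(all(suv_rows$estimate >= 95))
})

test_that("simulated Clopper-Pearson coverage is at least nominal", {
  set.seed(161)
  n_rep <- 10000
  for (n in c(10, 30, 100)) {
    for (p in c(0.05, 0.2, 0.5, 0.8, 0.95)) {
      x <- rbinom(n_rep, n, p)
      bounds <- vapply(0:n, clopper_pearson, numeric(2), n = n) / 100
      cover <- mean(bounds[1, x + 1] <= p & p <= bounds[2, x + 1])
      expect_gte(cover, 0.945)
    }
  }
})
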
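# Textbook-formula oracle, written independently of the implementation.
oracle_t <- function(a, b) {
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2)
  t <- (mean(a) - mean(b)) /
    sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  p <- 2 * stats::pt(-abs(t), length(a) + length(b) - 2)
  c(t = t, p = p)
}

oracle_d <- function(a, b) {
  sp <- sqrt((sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
               (length(a) + length(b) - 2))
  (mean(a) - mean(b)) / sp
}

test_that("pooled t-test matches the textbook formula and t.test", {
  a <- c(1, 2, 3, 4, 5); b <- c(3, 4, 5, 6, 7)
  res <- two_sample_ttest(a, b)
  o <- oracle_t(a, b)
  expect_equal(res$t, unname(o["t"]), tolerance = 1e-10)
  expect_equal(res$p, unname(o["p"]), tolerance = 1e-10)
  tt <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  set.seed(12)
  for (r in 1:10) {
    x <- rnorm(sample(3:20, 1)); y <- rnorm(sample(3:20, 1), mean = 0.4)
    res <- two_sample_ttest(x, y)
    o <- oracle_t(x, y)
    expect_equal(res$t, unname(o["t"]), tolerance = 1e-10)
    expect_equal(res$p, unname(o["p"]), tolerance = 1e-10)
    expect_equal(cohens_d(x, y), oracle_d(x, y), tolerance = 1e-10)
  }
})

test_that("t-test symmetry and degenerate-group behavior", {
  a <- c(1.2, 3.1, 0.4, 2.2); b <- c(2.5, 1.1, 4.0)
  r1 <- two_sample_ttest(a, b); r2 <- two_sample_ttest(b, a)
  expect_equal(r1$t, -r2$t)
  expect_equal(r1$p, r2$p)
  same <- two_sample_ttest(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(two_sample_ttest(c(2, 2), c(3, 3)), "zero pooled variance")
  expect_error(two_sample_ttest(1, c(1, 2)), "at least 2")
})

test_that("Cohen's d conventions", {
  s <- 1 / sqrt(2)                       # two-point samples with sd 1
  expect_equal(cohens_d(1 + c(-s, s), 0 + c(-s, s)), 1)
  expect_equal(cohens_d(c(1, 2, 3), c(3, 2, 1)), 0)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "zero pooled")
  # sign matches the direction of the mean difference
  set.seed(2)
  x <- rnorm(10, 1); y <- rnorm(10)
  expect_equal(sign(cohens_d(x, y)), sign(mean(x) - mean(y)))
})

test_that("ROI aggregation averages member channels", {
  m <- default_montage()
  ones <- stats::setNames(rep(1, 30), m$channel_names)
  expect_true(all(roi_aggregate(ones, m, "lobe") == 1))
  v <- stats::setNames(rep(0, 30), m$channel_names)
  v[shipped_rois(m)$left_frontotemporal] <- 2
  h <- roi_aggregate(v, m, "hemisphere")
  expect_equal(unname(h["left_frontotemporal"]), 2)
  expect_equal(unname(h["right_frontotemporal"]), 0)
  set.seed(3)
  rv <- stats::setNames(runif(30), m$channel_names)
  lob <- roi_aggregate(rv, m, "lobe")
  expect_equal(unname(lob["occipital"]),
               mean(rv[c("PO3", "PO4", "O1", "Oz", "O2")]))
  expect_error(roi_aggregate(rv[-1], m, "lobe"), "Fp1")
  expect_error(roi_aggregate(rv, m, list(x = c("Fp1", "Nope"))), "Nope")
})

test_that("state labeling reproduces the canonical rule rows", {
  expect_equal(label_state(subjective_scale(
    "high", "medium", "low", "very-low", "high", "medium")), "attentive")
  expect_equal(label_state(subjective_scale(
    "medium", "medium", "medium", "high", "low", "medium")), "fatigue")
  expect_equal(label_state(subjective_scale(
    "low", "low", "medium", "low", "low", "low")), "inattentive")
  expect_equal(label_state(subjective_scale(
    "medium", "high", "high", "low", "very-high", "high")), "positive")
  expect_equal(label_state(subjective_scale(
    "medium", "high", "low", "low", "medium", "low")), "negative")
  expect_equal(label_state(subjective_scale(
    "very-high", "very-high", "very-high", "very-high", "very-high",
    "very-high")), "unclassified")
  expect_error(subjective_scale("high", "medium", "low", "so-so",
                                "high", "medium"), "invalid grade")
})

test_that("labeling is total, deterministic and first-match over all vectors", {
  grades <- c("very-low", "low", "medium", "high", "very-high")
  ge_med <- c("medium", "high", "very-high")
  combos <- expand.grid(effort = grades, temporal_demand = grades,
                        performance = grades, fatigue_degree = grades,
                        arousal = grades, valence = grades,
                        stringsAsFactors = FALSE)
  expect_equal(nrow(combos), 5^6)
  # independent re-statement of the rule rows, in precedence order
  expected <- with(combos, {
    att <- temporal_demand == "medium" & arousal %in% ge_med &
      valence == "medium"
    ina <- effort == "low" & temporal_demand == "low" &
      arousal == "low" & valence == "low"
    fat <- fatigue_degree == "high" & arousal == "low" & valence == "medium"
    pos <- performance == "high" & arousal %in% ge_med & valence == "high"
    neg <- performance == "low" & arousal %in% ge_med & valence == "low"
    out <- rep("unclassified", length(att))
    out[neg] <- "negative"; out[pos] <- "positive"; out[fat] <- "fatigue"
    out[ina] <- "inattentive"; out[att] <- "attentive"
    out
  })
  got <- vapply(seq_len(nrow(combos)), function(i)
    label_state(subjective_scale(
      combos$effort[i], combos$temporal_demand[i], combos$performance[i],
      combos$fatigue_degree[i], combos$arousal[i], combos$valence[i]),
      quiet = TRUE),
    character(1))
  expect_identical(got, expected)
  expect_true(all(got %in% c(names(plinet:::state_rules()), "unclassified")))
})

test_that("compare_scores recovers a known shift and degenerate case", {
  set.seed(21)
  before <- rnorm(13, 10, 1)
  after <- before + rnorm(13, 2, 0.5)
  res <- compare_scores(before, after)
  expect_gt(res$t, 0)
  expect_gt(res$d, 1)
  expect_equal(res$mean_a - res$mean_b, mean(after) - mean(before))
  same <- compare_scores(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(same$d, 0)
})

test_that("compare_conditions validates inputs and orders groups", {
  set.seed(8)
  df <- data.frame(condition = rep(c("x", "y"), each = 5),
                   sigma = c(rnorm(5, 3), rnorm(5, 1)))
  res <- compare_conditions(df, "sigma", c("x", "y"))
  expect_equal(res$group_a, "x")
  expect_gt(res$t, 0)
  expect_error(compare_conditions(df, "nonexistent"), "not found")
  df1 <- data.frame(condition = c("x", "y", "y"), sigma = 1:3)
  expect_error(compare_conditions(df1, "sigma"), "at least 2 subjects")
})
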
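test_that("ROC AUC equals Mann-Whitney concordance, including ties", {
  perfect <- tibble::tibble(score = c(3, 4, 1, 2), label = c(1, 1, 0, 0))
  expect_equal(roc_curve_auc(perfect)$area, 1.0)
  ties <- tibble::tibble(score = rep(2, 6), label = c(1, 0, 1, 0, 1, 0))
  expect_equal(roc_curve_auc(ties)$area, 0.5)
  set.seed(31)
  for (rep in 1:10) {
    n <- 30
    d <- tibble::tibble(score = sample(seq(0, 1, 0.1), n, replace = TRUE),
                        label = rbinom(n, 1, 0.4))
    if (sum(d$label) %in% c(0, n)) next
    expect_lt(abs(roc_curve_auc(d)$area -
                    auc_concordance_oracle(d$score, d$label)), 1e-9)
  }
  expect_error(roc_curve_auc(tibble::tibble(score = 1:3, label = c(1, 1, 1))),
               "both classes")
})

test_that("ROC AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  d <- tibble::tibble(score = rnorm(40), label = rbinom(40, 1, 0.5))
  ref <- suppressMessages(as.numeric(pROC::auc(d$label, d$score,
                                               direction = "<")))
  expect_equal(roc_curve_auc(d)$area, ref, tolerance = 1e-9)
})

test_that("ROC curves start at (0,0) and end at (1,1)", {
  set.seed(19)
  d <- tibble::tibble(score = rnorm(25), label = rbinom(25, 1, 0.5))
  pts <- tidy(roc_curve_auc(d))
  expect_equal(c(pts$fpr[1], pts$tpr[1]), c(0, 0))
  expect_equal(c(pts$fpr[nrow(pts)], pts$tpr[nrow(pts)]), c(1, 1))
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
})

test_that("average precision follows the step-weighted definition", {
  perfect <- tibble::tibble(score = c(3, 4, 1, 2), label = c(1, 1, 0, 0))
  expect_equal(pr_curve_ap(perfect)$area, 1.0)
  ## single positive ranked last among 5: only at the lowest threshold does
  ## recall move 0 -> 1, with precision 1/5
  worst <- tibble::tibble(score = c(5, 4, 3, 2, 1), label = c(0, 0, 0, 0, 1))
  expect_equal(pr_curve_ap(worst)$area, 1 / 5)
  set.seed(23)
  for (rep in 1:10) {
    d <- tibble::tibble(score = sample(seq(0, 2, 0.25), 20, replace = TRUE),
                        label = rbinom(20, 1, 0.5))
    if (sum(d$label) == 0) next
    expect_lt(abs(pr_curve_ap(d)$area - ap_oracle(d$score, d$label)), 1e-9)
  }
  expect_error(pr_curve_ap(tibble::tibble(score = 1:3, label = c(0, 0, 0))),
               "positive")
})

test_that("the optimal cutoff minimizes distance to (0,1) with ties to the higher threshold", {
  sep <- tibble::tibble(score = c(5, 4, 1, 2), label = c(1, 1, 0, 0))
  curve <- roc_curve_auc(sep)
  thr <- optimal_cutoff(curve)
  pts <- curve$points
  best <- pts[pts$threshold == thr, ]
  expect_equal(best$fpr^2 + (1 - best$tpr)^2, 0)
  ## exhaustive-minimum property on random data
  set.seed(37)
  d <- tibble::tibble(score = rnorm(30), label = rbinom(30, 1, 0.5))
  c2 <- roc_curve_auc(d)
  t2 <- optimal_cutoff(c2)
  d2 <- c2$points$fpr^2 + (1 - c2$points$tpr)^2
  expect_equal(min(d2), d2[c2$points$threshold == t2])
  ## equidistant points (0, 0.5) and (0.5, 1): the higher threshold wins
  tie <- tibble::tibble(score = c(4, 2, 3, 1), label = c(1, 1, 0, 0))
  expect_equal(optimal_cutoff(roc_curve_auc(tie)), 4)
})

test_that("leave-one-volume-out PPV/NPV reproduces a hand-traced run", {
  ## fold A trains on B+C -> cutoff 3; fold B trains on A+C -> cutoff 3;
  ## fold C trains on A+B -> cutoff 4, so C's positive (score 3) is missed:
  ## PPV undefined (no predicted positives), NPV = 1/2.
  d <- tibble::tibble(
    volume_id = rep(c("A", "B", "C"), each = 2),
    score = c(5, 1, 4, 2, 3, 2.5),
    label = rep(c(1, 0), 3)
  )
  res <- loo_ppv_npv(d)
  pv <- tidy(res)
  expect_equal(pv$threshold, c(3, 3, 4))
  expect_equal(pv$ppv, c(1, 1, NA))
  expect_equal(pv$npv, c(1, 1, 0.5))
  expect_equal(pv$tp, c(1, 1, 0))
  expect_equal(pv$fn, c(0, 0, 1))
  g <- glance(res)
  expect_equal(g$ppv_mean, 1)
  expect_equal(g$npv_mean, mean(c(1, 1, 0.5)))
  expect_equal(g$n_missing_ppv, 1L)
})

test_that("LOO handles volumes with a single class", {
  ## volume D has only anomalous slices, all flagged positive: NPV missing
  d <- tibble::tibble(
    volume_id = rep(c("A", "B", "D"), each = 2),
    score = c(5, 1, 4, 2, 9, 8),
    label = c(1, 0, 1, 0, 1, 1)
  )
  res <- loo_ppv_npv(d)
  row_d <- dplyr::filter(tidy(res), volume_id == "D")
  expect_equal(row_d$ppv, 1)
  expect_true(is.na(row_d$npv))
  expect_error(loo_ppv_npv(dplyr::filter(d, volume_id == "A")), "2 volumes")
})

test_that("a single global fold reduces to ordinary PPV/NPV at the optimal cutoff", {
  set.seed(41)
  s <- rnorm(20, 1.2)
  d <- tibble::tibble(
    volume_id = rep(c("u", "v"), each = 20),
    score = rep(s, 2),
    label = rep(rbinom(20, 1, 0.5), 2),
  )
  ## duplicated volumes: each fold trains on a copy of the test volume, so
  ## the transferred cutoff equals the global one
  thr <- optimal_cutoff(roc_curve_auc(d))
  res <- tidy(loo_ppv_npv(d))
  pred <- d$score[d$volume_id == "u"] >= thr
  lab <- d$label[d$volume_id == "u"] == 1
  expect_equal(res$ppv[1], sum(pred & lab) / sum(pred))
  expect_equal(res$npv[1], sum(!pred & !lab) / sum(!pred))
})

test_that("anomaly profiles interpolate to relative positions exactly", {
  d <- tibble::tibble(volume_id = "a", slice_index = 1:2, score = c(0, 1))
  p <- anomaly_profile(d, target_length = 3)
  expect_equal(p$mean_score, c(0, 0.5, 1))
  expect_equal(p$position, c(0, 0.5, 1))
  ## constant volumes give a constant profile
  d2 <- tibble::tibble(volume_id = rep(c("a", "b"), each = 4),
                       slice_index = rep(1:4, 2), score = 0.7)
  expect_true(all(anomaly_profile(d2, 10)$mean_score == 0.7))
  ## identity when already at the target length
  d3 <- tibble::tibble(volume_id = "a", slice_index = 1:5,
                       score = c(3, 1, 4, 1, 5))
  expect_equal(anomaly_profile(d3, 5)$mean_score, d3$score)
  ## knot-aligned piecewise-linear input is reproduced exactly
  d4 <- tibble::tibble(volume_id = "a", slice_index = 1:3, score = c(1, 5, 2))
  expect_equal(anomaly_profile(d4, 5)$mean_score, c(1, 3, 5, 3.5, 2))
  ## classes are averaged separately
  d5 <- dplyr::bind_rows(
    tibble::tibble(volume_id = "a", slice_index = 1:2, score = 1, class = "x"),
    tibble::tibble(volume_id = "b", slice_index = 1:2, score = 3, class = "y"))
  p5 <- anomaly_profile(d5, 4)
  expect_equal(unique(p5$mean_score[p5$class == "x"]), 1)
  expect_equal(unique(p5$mean_score[p5$class == "y"]), 3)
})

test_that("severity scores threshold the maps and correlate with lesion area", {
  mp <- matrix(c(0.1, 0.2, 0.4, 0.6), 2, 2)
  mk0 <- matrix(0L, 2, 2)
  sev <- severity_scores(list(mp), list(mk0), threshold = 0.3)
  expect_equal(tidy(sev)$map_score, 0.5)  # mean of {0.4, 0.6}
  expect_equal(tidy(sev)$relative_lesion_area, 0)
  low <- severity_scores(list(matrix(0.1, 2, 2)), list(mk0), threshold = 0.3)
  expect_equal(tidy(low)$map_score, 0)
  ## co-monotone area and score series: Spearman rho = 1
  maps <- lapply(1:6, function(i) matrix(0.3 + i / 10, 4, 4))
  masks <- lapply(1:6, function(i) {
    m <- matrix(0L, 4, 4); m[seq_len(i)] <- 1L; m
  })
  sev2 <- severity_scores(maps, masks, threshold = 0.3)
  expect_equal(sev2$spearman, 1.0)
  ## raising an above-threshold value never lowers the map score
  m_lo <- matrix(c(0.1, 0.4, 0.5, 0.2), 2, 2)
  m_hi <- m_lo; m_hi[2, 1] <- 0.9
  s_lo <- tidy(severity_scores(list(m_lo), list(mk0), 0.3))$map_score
  s_hi <- tidy(severity_scores(list(m_hi), list(mk0), 0.3))$map_score
  expect_gte(s_hi, s_lo)
  ## constant series: correlation undefined, reported missing
  sev3 <- severity_scores(list(mp, mp), list(mk0, mk0), 0.3)
  expect_true(is.na(sev3$spearman))
  expect_error(severity_scores(list(mp), list(matrix(0, 3, 3)), 0.3), "shape")
})

test_that("the training threshold is the pixel-weighted mean of map values", {
  expect_equal(training_threshold(list(matrix(0.42, 3, 3))), 0.42)
  expect_equal(training_threshold(list(matrix(0.2, 2, 2), matrix(0.4, 2, 2))),
               0.3)
  ## unequal sizes: flatten-and-average oracle
  set.seed(43)
  maps <- list(matrix(runif(4), 2, 2), matrix(runif(36), 6, 6))
  expect_equal(training_threshold(maps),
               mean(c(as.vector(maps[[1]]), as.vector(maps[[2]]))))
  expect_error(training_threshold(list()), "empty")
})
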
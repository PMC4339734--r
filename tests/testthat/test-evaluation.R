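test_that("confusion counts follow the sleep-positive convention", {
  p <- hypnogram(c("sleep", "sleep", "wake", "wake"))
  r <- hypnogram(c("sleep", "wake", "sleep", "wake"))
  cc <- confusion_counts(p, r)
  expect_equal(cc, list(tp = 1, tn = 1, fp = 1, fn = 1))
  expect_equal(confusion_counts(p, p)$fp + confusion_counts(p, p)$fn, 0)
  all_sleep <- hypnogram(rep("sleep", 4))
  cc2 <- confusion_counts(all_sleep, r)
  expect_equal(cc2$fn, 0); expect_equal(cc2$tn, 0)
  expect_error(confusion_counts(p, hypnogram("sleep")), "lengths")

  withr::with_seed(21, {
    a <- sample(c("sleep", "wake"), 500, replace = TRUE)
    b <- sample(c("sleep", "wake"), 500, replace = TRUE)
  })
  cc3 <- confusion_counts(hypnogram(a), hypnogram(b))
  expect_equal(cc3$tp, sum(a == "sleep" & b == "sleep"))
  expect_equal(Reduce(`+`, cc3), 500)
})

test_that("epoch metrics reproduce the hand-derived example to 3 decimals", {
  m <- epoch_metrics(list(tp = 50, tn = 20, fp = 10, fn = 20))
  expect_equal(round(m$sen, 3), 0.714)
  expect_equal(round(m$spc, 3), 0.667)
  expect_equal(round(m$ppv, 3), 0.833)
  expect_equal(round(m$npv, 3), 0.500)
  expect_equal(round(m$acu, 3), 0.700)
  expect_equal(round(m$pe, 3), 0.540)
  expect_equal(round(m$kappa, 3), 0.348)
})

test_that("kappa is 1 for perfect agreement and 0 for constant predictions", {
  withr::with_seed(22, r <- sample(c("sleep", "wake"), 200, replace = TRUE))
  perfect <- epoch_metrics(confusion_counts(hypnogram(r), hypnogram(r)))
  expect_equal(perfect$acu, 1); expect_equal(perfect$kappa, 1)

  const <- epoch_metrics(confusion_counts(hypnogram(rep("sleep", 200)),
                                          hypnogram(r)))
  expect_equal(const$kappa, 0)
  expect_true(is.na(const$npv))          # tn + fn = 0: flagged, no crash
})

test_that("subject evaluation reports per-subject, mean, and pooled views", {
  withr::with_seed(23, {
    refs <- lapply(1:3, function(i) {
      hypnogram(sample(c("sleep", "wake"), 60, replace = TRUE))
    })
    preds <- lapply(refs, function(r) {
      flip <- runif(60) < 0.1
      hypnogram(ifelse(flip, ifelse(r == "sleep", "wake", "sleep"),
                       as.character(r)))
    })
  })
  ev <- evaluate_subjects(preds, refs)
  expect_equal(nrow(ev$per_subject), 3)
  expect_gte(ev$subject_mean[["kappa"]], 0.5)
  expect_equal(ev$pooled$acu,
               sum(mapply(function(p, r) sum(p == r), preds, refs)) / 180)
})

test_that("AUC identities: perfect separation, chance, and the rank oracle", {
  ## perfect separation
  s <- c(rep(-0.9, 50), rep(0.9, 50))
  r <- hypnogram(c(rep("sleep", 50), rep("wake", 50)))
  expect_equal(roc_auc(list(s), list(r))$auc, 1)

  ## chance level at n = 1e4
  withr::with_seed(24, {
    s2 <- runif(1e4, -1, 1)
    r2 <- hypnogram(sample(c("sleep", "wake"), 1e4, replace = TRUE))
  })
  expect_lt(abs(roc_auc(list(s2), list(r2))$auc - 0.5), 0.02)

  ## pairwise-concordance equality on a small tied set
  withr::with_seed(25, {
    s3 <- round(runif(20, -1, 1), 1)
    r3 <- hypnogram(sample(c("sleep", "wake"), 20, replace = TRUE,
                           prob = c(0.6, 0.4)))
  })
  expect_equal(roc_auc(list(s3), list(r3))$auc,
               concordance_auc(s3, as.character(r3) == "sleep"),
               tolerance = 1e-9)
  expect_error(roc_auc(list(s), list(hypnogram(rep("sleep", 100)))),
               "single class")
})

test_that("profile-offset sweep equals concordance on threshold-relative scores", {
  withr::with_seed(26, {
    swls <- lapply(1:2, function(i) runif(80, -1, 1))
    refs <- lapply(1:2, function(i) {
      hypnogram(sample(c("sleep", "wake"), 80, replace = TRUE))
    })
    profs <- lapply(1:2, function(i) time_varying_threshold(runif(1, -0.2, 0.2), 80))
  })
  got <- roc_auc(swls, refs, profs)$auc
  stat <- unlist(mapply(function(s, p) s - p$per_epoch, swls, profs,
                        SIMPLIFY = FALSE))
  lab <- unlist(lapply(refs, as.character)) == "sleep"
  expect_equal(got, concordance_auc(stat, lab), tolerance = 1e-9)
})

test_that("Bland-Altman statistics match direct arithmetic", {
  b <- bland_altman(c(2, 4, 6), c(1, 2, 3))
  expect_equal(b$mean_diff, 2)
  expect_equal(b$sd_diff, 1)
  expect_equal(b$loa_low, 0.04)
  expect_equal(b$loa_high, 3.96)

  same <- bland_altman(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$mean_diff, 0); expect_equal(same$sd_diff, 0)

  b2 <- bland_altman(c(6, 7, 8), c(1, 2, 3))
  expect_equal(b2$mean_diff, 5)          # direction is BSA - PSG
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("covariate correlation returns Pearson r with its p-value", {
  expect_equal(covariate_correlation(1:10, 2 * (1:10) + 3)$r, 1)
  expect_equal(covariate_correlation(1:10, -3 * (1:10))$r, -1)
  withr::with_seed(27, {
    k <- rnorm(500); v <- rnorm(500)
  })
  ct <- covariate_correlation(k, v)
  expect_lt(abs(ct$r), 0.15)
  expect_equal(ct$p_value, cor.test(k, v)$p.value)
  expect_error(covariate_correlation(c(1, 2, 3), c(5, 5, 5)), "constant")
})

test_that("audio-reference alignment recovers a constructed delay", {
  withr::with_seed(28, v <- cumsum(rnorm(8000)))   # smooth random walk
  a <- list(values = v, dt_s = 0.015)
  expect_equal(align_to_reference(a, a), 0)

  shift <- 30                                      # 30 * 15 ms = 450 ms
  ref <- list(values = c(rep(v[1], shift), v[1:(8000 - shift)]), dt_s = 0.015)
  lag <- align_to_reference(a, ref)
  expect_equal(lag, 0.450, tolerance = 0.015)
  expect_equal(lag / 0.015, round(lag / 0.015), tolerance = 1e-9)

  expect_error(align_to_reference(list(values = v[1:100], dt_s = 0.015),
                                  list(values = v[1:100], dt_s = 0.015)),
               "overlap")
})
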
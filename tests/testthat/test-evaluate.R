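test_that("confusion metrics match hand arithmetic on a 2-class table", {
  # TP=8, FN=2 (true a), FP=1, TN=9 for class a
  truth <- rep(c("a", "b"), c(10, 10))
  pred <- c(rep("a", 8), rep("b", 2), "a", rep("b", 9))
  cs <- confusion_summary(pred, truth)
  m <- cs$metrics[cs$metrics$class == "a", ]
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.9)
  expect_equal(m$precision, 8 / 9)
  expect_equal(m$f1, 2 * (8 / 9 * 0.8) / (8 / 9 + 0.8))
  expect_equal(cs$error_rate, 3 / 20)
})

test_that("perfect and constant predictors give the expected rates", {
  y <- rep(c("x", "y", "z"), c(5, 3, 2))
  cs <- confusion_summary(y, y)
  expect_equal(cs$error_rate, 0)
  expect_true(all(cs$metrics$sensitivity == 1))
  expect_true(all(cs$metrics$specificity == 1))
  y2 <- rep(c("a", "b"), c(70, 30))
  cs2 <- confusion_summary(rep("a", 100), y2)
  expect_equal(cs2$error_rate, 0.30)
})

test_that("classes absent from truth are undefined, not zero", {
  cs <- confusion_summary(factor(c("a", "b"), levels = c("a", "b", "c")),
                          factor(c("a", "b"), levels = c("a", "b", "c")))
  m <- cs$metrics[cs$metrics$class == "c", ]
  expect_true(is.na(m$sensitivity))
  expect_true(is.na(m$f1))
  expect_equal(m$support, 0L)
})

test_that("confusion marginals and rates survive a brute-force recount", {
  set.seed(44)
  classes <- c("awake", "NREM1", "NREM2&3", "REM")
  truth <- sample(classes, 300, TRUE, prob = c(.4, .1, .4, .1))
  pred <- ifelse(runif(300) < 0.7, truth, sample(classes, 300, TRUE))
  cs <- confusion_summary(pred, truth, classes)
  expect_equal(sum(cs$table), 300)
  expect_equal(as.numeric(colSums(cs$table)),
               as.numeric(table(factor(truth, classes))))
  expect_equal(as.numeric(rowSums(cs$table)),
               as.numeric(table(factor(pred, classes))))
  for (cl in classes) {
    tp <- sum(pred == cl & truth == cl)
    fn <- sum(pred != cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    m <- cs$metrics[cs$metrics$class == cl, ]
    expect_equal(m$sensitivity, tp / (tp + fn))
    expect_equal(m$precision, tp / (tp + fp))
  }
  expect_equal(cs$error_rate, mean(pred != truth))
})

test_that("per-subject errors aggregate with the documented sd convention", {
  pred <- c("a", "a", "b", "b")
  truth <- c("a", "a", "a", "b")      # s1: 0 errors; s2: 1/2
  subj <- c("s1", "s1", "s2", "s2")
  pe <- per_subject_error(pred, truth, subj)
  expect_equal(pe$per_subject$error_rate, c(0, 0.5))
  expect_equal(pe$mean, 0.25)
  # subjects with error rates {0, 0.2}: mean 0.1, population sd 0.1
  pred2 <- c("a", rep("a", 4), "b")
  truth2 <- c("a", rep("a", 3), "b", "b")     # s1: 0/1; s2: 1/5
  subj2 <- c("s1", rep("s2", 5))
  pe2 <- per_subject_error(pred2, truth2, subj2)
  expect_equal(pe2$per_subject$error_rate, c(0, 0.2))
  expect_equal(pe2$mean, 0.1)
  expect_equal(pe2$sd, 0.1)
  same <- per_subject_error(c("a", "b"), c("b", "a"), c("s1", "s2"))
  expect_equal(same$sd, 0)
  one <- per_subject_error("a", "b", "s1")
  expect_true(is.na(one$sd))
  samp <- per_subject_error(pred, truth, subj, sd_type = "sample")
  expect_equal(samp$sd, sd(c(0, 0.5)))
})

test_that("experiment cells are reproducible and respect band subsets", {
  feats <- with_seed(19, {
    n <- 60
    data.frame(subject = rep(c("p1", "p2"), each = n / 2),
               epoch = seq_len(n),
               stage = rep(c("W", "N2", "R"), n / 3),
               high_beta = rnorm(n), low_gamma = rnorm(n),
               delta = rnorm(n))
  })
  feats$low_gamma <- feats$low_gamma + 2 * (feats$stage == "W")
  feats$high_beta <- feats$high_beta + 2 * (feats$stage == "R")
  e1 <- run_experiment(feats, arch = "original", scheme = "three_state",
                       epochs = 30, seed = 3, batch_size = 16)
  e2 <- run_experiment(feats, arch = "original", scheme = "three_state",
                       epochs = 30, seed = 3, batch_size = 16)
  expect_identical(e1$confusion$table, e2$confusion$table)
  expect_identical(e1$model$params, e2$model$params)
  hb <- run_experiment(feats, arch = "original", scheme = "three_state",
                       bands = "high_beta", epochs = 10, seed = 3,
                       batch_size = 16)
  expect_equal(hb$model$spec$n_features, 1L)
  expect_error(run_experiment(feats, bands = "sigma"), "sigma")
})

test_that("full-dataset normalization is available but distinct", {
  feats <- with_seed(23, data.frame(
    subject = "p1", epoch = 1:40, stage = rep(c("W", "R"), 20),
    delta = rnorm(40), low_gamma = c(rnorm(20), rnorm(20) + 3)[order(rep(c(1, 2), 20))]))
  feats$low_gamma <- rnorm(40) + 3 * (feats$stage == "W")
  tr_only <- run_experiment(feats, arch = "original", scheme = "three_state",
                            epochs = 5, seed = 2, batch_size = 8)
  full <- run_experiment(feats, arch = "original", scheme = "three_state",
                         epochs = 5, seed = 2, batch_size = 8,
                         normalization = "full")
  expect_false(identical(tr_only$test$low_gamma, full$test$low_gamma))
})

# Fast-mixing chains so short sessions still express every stage in stable
# proportions (per-subject normalization is composition-sensitive).
loso_cohort <- function(n_subj = 4, hours = 0.75, seed = 90,
                        shuffle_bands = FALSE) {
  sessions <- lapply(seq_len(n_subj), function(s) {
    prof <- default_stage_profiles()
    if (shuffle_bands) {
      perm <- with_seed(seed + s, sample(ncol(prof)))
      prof <- prof[, perm]
      colnames(prof) <- band_scheme()$band
    }
    cfg <- sim_config(n_subjects = n_subj, session_hours = hours,
                      transition_matrix = default_transition_matrix(
                        persist = 0.6),
                      stage_profiles = prof, seed = seed)
    simulate_session(cfg, s)
  })
  extract_cohort_features(sessions)
}

test_that("leave-one-subject-out yields one fold per subject", {
  feats <- loso_cohort(3, hours = 0.5)
  res <- loso_evaluate(feats, arch = "original", epochs = 40, seed = 2)
  expect_equal(nrow(res$per_subject), 3)
  expect_setequal(res$per_subject$subject, unique(feats$subject))
  one <- feats[feats$subject == feats$subject[1], ]
  expect_error(loso_evaluate(one), "2 subjects")
})

test_that("homogeneous subjects generalize across the LOSO boundary", {
  feats <- loso_cohort(4, seed = 91)
  within <- run_experiment(feats, arch = "original", scheme = "four_state",
                           seed = 5)
  loso <- loso_evaluate(feats, arch = "original",
                        scheme = label_scheme("four_state"), seed = 5)
  expect_lt(abs(loso$mean - within$confusion$error_rate), 0.05)
})

test_that("heterogeneous band profiles break LOSO generalization", {
  feats <- loso_cohort(4, seed = 92, shuffle_bands = TRUE)
  within <- run_experiment(feats, arch = "original", scheme = "four_state",
                           seed = 5)
  loso <- loso_evaluate(feats, arch = "original",
                        scheme = label_scheme("four_state"), seed = 5)
  expect_gt(loso$mean, within$confusion$error_rate)
})
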
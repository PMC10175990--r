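test_that("the bundled outcome table matches its documented shape", {
  tab <- read_outcomes()
  expect_identical(nrow(tab), 28L)
  expect_false(anyNA(tab$pre))
  expect_false(anyNA(tab$post))
  expect_identical(sum(!is.na(tab$week1)), 12L)
  expect_identical(sum(!is.na(tab$month1)), 13L)
  # scores outside 0-21 are rejected
  path <- withr::local_tempfile(fileext = ".tsv")
  bad <- tab; bad$pre[1] <- 25L
  write.table(bad, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_outcomes(path), class = "agiletms_config_error")
})

test_that("time-point mean imputation fills gaps and preserves means", {
  tab <- data.frame(subject_id = 1:3, age = 30, gender = "male",
                    pre = c(4L, NA, 8L), post = c(1L, 2L, 3L),
                    week1 = NA_integer_, month1 = c(NA, 5L, NA))
  imp <- impute_time_point_mean(tab, c("pre", "post", "month1"))
  expect_equal(imp$pre, c(4, 6, 8))
  expect_equal(imp$post, c(1, 2, 3))        # untouched when complete
  expect_equal(imp$month1, c(5, 5, 5))
  expect_error(impute_time_point_mean(tab, "week1"),
               class = "agiletms_degenerate_error")
  # mean preservation on the bundled cohort, at full precision
  full <- read_outcomes()
  imp_full <- impute_time_point_mean(full)
  for (tp in c("post", "week1", "month1"))
    expect_equal(mean(imp_full[[tp]]), mean(full[[tp]], na.rm = TRUE),
                 tolerance = 1e-12)
})

test_that("paired_t agrees with the closed-form statistic on random tables", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(5:30, 1)
    tab <- data.frame(subject_id = 1:n, age = 40, gender = "female",
                      pre = sample(0:21, n, TRUE),
                      post = sample(0:21, n, TRUE),
                      week1 = NA_integer_, month1 = NA_integer_)
    if (var(tab$pre - tab$post) == 0) next
    res <- paired_t(tab, "pre", "post")
    d <- tab$pre - tab$post
    expect_equal(res$statistic, mean(d) / (sd(d) / sqrt(n)),
                 tolerance = 1e-12)
    expect_identical(res$df, n - 1)
    expect_equal(res$p_value,
                 2 * pt(abs(res$statistic), n - 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("zero-variance differences raise a degenerate-statistics error", {
  # identical samples have mean difference 0 with SD 0: the statistic is
  # undefined (0/0), reported as an error rather than silently as 0
  tab <- data.frame(subject_id = 1:4, age = 20, gender = "male",
                    pre = c(2L, 4L, 6L, 5L), post = c(2L, 4L, 6L, 5L),
                    week1 = c(2L, 4L, 7L, 5L), month1 = NA_integer_)
  expect_error(paired_t(tab, "pre", "post"),
               class = "agiletms_degenerate_error")
  # a nearly-identical pair is well defined and close to zero
  expect_lt(abs(paired_t(tab, "pre", "week1")$statistic), 1.01)
})

test_that("two-time-point repeated-measures F equals the squared paired t", {
  tab <- read_outcomes()
  f_res <- rm_anova(tab, c("pre", "post"))
  t_res <- paired_t(tab, "pre", "post")
  expect_equal(f_res$statistic, t_res$statistic^2, tolerance = 1e-8)
  expect_equal(f_res$df, c(1, 27))
  set.seed(33)
  rnd <- data.frame(subject_id = 1:9, age = 1, gender = "male",
                    pre = sample(0:21, 9, TRUE), post = sample(0:21, 9, TRUE),
                    week1 = NA_integer_, month1 = NA_integer_)
  expect_equal(rm_anova(rnd, c("pre", "post"))$statistic,
               paired_t(rnd, "pre", "post")$statistic^2, tolerance = 1e-8)
})

test_that("rm_anova matches a brute-force decomposition and aov", {
  y <- matrix(c(3, 5, 4,
                6, 8, 7,
                2, 3, 1), nrow = 3, byrow = TRUE)  # 3 subjects x 3 times
  tab <- data.frame(subject_id = 1:3, age = 1, gender = "male",
                    pre = y[, 1], post = y[, 2], week1 = y[, 3],
                    month1 = NA_integer_)
  res <- rm_anova(tab, c("pre", "post", "week1"))
  # brute-force sums of squares
  grand <- mean(y)
  ss_time <- 3 * sum((colMeans(y) - grand)^2)
  ss_subj <- 3 * sum((rowMeans(y) - grand)^2)
  ss_err <- sum((y - grand)^2) - ss_time - ss_subj
  f_hand <- (ss_time / 2) / (ss_err / 4)
  expect_equal(res$statistic, f_hand, tolerance = 1e-12)
  expect_equal(res$df, c(2, 4))
  # independent route through aov with subjects as the error stratum
  long <- data.frame(y = as.vector(y),
                     subject = factor(rep(1:3, 3)),
                     time = factor(rep(1:3, each = 3)))
  aov_tab <- summary(aov(y ~ time + Error(subject), data = long))
  f_aov <- aov_tab[["Error: Within"]][[1]]["time", "F value"]
  expect_equal(res$statistic, f_aov, tolerance = 1e-8)
  # near-constant subjects: time effect indistinguishable from zero
  jit <- tab
  jit[, c("pre", "post", "week1")] <-
    matrix(rep(c(5, 9, 2), 3), 3) + matrix(rnorm(9, sd = 1e-6), 3)
  expect_lt(rm_anova(jit, c("pre", "post", "week1"))$statistic, 10)
})

test_that("cohort descriptives summarize demographics and time points", {
  d <- cohort_descriptives(read_outcomes())
  expect_identical(d$n, 28L)
  expect_identical(as.integer(d$n_by_gender[["male"]]), 18L)
  expect_identical(as.integer(d$n_by_gender[["female"]]), 10L)
  expect_equal(d$age_mean, 38.2, tolerance = 0.05)
  expect_equal(d$age_sd, 14.8, tolerance = 0.05)
  tp <- d$time_points
  expect_identical(tp$n_observed[tp$time_point == "week1"], 12L)
  # empty table gives an empty summary
  empty <- cohort_descriptives(read_outcomes()[0, ])
  expect_identical(empty$n, 0L)
})

test_that("target frequencies reproduce the cohort tabulations", {
  freq <- target_frequencies()
  by_p <- freq$by_parcel
  row <- function(id) by_p[by_p$parcel_id == id, ]
  expect_identical(row("L_8Av")$n_subjects, 24L)
  expect_identical(row("L_8Av")$pct_ctbs, 83)
  expect_identical(row("L_PGs")$n_subjects, 18L)
  expect_identical(row("L_PGs")$pct_ctbs, 78)
  expect_identical(freq$n_without_8av_pgs, 1L)
  expect_identical(freq$n_subjects, 28L)
  # multiset property: parcels count subjects with repetition across parcels
  expect_gte(sum(by_p$n_subjects), freq$n_subjects)
  # 15 participants carry both left 8Av and left PGs in the table
  presc <- read_prescription_table()
  both <- intersect(presc$subject_id[presc$parcel_id == "L_8Av"],
                    presc$subject_id[presc$parcel_id == "L_PGs"])
  expect_identical(length(both), 15L)
})
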
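test_that("rank transform uses average ranks and conserves the rank sum", {
  expect_equal(rank_transform(c(10, 20, 30)), c(1, 2, 3))
  expect_equal(rank_transform(c(10, 10, 30)), c(1.5, 1.5, 3))
  set.seed(2)
  x <- rnorm(57)
  expect_equal(sum(rank_transform(x)), 57 * 58 / 2)
  expect_error(rank_transform(c(1, NA)), "finite")
  expect_error(rank_transform(numeric(0)), "empty")
})

test_that("design degrees of freedom match the study shapes", {
  set.seed(10)
  rm_tab <- random_rm_table(10, 5, 4)   # 10 subjects x 5 blocks x 4 events
  a <- rm_anova2(rm_tab, within = c("w1", "w2"), use_ranks = TRUE)
  expect_equal(a$df_num, c(4, 3, 12))
  expect_equal(a$df_den, c(36, 27, 108))

  mx_tab <- random_mixed_table(10, 4)   # 2 x 10 subjects x 4 events
  m <- mixed_anova(mx_tab)
  expect_equal(m$df_num, c(1, 3, 3))
  expect_equal(m$df_den, c(18, 54, 54))

  lv_tab <- random_rm_table(10, 4, 2)   # 10 subjects x 4 events x 2 last-var
  l <- rm_anova2(lv_tab, within = c("w1", "w2"))
  expect_equal(l$df_num, c(3, 1, 3))
  expect_equal(l$df_den, c(27, 9, 27))
})

test_that("constant data yields zero F; duplicated groups yield zero group F", {
  tab <- random_rm_table(6, 3, 2)
  tab$mean_rt <- 500
  a <- rm_anova2(tab, within = c("w1", "w2"))
  expect_true(all(a$F == 0))

  set.seed(3)
  half <- expand.grid(subject_id = sprintf("s%d", 1:4),
                      event = c("e1", "e2", "e3"),
                      stringsAsFactors = FALSE)
  half$mean_rt <- rnorm(nrow(half), 500, 50)
  other <- half
  other$subject_id <- sub("s", "t", other$subject_id)
  half$group <- "ME"; other$group <- "MI"
  m <- mixed_anova(rbind(half, other))
  expect_equal(m$F[m$effect == "group"], 0, tolerance = 1e-12)
})

test_that("RM ANOVA matches the brute-force GLM oracle on random designs", {
  set.seed(101)
  for (i in 1:60) {
    n <- sample(4:6, 1); a <- sample(2:4, 1); b <- sample(2:4, 1)
    tab <- random_rm_table(n, a, b)
    ranks <- (i %% 2 == 0)
    got <- rm_anova2(tab, within = c("w1", "w2"), use_ranks = ranks)
    want <- oracle_rm2(tab, within = c("w1", "w2"), use_ranks = ranks)
    expect_equal(got$F, unname(want[, "F"]), tolerance = 1e-8)
    expect_equal(got$p, unname(want[, "p"]), tolerance = 1e-8)
    expect_equal(got$df_num, unname(want[, "df_num"]))
    expect_equal(got$df_den, unname(want[, "df_den"]))
  }
})

test_that("mixed ANOVA matches the brute-force GLM oracle on random designs", {
  set.seed(202)
  for (i in 1:40) {
    n <- sample(3:6, 1); w <- sample(2:4, 1)
    tab <- random_mixed_table(n, w)
    got <- mixed_anova(tab)
    want <- oracle_mixed(tab)
    expect_equal(got$F, unname(want[, "F"]), tolerance = 1e-8)
    expect_equal(got$p, unname(want[, "p"]), tolerance = 1e-8)
    expect_equal(got$df_den, unname(want[, "df_den"]))
  }
})

test_that("RM ANOVA agrees with aov error-strata output", {
  set.seed(7)
  tab <- random_rm_table(8, 3, 4)
  got <- rm_anova2(tab, within = c("w1", "w2"))
  fit <- summary(aov(mean_rt ~ w1 * w2 +
                       Error(factor(subject_id) / (w1 * w2)), data = tab))
  fa <- fit[["Error: factor(subject_id):w1"]][[1]]["w1", "F value"]
  fb <- fit[["Error: factor(subject_id):w2"]][[1]]["w2", "F value"]
  fab <- fit[["Error: factor(subject_id):w1:w2"]][[1]]["w1:w2", "F value"]
  expect_equal(got$F, c(fa, fb, fab), tolerance = 1e-10)
})

test_that("sphericity epsilon and Mauchly test match the mlm machinery", {
  set.seed(88)
  n <- 25; a <- 4; b <- 2
  Y <- matrix(rnorm(n * a * b), n) + 0.8 * matrix(rnorm(n), n, a * b) +
    0.5 * matrix(rnorm(n * a), n, a)[, rep(1:a, b)]
  tab <- expand.grid(subject_id = sprintf("s%02d", 1:n),
                     w1 = paste0("a", 1:a), w2 = paste0("b", 1:b),
                     stringsAsFactors = FALSE)
  tab <- tab[order(tab$w2, tab$w1, tab$subject_id), ]
  tab$mean_rt <- as.vector(Y)
  got <- rm_anova2(tab, within = c("w1", "w2"))

  idata <- data.frame(A = factor(rep(1:a, b)), B = factor(rep(1:b, each = a)))
  fit <- lm(Y ~ 1)
  mt <- mauchly.test(fit, M = ~A, X = ~1, idata = idata)
  expect_equal(got$mauchly_W[1], unname(mt$statistic), tolerance = 1e-8)
  # p-values use the same chi-square expansion but differ in the tiny
  # second-order coefficient between implementations
  expect_equal(got$mauchly_p[1], mt$p.value, tolerance = 1e-3)

  av <- anova(fit, M = ~A, X = ~1, idata = idata, test = "Spherical")
  head_txt <- paste(attr(av, "heading"), collapse = "\n")
  eps <- as.numeric(sub(".*Greenhouse-Geisser epsilon: +([0-9.]+).*", "\\1",
                        head_txt))
  expect_equal(got$epsilon_gg[1], eps, tolerance = 1e-4)
  expect_equal(got$F[1], av$F[1], tolerance = 1e-10)
  expect_equal(got$p_gg[1], av[["G-G Pr"]][1], tolerance = 1e-6)
})

test_that("rank ANOVA is invariant under strictly monotone transforms", {
  set.seed(55)
  tab <- random_rm_table(6, 3, 3)
  a1 <- rm_anova2(tab, within = c("w1", "w2"), use_ranks = TRUE)
  tab2 <- tab
  tab2$mean_rt <- exp(tab$mean_rt / 100)
  a2 <- rm_anova2(tab2, within = c("w1", "w2"), use_ranks = TRUE)
  expect_equal(a1$F, a2$F)
  expect_equal(a1$p, a2$p)
})

test_that("incomplete subjects are dropped with a warning", {
  tab <- random_rm_table(5, 3, 2)
  tab <- tab[!(tab$subject_id == "s01" & tab$w1 == "a1" & tab$w2 == "b1"), ]
  expect_warning(a <- rm_anova2(tab, within = c("w1", "w2")), "s01")
  expect_equal(attr(a, "n_subjects"), 4)
  expect_equal(a$df_den, c(2, 1, 2) * 3)
})

test_that("Bonferroni pairwise tables carry the family correction", {
  set.seed(77)
  tab <- random_mixed_table(8, 4)
  pw <- pairwise_bonferroni(tab, "event", paired = TRUE)
  expect_equal(nrow(pw), choose(4, 2))
  expect_true(all(pw$m == 6))
  expect_equal(pw$p_bonf, pmin(1, 6 * pw$p_raw))
  expect_true(all(pw$p_bonf >= pw$p_raw))
  expect_true(all(pw$tier %in% c("p<0.05", "p<0.01", "ns")))
  # monotone in raw p for fixed m
  ord <- order(pw$p_raw)
  expect_true(all(diff(pw$p_bonf[ord]) >= 0))

  # m = 1 family leaves p unchanged
  two <- tab[tab$event %in% c("e1", "e2"), ]
  pw2 <- pairwise_bonferroni(two, "event")
  expect_equal(pw2$p_bonf, pw2$p_raw)

  # unpaired comparisons across groups, split by event (simple effects)
  pwg <- pairwise_bonferroni(tab, "group", paired = FALSE,
                             split_by = "event")
  expect_equal(nrow(pwg), 4)
  expect_true(all(pwg$m == 4))

  # zero-variance difference is flagged, not an error
  degen <- data.frame(subject_id = rep(sprintf("s%d", 1:4), 2),
                      event = rep(c("e1", "e2"), each = 4),
                      mean_rt = rep(c(1, 2), each = 4))
  pwd <- pairwise_bonferroni(degen, "event")
  expect_true(pwd$zero_variance)
  expect_true(is.na(pwd$p_raw))
})

test_that("sub-block slopes are exact OLS and tests use df = n - 1", {
  tab <- expand.grid(subject_id = sprintf("s%02d", 1:10), group = "ME",
                     block = 1L, sub_block = 1:3,
                     stringsAsFactors = FALSE)
  tab <- tab[order(tab$subject_id), ]
  tab$mean_rt <- rep(c(500, 480, 460), 10) + rep(rnorm(10, 0, 5), each = 3)
  res <- subblock_slope_test(tab)
  expect_equal(res$slopes$slope, rep(-20, 10))
  expect_equal(res$tests$df, 9)
  expect_true(res$tests$zero_variance)  # all slopes identical

  tab$mean_rt <- tab$mean_rt + rnorm(30, 0, 3)
  res2 <- subblock_slope_test(tab)
  expect_equal(res2$tests$df, 9)
  expect_false(res2$tests$zero_variance)
  # slope equals the closed form for 3 equally spaced points
  one <- tab[tab$subject_id == "s01", ]
  expect_equal(res2$slopes$slope[res2$slopes$subject_id == "s01"],
               (one$mean_rt[3] - one$mean_rt[1]) / 2)
})

test_that("slope t-test rejection rate matches the analytic power", {
  # subjects' slopes ~ N(-5, 5^2), n = 10: compare the simulated rejection
  # rate of the package's one-sample test against power.t.test
  set.seed(909)
  reps <- 1000
  rej <- 0L
  template <- expand.grid(subject_id = sprintf("s%02d", 1:10), group = "ME",
                          block = 1L, sub_block = 1:3,
                          stringsAsFactors = FALSE)
  template <- template[order(template$subject_id), ]
  for (r in seq_len(reps)) {
    sl <- rnorm(10, -5, 5)
    template$mean_rt <- 500 + rep(sl, each = 3) * template$sub_block
    res <- subblock_slope_test(template)
    rej <- rej + (res$tests$p < 0.05)
  }
  pow <- power.t.test(n = 10, delta = 5, sd = 5, sig.level = 0.05,
                      type = "one.sample")$power
  expect_lt(abs(rej / reps - pow), 3 * sqrt(pow * (1 - pow) / reps))
})

test_that("last-var ANOVA is symmetric-zero and detects planted crossing", {
  # symmetric table in last_var -> last_var F = 0
  tab <- expand.grid(subject_id = sprintf("s%02d", 1:6),
                     event = c("F1", "F2", "V2", "V3"),
                     last_var = c("V2", "V3"), stringsAsFactors = FALSE)
  set.seed(31)
  base <- rnorm(6 * 4, 600, 40)
  tab$mean_rt <- rep(base, 2)
  l <- lastvar_rm_anova(tab)
  expect_equal(l$F[l$effect == "last_var"], 0, tolerance = 1e-12)

  # planted crossed interaction is detected in most synthetic cohorts
  set.seed(32)
  hits <- 0L
  for (r in 1:25) {
    cfg <- default_config(n_per_group = 8, groups = "MI",
                          seed = 5000 + r)
    coh <- simulate_cohort(cfg)
    cm <- cell_means(filter_trials(coh)$trials, c("event", "last_var"))
    lt <- lastvar_rm_anova(cm)
    p <- lt$p[lt$effect == "event:last_var"]
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits, 20)   # >= 80% at the planted +/-25 ms crossing
})
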
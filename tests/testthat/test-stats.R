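test_that("grouped summaries match a hand-computed toy table", {
  toy <- data.frame(
    speaker = c("S1", "S1", "S1", "S2", "S2", "S2"),
    class = rep("voiceless_ejective", 6),
    onset_lag_ms = c(10, 20, 30, 40, 50, 66))
  gs <- group_summary(toy, "onset_lag_ms")
  s1 <- gs[gs$speaker == "S1", ]
  expect_equal(s1$count, 3)
  expect_equal(s1$mean, 20)
  expect_equal(s1$sd, 10)
  s2 <- gs[gs$speaker == "S2", ]
  expect_equal(s2$mean, 52)
  expect_equal(s2$sd, sd(c(40, 50, 66)))
  tot <- gs[gs$speaker == "Total", ]
  expect_equal(tot$count, 6)
  expect_equal(tot$mean, (3 * 20 + 3 * 52) / 6)
  expect_equal(tot$mean, pooled_weighted_mean(c(s1$mean, s2$mean),
                                              c(s1$count, s2$count)))
})

test_that("empty and single-observation cells are reported, not errors", {
  toy <- data.frame(speaker = c("S1", "S2"), class = "x",
                    v = c(5, NA))
  gs <- group_summary(toy, "v")
  expect_equal(gs$count[gs$speaker == "S1"], 1)
  expect_true(is.na(gs$sd[gs$speaker == "S1"]))     # single token: no SD
  expect_equal(gs$count[gs$speaker == "S2"], 0)     # empty cell
  expect_true(is.na(gs$mean[gs$speaker == "S2"]))
})

test_that("zero-SD simulation round-trips the cell means through group_summary", {
  p <- default_class_params()
  p$cells[, c("disp_sd", "ext_sd", "onset_sd", "target_sd", "dur_sd")] <- 0
  p$cells[, c("r_onset", "r_target")] <- 0
  tab <- apply_omission_rule(generate_study_tokens(params = p, seed = 5))$retained
  gs <- group_summary(tab, "lx_displacement_mm")
  for (i in seq_len(nrow(p$cells))) {
    got <- gs$mean[gs$speaker == p$cells$speaker[i] &
                   gs$class == p$cells$class[i]]
    expect_equal(got, p$cells$disp_mean[i])
  }
})

test_that("count-weighted pooling reduces to the arithmetic mean for equal counts", {
  expect_equal(pooled_weighted_mean(c(2, 4, 9), c(7, 7, 7)), 5)
  expect_error(pooled_weighted_mean(1:3, 1:2), "length")
  expect_error(pooled_weighted_mean(1:2, c(3, 0)), "positive")
})

test_that("Brown-Forsythe equals the two-step ANOVA-on-deviations oracle", {
  # independent oracle: transform to |x - median|, then textbook one-way ANOVA
  oracle_bf <- function(groups) {
    z <- unlist(lapply(groups, function(v) abs(v - median(v))))
    g <- factor(rep(seq_along(groups), lengths(groups)))
    a <- anova(lm(z ~ g))
    c(F = a$`F value`[1], p = a$`Pr(>F)`[1])
  }
  groups <- list(a = c(1, 2, 3, 4, 5), b = c(10, 20, 30, 40, 50))
  bf <- brown_forsythe(groups)
  or <- oracle_bf(groups)
  expect_equal(bf$statistic, unname(or["F"]))
  expect_equal(bf$p.value, unname(or["p"]))
  expect_equal(bf$df1, 1); expect_equal(bf$df2, 8)
  set.seed(12)
  for (i in 1:15) {
    k <- sample(2:4, 1)
    gl <- lapply(seq_len(k), function(j) rnorm(sample(5:40, 1), 0, runif(1, 0.5, 3)))
    bf <- brown_forsythe(gl)
    or <- oracle_bf(gl)
    expect_equal(bf$statistic, unname(or["F"]), tolerance = 1e-12)
    expect_equal(bf$p.value, unname(or["p"]), tolerance = 1e-12)
  }
})

test_that("Brown-Forsythe agrees with the car implementation", {
  skip_if_not_installed("car")
  set.seed(13)
  x <- c(rnorm(40, 0, 1), rnorm(35, 0, 2.2), rnorm(30, 5, 1.4))
  g <- factor(rep(1:3, c(40, 35, 30)))
  bf <- brown_forsythe(split(x, g))
  lt <- car::leveneTest(x, g, center = median)
  expect_equal(bf$statistic, lt$`F value`[1], tolerance = 1e-12)
  expect_equal(bf$p.value, lt$`Pr(>F)`[1], tolerance = 1e-12)
})

test_that("identical deviation profiles give F = 0 and p = 1", {
  bf <- brown_forsythe(list(c(1, 2, 3), c(11, 12, 13)))
  expect_equal(bf$statistic, 0)
  expect_equal(bf$p.value, 1)
  expect_error(brown_forsythe(list(1:3)), "2 groups")
  expect_error(brown_forsythe(list(1:3, 5)), "2 observations")
})

test_that("CV test is null on identical groups and powerful on CV 0.5 vs 1.5", {
  g <- list(c(4, 5, 6, 7), c(4, 5, 6, 7))
  cv <- cv_equality_test(g)
  expect_equal(cv$statistic, 0, tolerance = 1e-6)
  expect_equal(cv$p.value, 1, tolerance = 1e-3)
  set.seed(14)
  rej <- mean(replicate(200, {
    cv_equality_test(list(rnorm(80, 10, 5), rnorm(80, 10, 15)))$p.value < 0.05
  }))
  expect_gt(rej, 0.8)
})

test_that("CV test handles negative means by reflection and flags zero means", {
  set.seed(15)
  a <- rnorm(60, -50, 10); b <- rnorm(60, 40, 8)
  cv <- cv_equality_test(list(a, b))
  expect_true(all(cv$cv > 0))
  expect_warning(cv_equality_test(list(rep(0, 10) + rnorm(10, 0, 1) * 1e-20,
                                       rnorm(20, 5, 1), rnorm(20, 5, 1))),
                 "excluded")
  # bootstrap p-method returns a valid probability
  cvb <- cv_equality_test(list(rnorm(25, 10, 2), rnorm(25, 10, 3)),
                          p_method = "simulation", B = 200, seed = 2)
  expect_true(cvb$p.value > 0 && cvb$p.value <= 1)
})

test_that("lag-duration correlations recover constructed regimes", {
  expect_equal(lag_duration_correlation(
    data.frame(consonant = "b", onset_lag_ms = 1:10,
               lx_duration_ms = 2 * (1:10)))$r, 1)
  expect_equal(lag_duration_correlation(
    data.frame(consonant = "b", onset_lag_ms = -(1:10),
               lx_duration_ms = 1:10))$r, -1)
  # coupled vs uncoupled simulator regimes at large n
  d <- study_design(repetitions = 90)
  tab <- generate_study_tokens(d, seed = 16)
  cor_tab <- lag_duration_correlation(
    tab[tab$class %in% c("voiced_pulmonic", "voiced_implosive"), ])
  vp <- cor_tab[cor_tab$consonant %in% c("b", "d"), ]
  im <- cor_tab[cor_tab$consonant %in% c("'b", "'d"), ]
  expect_true(all(vp$r < -0.35))
  expect_true(all(abs(im$r) < 0.2))
  # constant series flagged
  flag <- lag_duration_correlation(
    data.frame(consonant = "x", onset_lag_ms = rep(1, 5),
               lx_duration_ms = 1:5))
  expect_true(flag$flagged)
})

test_that("the mixed-model contract reports near-zero F for a null effect", {
  set.seed(17)
  tab <- generate_study_tokens(seed = 17)
  tab$flat <- rnorm(nrow(tab), 10, 1)   # no class effect
  res <- mixed_model_contract(tab, "flat")
  expect_lt(res$F, 3)
  expect_gt(res$p.value, 0.01)
  expect_true(is.finite(res$df2))
})

test_that("a 3 mm class shift is detected in most simulated studies", {
  set.seed(19)
  d <- study_design()
  detect <- replicate(60, {
    tab <- generate_study_tokens(d)
    tab <- tab[tab$class %in% c("voiceless_ejective", "voiceless_pulmonic"), ]
    tab$shifted <- tab$lx_displacement_mm +
      ifelse(tab$class == "voiceless_ejective", 3, 0) -
      ave(tab$lx_displacement_mm, tab$class)   # remove table-driven effect
    mixed_model_contract(tab, "shifted")$p.value < 0.05
  })
  expect_gt(mean(detect), 0.8)
})

test_that("a zero random-effect variance is reported as singular", {
  set.seed(18)
  tab <- data.frame(speaker = rep(c("S1", "S2", "S3"), each = 60),
                    class = rep(rep(c("a", "b"), each = 30), 3),
                    consonant = rep(rep(c("p", "q", "r"), 20), 3),
                    condition = "c1",
                    y = rnorm(180))
  res <- mixed_model_contract(tab, "y", random = c("speaker", "consonant"))
  expect_true(isTRUE(res$singular))
})
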
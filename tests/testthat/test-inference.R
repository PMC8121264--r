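test_that("pooled-variance t-test matches the closed form", {
  a <- c(2.0, 2.2); b <- c(2.1, 2.3)
  res <- students_t_test(a, b)
  # hand-computed pooled-variance formula
  sp2 <- (var(a) + var(b)) / 2
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 2 + 1 / 2))
  expect_equal(res$t_statistic, t_hand, tolerance = 1e-10)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, 2 * pt(abs(t_hand), 2, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(res$mean_difference, -0.1)
  expect_equal(sign(res$t_statistic), sign(res$mean_difference))

  same <- students_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)

  far <- students_t_test(c(1, 2, 3), c(11, 12, 13))
  expect_lt(far$p_value, 0.001)
  expect_error(students_t_test(1, c(1, 2)), "at least 2")
})

test_that("Cohen's d uses the pooled standard deviation", {
  expect_equal(cohens_d(c(1, 2, 3), c(2, 3, 4))$cohens_d, -1.0)
  expect_equal(cohens_d(c(5, 6), c(5, 6))$cohens_d, 0)
  z <- cohens_d(rep(1, 3), rep(2, 3))
  expect_false(z$defined)
  expect_true(is.na(z$cohens_d))
})

test_that("Sidak adjustment follows its closed form and monotonicity", {
  expect_equal(sidak_adjust(0.01, 5), 1 - 0.99^5)
  expect_lt(abs(sidak_adjust(0.01, 5) - 0.049010), 1e-6)
  expect_equal(sidak_adjust(0, 5), 0)
  expect_equal(sidak_adjust(1, 5), 1)
  expect_equal(sidak_adjust(0.3, 1), 0.3)
  p <- seq(0, 1, by = 0.05)
  for (m in c(2, 5, 10)) {
    expect_true(all(diff(sidak_adjust(p, m)) >= 0))   # nondecreasing in p
    expect_true(all(sidak_adjust(p, m) >= p))         # >= raw p
    expect_true(all(sidak_adjust(p, m + 1) >= sidak_adjust(p, m))) # in m
  }
})

test_that("balanced 2x2 Type-III SS matches the hand decomposition", {
  d <- data.frame(
    y = c(1, 2, 3, 4, 5, 6, 7, 8),
    A = rep(c("a1", "a2"), each = 4),
    B = rep(c("b1", "b1", "b2", "b2"), 2)
  )
  fit <- two_way_anova(d, "y", "A", "B")
  tab <- fit$table
  expect_equal(tab$ss[tab$source == "A"], 32)
  expect_equal(tab$ss[tab$source == "B"], 8)
  expect_equal(tab$ss[tab$source == "A:B"], 0)
  expect_equal(tab$ss[tab$source == "residual"], 2)
  expect_equal(tab$df, c(1L, 1L, 1L, 4L))
})

test_that("balanced designs equal the textbook decomposition (property)", {
  set.seed(101)
  for (i in 1:25) {
    n_per_cell <- sample(2:4, 1)
    d <- expand.grid(A = c("R", "L"), B = position_levels(),
                     rep = seq_len(n_per_cell), stringsAsFactors = FALSE)
    d$y <- rnorm(nrow(d), mean = 2 + (d$A == "R") * 0.3)
    fit <- two_way_anova(d, "y", "A", "B")
    orc <- oracle_balanced_ss(d$y, d$A, d$B)
    tab <- fit$table
    expect_equal(tab$ss[1], orc$ss_a, tolerance = 1e-9)
    expect_equal(tab$ss[2], orc$ss_b, tolerance = 1e-9)
    expect_equal(tab$ss[3], orc$ss_ab, tolerance = 1e-9)
    expect_equal(tab$ss[4], orc$ss_e, tolerance = 1e-9)
    expect_equal(sum(tab$ss), fit$ss_total, tolerance = 1e-9)
  }
})

test_that("unbalanced Type-III SS matches car::Anova (independent oracle)", {
  skip_if_not_installed("car")
  set.seed(77)
  for (i in 1:25) {
    d <- expand.grid(A = c("R", "L"), B = position_levels(),
                     rep = 1:4, stringsAsFactors = FALSE)
    d <- d[-sample(nrow(d), sample(1:6, 1)), ] # unbalance by deletion
    if (any(table(d$A, d$B) == 0)) next
    d$y <- rnorm(nrow(d), mean = 1 + (d$A == "R") * 0.5 + (d$B == "MD") * 0.3)
    fit <- two_way_anova(d, "y", "A", "B")
    op <- options(contrasts = c("contr.sum", "contr.poly"))
    lm_fit <- lm(y ~ A * B, data = d)
    oracle <- car::Anova(lm_fit, type = 3)
    options(op)
    tab <- fit$table
    expect_equal(tab$ss[1], oracle[["Sum Sq"]][rownames(oracle) == "A"], tolerance = 1e-8)
    expect_equal(tab$ss[2], oracle[["Sum Sq"]][rownames(oracle) == "B"], tolerance = 1e-8)
    expect_equal(tab$ss[3], oracle[["Sum Sq"]][rownames(oracle) == "A:B"], tolerance = 1e-8)
    expect_equal(tab$f[1], oracle[["F value"]][rownames(oracle) == "A"], tolerance = 1e-8)
    expect_equal(tab$p[1], oracle[["Pr(>F)"]][rownames(oracle) == "A"], tolerance = 1e-8)
  }
})

test_that("unbalancing a design changes Type-III SS away from the balanced value", {
  set.seed(5)
  d <- expand.grid(A = c("R", "L"), B = c("p1", "p2"), rep = 1:3,
                   stringsAsFactors = FALSE)
  d$y <- rnorm(nrow(d), mean = (d$A == "R") * 1)
  bal <- two_way_anova(d, "y", "A", "B")
  unbal <- two_way_anova(d[-1, ], "y", "A", "B")
  expect_false(isTRUE(all.equal(bal$table$ss[1], unbal$table$ss[1])))
})

test_that("ANOVA degenerates gracefully and guards its preconditions", {
  d <- expand.grid(A = c("R", "L"), B = position_levels(), rep = 1:2,
                   stringsAsFactors = FALSE)
  d$y <- 5
  fit <- two_way_anova(d, "y", "A", "B")
  expect_true(fit$no_variance)
  expect_true(all(is.na(fit$table$f[1:3])))

  d2 <- d[!(d$A == "R" & d$B == "MD"), ]
  d2$y <- rnorm(nrow(d2))
  expect_error(two_way_anova(d2, "y", "A", "B"), "empty cell: R x MD")

  d3 <- d[!duplicated(paste(d$A, d$B)), ]
  d3$y <- rnorm(nrow(d3))
  expect_error(two_way_anova(d3, "y", "A", "B"), "residual")
})

test_that("two-group t-test squares to the hand-computed one-way F", {
  set.seed(12)
  for (i in 1:10) {
    g1 <- rnorm(sample(3:8, 1)); g2 <- rnorm(sample(3:8, 1), mean = 0.5)
    tt <- students_t_test(g1, g2)
    # one-way ANOVA F computed from first principles
    y <- c(g1, g2); grand <- mean(y)
    ssb <- length(g1) * (mean(g1) - grand)^2 + length(g2) * (mean(g2) - grand)^2
    ssw <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
    f <- ssb / (ssw / (length(y) - 2))
    expect_equal(tt$t_statistic^2, f, tolerance = 1e-10)
    expect_equal(tt$p_value, pf(f, 1, length(y) - 2, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("balanced fits agree with base aov sums of squares", {
  set.seed(30)
  d <- expand.grid(A = c("R", "L"), B = position_levels(), rep = 1:3,
                   stringsAsFactors = FALSE)
  d$y <- rnorm(nrow(d), mean = 1 + (d$B == "MD") * 0.4)
  fit <- two_way_anova(d, "y", "A", "B")
  base <- summary(aov(y ~ A * B, data = d))[[1]]
  expect_equal(fit$table$ss, unname(base[["Sum Sq"]]), tolerance = 1e-9)
  expect_equal(fit$table$f[1:3], unname(base[["F value"]][1:3]), tolerance = 1e-9)
  expect_equal(fit$table$p[1:3], unname(base[["Pr(>F)"]][1:3]), tolerance = 1e-9)
})

test_that("Sidak pairwise contrasts use the residual MS and family of 5", {
  ds <- tiny_study(4, 4, seed = 8)
  tab <- compute_endpoint_table(collapse_positions(ds), "normalized_fetal_weight")
  sub <- tab[tab$horn_side == "R", ]
  sub$group_label <- factor(sub$group_label, levels = c("dosed", "control"))
  fit <- two_way_anova(sub, "value", "group_label", "position")
  ctr <- sidak_pairwise(fit, "group_label", "position", alpha = 0.05)

  expect_equal(nrow(ctr), 5L)
  expect_setequal(ctr$within_level, position_levels())
  expect_equal(unique(ctr$m), 5L)
  expect_equal(ctr$sidak_p, 1 - (1 - ctr$raw_p)^5)
  expect_true(all(ctr$sidak_p >= ctr$raw_p))
  expect_equal(unique(ctr$df), fit$df_residual)

  # hand-recompute one contrast from the cell means
  row <- ctr[ctr$within_level == "MD", ]
  cm <- fit$cell_means
  m1 <- cm$mean[cm$group_label == "dosed" & cm$position == "MD"]
  m2 <- cm$mean[cm$group_label == "control" & cm$position == "MD"]
  se <- sqrt(fit$ms_residual * (1 / 4 + 1 / 4))
  expect_equal(row$t, (m1 - m2) / se, tolerance = 1e-12)
  expect_equal(row$raw_p, 2 * pt(abs(row$t), fit$df_residual, lower.tail = FALSE))
})

test_that("layered positional analyses recover an injected right-horn deficit", {
  cfg <- scenario_gd4_like()
  ds <- simulate_study(cfg, seed = 42)
  rep <- analyze_study(ds)
  an <- rep$endpoints$normalized_fetal_weight$analyses
  ct <- an$contrast_table

  # exactly 5 contrasts per (group, horn) family in the vs-control layer
  vs <- ct[ct$analysis == "group_vs_control", ]
  fams <- table(vs$group_label, vs$horn_side)
  expect_true(all(fams == 5L))

  # the right-horn MD contrast flags the injected 45% reduction
  rmd <- vs[vs$horn_side == "R" & vs$position == "MD", ]
  expect_true(rmd$significant)
  expect_lt(rmd$mean_1 / rmd$mean_2, 0.7)
  # the spared right cervical end does not
  rce <- vs[vs$horn_side == "R" & vs$position == "CE", ]
  expect_false(rce$significant)

  # within-group layer: horn marginal p and pooled t-test alternative exist
  wg <- an$within_group$GD4
  expect_true(is.finite(wg$horn_side_p))
  expect_true(is.list(wg$horn_t_test))
  expect_equal(nrow(wg$contrasts), 5L)
})
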
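test_that("variance-stabilizing transforms hit their closed forms and invert", {
  tab <- rates_table(g = c(0, 1, 0.5, rep(0.3, 15)),
                     s = rep(0.5, 18), f = rep(100, 18),
                     lambda = rep(10, 18))
  tt <- transform_vitals(tab)
  expect_equal(tt$g[1:3], c(0, pi / 2, pi / 4))
  expect_equal(tt$f[1], 2)
  expect_equal(tt$lambda[1], 1)

  back <- inverse_transform_vitals(tt)
  expect_equal(back$g, tab$g, tolerance = 1e-12)
  expect_equal(back$s, tab$s, tolerance = 1e-12)
  expect_equal(back$f, tab$f, tolerance = 1e-12)

  expect_error(transform_vitals(rates_table(g = rep(1.2, 18),
                                            s = rep(0.5, 18),
                                            f = rep(1, 18))),
               "\\[0, 1\\]")
  expect_error(transform_vitals(rates_table(g = rep(0.5, 18),
                                            s = rep(0.5, 18),
                                            f = rep(0, 18))),
               "positive")
})

test_that("a response with no between-group variation gives F = 0", {
  set.seed(31)
  tab <- rates_table(g = rep(0.5, 18), s = rep(0.5, 18), f = rep(100, 18))
  # pure replicate noise, orthogonal to the design: remove cell means
  y <- rnorm(18)
  cell <- interaction(tab$biotype, tab$selection)
  tab$y <- y - ave(y, cell)
  a <- anova_two_way(tab, "y", error = "residual")
  expect_equal(a$F, rep(0, 3), tolerance = 1e-12)
})

test_that("F statistics match hand-computed mean-square ratios", {
  # deterministic response: biotype shift 1, selection shifts (0, 2, 4),
  # an extra interaction bump in one cell, replicate pattern (-1, 0, 1)
  tab <- rates_table(g = rep(0.5, 18), s = rep(0.5, 18), f = rep(100, 18))
  bshift <- ifelse(tab$biotype == "wild", 0, 1)
  sshift <- c(early = 0, control = 2, long = 4)[tab$selection]
  ishift <- ifelse(tab$biotype == "hybrid" & tab$selection == "long",
                   0.5, 0)
  rshift <- c(-1, 0, 1)[tab$replicate]
  tab$y <- 10 + bshift + sshift + ishift + rshift

  # hand computation from first principles
  SS_B <- 9 * sum((tapply(tab$y, tab$biotype, mean) - mean(tab$y))^2)
  SS_S <- 6 * sum((tapply(tab$y, tab$selection, mean) - mean(tab$y))^2)
  cellm <- tapply(tab$y, interaction(tab$biotype, tab$selection), mean)
  SS_cells <- 3 * sum((cellm - mean(tab$y))^2)
  SS_BS <- SS_cells - SS_B - SS_S
  SS_res <- sum((tab$y - ave(tab$y,
                             interaction(tab$biotype, tab$selection)))^2)

  a <- anova_two_way(tab, "y", error = "residual")
  expect_equal(a$sum_sq, c(SS_B, SS_S, SS_BS), tolerance = 1e-10)
  expect_equal(a$F, c(SS_B / 1, SS_S / 2, SS_BS / 2) / (SS_res / 12),
               tolerance = 1e-10)

  # interaction-error convention divides main effects by the BxS mean square
  ai <- anova_two_way(tab, "y", error = "interaction")
  expect_equal(ai$F[1:2], c(SS_B / 1, SS_S / 2) / (SS_BS / 2),
               tolerance = 1e-10)
  expect_equal(ai$F[3], a$F[3])
})

test_that("the reported df structure is (1,2), (2,2), (2,12)", {
  set.seed(32)
  tab <- rates_table(g = runif(18, 0.3, 0.7), s = runif(18, 0.3, 0.7),
                     f = runif(18, 50, 150))
  a <- anova_two_way(transform_vitals(tab), "g")
  expect_equal(a$df1, c(1, 2, 2))
  expect_equal(a$df2, c(2, 2, 12))
  expect_equal(a$df2_residual, rep(12, 3))
  expect_error(anova_two_way(tab, "nope"), "response column not found")
})

test_that("Type-III sums of squares agree with car on an unbalanced table", {
  skip_if_not_installed("car")
  set.seed(33)
  tab <- rates_table(g = runif(18, 0.3, 0.7), s = runif(18, 0.3, 0.7),
                     f = runif(18, 50, 150))
  a <- anova_two_way(tab, "g", error = "residual")
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  fit <- stats::lm(g ~ biotype * selection, data = tab)
  ca <- car::Anova(fit, type = 3)
  expect_equal(a$sum_sq, ca[c("biotype", "selection", "biotype:selection"),
                            "Sum Sq"],
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("MANOVA has its null value when group structure is absent", {
  set.seed(34)
  tab <- rates_table(g = rep(0.5, 18), s = rep(0.5, 18), f = rep(100, 18))
  cell <- interaction(tab$biotype, tab$selection)
  for (col in c("g", "s", "f")) {
    y <- rnorm(18)
    tab[[col]] <- y - ave(y, cell)  # all cell means exactly zero
  }
  m <- vital_manova(tab)
  expect_equal(m$statistic, rep(0, 3), tolerance = 1e-12)
})

test_that("MANOVA df match the 2x3 design with three responses", {
  set.seed(35)
  tab <- rates_table(g = runif(18, 0.3, 0.7), s = runif(18, 0.3, 0.7),
                     f = runif(18, 50, 150))
  m <- vital_manova(transform_vitals(tab))
  expect_equal(m$df1[m$effect == "B"], 3)
  expect_equal(m$df2[m$effect == "B"], 10)
  expect_equal(m$df1[m$effect == "S"], 6)
  expect_equal(m$df2[m$effect == "S"], 22)
  # statistic families are configurable
  mw <- vital_manova(transform_vitals(tab), statistic = "Wilks")
  expect_true(all(mw$statistic <= 1))
  # collinear responses are refused with guidance
  tab$s2 <- tab$s
  expect_error(vital_manova(tab, responses = c("s", "s2")), "singular")
})

test_that("a strongly separated group is detected by the MANOVA", {
  set.seed(36)
  tab <- rates_table(g = rnorm(18, 0.5, 0.02), s = rnorm(18, 0.5, 0.02),
                     f = rnorm(18, 100, 2))
  tab$g[tab$biotype == "hybrid"] <- tab$g[tab$biotype == "hybrid"] + 0.3
  m <- vital_manova(tab)
  expect_lt(m$p[m$effect == "B"], 0.01)
})

test_that("Tukey on two groups reduces to the pooled t-test", {
  set.seed(37)
  tab <- rates_table(g = rnorm(18, 0.5, 0.05), s = rep(0.5, 18),
                     f = rep(100, 18))
  tk <- tukey_posthoc(tab, "g", factor = "biotype", error = "residual")
  expect_equal(nrow(tk), 1L)
  # independent route: q = t * sqrt(2) identity against the pooled t
  # computed from the same within-cell residual mean square
  fit <- stats::lm(g ~ biotype * selection, data = tab)
  MS_res <- sum(stats::resid(fit)^2) / 12
  means <- tapply(tab$g, tab$biotype, mean)
  t_stat <- (means[["wild"]] - means[["hybrid"]]) /
    sqrt(MS_res * (1 / 9 + 1 / 9))
  expect_equal(tk$q, abs(t_stat) * sqrt(2), tolerance = 1e-10)
  expect_equal(tk$p_adj, 2 * stats::pt(-abs(t_stat), 12), tolerance = 1e-6)
})

test_that("Tukey p-values agree with TukeyHSD under the residual error term", {
  set.seed(38)
  tab <- rates_table(g = rnorm(18, 0.5, 0.05), s = rep(0.5, 18),
                     f = rep(100, 18))
  tab$g <- tab$g + c(early = 0, control = 0.05, long = 0.1)[tab$selection]
  tk <- suppressWarnings(
    tukey_posthoc(tab, "g", factor = "selection", error = "residual"))
  tab_f <- transform(tab,
                     biotype = factor(biotype, c("wild", "hybrid")),
                     selection = factor(selection,
                                        c("early", "control", "long")))
  hsd <- stats::TukeyHSD(stats::aov(g ~ biotype * selection, data = tab_f),
                         "selection")$selection
  key <- paste(tk$level2, tk$level1, sep = "-")  # TukeyHSD orders later-first
  ours <- tk$p_adj[match(rownames(hsd), key)]
  expect_equal(unname(ours), unname(hsd[, "p adj"]), tolerance = 1e-8)
})

test_that("identical groups give adjusted p of 1 and a shifted group stands out", {
  tab <- rates_table(g = rep(0.5, 18), s = rep(0.5, 18), f = rep(100, 18))
  set.seed(39)
  tab$y <- rep(c(1, 2, 3), 6)  # same values in every selection level
  tk <- suppressWarnings(tukey_posthoc(tab, "y", factor = "selection"))
  expect_true(all(tk$p_adj > 0.999))

  tab$y <- rnorm(18, 0, 1)
  tab$y[tab$selection == "long"] <- tab$y[tab$selection == "long"] + 5
  tk2 <- tukey_posthoc(tab, "y", factor = "selection")
  sig <- tk2$p_adj[tk2$level1 == "long" | tk2$level2 == "long"]
  expect_true(all(sig < 0.05))
  expect_gt(tk2$p_adj[tk2$level1 == "early" & tk2$level2 == "control"],
            0.05)
})

test_that("the summary table gathers all responses in published layout", {
  set.seed(40)
  tab <- rates_table(g = runif(18, 0.3, 0.7), s = runif(18, 0.3, 0.7),
                     f = runif(18, 50, 150),
                     lambda = runif(18, 4, 6))
  st <- anova_summary_table(tab)
  expect_equal(st$effect, c("B", "S", "BxS"))
  expect_true(all(c("F_g", "F_s", "F_f", "F_lambda") %in% names(st)))
  expect_equal(st$df2, c(2, 2, 12))
})
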
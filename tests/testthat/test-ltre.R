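test_that("mean_matrix is the element-wise average", {
  M <- build_matrix(list(d = 0.1, g = 0.5, s = 0.7, f = 100))
  expect_equal(unclass(mean_matrix(rep(list(M), 6)))[1:3, 1:3],
               unclass(M)[1:3, 1:3], ignore_attr = TRUE)

  M2 <- build_matrix(list(d = 0.1, g = 0.5, s = 0.7, f = 300))
  avg <- mean_matrix(list(M, M2))
  expect_equal(avg[1, 3], 200)

  set.seed(21)
  ms <- replicate(6, build_matrix(random_rates()), simplify = FALSE)
  # brute-force loop average
  acc <- matrix(0, 3, 3)
  for (m in ms) acc <- acc + unclass(m)
  expect_equal(unclass(mean_matrix(ms))[1:3, 1:3], (acc / 6)[1:3, 1:3],
               ignore_attr = TRUE)
  expect_error(mean_matrix(list()), "empty")
})

test_that("the reference matrix pools the six control populations", {
  set.seed(22)
  mats <- random_design_matrices()
  ref <- reference_matrix(mats)
  ctrl <- mats[grepl("_control_", names(mats))]
  expect_length(ctrl, 6L)
  acc <- matrix(0, 3, 3)
  for (m in ctrl) acc <- acc + unclass(m)
  expect_equal(unclass(ref)[1:3, 1:3], (acc / 6)[1:3, 1:3],
               ignore_attr = TRUE)
  # grand-mean option pools all 18
  refg <- reference_matrix(mats, type = "grand")
  acc <- matrix(0, 3, 3)
  for (m in mats) acc <- acc + unclass(m)
  expect_equal(unclass(refg)[1:3, 1:3], (acc / 18)[1:3, 1:3],
               ignore_attr = TRUE)
})

test_that("treatment pooling is two-stage averaging, not a grand replicate pool", {
  set.seed(23)
  mats <- random_design_matrices()
  pooled <- treatment_matrices(mats)
  expect_length(pooled$cell, 6L)
  expect_length(pooled$biotype, 2L)
  expect_length(pooled$selection, 3L)

  # brute-force two-stage loop
  cell_mean <- function(b, s) {
    acc <- matrix(0, 3, 3)
    for (r in 1:3) acc <- acc + unclass(mats[[paste(b, s, r, sep = "_")]])
    acc / 3
  }
  for (b in c("wild", "hybrid")) {
    acc <- matrix(0, 3, 3)
    for (s in c("early", "control", "long")) acc <- acc + cell_mean(b, s)
    expect_equal(unclass(pooled$biotype[[b]])[1:3, 1:3], (acc / 3)[1:3, 1:3],
                 ignore_attr = TRUE)
  }
  for (s in c("early", "control", "long")) {
    acc <- cell_mean("wild", s) + cell_mean("hybrid", s)
    expect_equal(unclass(pooled$selection[[s]])[1:3, 1:3], (acc / 2)[1:3, 1:3],
                 ignore_attr = TRUE)
  }

  # a missing cell is named in the error
  expect_error(treatment_matrices(mats[!grepl("hybrid_long", names(mats))]),
               "missing design cell: hybrid/long")
})

test_that("an all-identical design yields an exactly zero decomposition", {
  mats <- constant_design_matrices()
  fit <- ltre(mats)
  for (kind in c("biotype", "selection", "interaction")) {
    expect_true(all(unlist(fit$effects$exact[[kind]]) == 0))
    expect_true(all(unlist(fit$effects$first_order[[kind]]) == 0))
    for (C in fit$contributions[[kind]]) expect_true(all(C == 0))
  }
  tab <- contribution_table(fit)
  expect_true(all(tab$contribution == 0))
  # 4 named vital-rate rows per effect level: 2 + 3 + 6 levels
  expect_equal(nrow(tab), 4L * (2L + 3L + 6L))
})

test_that("a pure fecundity shift puts its whole contribution on a13", {
  base <- list(d = 0.1, g = 0.5, s = 0.7, f = 200)
  ref <- build_matrix(base)
  for (mult in c(0.8, 0.9, 1.1, 1.2)) {
    trt <- build_matrix(modifyList(base, list(f = base$f * mult)))
    cmp <- ltre_compare(trt, ref)
    expect_equal(cmp$contributions[1, 3], cmp$first_order)
    rest <- cmp$contributions; rest[1, 3] <- 0
    expect_true(all(rest == 0))
    # first-order sum tracks the exact lambda difference within 5%
    expect_lt(abs(cmp$first_order - cmp$delta_lambda),
              0.05 * abs(cmp$delta_lambda))
    # direction mirrors the fecundity change
    expect_equal(sign(cmp$contributions[1, 3]), sign(mult - 1))
  }
})

test_that("the additive identity lambda_gs = lambda_ref + a + b + ab holds exactly", {
  set.seed(24)
  mats <- random_design_matrices()
  fit <- ltre(mats)
  for (b in c("wild", "hybrid")) for (s in c("early", "control", "long")) {
    cell <- paste(b, s, sep = "/")
    lhs <- fit$lambda$cell[[cell]]
    rhs <- fit$lambda_ref + fit$effects$exact$biotype[[b]] +
      fit$effects$exact$selection[[s]] +
      fit$effects$exact$interaction[[cell]]
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("relabelling replicates never changes an effect", {
  set.seed(25)
  mats <- random_design_matrices()
  fit <- ltre(mats)
  # swap replicate labels 1 and 3 inside every cell
  swapped <- mats
  for (b in c("wild", "hybrid")) for (s in c("early", "control", "long")) {
    n1 <- paste(b, s, 1, sep = "_"); n3 <- paste(b, s, 3, sep = "_")
    tmp <- swapped[[n1]]; swapped[[n1]] <- swapped[[n3]]
    swapped[[n3]] <- tmp
    attr(swapped[[n1]], "labels")$replicate <- 1L
    attr(swapped[[n3]], "labels")$replicate <- 3L
  }
  fit2 <- ltre(swapped)
  expect_equal(fit2$effects$exact, fit$effects$exact, tolerance = 1e-12)
  expect_equal(fit2$effects$first_order, fit$effects$first_order,
               tolerance = 1e-12)
})

test_that("contribution sums track exact lambda differences on full designs", {
  set.seed(26)
  for (rep_i in 1:5) {
    mats <- random_design_matrices(jitter = 0.15)
    fit <- ltre(mats)
    for (kind in c("biotype", "selection")) {
      ex <- fit$effects$exact[[kind]]
      fo <- fit$effects$first_order[[kind]]
      for (lv in names(ex)) {
        if (abs(ex[[lv]]) < 0.02) next  # relative error unstable near zero
        expect_lt(abs(fo[[lv]] - ex[[lv]]), 0.1 * abs(ex[[lv]]))
      }
    }
  }
})

test_that("contribution_table maps elements onto the named vital rates", {
  base <- list(d = 0.1, g = 0.5, s = 0.7, f = 200)
  mats <- constant_design_matrices(base)
  # lower fecundity in the early cells only
  for (r in 1:3) for (b in c("wild", "hybrid")) {
    nm <- paste(b, "early", r, sep = "_")
    mats[[nm]] <- build_matrix(modifyList(base, list(f = 150)),
                               labels = attr(mats[[nm]], "labels"))
  }
  fit <- ltre(mats)
  tab <- contribution_table(fit, effects = "selection")
  early_fec <- tab$contribution[tab$level == "early" &
                                  tab$vital_rate == "fecundity"]
  expect_lt(early_fec, 0)  # lower fecundity -> negative contribution
  other <- tab$contribution[tab$level == "early" &
                              tab$vital_rate != "fecundity"]
  expect_true(all(other == 0))
  # hand check: contribution = (a13^early - a13^ref) * S13(midpoint)
  pooled <- treatment_matrices(mats)
  ref <- reference_matrix(mats)
  mid <- (unclass(pooled$selection$early) + unclass(ref)) / 2
  S13 <- perturbation(mid)$S[1, 3]
  expect_equal(early_fec,
               (pooled$selection$early[1, 3] - ref[1, 3]) * S13,
               tolerance = 1e-12)
})

test_that("within-biotype comparisons support both control conventions", {
  set.seed(27)
  mats <- random_design_matrices()
  own <- within_biotype_comparison(mats, "wild", "early",
                                   control = "biotype")
  pool <- within_biotype_comparison(mats, "wild", "early",
                                    control = "pooled")
  pooled <- treatment_matrices(mats)
  expect_equal(own$delta_lambda,
               lambda1(pooled$cell[["wild/early"]]) -
                 lambda1(pooled$cell[["wild/control"]]),
               tolerance = 1e-12)
  expect_equal(pool$delta_lambda,
               lambda1(pooled$cell[["wild/early"]]) -
                 lambda1(reference_matrix(mats)),
               tolerance = 1e-12)
})

test_that("coef and summary expose both effect computations", {
  set.seed(28)
  mats <- random_design_matrices()
  fit <- ltre(mats)
  co <- coef(fit)
  expect_length(co, 2L + 3L + 6L)
  expect_equal(unname(co["biotype:wild"]),
               unname(fit$effects$exact$biotype[["wild"]]))
  sm <- summary(fit)
  expect_s3_class(sm, "summary.ltre")
  expect_equal(nrow(sm$table), 11L)
  expect_true(all(c("exact", "first_order") %in% names(sm$table)))
})
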
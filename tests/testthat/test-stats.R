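simGrouped <- function(n_groups, n_per, beta = 0, sd_b = 1, sd_e = 1,
                       seed = 1L) {
  set.seed(seed)
  g <- rep(seq_len(n_groups), each = n_per)
  x <- stats::rnorm(n_groups * n_per, 0, 3)
  b <- stats::rnorm(n_groups, 0, sd_b)
  data.frame(
    y = beta * x + b[g] + stats::rnorm(n_groups * n_per, 0, sd_e),
    x = x, g = factor(g)
  )
}

test_that("random-intercept fit recovers a known fixed effect", {
  df <- simGrouped(40L, 25L, beta = 0.12, seed = 7L)
  fit <- fitRandomIntercept(df, "y", fixed = "x", random = "g")
  co <- fixedEffects(fit)
  expect_lt(abs(co["x", "estimate"] - 0.12), 0.05)
  expect_true(co["x", "ci_lower"] < 0.12 && 0.12 < co["x", "ci_upper"])
  expect_gt(co["x", "df"], 100)  # character-level effect, many residual df
  expect_false(isSingular(fit))
  vc <- varianceComponents(fit)
  expect_lt(abs(vc[["g"]] - 1), 0.5)
  expect_lt(abs(vc[["Residual"]] - 1), 0.2)
})

test_that("zero between-group variance is flagged singular with a 0 component", {
  df <- simGrouped(20L, 10L, sd_b = 0, seed = 1L)
  expect_warning(fit <- fitRandomIntercept(df, "y", random = "g"), "singular")
  expect_true(isSingular(fit))
  expect_lt(varianceComponents(fit)[["g"]], 0.05)
})

test_that("degenerate grouping structures are rejected", {
  df <- data.frame(y = stats::rnorm(10), g = factor(1:10))
  expect_error(suppressWarnings(fitRandomIntercept(df, "y", random = "g")))
  df1 <- data.frame(y = stats::rnorm(10), g = factor(rep(1, 10)))
  expect_error(fitRandomIntercept(df1, "y", random = "g"), "fewer than 2")
})

test_that("delta AIC is antisymmetric, ~-2 for noise and large for signal", {
  df <- simGrouped(30L, 10L, beta = 0, seed = 11L)
  set.seed(11L)
  df$junk <- stats::rnorm(nrow(df))
  null_fit <- fitRandomIntercept(df, "y", random = "g")
  junk_fit <- fitRandomIntercept(df, "y", fixed = "junk", random = "g")
  expect_identical(deltaAIC(null_fit, null_fit), 0)
  d_junk <- deltaAIC(null_fit, junk_fit)
  expect_lt(abs(d_junk - (-2)), 1)          # penalty-only difference
  expect_equal(deltaAIC(junk_fit, null_fit), -d_junk)

  df2 <- simGrouped(30L, 10L, beta = 0.5, seed = 11L)
  null2 <- fitRandomIntercept(df2, "y", random = "g")
  test2 <- fitRandomIntercept(df2, "y", fixed = "x", random = "g")
  expect_gt(deltaAIC(null2, test2), 2)

  other <- fitRandomIntercept(simGrouped(10L, 5L, seed = 3L), "y", random = "g")
  expect_error(deltaAIC(null_fit, other), "different outcome")
})

test_that("ICC recovers the variance split and honors its invariances", {
  df <- simGrouped(50L, 20L, sd_b = 1, sd_e = 1, seed = 3L)
  icc <- intraclassCorrelation(df$y, df$g)
  expect_lt(abs(icc - 0.5), 0.05)
  # shift invariance and scale equivariance
  expect_equal(intraclassCorrelation(df$y + 100, df$g), icc)
  expect_equal(intraclassCorrelation(df$y * 7, df$g), icc, tolerance = 1e-6)
  # no between-group signal -> near 0; no within-group noise -> 1
  set.seed(9)
  expect_lt(intraclassCorrelation(stats::rnorm(200), rep(letters[1:10], 20)),
            0.05)
  expect_equal(intraclassCorrelation(rep(1:5, each = 4),
                                     rep(letters[1:5], each = 4)), 1)
  # log-transform convention for byte-scale measures
  expect_equal(intraclassCorrelation(exp(df$y), df$g, log_transform = TRUE),
               icc)
})

test_that("JZS Bayes factor matches direct marginal-likelihood quadrature", {
  # oracle: integrate the noncentral-t likelihood against the Cauchy prior
  oracle <- function(t, n, r = sqrt(2) / 2) {
    nu <- n - 1
    alt <- stats::integrate(function(delta) {
      suppressWarnings(stats::dt(t, nu, ncp = delta * sqrt(n))) *
        stats::dcauchy(delta, 0, r)
    }, -Inf, Inf, rel.tol = 1e-10)$value
    stats::dt(t, nu) / alt
  }
  for (tt in c(0, 0.5, 1, 2, 3)) {
    for (nn in c(5L, 29L, 100L)) {
      got <- bayesFactorNull(jzsBayesFactor(t = tt, n = nn))
      expect_lt(abs(got - oracle(tt, nn)) / oracle(tt, nn), 0.01)
    }
  }
  # the null is favored at the point null, for any n
  for (nn in c(3L, 10L, 50L)) {
    expect_gt(bayesFactorNull(jzsBayesFactor(t = 0, n = nn)), 1)
  }
  # monotone decreasing in |t| at fixed n
  grid <- vapply(seq(0, 6, by = 0.5),
                 function(tt) bayesFactorNull(jzsBayesFactor(t = tt, n = 29L)),
                 numeric(1L))
  expect_true(all(diff(grid) < 0))
  expect_lt(grid[length(grid)], 0.01)  # large |t| crushes the null
  # vector interface matches the t/n interface
  set.seed(15)
  x <- stats::rnorm(20, 0.2)
  tt <- mean(x) / (stats::sd(x) / sqrt(20))
  expect_equal(bayesFactorNull(jzsBayesFactor(x)),
               bayesFactorNull(jzsBayesFactor(t = tt, n = 20L)))
  expect_error(jzsBayesFactor(c(1)), "at least 2")
  expect_error(jzsBayesFactor(rep(2, 5)), "zero variance")
})

test_that("ancestry differentials average per ancestor before testing", {
  inv <- mkInventory(c("Anc1", "Anc2", sprintf("De%02d", 1:6)), "LR",
                     ancestor = c(NA, NA, rep("Anc1", 5), "Anc2"))
  means <- c(Anc1 = 10, Anc2 = 20,
             De01 = 12, De02 = 9, De03 = 14, De04 = 11, De05 = 10, De06 = 26)
  res <- ancestryDifferentials(inv, means)
  expect_identical(nrow(res$pairs), 6L)
  expect_identical(nrow(res$per_ancestor), 2L)  # one value per ancestor
  expect_equal(sort(res$per_ancestor$n_descendants), c(1L, 5L))
  expect_equal(res$per_ancestor$differential[res$per_ancestor$ancestor == "Anc1"],
               mean(c(2, -1, 4, 1, 0)))
  expect_equal(res$per_ancestor$differential[res$per_ancestor$ancestor == "Anc2"],
               6)
  # descendants identical to ancestors: all differentials zero, null favored
  means0 <- means
  means0[3:8] <- c(10, 10, 10, 10, 10, 20)
  res0 <- suppressWarnings(ancestryDifferentials(inv, means0))
  expect_true(all(res0$pairs$differential == 0))
  expect_gt(bayesFactorNull(res0$bayes), 1)
  # unmeasured ancestor pairs are skipped with a message
  inv2 <- rbind(inv, mkInventory("De07", "LR", ancestor = "Gone"))
  expect_message(res2 <- ancestryDifferentials(inv2, means), "skipping")
  expect_identical(res2$skipped$code, "De07")
})

test_that("a null ancestry world mostly supports the null hypothesis", {
  set.seed(5)
  bfs <- replicate(200, {
    diffs <- stats::rnorm(29, 0, 5)  # 29 ancestors, no drift
    bayesFactorNull(jzsBayesFactor(diffs))
  })
  expect_gt(stats::median(bfs), 1)
})

test_that("order models recover a built-in first-half advantage", {
  # construct half tables numerically with a known order effect on AC
  set.seed(19)
  n_scripts <- 12L
  n_chars <- 15L
  scripts <- sprintf("S%02d", seq_len(n_scripts))
  dirs <- rep(c("LR", "RL"), length.out = n_scripts)
  rows <- list()
  for (i in seq_len(n_scripts)) {
    for (j in seq_len(n_chars)) {
      first_ac <- 500 + stats::rnorm(1, 0, 40)
      last_ac <- first_ac - 60 + stats::rnorm(1, 0, 40)
      left_ac <- if (dirs[i] == "LR") first_ac else last_ac
      right_ac <- if (dirs[i] == "LR") last_ac else first_ac
      rows[[length(rows) + 1L]] <- data.frame(
        script = scripts[i], family = rep(c("A", "B"), 6L)[i],
        codepoint = sprintf("%04X", j), directionality = dirs[i],
        side = c("left", "right"),
        order = if (dirs[i] == "LR") c("first", "last") else c("last", "first"),
        C = c(left_ac, right_ac) / 100, AC = c(left_ac, right_ac)
      )
    }
  }
  halves <- do.call(rbind, rows)
  halves <- discrepancyScores(halves)
  l <- halves[halves$side == "left", ]
  r <- halves[halves$side == "right", ]
  chars <- data.frame(
    script = l$script, family = l$family, codepoint = l$codepoint,
    directionality = l$directionality,
    dLR_ac = l$AC - r$AC,
    dFL_ac = firstLastDifferential(l$AC, r$AC, l$directionality)
  )
  om <- suppressWarnings(orderModels(list(halves = halves, characters = chars),
                                     "ac"))
  co <- fixedEffects(om$intercept)
  expect_gt(co["(Intercept)", "estimate"], 30)
  expect_lt(co["(Intercept)", "p"], 0.05)
  # order explains half-level AC better than side does
  expect_gt(om$order_vs_side_daic, 2)
  expect_lt(fixedEffects(om$order_fit)["orderlast", "estimate"], -30)
  # directionality flips the left-right differential: negative RL estimate
  co_lat <- fixedEffects(om$lateral_dir)
  expect_lt(co_lat["directionalityRL", "estimate"], -60)
  expect_lt(co_lat["directionalityRL", "p"], 0.05)
})

test_that("order models report null effects for symmetric characters", {
  set.seed(29)
  n_scripts <- 10L
  rows <- list()
  for (i in seq_len(n_scripts)) {
    for (j in 1:12) {
      ac <- 400 + stats::rnorm(2, 0, 30)
      d <- if (i %% 2 == 0) "LR" else "RL"
      rows[[length(rows) + 1L]] <- data.frame(
        script = sprintf("S%02d", i), family = rep(c("A", "B"), 5L)[i],
        codepoint = sprintf("%04X", j), directionality = d,
        side = c("left", "right"),
        order = if (d == "LR") c("first", "last") else c("last", "first"),
        C = ac / 100, AC = ac
      )
    }
  }
  halves <- discrepancyScores(do.call(rbind, rows))
  l <- halves[halves$side == "left", ]
  r <- halves[halves$side == "right", ]
  chars <- data.frame(
    script = l$script, family = l$family, codepoint = l$codepoint,
    directionality = l$directionality,
    dLR_ac = l$AC - r$AC,
    dFL_ac = firstLastDifferential(l$AC, r$AC, l$directionality)
  )
  om <- suppressWarnings(orderModels(list(halves = halves, characters = chars),
                                     "ac"))
  expect_gt(fixedEffects(om$intercept)["(Intercept)", "p"], 0.05)
  expect_gt(fixedEffects(om$discrepancy)["sideright", "p"], 0.05)
})

test_that("large-script exclusion drops only scripts at the threshold", {
  inv <- mkInventory(c("Aaaa", "Bbbb", "Cccc"), "LR")
  inv$inventory_size <- c(52L, 199L, 200L)
  kept <- excludeLargeScripts(inv)
  expect_identical(kept$code, c("Aaaa", "Bbbb"))
})
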
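test_that("blocked disability reduces LE to the truncated geometric series", {
  a <- -6  # constant monthly death logit
  q <- exp(a) / (1 + exp(a))
  pars <- make_params(alpha_01 = -50, alpha_10 = -50, alpha_02 = a,
                      alpha_12 = a)
  for (start in c(50, 65)) {
    M <- (110 - start) * 12
    ex <- state_expectancies(pars, new_profile(0, 0, 0), start)
    expect_equal(ex$LE0, (1 / 12) * (1 - q) / q * (1 - (1 - q)^M),
                 tolerance = 1e-9)
    expect_lt(ex$e["0", "1"], 1e-12)  # never disabled
  }
})

test_that("certain immediate death gives zero expectancies", {
  pars <- make_params(alpha_02 = 50, alpha_12 = 50)
  ex <- state_expectancies(pars, new_profile(1, 1, 1), 50)
  expect_lt(ex$LE0, 1e-12)
  expect_lt(ex$LE1, 1e-12)
})

test_that("decomposition LE_j = e_j0 + e_j1 and sanity bounds on a grid", {
  lt <- life_table(default_truth())
  expect_equal(lt$LE0, lt$e00 + lt$e01, tolerance = 1e-9)
  expect_equal(lt$LE1, lt$e10 + lt$e11, tolerance = 1e-9)
  expect_true(all(lt$HLE <= lt$LE + 1e-12))
  expect_true(all(lt$pct_healthy >= 0 & lt$pct_healthy <= 100))
  expect_true(all(lt$LE >= 0 & is.finite(lt$LE)))
  # mortality rises with age, so LE must fall along the age grid
  for (i in seq(1, nrow(lt), by = 5)) {
    expect_true(all(diff(lt$LE[i:(i + 4)]) < 0))
  }
})

test_that("period prevalence behaves at the structural limits", {
  prof <- new_profile(0, 0, 0)
  ages <- c(50, 60, 70, 85)
  # disability blocked -> prevalence identically 0
  none <- make_params(alpha_01 = -50, alpha_10 = -50, alpha_02 = -6,
                      alpha_12 = -6)
  expect_equal(unname(period_prevalence(none, prof, ages)), rep(0, 4),
               tolerance = 1e-12)
  # no recovery, equal death rows -> nondecreasing prevalence, checked
  # against an independent direct propagation of the full 3-state chain
  pars <- make_params(alpha_01 = -4, alpha_10 = -50, alpha_02 = -6,
                      alpha_12 = -6, beta1_01 = 0.05)
  pi1 <- period_prevalence(pars, prof, ages)
  expect_true(all(diff(pi1) >= 0))
  v <- c(1, 0, 0)
  expected <- numeric(0)
  for (m in 0:(35 * 12 - 1)) {
    if ((m %% 12) == 0 && (50 + m / 12) %in% ages) {
      expected <- c(expected, v[2] / (v[1] + v[2]))
    }
    v <- v %*% step_transition_matrix(pars, 50 + m / 12, prof)
  }
  expected <- c(expected, v[2] / (v[1] + v[2]))  # age 85 endpoint
  expect_equal(unname(pi1), expected, tolerance = 1e-12)
  # symmetric flows and equal death rates -> prevalence tends to 1/2
  sym <- make_params(alpha_01 = -2, alpha_10 = -2, alpha_02 = -5,
                     alpha_12 = -5)
  expect_equal(unname(period_prevalence(sym, prof, 100)), 0.5,
               tolerance = 1e-3)
})

test_that("population mixing is the prevalence-weighted combination", {
  ex <- state_expectancies(default_truth(), new_profile(1, 0, 0), 65)
  p0 <- population_expectancies(ex, 0)
  expect_identical(p0$LE, ex$LE0)
  expect_identical(p0$HLE, ex$e["0", "0"])
  p <- population_expectancies(ex, 0.3)
  expect_equal(p$LE, 0.7 * ex$LE0 + 0.3 * ex$LE1, tolerance = 1e-12)
  expect_equal(p$HLE, 0.7 * ex$e["0", "0"] + 0.3 * ex$e["1", "0"],
               tolerance = 1e-12)
})

test_that("percent healthy reproduces the published worked examples", {
  expect_identical(pct_healthy(28.32, 26.68), 94.21)
  expect_identical(pct_healthy(5.73, 1.75), 30.54)
  expect_true(is.na(pct_healthy(0, 0)))
})

test_that("raising the truncation age from 110 to 120 moves LE(50) by < 0.01", {
  # holds for steep enough age slopes on mortality (here 0.095 and 0.08/yr)
  pars <- default_truth()
  prof <- new_profile(0, 0, 0)
  le110 <- state_expectancies(pars, prof, 50, truncation_age = 110)$LE0
  le120 <- state_expectancies(pars, prof, 50, truncation_age = 120)$LE0
  expect_lt(abs(le120 - le110), 0.01)
})

test_that("e_jk matches the Monte-Carlo trajectory oracle (scaled down)", {
  # 20k trajectories here keep the unit suite fast; the acceptance suite
  # runs the full 100k version.
  pars <- default_truth()
  prof <- new_profile(0, 0, 0)
  ex <- state_expectancies(pars, prof, 65)
  for (s0 in c(0L, 1L)) {
    tr <- simulate_trajectories(pars, prof, 65, n = 20000, start_state = s0,
                                seed = 71 + s0)
    for (k in c("years0", "years1")) {
      mc <- mean(tr[[k]])
      se <- sd(tr[[k]]) / sqrt(nrow(tr))
      expect_lt(abs(mc - ex$e[as.character(s0),
                              if (k == "years0") "0" else "1"]),
                3 * se)
    }
  }
})

test_that("life table I/O and formatting", {
  lt <- life_table(default_truth(), ages = c(50, 65))
  f <- withr::local_tempfile(fileext = ".csv")
  write_life_table(lt, f)
  back <- read.csv(f)
  expect_equal(back$LE, lt$LE, tolerance = 1e-9)
  txt <- format_life_table(lt)
  expect_true(any(grepl("^50", txt)))
  expect_identical(length(grep("%", txt, fixed = TRUE)), 2L)
  txtc <- format_life_table(lt, "conditional")
  expect_true(any(grepl("conditional", txtc)))
})

test_that("start below model support warns but computes", {
  expect_warning(ex <- state_expectancies(default_truth(),
                                          new_profile(0, 0, 0), 45),
                 "extrapolation")
  expect_gt(ex$LE0, 0)
})
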
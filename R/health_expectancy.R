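# Multistate life-table quantities from a fitted (or true) transition model.
#
# All quantities come from monthly propagation of the 3x3 transition matrices
# up to a truncation age (default 110): occupancy is counted at the end of
# each completed month (rectangle rule, no half-step start correction), so
# with disability blocked and a constant monthly death probability q the
# expectancy reduces exactly to the truncated geometric series
# (1/12) (1-q)/q (1 - (1-q)^M). Any survival mass left at the truncation age
# is treated as dying there.

OMEGA_DEFAULT <- 110

# Live-row step probabilities for a fixed profile at a vector of ages
# (years); returns list of n x 3 matrices row0, row1. Vectorized so the
# life-table propagation is cheap.
step_rows_vec <- function(params, ages, profile) {
  p <- as_profile(profile)
  b <- unclass(params)
  eta <- sapply(TRANSITIONS, function(tr) {
    b[tr, "intercept"] + b[tr, "age"] * ages + b[tr, "sex"] * p[["sex"]] +
      b[tr, "hyp"] * p[["hyp"]] + b[tr, "diab"] * p[["diab"]]
  })
  eta <- matrix(eta, ncol = 4, dimnames = list(NULL, TRANSITIONS))
  r0m <- pmax(0, eta[, "01"], eta[, "02"])
  w0s <- exp(-r0m); w01 <- exp(eta[, "01"] - r0m); w02 <- exp(eta[, "02"] - r0m)
  d0 <- w0s + w01 + w02
  r1m <- pmax(0, eta[, "10"], eta[, "12"])
  w10 <- exp(eta[, "10"] - r1m); w1s <- exp(-r1m); w12 <- exp(eta[, "12"] - r1m)
  d1 <- w10 + w1s + w12
  list(row0 = cbind(w0s / d0, w01 / d0, w02 / d0),
       row1 = cbind(w10 / d1, w1s / d1, w12 / d1))
}

#' State-specific expectancies
#'
#' Expected years e_jk spent in live state k between `start_age` and
#' `truncation_age`, given occupancy of live state j at `start_age`, from the
#' monthly product of transition matrices:
#' `e_jk = (1/12) * sum_{m=1..M} [prod_{t<m} P(start_age + t/12)]_{jk}`.
#'
#' @param params a `model_params`
#' @param profile covariate profile
#' @param start_age starting age in years (a warning is issued below 50, the
#'   lower end of model support)
#' @param truncation_age closure age omega (default 110); remaining survivors
#'   are treated as dying there
#' @return list with `e` (2x2 matrix, `e["0","1"]` = years disabled given
#'   healthy at start, etc.), `LE0`, `LE1` (row sums: total remaining years by
#'   starting state)
#' @export
state_expectancies <- function(params, profile, start_age,
                               truncation_age = OMEGA_DEFAULT) {
  stopifnot(start_age < truncation_age)
  if (start_age < 50) {
    warning("start_age ", start_age, " is below model support (50): ",
            "extrapolation", call. = FALSE)
  }
  M <- round((truncation_age - start_age) * 12)
  rows <- step_rows_vec(params, start_age + (seq_len(M) - 1) / 12, profile)
  # occ[j, ] = live-state occupancy distribution after m months, start j
  occ <- diag(2)
  e <- matrix(0, 2, 2, dimnames = list(c("0", "1"), c("0", "1")))
  for (m in seq_len(M)) {
    # 2x2 live-live block; row0 = (stay0, to1), row1 = (to0, stay1)
    A <- rbind(rows$row0[m, 1:2], rows$row1[m, 1:2])
    occ <- occ %*% A
    e <- e + occ
  }
  e <- e / 12
  list(e = e, LE0 = sum(e[1, ]), LE1 = sum(e[2, ]))
}

#' Period (implied) prevalence of disability
#'
#' Propagates the live-state distribution from all-healthy at `base_age`
#' through the monthly matrices and reports the disabled share among
#' survivors at each requested age — the cross-sectional prevalence the
#' fitted incidence model implies for a stationary population.
#'
#' @param params a `model_params`
#' @param profile covariate profile
#' @param ages ages (years) at which to report, all `>= base_age`
#' @param base_age age at which everyone is healthy (default 50)
#' @return named numeric vector pi_1(age)
#' @export
period_prevalence <- function(params, profile, ages,
                              base_age = 50) {
  stopifnot(all(ages >= base_age))
  target_m <- round((ages - base_age) * 12)
  M <- max(target_m, 0L)
  out <- numeric(length(ages))
  v <- c(1, 0)  # live-state occupancy (healthy, disabled), unnormalized
  out[target_m == 0] <- 0
  if (M > 0) {
    rows <- step_rows_vec(params, base_age + (seq_len(M) - 1) / 12, profile)
    for (m in seq_len(M)) {
      A <- rbind(rows$row0[m, 1:2], c(rows$row1[m, 1], rows$row1[m, 2]))
      v <- v %*% A
      hit <- which(target_m == m)
      if (length(hit)) out[hit] <- v[2] / sum(v)
    }
  }
  setNames(out, ages)
}

round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Percentage of remaining life without functional incapacity
#'
#' `100 * HLE / LE`, rounded half-up to 2 decimals (the reporting convention
#' of the published tables). Undefined (NA) when LE is 0.
#'
#' @param LE life expectancy (years)
#' @param HLE healthy life expectancy (years)
#' @return percentage on the 0-100 scale
#' @export
pct_healthy <- function(LE, HLE) {
  ifelse(LE > 0, round_half_up(100 * HLE / LE, 2), NA_real_)
}

#' Population-level LE, HLE and percent healthy
#'
#' Mixes the state-conditional expectancies by the disabled prevalence pi_1
#' at the starting age: `LE = (1-pi_1) LE_0 + pi_1 LE_1`,
#' `HLE = (1-pi_1) e_00 + pi_1 e_10`.
#'
#' @param exps output of [state_expectancies()]
#' @param prev1 disabled prevalence at the starting age (scalar in \[0,1\])
#' @return list `LE`, `HLE`, `pct_healthy`
#' @export
population_expectancies <- function(exps, prev1) {
  stopifnot(prev1 >= 0, prev1 <= 1)
  LE <- (1 - prev1) * exps$LE0 + prev1 * exps$LE1
  HLE <- (1 - prev1) * exps$e["0", "0"] + prev1 * exps$e["1", "0"]
  list(LE = LE, HLE = HLE, pct_healthy = pct_healthy(LE, HLE))
}

#' Multistate life table over ages and covariate profiles
#'
#' Assembles state expectancies, implied prevalence and population LE / HLE /
#' percent-healthy over an age grid for each covariate profile. Population
#' values weight the starting state by the period prevalence propagated from
#' all-healthy at `base_age`; the healthy-at-age conditional values are the
#' `LE0` / `e00` columns.
#'
#' @param params a `model_params`
#' @param ages age grid (default the published 50/60/65/75/85)
#' @param profiles data.frame with columns sex, hyp, diab (default all 8)
#' @param truncation_age closure age (default 110)
#' @param base_age prevalence propagation origin (default 50)
#' @return data.frame of class `hlemc_life_table` with one row per profile x
#'   age: e00, e01, e10, e11, LE0, LE1, prevalence, LE, HLE, pct_healthy
#' @export
life_table <- function(params, ages = c(50, 60, 65, 75, 85),
                       profiles = covariate_profiles(),
                       truncation_age = OMEGA_DEFAULT, base_age = 50) {
  rows <- list()
  for (i in seq_len(nrow(profiles))) {
    pr <- new_profile(profiles$sex[i], profiles$hyp[i], profiles$diab[i])
    prev <- period_prevalence(params, pr, ages, base_age = base_age)
    for (a in seq_along(ages)) {
      ex <- state_expectancies(params, pr, ages[a], truncation_age)
      pop <- population_expectancies(ex, prev[[a]])
      rows[[length(rows) + 1L]] <- data.frame(
        sex = profiles$sex[i], hyp = profiles$hyp[i], diab = profiles$diab[i],
        age = ages[a],
        e00 = ex$e["0", "0"], e01 = ex$e["0", "1"],
        e10 = ex$e["1", "0"], e11 = ex$e["1", "1"],
        LE0 = ex$LE0, LE1 = ex$LE1,
        prevalence = prev[[a]],
        LE = pop$LE, HLE = pop$HLE, pct_healthy = pop$pct_healthy)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("hlemc_life_table", "data.frame")
  attr(out, "truncation_age") <- truncation_age
  attr(out, "base_age") <- base_age
  out
}

#' Write a life table as CSV
#'
#' @param lt an `hlemc_life_table`
#' @param path output path
#' @return invisibly `path`
#' @export
write_life_table <- function(lt, path) {
  write.csv(as.data.frame(lt), path, row.names = FALSE)
  invisible(path)
}

#' Format a life table in the published layout
#'
#' One block per age with LE / HLE / percent rows and one column per
#' sex-by-hypertension-by-diabetes profile, for either the prevalence-weighted
#' population values (default headline) or the healthy-at-age conditional
#' ones.
#'
#' @param lt an `hlemc_life_table`
#' @param which `"population"` (prevalence-weighted) or `"conditional"`
#'   (healthy at the index age)
#' @return character vector of lines
#' @export
format_life_table <- function(lt, which = c("population", "conditional")) {
  which <- match.arg(which)
  profs <- unique(as.data.frame(lt)[, c("sex", "hyp", "diab")])
  hdr <- sprintf("%-9s", c("Age", ""))
  lab <- apply(profs, 1, function(r) {
    paste0(ifelse(r["sex"] == 1, "M", "F"), ifelse(r["hyp"] == 1, "+H", "-H"),
           ifelse(r["diab"] == 1, "+D", "-D"))
  })
  lines <- c(sprintf("Life table (%s; omega = %s)", which,
                     attr(lt, "truncation_age")),
             paste0(paste(hdr, collapse = ""),
                    paste(sprintf("%9s", lab), collapse = "")))
  for (a in unique(lt$age)) {
    sub <- lt[lt$age == a, ]
    key <- paste(sub$sex, sub$hyp, sub$diab)
    ord <- match(paste(profs$sex, profs$hyp, profs$diab), key)
    if (which == "population") {
      le <- sub$LE[ord]; hle <- sub$HLE[ord]
    } else {
      le <- sub$LE0[ord]; hle <- sub$e00[ord]
    }
    lines <- c(lines,
      paste0(sprintf("%-9s%-9s", a, "LE"),
             paste(sprintf("%9.2f", le), collapse = "")),
      paste0(sprintf("%-9s%-9s", "", "HLE"),
             paste(sprintf("%9.2f", hle), collapse = "")),
      paste0(sprintf("%-9s%-9s", "", "%"),
             paste(sprintf("%9.2f", pct_healthy(le, hle)), collapse = "")))
  }
  lines
}

#' @export
print.hlemc_life_table <- function(x, ...) {
  cat(format_life_table(x), sep = "\n")
  invisible(x)
}

#' @export
`[.hlemc_life_table` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- "data.frame"
  out
}
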
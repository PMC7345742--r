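# Synthetic aging-cohort generator.
#
# Emulates a five-wave longitudinal study on aging: baseline respondents aged
# 50+, interviews at months 0/36/84/132/180, ADL state recorded at attended
# waves, death dates at month resolution always ascertained within the study
# window (registry linkage), non-informative wave non-response and dropout.
# The latent process is the exact monthly 3-state chain of the transition
# model, so the generator shares no code path with the likelihood beyond the
# step probabilities it is meant to exercise.

BASELINE_MONTH <- 1996L * 12L + 3L  # interviews anchored at 03/1996

#' Default "true" transition coefficients
#'
#' A fixed, documented parameter set used as simulation truth: positive age
#' slopes for death and disability onset, recovery allowed and declining with
#' age, male excess mortality, hypertension loading mainly on disability
#' onset, diabetes raising both onset and mortality. Chosen once so implied
#' life expectancy at age 50 falls in the plausible 22-34 year band for all
#' eight covariate profiles (a plausibility envelope, not a fit to any data).
#'
#' @return a `model_params`
#' @export
default_truth <- function() {
  model_params(rbind(
    #            intercept    age     sex    hyp    diab
    "01" = c(       -12.00,  0.090, -0.15,  0.35,  0.55),
    "02" = c(       -13.10,  0.095,  0.35,  0.10,  0.50),
    "10" = c(        -1.45, -0.020,  0.10, -0.05, -0.25),
    "12" = c(       -10.85,  0.080,  0.35,  0.10,  0.45)))
}

#' Cohort generator configuration
#'
#' Defaults reproduce the stated baseline structure of the emulated survey:
#' n = 5131 respondents aged 50+, male fraction 0.5296, hypertension 0.2468,
#' diabetes 0.1059, baseline ADL-disabled fraction 0.10, age-bin mix from the
#' published baseline table, waves at months 0/36/84/132/180.
#'
#' @param n number of subjects
#' @param seed RNG seed (simulation is deterministic given the config)
#' @param wave_months interview months relative to baseline, strictly
#'   increasing, first must be 0
#' @param baseline_age_probs probabilities over the age bins 50-54, 55-59,
#'   60-64, 65-69, 70-74, 75+ (count shares 602/817/675/921/1046/1070)
#' @param p_male,p_hypertension,p_diabetes covariate prevalences
#' @param p_baseline_disabled probability of starting ADL-disabled
#' @param truth `model_params` generating the latent chain
#' @param p_missed_wave probability an alive, retained subject misses a
#'   follow-up wave (recorded state 9); follow-up response stays above 80%
#' @param p_dropout_per_wave per-wave probability of permanent dropout from
#'   interviews (deaths remain ascertained)
#' @return list of class `cohort_config`
#' @export
cohort_config <- function(n = 5131, seed = 1,
                          wave_months = c(0, 36, 84, 132, 180),
                          baseline_age_probs =
                            c(602, 817, 675, 921, 1046, 1070) / 5131,
                          p_male = 0.5296, p_hypertension = 0.2468,
                          p_diabetes = 0.1059, p_baseline_disabled = 0.10,
                          truth = default_truth(),
                          p_missed_wave = 0.10, p_dropout_per_wave = 0.05) {
  probs <- c(p_male, p_hypertension, p_diabetes, p_baseline_disabled,
             p_missed_wave, p_dropout_per_wave, baseline_age_probs)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(baseline_age_probs) - 1) > 1e-8 ||
      length(baseline_age_probs) != 6L) {
    stop("baseline_age_probs must be 6 probabilities summing to 1",
         call. = FALSE)
  }
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (is.unsorted(wave_months, strictly = TRUE) || wave_months[1] != 0) {
    stop("wave_months must be strictly increasing and start at 0",
         call. = FALSE)
  }
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 wave_months = as.integer(wave_months),
                 baseline_age_probs = baseline_age_probs,
                 p_male = p_male, p_hypertension = p_hypertension,
                 p_diabetes = p_diabetes,
                 p_baseline_disabled = p_baseline_disabled,
                 truth = model_params(unclass(truth)),
                 p_missed_wave = p_missed_wave,
                 p_dropout_per_wave = p_dropout_per_wave),
            class = "cohort_config")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Vectorized monthly etas for all four transitions at subject-specific ages.
etas_at <- function(truth, age_years, sex, hyp, diab) {
  b <- unclass(truth)
  lapply(TRANSITIONS, function(tr) {
    b[tr, "intercept"] + b[tr, "age"] * age_years + b[tr, "sex"] * sex +
      b[tr, "hyp"] * hyp + b[tr, "diab"] * diab
  }) |> setNames(TRANSITIONS)
}

# One vectorized elementary step: current states (0/1/2), returns next states.
step_states <- function(truth, states, age_years, sex, hyp, diab, u) {
  nxt <- states
  live0 <- which(states == 0L)
  live1 <- which(states == 1L)
  eta <- etas_at(truth, age_years, sex, hyp, diab)
  if (length(live0)) {
    m <- pmax(0, eta[["01"]][live0], eta[["02"]][live0])
    w_stay <- exp(-m)
    w1 <- exp(eta[["01"]][live0] - m)
    w2 <- exp(eta[["02"]][live0] - m)
    d <- w_stay + w1 + w2
    p1 <- w1 / d; p2 <- w2 / d
    uu <- u[live0]
    nxt[live0] <- ifelse(uu < p1, 1L, ifelse(uu < p1 + p2, 2L, 0L))
  }
  if (length(live1)) {
    m <- pmax(0, eta[["10"]][live1], eta[["12"]][live1])
    w_stay <- exp(-m)
    w0 <- exp(eta[["10"]][live1] - m)
    w2 <- exp(eta[["12"]][live1] - m)
    d <- w_stay + w0 + w2
    p0 <- w0 / d; p2 <- w2 / d
    uu <- u[live1]
    nxt[live1] <- ifelse(uu < p0, 0L, ifelse(uu < p0 + p2, 2L, 1L))
  }
  nxt
}

#' Simulate an interval-censored panel cohort
#'
#' Draws covariates and baseline ages, simulates each subject's latent monthly
#' three-state chain from `config$truth`, and observes it through the wave
#' schedule: the baseline interview is always recorded; later waves are
#' missed (state 9) with `p_missed_wave` or dropped permanently with
#' `p_dropout_per_wave`; death months within the study window are always
#' recorded exactly. Deterministic given the config (including its seed).
#'
#' @param config a [cohort_config()]
#' @param keep_history if `TRUE`, attach the latent monthly state matrix
#'   (subjects x months 0..last wave) and baseline age in months as
#'   attributes `history` / `age_months0` — used by calibration tests
#' @return list with `dataset` (a `panel_dataset`), `truth` (the generating
#'   `model_params`) and `config`
#' @export
simulate_cohort <- function(config, keep_history = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n <- config$n
    sex <- rbinom(n, 1, config$p_male)
    hyp <- rbinom(n, 1, config$p_hypertension)
    diab <- rbinom(n, 1, config$p_diabetes)
    bin <- sample.int(6L, n, replace = TRUE, prob = config$baseline_age_probs)
    bin_lo <- c(50L, 55L, 60L, 65L, 70L, 75L) * 12L
    bin_w <- c(60L, 60L, 60L, 60L, 60L, 180L)  # 75+ spread over 75-90
    age0 <- bin_lo[bin] + as.integer(floor(runif(n) * bin_w[bin]))
    birth <- BASELINE_MONTH - age0
    state <- rbinom(n, 1, config$p_baseline_disabled)
    last_off <- config$wave_months[length(config$wave_months)]

    # latent chain; keep the state at every wave month
    K <- length(config$wave_months)
    death_month <- rep(NA_integer_, n)
    wave_state <- matrix(NA_integer_, n, K)
    wave_state[, 1L] <- state
    hist <- if (keep_history) matrix(NA_integer_, n, last_off + 1L)
    if (keep_history) hist[, 1L] <- state
    for (m in seq_len(last_off)) {
      u <- runif(n)
      nxt <- step_states(config$truth, state, (age0 + m - 1L) / 12,
                         sex, hyp, diab, u)
      died <- which(state != 2L & nxt == 2L)
      death_month[died] <- BASELINE_MONTH + m
      state <- nxt
      w <- match(m, config$wave_months)
      if (!is.na(w)) wave_state[, w] <- state
      if (keep_history) hist[, m + 1L] <- state
    }

    # observation process
    miss <- matrix(runif(n * K) < config$p_missed_wave, n, K)
    miss[, 1L] <- FALSE
    drop_draw <- matrix(runif(n * K) < config$p_dropout_per_wave, n, K)
    drop_draw[, 1L] <- FALSE
    dropped_from <- apply(drop_draw, 1L, function(r) {
      w <- which(r)
      if (length(w)) w[1] else K + 1L
    })

    ids <- sprintf("S%05d", seq_len(n))
    weight <- round(exp(rnorm(n, 0, 0.25)), 4)
    obs <- vector("list", n)
    for (i in seq_len(n)) {
      months <- integer(0); states <- integer(0)
      for (w in seq_len(K)) {
        mw <- BASELINE_MONTH + config$wave_months[w]
        if (w >= dropped_from[i]) break
        if (!is.na(death_month[i]) && death_month[i] <= mw) break
        months <- c(months, mw)
        states <- c(states,
                    if (miss[i, w]) STATE_MISSING else wave_state[i, w])
      }
      if (length(months)) {
        obs[[i]] <- data.frame(id = ids[i], month = months, state = states,
                               stringsAsFactors = FALSE)
      }
    }
    subjects <- data.frame(id = ids, weight = weight, birth = birth,
                           death = death_month, sex = sex, hyp = hyp,
                           diab = diab, stringsAsFactors = FALSE)
    ds <- panel_dataset(subjects, do.call(rbind, obs[!vapply(obs, is.null,
                                                             TRUE)]),
                        wave_labels = paste0("wave", seq_len(K)),
                        window = BASELINE_MONTH + last_off)
    if (keep_history) {
      attr(ds, "history") <- hist
      attr(ds, "age_months0") <- age0
    }
    list(dataset = ds, truth = config$truth, config = config)
  })
}

#' Simulate monthly trajectories at fixed age and profile
#'
#' Direct Monte-Carlo of the latent chain for `n` subjects who share one
#' starting age, state and covariate profile; the sojourn accountancy matches
#' the life-table convention (state counted at the end of each completed
#' month, truncation at `truncation_age`). Used as the independent simulation
#' oracle for [state_expectancies()].
#'
#' @param params a `model_params`
#' @param profile covariate profile
#' @param start_age starting age in years
#' @param n number of trajectories
#' @param start_state 0 or 1
#' @param truncation_age closure age
#' @param seed RNG seed
#' @return data.frame with per-trajectory `years0`, `years1` (sojourn years in
#'   each live state)
#' @export
simulate_trajectories <- function(params, profile, start_age, n,
                                  start_state = 0L,
                                  truncation_age = OMEGA_DEFAULT, seed = 1) {
  p <- as_profile(profile)
  M <- round((truncation_age - start_age) * 12)
  with_seed(seed, {
    state <- rep(as.integer(start_state), n)
    cnt0 <- integer(n); cnt1 <- integer(n)
    sex <- rep(p[["sex"]], n); hy <- rep(p[["hyp"]], n)
    db <- rep(p[["diab"]], n)
    for (m in seq_len(M)) {
      state <- step_states(params, state, start_age + (m - 1) / 12,
                           sex, hy, db, runif(n))
      cnt0 <- cnt0 + (state == 0L)
      cnt1 <- cnt1 + (state == 1L)
      if (all(state == 2L)) break
    }
    data.frame(years0 = cnt0 / 12, years1 = cnt1 / 12)
  })
}

#' Write the simulation-truth sidecar
#'
#' JSON record of the generating parameters and full generator configuration,
#' written next to a simulated panel so recovery tests are self-contained.
#'
#' @param sim output of [simulate_cohort()]
#' @param path output path
#' @return invisibly `path`
#' @export
write_truth_sidecar <- function(sim, path) {
  cfg <- sim$config
  payload <- list(
    truth = as.list(params_to_vector(sim$truth)),
    config = list(n = cfg$n, seed = cfg$seed, wave_months = cfg$wave_months,
                  baseline_age_probs = cfg$baseline_age_probs,
                  p_male = cfg$p_male, p_hypertension = cfg$p_hypertension,
                  p_diabetes = cfg$p_diabetes,
                  p_baseline_disabled = cfg$p_baseline_disabled,
                  p_missed_wave = cfg$p_missed_wave,
                  p_dropout_per_wave = cfg$p_dropout_per_wave))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
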
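# Shared fixtures and independent oracles.

# Named length-20 parameter vector -> model_params, zeros elsewhere.
make_params <- function(...) {
  v <- setNames(rep(0, 20), names(params_to_vector(default_truth())))
  upd <- c(...)
  stopifnot(all(names(upd) %in% names(v)))
  v[names(upd)] <- upd
  model_params(v)
}

# Random coefficient draw on a scale where monthly probabilities stay sane:
# intercepts around -4, mild slopes.
random_params <- function() {
  v <- params_to_vector(default_truth())
  v[] <- 0
  v[grepl("^alpha", names(v))] <- runif(4, -6, -2)
  v[grepl("^beta1", names(v))] <- runif(4, -0.03, 0.03)
  v[grepl("^beta[234]", names(v))] <- runif(12, -0.5, 0.5)
  model_params(v)
}

# Two-subject toy dataset: A alive throughout, B dies.
toy_dataset <- function() {
  subjects <- data.frame(
    id = c("A", "B"), weight = c(1, 1.5),
    birth = parse_month(c("06/1940", "01/1935")),
    death = c(NA, parse_month("05/2000")),
    sex = c(1L, 0L), hyp = c(0L, 1L), diab = c(0L, 0L),
    stringsAsFactors = FALSE)
  obs <- data.frame(
    id = c("A", "A", "B"),
    month = c(parse_month("03/1996"), parse_month("03/1999"),
              parse_month("03/1996")),
    state = c(0L, 1L, 0L))
  panel_dataset(subjects, obs)
}

# Brute-force interval transition probability by exhaustive enumeration of
# the latent monthly state sequence (independent of interval_matrix).
# endpoint: "state" (land in s1, cumulative for s1 = 2), "exact_death"
# (alive through the penultimate month, die in the last one), or "alive"
# (any live state at the end).
enum_interval_prob <- function(params, start_month, end_month, birth,
                               profile, s0, s1 = NULL,
                               endpoint = "state") {
  gap <- end_month - start_month
  steps <- lapply(seq_len(gap), function(g) {
    step_transition_matrix(params, (start_month + g - 1 - birth) / 12, profile)
  })
  finals <- switch(endpoint,
                   state = s1,
                   exact_death = 2L,
                   alive = c(0L, 1L))
  mid_states <- if (endpoint == "exact_death") 0:1 else 0:2
  total <- 0
  mids <- if (gap == 1L) {
    matrix(integer(0), nrow = 1, ncol = 0)
  } else {
    as.matrix(expand.grid(rep(list(mid_states), gap - 1L)))
  }
  for (r in seq_len(nrow(mids))) {
    inner <- as.integer(mids[r, ])
    for (sf in finals) {
      path <- c(s0, inner, sf)
      p <- 1
      for (g in seq_len(gap)) {
        p <- p * steps[[g]][path[g] + 1L, path[g + 1L] + 1L]
      }
      total <- total + p
    }
  }
  total
}

# Matrix power by squaring (oracle for age-constant interval products).
mat_pow <- function(M, n) {
  R <- diag(nrow(M))
  while (n > 0) {
    if (n %% 2 == 1) R <- R %*% M
    M <- M %*% M
    n <- n %/% 2
  }
  R
}
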
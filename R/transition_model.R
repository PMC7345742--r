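# Polychotomous logistic transition model over the three states
# 0 = healthy, 1 = ADL-disabled, 2 = dead (absorbing).
#
# For a live origin state j, the log-odds of moving to k != j relative to
# staying in j over one elementary step (one month) are linear in age and the
# binary covariates:
#
#   ln P_jk / P_jj = alpha_jk + b1_jk * age + b2_jk * sex
#                            + b3_jk * hyp + b4_jk * diab
#
# which inverts to a softmax over {stay, destinations}. Four live transitions
# are parameterized: 0->1 (onset), 0->2, 1->0 (recovery), 1->2; 20
# coefficients in all.

TRANSITIONS <- c("01", "02", "10", "12")
TERMS <- c("intercept", "age", "sex", "hyp", "diab")

#' Transition model parameters
#'
#' Container for the 20 coefficients: for each live transition 0->1, 0->2,
#' 1->0, 1->2 an intercept plus slopes on age (per year), sex (1 = male),
#' hypertension and diabetes. Accepts a 4x5 matrix (rows in transition order,
#' columns intercept/age/sex/hyp/diab) or a named length-20 vector with names
#' like `alpha_01`, `beta1_01` (age), `beta2_01` (sex), `beta3_01` (hyp),
#' `beta4_01` (diab).
#'
#' @param x 4x5 numeric matrix or named length-20 vector
#' @return object of class `model_params` (a 4x5 matrix with dimnames)
#' @export
model_params <- function(x) {
  if (is.matrix(x)) {
    stopifnot(identical(dim(x), c(4L, 5L)))
    m <- x
  } else if (is.numeric(x) && length(x) == 20L) {
    if (!is.null(names(x))) {
      m <- matrix(NA_real_, 4, 5)
      key <- outer(c("alpha", "beta1", "beta2", "beta3", "beta4"),
                   TRANSITIONS, function(a, t) paste0(a, "_", t))
      # key is 5x4 (terms x transitions); fill transposed
      for (ti in 1:4) for (ci in 1:5) m[ti, ci] <- x[[key[ci, ti]]]
    } else {
      m <- matrix(x, 4, 5, byrow = TRUE)
    }
  } else {
    stop("x must be a 4x5 matrix or a numeric vector of length 20",
         call. = FALSE)
  }
  if (any(!is.finite(m))) stop("all 20 coefficients must be finite",
                               call. = FALSE)
  dimnames(m) <- list(TRANSITIONS, TERMS)
  class(m) <- c("model_params", "matrix")
  m
}

#' @export
print.model_params <- function(x, digits = 4, ...) {
  cat("model_params (monthly multinomial-logit transition coefficients):\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Flatten parameters to the canonical length-20 vector
#'
#' Order: transitions 0->1, 0->2, 1->0, 1->2; within each,
#' intercept, age, sex, hyp, diab. Names are `alpha_jk`, `beta1_jk`, ...,
#' `beta4_jk`.
#'
#' @param params a `model_params`
#' @return named numeric vector of length 20
#' @export
params_to_vector <- function(params) {
  params <- model_params(unclass(params))
  v <- as.vector(t(unclass(params)))
  names(v) <- as.vector(vapply(TRANSITIONS, function(t) {
    paste0(c("alpha", "beta1", "beta2", "beta3", "beta4"), "_", t)
  }, character(5)))
  v
}

#' Write / read parameters as flat key=value text
#'
#' One `name=value` line per coefficient (`alpha_01=...`), full double
#' precision, round-trippable.
#'
#' @param params a `model_params`
#' @param path file path
#' @return `write_params`: invisibly `path`; `read_params`: a `model_params`
#' @export
write_params <- function(params, path) {
  v <- params_to_vector(params)
  writeLines(sprintf("%s=%s", names(v), formatC(v, format = "g", digits = 17)),
             path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("unparsable parameter line(s): ",
                     paste(lines[bad], collapse = "; "), call. = FALSE)
  v <- setNames(as.numeric(vapply(kv, `[`, "", 2L)),
                trimws(vapply(kv, `[`, "", 1L)))
  model_params(v)
}

#' Covariate profile
#'
#' @param sex 1 = male, 0 = female
#' @param hyp 1 = hypertension
#' @param diab 1 = diabetes
#' @return named 0/1 vector
#' @export
new_profile <- function(sex, hyp, diab) {
  v <- c(sex = sex, hyp = hyp, diab = diab)
  if (any(!v %in% c(0, 1))) stop("profile entries must be 0 or 1",
                                 call. = FALSE)
  storage.mode(v) <- "double"
  v
}

#' All eight covariate profiles
#'
#' @return data.frame with columns sex, hyp, diab (2 x 2 x 2 grid) and a
#'   human-readable `label`
#' @export
covariate_profiles <- function() {
  g <- expand.grid(diab = 0:1, hyp = 0:1, sex = 1:0)[, c("sex", "hyp", "diab")]
  g$label <- paste0(ifelse(g$sex == 1, "male", "female"),
                    ifelse(g$hyp == 1, "/hyp", "/no-hyp"),
                    ifelse(g$diab == 1, "/diab", "/no-diab"))
  rownames(g) <- NULL
  g
}

as_profile <- function(profile) {
  if (is.list(profile) || is.data.frame(profile)) {
    profile <- c(sex = profile$sex, hyp = profile$hyp, diab = profile$diab)
  }
  new_profile(profile[["sex"]], profile[["hyp"]], profile[["diab"]])
}

#' Linear predictor of one transition equation
#'
#' eta_jk = alpha_jk + beta1_jk * age + beta2_jk * sex + beta3_jk * hyp +
#' beta4_jk * diab, for a live origin j and destination k != j. Age is in
#' years (fractional ages are meaningful: the elementary step is one month).
#'
#' @param params a `model_params`
#' @param j origin state, 0 or 1
#' @param k destination state in \{0,1,2\}, k != j
#' @param age age in years
#' @param profile covariate profile (see [new_profile()])
#' @return numeric linear predictor
#' @export
linear_predictor <- function(params, j, k, age, profile) {
  if (j == 2) stop("state 2 (dead) is absorbing: no transition equations",
                   call. = FALSE)
  if (!j %in% c(0, 1) || !k %in% c(0, 1, 2) || k == j) {
    stop("invalid transition (", j, ",", k, ")", call. = FALSE)
  }
  p <- as_profile(profile)
  b <- unclass(params)[paste0(j, k), ]
  unname(b["intercept"] + b["age"] * age +
           b["sex"] * p["sex"] + b["hyp"] * p["hyp"] + b["diab"] * p["diab"])
}

# Softmax over {stay, dest1, dest2} with log-sum-exp stabilization;
# the stay category has logit 0.
softmax_row <- function(eta1, eta2) {
  m <- max(0, eta1, eta2)
  w <- exp(c(0, eta1, eta2) - m)
  w / sum(w)
}

#' One-month transition matrix
#'
#' Row-stochastic 3x3 matrix of one-elementary-step (one month) transition
#' probabilities at a given exact age and covariate profile. Live rows come
#' from the multinomial-logit inversion `P_jk = exp(eta_jk) / (1 + sum_k'
#' exp(eta_jk'))` computed with log-sum-exp stabilization; the dead row is
#' exactly (0, 0, 1).
#'
#' @inheritParams linear_predictor
#' @return 3x3 matrix, rows/cols named "0","1","2"; attributes `age` and
#'   `step_h` (years, fixed 1/12)
#' @export
step_transition_matrix <- function(params, age, profile) {
  p <- as_profile(profile)
  b <- unclass(params)
  eta <- b[, "intercept"] + b[, "age"] * age +
    b[, "sex"] * p[["sex"]] + b[, "hyp"] * p[["hyp"]] + b[, "diab"] * p[["diab"]]
  if (any(!is.finite(eta))) {
    stop("non-finite linear predictor for transition(s) ",
         paste(TRANSITIONS[!is.finite(eta)], collapse = ", "), call. = FALSE)
  }
  r0 <- softmax_row(eta[["01"]], eta[["02"]])  # (stay0, to1, to2)
  r1 <- softmax_row(eta[["10"]], eta[["12"]])  # (stay1, to0, to2)
  P <- rbind(c(r0[1], r0[2], r0[3]),
             c(r1[2], r1[1], r1[3]),
             c(0, 0, 1))
  dimnames(P) <- list(c("0", "1", "2"), c("0", "1", "2"))
  attr(P, "age") <- age
  attr(P, "step_h") <- 1 / 12
  P
}

#' Multi-month transition matrix between two calendar months
#'
#' Ordered product of one-month matrices over `[start_month, end_month)`; the
#' factor for calendar month m is evaluated at the subject's exact age
#' `(m - birth) / 12` years. This is the interpolated-Markov-chain bridge
#' between sparse interview dates.
#'
#' @param params a `model_params`
#' @param start_month,end_month absolute month indices, `end_month >
#'   start_month`
#' @param birth subject's birth as an absolute month index
#' @param profile covariate profile
#' @return 3x3 row-stochastic matrix
#' @export
interval_matrix <- function(params, start_month, end_month, birth, profile) {
  if (end_month <= start_month) {
    stop("end_month must be strictly after start_month", call. = FALSE)
  }
  P <- diag(3)
  for (m in seq.int(start_month, end_month - 1L)) {
    P <- P %*% step_transition_matrix(params, (m - birth) / 12, profile)
  }
  dimnames(P) <- list(c("0", "1", "2"), c("0", "1", "2"))
  P
}
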
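# Maximum-likelihood fitting.
#
# Optimization runs on a centered-age parameterization: inside each transition
# block the predictor is rewritten as a' + b1' * (age - 75) / 10 + ..., i.e.
# a' = alpha + 75 * beta1 and b1' = 10 * beta1. Raw-age intercepts sit 50-110
# predictor units away from the data and condition quasi-Newton steps badly;
# the centered scale puts all coordinates on comparable footing. Reported
# coefficients are always back-transformed to the per-year scale.

AGE_CENTER <- 75
AGE_SCALE <- 10

scale_theta <- function(theta) {
  for (t in 0:3) {
    a <- 5 * t + 1
    theta[a] <- theta[a] + AGE_CENTER * theta[a + 1]
    theta[a + 1] <- AGE_SCALE * theta[a + 1]
  }
  theta
}

unscale_theta <- function(theta_s) {
  for (t in 0:3) {
    a <- 5 * t + 1
    theta_s[a + 1] <- theta_s[a + 1] / AGE_SCALE
    theta_s[a] <- theta_s[a] - AGE_CENTER * theta_s[a + 1]
  }
  theta_s
}

# Jacobian d(theta_year) / d(theta_scaled): block diagonal, per block
# alpha = a' - 7.5 b1', beta1 = b1'/10, rest identity.
unscale_jacobian <- function() {
  J <- diag(20)
  for (t in 0:3) {
    a <- 5 * t + 1
    J[a, a + 1] <- -AGE_CENTER / AGE_SCALE
    J[a + 1, a + 1] <- 1 / AGE_SCALE
  }
  J
}

#' Optimizer settings for [fit()]
#'
#' @param maxit iteration cap per BFGS run
#' @param reltol relative log-likelihood convergence tolerance
#' @param grad_tol max-norm tolerance for the numerical gradient on the
#'   scaled parameterization; convergence requires both criteria
#' @param ndeps central-difference step on the scaled parameters
#' @param max_restarts cap on damped Newton polish steps after BFGS if the
#'   gradient criterion is not yet met
#' @param gradient `"analytic"` (exact forward-sensitivity gradient from the
#'   compiled kernel, default) or `"numerical"` (central differences, step
#'   `ndeps`); the two agree to ~1e-6 and the numerical route is kept as an
#'   independent check
#' @return list of class `fit_options`
#' @export
fit_options <- function(maxit = 500L, reltol = 1e-8, grad_tol = 1e-4,
                        ndeps = 1e-5, max_restarts = 3L,
                        gradient = c("analytic", "numerical")) {
  structure(list(maxit = as.integer(maxit), reltol = reltol,
                 grad_tol = grad_tol, ndeps = ndeps,
                 max_restarts = as.integer(max_restarts),
                 gradient = match.arg(gradient)),
            class = "fit_options")
}

default_init <- function() {
  m <- matrix(0, 4, 5)
  m[, 1] <- -4  # monthly transition probability ~ 1.8%: a stable basin
  model_params(m)
}

num_gradient <- function(fn, x, h) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (fn(x + e) - fn(x - e)) / (2 * h)
  }, 0)
}

# Which of the four transition types have at least one directly observed
# endpoint pair (s0, s1)?
observed_transition_types <- function(tab) {
  have <- function(s0, s1) any(tab[, "s0"] == s0 & tab[, "s1"] == s1)
  c("01" = have(0L, 1L), "02" = have(0L, 2L),
    "10" = have(1L, 0L), "12" = have(1L, 2L))
}

#' Fit the transition model by maximum likelihood
#'
#' Quasi-Newton (BFGS) maximization of the interval-censored log-likelihood
#' with central-difference numerical gradients on the centered-age scale.
#' Deterministic given the dataset, initial values and settings.
#'
#' If a transition type has no directly observed endpoint pair its five
#' coefficients are weakly identified; they are then held at the initial
#' values (intercept bounded at the default -4, slopes 0) and a warning
#' `no_observed_transition(j,k)` is attached.
#'
#' @param dataset a `panel_dataset`
#' @param init initial `model_params`, or `NULL` for the default (all slopes
#'   0, intercepts -4)
#' @param options a [fit_options()]
#' @param lik_options a [likelihood_options()]
#' @return object of class `hlemc_fit`: `params_hat`, `loglik`, `converged`,
#'   `n_iterations`, `gradient_norm`, `standard_errors` (named length-20
#'   vector or `NULL`), `vcov` (per-year scale, or `NULL`), `warnings`,
#'   `loglik_init`, `n_pairs`
#' @export
fit <- function(dataset, init = NULL, options = fit_options(),
                lik_options = likelihood_options()) {
  stopifnot(inherits(dataset, "panel_dataset"))
  tab <- build_pair_table(dataset, lik_options)
  if (!nrow(tab)) stop("dataset has no usable observation pairs",
                       call. = FALSE)
  pairs <- tab[, 1:7, drop = FALSE]
  if (is.null(init)) init <- default_init()
  init <- model_params(unclass(init))

  warnings <- character(0)
  obs_types <- observed_transition_types(tab)
  free <- rep(TRUE, 20)
  for (t in seq_along(TRANSITIONS)) {
    if (!obs_types[t]) {
      jk <- TRANSITIONS[t]
      warnings <- c(warnings, sprintf("no_observed_transition(%s,%s)",
                                      substr(jk, 1, 1), substr(jk, 2, 2)))
      free[(5 * (t - 1) + 1):(5 * t)] <- FALSE
    }
  }

  theta0 <- unname(params_to_vector(init))
  theta0_s <- scale_theta(theta0)
  full_s <- theta0_s

  negll_free <- function(x) {
    full_s[free] <- x
    -cpp_dataset_loglik(unscale_theta(full_s), pairs)
  }
  # gradient of -loglik wrt the scaled free coordinates; chain rule through
  # the unscale map (J = d theta_year / d theta_scaled)
  Jt <- t(unscale_jacobian())
  grad_free <- if (options$gradient == "analytic") {
    function(x) {
      full_s[free] <- x
      lg <- cpp_dataset_loglik_grad(unscale_theta(full_s), pairs)
      drop(Jt %*% (-lg$gradient))[free]
    }
  } else {
    function(x) num_gradient(negll_free, x, options$ndeps)
  }

  f0 <- negll_free(theta0_s[free])
  if (!is.finite(f0)) {
    stop("log-likelihood is not finite at the initial values", call. = FALSE)
  }

  ctrl <- list(maxit = options$maxit, reltol = options$reltol)
  cur <- theta0_s[free]
  opt <- optim(cur, negll_free, gr = grad_free, method = "BFGS",
               control = ctrl)
  n_iterations <- opt$counts[["function"]]
  cur <- opt$par
  fcur <- opt$value

  # BFGS stops on relative change in f; polish with damped (Levenberg-style)
  # Newton steps on the numerical Hessian until the gradient max-norm
  # criterion is met too, falling back to a tighter BFGS restart when a
  # near-singular Hessian blocks progress.
  H <- NULL
  h_at_cur <- FALSE
  hstep <- if (options$gradient == "analytic") 1e-5 else 1e-4
  g <- grad_free(cur)
  for (polish in seq_len(options$max_restarts + 7L)) {
    if (max(abs(g)) <= options$grad_tol) break
    H <- optimHess(cur, negll_free, gr = grad_free,
                   control = list(ndeps = rep(hstep, sum(free))))
    h_at_cur <- TRUE
    scale_h <- max(abs(diag(H)), 1)
    moved <- FALSE
    for (ridge in c(0, 1e-8, 1e-5, 1e-2) * scale_h) {
      step <- tryCatch(solve(H + diag(ridge, nrow(H)), g),
                       error = function(e) NULL)
      if (is.null(step)) next
      lam <- 1
      while (lam >= 1e-6) {
        fnew <- negll_free(cur - lam * step)
        if (is.finite(fnew) && fnew < fcur - 1e-10) {
          cur <- cur - lam * step
          fcur <- fnew
          moved <- TRUE
          break
        }
        lam <- lam / 2
      }
      if (moved) break
    }
    if (!moved) {
      # Newton blocked: restart BFGS from the incumbent with a tighter
      # function tolerance
      ctrl$reltol <- max(ctrl$reltol / 100, 1e-15)
      opt2 <- optim(cur, negll_free, gr = grad_free, method = "BFGS",
                    control = ctrl)
      n_iterations <- n_iterations + opt2$counts[["function"]]
      if (opt2$value > fcur - 1e-12) {
        g <- grad_free(cur)
        break  # no progress either way: report honestly
      }
      cur <- opt2$par
      fcur <- opt2$value
    }
    h_at_cur <- FALSE
    n_iterations <- n_iterations + 1L
    g <- grad_free(cur)
  }
  gradient_norm <- max(abs(g))
  converged <- opt$convergence == 0L && gradient_norm <= options$grad_tol
  if (!converged) {
    warnings <- c(warnings, sprintf(
      "not_converged: optim code %d, gradient max-norm %.3g",
      opt$convergence, gradient_norm))
  }

  full_s[free] <- cur
  theta_hat <- unscale_theta(full_s)
  params_hat <- model_params(setNames(theta_hat,
                                      names(params_to_vector(init))))
  loglik <- -fcur
  if (loglik < -f0 - 1e-8) {
    warnings <- c(warnings, "loglik_below_init")  # should never happen
  }

  # standard errors from the observed information at the optimum; reuse the
  # last polish Hessian when it was computed at `cur`
  if (is.null(H) || !h_at_cur) {
    H <- optimHess(cur, negll_free, gr = grad_free,
                   control = list(ndeps = rep(hstep, sum(free))))
  }
  se <- vcov_year <- NULL
  ch <- tryCatch(chol(H), error = function(e) NULL)
  if (is.null(ch)) {
    warnings <- c(warnings,
                  "observed information not positive definite; no standard errors")
  } else {
    cov_s <- matrix(0, 20, 20)
    cov_s[free, free] <- chol2inv(ch)
    J <- unscale_jacobian()
    vcov_year <- J %*% cov_s %*% t(J)
    nms <- names(params_to_vector(init))
    dimnames(vcov_year) <- list(nms, nms)
    se <- setNames(sqrt(pmax(diag(vcov_year), 0)), nms)
    se[!free] <- NA_real_
  }

  structure(list(params_hat = params_hat, loglik = loglik,
                 converged = converged, n_iterations = n_iterations,
                 gradient_norm = gradient_norm,
                 standard_errors = se, vcov = vcov_year,
                 warnings = warnings, loglik_init = -f0,
                 n_pairs = nrow(pairs), free = free),
            class = "hlemc_fit")
}

#' @export
print.hlemc_fit <- function(x, ...) {
  cat(sprintf("hlemc_fit: loglik %.4f over %d pairs; %s (grad max-norm %.2g)\n",
              x$loglik, x$n_pairs,
              if (x$converged) "converged" else "NOT converged",
              x$gradient_norm))
  v <- params_to_vector(x$params_hat)
  tab <- data.frame(estimate = round(v, 5))
  if (!is.null(x$standard_errors)) tab$se <- round(x$standard_errors, 5)
  print(tab)
  if (length(x$warnings)) cat("warnings:", paste(x$warnings, collapse = "; "),
                              "\n")
  invisible(x)
}

# SEs from a numerical Hessian of the negative log-likelihood; seam shared
# with fit() and testable with an injected quadratic objective.
se_from_negloglik <- function(negll, par_scaled, free = rep(TRUE, 20),
                              hess_step = 1e-4) {
  H <- optimHess(par_scaled[free], function(x) {
    full <- par_scaled; full[free] <- x
    negll(full)
  }, control = list(ndeps = rep(hess_step, sum(free))))
  ch <- tryCatch(chol(H), error = function(e) NULL)
  if (is.null(ch)) {
    warning("observed information not positive definite; no standard errors",
            call. = FALSE)
    return(NULL)
  }
  cov_free <- chol2inv(ch)
  cov_s <- matrix(0, length(par_scaled), length(par_scaled))
  cov_s[free, free] <- cov_free
  J <- unscale_jacobian()
  vcov_year <- J %*% cov_s %*% t(J)
  list(se = sqrt(pmax(diag(vcov_year), 0)), vcov = vcov_year)
}

#' Standard errors from the observed information
#'
#' Square roots of the diagonal of the inverse numerical Hessian of the
#' negative log-likelihood at `params_hat` (computed on the centered-age
#' scale and mapped back to the per-year scale by the delta method). Returns
#' `NULL` with a warning if the Hessian is not positive definite (e.g. a
#' covariate column without variation).
#'
#' @param dataset a `panel_dataset`
#' @param params_hat fitted `model_params`
#' @param free logical length-20 mask of coefficients that were optimized
#' @param lik_options a [likelihood_options()]
#' @return list with `se` (named length-20 vector; fixed coefficients get
#'   `NA`) and `vcov` (20x20 per-year covariance); or `NULL` with a warning
#' @export
observed_information_se <- function(dataset, params_hat,
                                    free = rep(TRUE, 20),
                                    lik_options = likelihood_options()) {
  tab <- build_pair_table(dataset, lik_options)
  pairs <- tab[, 1:7, drop = FALSE]
  negll <- function(theta_s) -cpp_dataset_loglik(unscale_theta(theta_s), pairs)
  par_s <- scale_theta(unname(params_to_vector(params_hat)))
  out <- se_from_negloglik(negll, par_s, free = free)
  if (is.null(out)) return(NULL)
  nms <- names(params_to_vector(params_hat))
  se <- setNames(out$se, nms)
  se[!free] <- NA_real_
  dimnames(out$vcov) <- list(nms, nms)
  list(se = se, vcov = out$vcov)
}

#' Write / read a fit result as JSON
#'
#' The JSON sidecar carries the full `hlemc_fit` payload; a plain-text
#' coefficient table can be written alongside by [format_fit_table()].
#'
#' @param fit_result an `hlemc_fit`
#' @param path output path
#' @return `write_fit`: invisibly `path`; `read_fit`: an `hlemc_fit`
#' @export
write_fit <- function(fit_result, path) {
  x <- fit_result
  payload <- list(
    params_hat = as.list(params_to_vector(x$params_hat)),
    loglik = x$loglik, converged = x$converged,
    n_iterations = x$n_iterations, gradient_norm = x$gradient_norm,
    standard_errors = if (is.null(x$standard_errors)) NULL else
      as.list(x$standard_errors),
    warnings = x$warnings, loglik_init = x$loglik_init, n_pairs = x$n_pairs)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  se <- NULL
  if (!is.null(p$standard_errors)) {
    se <- unlist(p$standard_errors)
    storage.mode(se) <- "double"
  }
  structure(list(params_hat = model_params(unlist(p$params_hat)),
                 loglik = p$loglik, converged = p$converged,
                 n_iterations = p$n_iterations,
                 gradient_norm = p$gradient_norm,
                 standard_errors = se, vcov = NULL,
                 warnings = if (length(p$warnings)) unlist(p$warnings)
                            else character(0),
                 loglik_init = p$loglik_init, n_pairs = p$n_pairs),
            class = "hlemc_fit")
}

#' Coefficient table as text
#'
#' @param fit_result an `hlemc_fit`
#' @return character vector of lines
#' @export
format_fit_table <- function(fit_result) {
  v <- params_to_vector(fit_result$params_hat)
  se <- fit_result$standard_errors
  if (is.null(se)) se <- rep(NA_real_, 20)
  c(sprintf("%-12s %12s %12s", "coefficient", "estimate", "se"),
    sprintf("%-12s %12.6f %12.6f", names(v), v, se))
}
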
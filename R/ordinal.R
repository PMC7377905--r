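#' Build the design matrix for the ordinal confidence model
#'
#' Prepares per-trial predictors of the confidence report: contrast-coded
#' coherence (levels 1..4 coded -1.5/-0.5/0.5/1.5, then z-scored),
#' log-transformed choice reaction time (z-scored), a dummy variable for
#' each explicitly signalled context, and optional z-scored nuisance
#' predictors (choice, motion direction, marker start position). Hidden- or
#' missing-context trials receive all-zero context dummies; they anchor the
#' no-context baseline of the report scale. Without such trials the four
#' dummies sum to one on every row and are collinear with the ordered
#' thresholds, leaving the context weights identified only up to an additive
#' constant — [fit_ordinal_probit()] warns in that case.
#'
#' z-scoring parameters are taken from the fitting set and stored so they
#' can be re-applied unchanged to held-out (scan-session) trials.
#'
#' @param trials Tibble with columns `coherence_level` (1..4), `rt` (s),
#'   `report` (1..6), `context`, and optionally `choice`, `direction`,
#'   `marker_start`.
#' @param nuisance Character vector of nuisance columns to include (only
#'   those present in `trials` are used).
#' @param scaling `NULL` to compute z-scoring parameters from `trials`
#'   (fitting set), or the `scaling` element of a previous design/fit to
#'   re-apply.
#' @param drop_hidden Drop trials whose context is hidden/`NA` instead of
#'   keeping them as zero-dummy baseline rows (default `FALSE`).
#' @return A list of class `ordinal_design`: `X` (numeric matrix), `y`
#'   (integer reports, `NA`-free only if `trials$report` is), `scaling`,
#'   `context_cols`, `kept` (row indices of `trials` retained).
#' @export
ordinal_design <- function(trials,
                           nuisance = c("choice", "direction", "marker_start"),
                           scaling = NULL, drop_hidden = FALSE) {
  trials <- as_tibble(trials)
  need <- c("coherence_level", "rt")
  miss <- setdiff(need, names(trials))
  if (length(miss)) abort(paste0("`trials` lacks column(s): ",
                                 paste(miss, collapse = ", "), "."))
  if (any(trials$rt <= 0, na.rm = TRUE)) abort("`rt` must be positive.")
  hidden <- is.na(trials$context) | trials$context == "hidden"
  kept <- if (drop_hidden) which(!hidden) else seq_len(nrow(trials))
  tr <- trials[kept, ]
  hid <- hidden[kept]

  base <- list(
    coherence = as.numeric(tr$coherence_level) - 2.5,
    log_rt = log(tr$rt)
  )
  nuisance <- intersect(nuisance, names(trials))
  for (nm in nuisance) base[[nm]] <- as.numeric(tr[[nm]])

  if (is.null(scaling)) {
    scaling <- lapply(base, zscore_fit)
  }
  cols <- lapply(names(base), function(nm) {
    zs <- scaling[[nm]]
    if (is.null(zs)) abort(sprintf("scaling lacks parameters for `%s`.", nm))
    zscore_apply(base[[nm]], zs)
  })
  names(cols) <- names(base)
  X <- do.call(cbind, cols)

  ctx <- matrix(0, nrow(tr), length(PARTNER_LEVELS),
                dimnames = list(NULL, paste0("context_", PARTNER_LEVELS)))
  for (i in seq_along(PARTNER_LEVELS)) {
    ctx[!hid & tr$context == PARTNER_LEVELS[i], i] <- 1
  }
  X <- cbind(X, ctx)
  y <- if ("report" %in% names(tr)) as.integer(tr$report) else NULL
  structure(
    list(X = X, y = y, scaling = scaling,
         context_cols = colnames(ctx), kept = kept),
    class = "ordinal_design"
  )
}

# negative log-likelihood and analytic gradient of the cumulative probit
# model in the unconstrained parameterisation theta = (beta, tau1, log-gaps)
probit_nll <- function(theta, X, y, n_beta) {
  beta <- theta[seq_len(n_beta)]
  tau <- theta[n_beta + 1] + c(0, cumsum(exp(theta[(n_beta + 2):(n_beta + 5)])))
  eta <- drop(X %*% beta)
  taul <- c(-Inf, tau)[y]       # tau_{j-1}
  tauu <- c(tau, Inf)[y]        # tau_j
  P <- pnorm(tauu - eta) - pnorm(taul - eta)
  -sum(log(pmax(P, 1e-300)))
}

probit_grad <- function(theta, X, y, n_beta) {
  beta <- theta[seq_len(n_beta)]
  gaps <- exp(theta[(n_beta + 2):(n_beta + 5)])
  tau <- theta[n_beta + 1] + c(0, cumsum(gaps))
  eta <- drop(X %*% beta)
  taul <- c(-Inf, tau)[y]
  tauu <- c(tau, Inf)[y]
  a <- tauu - eta
  b <- taul - eta
  P <- pmax(pnorm(a) - pnorm(b), 1e-300)
  da <- dnorm(a)
  db <- dnorm(b)
  g_beta <- drop(crossprod(X, (da - db) / P))
  # accumulate d(-logL)/d tau_m : upper bound contributes -phi(a)/P at m = y,
  # lower bound +phi(b)/P at m = y - 1
  g_tau <- numeric(5)
  up <- rowsum((-da / P), y)            # grouped by y = 1..6
  lo <- rowsum((db / P), y)
  ylev <- as.integer(rownames(up))
  for (i in seq_along(ylev)) {
    j <- ylev[i]
    if (j <= 5) g_tau[j] <- g_tau[j] + up[i]
    if (j >= 2) g_tau[j - 1] <- g_tau[j - 1] + lo[i]
  }
  g_t1 <- sum(g_tau)
  g_g <- gaps * rev(cumsum(rev(g_tau)))[2:5]
  c(g_beta, g_t1, g_g)
}

#' Fit the cumulative probit model of confidence reports
#'
#' Maximum-likelihood cumulative ("ordered") probit regression,
#' \eqn{P(r \le j) = \Phi(\tau_j - X\beta)}, fitted by quasi-Newton (BFGS)
#' optimisation of the negative log-likelihood with analytic gradients.
#' Threshold ordering is guaranteed by reparameterising the gaps between
#' consecutive thresholds as exponentials, and a small multi-start (default
#' 3 starts: a closed-form null-model start plus jittered copies) guards
#' against local minima. Non-convergence and apparent separation (a
#' predictor perfectly ordering the reports, recognisable by diverging
#' weights) are flagged, never silently returned.
#'
#' @param design An `ordinal_design`, or a trials tibble (then passed to
#'   [ordinal_design()] with defaults).
#' @param n_starts Number of optimisation starts.
#' @param reltol Optimiser relative tolerance.
#' @param seed Seed for start jitter.
#' @return An object of class `ordinal_fit`: `beta` (named weights), `tau`
#'   (5 strictly increasing thresholds), `logLik`, `converged`, `separation`,
#'   `n`, `scaling`, `context_cols`, `levels_present`.
#' @export
fit_ordinal_probit <- function(design, n_starts = 3, reltol = 1e-10,
                               seed = 1L) {
  if (!inherits(design, "ordinal_design")) design <- ordinal_design(design)
  X <- design$X
  y <- design$y
  if (is.null(y)) abort("design carries no `report` response.")
  assert_reports(y, "report")
  if (length(unique(y)) < 2L) {
    abort("need >= 2 distinct report levels to fit the ordinal model.")
  }
  dup <- duplicated(t(X))
  if (any(dup)) {
    abort(paste0("collinear duplicate predictor column(s): ",
                 paste(colnames(X)[dup], collapse = ", "), "."))
  }
  ctx <- X[, design$context_cols, drop = FALSE]
  if (ncol(ctx) && all(rowSums(ctx) == 1)) {
    warn(paste0("every trial carries a signalled context: the context ",
                "weights are identified only up to a constant absorbed by ",
                "the thresholds; include hidden-context (baseline) trials."))
  }
  p <- ncol(X)
  # null-model start: thresholds from the marginal report CDF (smoothed so
  # empty categories stay finite), weights at zero
  cnt <- tabulate(y, 6L) + 0.5
  cum <- cumsum(cnt / sum(cnt))[1:5]
  tau0 <- qnorm(cum)
  theta0 <- c(rep(0, p), tau0[1], log(pmax(diff(tau0), 1e-3)))
  starts <- with_rng(seed, lapply(seq_len(n_starts), function(s) {
    if (s == 1) theta0 else theta0 + rnorm(length(theta0), sd = 0.3)
  }))
  fits <- lapply(starts, function(th) {
    stats::optim(th, fn = probit_nll, gr = probit_grad,
                 X = X, y = y, n_beta = p,
                 method = "BFGS",
                 control = list(maxit = 1000, reltol = reltol))
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  beta <- setNames(best$par[seq_len(p)], colnames(X))
  tau <- best$par[p + 1] + c(0, cumsum(exp(best$par[(p + 2):(p + 5)])))
  separation <- any(abs(beta) > 10)
  converged <- best$convergence == 0
  if (!converged) warn("ordinal probit fit did not converge; inspect `converged`.")
  if (separation) warn("possible separation: a weight diverged (|beta| > 10).")
  structure(
    list(beta = beta, tau = tau, logLik = -best$value,
         converged = converged, separation = separation,
         n = length(y), scaling = design$scaling,
         context_cols = design$context_cols,
         levels_present = sort(unique(y))),
    class = "ordinal_fit"
  )
}

#' Predicted report distribution for new trials
#'
#' Applies a fitted cumulative probit model to new trials, re-using the
#' fitting set's z-scoring parameters, and returns the probability of each
#' report 1..6 per trial: \eqn{P(r=j) = \Phi(\tau_j - X\beta) -
#' \Phi(\tau_{j-1} - X\beta)} with \eqn{\tau_0 = -\infty},
#' \eqn{\tau_6 = +\infty}.
#'
#' @param model An `ordinal_fit`.
#' @param trials New trials tibble (hidden-context trials get all-zero
#'   context dummies), or an `ordinal_design` built with the model's
#'   scaling.
#' @param zero_context Force the fitted context weights to zero before
#'   predicting (the counterfactual used by [private_confidence()]).
#' @return Matrix `n x 6` of probabilities, rows summing to 1.
#' @export
predict_report_distribution <- function(model, trials, zero_context = FALSE) {
  stopifnot(inherits(model, "ordinal_fit"))
  design <- if (inherits(trials, "ordinal_design")) trials
            else ordinal_design(trials, scaling = model$scaling,
                                drop_hidden = FALSE)
  X <- design$X
  if (!identical(colnames(X), names(model$beta))) {
    abort("design columns do not match the fitted model's predictors.")
  }
  beta <- model$beta
  if (zero_context) {
    if (!all(model$context_cols %in% names(beta))) {
      abort(paste0("model has no context columns; refit with context dummies ",
                   "before computing private confidence."))
    }
    beta[model$context_cols] <- 0
  }
  eta <- drop(X %*% beta)
  cum <- vapply(model$tau, function(t) pnorm(t - eta), numeric(length(eta)))
  cum <- matrix(cum, ncol = 5)
  probs <- cbind(cum, 1) - cbind(0, cum)
  colnames(probs) <- paste0("p_", 1:6)
  probs
}

#' Counterfactual private confidence
#'
#' Estimates the confidence a subject would have reported in the absence of
#' contextual (partner-specific) modulation: the fitted model (from the
#' final behavioural phase) is applied to scan-session trials with the
#' context weights set to zero, and the expectation of the resulting report
#' distribution, \eqn{\sum_j j \, P(r=j)}, is taken as the per-trial private
#' confidence. The output is by construction invariant to the trials'
#' context labels.
#'
#' @param model An `ordinal_fit` with context columns.
#' @param trials Scan-session trials tibble.
#' @return `trials` with an added `private_confidence` column (values in
#'   `[1, 6]`).
#' @export
private_confidence <- function(model, trials) {
  probs <- predict_report_distribution(model, trials, zero_context = TRUE)
  out <- as_tibble(trials)
  out$private_confidence <- drop(probs %*% (1:6))
  out
}

#' Group-level test of per-subject coefficients
#'
#' One-sample t-test of a vector of per-subject regression coefficients
#' against zero (df = number of subjects minus 1). A zero-variance input
#' (all coefficients identical) yields an infinite t and is flagged.
#'
#' @param coefficients Numeric vector, one value per subject (n >= 2).
#' @return One-row tibble: `estimate`, `t`, `df`, `p_value`, `degenerate`.
#' @export
group_level_test <- function(coefficients) {
  if (length(coefficients) < 2L) abort("need >= 2 subjects.")
  if (any(!is.finite(coefficients))) abort("coefficients must be finite.")
  s <- stats::sd(coefficients)
  m <- mean(coefficients)
  n <- length(coefficients)
  if (s == 0) {
    warn("zero variance across subjects; t statistic is infinite.")
    return(tibble(estimate = m, t = ifelse(m == 0, NaN, sign(m) * Inf),
                  df = n - 1, p_value = ifelse(m == 0, NaN, 0),
                  degenerate = TRUE))
  }
  tt <- stats::t.test(coefficients, mu = 0)
  tibble(estimate = m, t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, degenerate = FALSE)
}

#' @export
print.ordinal_fit <- function(x, ...) {
  cat(sprintf("Cumulative probit confidence model (n = %d, logLik = %.2f%s)\n",
              x$n, x$logLik, if (x$converged) "" else ", NOT converged"))
  cat("  weights:\n")
  for (nm in names(x$beta)) cat(sprintf("    %-22s %8.4f\n", nm, x$beta[nm]))
  cat("  thresholds:", paste(sprintf("%.3f", x$tau), collapse = " "), "\n")
  invisible(x)
}

#' @rdname fit_ordinal_probit
#' @param x An `ordinal_fit`.
#' @param ... Unused.
#' @export
tidy.ordinal_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble(term = names(x$beta), type = "weight", estimate = unname(x$beta)),
    tibble(term = paste0("tau_", 1:5), type = "threshold",
           estimate = x$tau)
  )
}

#' @rdname fit_ordinal_probit
#' @export
glance.ordinal_fit <- function(x, ...) {
  k <- length(x$beta) + 5
  tibble(logLik = x$logLik, AIC = 2 * k - 2 * x$logLik, nobs = x$n,
         converged = x$converged, separation = x$separation)
}

#' Serialise a fitted confidence model to JSON
#'
#' Writes/reads weights, thresholds, z-scoring parameters and fit metadata,
#' so a model fitted on the behavioural session can be re-applied later.
#'
#' @param model An `ordinal_fit`.
#' @param path JSON file path.
#' @export
write_ordinal_model <- function(model, path) {
  stopifnot(inherits(model, "ordinal_fit"))
  obj <- unclass(model)
  obj$beta <- as.list(obj$beta)
  obj$scaling <- lapply(obj$scaling, function(z) list(center = z$center,
                                                     scale = z$scale))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ordinal_model
#' @export
read_ordinal_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(beta = unlist(obj$beta), tau = obj$tau, logLik = obj$logLik,
         converged = obj$converged, separation = obj$separation,
         n = obj$n,
         scaling = lapply(obj$scaling, function(z) list(center = z$center,
                                                       scale = z$scale)),
         context_cols = obj$context_cols,
         levels_present = obj$levels_present),
    class = "ordinal_fit"
  )
}
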
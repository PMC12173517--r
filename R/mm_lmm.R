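## Linear mixed models with a catchment random intercept and a
## multimembership site random effect, fitted by profiled (RE)ML.
##
## Pairwise synchrony data violate independence because every site enters
## many pairs. Each observation (a site pair) is treated as a group with
## its two sites as members: the random-effects design has one column per
## site and two unit entries per row. The model is
##   y = X beta + Z_c u_c + Z_s u_s + e,
##   u_c ~ N(0, s2_c I), u_s ~ N(0, s2_s I), e ~ N(0, s2_e I).
## The likelihood is profiled over the variance ratios g_k = s2_k / s2_e;
## all linear algebra is reduced to q x q systems (q = number of random
## columns) through the Woodbury identity, so fits scale with the number of
## sites, not the number of pairs.

#' Build fixed and random design matrices for a pairwise mixed model
#'
#' @param formula fixed-effects formula evaluated in `data`.
#' @param data data.frame of observations (one row per site pair).
#' @param members character vector of two column names holding the member
#'   site ids of each observation, or `NULL` for no multimembership term.
#' @param group column name of the grouping random intercept (e.g.
#'   catchment), or `NULL`.
#' @param member_weight weight of each membership indicator (1 by default;
#'   0.5 spreads a unit weight over the two sites).
#' @return list with `X` (fixed design), `y`, `blocks` (named list of
#'   random-effect design matrices), `terms`.
#' @export
mm_design <- function(formula, data, members = c("site_a", "site_b"),
                      group = "catchment", member_weight = 1) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  X <- stats::model.matrix(formula, mf)
  y <- stats::model.response(mf)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[seq(qr_x$rank + 1L, ncol(X))]]
    stop("fixed design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  blocks <- list()
  if (!is.null(group)) {
    g <- factor(data[[group]])
    Zg <- matrix(0, nrow(data), nlevels(g),
                 dimnames = list(NULL, levels(g)))
    Zg[cbind(seq_len(nrow(data)), as.integer(g))] <- 1
    blocks$group <- Zg
  }
  if (!is.null(members)) {
    stopifnot(length(members) == 2L)
    s1 <- as.character(data[[members[1]]])
    s2 <- as.character(data[[members[2]]])
    sites <- sort(unique(c(s1, s2)))
    Zs <- matrix(0, nrow(data), length(sites),
                 dimnames = list(NULL, sites))
    Zs[cbind(seq_len(nrow(data)), match(s1, sites))] <- member_weight
    Zs[cbind(seq_len(nrow(data)), match(s2, sites))] <-
      Zs[cbind(seq_len(nrow(data)), match(s2, sites))] + member_weight
    blocks$member <- Zs
  }
  list(X = X, y = y, blocks = blocks, terms = stats::terms(mf))
}

## criterion pieces at variance ratios `gamma` (one per block); finite-
## difference gradient probes may step marginally below the zero bound,
## so clamp
mm_profile <- function(gamma, pre) {
  d <- sqrt(rep(pmax(gamma, 0), times = pre$block_sizes))
  W <- pre$A * tcrossprod(d)
  diag(W) <- diag(W) + 1
  R <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  logdetW <- 2 * sum(log(diag(R)))
  solveW <- function(M) backsolve(R, backsolve(R, M, transpose = TRUE))
  dB <- d * pre$B
  dc <- d * pre$cz
  WdB <- solveW(dB)
  Wdc <- solveW(dc)
  XtVX <- pre$XtX - crossprod(dB, WdB)
  XtVy <- pre$Xty - crossprod(dB, Wdc)
  ytVy <- pre$yty - sum(dc * Wdc)
  Rx <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(Rx)) return(NULL)
  beta <- backsolve(Rx, backsolve(Rx, XtVy, transpose = TRUE))
  yPy <- max(ytVy - sum(XtVy * beta), 1e-300)
  list(logdetW = logdetW, logdetXtVX = 2 * sum(log(diag(Rx))),
       beta = drop(beta), yPy = yPy, XtVX = XtVX)
}

mm_criterion <- function(gamma, pre, reml) {
  pr <- mm_profile(gamma, pre)
  if (is.null(pr)) return(1e10)
  n <- pre$n; p <- pre$p
  if (reml)
    (n - p) * log(pr$yPy / (n - p)) + pr$logdetW + pr$logdetXtVX +
      (n - p) * (1 + log(2 * pi))
  else
    n * log(pr$yPy / n) + pr$logdetW + n * (1 + log(2 * pi))
}

#' Fit a multimembership linear mixed model
#'
#' Variance ratios are optimized by bounded quasi-Newton search on the
#' profiled criterion (restricted likelihood for `method = "REML"`, full
#' likelihood for `"ML"`), started from all variance components equal to a
#' third of the OLS residual variance, i.e. unit ratios. Fixed effects are
#' the GLS solution at the optimum; their covariance uses the plug-in
#' variance estimates, and p-values use the large-sample normal reference
#' (pairwise synchrony datasets have hundreds to thousands of rows).
#'
#' A fit with any variance ratio at the zero boundary (< 1e-6), or with a
#' random block of a single level (whose variance is confounded with the
#' intercept), is flagged `singular`, and reported, not suppressed.
#'
#' @inheritParams mm_design
#' @param method `"REML"` (default, for inference within one fixed
#'   structure) or `"ML"` (for AIC / likelihood-ratio comparison of nested
#'   fixed structures).
#' @return object of class `mm_lmm`: coefficient table, variance
#'   components, log-likelihood, AIC, R-squared inputs.
#' @examples
#' d <- data.frame(y = rnorm(30), x = runif(30),
#'                 site_a = sample(letters[1:6], 30, TRUE),
#'                 site_b = sample(letters[7:12], 30, TRUE),
#'                 catchment = sample(c("c1", "c2"), 30, TRUE))
#' fit <- fit_mm_lmm(y ~ x, d)
#' coef(fit)
#' @export
fit_mm_lmm <- function(formula, data, members = c("site_a", "site_b"),
                       group = "catchment", member_weight = 1,
                       method = c("REML", "ML")) {
  method <- match.arg(method)
  reml <- method == "REML"
  des <- mm_design(formula, data, members, group, member_weight)
  X <- des$X; y <- des$y
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("more fixed-effect columns than observations")
  Z <- do.call(cbind, des$blocks)
  nb <- length(des$blocks)
  pre <- list(n = n, p = p,
              XtX = crossprod(X), Xty = drop(crossprod(X, y)),
              yty = sum(y^2),
              block_sizes = vapply(des$blocks, ncol, 0L))
  if (nb > 0L) {
    pre$A <- crossprod(Z)
    pre$B <- crossprod(Z, X)
    pre$cz <- drop(crossprod(Z, y))
  }

  if (nb == 0L) {
    fit0 <- stats::lm.fit(X, y)
    s2 <- sum(fit0$residuals^2) / (if (reml) n - p else n)
    gamma_hat <- numeric(0)
    pr <- list(beta = fit0$coefficients,
               XtVX = pre$XtX, yPy = sum(fit0$residuals^2),
               logdetW = 0, logdetXtVX = 2 * sum(log(abs(diag(qr.R(fit0$qr))))))
    crit <- mm_criterion_ols(pre, pr, reml)
    conv <- TRUE
  } else {
    start <- rep(1, nb)   # s2_k = s2_OLS / 3 for all components
    opt <- stats::optim(start, mm_criterion, pre = pre, reml = reml,
                        method = "L-BFGS-B", lower = rep(0, nb),
                        control = list(maxit = 500, factr = 1e5))
    ## boundary optima (ratios at 0, typical for null-like data) can abort
    ## the quasi-Newton line search; a derivative-free polish on the
    ## square-root scale (gamma = t^2, boundary becomes an interior
    ## stationary point) is run from the same point and the better
    ## criterion kept -- deterministic, no restarts
    pol <- if (nb == 1L) {
      o <- stats::optimize(function(t) mm_criterion(t^2, pre, reml),
                           c(0, sqrt(max(100, 10 * opt$par))), tol = 1e-10)
      list(par = o$minimum, value = o$objective, convergence = 0L)
    } else {
      stats::optim(sqrt(pmax(opt$par, 0)),
                   function(t) mm_criterion(t^2, pre, reml),
                   method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12))
    }
    if (pol$value <= opt$value) {
      gamma_hat <- pol$par^2
      crit <- pol$value
      conv <- pol$convergence == 0L || opt$convergence == 0L
    } else {
      gamma_hat <- opt$par
      crit <- opt$value
      conv <- opt$convergence == 0L
    }
    ## a ratio stuck just above zero is re-evaluated at exactly zero
    near0 <- gamma_hat < 1e-5 & gamma_hat > 0
    if (any(near0)) {
      g0 <- gamma_hat; g0[near0] <- 0
      if (mm_criterion(g0, pre, reml) <= crit + 1e-10) {
        gamma_hat <- g0
        crit <- mm_criterion(g0, pre, reml)
      }
    }
    if (!conv)
      stop("variance-component optimizer failed to converge (criterion ",
           format(crit), ")")
    pr <- mm_profile(gamma_hat, pre)
    s2 <- pr$yPy / (if (reml) n - p else n)
  }

  sigma2 <- c(gamma_hat * s2, residual = s2)
  if (nb > 0L) names(sigma2)[seq_len(nb)] <- names(des$blocks)
  vcov_beta <- s2 * solve(pr$XtVX)
  se <- sqrt(diag(vcov_beta))
  est <- pr$beta
  tval <- est / se
  pval <- 2 * stats::pnorm(-abs(tval))
  coefs <- data.frame(term = colnames(X), estimate = est, std_error = se,
                      t_value = tval, p_value = pval,
                      stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  k <- p + nb + 1L     # fixed effects + variance components + residual
  fit <- list(coefficients = coefs, vcov = vcov_beta, sigma2 = sigma2,
              gamma = gamma_hat, logLik = -crit / 2, criterion = crit,
              method = method, AIC = crit + 2 * k, n = n, p = p, df = k,
              singular = any(gamma_hat < 1e-6) ||
                any(pre$block_sizes == 1L),
              fitted_fixed = drop(X %*% est),
              formula = formula, converged = conv)
  class(fit) <- "mm_lmm"
  fit
}

mm_criterion_ols <- function(pre, pr, reml) {
  n <- pre$n; p <- pre$p
  if (reml)
    (n - p) * log(pr$yPy / (n - p)) + pr$logdetXtVX +
      (n - p) * (1 + log(2 * pi))
  else
    n * log(pr$yPy / n) + n * (1 + log(2 * pi))
}

#' @export
coef.mm_lmm <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
logLik.mm_lmm <- function(object, ...) {
  structure(object$logLik, df = object$df, class = "logLik")
}

#' @export
print.mm_lmm <- function(x, ...) {
  cat(sprintf("multimembership LMM (%s)%s; n = %d\n", x$method,
              if (x$singular) " [singular]" else "", x$n))
  print(x$coefficients, digits = 4)
  cat("variance components:\n")
  print(x$sigma2, digits = 4)
  r2 <- r2_nakagawa(x)
  cat(sprintf("R2 marginal %.3f, conditional %.3f; AIC %.1f\n",
              r2[["marginal"]], r2[["conditional"]], x$AIC))
  invisible(x)
}

#' Wald tests of the fixed effects
#'
#' t = estimate / SE from the GLS covariance at the variance-component
#' optimum; two-sided p-values from the standard normal reference.
#'
#' @param fit an [fit_mm_lmm()] object.
#' @return the coefficient table (term, estimate, std_error, t_value,
#'   p_value).
#' @export
wald_tests <- function(fit) {
  stopifnot(inherits(fit, "mm_lmm"))
  fit$coefficients
}

#' Marginal and conditional R-squared of a mixed model
#'
#' Variance-explained decomposition for mixed models: marginal R2 is the
#' variance of the fixed-effect predictor over the total (fixed +
#' all random components + residual); conditional R2 adds the random
#' components to the numerator.
#'
#' @param fit an [fit_mm_lmm()] object.
#' @return named numeric vector `marginal`, `conditional`.
#' @export
r2_nakagawa <- function(fit) {
  stopifnot(inherits(fit, "mm_lmm"))
  var_f <- stats::var(fit$fitted_fixed)
  nb <- length(fit$sigma2) - 1L
  var_r <- if (nb > 0) sum(fit$sigma2[seq_len(nb)]) else 0
  tot <- var_f + var_r + fit$sigma2[["residual"]]
  c(marginal = var_f / tot, conditional = (var_f + var_r) / tot)
}

## ---- synchrony-model presets -------------------------------------------

#' Prepare synchrony records for mixed modelling
#'
#' Adds the model covariates used throughout: `sqrt_d_km` (square root of
#' watercourse distance in kilometres; the square root linearizes the
#' concave distance decay of synchrony), and 0/1 versions of
#' flow-connectedness and fragment-border crossing.
#'
#' @param records [pairwise_synchrony()] output.
#' @return records with `sqrt_d_km`, `flow01`, `barrier01` columns.
#' @export
synchrony_model_frame <- function(records) {
  records$sqrt_d_km <- sqrt(records$d_w_m / 1000)
  records$flow01 <- as.numeric(records$flow_connected)
  records$barrier01 <- as.numeric(records$barrier_crossed)
  records
}

#' Fit a preset synchrony mixed model
#'
#' Presets: `"threeway"` regresses pair synchrony on the main effects and
#' full three-way interaction of sqrt-watercourse-distance,
#' flow-connectedness and fragment-border crossing; `"distbarrier"` on
#' distance, barrier crossing and their interaction (typically on a
#' flow-stratified subset); `"maineffects"` drops that interaction. All
#' presets carry the catchment random intercept and the multimembership
#' site effect.
#'
#' @param records [pairwise_synchrony()] output.
#' @param preset model preset.
#' @param flow optional subset: `"connected"` or `"unconnected"`.
#' @param method `"REML"` or `"ML"`.
#' @return an [fit_mm_lmm()] object.
#' @export
fit_synchrony_lmm <- function(records,
                              preset = c("threeway", "distbarrier",
                                         "maineffects"),
                              flow = NULL, method = "REML") {
  preset <- match.arg(preset)
  d <- synchrony_model_frame(records)
  if (!is.null(flow)) {
    flow <- match.arg(flow, c("connected", "unconnected"))
    d <- d[if (flow == "connected") d$flow_connected else !d$flow_connected, ,
           drop = FALSE]
  }
  form <- switch(preset,
    threeway    = rho ~ sqrt_d_km * flow01 * barrier01,
    distbarrier = rho ~ sqrt_d_km * barrier01,
    maineffects = rho ~ sqrt_d_km + barrier01)
  fit_mm_lmm(form, d, members = c("site_a", "site_b"), group = "catchment",
             method = method)
}

#' Type-I-error simulation of the three-way synchrony model
#'
#' Simulates null density panels (identity correlation, no trends) on a
#' fixed riverscape, runs the full synchrony pipeline (pairwise Spearman,
#' minimum matching years, between-fragment truncation) and the three-way
#' multimembership model on each, and reports the proportion of p-values
#' below `alpha` per model term, with binomial Monte Carlo standard errors.
#' Under a well-calibrated model every non-intercept proportion is
#' compatible with `alpha`.
#'
#' @param cfg [sim_config()] describing the riverscape and panel.
#' @param n_reps number of null replicates.
#' @param alpha nominal level.
#' @param seed integer; replicate r uses seed `seed + r`.
#' @param min_years minimum matching years for the synchrony filter.
#' @return list with `proportions` (data.frame term, rejections, n_reps,
#'   proportion, mc_se), `n_failed` (replicates dropped for convergence or
#'   data degeneracies), `alpha`.
#' @export
type1_simulation <- function(cfg, n_reps = 500, alpha = 0.05, seed = 1L,
                             min_years = 6) {
  rs <- generate_riverscape(cfg)
  geometry <- riverscape_geometry(rs)
  pmat <- NULL
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    dens <- null_riverscape_densities(rs, cfg, seed = seed + r)
    fit <- tryCatch({
      rec <- pairwise_synchrony(dens, geometry, min_years = min_years)
      rec <- truncate_between_fragment_pairs(rec)
      fit_synchrony_lmm(rec, "threeway", method = "REML")
    }, error = function(e) NULL)
    if (is.null(fit)) { n_failed <- n_failed + 1L; next }
    pv <- stats::setNames(fit$coefficients$p_value, fit$coefficients$term)
    pmat <- rbind(pmat, pv)
  }
  if (is.null(pmat)) stop("all type-I replicates failed")
  used <- nrow(pmat)
  rej <- colSums(pmat < alpha)
  prop <- rej / used
  out <- data.frame(term = colnames(pmat), rejections = as.integer(rej),
                    n_reps = used, proportion = prop,
                    mc_se = sqrt(prop * (1 - prop) / used),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  list(proportions = out, n_failed = n_failed, alpha = alpha)
}
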
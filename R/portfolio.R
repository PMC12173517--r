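## Taylor's power law and the mean-variance-CV portfolio effect.
##
## Across subpopulations, temporal variance scales with temporal mean as
## var = c * mean^z (Taylor's power law). The portfolio effect (PE) of a
## fragment metapopulation is the CV the summed population would have if it
## were one uniform population of the same total mean -- extrapolated from
## the fitted power law -- divided by the CV actually observed. PE > 1
## means the aggregate is more stable than a uniform population of equal
## size; asynchrony among subpopulations is what generates that gap.

#' Fit Taylor's power law across subpopulation time series
#'
#' Ordinary least squares of log10(temporal variance) on log10(temporal
#' mean), one point per subpopulation (site), pooled across all
#' metapopulations of a species.
#'
#' @param panel long data.frame `site`, `year`, `density`.
#' @param min_obs minimum observations per subpopulation to contribute a
#'   (mean, variance) point (2 by default; variance needs two).
#' @return object of class `taylor_fit`: `z` (slope), `log_c` (log10
#'   intercept), `se_z`, `points` (per-subpopulation mean/variance), `fit`
#'   (the underlying `lm`).
#' @export
taylor_fit <- function(panel, min_obs = 2) {
  sp <- split(panel$density, panel$site)
  mu <- vapply(sp, mean, 0)
  v <- vapply(sp, stats::var, 0)
  nobs <- vapply(sp, length, 0L)
  keep <- nobs >= min_obs & mu > 0 & v > 0
  pts <- data.frame(site = names(sp)[keep], mean = mu[keep],
                    variance = v[keep], n_obs = nobs[keep],
                    stringsAsFactors = FALSE)
  if (nrow(pts) < 3)
    stop("need at least 3 subpopulations with positive mean and variance")
  fit <- stats::lm(log10(variance) ~ log10(mean), data = pts)
  out <- list(z = unname(stats::coef(fit)[2]),
              log_c = unname(stats::coef(fit)[1]),
              ## exact power-law points fit perfectly; the SE is then 0
              se_z = suppressWarnings(summary(fit)$coefficients[2, 2]),
              points = pts, fit = fit)
  class(out) <- "taylor_fit"
  out
}

#' @export
print.taylor_fit <- function(x, ...) {
  cat(sprintf("Taylor power law: z = %.3f (SE %.3f), log10(c) = %.3f, %d subpopulations\n",
              x$z, x$se_z, x$log_c, nrow(x$points)))
  invisible(x)
}

#' Choose the portfolio-effect metric from the Taylor exponent
#'
#' The average-CV portfolio effect assumes `z = 2`; when the fitted
#' exponent is materially different the more conservative mean-variance-CV
#' metric is required.
#'
#' @param z fitted Taylor exponent.
#' @param tol tolerance around 2 within which the average-CV metric is
#'   permitted (0.1 by default).
#' @return `"mean_variance"` or `"average_cv"` with attribute `"z"`.
#' @export
choose_pe_metric <- function(z, tol = 0.1) {
  metric <- if (abs(z - 2) > tol) "mean_variance" else "average_cv"
  structure(metric, z = z)
}

#' Mean-variance-CV portfolio effect of one fragment
#'
#' Subpopulations are the fragment's sites. Eligibility requires at least
#' `min_subpops` subpopulations, each with at least `min_occasions` sampled
#' occasions. The metapopulation series is the per-year sum of
#' subpopulation densities over the years in which *all* eligible
#' subpopulations were sampled (the strict common-year rule, so the sum is
#' always a sum of the same populations). `cv_obs` is sd/mean of that
#' series; `cv_uniform` is the Taylor-extrapolated CV of a single uniform
#' population with the metapopulation's mean,
#' `sqrt(10^log_c * mu^z) / mu`; the PE is `cv_uniform / cv_obs`.
#'
#' @param panel long data.frame `site`, `year`, `density` for the
#'   fragment's sites.
#' @param taylor a [taylor_fit()] (species-level).
#' @param min_subpops,min_occasions eligibility thresholds.
#' @return one-row data.frame `n_subpops`, `n_years`, `cv_obs`,
#'   `cv_uniform`, `pe`, `eligible`, `reason`; ineligible fragments carry
#'   `NA` metrics and the reason.
#' @export
portfolio_effect <- function(panel, taylor, min_subpops = 4,
                             min_occasions = 10) {
  cnt <- table(panel$site)
  elig_sites <- names(cnt)[cnt >= min_occasions]
  bail <- function(reason, n_sub = length(elig_sites), n_yr = NA_integer_)
    data.frame(n_subpops = n_sub, n_years = n_yr, cv_obs = NA_real_,
               cv_uniform = NA_real_, pe = NA_real_, eligible = FALSE,
               reason = reason, stringsAsFactors = FALSE)
  if (length(elig_sites) < min_subpops)
    return(bail("too_few_subpopulations"))
  sub <- panel[panel$site %in% elig_sites, , drop = FALSE]
  ## strict common-year rule
  yr_tab <- table(unique(sub[c("site", "year")])$year)
  common <- as.numeric(names(yr_tab)[yr_tab == length(elig_sites)])
  if (length(common) < 2)
    return(bail("no_common_years", n_yr = length(common)))
  sub <- sub[sub$year %in% common, , drop = FALSE]
  meta <- tapply(sub$density, sub$year, sum)
  mu_t <- mean(meta)
  cv_obs <- stats::sd(meta) / mu_t
  if (!is.finite(cv_obs) || cv_obs <= 0)
    return(bail("degenerate_metapopulation_series", n_yr = length(common)))
  cv_uniform <- sqrt(10^taylor$log_c * mu_t^taylor$z) / mu_t
  data.frame(n_subpops = length(elig_sites), n_years = length(common),
             cv_obs = cv_obs, cv_uniform = cv_uniform,
             pe = cv_uniform / cv_obs, eligible = TRUE, reason = NA_character_,
             stringsAsFactors = FALSE)
}

#' Portfolio effects for every fragment of a panel
#'
#' @param densities long data.frame `site`, `year`, `density`.
#' @param fragments [assign_fragments()]-style map (`site`, `fragment`,
#'   `catchment`).
#' @param taylor optional [taylor_fit()]; fitted on `densities` when
#'   omitted.
#' @inheritParams portfolio_effect
#' @return data.frame, one row per fragment: `fragment`, `catchment` plus
#'   the [portfolio_effect()] columns.
#' @export
fragment_portfolio_effects <- function(densities, fragments, taylor = NULL,
                                       min_subpops = 4, min_occasions = 10) {
  if (is.null(taylor)) taylor <- taylor_fit(densities)
  densities$fragment <- fragments$fragment[match(densities$site,
                                                 fragments$site)]
  sp <- split(densities, densities$fragment)
  out <- do.call(rbind, lapply(names(sp), function(f) {
    pe <- portfolio_effect(sp[[f]], taylor, min_subpops, min_occasions)
    cbind(data.frame(fragment = f,
                     catchment = fragments$catchment[
                       match(f, fragments$fragment)],
                     stringsAsFactors = FALSE),
          pe)
  }))
  rownames(out) <- NULL
  out
}

#' Association between fragment synchrony and the portfolio effect
#'
#' Linear mixed model of the portfolio effect on arithmetic mean fragment
#' synchrony with a catchment random intercept (fragments of the same
#' catchment are not independent). A negative slope means more synchronous
#' fragments are less stabilized.
#'
#' @param pe_table [fragment_portfolio_effects()] output (eligible rows are
#'   used).
#' @param frag_sync [fragment_mean_synchrony()] output.
#' @return an [fit_mm_lmm()] object (catchment random intercept only).
#' @export
pe_synchrony_association <- function(pe_table, frag_sync) {
  d <- merge(pe_table[pe_table$eligible, c("fragment", "catchment", "pe")],
             frag_sync[, c("fragment", "mean_rho")], by = "fragment")
  if (nrow(d) < 5)
    stop("need at least 5 eligible fragments with synchrony estimates")
  fit_mm_lmm(pe ~ mean_rho, d, members = NULL, group = "catchment",
             method = "REML")
}
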
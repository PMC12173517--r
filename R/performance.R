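## Fragment-level population performance metrics and their association
## with fragment synchrony.
##
## Five metrics per fragment: occurrence rate, mean log-density, s.d. of
## log-density (all site-level, averaged to the fragment), plus residual
## s.d. and trajectory slope from one detrending regression per fragment.
## Densities enter on the log(density + 1) scale throughout so that zero
## catches are representable.

#' Site-level performance metrics
#'
#' @param series data.frame `year`, `density` of one site (sampled
#'   occasions only).
#' @return one-row data.frame: `occurrence` (fraction of sampled occasions
#'   with density > 0), `mean_log_density` and `sd_log_density` (computed
#'   on `log(density + 1)`), `n_obs`.
#' @export
site_metrics <- function(series) {
  ld <- log1p(series$density)
  data.frame(occurrence = mean(series$density > 0),
             mean_log_density = mean(ld),
             sd_log_density = if (length(ld) > 1) stats::sd(ld) else 0,
             n_obs = length(ld))
}

#' Aggregate site metrics to fragments
#'
#' Unweighted mean of each site-level metric across the sites of a
#' fragment.
#'
#' @param densities long data.frame `site`, `year`, `density`.
#' @param fragments fragment map (`site`, `fragment`, `catchment`).
#' @return data.frame `fragment`, `catchment`, `occurrence`,
#'   `mean_log_density`, `sd_log_density`, `n_sites`.
#' @export
aggregate_to_fragment <- function(densities, fragments) {
  sm <- do.call(rbind, lapply(split(densities, densities$site), site_metrics))
  sm$site <- rownames(sm)
  sm$fragment <- fragments$fragment[match(sm$site, fragments$site)]
  sp <- split(sm, sm$fragment)
  out <- do.call(rbind, lapply(names(sp), function(f) data.frame(
    fragment = f,
    catchment = fragments$catchment[match(f, fragments$fragment)],
    occurrence = mean(sp[[f]]$occurrence),
    mean_log_density = mean(sp[[f]]$mean_log_density),
    sd_log_density = mean(sp[[f]]$sd_log_density),
    n_sites = nrow(sp[[f]]), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Detrended variability and trajectory of one fragment
#'
#' One regression per fragment of `log(density + 1)` on year in
#' interaction with site identity -- fully separate intercept and slope per
#' site. The residual standard deviation measures year-to-year variability
#' with every site's own linear trend removed (adding a common trend to all
#' sites changes the trajectory, never the residual s.d.); the trajectory
#' is the unweighted mean of the per-site year slopes.
#'
#' @param panel long data.frame `site`, `year`, `density` of one
#'   fragment's sites.
#' @return one-row data.frame `residual_sd`, `trajectory`, `n_sites`,
#'   `n_obs`, `dropped` (TRUE with NA metrics when the fragment has fewer
#'   observations than parameters).
#' @export
fragment_trend_model <- function(panel) {
  ## sites with a single year cannot carry a slope; they are left out of
  ## the regression
  cnt <- table(panel$site)
  usable <- names(cnt)[cnt >= 2]
  sub <- panel[panel$site %in% usable, , drop = FALSE]
  n_par <- 2L * length(usable)
  if (length(usable) < 1L || nrow(sub) <= n_par)
    return(data.frame(residual_sd = NA_real_, trajectory = NA_real_,
                      n_sites = length(usable), n_obs = nrow(sub),
                      dropped = TRUE))
  sub$site <- factor(sub$site)
  sub$ld <- log1p(sub$density)
  ## a one-site fragment reduces to a plain site-level trend regression
  fit <- if (nlevels(sub$site) == 1L) stats::lm(ld ~ year, data = sub)
    else stats::lm(ld ~ 0 + site + site:year, data = sub)
  cf <- stats::coef(fit)
  slopes <- cf[grepl("year", names(cf))]
  data.frame(residual_sd = stats::sd(stats::residuals(fit)),
             trajectory = mean(slopes),
             n_sites = length(usable), n_obs = nrow(sub), dropped = FALSE)
}

#' Full fragment performance table
#'
#' @inheritParams aggregate_to_fragment
#' @return data.frame per fragment: occurrence, mean/sd log-density,
#'   residual sd, trajectory, site and observation counts.
#' @export
fragment_performance <- function(densities, fragments) {
  agg <- aggregate_to_fragment(densities, fragments)
  densities$fragment <- fragments$fragment[match(densities$site,
                                                 fragments$site)]
  tr <- do.call(rbind, lapply(split(densities, densities$fragment),
                              fragment_trend_model))
  tr$fragment <- rownames(tr)
  out <- merge(agg, tr[, c("fragment", "residual_sd", "trajectory",
                           "dropped")], by = "fragment")
  rownames(out) <- NULL
  out
}

#' Associations between fragment synchrony and performance metrics
#'
#' One mixed model per response -- the five performance metrics plus the
#' portfolio effect -- with arithmetic mean fragment synchrony as the
#' explanatory variable and a catchment random intercept. Nominal p-values
#' are adjusted with the Benjamini-Hochberg step-up procedure across the
#' six tests (the portfolio-effect test belongs to the same family).
#' Singular fits (a variance component on the zero boundary) are flagged,
#' not suppressed.
#'
#' @param perf [fragment_performance()] output.
#' @param frag_sync [fragment_mean_synchrony()] output.
#' @param pe_table optional [fragment_portfolio_effects()] output; adds the
#'   portfolio-effect row when given.
#' @return data.frame `metric`, `slope`, `t_value`, `p_value`,
#'   `p_adjusted`, `singular`, `n`.
#' @export
performance_associations <- function(perf, frag_sync, pe_table = NULL) {
  d <- merge(perf, frag_sync[, c("fragment", "mean_rho")], by = "fragment")
  metrics <- c(occurrence = "occurrence",
               mean_log_density = "mean_log_density",
               sd_log_density = "sd_log_density",
               residual_sd = "residual_sd",
               trajectory = "trajectory")
  one <- function(dd, resp) {
    dd <- dd[is.finite(dd[[resp]]), , drop = FALSE]
    fit <- tryCatch(
      fit_mm_lmm(stats::reformulate("mean_rho", response = resp), dd,
                 members = NULL, group = "catchment"),
      error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(metric = resp, slope = NA_real_, t_value = NA_real_,
                        p_value = NA_real_, singular = NA, n = nrow(dd),
                        stringsAsFactors = FALSE))
    co <- fit$coefficients[fit$coefficients$term == "mean_rho", ]
    data.frame(metric = resp, slope = co$estimate, t_value = co$t_value,
               p_value = co$p_value, singular = fit$singular, n = fit$n,
               stringsAsFactors = FALSE)
  }
  rows <- lapply(metrics, function(m) one(d, m))
  if (!is.null(pe_table)) {
    dp <- merge(pe_table[pe_table$eligible, ],
                frag_sync[, c("fragment", "mean_rho")], by = "fragment")
    rows <- c(list(one(dp, "pe")), rows)
    rows[[1]]$metric <- "portfolio_effect"
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out[, c("metric", "slope", "t_value", "p_value", "p_adjusted",
          "singular", "n")]
}
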
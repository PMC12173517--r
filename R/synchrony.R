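#' Spearman synchrony of one site pair
#'
#' Spearman rank correlation of the two density series over the years
#' sampled at both sites (average ranks for ties). The pair is excluded --
#' with a reason -- when fewer than `min_years` matching years exist, when
#' no matching year has positive density at both sites (such pairs carry
#' negatively biased correlations), or when either series is constant over
#' the matching years (rank correlation undefined).
#'
#' @param series_a,series_b data.frames with columns `year`, `density`.
#' @param min_years minimum matching years (6 by default; 10 for the
#'   sensitivity analysis).
#' @param positive_rule `"both"` (default) requires at least one matching
#'   year where both densities are > 0; `"either"` requires one where at
#'   least one is.
#' @return list with `rho`, `n_matching_years`, `excluded` (logical) and
#'   `reason` (`NA`, `"too_few_years"`, `"no_positive_overlap"`,
#'   `"constant_series"`).
#' @export
pair_synchrony <- function(series_a, series_b, min_years = 6,
                           positive_rule = c("both", "either")) {
  positive_rule <- match.arg(positive_rule)
  m <- match(series_a$year, series_b$year)
  keep <- !is.na(m)
  x <- series_a$density[keep]
  y <- series_b$density[m[keep]]
  spearman_pair(x, y, min_years, positive_rule)
}

## core shared with the vectorised panel path
spearman_pair <- function(x, y, min_years, positive_rule = "both") {
  n <- length(x)
  if (n < min_years)
    return(list(rho = NA_real_, n_matching_years = n, excluded = TRUE,
                reason = "too_few_years"))
  pos <- if (positive_rule == "both") any(x > 0 & y > 0) else any(x > 0 | y > 0)
  if (!pos)
    return(list(rho = NA_real_, n_matching_years = n, excluded = TRUE,
                reason = "no_positive_overlap"))
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    return(list(rho = NA_real_, n_matching_years = n, excluded = TRUE,
                reason = "constant_series"))
  list(rho = stats::cor(rx, ry), n_matching_years = n, excluded = FALSE,
       reason = NA_character_)
}

#' Pairwise synchrony records for a density panel
#'
#' Computes [pair_synchrony()] for every site pair of the geometry table
#' that has density data, and joins the pair's geometry. Pairs failing the
#' filters are reported in the `"exclusions"` attribute.
#'
#' @param densities long data.frame `site`, `year`, `density` (a `species`
#'   column, if present, must already be filtered to one species).
#' @param geometry [pair_geometry_table()] rows (possibly several
#'   catchments).
#' @param min_years minimum matching years.
#' @param positive_rule see [pair_synchrony()].
#' @return data.frame: geometry columns plus `rho`, `n_matching_years`.
#' @export
pairwise_synchrony <- function(densities, geometry, min_years = 6,
                               positive_rule = c("both", "either")) {
  positive_rule <- match.arg(positive_rule)
  sites <- sort(unique(densities$site))
  years <- sort(unique(densities$year))
  dmat <- matrix(NA_real_, length(sites), length(years),
                 dimnames = list(sites, as.character(years)))
  dmat[cbind(match(densities$site, sites),
             match(densities$year, years))] <- densities$density
  ok <- geometry$site_a %in% sites & geometry$site_b %in% sites
  geo <- geometry[ok, , drop = FALSE]
  ia <- match(geo$site_a, sites)
  ib <- match(geo$site_b, sites)
  rho <- n_match <- numeric(nrow(geo))
  reason <- character(nrow(geo))
  for (k in seq_len(nrow(geo))) {
    xa <- dmat[ia[k], ]; xb <- dmat[ib[k], ]
    shared <- !is.na(xa) & !is.na(xb)
    r <- spearman_pair(xa[shared], xb[shared], min_years, positive_rule)
    rho[k] <- r$rho
    n_match[k] <- r$n_matching_years
    reason[k] <- if (r$excluded) r$reason else NA_character_
  }
  out <- geo
  out$rho <- rho
  out$n_matching_years <- as.integer(n_match)
  excl <- !is.na(reason)
  exclusions <- data.frame(site_a = geo$site_a[excl], site_b = geo$site_b[excl],
                           n_matching_years = as.integer(n_match[excl]),
                           reason = reason[excl], stringsAsFactors = FALSE)
  out <- out[!excl, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- exclusions
  out
}

#' Truncate between-fragment pairs to the within-fragment distance range
#'
#' For each catchment, drops every between-fragment pair whose watercourse
#' distance exceeds the catchment's maximum within-fragment pair distance.
#' Within-fragment records are never touched. This removes the unequal
#' distance ranges of the two groups that would otherwise distort
#' distance-by-barrier interactions. A catchment without any within-fragment
#' pair loses all its between-fragment pairs, with a warning.
#'
#' @param records [pairwise_synchrony()] output (needs `catchment`,
#'   `barrier_crossed`, `d_w_m`).
#' @return filtered records.
#' @export
truncate_between_fragment_pairs <- function(records) {
  keep <- rep(TRUE, nrow(records))
  for (cid in unique(records$catchment)) {
    inc <- records$catchment == cid
    within <- inc & !records$barrier_crossed
    if (!any(within)) {
      if (any(inc & records$barrier_crossed))
        warning(sprintf(
          "catchment %s has no within-fragment pair; dropping its %d between-fragment pairs",
          cid, sum(inc & records$barrier_crossed)))
      keep[inc & records$barrier_crossed] <- FALSE
    } else {
      dmax <- max(records$d_w_m[within])
      keep[inc & records$barrier_crossed & records$d_w_m > dmax] <- FALSE
    }
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Arithmetic mean synchrony per fragment
#'
#' Keeps only pairs whose two sites share a fragment and averages their
#' Spearman correlations per fragment. Fragments without any retained
#' within-fragment pair are omitted.
#'
#' @param records [pairwise_synchrony()] output (needs `fragment_a`,
#'   `fragment_b`, `rho`, `catchment`).
#' @return data.frame `fragment`, `mean_rho`, `n_pairs`, `catchment`.
#' @export
fragment_mean_synchrony <- function(records) {
  within <- records[records$fragment_a == records$fragment_b, , drop = FALSE]
  if (!nrow(within))
    return(data.frame(fragment = character(), mean_rho = numeric(),
                      n_pairs = integer(), catchment = character(),
                      stringsAsFactors = FALSE))
  sp <- split(within, within$fragment_a)
  out <- do.call(rbind, lapply(sp, function(d)
    data.frame(fragment = d$fragment_a[1], mean_rho = mean(d$rho),
               n_pairs = nrow(d), catchment = d$catchment[1],
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[order(out$fragment), , drop = FALSE]
}
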
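## Fluvial synchrogram categories and the barrier-information model test.
##
## Site pairs are classified by how their straight-line separation (d_E)
## relates to their along-channel separation (d_W): the quotient q =
## d_E / d_W indexes functional connectivity (q near 1: same branch; q
## small: nearby points of different branches). Crossing catchment-wise
## median splits of d_E (short/long) and q (high/low) gives four classes:
##   D1 short d_E, high q  -- same branch, near
##   D2 long  d_E, high q  -- same branch, far
##   D3 short d_E, low  q  -- adjacent branches, near
##   D4 long  d_E, low  q  -- separate branches, far

#' Classify site pairs into synchrogram categories D1-D4
#'
#' Splits are at the catchment-wise medians of `d_E` and of `q = d_E/d_W`.
#' Ties are deterministic: a `d_E` equal to its median counts as short,
#' and a `q` equal to its median counts as high -- so that a perfectly
#' straight channel, where every pair has `q = 1`, classifies as
#' same-branch (D1/D2). Pairs with `d_W = 0` (coincident sites) are
#' excluded. Category assignment is invariant to rescaling the distance
#' unit, since both medians rescale identically.
#'
#' @param records pair records carrying `d_e_m`, `d_w_m`, `catchment`.
#' @return records with added `q` and `d_class` (factor D1-D4) columns;
#'   coincident-site rows removed.
#' @export
classify_pairs <- function(records) {
  keep <- records$d_w_m > 0
  out <- records[keep, , drop = FALSE]
  out$q <- out$d_e_m / out$d_w_m
  out$d_class <- NA_character_
  for (cid in unique(out$catchment)) {
    inc <- out$catchment == cid
    med_de <- stats::median(out$d_e_m[inc])
    med_q <- stats::median(out$q[inc])
    short <- out$d_e_m[inc] <= med_de
    high <- out$q[inc] >= med_q
    out$d_class[inc] <- ifelse(short & high, "D1",
                        ifelse(!short & high, "D2",
                        ifelse(short & !high, "D3", "D4")))
  }
  out$d_class <- factor(out$d_class, levels = c("D1", "D2", "D3", "D4"))
  rownames(out) <- NULL
  out
}

#' Mean synchrony per synchrogram category, split by barrier crossing
#'
#' @param records [classify_pairs()] output carrying `rho` and
#'   `barrier_crossed`.
#' @return data.frame `d_class`, `barrier_crossed`, `mean_rho`, `n_pairs`.
#' @export
synchrogram_summary <- function(records) {
  sp <- split(records, list(records$d_class, records$barrier_crossed),
              drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    d_class = as.character(d$d_class[1]),
    barrier_crossed = d$barrier_crossed[1],
    mean_rho = mean(d$rho), n_pairs = nrow(d), stringsAsFactors = FALSE)))
  out <- out[order(out$d_class, out$barrier_crossed), ]
  rownames(out) <- NULL
  out
}

#' Does barrier information improve the synchrogram model?
#'
#' Fits two maximum-likelihood mixed models of pair synchrony with the
#' usual catchment + multimembership random structure: one with the
#' synchrogram category main effect only, and one adding the interaction
#' with fragment-border crossing. Reports both AICs, their difference, and
#' the likelihood-ratio p-value for the added barrier terms. ML (not REML)
#' likelihoods are used because the two fixed structures differ.
#'
#' Category-by-barrier cells that are empty make the corresponding
#' interaction columns all-zero; those columns are dropped from the design
#' and listed in `dropped_terms`.
#'
#' @param records [classify_pairs()] output carrying `rho`,
#'   `barrier_crossed`, `site_a`, `site_b`, `catchment`.
#' @return list: `fit_category` and `fit_barrier` ([fit_mm_lmm()]
#'   objects), `aic_category`, `aic_barrier`, `delta_aic` (category-only
#'   minus barrier: positive favours the barrier model), `lrt_stat`,
#'   `df_added`, `lrt_p`, `dropped_terms`.
#' @export
compare_barrier_models <- function(records) {
  d <- records[!is.na(records$rho), , drop = FALSE]
  if (nlevels(droplevels(d$d_class)) < 2)
    stop("need at least two synchrogram categories present")
  if (length(unique(d$barrier_crossed)) < 2)
    stop("need both barrier classes present")
  d$d_class <- droplevels(d$d_class)
  d$barrier01 <- as.numeric(d$barrier_crossed)
  X0 <- stats::model.matrix(~ d_class, d)
  X1 <- stats::model.matrix(~ d_class * barrier01, d)
  ## drop all-zero or collinear added columns (empty category x barrier cell)
  keep <- colSums(abs(X1)) > 0
  qr1 <- qr(X1[, keep, drop = FALSE])
  keep_names <- colnames(X1)[keep][qr1$pivot[seq_len(qr1$rank)]]
  dropped <- setdiff(colnames(X1), keep_names)
  d1 <- cbind(d, as.data.frame(X1[, setdiff(keep_names, colnames(X0)),
                                  drop = FALSE]))
  added <- setdiff(keep_names, colnames(X0))
  names(d1)[match(added, names(d1))] <- make.names(added)
  form1 <- stats::reformulate(c("d_class", make.names(added)),
                              response = "rho")
  fit0 <- fit_mm_lmm(rho ~ d_class, d, method = "ML")
  fit1 <- fit_mm_lmm(form1, d1, method = "ML")
  stat <- max(0, 2 * (fit1$logLik - fit0$logLik))
  df_added <- length(added)
  list(fit_category = fit0, fit_barrier = fit1,
       aic_category = fit0$AIC, aic_barrier = fit1$AIC,
       delta_aic = fit0$AIC - fit1$AIC,
       lrt_stat = stat, df_added = df_added,
       lrt_p = stats::pchisq(stat, df_added, lower.tail = FALSE),
       dropped_terms = dropped)
}
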
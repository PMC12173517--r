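test_that("Taylor fit recovers exact power-law data", {
  ## variance = mean^2 exactly -> z = 2
  means <- c(1, 2, 5, 10, 20)
  panel <- do.call(rbind, lapply(seq_along(means), function(i) {
    ## two-point series with prescribed mean m and variance m^2:
    ## m +- m/sqrt(2) has var((m-a)^2...)  = m^2 for a 2-point sample
    m <- means[i]
    data.frame(site = paste0("s", i), year = 1:2,
               density = c(m - m / sqrt(2), m + m / sqrt(2)))
  }))
  tf <- taylor_fit(panel)
  expect_equal(tf$z, 2, tolerance = 1e-9)
  expect_equal(tf$log_c, 0, tolerance = 1e-9)
  ## variance = 0.5 * mean^1.5
  panel2 <- do.call(rbind, lapply(seq_along(means), function(i) {
    m <- means[i]
    s <- sqrt(0.5 * m^1.5 / 2)
    data.frame(site = paste0("s", i), year = 1:2, density = c(m - s, m + s))
  }))
  tf2 <- taylor_fit(panel2)
  expect_equal(tf2$z, 1.5, tolerance = 1e-9)
  expect_equal(tf2$log_c, log10(0.5), tolerance = 1e-9)
  expect_error(taylor_fit(panel[panel$site %in% c("s1", "s2"), ]),
               "at least 3")
})

test_that("Taylor fit recovers the generating exponent from noisy panels", {
  set.seed(20)
  z_true <- 1.6
  panel <- do.call(rbind, lapply(1:200, function(i) {
    m <- exp(runif(1, 0, 3))
    cv <- sqrt(10^(-0.3) * m^z_true) / m
    data.frame(site = paste0("s", i), year = 1:40,
               density = rlnorm_mean_cv(40, m, cv))
  }))
  tf <- taylor_fit(panel)
  expect_lt(abs(tf$z - z_true), 2 * tf$se_z + 0.05)
})

test_that("PE metric choice follows the distance of z from 2", {
  expect_equal(as.character(choose_pe_metric(1.61)), "mean_variance")
  expect_equal(as.character(choose_pe_metric(2.0)), "average_cv")
  expect_equal(as.character(choose_pe_metric(2.05, tol = 0.1)), "average_cv")
  expect_equal(as.character(choose_pe_metric(1.85, tol = 0.1)), "mean_variance")
})

test_that("portfolio effect reproduces definitional arithmetic", {
  ## craft a fragment whose observed CV and uniform CV are known:
  ## cv_uniform/cv_obs with z = 2, log_c = log10(cv^2): cv_uniform = cv
  set.seed(42)
  tf <- taylor_exact(z = 2, log_c = log10(0.04))   # uniform CV = 0.2
  years <- 1:12
  panel <- rbind(
    data.frame(site = "a", year = years, density = 10 + 0 * years),
    data.frame(site = "b", year = years, density = 10 + (years %% 2)),
    data.frame(site = "c", year = years, density = 12 + (years %% 3)),
    data.frame(site = "d", year = years, density = 11 + 0 * years))
  pe <- portfolio_effect(panel, tf)
  expect_true(pe$eligible)
  meta <- tapply(panel$density, panel$year, sum)    # all years common
  expect_equal(pe$cv_obs, sd(meta) / mean(meta))
  expect_equal(pe$cv_uniform, 0.2, tolerance = 1e-12)
  expect_equal(pe$pe, 0.2 / (sd(meta) / mean(meta)))
})

test_that("eligibility rules drop small or sparsely sampled fragments", {
  tf <- taylor_exact(2, 0)
  few_sites <- data.frame(site = rep(c("a", "b", "c"), each = 12),
                          year = 1:12, density = runif(36, 1, 2))
  expect_false(portfolio_effect(few_sites, tf)$eligible)
  short <- data.frame(site = rep(c("a", "b", "c", "d"), each = 5),
                      year = 1:5, density = runif(20, 1, 2))
  r <- portfolio_effect(short, tf)
  expect_false(r$eligible)
  expect_equal(r$reason, "too_few_subpopulations")
  ## disjoint sampling years -> no common years
  disj <- rbind(
    data.frame(site = rep(c("a", "b", "c"), each = 12),
               year = 1:12, density = runif(36, 1, 2)),
    data.frame(site = "d", year = 21:32, density = runif(12, 1, 2)))
  r2 <- portfolio_effect(disj, tf)
  expect_false(r2$eligible)
  expect_equal(r2$reason, "no_common_years")
})

test_that("two independent equal-CV subpopulations give PE near sqrt(2)", {
  set.seed(7)
  cv <- 0.3
  tf <- taylor_exact(z = 2, log_c = log10(cv^2))
  T <- 4000
  panel <- rbind(
    data.frame(site = "a", year = 1:T, density = rlnorm_mean_cv(T, 10, cv)),
    data.frame(site = "b", year = 1:T, density = rlnorm_mean_cv(T, 10, cv)),
    data.frame(site = "c", year = 1:T, density = rlnorm_mean_cv(T, 10, cv)),
    data.frame(site = "d", year = 1:T, density = rlnorm_mean_cv(T, 10, cv)))
  ## 4 subpops to pass eligibility; for the sqrt(2) identity use 2 of them
  pe2 <- portfolio_effect(panel[panel$site %in% c("a", "b"), ], tf,
                          min_subpops = 2)
  expect_equal(pe2$pe, sqrt(2), tolerance = 0.02)
  ## perfectly correlated identical subpopulations: no diversification
  dup <- panel[panel$site == "a", ]
  dup2 <- dup; dup2$site <- "b"
  pe1 <- portfolio_effect(rbind(dup, dup2), tf, min_subpops = 2)
  expect_equal(pe1$pe, 1, tolerance = 0.02)
})

test_that("PE does not increase with within-fragment correlation", {
  set.seed(99)
  cv <- 0.3
  tf <- taylor_exact(z = 2, log_c = log10(cv^2))
  s2 <- log(1 + cv^2)
  pe_at <- function(r, T = 1500, K = 4, reps = 8) {
    mean(replicate(reps, {
      Sig <- matrix(r, K, K); diag(Sig) <- 1
      L <- chol(Sig)
      Z <- matrix(rnorm(T * K), T, K) %*% L
      dens <- exp(log(10) - s2 / 2 + sqrt(s2) * Z)
      panel <- data.frame(site = rep(paste0("s", 1:K), each = T),
                          year = rep(1:T, K), density = as.vector(dens))
      portfolio_effect(panel, tf)$pe
    }))
  }
  grid <- c(0, 0.3, 0.6, 0.9)
  pes <- vapply(grid, pe_at, 0)
  expect_true(all(diff(pes) <= 0.03))
  expect_gt(pes[1], pes[4])
})

test_that("synchrony-PE association recovers a negative slope and flags singular fits", {
  set.seed(13)
  ## fragments with PE constructed to decline in synchrony
  d <- data.frame(fragment = paste0("f", 1:30),
                  catchment = rep(paste0("c", 1:5), 6))
  sync <- runif(30, 0, 0.8)
  pe_tab <- data.frame(fragment = d$fragment, catchment = d$catchment,
                       pe = 1.8 - 1.2 * sync + rnorm(30, 0, 0.1),
                       eligible = TRUE)
  fs <- data.frame(fragment = d$fragment, mean_rho = sync)
  fit <- pe_synchrony_association(pe_tab, fs)
  co <- fit$coefficients[fit$coefficients$term == "mean_rho", ]
  expect_lt(co$estimate, 0)
  expect_lt(co$p_value, 0.05)
  ## single catchment: group variance on the boundary
  pe1 <- pe_tab; pe1$catchment <- "c1"
  fit1 <- pe_synchrony_association(pe1, fs)
  expect_true(fit1$singular)
})
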
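#' Log-linear estimation of an observed pseudo-first-order rate constant
#'
#' For a first-order decay the remaining fraction P satisfies
#' `-ln(P/P0) = k_obs * t`. The observed rate constant is estimated as the
#' slope of an ordinary least-squares regression of `-ln(P/P0)` on time,
#' with a free intercept (reported for diagnostics; a nonzero intercept
#' flags normalization offsets at t = 0). `P0` is the observable at the
#' first usable time point. Points with non-positive observable values
#' (possible after noisy normalization) are excluded with a warning.
#'
#' @param tc A `timecourse` data frame (see [to_timecourse()]) or any data
#'   frame with a `t_h` column and the observable column.
#' @param observable Column to fit, e.g. `"primer"` or `"primer_gly"`.
#' @return An object of class `kobs_fit`: `k_obs` (h^-1), `se`, `intercept`,
#'   `n_points`, `n_excluded`, `residuals`.
#' @examples
#' tc <- data.frame(t_h = seq(0, 1, 0.1), primer = exp(-1.81 * seq(0, 1, 0.1)))
#' fit_kobs(tc, "primer")$k_obs
#' @export
fit_kobs <- function(tc, observable = "primer") {
  if (!observable %in% names(tc)) {
    stop("observable `", observable, "` not present in the time course",
         call. = FALSE)
  }
  t <- tc$t_h
  p <- tc[[observable]]
  keep <- is.finite(p) & p > 0
  n_excluded <- sum(!keep)
  if (n_excluded > 0L) {
    warning(sprintf(
      "excluding %d point(s) with non-positive `%s` at t = %s h",
      n_excluded, observable,
      paste(signif(t[!keep], 4), collapse = ", ")), call. = FALSE)
  }
  t <- t[keep]; p <- p[keep]
  if (length(p) < 2L) {
    stop("need at least 2 usable points to fit k_obs (have ", length(p), ")",
         call. = FALSE)
  }
  p0 <- p[which.min(t)]
  y <- -log(p / p0)
  fit <- stats::lm(y ~ t)
  # summary.lm warns on numerically perfect (noise-free) fits; harmless here
  cf <- suppressWarnings(summary(fit))$coefficients
  se <- if (nrow(cf) >= 2L && ncol(cf) >= 2L) cf["t", "Std. Error"] else
    NA_real_
  structure(list(
    k_obs = unname(stats::coef(fit)[["t"]]),
    se = unname(se),
    intercept = unname(stats::coef(fit)[["(Intercept)"]]),
    n_points = length(p),
    n_excluded = n_excluded,
    residuals = unname(stats::residuals(fit))
  ), class = "kobs_fit")
}

#' @export
print.kobs_fit <- function(x, ...) {
  cat(sprintf("k_obs = %.4g h^-1 (se %.2g, n = %d, intercept %.2g)\n",
              x$k_obs, x$se, x$n_points, x$intercept))
  invisible(x)
}

#' First-order half-life
#'
#' `t1/2 = ln(2) / k_obs` for a first-order process.
#'
#' @param k_obs Observed rate constant, h^-1, strictly positive.
#' @return Half-life in hours.
#' @export
half_life <- function(k_obs) {
  if (!is.numeric(k_obs) || any(!is.finite(k_obs)) || any(k_obs <= 0)) {
    stop("`k_obs` must be finite and > 0", call. = FALSE)
  }
  log(2) / k_obs
}

#' Fold change between two rate constants
#'
#' @param k_a,k_b Rates (h^-1); `k_b` must be > 0.
#' @return The ratio `k_a / k_b`.
#' @export
fold_change <- function(k_a, k_b) {
  if (!is.numeric(k_b) || any(!is.finite(k_b)) || any(k_b <= 0)) {
    stop("denominator rate must be finite and > 0", call. = FALSE)
  }
  k_a / k_b
}

# sum of squared residuals of the closed-form model against observed
# total primer and NP+1 fractions, pooled over all rows (replicates)
k1_ssr <- function(k1, t, primer, product, k2, k3, p_gly0, pooled) {
  s <- closed_form_core(k1, k2, k3, p_gly0, t)
  r_primer <- (s$p_gly + s$p_rna) - primer
  model_product <- if (pooled) s$p_gly1 + s$p_rna1 else s$p_gly1
  sum(r_primer^2) + sum((model_product - product)^2)
}

#' Nonlinear estimation of the aminoacyl extension rate k1
#'
#' Fits the single free parameter `k1` of the closed-form kinetic model to
#' the observed total-primer fraction (`primer` = P_gly + P_rna, one
#' co-migrating band) and the phosphoramidate +1 fraction (`np1`), jointly
#' over all time points and replicates, by minimizing the unweighted pooled
#' sum of squared residuals. `k2`, `k3` and `p_gly0` are fixed from
#' independent measurements, as in the study design. The optimizer is
#' bounded scalar least squares (`k1` in \[0, 1e4\] h^-1, L-BFGS-B) with
#' multi-starts at 0.1x, 1x and 10x a slope-based initial guess.
#'
#' @param tc A `timecourse` data frame with `t_h`, `primer` and `np1`
#'   columns (extension band map), or with a `ligated` column for ligation
#'   data (see Details).
#' @param k2 Aminoacyl ester hydrolysis rate, h^-1 (fixed).
#' @param k3 Native-RNA extension (or ligation) rate, h^-1 (fixed).
#' @param p_gly0 Initial aminoacylated fraction (fixed).
#' @return An object of class `k1_fit`: `k1`, `ssr`, `converged`,
#'   `boundary` (TRUE if the estimate sits at 0), `n_points`, the fixed
#'   inputs, `method`.
#' @details For ligation experiments the same three-species model applies
#'   with `k1` read as the aminoacyl ligation rate and `k3` as the native
#'   RNA ligation rate. The single ligated gel band pools both products:
#'   when `tc` carries a `ligated` column (and no `np1`) the model response
#'   for that band is the pooled product `p_gly1 + p_rna1`. Fits use only
#'   censored time points ([censor_ligation()]) where the native
#'   contribution is negligible, so the band is attributable to the
#'   aminoacyl pathway.
#' @export
fit_k1 <- function(tc, k2, k3, p_gly0) {
  for (col in c("t_h", "primer")) {
    if (!col %in% names(tc)) {
      stop("time course lacks required column `", col, "`", call. = FALSE)
    }
  }
  pooled <- !"np1" %in% names(tc) && "ligated" %in% names(tc)
  product_col <- if (pooled) "ligated" else "np1"
  if (!product_col %in% names(tc)) {
    stop("time course lacks a product observable (`np1` or `ligated`)",
         call. = FALSE)
  }
  if (nrow(tc) < 1L) stop("empty time course", call. = FALSE)
  rate_constants(0, k2, k3)          # validates k2, k3
  p_gly0 <- as_init(p_gly0)$p_gly0
  product <- tc[[product_col]]

  # slope-based initial guess: early-time product rise is ~ k1 * p_gly0 * t
  pos <- tc$t_h > 0 & product > 0
  guess <- if (any(pos) && p_gly0 > 0) {
    stats::median(product[pos] / (p_gly0 * tc$t_h[pos]))
  } else 1
  guess <- min(max(guess, 1e-3), 1e3)

  t_h <- tc$t_h; primer <- tc$primer
  obj <- function(k1) k1_ssr(k1, t_h, primer, product, k2, k3, p_gly0,
                             pooled)
  best <- NULL
  for (start in unique(pmin(pmax(guess * c(0.1, 1, 10), 1e-6), 1e4))) {
    res <- tryCatch(
      stats::optim(start, obj, method = "L-BFGS-B", lower = 0, upper = 1e4),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) {
      best <- res
    }
  }
  if (is.null(best)) {
    return(structure(list(
      k1 = NA_real_, ssr = NA_real_, converged = FALSE, boundary = FALSE,
      n_points = nrow(tc), k2 = k2, k3 = k3, p_gly0 = p_gly0,
      method = "closed-form nonlinear LS"), class = "k1_fit"))
  }
  structure(list(
    k1 = best$par,
    ssr = best$value,
    converged = best$convergence == 0,
    boundary = best$par <= 1e-8,
    n_points = nrow(tc),
    k2 = k2, k3 = k3, p_gly0 = p_gly0,
    method = "closed-form nonlinear LS"
  ), class = "k1_fit")
}

#' @export
print.k1_fit <- function(x, ...) {
  cat(sprintf("k1 = %.4g h^-1 (ssr %.3g, n = %d%s%s)\n", x$k1, x$ssr,
              x$n_points,
              if (!x$converged) ", NOT converged" else "",
              if (x$boundary) ", at zero boundary" else ""))
  if (!is.null(x$mc_sd)) {
    cat(sprintf("  Monte Carlo: sd %.3g, 16%%/84%% = %.4g / %.4g (%d draws)\n",
                x$mc_sd, x$q16, x$q84, x$n_draws))
  }
  invisible(x)
}

#' Uncertainty specification for Monte Carlo propagation
#'
#' Means and standard deviations of the independently measured model inputs
#' (`p_gly0`, `k2`, `k3`), the number of Monte Carlo draws, and the seed.
#'
#' @param p_gly0,k2,k3 Length-2 numeric vectors `c(mean, sd)`; sd >= 0.
#' @param n_draws Number of Monte Carlo draws (default 1000).
#' @param seed Integer seed (mandatory: propagation is stochastic).
#' @return An object of class `uncertainty_spec`.
#' @export
uncertainty_spec <- function(p_gly0, k2, k3, n_draws = 1000, seed) {
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is mandatory for Monte Carlo propagation", call. = FALSE)
  }
  for (nm in c("p_gly0", "k2", "k3")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 2L || any(!is.finite(v)) || v[2L] < 0) {
      stop("`", nm, "` must be c(mean, sd) with sd >= 0", call. = FALSE)
    }
  }
  if (!is.numeric(n_draws) || n_draws < 1) {
    stop("`n_draws` must be >= 1", call. = FALSE)
  }
  structure(list(p_gly0 = p_gly0, k2 = k2, k3 = k3,
                 n_draws = as.integer(n_draws), seed = as.integer(seed)),
            class = "uncertainty_spec")
}

# one draw from N(mean, sd) truncated to [lower, upper], by rejection;
# degenerates to the mean when sd = 0
rtruncnorm1 <- function(mean, sd, lower = 0, upper = Inf) {
  if (sd == 0) return(min(max(mean, lower), upper))
  repeat {
    x <- stats::rnorm(1L, mean, sd)
    if (x >= lower && x <= upper) return(x)
  }
}

#' Monte Carlo propagation of fixed-input uncertainty into k1
#'
#' The k1 estimate conditions on independently measured `p_gly0`, `k2` and
#' `k3`; their measurement error propagates into k1 by simulation. Each draw
#' samples the three inputs from normal distributions truncated at 0
#' (`p_gly0` also at 1) and refits k1. The reported estimate is the median
#' across draws, with the standard deviation and the 16th/84th percentiles
#' as the uncertainty. Reproducible under the seed in `spec`.
#'
#' @param tc Time course as for [fit_k1()].
#' @param spec An [uncertainty_spec()].
#' @return A `k1_fit` whose `k1` is the Monte Carlo median, with extra
#'   fields `mc_sd`, `q16`, `q84`, `n_draws`, `n_failed`, `seed`, and
#'   `point_fit` (the fit at the input means).
#' @export
mc_propagate <- function(tc, spec) {
  if (!inherits(spec, "uncertainty_spec")) {
    stop("`spec` must be an uncertainty_spec object", call. = FALSE)
  }
  point_fit <- fit_k1(tc, spec$k2[1L], spec$k3[1L], spec$p_gly0[1L])

  draws <- numeric(spec$n_draws)
  failed <- 0L
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  for (i in seq_len(spec$n_draws)) {
    p0 <- rtruncnorm1(spec$p_gly0[1L], spec$p_gly0[2L], 0, 1)
    k2 <- rtruncnorm1(spec$k2[1L], spec$k2[2L], 0)
    k3 <- rtruncnorm1(spec$k3[1L], spec$k3[2L], 0)
    f <- fit_k1(tc, k2, k3, p0)
    if (isTRUE(f$converged)) {
      draws[i] <- f$k1
    } else {
      draws[i] <- NA_real_
      failed <- failed + 1L
    }
  }
  if (failed > 0.2 * spec$n_draws) {
    stop(sprintf(
      "Monte Carlo propagation failed: %d of %d draws did not converge",
      failed, spec$n_draws), call. = FALSE)
  }
  ok <- draws[!is.na(draws)]
  out <- point_fit
  out$k1 <- stats::median(ok)
  out$mc_sd <- if (length(ok) > 1L) stats::sd(ok) else 0
  qq <- stats::quantile(ok, c(0.16, 0.84), names = FALSE, type = 7)
  out$q16 <- qq[1L]; out$q84 <- qq[2L]
  out$n_draws <- spec$n_draws
  out$n_failed <- failed
  out$seed <- spec$seed
  out$point_fit <- point_fit
  out
}

#' Censor ligation time points by the pure-RNA control
#'
#' The ligation product bands of aminoacylated and pure-RNA primers
#' co-migrate, so the single ligated band is attributable to the aminoacyl
#' pathway only while the native contribution is negligible. This keeps only
#' time points at which the pure-RNA control produced less than `threshold`
#' (default 2%) ligated product.
#'
#' @param tc_amino Aminoacyl-arm time course (any observables).
#' @param tc_rna_control Control-arm time course with a `ligated` column,
#'   on the same time grid (within 1e-6 h).
#' @param threshold Censoring threshold on the control's ligated fraction.
#' @return `tc_amino` restricted to the surviving time points (a
#'   subsequence; ordering preserved).
#' @export
censor_ligation <- function(tc_amino, tc_rna_control, threshold = 0.02) {
  if (!"ligated" %in% names(tc_rna_control)) {
    stop("control time course lacks a `ligated` observable", call. = FALSE)
  }
  ta <- sort(unique(tc_amino$t_h))
  tctl <- sort(unique(tc_rna_control$t_h))
  if (length(ta) != length(tctl) || any(abs(ta - tctl) > 1e-6)) {
    stop("aminoacyl and control time courses are not on the same time grid",
         call. = FALSE)
  }
  # worst control replicate decides: a point survives only if every control
  # lane is below threshold
  ctl_max <- vapply(split(tc_rna_control$ligated,
                          match(tc_rna_control$t_h, tctl)),
                    max, numeric(1))
  keep_t <- tctl[ctl_max < threshold]
  keep <- vapply(tc_amino$t_h,
                 function(t) any(abs(keep_t - t) <= 1e-6), logical(1))
  out <- tc_amino[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    stop("no time points survive the <", threshold * 100,
         "% control censoring rule", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}
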
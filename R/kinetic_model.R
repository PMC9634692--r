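#' Rate constants for the three-species competing-pathway model
#'
#' The model tracks four primer species on a template-saturated
#' primer-template duplex: the aminoacylated (e.g. glycyl-terminal) primer
#' `P_gly`, the native RNA primer `P_rna`, and their respective +1 extension
#' products. Three pseudo-first-order rate constants govern the dynamics:
#'
#' * `k1` — extension of the aminoacylated primer via phosphoramidate (N-P)
#'   bond formation, producing the "NP+1" product (h^-1);
#' * `k2` — hydrolysis of the labile aminoacyl ester, converting the
#'   aminoacylated primer back to native RNA primer (h^-1);
#' * `k3` — canonical phosphodiester extension of the native RNA primer,
#'   producing the "OP+1" product (h^-1).
#'
#' @param k1,k2,k3 Non-negative, finite rates in h^-1.
#' @return An object of class `rate_constants` (named list).
#' @examples
#' rate_constants(k1 = 12.0, k2 = 0.7, k3 = 0.118)
#' @export
rate_constants <- function(k1, k2, k3) {
  for (nm in c("k1", "k2", "k3")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("`", nm, "` must be a single finite non-negative number, got: ",
           deparse(v), call. = FALSE)
    }
  }
  structure(list(k1 = as.numeric(k1), k2 = as.numeric(k2),
                 k3 = as.numeric(k3)),
            class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat(sprintf("rate constants (h^-1): k1 = %g, k2 = %g, k3 = %g\n",
              x$k1, x$k2, x$k3))
  invisible(x)
}

#' Initial composition of the primer pool
#'
#' Acylation by Flexizyme is incomplete (the study's yields span 26-60%), so
#' the primer pool at t = 0 is a mixture: a fraction `p_gly0` carries the
#' aminoacyl group and the complement `1 - p_gly0` is native RNA.
#'
#' @param p_gly0 Initial aminoacylated fraction, in \[0, 1\].
#' @return An object of class `initial_composition`.
#' @export
initial_composition <- function(p_gly0) {
  if (!is.numeric(p_gly0) || length(p_gly0) != 1L || !is.finite(p_gly0) ||
      p_gly0 < 0 || p_gly0 > 1) {
    stop("`p_gly0` must be a single number in [0, 1], got: ",
         deparse(p_gly0), call. = FALSE)
  }
  structure(list(p_gly0 = as.numeric(p_gly0), p_rna0 = 1 - as.numeric(p_gly0)),
            class = "initial_composition")
}

as_rates <- function(x) {
  if (inherits(x, "rate_constants")) return(x)
  if (is.numeric(x) && length(x) == 3L) {
    return(rate_constants(x[[1L]], x[[2L]], x[[3L]]))
  }
  if (is.list(x) && all(c("k1", "k2", "k3") %in% names(x))) {
    return(rate_constants(x$k1, x$k2, x$k3))
  }
  stop("cannot interpret `rates`; supply rate_constants() or a length-3 ",
       "numeric vector (k1, k2, k3)", call. = FALSE)
}

as_init <- function(x) {
  if (inherits(x, "initial_composition")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(initial_composition(x))
  if (is.list(x) && "p_gly0" %in% names(x)) {
    return(initial_composition(x$p_gly0))
  }
  stop("cannot interpret `init`; supply initial_composition() or a single ",
       "p_gly0 fraction", call. = FALSE)
}

# relative tolerance below which k3 and k1+k2 are treated as degenerate
# (the resolvent denominator of the native-primer solution vanishes there)
.degenerate_rtol <- 1e-9

#' Closed-form solution of the competing-pathway kinetic model
#'
#' Evaluates the analytic solution of the linear first-order system
#' \deqn{dP_{gly}/dt = -(k_1 + k_2) P_{gly}}
#' \deqn{dP_{rna}/dt = k_2 P_{gly} - k_3 P_{rna}}
#' \deqn{dP_{gly+1}/dt = k_1 P_{gly}}
#' \deqn{dP_{rna+1}/dt = k_3 P_{rna}}
#' at the requested times. With `K = k1 + k2`:
#' \deqn{P_{gly}(t) = P_{gly_0} e^{-K t}}
#' \deqn{P_{gly+1}(t) = \frac{k_1}{K} P_{gly_0} (1 - e^{-K t})}
#' \deqn{P_{rna}(t) = (1 - P_{gly_0}) e^{-k_3 t} +
#'   k_2 P_{gly_0} \frac{e^{-k_3 t} - e^{-K t}}{K - k_3}}
#' and `P_{rna+1}` by mass balance. The degenerate case `k3 = K` uses the
#' analytic limit `k2 * P_gly0 * t * exp(-k3 t)` for the transfer term, and
#' `K = 0` reduces each branch to its constant limit, so the evaluation is
#' continuous across both boundaries.
#'
#' @param rates A [rate_constants()] object (or coercible).
#' @param init An [initial_composition()] object (or a single `p_gly0`).
#' @param t Non-negative time(s) in hours.
#' @return A data frame with columns `t_h`, `p_gly`, `p_rna`, `p_gly1`,
#'   `p_rna1`; fractions sum to 1 at every time.
#' @seealso [integrate_numeric()] for the numeric ODE cross-check,
#'   [branching_yield()] for the t -> Inf limit of `p_gly1`.
#' @examples
#' eval_closed_form(rate_constants(2, 1, 0.5), initial_composition(0.6), 1)
#' @export
eval_closed_form <- function(rates, init, t) {
  rates <- as_rates(rates)
  init <- as_init(init)
  if (!is.numeric(t) || length(t) < 1L || any(!is.finite(t)) || any(t < 0)) {
    stop("`t` must be finite non-negative time(s) in hours", call. = FALSE)
  }
  s <- closed_form_core(rates$k1, rates$k2, rates$k3, init$p_gly0, t)
  structure(
    data.frame(t_h = t, p_gly = s$p_gly, p_rna = s$p_rna,
               p_gly1 = s$p_gly1, p_rna1 = s$p_rna1),
    class = c("trajectory", "data.frame")
  )
}

# unchecked numeric kernel of the closed-form solution (hot path for the
# nonlinear fit and Monte Carlo propagation)
closed_form_core <- function(k1, k2, k3, p0, t) {
  K <- k1 + k2
  eK <- exp(-K * t)
  e3 <- exp(-k3 * t)
  p_gly <- p0 * eK
  p_gly1 <- if (K > 0) (k1 / K) * p0 * (1 - eK) else rep(0, length(t))

  degenerate <- abs(k3 - K) < .degenerate_rtol * max(k3, K, 1e-300)
  transfer <- if (k2 == 0 || p0 == 0) {
    rep(0, length(t))
  } else if (degenerate) {
    k2 * p0 * t * e3
  } else {
    k2 * p0 * (e3 - eK) / (K - k3)
  }
  p_rna <- (1 - p0) * e3 + transfer
  list(p_gly = p_gly, p_rna = p_rna, p_gly1 = p_gly1,
       p_rna1 = 1 - (p_gly + p_rna + p_gly1))
}

#' Simulate a species trajectory from the closed-form solutions
#'
#' Vectorized [eval_closed_form()] over a strictly increasing time grid.
#'
#' @inheritParams eval_closed_form
#' @param times Strictly increasing non-negative times (hours).
#' @return A `trajectory` data frame (one row per time).
#' @export
simulate_trajectory <- function(rates, init, times) {
  check_time_grid(times)
  eval_closed_form(rates, init, times)
}

check_time_grid <- function(times) {
  if (!is.numeric(times) || length(times) < 1L || any(!is.finite(times)) ||
      any(times < 0)) {
    stop("`times` must be nonempty, finite and non-negative", call. = FALSE)
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  invisible(times)
}

#' Numerically integrate the kinetic ODE system
#'
#' Solves the same linear system as [eval_closed_form()] with a stiff-capable
#' general-purpose integrator (`deSolve::lsoda`). This path exists as an
#' independent brute-force oracle for the closed-form solutions; analyses use
#' the closed form.
#'
#' @inheritParams simulate_trajectory
#' @param rtol,atol Solver tolerances passed to `deSolve::lsoda`.
#' @return A `trajectory` data frame on `times`.
#' @export
integrate_numeric <- function(rates, init, times, rtol = 1e-10, atol = 1e-12) {
  rates <- as_rates(rates)
  init <- as_init(init)
  check_time_grid(times)
  y0 <- c(p_gly = init$p_gly0, p_rna = init$p_rna0, p_gly1 = 0, p_rna1 = 0)
  rhs <- function(t, y, p) {
    list(c(
      -(p$k1 + p$k2) * y[1L],
      p$k2 * y[1L] - p$k3 * y[2L],
      p$k1 * y[1L],
      p$k3 * y[2L]
    ))
  }
  solve_times <- if (times[1L] > 0) c(0, times) else times
  if (length(solve_times) == 1L) {   # times = 0 alone: no integration needed
    return(structure(
      data.frame(t_h = 0, p_gly = y0[["p_gly"]], p_rna = y0[["p_rna"]],
                 p_gly1 = 0, p_rna1 = 0),
      class = c("trajectory", "data.frame")))
  }
  sol <- deSolve::lsoda(y0, solve_times, rhs, rates, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0) {
    stop(sprintf(
      "ODE solver failed for k1=%g, k2=%g, k3=%g, p_gly0=%g",
      rates$k1, rates$k2, rates$k3, init$p_gly0), call. = FALSE)
  }
  sol <- as.data.frame(sol)
  sol <- sol[sol$time %in% times, , drop = FALSE]
  structure(
    data.frame(t_h = sol$time, p_gly = sol$p_gly, p_rna = sol$p_rna,
               p_gly1 = sol$p_gly1, p_rna1 = sol$p_rna1,
               row.names = NULL),
    class = c("trajectory", "data.frame")
  )
}

#' Asymptotic phosphoramidate branching yield
#'
#' The aminoacylated primer is consumed by two competing first-order
#' pathways, extension (`k1`) and ester hydrolysis (`k2`); as t -> Inf the
#' fraction of total primer ending as phosphoramidate-linked +1 product is
#' `p_gly0 * k1 / (k1 + k2)`.
#'
#' @inheritParams eval_closed_form
#' @return A single fraction in \[0, 1\].
#' @export
branching_yield <- function(rates, init) {
  rates <- as_rates(rates)
  init <- as_init(init)
  if (rates$k1 + rates$k2 <= 0) {
    stop("branching yield undefined when k1 + k2 = 0 (the aminoacylated ",
         "primer never reacts)", call. = FALSE)
  }
  init$p_gly0 * rates$k1 / (rates$k1 + rates$k2)
}
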
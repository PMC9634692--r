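#' Format a value with one-significant-digit uncertainty in parentheses
#'
#' Compact uncertainty notation, e.g. `72(2)` for 72 +/- 2 h or `20.1(9)`
#' for 20.1 +/- 0.9 h: the uncertainty is rounded to one significant digit
#' and the value to the matching decimal place.
#'
#' @param value Point estimate.
#' @param sd Standard deviation (0 or NA suppresses the parentheses).
#' @return A character scalar.
#' @examples
#' format_uncertain(72.3, 2.1)   # "72(2)"
#' format_uncertain(20.14, 0.9)  # "20.1(9)"
#' @export
format_uncertain <- function(value, sd) {
  if (is.na(sd) || sd <= 0) return(formatC(signif(value, 3), format = "fg"))
  digits <- -floor(log10(sd))
  u <- round(sd, digits)
  if (u >= 10^(1 - digits)) digits <- digits - 1L   # 0.97 rounds to 1
  v <- round(value, digits)
  if (digits <= 0) {
    sprintf("%.0f(%.0f)", v, round(sd, digits))
  } else {
    sprintf(paste0("%.", digits, "f(%.0f)"), v, round(sd, digits) * 10^digits)
  }
}

#' Fold-change report between fitted conditions
#'
#' One row per (numerator, denominator) pair, with the ratio of estimates
#' and a first-order delta-method uncertainty assuming independent errors:
#' `sd(a/b)^2 ~ (sd_a/b)^2 + (a sd_b / b^2)^2`.
#'
#' @param rate_table Data frame with columns `condition`, `estimate`, `sd`.
#' @param pairs List of length-2 character vectors
#'   `c(numerator, denominator)`.
#' @return Data frame: `numerator`, `denominator`, `fold`, `fold_sd`.
#' @export
report_folds <- function(rate_table, pairs) {
  rows <- lapply(pairs, function(pr) {
    num <- rate_table[rate_table$condition == pr[[1L]], , drop = FALSE]
    den <- rate_table[rate_table$condition == pr[[2L]], , drop = FALSE]
    if (nrow(num) != 1L || nrow(den) != 1L) {
      stop("fold pair (", pr[[1L]], ", ", pr[[2L]],
           ") does not match exactly one rate-table row each", call. = FALSE)
    }
    if (!is.finite(den$estimate) || den$estimate <= 0) {
      stop("denominator estimate for ", pr[[2L]], " must be > 0",
           call. = FALSE)
    }
    a <- num$estimate; b <- den$estimate
    sa <- ifelse(is.na(num$sd), 0, num$sd)
    sb <- ifelse(is.na(den$sd), 0, den$sd)
    data.frame(numerator = pr[[1L]], denominator = pr[[2L]],
               fold = a / b,
               fold_sd = sqrt((sa / b)^2 + (a * sb / b^2)^2))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

parse_design <- function(x, default_seed) {
  noise <- if (!is.null(x$noise)) {
    do.call(noise_model, x$noise)
  } else {
    noise_model()
  }
  experiment_design(
    type = x$type,
    condition = x$condition,
    rates = rate_constants(x$k1 %||% 0, x$k2 %||% 0, x$k3 %||% 0),
    p_gly0 = x$p_gly0,
    times = unlist(x$times),
    replicates = x$replicates %||% 3L,
    noise = noise,
    seed = x$seed %||% default_seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a run configuration from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return The configuration list (validated by [run_pipeline()]).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    stop("config must be .yaml/.yml or .json", call. = FALSE)
  }
}

validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_config(config)
  }
  if (is.null(config$experiments) || length(config$experiments) == 0L) {
    stop("configuration error: `experiments` must list at least one ",
         "experiment", call. = FALSE)
  }
  has_synthetic <- any(vapply(config$experiments,
                              function(e) is.null(e$table), logical(1)))
  if (has_synthetic && is.null(config$seed)) {
    stop("configuration error: a global `seed` is mandatory when any ",
         "experiment is synthetic", call. = FALSE)
  }
  recipes <- vapply(config$experiments,
                    function(e) e$recipe %||% "", character(1))
  bad <- setdiff(recipes, c("kobs", "k1", "hydrolysis", "ligation"))
  if (length(bad) > 0L) {
    stop("configuration error: unknown recipe(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  nms <- vapply(config$experiments, function(e) e$name %||% "", character(1))
  if (any(!nzchar(nms)) || anyDuplicated(nms)) {
    stop("configuration error: every experiment needs a unique `name`",
         call. = FALSE)
  }
  config
}

run_one_experiment <- function(exp, seed, mc_defaults, log) {
  recipe <- exp$recipe
  fixed <- exp$fixed

  get_tc <- function(map_type) {
    if (map_type == "ligation" && !is.null(exp$table_amino)) {
      read_arm <- function(path, mt) {
        to_timecourse(read_band_table(path), band_map(mt))
      }
      log(sprintf("experiment %s: read ligation arms from disk", exp$name))
      return(list(
        amino = read_arm(exp$table_amino, "ligation"),
        control = read_arm(exp$table_control, "ligation"),
        hydrolysis = read_arm(exp$table_hydrolysis, "hydrolysis_acidic"),
        manifest = NULL))
    }
    if (!is.null(exp$table)) {
      tab <- read_band_table(exp$table)
      log(sprintf("experiment %s: read %d lanes from %s", exp$name,
                  nrow(tab), exp$table))
      return(to_timecourse(tab, band_map(map_type)))
    }
    design <- parse_design(exp$design, seed)
    if (map_type == "ligation") {
      gen <- gen_ligation_experiment(design)
      log(sprintf("experiment %s: simulated ligation arms (seed %d)",
                  exp$name, design$seed))
      return(list(
        amino = to_timecourse(gen$amino, band_map("ligation")),
        control = to_timecourse(gen$control, band_map("ligation")),
        hydrolysis = to_timecourse(gen$hydrolysis,
                                   band_map("hydrolysis_acidic")),
        manifest = gen$manifest))
    }
    gen <- if (map_type == "hydrolysis_acidic") {
      gen_hydrolysis_experiment(design)
    } else {
      gen_extension_experiment(design)
    }
    log(sprintf("experiment %s: simulated %s (seed %d)", exp$name,
                design$type, design$seed))
    attr(gen$table, "manifest") <- gen$manifest
    to_timecourse(gen$table, band_map(map_type))
  }

  if (recipe == "kobs") {
    tc <- get_tc("extension")
    fit <- fit_kobs(tc, exp$observable %||% "primer")
    log(sprintf("experiment %s: k_obs = %.4g h^-1 (n = %d, excluded %d)",
                exp$name, fit$k_obs, fit$n_points, fit$n_excluded))
    return(data.frame(condition = exp$name, parameter = "k_obs",
                      estimate = fit$k_obs, sd = fit$se,
                      n = fit$n_points, method = "log-linear",
                      half_life_h = NA_real_))
  }

  if (recipe == "hydrolysis") {
    tc <- get_tc("hydrolysis_acidic")
    fit <- fit_kobs(tc, "primer_gly")
    hl <- half_life(fit$k_obs)
    hl_sd <- if (is.na(fit$se)) NA_real_ else hl * fit$se / fit$k_obs
    log(sprintf("experiment %s: k_obs = %.4g h^-1, t1/2 = %s h", exp$name,
                fit$k_obs, format_uncertain(hl, hl_sd %||% 0)))
    return(data.frame(condition = exp$name, parameter = "k_obs",
                      estimate = fit$k_obs, sd = fit$se,
                      n = fit$n_points, method = "log-linear",
                      half_life_h = hl))
  }

  if (recipe == "k1") {
    tc <- get_tc("extension")
    if (is.null(fixed)) {
      stop("experiment ", exp$name,
           ": recipe k1 requires `fixed` (k2, k3, p_gly0)", call. = FALSE)
    }
    mc <- exp$mc %||% mc_defaults
    if (!is.null(mc)) {
      spec <- uncertainty_spec(
        p_gly0 = c(fixed$p_gly0, mc$sd_p_gly0 %||% 0),
        k2 = c(fixed$k2, mc$sd_k2 %||% 0),
        k3 = c(fixed$k3, mc$sd_k3 %||% 0),
        n_draws = mc$n_draws %||% 1000,
        seed = seed + 1L)
      fit <- mc_propagate(tc, spec)
      log(sprintf(
        "experiment %s: k1 = %.4g h^-1 (MC sd %.3g, %d draws, seed %d)",
        exp$name, fit$k1, fit$mc_sd, fit$n_draws, spec$seed))
      return(data.frame(condition = exp$name, parameter = "k1",
                        estimate = fit$k1, sd = fit$mc_sd,
                        n = fit$n_points, method = "nonlinear LS + MC",
                        half_life_h = NA_real_))
    }
    fit <- fit_k1(tc, fixed$k2, fixed$k3, fixed$p_gly0)
    log(sprintf("experiment %s: k1 = %.4g h^-1 (ssr %.3g)", exp$name,
                fit$k1, fit$ssr))
    return(data.frame(condition = exp$name, parameter = "k1",
                      estimate = fit$k1, sd = NA_real_,
                      n = fit$n_points, method = "nonlinear LS",
                      half_life_h = NA_real_))
  }

  # ligation: derive k3 from the control arm, k2 from the hydrolysis arm,
  # censor by the control, then fit k1 on the surviving points
  arms <- get_tc("ligation")
  ctl_fit <- fit_kobs(arms$control, "primer")
  hyd_fit <- fit_kobs(arms$hydrolysis, "primer_gly")
  censored <- censor_ligation(arms$amino, arms$control,
                              exp$threshold %||% 0.02)
  p0 <- fixed$p_gly0 %||% arms$manifest$p_gly0
  if (is.null(p0)) {
    stop("experiment ", exp$name, ": ligation recipe needs p_gly0 in ",
         "`fixed` (or a synthetic design manifest)", call. = FALSE)
  }
  fit <- fit_k1(censored, hyd_fit$k_obs, ctl_fit$k_obs, p0)
  log(sprintf(
    "experiment %s: ligation k1 = %.4g h^-1 (k2 = %.4g, k3 = %.4g, %d/%d points kept)",
    exp$name, fit$k1, hyd_fit$k_obs, ctl_fit$k_obs,
    length(unique(censored$t_h)), length(unique(arms$amino$t_h))))
  data.frame(condition = exp$name, parameter = "k1",
             estimate = fit$k1, sd = NA_real_,
             n = fit$n_points, method = "censored nonlinear LS",
             half_life_h = NA_real_)
}

#' Run a configuration-driven kinetic analysis
#'
#' Chains generation (or ingestion), lane normalization, fitting,
#' uncertainty propagation and reporting. The configuration (a list, or a
#' path to YAML/JSON) names experiments, each with a `recipe`:
#'
#' * `kobs` — log-linear k_obs fit on an observable;
#' * `k1` — nonlinear k1 fit on extension data, with optional Monte Carlo
#'   propagation (`mc:` block);
#' * `hydrolysis` — k_obs fit on the acidic-gel glycyl band plus half-life;
#' * `ligation` — three-arm analysis: control k3, hydrolysis k2, censoring,
#'   censored k1 fit.
#'
#' Each experiment supplies either a `table:` path to a band CSV or an
#' inline synthetic `design:`. Re-running with the same config and seed
#' reproduces identical outputs. Per-experiment failures are reported and
#' the remaining experiments still run.
#'
#' @param config A list or a path to a YAML/JSON file.
#' @param out_dir Output directory (defaults to `config$out_dir`); created
#'   if needed. `NULL` suppresses file output.
#' @param seed Optional integer overriding `config$seed`.
#' @return A list: `rates` (rate-constant table), `half_lives`, `folds`
#'   (if `fold_pairs` configured), `log` (character), `errors`.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  config <- validate_config(config)
  seed <- as.integer(seed %||% config$seed %||% 1L)
  out_dir <- out_dir %||% config$out_dir
  log_lines <- character(0)
  log <- function(msg) log_lines <<- c(log_lines, msg)
  log(sprintf("run_pipeline: %d experiment(s), global seed %d",
              length(config$experiments), seed))

  rows <- list(); errors <- list()
  for (i in seq_along(config$experiments)) {
    exp <- config$experiments[[i]]
    exp_seed <- seed + 1000L * i
    res <- tryCatch(
      run_one_experiment(exp, exp_seed, config$mc, log),
      error = function(e) e)
    if (inherits(res, "error")) {
      errors[[exp$name]] <- conditionMessage(res)
      log(sprintf("experiment %s: FAILED (%s)", exp$name,
                  conditionMessage(res)))
    } else {
      rows[[exp$name]] <- res
    }
  }
  rates <- if (length(rows) > 0L) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(condition = character(0), parameter = character(0),
               estimate = numeric(0), sd = numeric(0), n = integer(0),
               method = character(0), half_life_h = numeric(0))
  }
  rownames(rates) <- NULL

  half_lives <- rates[!is.na(rates$half_life_h), , drop = FALSE]
  if (nrow(half_lives) > 0L) {
    hl_sd <- ifelse(is.na(half_lives$sd), 0,
                    half_lives$half_life_h * half_lives$sd /
                      half_lives$estimate)
    half_lives <- data.frame(
      condition = half_lives$condition,
      k_obs = half_lives$estimate,
      half_life_h = half_lives$half_life_h,
      formatted = mapply(format_uncertain, half_lives$half_life_h, hl_sd))
    rownames(half_lives) <- NULL
  } else {
    half_lives <- data.frame(condition = character(0), k_obs = numeric(0),
                             half_life_h = numeric(0),
                             formatted = character(0))
  }

  folds <- NULL
  if (!is.null(config$fold_pairs) && nrow(rates) > 0L) {
    folds <- tryCatch(report_folds(rates, config$fold_pairs),
                      error = function(e) {
                        errors[["folds"]] <<- conditionMessage(e)
                        NULL
                      })
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(rates, file.path(out_dir, "rate_constants.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(half_lives, file.path(out_dir, "half_lives.csv"),
                     row.names = FALSE, quote = FALSE)
    if (!is.null(folds)) {
      utils::write.csv(folds, file.path(out_dir, "fold_changes.csv"),
                       row.names = FALSE, quote = FALSE)
    }
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }

  list(rates = rates, half_lives = half_lives, folds = folds,
       log = log_lines, errors = errors)
}
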
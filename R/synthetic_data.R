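#' Densitometry noise model
#'
#' Band intensities are perturbed multiplicatively (lognormal, sd on the log
#' scale) so that error scales with band size, as densitometry error does;
#' an optional additive baseline emulates residual background. Per-lane
#' loading totals are drawn lognormally (sd 0.2) around `lane_total` so that
#' lane normalization is nontrivially exercised.
#'
#' @param sd_mult Multiplicative lognormal sd per band (default 0.05).
#' @param baseline Additive baseline fraction of the lane total (default 0).
#' @param sd_loading Lognormal sd of the per-lane loading total (default
#'   0.2).
#' @param lane_total Mean raw lane total in arbitrary units (default 1e4).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sd_mult = 0.05, baseline = 0, sd_loading = 0.2,
                        lane_total = 1e4) {
  for (nm in c("sd_mult", "baseline", "sd_loading")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("`", nm, "` must be a single finite non-negative number",
           call. = FALSE)
    }
  }
  structure(list(sd_mult = sd_mult, baseline = baseline,
                 sd_loading = sd_loading, lane_total = lane_total),
            class = "noise_model")
}

no_noise <- function() noise_model(sd_mult = 0, baseline = 0, sd_loading = 0)

#' Synthetic experiment design
#'
#' Describes one simulated gel experiment: its type, condition label, true
#' rate constants, initial acylation, time grid, replicate count, noise
#' model and seed. When `p_gly0` is `NULL` it is drawn uniformly from the
#' study's observed acylation-yield range, 26-60%.
#'
#' @param type `"extension"`, `"hydrolysis_acidic"`, `"ligation"`, or
#'   `"no_template"`.
#' @param condition Condition label (e.g. `"0 mM Mg"`).
#' @param rates A [rate_constants()] object (or coercible).
#' @param p_gly0 Initial aminoacylated fraction, or `NULL` to draw from
#'   U(0.26, 0.60) at generation time.
#' @param times Strictly increasing sampling times, hours.
#' @param replicates Number of technical replicates (default 3, as in the
#'   study).
#' @param noise A [noise_model()] (default 5% multiplicative).
#' @param seed Integer seed for the generator.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(type = c("extension", "hydrolysis_acidic",
                                       "ligation", "no_template"),
                              condition, rates, p_gly0 = NULL, times,
                              replicates = 3, noise = noise_model(),
                              seed = 1L) {
  type <- match.arg(type)
  rates <- as_rates(rates)
  check_time_grid(times)
  if (!is.null(p_gly0)) p_gly0 <- as_init(p_gly0)$p_gly0
  if (!is.numeric(replicates) || replicates < 1) {
    stop("`replicates` must be >= 1", call. = FALSE)
  }
  if (!inherits(noise, "noise_model")) {
    stop("`noise` must be a noise_model object", call. = FALSE)
  }
  if (type == "hydrolysis_acidic" && (rates$k1 != 0 || rates$k3 != 0)) {
    stop("hydrolysis_acidic experiments contain no activated substrate: ",
         "k1 and k3 must be 0", call. = FALSE)
  }
  structure(list(type = type, condition = as.character(condition),
                 rates = rates, p_gly0 = p_gly0, times = as.numeric(times),
                 replicates = as.integer(replicates), noise = noise,
                 seed = as.integer(seed)),
            class = "experiment_design")
}

# per-(replicate, time) lane: true fractions -> noisy raw intensities
emit_lanes <- function(fractions, bands, design) {
  nm <- design$noise
  rows <- vector("list", design$replicates * length(design$times))
  idx <- 0L
  for (rep_i in seq_len(design$replicates)) {
    for (t_i in seq_along(design$times)) {
      idx <- idx + 1L
      total <- nm$lane_total *
        if (nm$sd_loading > 0) exp(stats::rnorm(1L, 0, nm$sd_loading)) else 1
      frac <- fractions[[t_i]]
      raw <- frac * total + nm$baseline * total
      if (nm$sd_mult > 0) {
        raw <- raw * exp(stats::rnorm(length(raw), 0, nm$sd_mult))
      }
      rows[[idx]] <- data.frame(
        condition = design$condition,
        replicate = rep_i,
        time_h = design$times[t_i],
        band = bands,
        intensity = raw,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}

resolve_p_gly0 <- function(design) {
  if (!is.null(design$p_gly0)) return(design$p_gly0)
  stats::runif(1L, 0.26, 0.60)   # the study's acylation-yield range
}

manifest_of <- function(design, p_gly0, extra = list()) {
  c(list(type = design$type, condition = design$condition,
         k1 = design$rates$k1, k2 = design$rates$k2, k3 = design$rates$k3,
         p_gly0 = p_gly0, times = design$times,
         replicates = design$replicates, seed = design$seed,
         noise = unclass(design$noise)),
    extra)
}

#' Generate a synthetic primer-extension gel experiment
#'
#' True species fractions follow the closed-form kinetic model. On the
#' standard gel the aminoacylated and native primers co-migrate, so three
#' bands are emitted per lane: `primer` (= P_gly + P_rna), `np1`
#' (phosphoramidate +1) and `op1` (phosphodiester +1). Raw intensities are
#' fractions times a random per-lane loading total, perturbed by the noise
#' model.
#'
#' @param design An [experiment_design()] with `type = "extension"` (the
#'   `"no_template"` type is also accepted: same band structure, with the
#'   design's rates understood as slow non-templated accumulation).
#' @return A list with `table` (lane table) and `manifest` (ground truth:
#'   rates, p_gly0, seed, design).
#' @export
gen_extension_experiment <- function(design) {
  if (!inherits(design, "experiment_design") ||
      !design$type %in% c("extension", "no_template")) {
    stop("`design` must be an experiment_design of type extension or ",
         "no_template", call. = FALSE)
  }
  set.seed(design$seed)
  p0 <- resolve_p_gly0(design)
  traj <- simulate_trajectory(design$rates, p0, design$times)
  fractions <- lapply(seq_len(nrow(traj)), function(i) {
    c(primer = traj$p_gly[i] + traj$p_rna[i],
      np1 = traj$p_gly1[i], op1 = traj$p_rna1[i])
  })
  tab <- emit_lanes(fractions, c("primer", "np1", "op1"), design)
  list(table = tab, manifest = manifest_of(design, p0))
}

#' Generate a synthetic acidic-gel hydrolysis experiment
#'
#' Ester hydrolysis is followed on acidic gels where the aminoacylated and
#' native primers resolve. No activated substrate is present (k1 = k3 = 0),
#' so the dynamics are a single first-order decay of `primer_gly` at `k2`
#' with `primer_rna` gaining the lost mass.
#'
#' @param design An [experiment_design()] with `type = "hydrolysis_acidic"`.
#' @return A list with `table` and `manifest`.
#' @export
gen_hydrolysis_experiment <- function(design) {
  if (!inherits(design, "experiment_design") ||
      design$type != "hydrolysis_acidic") {
    stop("`design` must be an experiment_design of type hydrolysis_acidic",
         call. = FALSE)
  }
  set.seed(design$seed)
  p0 <- resolve_p_gly0(design)
  k2 <- design$rates$k2
  fractions <- lapply(design$times, function(t) {
    g <- p0 * exp(-k2 * t)
    c(primer_gly = g, primer_rna = 1 - g)
  })
  tab <- emit_lanes(fractions, c("primer_gly", "primer_rna"), design)
  list(table = tab, manifest = manifest_of(design, p0))
}

#' Generate a synthetic three-arm ligation experiment
#'
#' Emulates the ligation study design: an aminoacyl arm evolving under
#' (k1 = aminoacyl ligation rate, k2 = ester hydrolysis, k3 = native RNA
#' ligation rate) whose two ligation products co-migrate as one `ligated`
#' band (= np1 + op1); a pure-RNA control arm (p_gly0 = 0, same k3), from
#' which k3 and the censoring rule are derived; and an acidic-gel hydrolysis
#' arm (unactivated ligator) from which k2 is measured.
#'
#' @param design An [experiment_design()] with `type = "ligation"`.
#' @return A list with `amino`, `control`, `hydrolysis` (lane tables) and
#'   `manifest`.
#' @export
gen_ligation_experiment <- function(design) {
  if (!inherits(design, "experiment_design") || design$type != "ligation") {
    stop("`design` must be an experiment_design of type ligation",
         call. = FALSE)
  }
  set.seed(design$seed)
  p0 <- resolve_p_gly0(design)

  arm <- function(suffix, seed_offset) {
    d <- design
    d$condition <- paste0(design$condition, suffix)
    d$seed <- design$seed + seed_offset
    d
  }

  traj <- simulate_trajectory(design$rates, p0, design$times)
  amino_frac <- lapply(seq_len(nrow(traj)), function(i) {
    c(primer = traj$p_gly[i] + traj$p_rna[i],
      ligated = traj$p_gly1[i] + traj$p_rna1[i])
  })
  amino <- emit_lanes(amino_frac, c("primer", "ligated"), arm("", 0L))

  ctl_traj <- simulate_trajectory(design$rates, 0, design$times)
  ctl_frac <- lapply(seq_len(nrow(ctl_traj)), function(i) {
    c(primer = ctl_traj$p_rna[i], ligated = ctl_traj$p_rna1[i])
  })
  set.seed(design$seed + 1L)
  control <- emit_lanes(ctl_frac, c("primer", "ligated"),
                        arm("_rna_control", 1L))

  hyd_design <- experiment_design(
    type = "hydrolysis_acidic",
    condition = paste0(design$condition, "_hydrolysis"),
    rates = rate_constants(0, design$rates$k2, 0),
    p_gly0 = p0, times = design$times,
    replicates = design$replicates, noise = design$noise,
    seed = design$seed + 2L)
  hydrolysis <- gen_hydrolysis_experiment(hyd_design)$table

  list(amino = amino, control = control, hydrolysis = hydrolysis,
       manifest = manifest_of(design, p0))
}

#' Generate a panel of conditions as one lane table
#'
#' Concatenates several extension/hydrolysis designs (e.g. an Mg2+ series
#' or an amino acid panel) into a single lane table with one manifest per
#' condition. Condition labels must be unique.
#'
#' @param designs A list of [experiment_design()] objects.
#' @return A list with `table` (concatenated lane table) and `manifests`
#'   (named by condition).
#' @export
gen_condition_panel <- function(designs) {
  if (!is.list(designs) || length(designs) < 1L) {
    stop("`designs` must be a nonempty list of experiment designs",
         call. = FALSE)
  }
  labels <- vapply(designs, function(d) d$condition, character(1))
  if (anyDuplicated(labels)) {
    stop("duplicate condition label(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  gens <- lapply(designs, function(d) {
    switch(d$type,
      extension = ,
      no_template = gen_extension_experiment(d),
      hydrolysis_acidic = gen_hydrolysis_experiment(d),
      stop("gen_condition_panel supports extension/no_template/",
           "hydrolysis_acidic designs; use gen_ligation_experiment for ",
           "ligation arms", call. = FALSE))
  })
  tab <- do.call(rbind, c(lapply(gens, `[[`, "table"),
                          list(make.row.names = FALSE)))
  rownames(tab) <- NULL
  manifests <- stats::setNames(lapply(gens, `[[`, "manifest"), labels)
  list(table = tab, manifests = manifests)
}
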
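#' Band-to-observable co-migration maps
#'
#' On standard (TBE) denaturing gels the aminoacylated and native primers
#' co-migrate as a single "primer" band, while the two +1 extension products
#' resolve ("np1" = phosphoramidate-linked, "op1" = phosphodiester). On
#' acidic gels used for ester-hydrolysis experiments the two primer species
#' resolve instead. In ligation experiments the two ligation products do not
#' resolve, giving a single "ligated" band. A band map records, per
#' experiment type, which raw gel bands feed each model observable.
#'
#' @param type One of `"extension"`, `"hydrolysis_acidic"`, `"ligation"`.
#' @param bands Optional named list observable -> character vector of band
#'   labels; defaults to the canonical bands of the experiment type.
#' @return An object of class `band_map`.
#' @examples
#' band_map("extension")
#' band_map("ligation", list(primer = "P", ligated = "lig"))
#' @export
band_map <- function(type = c("extension", "hydrolysis_acidic", "ligation"),
                     bands = NULL) {
  type <- match.arg(type)
  default <- switch(type,
    extension = list(primer = "primer", np1 = "np1", op1 = "op1"),
    hydrolysis_acidic = list(primer_gly = "primer_gly",
                             primer_rna = "primer_rna"),
    ligation = list(primer = "primer", ligated = "ligated")
  )
  if (is.null(bands)) bands <- default
  if (is.null(names(bands)) || any(!nzchar(names(bands)))) {
    stop("`bands` must be a named list (observable -> band labels)",
         call. = FALSE)
  }
  if (!setequal(names(bands), names(default))) {
    stop("a ", type, " band map must define exactly the observables: ",
         paste(names(default), collapse = ", "), call. = FALSE)
  }
  all_bands <- unlist(bands, use.names = FALSE)
  if (anyDuplicated(all_bands)) {
    stop("each band may be claimed by exactly one observable; duplicated: ",
         paste(unique(all_bands[duplicated(all_bands)]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(type = type, bands = lapply(bands, as.character)),
            class = "band_map")
}

check_lane_table <- function(table) {
  required <- c("condition", "replicate", "time_h", "band", "intensity")
  missing <- setdiff(required, names(table))
  if (length(missing) > 0L) {
    stop("lane table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(table) > 0L) {
    if (any(!is.finite(table$intensity)) || any(table$intensity < 0)) {
      stop("band intensities must be finite and non-negative", call. = FALSE)
    }
    if (any(!is.finite(table$time_h)) || any(table$time_h < 0)) {
      stop("times must be finite non-negative hours", call. = FALSE)
    }
    key <- paste(table$condition, table$replicate, table$time_h, table$band,
                 sep = "\r")
    if (anyDuplicated(key)) {
      dup <- table[duplicated(key), , drop = FALSE][1L, ]
      stop(sprintf(
        "duplicate (condition, replicate, time, band) row: %s / %s / %g / %s",
        dup$condition, dup$replicate, dup$time_h, dup$band), call. = FALSE)
    }
  }
  invisible(table)
}

#' Normalize one gel lane to band fractions
#'
#' Each band's integrated intensity is divided by the lane total, expressing
#' species as fractions that sum to one. This is the per-lane normalization
#' applied to every densitometry measurement before any kinetic fit.
#'
#' @param intensities Named non-negative numeric vector of raw band
#'   intensities (arbitrary units) for a single lane.
#' @return Named numeric vector of fractions summing to 1.
#' @examples
#' normalize_lane(c(a = 200, b = 200, c = 600))
#' @export
normalize_lane <- function(intensities) {
  if (!is.numeric(intensities) || length(intensities) < 1L) {
    stop("`intensities` must be a nonempty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(intensities)) || any(intensities < 0)) {
    stop("intensities must be finite and non-negative", call. = FALSE)
  }
  total <- sum(intensities)
  if (total <= 0) {
    stop("all-zero lane (", paste(names(intensities), collapse = ", "),
         "): cannot normalize", call. = FALSE)
  }
  intensities / total
}

#' Convert a lane table to observable time courses
#'
#' Lane-normalizes every (condition, replicate, time) lane and aggregates
#' band fractions into model observables through a [band_map()]. The result
#' is one long data frame with a row per lane and a column per observable.
#'
#' @param table A lane table (data frame with columns `condition`,
#'   `replicate`, `time_h`, `band`, `intensity`), e.g. from
#'   [read_band_table()] or a generator.
#' @param map A [band_map()] claiming every band present in `table`.
#' @return A `timecourse` data frame with columns `condition`, `replicate`,
#'   `t_h` and one column per observable; rows sorted by condition,
#'   replicate, time.
#' @export
to_timecourse <- function(table, map) {
  check_lane_table(table)
  if (!inherits(map, "band_map")) stop("`map` must be a band_map object",
                                       call. = FALSE)
  band2obs <- rep(names(map$bands), lengths(map$bands))
  names(band2obs) <- unlist(map$bands, use.names = FALSE)
  unmapped <- setdiff(unique(table$band), names(band2obs))
  if (length(unmapped) > 0L) {
    stop("band(s) not claimed by the band map: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  observables <- names(map$bands)

  lanes <- split(table, list(table$condition, table$replicate, table$time_h),
                 drop = TRUE)
  rows <- lapply(lanes, function(lane) {
    fr <- normalize_lane(stats::setNames(lane$intensity, lane$band))
    obs <- vapply(observables, function(o) {
      sum(fr[names(fr) %in% map$bands[[o]]])
    }, numeric(1))
    out <- data.frame(condition = lane$condition[1L],
                      replicate = lane$replicate[1L],
                      t_h = lane$time_h[1L], stringsAsFactors = FALSE)
    out[observables] <- as.list(obs)
    out
  })
  tc <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  tc <- tc[order(tc$condition, tc$replicate, tc$t_h), , drop = FALSE]
  rownames(tc) <- NULL
  structure(tc, class = c("timecourse", "data.frame"),
            experiment_type = map$type)
}

#' Read a band-intensity table from delimited text
#'
#' Expects comma-delimited UTF-8 text with the header
#' `condition,replicate,time_h,band,intensity`. Schema is validated
#' strictly; malformed rows abort with the offending line.
#'
#' @param path Path to a CSV file.
#' @return A validated lane table data frame (possibly 0 rows).
#' @export
read_band_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("condition", "replicate", "time_h", "band", "intensity")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop("band table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("time_h", "intensity")) {
    if (nrow(tab) > 0L && !is.numeric(tab[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(tab[[col]]))))[1L]
      stop(sprintf("non-numeric `%s` in %s at data line %d", col, path,
                   if (is.na(bad)) 1L else bad), call. = FALSE)
    }
  }
  check_lane_table(tab)
  tab
}

#' Write a lane table to CSV
#'
#' @param table A lane table data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_band_table <- function(table, path) {
  check_lane_table(table)
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write fit results to delimited text
#'
#' Serializes a list of fit objects ([fit_kobs()], [fit_k1()],
#' [mc_propagate()] results) to a tidy CSV with one row per fitted
#' parameter: `condition, parameter, estimate, sd, n_points, method, seed`.
#'
#' @param fits A named list of fit objects; names become condition labels
#'   unless a fit carries its own `condition`.
#' @param path Output path (`.csv`; a sibling `.json` is written too).
#' @return The tidy data frame, invisibly.
#' @export
write_results <- function(fits, path) {
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    cond <- if (!is.null(f$condition)) f$condition else names(fits)[i]
    if (inherits(f, "kobs_fit")) {
      data.frame(condition = cond, parameter = "k_obs",
                 estimate = f$k_obs, sd = f$se, n_points = f$n_points,
                 method = "log-linear", seed = NA_integer_)
    } else if (inherits(f, "k1_fit")) {
      data.frame(condition = cond, parameter = "k1",
                 estimate = f$k1, sd = if (is.null(f$mc_sd)) NA_real_ else
                   f$mc_sd,
                 n_points = f$n_points, method = f$method,
                 seed = if (is.null(f$seed)) NA_integer_ else f$seed)
    } else {
      stop("unsupported fit object at position ", i, call. = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(out, sub("\\.csv$", ".json", path),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(out)
}
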
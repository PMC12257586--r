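#' @title PARCH value computation
#' @name parch_core
#' @description
#' The PARCH value of a region is computed in three steps from its
#' water-count series eta(t): the lag autocorrelation
#' C(tau) = < eta(t) eta(t + tau) > (no mean subtraction — the product is
#' taken on the counts themselves, so a region with no water exposure has
#' C identically zero), its time-integral average
#' Cbar = (1/tau_max) * integral of C over [0, tau_max], and the normalized
#' score PV = 10 * Cbar / Cbar_ref, where Cbar_ref is the same quantity for
#' a zwitterionic-lysine reference run. The factor 10 is a fixed scale so
#' that small ratios stay readable; the reference puts nucleotides and amino
#' acids on one common hydropathy scale. A region embedded in the fold with
#' no water access has Cbar = 0 and therefore PV = 0 exactly.
NULL

# ---- configuration ---------------------------------------------------------

.eta_registry <- new.env(parent = emptyenv())
.eta_registry$identity <- function(counts) as.numeric(counts)

.combine_registry <- new.env(parent = emptyenv())
.combine_registry$mean_Cbar <- function(cbars) mean(cbars)
.combine_registry$median_Cbar <- function(cbars) stats::median(cbars)

#' Register a count-to-eta mapping
#'
#' The default mapping is the identity (eta is the raw count). Any fixed
#' linear mapping cancels between target and reference in the final ratio;
#' nonlinear alternatives can be registered by name and are then applied
#' identically to targets and reference.
#'
#' @param name mapping identifier.
#' @param fn function from a numeric count vector to a numeric eta vector.
#' @export
register_eta_mapping <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = .eta_registry)
  invisible(name)
}

#' Map a water-count series to eta
#'
#' @param counts numeric vector of per-frame water counts.
#' @param mapping registered mapping identifier (default `"identity"`).
#' @return numeric eta series.
#' @export
eta_map <- function(counts, mapping = "identity") {
  fn <- get0(mapping, envir = .eta_registry, inherits = FALSE)
  if (is.null(fn))
    stop_validation("unknown eta mapping '", mapping, "'; registered: ",
                    paste(ls(.eta_registry), collapse = ", "))
  fn(counts)
}

#' PARCH computation configuration
#'
#' @param tau_max lag horizon in ps; default half the series span. Long lags
#'   rest on few pairs and are noise-dominated, so the horizon excludes them.
#' @param eta_mapping registered mapping name.
#' @param integration_rule quadrature for the lag integral (`"trapezoid"`,
#'   exact for the piecewise-linear interpolant on the uniform lag grid).
#' @param scale the fixed factor 10 of the PARCH definition.
#' @param replicate_combine how replicate Cbar values are combined before
#'   normalization (`"mean_Cbar"` or `"median_Cbar"`).
#' @return a `parch_config`.
#' @export
parch_config <- function(tau_max = NULL, eta_mapping = "identity",
                         integration_rule = "trapezoid", scale = 10,
                         replicate_combine = "mean_Cbar") {
  if (!is.null(tau_max) && (!is.numeric(tau_max) || tau_max <= 0))
    stop_validation("tau_max must be > 0")
  if (!identical(integration_rule, "trapezoid"))
    stop_validation("unknown integration rule '", integration_rule, "'")
  if (is.null(get0(replicate_combine, envir = .combine_registry)))
    stop_validation("unknown replicate_combine '", replicate_combine, "'")
  structure(list(tau_max = tau_max, eta_mapping = eta_mapping,
                 integration_rule = integration_rule, scale = scale,
                 replicate_combine = replicate_combine),
            class = "parch_config")
}

# ---- estimators ------------------------------------------------------------

#' Lag autocorrelation of an eta series
#'
#' Estimates C(tau_k) = (1 / (N - k)) * sum_t eta_t eta_(t+k) on the uniform
#' lag grid tau_k = k * dt, k = 0 .. floor(tau_max / dt). No mean is
#' subtracted: the correlation is taken on the counts themselves, so the
#' zero-exposure case propagates to C = 0. Each lag divides by its number of
#' available pairs. Computed via FFT in O(N log N).
#'
#' @param eta numeric series (length >= 2).
#' @param dt sample spacing, ps.
#' @param tau_max lag horizon, ps; default half the series span
#'   `(N - 1) * dt / 2`; must not exceed the span.
#' @return a `parch_autocorr`: list with `lags` (ps), `C`, `n_samples`, `dt`.
#' @export
autocorrelation <- function(eta, dt, tau_max = NULL) {
  eta <- as.numeric(eta)
  n <- length(eta)
  if (n < 2L) stop_validation("degenerate series: need at least 2 samples")
  if (!is.numeric(dt) || dt <= 0) stop_validation("dt must be > 0")
  span <- (n - 1L) * dt
  tau_max <- tau_max %||% (span / 2)
  if (tau_max <= 0 || tau_max > span + 1e-9 * span)
    stop_validation("tau_max must lie in (0, (N-1)*dt]")
  kmax <- floor(tau_max / dt + 1e-9)
  # lag sums S_k = sum_t eta_t eta_(t+k) via the power spectrum
  len <- stats::nextn(2L * n, 2L)
  f <- stats::fft(c(eta, numeric(len - n)))
  s <- Re(stats::fft(f * Conj(f), inverse = TRUE)) / len
  k <- 0:kmax
  C <- s[k + 1L] / (n - k)
  structure(list(lags = k * dt, C = C, n_samples = n, dt = dt),
            class = "parch_autocorr")
}

#' Time-integral average of an autocorrelation curve
#'
#' Cbar = (1 / tau_max) * integral of C(tau) over [0, tau_max], evaluated by
#' trapezoid on the uniform lag grid (exact for the piecewise-linear
#' interpolant). Nonnegative whenever eta is nonnegative.
#'
#' @param ac a `parch_autocorr` from [autocorrelation()].
#' @return Cbar, a scalar.
#' @export
mean_autocorrelation <- function(ac) {
  lags <- ac$lags
  C <- ac$C
  if (length(lags) < 2L)
    stop_validation("quadrature needs at least 2 lag points")
  d <- diff(lags)
  if (diff(range(d)) > 1e-9 * max(d))
    stop_validation("lag grid must be uniform")
  tau_max <- lags[length(lags)] - lags[1L]
  sum((C[-1L] + C[-length(C)]) / 2 * d) / tau_max
}

#' PARCH value from a mean autocorrelation
#'
#' PV = scale * Cbar / Cbar_ref; PV is 0 exactly when Cbar is 0 (the
#' zero-exposure rule).
#'
#' @param Cbar mean autocorrelation of the target region (>= 0).
#' @param calibration a `parch_calibration` (or a positive scalar Cbar_ref).
#' @param scale the PARCH scale factor (10).
#' @return PV, a nonnegative scalar.
#' @export
parch_value <- function(Cbar, calibration, scale = 10) {
  cref <- if (inherits(calibration, "parch_calibration"))
    calibration$Cbar_ref else as.numeric(calibration)
  if (!is.numeric(cref) || length(cref) != 1L || !is.finite(cref) || cref <= 0)
    stop_validation("calibration Cbar_ref must be a positive scalar")
  if (Cbar < 0) stop_validation("Cbar must be >= 0")
  scale * Cbar / cref
}

# ---- calibration -----------------------------------------------------------

.counts_to_replicates <- function(counts) {
  # split a parch_counts frame (single region) into per-replicate series
  stopifnot(is.data.frame(counts))
  reps <- split(counts, counts$replicate)
  lapply(reps, function(df) {
    df <- df[order(df$time_ps), , drop = FALSE]
    list(counts = df$count, dt = if (nrow(df) > 1L) diff(df$time_ps[1:2]) else NA)
  })
}

.series_cbar <- function(counts, dt, config) {
  eta <- eta_map(counts, config$eta_mapping)
  ac <- autocorrelation(eta, dt, tau_max = config$tau_max)
  mean_autocorrelation(ac)
}

#' Calibrate the reference Cbar
#'
#' Runs the reference water-count series (the protocol's zwitterionic-lysine
#' run, counted at the amino-acid cutoff) through the identical
#' eta-map / autocorrelation / integral path and replicate-combination rule
#' as any target, and records provenance. A series used as both target and
#' reference therefore yields PV = 10 exactly.
#'
#' @param series reference counts: a numeric vector, a list of numeric
#'   vectors (replicates), or a `parch_counts` frame of a single region.
#' @param dt sample spacing in ps (ignored for `parch_counts` input).
#' @param config a [parch_config()].
#' @param provenance free-text description of the reference run (residue,
#'   cutoff, schedule, seed).
#' @return a `parch_calibration`: list with `Cbar_ref` and `provenance`.
#' @export
calibrate_reference <- function(series, dt = 10, config = parch_config(),
                                provenance = "zwitterionic lysine reference") {
  if (inherits(series, "parch_counts") ||
      (is.data.frame(series) && "count" %in% names(series))) {
    reps <- .counts_to_replicates(series)
    cbars <- vapply(reps, function(r) .series_cbar(r$counts, r$dt, config),
                    numeric(1L))
  } else {
    if (is.numeric(series)) series <- list(series)
    if (!length(series)) stop_validation("need at least 1 reference replicate")
    cbars <- vapply(series, function(x) .series_cbar(x, dt, config),
                    numeric(1L))
  }
  combine <- get(config$replicate_combine, envir = .combine_registry)
  cref <- combine(cbars)
  if (cref <= 0)
    stop_validation("reference series has no water exposure (Cbar_ref = 0); ",
                    "a PARCH reference must be hydrated")
  structure(list(Cbar_ref = cref,
                 provenance = list(description = provenance,
                                   n_replicates = length(cbars),
                                   replicate_Cbar = unname(cbars),
                                   config = unclass(config))),
            class = "parch_calibration")
}

#' @export
print.parch_calibration <- function(x, ...) {
  cat(sprintf("parch_calibration: Cbar_ref = %.6g (%d replicate(s)) - %s\n",
              x$Cbar_ref, x$provenance$n_replicates,
              x$provenance$description))
  invisible(x)
}

# ---- full table ------------------------------------------------------------

#' Compute the PARCH table from water-count series
#'
#' For every region in the counts: per-replicate Cbar through the eta-map /
#' autocorrelation / lag-integral path, combined across replicates (default:
#' arithmetic mean of Cbar), then normalized by the reference. Nucleotides
#' end up with two rows (BB and NB), amino acids with one (AA).
#'
#' @param counts a `parch_counts` data frame (possibly several replicates
#'   per region; all replicates of a region must share their time grid), or
#'   a path to a counts CSV.
#' @param config a [parch_config()].
#' @param calibration a `parch_calibration` from [calibrate_reference()].
#' @return a `parch_table`: data frame with columns `chain`, `resseq`,
#'   `resname`, `alpha`, `Cbar`, `PV`, carrying the config and calibration
#'   as attributes.
#' @export
compute_parch <- function(counts, config = parch_config(), calibration) {
  if (is.character(counts)) counts <- read_counts(counts)
  if (missing(calibration) || !inherits(calibration, "parch_calibration"))
    stop_validation("compute_parch needs a parch_calibration")
  combine <- get(config$replicate_combine, envir = .combine_registry)
  key <- paste(counts$chain, counts$resseq, counts$resname, counts$alpha,
               sep = "\r")
  rows <- lapply(split(seq_len(nrow(counts)),
                       factor(key, levels = unique(key))), function(i) {
    df <- counts[i, , drop = FALSE]
    reps <- .counts_to_replicates(df)
    grids <- lapply(split(df$time_ps, df$replicate), sort)
    if (length(unique(vapply(grids, length, 1L))) != 1L ||
        (length(grids) > 1L &&
         max(vapply(grids[-1L], function(g)
           max(abs(g - grids[[1L]])), numeric(1L))) > 1e-6))
      stop_validation("replicate time grids differ for region ",
                      df$chain[1L], ":", df$resseq[1L], ":", df$alpha[1L])
    cbars <- vapply(reps, function(r) .series_cbar(r$counts, r$dt, config),
                    numeric(1L))
    cbar <- combine(cbars)
    data.frame(chain = df$chain[1L], resseq = df$resseq[1L],
               resname = df$resname[1L], alpha = df$alpha[1L],
               Cbar = cbar,
               PV = parch_value(cbar, calibration, scale = config$scale),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("parch_table", "data.frame")
  attr(out, "config") <- config
  attr(out, "calibration") <- calibration
  out
}

#' Write / read a PARCH table
#'
#' The on-disk form is the reporting layout of the scale: one row per
#' residue with `PV_BB`, `PV_NB` columns for nucleotides and `PV_AA` for
#' amino acids.
#'
#' @param table a `parch_table`.
#' @param file CSV path.
#' @export
write_parch_table <- function(table, file) {
  wide <- parch_table_wide(table)
  utils::write.csv(wide, file, row.names = FALSE, na = "")
  invisible(file)
}

#' @rdname write_parch_table
#' @export
read_parch_table <- function(file) {
  if (!file.exists(file)) stop_io("no such file: ", file)
  wide <- utils::read.csv(file, stringsAsFactors = FALSE)
  long <- do.call(rbind, lapply(seq_len(nrow(wide)), function(i) {
    r <- wide[i, ]
    alphas <- c(BB = "PV_BB", NB = "PV_NB", AA = "PV_AA")
    alphas <- alphas[alphas %in% names(wide)]
    keep <- !is.na(unlist(r[alphas]))
    if (!any(keep)) return(NULL)
    data.frame(chain = as.character(r$chain), resseq = r$resseq,
               resname = r$resname, alpha = names(alphas)[keep],
               Cbar = NA_real_, PV = unlist(r[alphas])[keep],
               stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL
  class(long) <- c("parch_table", "data.frame")
  long
}

#' @rdname write_parch_table
#' @export
parch_table_wide <- function(table) {
  key <- paste(table$chain, table$resseq, table$resname, sep = "\r")
  rows <- lapply(split(seq_len(nrow(table)),
                       factor(key, levels = unique(key))), function(i) {
    df <- table[i, , drop = FALSE]
    pv <- function(a) if (a %in% df$alpha) df$PV[df$alpha == a][1L] else NA_real_
    data.frame(chain = df$chain[1L], resseq = df$resseq[1L],
               resname = df$resname[1L], PV_BB = pv("BB"), PV_NB = pv("NB"),
               PV_AA = pv("AA"), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.parch_table <- function(x, n = 10L, ...) {
  cat("parch_table:", nrow(x), "region scores\n")
  print.data.frame(utils::head(x, n))
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more rows\n")
  invisible(x)
}
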
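#' Acquisition grid for an MRS experiment
#'
#' Describes the sampling of a free induction decay (FID): dwell time,
#' number of complex points, spectrometer frequency and the chemical-shift
#' (ppm) value assigned to the zero-frequency offset. All frequency and
#' ppm axes derived from a grid place frequency zero at the centre bin
#' (ascending-ppm convention).
#'
#' @param dwell_time seconds per FID sample (> 0).
#' @param n_points number of complex samples per FID (>= 2).
#' @param spectrometer_freq spectrometer frequency in MHz.
#' @param ppm_reference ppm value at zero frequency offset.
#' @return an object of class `acquisition_grid`.
#' @export
acquisition_grid <- function(dwell_time, n_points, spectrometer_freq,
                             ppm_reference = 4.65) {
  if (!is.numeric(dwell_time) || length(dwell_time) != 1 || dwell_time <= 0)
    stop_domain("dwell_time must be a positive scalar")
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 2)
    stop_domain("n_points must be an integer >= 2")
  if (!is.numeric(spectrometer_freq) || spectrometer_freq <= 0)
    stop_domain("spectrometer_freq must be positive (MHz)")
  structure(list(dwell_time = dwell_time, n_points = n_points,
                 spectrometer_freq = spectrometer_freq,
                 ppm_reference = ppm_reference),
            class = "acquisition_grid")
}

#' FID time axis tau (seconds)
#' @param grid an [acquisition_grid()].
#' @return numeric vector of length `n_points`.
#' @export
time_axis <- function(grid) {
  (seq_len(grid$n_points) - 1) * grid$dwell_time
}

#' Frequency axis (Hz offsets, ascending, fftshifted)
#'
#' Spans the bandwidth `1/dwell_time` with zero offset at the centre bin
#' (`floor(n/2) + 1`, 1-based).
#' @param grid an [acquisition_grid()].
#' @return numeric vector of length `n_points`.
#' @export
freq_axis <- function(grid) {
  n <- grid$n_points
  ((seq_len(n) - 1) - floor(n / 2)) / (n * grid$dwell_time)
}

#' ppm axis (ascending), affine in the frequency axis
#' @param grid an [acquisition_grid()].
#' @return numeric vector of length `n_points`.
#' @export
ppm_axis <- function(grid) {
  grid$ppm_reference + freq_axis(grid) / grid$spectrometer_freq
}

#' A series of complex FID transients sharing one acquisition grid
#'
#' @param transients complex matrix, one row per transient (dynamic time
#'   point), `n_points` columns.
#' @param grid an [acquisition_grid()].
#' @param labels optional character vector of transient identifiers.
#' @return an object of class `fid_series`.
#' @export
fid_series <- function(transients, grid, labels = NULL) {
  if (is.null(dim(transients))) transients <- matrix(transients, nrow = 1)
  if (!is.complex(transients)) transients <- transients + 0i
  if (ncol(transients) != grid$n_points)
    stop_shape(sprintf("transients have %d columns but grid has %d points",
                       ncol(transients), grid$n_points))
  if (nrow(transients) < 1) stop_shape("need at least one transient")
  if (!is.null(labels) && length(labels) != nrow(transients))
    stop_shape("labels length must equal number of transients")
  structure(list(transients = transients, grid = grid, labels = labels),
            class = "fid_series")
}

#' @export
print.fid_series <- function(x, ...) {
  cat(sprintf("<fid_series> %d transients x %d points, dwell %.3g s, %.5g MHz\n",
              nrow(x$transients), x$grid$n_points, x$grid$dwell_time,
              x$grid$spectrometer_freq))
  invisible(x)
}

#' Number of transients in a series
#' @param x an [fid_series()].
#' @export
n_transients <- function(x) nrow(x$transients)

#' A named basis set of complex metabolite FIDs
#'
#' @param fids complex matrix, one row per metabolite (`K x n_points`).
#' @param names character vector of unique metabolite names.
#' @param grid an [acquisition_grid()] shared with the data.
#' @param groups optional map metabolite name -> metabolite-group label;
#'   metabolites in the same group share Lorentzian broadening (gamma) and
#'   frequency shift (eps). Default: one group per metabolite.
#' @param per_timepoint optional list of per-condition basis sets (each a
#'   `basis_set` with identical names) for condition-dependent bases, e.g.
#'   spectral editing.
#' @return an object of class `basis_set`.
#' @export
basis_set <- function(fids, names, grid, groups = NULL, per_timepoint = NULL) {
  if (is.null(dim(fids))) fids <- matrix(fids, nrow = 1)
  if (!is.complex(fids)) fids <- fids + 0i
  if (length(names) != nrow(fids))
    stop_shape("names length must match number of basis FIDs")
  if (anyDuplicated(names)) stop_format("duplicate metabolite names in basis")
  if (ncol(fids) != grid$n_points)
    stop_shape("basis FIDs do not match grid n_points")
  if (is.null(groups)) {
    groups <- stats::setNames(names, names)
  } else {
    groups <- unlist(groups)
    if (!all(names %in% base::names(groups)))
      stop_format("every metabolite name needs a group assignment")
    groups <- groups[names]
  }
  if (!is.null(per_timepoint)) {
    for (b in per_timepoint) {
      if (!identical(b$names, names))
        stop_format("per-condition basis sets must share identical names")
    }
  }
  rownames(fids) <- names
  structure(list(names = names, fids = fids, grid = grid,
                 groups = groups, per_timepoint = per_timepoint),
            class = "basis_set")
}

#' @export
print.basis_set <- function(x, ...) {
  cat(sprintf("<basis_set> %d metabolites (%d groups)%s\n", length(x$names),
              length(unique(x$groups)),
              if (!is.null(x$per_timepoint))
                sprintf(", %d conditions", length(x$per_timepoint)) else ""))
  invisible(x)
}

#' Group labels and 0-based group index of a basis set
#' @keywords internal
basis_group_index <- function(basis) {
  labs <- unique(unname(basis$groups))
  idx <- match(unname(basis$groups), labs) - 1L
  list(labels = labs, index = idx)
}

#' Per-transient experimental covariates (the "time variable")
#'
#' Holds the experimental design leading to dynamic changes: a stimulus
#' design matrix for functional MRS, b-values and gradient directions for
#' diffusion-weighted MRS, or arbitrary covariates.
#'
#' @param columns data.frame (or named list of equal-length vectors), one
#'   row per transient.
#' @param kind one of "design_matrix", "bval_bvec", "custom"; inferred
#'   from column names when `NULL` (`b`,`gx`,`gy`,`gz` present implies
#'   `bval_bvec`).
#' @return an object of class `time_variable`.
#' @export
time_variable <- function(columns, kind = NULL) {
  columns <- as.data.frame(columns)
  if (nrow(columns) < 1) stop_shape("time variable needs at least one row")
  if (is.null(kind)) {
    kind <- if (all(c("b", "gx", "gy", "gz") %in% names(columns)))
      "bval_bvec" else "design_matrix"
  }
  if (kind == "bval_bvec") {
    if (!all(c("b", "gx", "gy", "gz") %in% names(columns)))
      stop_format("bval_bvec time variable requires columns b, gx, gy, gz")
    if (any(columns$b < 0)) stop_domain("b-values must be >= 0")
    gn <- sqrt(columns$gx^2 + columns$gy^2 + columns$gz^2)
    bad <- columns$b > 0 & abs(gn - 1) > 1e-8
    if (any(bad)) {
      warning("normalizing non-unit gradient directions at b > 0")
      columns$gx[bad] <- columns$gx[bad] / gn[bad]
      columns$gy[bad] <- columns$gy[bad] / gn[bad]
      columns$gz[bad] <- columns$gz[bad] / gn[bad]
    }
  }
  structure(list(columns = columns, kind = kind), class = "time_variable")
}

#' @export
print.time_variable <- function(x, ...) {
  cat(sprintf("<time_variable> kind=%s, T=%d, columns: %s\n", x$kind,
              nrow(x$columns), paste(names(x$columns), collapse = ", ")))
  invisible(x)
}
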
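# Readers/writers: JSON header + TSV complex matrix as the canonical
# interchange dialect; per-metabolite JSON basis files; TSV time
# variables and results; minimal NIfTI-MRS read/write as convenience.

fmt_num <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)

#' Write an FID series as JSON header + TSV complex matrix
#'
#' Creates `<stem>.json` (acquisition grid and labels) and `<stem>.tsv`
#' (one row per transient; alternating `re_i`/`im_i` columns).
#'
#' @param x an [fid_series()].
#' @param stem output path stem (without extension).
#' @return the stem, invisibly.
#' @export
write_fid_series <- function(x, stem) {
  hdr <- list(dwell_time = x$grid$dwell_time, n_points = x$grid$n_points,
              spectrometer_freq = x$grid$spectrometer_freq,
              ppm_reference = x$grid$ppm_reference,
              n_transients = nrow(x$transients))
  if (!is.null(x$labels)) hdr$transient_labels <- x$labels
  jsonlite::write_json(hdr, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  n <- x$grid$n_points
  M <- matrix(0, nrow(x$transients), 2L * n)
  M[, seq(1, 2 * n, by = 2)] <- Re(x$transients)
  M[, seq(2, 2 * n, by = 2)] <- Im(x$transients)
  colnames(M) <- as.vector(rbind(paste0("re_", seq_len(n) - 1L),
                                 paste0("im_", seq_len(n) - 1L)))
  utils::write.table(apply(M, 2, fmt_num), paste0(stem, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(stem)
}

#' Read an FID series (JSON+TSV stem or minimal NIfTI-MRS)
#'
#' @param path a stem written by [write_fid_series()] (with or without
#'   the `.json`/`.tsv` extension), or a `.nii` NIfTI-MRS file.
#' @return an [fid_series()].
#' @export
read_fid_series <- function(path) {
  if (grepl("\\.nii$", path)) return(read_nifti_mrs(path))
  stem <- sub("\\.(json|tsv)$", "", path)
  jf <- paste0(stem, ".json"); tf <- paste0(stem, ".tsv")
  if (!file.exists(jf)) stop_format(sprintf("missing header file %s", jf))
  hdr <- jsonlite::fromJSON(jf)
  for (f in c("dwell_time", "n_points", "spectrometer_freq"))
    if (is.null(hdr[[f]])) stop_format(sprintf("header lacks field '%s'", f))
  grid <- acquisition_grid(hdr$dwell_time, hdr$n_points,
                           hdr$spectrometer_freq,
                           hdr$ppm_reference %||% 4.65)
  M <- as.matrix(utils::read.table(tf, header = TRUE, sep = "\t"))
  if (ncol(M) != 2L * grid$n_points)
    stop_shape(sprintf("row length %d does not match 2 x n_points = %d",
                       ncol(M), 2L * grid$n_points))
  tr <- M[, seq(1, ncol(M), by = 2), drop = FALSE] +
    1i * M[, seq(2, ncol(M), by = 2), drop = FALSE]
  fid_series(tr, grid, labels = hdr$transient_labels)
}

# ---- basis sets ------------------------------------------------------------

write_basis_entry <- function(name, fid, grid, group, dir) {
  jsonlite::write_json(
    list(name = name, dwell_time = grid$dwell_time,
         n_points = grid$n_points,
         spectrometer_freq = grid$spectrometer_freq,
         ppm_reference = grid$ppm_reference, group = group,
         fid_re = Re(fid), fid_im = Im(fid)),
    file.path(dir, paste0(name, ".json")), auto_unbox = TRUE, digits = NA)
}

#' Write a basis set as a directory of per-metabolite JSON files
#'
#' Per-condition bases (`per_timepoint`) go to subdirectories named
#' `cond01`, `cond02`, ...
#'
#' @param basis a [basis_set()].
#' @param dir output directory (created if needed).
#' @export
write_basis <- function(basis, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(basis$per_timepoint)) {
    for (i in seq_along(basis$names))
      write_basis_entry(basis$names[i], basis$fids[i, ], basis$grid,
                        unname(basis$groups[i]), dir)
  } else {
    for (ci in seq_along(basis$per_timepoint)) {
      sub <- file.path(dir, sprintf("cond%02d", ci))
      dir.create(sub, showWarnings = FALSE)
      b <- basis$per_timepoint[[ci]]
      for (i in seq_along(b$names))
        write_basis_entry(b$names[i], b$fids[i, ], b$grid,
                          unname(b$groups[i]), sub)
    }
  }
  invisible(dir)
}

read_basis_dir_flat <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  if (!length(files)) stop_format(sprintf("no basis JSON files in %s", dir))
  entries <- lapply(files, jsonlite::fromJSON)
  g0 <- entries[[1]]
  for (e in entries) {
    if (abs(e$dwell_time - g0$dwell_time) > 1e-15 ||
        e$n_points != g0$n_points ||
        abs(e$spectrometer_freq - g0$spectrometer_freq) > 1e-12)
      stop_format("basis entries have incompatible dwell/points/frequency")
  }
  nms <- vapply(entries, function(e) e$name, "")
  if (anyDuplicated(nms)) stop_format("duplicate metabolite name in basis")
  ord <- order(nms)
  entries <- entries[ord]; nms <- nms[ord]
  grid <- acquisition_grid(g0$dwell_time, g0$n_points, g0$spectrometer_freq,
                           g0$ppm_reference %||% 4.65)
  fids <- t(vapply(entries, function(e) complex(real = e$fid_re,
                                                imaginary = e$fid_im),
                   complex(g0$n_points)))
  groups <- stats::setNames(vapply(entries, function(e) e$group %||% e$name,
                                   ""), nms)
  basis_set(fids, nms, grid, groups = groups)
}

#' Read a basis set from a directory (or single JSON file)
#'
#' A directory with subdirectories is read as a per-condition basis
#' (sorted subdirectory order, e.g. `OFF`, `ON`); names must match across
#' conditions. Metabolites are sorted by name for determinism.
#'
#' @param path basis directory or single JSON file.
#' @return a [basis_set()].
#' @export
read_basis <- function(path) {
  if (!dir.exists(path)) {
    if (!file.exists(path)) stop_format(sprintf("no such basis: %s", path))
    e <- jsonlite::fromJSON(path)
    grid <- acquisition_grid(e$dwell_time, e$n_points, e$spectrometer_freq,
                             e$ppm_reference %||% 4.65)
    return(basis_set(matrix(complex(real = e$fid_re, imaginary = e$fid_im),
                            nrow = 1),
                     e$name, grid,
                     groups = stats::setNames(e$group %||% e$name, e$name)))
  }
  subs <- sort(list.dirs(path, recursive = FALSE))
  if (length(subs) == 0) return(read_basis_dir_flat(path))
  conds <- lapply(subs, read_basis_dir_flat)
  for (b in conds[-1])
    if (!identical(b$names, conds[[1]]$names))
      stop_format("per-condition basis names differ between conditions")
  first <- conds[[1]]
  basis_set(first$fids, first$names, first$grid, groups = first$groups,
            per_timepoint = conds)
}

# ---- time variables --------------------------------------------------------

#' Read a time variable from a delimited table
#'
#' One row per transient, named columns. `kind` is inferred from column
#' names (`b`,`gx`,`gy`,`gz` imply `bval_bvec`) unless given.
#'
#' @param path TSV/CSV file path.
#' @param kind optional kind override.
#' @param n_transients optional expected T (validated when given).
#' @return a [time_variable()].
#' @export
read_time_variable <- function(path, kind = NULL, n_transients = NULL) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep)
  if (!is.null(n_transients) && nrow(df) != n_transients)
    stop_shape(sprintf("time variable has %d rows, expected %d", nrow(df),
                       n_transients))
  time_variable(df, kind = kind)
}

#' Write a time variable
#' @param tvar a [time_variable()].
#' @param path output TSV path.
#' @export
write_time_variable <- function(tvar, path) {
  utils::write.table(tvar$columns, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a results table (estimates, uncertainties, diagnostics) as TSV
#' @param res a [results_table()].
#' @param path output TSV path.
#' @export
write_results <- function(res, path) {
  df <- data.frame(parameter = names(res$par), estimate = unname(res$par),
                   sd = if (!is.null(res$uncertainties))
                     unname(res$uncertainties) else NA_real_)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- minimal NIfTI-MRS -----------------------------------------------------
# Just enough NIfTI-1 to round-trip single-voxel MRS: singleton spatial
# dims, dim4 = FID samples, dim5 = transients, complex64/128 data, and a
# JSON header extension (ecode 44) carrying SpectrometerFrequency (MHz)
# and dwell time in pixdim[4]. Not a conformant implementation.

#' Write a minimal NIfTI-MRS file
#' @param x an [fid_series()].
#' @param path output `.nii` path.
#' @export
write_nifti_mrs <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  n <- x$grid$n_points; T_n <- nrow(x$transients)
  json <- jsonlite::toJSON(list(SpectrometerFrequency = x$grid$spectrometer_freq,
                                ResonantNucleus = "1H",
                                PpmReference = x$grid$ppm_reference),
                           auto_unbox = TRUE)
  ext_raw <- charToRaw(as.character(json))
  esize <- 8L + length(ext_raw)
  esize <- as.integer(ceiling(esize / 16) * 16)
  pad <- esize - 8L - length(ext_raw)
  vox_offset <- 352L + esize

  writeBin(348L, con, size = 4)                     # sizeof_hdr
  writeBin(raw(36), con)                            # unused
  writeBin(as.integer(c(5, 1, 1, 1, n, T_n, 1, 1)), con, size = 2) # dim
  writeBin(raw(14), con)                            # intent etc.
  writeBin(as.integer(1792), con, size = 2)         # datatype complex128
  writeBin(as.integer(128), con, size = 2)          # bitpix
  writeBin(as.integer(0), con, size = 2)            # slice_start
  writeBin(c(0, 1, 1, 1, x$grid$dwell_time, 0, 0, 0), con, size = 4) # pixdim
  writeBin(as.numeric(vox_offset), con, size = 4)   # vox_offset
  writeBin(raw(348 - 112), con)                     # rest of header zeroed
  seek(con, 344)
  writeBin(charToRaw("n+1"), con); writeBin(raw(1), con)  # magic
  writeBin(as.integer(c(1, 0, 0, 0)), con, size = 1)      # extension flag
  writeBin(as.integer(c(esize, 44)), con, size = 4)       # esize, ecode
  writeBin(ext_raw, con)
  if (pad > 0) writeBin(raw(pad), con)
  dat <- as.vector(t(x$transients))                 # column-major: tau fastest
  inter <- as.vector(rbind(Re(dat), Im(dat)))
  writeBin(inter, con, size = 8)
  invisible(path)
}

#' Read a minimal NIfTI-MRS file
#' @param path `.nii` path with singleton spatial dimensions.
#' @return an [fid_series()].
#' @export
read_nifti_mrs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_size <- readBin(con, "integer", 1, size = 4)
  if (hdr_size != 348) stop_format("not a NIfTI-1 file (sizeof_hdr != 348)")
  seek(con, 40)
  dims <- readBin(con, "integer", 8, size = 2)
  if (any(dims[2:4] != 1))
    stop_format("only singleton spatial dimensions are supported")
  n <- dims[5]; T_n <- max(dims[6], 1L)
  seek(con, 70)
  datatype <- readBin(con, "integer", 1, size = 2)
  if (!datatype %in% c(32L, 1792L))
    stop_format("unsupported datatype (need complex64/complex128)")
  seek(con, 76)
  pixdim <- readBin(con, "numeric", 8, size = 4)
  dwell <- pixdim[5]
  vox_offset <- readBin(con, "numeric", 1, size = 4)
  seek(con, 348)
  ext_flag <- readBin(con, "integer", 4, size = 1)
  sf <- NA_real_; ppm_ref <- 4.65
  if (length(ext_flag) >= 1 && ext_flag[1] == 1) {
    esize <- readBin(con, "integer", 1, size = 4)
    ecode <- readBin(con, "integer", 1, size = 4)
    raw_js <- readBin(con, "raw", esize - 8L)
    js <- tryCatch(jsonlite::fromJSON(rawToChar(raw_js[raw_js != as.raw(0)])),
                   error = function(e) NULL)
    if (!is.null(js)) {
      sf <- js$SpectrometerFrequency[1] %||% NA_real_
      ppm_ref <- js$PpmReference %||% 4.65
    }
  }
  if (is.na(sf)) stop_format("missing SpectrometerFrequency header extension")
  seek(con, vox_offset)
  sz <- if (datatype == 1792L) 8L else 4L
  vals <- readBin(con, "numeric", 2L * n * T_n, size = sz)
  cx <- vals[seq(1, length(vals), 2)] + 1i * vals[seq(2, length(vals), 2)]
  tr <- t(matrix(cx, nrow = n))
  fid_series(tr, acquisition_grid(dwell, n, sf, ppm_ref))
}
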
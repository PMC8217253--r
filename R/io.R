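## Plain-text readers and writers for the four techniques' data formats:
## 3/4-column reflectivity ASCII, QCM-D CSV (+ YAML step sidecar),
## force-volume directories (index.yaml + two-column ramp files) and
## ellipsometry CSV series. All writers emit self-describing headers.

#' Write a reflectivity measurement as ASCII
#'
#' Columns: Q (Angstrom^-1), R, dR and dQ (FWHM). Header comments name the
#' contrast and solvent SLD.
#'
#' @param meas a [contrast_measurement()].
#' @param file output path.
#' @export
write_reflectivity <- function(meas, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# contrast: %s", meas$contrast$name),
    sprintf("# solvent_sld: %.4f", meas$contrast$solvent_sld),
    sprintf("# d2o_volume_fraction: %.4f", meas$contrast$d2o_volume_fraction),
    "# columns: Q(A^-1) R dR dQ_FWHM"), con)
  utils::write.table(
    data.frame(meas$q, meas$reflectivity, meas$dr, meas$dq_over_q * meas$q),
    con, row.names = FALSE, col.names = FALSE)
}

#' Read a reflectivity ASCII file
#'
#' Accepts whitespace- or comma-separated 3/4-column data (Q, R, dR and
#' optionally dQ FWHM); `#` lines are comments. Contrast metadata is taken from the
#' header if present, else from the `contrast` argument.
#'
#' @param file path.
#' @param contrast optional [contrast_definition()] override.
#' @param dq_over_q fallback relative resolution for 3-column files.
#' @return a [contrast_measurement()].
#' @export
read_reflectivity <- function(file, contrast = NULL, dq_over_q = 0.04) {
  lines <- readLines(file)
  hdr <- grep("^#", lines, value = TRUE)
  get_hdr <- function(key) {
    m <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (!length(m)) return(NULL)
    trimws(sub(paste0("^#\\s*", key, ":"), "", m[1]))
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  body <- gsub(",", " ", body)
  dat <- utils::read.table(text = body)
  if (is.null(contrast)) {
    sld <- as.numeric(get_hdr("solvent_sld"))
    frac <- as.numeric(get_hdr("d2o_volume_fraction"))
    nm <- get_hdr("contrast")
    if (is.null(sld) || is.null(frac))
      stop("file has no contrast header; supply `contrast`", call. = FALSE)
    contrast <- contrast_definition(if (is.null(nm)) "unnamed" else nm,
                                    sld, frac)
  }
  dq <- if (ncol(dat) >= 4) mean(dat[[4]] / dat[[1]]) else dq_over_q
  contrast_measurement(dat[[1]], dat[[2]], dat[[3]], dq, contrast)
}

#' Write a QCM-D trace as CSV (+ YAML step sidecar)
#'
#' On-disk convention: overtone-normalised frequency shifts (df_raw/n),
#' columns `time_s, f3, d3, f5, d5, f7, d7`. Step annotations go to
#' `<file>.steps.yaml` unless `steps_file` is given.
#'
#' @param trace a [qcmd_trace()].
#' @param file CSV path.
#' @param steps_file optional sidecar path.
#' @export
write_qcmd_csv <- function(trace, file, steps_file = NULL) {
  df <- sweep(trace$df, 2, trace$overtones, "/")  # raw -> normalised
  out <- data.frame(time_s = trace$time)
  for (k in seq_along(trace$overtones)) {
    out[[paste0("f", trace$overtones[k])]] <- df[, k]
    out[[paste0("d", trace$overtones[k])]] <- trace$dd[, k]
  }
  utils::write.csv(out, file, row.names = FALSE)
  if (!is.null(trace$steps)) {
    if (is.null(steps_file)) steps_file <- paste0(file, ".steps.yaml")
    yaml::write_yaml(list(steps = lapply(seq_len(nrow(trace$steps)),
      function(i) list(label = trace$steps$label[i],
                       start = trace$steps$start[i]))), steps_file)
  }
}

#' Read a QCM-D CSV trace (+ YAML step sidecar)
#'
#' @param file CSV path (normalised df convention; converted to raw
#'   internally).
#' @param steps_file sidecar path (default `<file>.steps.yaml` if present).
#' @return a [qcmd_trace()].
#' @export
read_qcmd_csv <- function(file, steps_file = NULL) {
  dat <- utils::read.csv(file)
  f_cols <- grep("^f[0-9]+$", names(dat), value = TRUE)
  overtones <- as.integer(sub("^f", "", f_cols))
  df <- as.matrix(dat[f_cols])
  df <- sweep(df, 2, overtones, "*")              # normalised -> raw
  dd <- as.matrix(dat[paste0("d", overtones)])
  steps <- NULL
  if (is.null(steps_file) && file.exists(paste0(file, ".steps.yaml")))
    steps_file <- paste0(file, ".steps.yaml")
  if (!is.null(steps_file) && file.exists(steps_file)) {
    y <- yaml::read_yaml(steps_file)
    steps <- data.frame(
      label = vapply(y$steps, `[[`, character(1), "label"),
      start = vapply(y$steps, function(s) as.numeric(s$start), numeric(1)),
      stringsAsFactors = FALSE)
  }
  qcmd_trace(dat$time_s, df, dd, overtones = overtones, steps = steps)
}

#' Write a force-volume dataset to a directory
#'
#' Layout: `index.yaml` (grid shape, scan size, speed, ramp file list),
#' `reference.txt` and one two-column `ramp_NNNN.txt` (piezo_nm, signal_V)
#' per ramp.
#'
#' @param fv a [gen_force_volume()]-style list (`ramps`, `reference`,
#'   `grid_shape`).
#' @param dir output directory (created).
#' @param scan_size_um,speed_um_s metadata for the index.
#' @export
write_force_volume <- function(fv, dir, scan_size_um = 2, speed_um_s = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("ramp_%04d.txt", seq_along(fv$ramps))
  yaml::write_yaml(list(grid_shape = as.integer(fv$grid_shape),
                        scan_size_um = scan_size_um,
                        speed_um_s = speed_um_s,
                        reference = "reference.txt",
                        ramps = files), file.path(dir, "index.yaml"))
  wr <- function(r, f) utils::write.table(
    data.frame(r$piezo_z, r$signal), f, row.names = FALSE, col.names = FALSE)
  wr(fv$reference, file.path(dir, "reference.txt"))
  for (i in seq_along(fv$ramps)) wr(fv$ramps[[i]], file.path(dir, files[i]))
}

#' Read a force-volume directory
#'
#' @param dir directory written by [write_force_volume()].
#' @return list `ramps`, `reference`, `grid_shape`.
#' @export
read_force_volume <- function(dir) {
  idx <- yaml::read_yaml(file.path(dir, "index.yaml"))
  rd <- function(f) {
    d <- utils::read.table(file.path(dir, f))
    force_ramp(d[[1]], d[[2]])
  }
  list(ramps = lapply(idx$ramps, rd), reference = rd(idx$reference),
       grid_shape = unlist(idx$grid_shape))
}

#' Write / read an ellipsometry CSV series
#'
#' Columns `time_s, n_f, d_f_nm` (processed mode) or
#' `time_s, psi_deg, delta_deg` (raw mode).
#'
#' @param series data frame from [gen_ellipsometry()] or equivalent.
#' @param file path.
#' @export
write_ellipsometry_csv <- function(series, file) {
  out <- series
  names(out) <- sub("^time$", "time_s", names(out))
  names(out) <- sub("^d_f$", "d_f_nm", names(out))
  names(out) <- sub("^psi$", "psi_deg", names(out))
  names(out) <- sub("^delta$", "delta_deg", names(out))
  utils::write.csv(out, file, row.names = FALSE)
}

#' @rdname write_ellipsometry_csv
#' @return `read_ellipsometry_csv`: a data frame with columns `time` plus
#'   `n_f, d_f` or `psi, delta`.
#' @export
read_ellipsometry_csv <- function(file) {
  dat <- utils::read.csv(file)
  names(dat) <- sub("^time_s$", "time", names(dat))
  names(dat) <- sub("^d_f_nm$", "d_f", names(dat))
  names(dat) <- sub("^psi_deg$", "psi", names(dat))
  names(dat) <- sub("^delta_deg$", "delta", names(dat))
  dat
}
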
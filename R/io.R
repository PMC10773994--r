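#' Read a tip-angle trajectory from CSV
#'
#' Schema-flexible reader for delimited trajectory tables. Column aliases
#' are resolved case-insensitively (`time`/`t`/`hours`/`time_h` and
#' `theta_tip`/`tip_angle`/`theta`/`angle`; `theta_gz0`/`gz0_angle`;
#' `length`/`length_mm`/`l`), and can be overridden with `hints`. Leading
#' comment lines of the form `# key: value` are parsed as metadata; the
#' keys `angle_unit` (`rad`/`deg`) and `time_unit` (`h`/`min`) trigger unit
#' conversion on read. Internally angles are radians and times hours.
#'
#' @param path CSV file path.
#' @param hints Optional named list overriding column mapping and units,
#'   e.g. `list(time = "frame_hours", theta_tip = "tip", angle_unit = "deg")`.
#' @return A trajectory tibble with the parsed metadata in the `metadata`
#'   attribute.
#' @export
read_trajectory <- function(path, hints = NULL) {
  meta <- read_metadata(path)
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  if (nrow(df) == 0) {
    abort("Empty trajectory file.", class = "gravitroot_invalid_format")
  }
  nm <- tolower(names(df))
  pick <- function(key, aliases) {
    if (!is.null(hints[[key]])) {
      hit <- which(nm == tolower(hints[[key]]))
    } else {
      hit <- which(nm %in% aliases)
    }
    if (length(hit) == 0) NA_integer_ else hit[1]
  }
  i_time <- pick("time", c("time", "t", "hours", "time_h", "time_hours"))
  i_tip <- pick("theta_tip", c("theta_tip", "tip_angle", "theta", "angle",
                               "angle_tip", "tip"))
  if (is.na(i_time) || is.na(i_tip)) {
    abort(sprintf(
      "Required trajectory columns not found. Need a time and a tip-angle column; file has: %s.",
      paste(names(df), collapse = ", ")
    ), class = "gravitroot_invalid_format")
  }
  i_gz0 <- pick("theta_gz0", c("theta_gz0", "gz0_angle", "angle_gz0", "gz0"))
  i_len <- pick("length", c("length", "length_mm", "l", "organ_length"))
  angle_unit <- tolower(hints[["angle_unit"]] %||% meta[["angle_unit"]] %||% "rad")
  time_unit <- tolower(hints[["time_unit"]] %||% meta[["time_unit"]] %||% "h")
  afac <- if (angle_unit %in% c("deg", "degree", "degrees")) pi / 180 else 1
  tfac <- if (time_unit %in% c("min", "minute", "minutes")) 1 / 60 else 1
  traj <- tip_trajectory(
    df[[i_time]] * tfac, df[[i_tip]] * afac,
    theta_gz0 = if (!is.na(i_gz0)) df[[i_gz0]] * afac else NULL,
    length_mm = if (!is.na(i_len)) df[[i_len]] else NULL
  )
  attr(traj, "metadata") <- meta
  traj
}

read_metadata <- function(path) {
  lines <- readLines(path, n = 50, warn = FALSE)
  metas <- grep("^#", lines, value = TRUE)
  out <- list()
  for (m in metas) {
    m <- sub("^#\\s*", "", m)
    kv <- strsplit(m, ":", fixed = TRUE)[[1]]
    if (length(kv) >= 2) {
      out[[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = ":"))
    }
  }
  out
}

#' Write a tip-angle trajectory to CSV
#'
#' Writes radians and hours (declared in the metadata header) so that
#' write/read round-trips are exact to floating-point printing precision.
#'
#' @param traj A trajectory tibble.
#' @param path Output path.
#' @param metadata Named list written as `# key: value` header lines.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, metadata = list()) {
  traj <- as_tip_trajectory(traj)
  metadata <- modifyList(list(angle_unit = "rad", time_unit = "h"), metadata)
  header <- sprintf("# %s: %s", names(metadata), unlist(metadata))
  body <- readr::format_csv(traj)
  writeLines(c(header, sub("\n$", "", body)), path)
  invisible(path)
}

#' Read / write a curvature kymograph
#'
#' Long-format CSV with columns `time_h`, `s_mm`, `kappa_per_mm` and
#' optionally `length_mm`; masked cells (beyond the organ tip) are simply
#' absent from the file and stay absent — never zero-filled — after
#' reading. Write followed by read is the identity.
#'
#' @param kymo Long kymograph tibble (`time_h`, `s_mm`, `kappa`, optional
#'   `length_mm`).
#' @param path File path.
#' @return `write_kymograph()`: `path`, invisibly. `read_kymograph()`: the
#'   kymograph tibble.
#' @export
write_kymograph <- function(kymo, path) {
  check_kymograph(kymo)
  out <- tibble(time_h = kymo$time_h, s_mm = kymo$s_mm,
                kappa_per_mm = kymo$kappa)
  if (!is.null(kymo[["length_mm"]])) out$length_mm <- kymo$length_mm
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_kymograph
#' @export
read_kymograph <- function(path) {
  df <- tryCatch(
    readr::read_csv(path, comment = "#", show_col_types = FALSE),
    error = function(e) {
      abort("Unreadable kymograph file.", class = "gravitroot_invalid_format")
    }
  )
  if (nrow(df) == 0 || !all(c("time_h", "s_mm", "kappa_per_mm") %in% names(df))) {
    abort(sprintf(
      "A kymograph file needs columns time_h, s_mm, kappa_per_mm; found: %s.",
      paste(names(df), collapse = ", ")
    ), class = "gravitroot_invalid_format")
  }
  out <- tibble(time_h = df$time_h, s_mm = df$s_mm, kappa = df$kappa_per_mm)
  if (!is.null(df[["length_mm"]])) out$length_mm <- df$length_mm
  check_kymograph(out)
  out
}

#' Serialise a response summary to JSON
#'
#' @param summary A one-row tibble from [response_summary()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_report <- function(summary, path) {
  jsonlite::write_json(as.list(summary), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
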
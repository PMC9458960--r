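#' Write a reference motion to CSV
#'
#' The file starts with a `# treadgait-motion v1` schema header and
#' `# key: value` metadata lines (speed, cycle duration, mode), followed by
#' one CSV row per phase sample.  Numbers are written with shortest
#' round-trip precision, so a save/load round trip preserves every field.
#'
#' @param motion A `reference_motion`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_motion <- function(motion, path) {
  if (!all(c("phase") %in% names(motion)))
    abort("not a reference motion (missing `phase`).",
          class = "treadgait_schema_error")
  meta <- c(
    "# treadgait-motion v1",
    sprintf("# speed: %.17g", attr(motion, "speed")),
    sprintf("# cycle_duration: %.17g", attr(motion, "cycle_duration")),
    sprintf("# mode: %s", attr(motion, "mode") %||% "walk"),
    sprintf("# seed: %d", attr(motion, "seed") %||% 1L))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.table(.format_full(motion), con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# shortest round-trip decimal representation per column
.format_full <- function(df) {
  as.data.frame(lapply(df, function(col) {
    if (is.double(col)) vapply(col, function(v) format(v, digits = 17),
                               character(1))
    else col
  }), check.names = FALSE)
}

#' Read a reference motion from CSV
#'
#' @param path Path to a file written by [write_motion()].
#' @return A `reference_motion` tibble.
#' @export
read_motion <- function(path) {
  if (!file.exists(path))
    abort(paste0("cannot read motion file: ", path), class = "treadgait_io_error")
  lines <- tryCatch(readLines(path, n = 50L), error = function(e)
    abort(paste0("cannot read motion file: ", path), class = "treadgait_io_error"))
  if (length(lines) == 0)
    abort("motion file is empty.", class = "treadgait_io_error")
  if (!identical(lines[1], "# treadgait-motion v1"))
    abort("missing `# treadgait-motion v1` schema header.",
          class = "treadgait_schema_error")
  meta_lines <- grep("^# [a-z_]+: ", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^# ", "", ml)
    key <- sub(":.*$", "", kv)
    meta[[key]] <- sub("^[a-z_]+: ", "", kv)
  }
  dat <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (nrow(dat) == 0)
    abort("motion file has no data rows.", class = "treadgait_schema_error")
  need <- c("phase", paste0("ang_", .joint_names), paste0("vel_", .joint_names),
            "root_x", "root_z", "root_pitch")
  missing_cols <- setdiff(need, names(dat))
  if (length(missing_cols) > 0)
    abort(paste0("motion file is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "treadgait_schema_error")
  structure(dat,
            speed = as.numeric(meta$speed),
            cycle_duration = as.numeric(meta$cycle_duration),
            mode = meta$mode %||% "walk",
            seed = as.integer(meta$seed %||% 1L),
            class = c("reference_motion", class(tibble())))
}
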
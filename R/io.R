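#' Write a labeled trace/spectrum set as delimited text
#'
#' Comma-separated dialect with `#`-prefixed comment lines: the header
#' comments carry labels and split flags (one token per trace), the
#' first column is the variable axis (time in ps or frequency in THz)
#' and each further column one sample.
#'
#' @param data a [spectral_set].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_set_csv <- function(data, path) {
  stopifnot(inherits(data, "spectral_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# thzfb spectral_set axis_unit=%s", data$axis_unit),
    sprintf("# labels: %s", paste(data$labels, collapse = ",")),
    sprintf("# split: %s", paste(data$split, collapse = ","))
  ), con)
  tab <- cbind(data$variable_axis, t(data$features))
  utils::write.table(tab, con, sep = ",", row.names = FALSE,
                     col.names = c("axis", paste0("s", seq_len(nrow(data$features)))))
  invisible(path)
}

#' Read a delimited-text set written by [write_set_csv()]
#'
#' @param path file path.
#' @return A [spectral_set].
#' @export
read_set_csv <- function(path) {
  lines <- readLines(path, n = 16L)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    ln <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    if (!length(ln)) stop_invalid(sprintf("missing '# %s:' header", key))
    strsplit(sub(sprintf("^# %s:\\s*", key), "", ln[1]), ",")[[1]]
  }
  unit <- sub(".*axis_unit=([A-Za-z]+).*", "\\1",
              grep("axis_unit=", hdr, value = TRUE)[1])
  tab <- utils::read.csv(path, comment.char = "#")
  spectral_set(t(as.matrix(tab[, -1L, drop = FALSE])),
               labels = get_field("labels"),
               variable_axis = tab[[1L]],
               split = get_field("split"),
               axis_unit = unit)
}

#' Save / load a dataset as a grouped container
#'
#' Serializes the set as a single-file container with named datasets
#' `time` (or `frequency`), `traces`, `labels`, `split` using R's native
#' serialization.
#'
#' @param data a [spectral_set].
#' @param path file path (conventionally `.rds`).
#' @return `path` invisibly; `read_set_container()` returns the set.
#' @export
write_set_container <- function(data, path) {
  stopifnot(inherits(data, "spectral_set"))
  axis_name <- if (data$axis_unit == "ps") "time" else "frequency"
  obj <- list(traces = data$features, labels = as.character(data$labels),
              split = data$split, axis_unit = data$axis_unit,
              metadata = data$metadata)
  obj[[axis_name]] <- data$variable_axis
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_set_container
#' @export
read_set_container <- function(path) {
  obj <- readRDS(path)
  axis <- if (!is.null(obj$time)) obj$time else obj$frequency
  spectral_set(obj$traces, obj$labels, axis, obj$split,
               axis_unit = obj$axis_unit, metadata = obj$metadata)
}

#' Save / load an image cube as a grouped container
#'
#' Datasets `cube` (nx x ny x n_time) and `time`, with attributes
#' `dx_mm`, `dy_mm`.
#'
#' @param cube a [thz_cube].
#' @param path file path.
#' @return `path` invisibly; `read_cube_container()` returns the cube.
#' @export
write_cube_container <- function(cube, path) {
  stopifnot(inherits(cube, "thz_cube"))
  saveRDS(list(cube = cube$cube, time = cube$time,
               dx_mm = cube$dx_mm, dy_mm = cube$dy_mm), path)
  invisible(path)
}

#' @rdname write_cube_container
#' @export
read_cube_container <- function(path) {
  obj <- readRDS(path)
  thz_cube(obj$cube, obj$time, dx_mm = obj$dx_mm, dy_mm = obj$dy_mm)
}

#' Export a grayscale map
#'
#' `write_map_csv()` writes the values as plain delimited text;
#' `write_map_png()` writes an 8-bit grayscale PNG (values are rescaled
#' to the observed range unless the map is already windowed to [0, 1]).
#'
#' @param map a `grayscale_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(map, path) {
  stopifnot(inherits(map, "grayscale_map"))
  utils::write.table(map$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_map_csv
#' @export
write_map_png <- function(map, path) {
  stopifnot(inherits(map, "grayscale_map"))
  v <- map$values
  rng <- range(v)
  if (!is.null(map$window)) {
    v01 <- pmin(pmax(v, 0), 1)
  } else if (rng[2] > rng[1]) {
    v01 <- (v - rng[1]) / (rng[2] - rng[1])
  } else {
    v01 <- v * 0
  }
  png::writePNG(v01, path)
  invisible(path)
}
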
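#' Write an en-face stack as multi-page TIFF plus YAML sidecar
#'
#' Channels are interleaved ImageJ-style (tracer plane 1, autofluorescence
#' plane 1, tracer plane 2, ...), 16-bit.  Intensities are scaled into
#' the 16-bit range; the scale factor and the physical voxel spacings go
#' in a YAML sidecar so the round trip is lossless to 16-bit
#' quantization.
#'
#' @param stack An `enface_stack`.
#' @param tiff_path Output TIFF path.
#' @param yaml_path Output sidecar path (default: TIFF path with
#'   `.yaml`).
#' @return Invisibly, the sidecar metadata list.
#' @export
write_enface_stack <- function(stack, tiff_path,
                               yaml_path = sub("\\.tiff?$", ".yaml",
                                               tiff_path)) {
  stopifnot(inherits(stack, "enface_stack"))
  scale <- max(stack$tracer, stack$auto, 1e-12)
  n_z <- dim(stack$tracer)[3]
  pages <- vector("list", 2 * n_z)
  for (i in seq_len(n_z)) {
    pages[[2 * i - 1]] <- pmin(stack$tracer[, , i] / scale, 1)
    pages[[2 * i]] <- pmin(stack$auto[, , i] / scale, 1)
  }
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 16L)
  meta <- list(channels = c("tracer", "autofluorescence"),
               interleave = "imagej",
               pixel_size_xy_um = stack$pixel_size_xy,
               z_spacing_um = stack$z_spacing,
               x_origin_um = min(stack$x_um) - 0.5 * stack$pixel_size_xy,
               intensity_scale = scale)
  yaml::write_yaml(meta, yaml_path)
  invisible(meta)
}

#' Read an en-face stack written by [write_enface_stack()]
#'
#' @param tiff_path TIFF path.
#' @param yaml_path Sidecar path.
#' @return An `enface_stack`.
#' @export
read_enface_stack <- function(tiff_path,
                              yaml_path = sub("\\.tiff?$", ".yaml",
                                              tiff_path)) {
  meta <- yaml::read_yaml(yaml_path)
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  n_z <- length(pages) / 2
  d <- dim(pages[[1]])
  tracer <- array(0, c(d[1], d[2], n_z))
  auto <- array(0, c(d[1], d[2], n_z))
  for (i in seq_len(n_z)) {
    tracer[, , i] <- pages[[2 * i - 1]] * meta$intensity_scale
    auto[, , i] <- pages[[2 * i]] * meta$intensity_scale
  }
  px <- meta$pixel_size_xy_um
  structure(
    list(tracer = tracer, auto = auto, pixel_size_xy = px,
         z_spacing = meta$z_spacing_um,
         x_um = meta$x_origin_um + ((seq_len(d[1]) - 1) + 0.5) * px,
         y_um = ((seq_len(d[2]) - 1) + 0.5) * px),
    class = "enface_stack")
}

#' Write / read an uptake profile as CSV
#'
#' Columns `x_um`, `intensity`, `n_pixels`.
#'
#' @param profile An `uptake_profile`.
#' @param path CSV path.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  df <- utils::read.csv(path)
  structure(df, class = c("uptake_profile", "data.frame"))
}

#' Write / read a Doppler trace as CSV
#'
#' Columns `t_s`, `v_cm_s`; the sample rate is recovered from the time
#' axis on read.
#'
#' @param trace A `doppler_trace`.
#' @param path CSV path.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(data.frame(t_s = trace$t_s, v_cm_s = trace$v_cm_s),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  structure(df, sample_rate = 1 / stats::median(diff(df$t_s)),
            class = c("doppler_trace", "data.frame"))
}

#' Write / read a surface scalar field as CSV
#'
#' Columns `s_um`, `theta_rad`, `value_pa`.
#'
#' @param field data.frame with `s_um`, `theta_rad`, `value`.
#' @param path CSV path.
#' @export
write_field_csv <- function(field, path) {
  utils::write.csv(data.frame(s_um = field$s_um,
                              theta_rad = field$theta_rad,
                              value_pa = field$value),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(path) {
  df <- utils::read.csv(path)
  data.frame(s_um = df$s_um, theta_rad = df$theta_rad,
             value = df$value_pa)
}

#' Write / read a lumen geometry as centerline + contour CSV files
#'
#' The centerline CSV has columns `x_um`, `y_um`, `z_um`; the contour
#' CSV has `station`, `s_um`, `vx_um`, `vy_um` (vertices in the local
#' cross-section plane, in station order).
#'
#' @param geometry A `lumen_geometry`.
#' @param centerline_path,contours_path CSV paths.
#' @export
write_geometry_csv <- function(geometry, centerline_path, contours_path) {
  cl <- geometry$centerline
  utils::write.csv(data.frame(x_um = cl[, 1], y_um = cl[, 2],
                              z_um = cl[, 3]),
                   centerline_path, row.names = FALSE)
  rows <- lapply(seq_along(geometry$contours), function(i) {
    cc <- geometry$contours[[i]]
    data.frame(station = i, s_um = geometry$s[i],
               vx_um = cc[, 1], vy_um = cc[, 2])
  })
  utils::write.csv(do.call(rbind, rows), contours_path, row.names = FALSE)
  invisible(NULL)
}

#' @rdname write_geometry_csv
#' @export
read_geometry_csv <- function(centerline_path, contours_path) {
  cl <- utils::read.csv(centerline_path)
  cc <- utils::read.csv(contours_path)
  stations <- sort(unique(cc$station))
  contours <- lapply(stations, function(i) {
    sub <- cc[cc$station == i, ]
    cbind(sub$vx_um, sub$vy_um)
  })
  s <- vapply(stations, function(i) cc$s_um[cc$station == i][1], 0)
  structure(
    list(centerline = as.matrix(cl), s = s, contours = contours,
         station_spacing = if (length(s) > 1) diff(s)[1] else NA_real_),
    class = "lumen_geometry")
}

#' Write ground truth (or any report) as JSON
#'
#' @param x A list (matrices are stored as nested arrays).
#' @param path JSON path.
#' @export
write_truth_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' Read a YAML run configuration
#'
#' @param path YAML path.
#' @return A named list.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)
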
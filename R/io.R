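#' Read and write event streams as CSV
#'
#' Plain-text interchange format with header `t_us,x,y,p`; integer fields
#' round-trip bit-exactly.
#'
#' @param events An [event_stream()].
#' @param path File path.
#' @return `write_event_csv()` the path invisibly; `read_event_csv()` an
#'   [event_stream()] (sensor shape recovered from `sensor_shape` or from
#'   the event extent when not supplied).
#' @export
write_event_csv <- function(events, path) {
  readr::write_csv(tibble::as_tibble(events)[, c("t_us", "x", "y", "p")],
                   path)
  invisible(path)
}

#' @rdname write_event_csv
#' @param sensor_shape Optional `c(rows, cols)` for the reconstructed stream.
#' @export
read_event_csv <- function(path, sensor_shape = NULL) {
  ev <- readr::read_csv(path, col_types = readr::cols(
    t_us = readr::col_integer(), x = readr::col_integer(),
    y = readr::col_integer(), p = readr::col_integer()))
  if (is.null(sensor_shape)) {
    sensor_shape <- if (nrow(ev)) c(max(ev$y) + 1L, max(ev$x) + 1L) else
      c(1L, 1L)
  }
  event_stream(ev$t_us, ev$x, ev$y, ev$p, sensor_shape = sensor_shape)
}

#' Serialize configuration objects to a flat key-value file
#'
#' Writes `key = value` lines (SI units, meters and seconds) for an
#' [optical_config()], [lens_stack()] and/or [sweep_profile()];
#' `read_dff_config()` reconstructs the objects.
#'
#' @param path File path.
#' @param cfg,stack,profile Objects to serialize (any may be `NULL`).
#' @return The path invisibly; for the reader, a list with elements `cfg`,
#'   `stack`, `profile` (present when found in the file).
#' @export
write_dff_config <- function(path, cfg = NULL, stack = NULL, profile = NULL) {
  fmt <- function(prefix, obj) {
    vapply(names(obj), function(nm) {
      v <- obj[[nm]]
      sprintf("%s.%s = %s", prefix, nm, paste(format(v, digits = 17),
                                              collapse = " "))
    }, character(1))
  }
  lines <- character()
  if (!is.null(cfg)) lines <- c(lines, fmt("optics", unclass(cfg)))
  if (!is.null(stack)) lines <- c(lines, fmt("lens", unclass(stack)))
  if (!is.null(profile)) lines <- c(lines, fmt("sweep", unclass(profile)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_dff_config
#' @export
read_dff_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- trimws(vapply(kv, function(p) paste(p[-1], collapse = "="), ""))
  get <- function(prefix) {
    sel <- startsWith(keys, paste0(prefix, "."))
    out <- lapply(vals[sel], function(v) {
      parts <- strsplit(v, " +")[[1]]
      num <- suppressWarnings(as.numeric(parts))
      if (any(is.na(num))) parts else num
    })
    names(out) <- sub(paste0("^", prefix, "\\."), "", keys[sel])
    out
  }
  res <- list()
  o <- get("optics")
  if (length(o)) {
    res$cfg <- optical_config(f_eq = o$f_eq, N = o$N, alpha = o$alpha,
                              pixel_pitch = o$pixel_pitch,
                              sensor_shape = o$sensor_shape,
                              event_threshold_n = o$event_threshold_n)
  }
  l <- get("lens")
  if (length(l)) {
    res$stack <- lens_stack(f_ll_range = l$f_ll_range, f_offset = l$f_offset,
                            f_objective = l$f_objective,
                            D_cam_obj = l$D_cam_obj)
  }
  s <- get("sweep")
  if (length(s)) {
    res$profile <- sweep_profile(t_start = s$t_start, t_end = s$t_end,
                                 d_start = s$d_start, d_end = s$d_end,
                                 shape = s$shape, period = s$period)
  }
  res
}

#' Depth-map writers
#'
#' `write_depth_csv()` writes the depth matrix as plain CSV (meters, empty
#' cells where invalid). `write_depth_png()` writes a 16-bit grayscale PNG
#' scaled to the valid depth range, with the scale recorded in a sidecar
#' text file (`<path>.scale.txt`) so metric depth can be recovered.
#' `write_depth_color_png()` writes a display rendering on a perceptually
#' uniform ramp with near depths warm and far depths cool.
#'
#' @param dm A [assemble_depth_map()] result.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_depth_csv <- function(dm, path) {
  m <- depth_matrix(dm)
  utils::write.table(m, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_depth_csv
#' @export
write_depth_png <- function(dm, path) {
  m <- depth_matrix(dm)
  rng <- range(m, na.rm = TRUE)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  img <- (m - rng[1]) / scale
  img[is.na(img)] <- 0
  write_png16_gray(img, path)
  writeLines(c(sprintf("depth_min_m = %.9g", rng[1]),
               sprintf("depth_max_m = %.9g", rng[2]),
               "encoding = value/65535 * (depth_max_m - depth_min_m) + depth_min_m",
               "invalid = 0"),
             paste0(path, ".scale.txt"))
  invisible(path)
}

# Minimal 16-bit grayscale PNG encoder (the installed raster writers only
# emit 8-bit). Input in [0, 1]; one IDAT chunk, filter type 0 per scanline.
write_png16_gray <- function(img, path) {
  stopifnot(is.matrix(img), all(img >= 0 & img <= 1))
  vals <- round(t(img) * 65535) # PNG scans row-major
  hi <- as.raw(floor(vals / 256))
  lo <- as.raw(vals %% 256)
  h <- ncol(vals); w <- nrow(vals)
  scan <- matrix(raw(1), 2 * w + 1, h) # leading filter byte per scanline
  # interleave hi/lo per pixel, row by row
  for (r in seq_len(h)) {
    idx <- (r - 1) * w + seq_len(w)
    scan[2 * seq_len(w), r] <- hi[idx]
    scan[2 * seq_len(w) + 1, r] <- lo[idx]
  }
  idat <- memCompress(as.vector(scan), type = "gzip")
  u32 <- function(x) as.raw(c(x %/% 16777216, x %/% 65536 %% 256,
                              x %/% 256 %% 256, x %% 256))
  chunk <- function(type, data) {
    body <- c(charToRaw(type), data)
    c(u32(length(data)), body, u32(png_crc32(body)))
  }
  ihdr <- c(u32(w), u32(h), as.raw(c(16, 0, 0, 0, 0))) # 16-bit grayscale
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)), con)
  writeBin(chunk("IHDR", ihdr), con)
  writeBin(chunk("IDAT", idat), con)
  writeBin(chunk("IEND", raw(0)), con)
  invisible(path)
}

png_crc_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      tab <<- vapply(0:255, function(n) {
        c <- n
        for (k in 1:8) {
          c <- if (bitwAnd(c, 1L) == 1L) {
            bitwXor(bitwShiftR(c, 1L), -306674912L) # 0xEDB88320 as signed
          } else bitwShiftR(c, 1L)
        }
        c
      }, integer(1))
    }
    tab
  }
})

png_crc32 <- function(bytes) {
  tab <- png_crc_table()
  crc <- -1L # 0xFFFFFFFF
  for (b in as.integer(bytes)) {
    crc <- bitwXor(tab[bitwAnd(bitwXor(crc, b), 255L) + 1L],
                   bitwShiftR(crc, 8L))
  }
  crc <- bitwXor(crc, -1L)
  if (crc < 0) crc + 4294967296 else crc
}

#' @rdname write_depth_csv
#' @export
write_depth_color_png <- function(dm, path) {
  m <- depth_matrix(dm)
  rng <- range(m, na.rm = TRUE)
  u <- (m - rng[1]) / max(diff(rng), .Machine$double.eps)
  pal <- grDevices::hcl.colors(256, "Plasma") # index 1 = warm, for near
  idx <- pmin(pmax(round(u * 255) + 1, 1), 256)
  rgb <- grDevices::col2rgb(pal[idx]) / 255
  arr <- array(0, c(nrow(m), ncol(m), 3))
  arr[, , 1] <- matrix(rgb[1, ], nrow(m))
  arr[, , 2] <- matrix(rgb[2, ], nrow(m))
  arr[, , 3] <- matrix(rgb[3, ], nrow(m))
  for (ch in 1:3) {
    layer <- arr[, , ch]
    layer[is.na(m)] <- 0
    arr[, , ch] <- layer
  }
  png::writePNG(arr, target = path)
  invisible(path)
}

#' Write OUT spike times as CSV
#'
#' One row per spike, columns `neuron_id` (row-major pixel index within the
#' ROI) and `t_us`. Requires a run with `record = "full"`.
#'
#' @param rec An [run_network()] result (with `record = "full"`).
#' @param path Output path.
#' @export
write_spike_csv <- function(rec, path) {
  sp <- attr(rec, "out_spikes")
  if (is.null(sp)) {
    abort("no spike record: run the network with record = \"full\".")
  }
  readr::write_csv(dplyr::transmute(sp, neuron_id = .data$pixel,
                                    t_us = as.integer(round(.data$t_us))),
                   path)
  invisible(path)
}
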
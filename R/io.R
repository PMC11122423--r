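# Image-stack and table I/O.
#
# No TIFF package is available in the target R environment, so a minimal
# baseline-TIFF codec is implemented here: little-endian, uncompressed,
# one strip per page, grayscale, 16-bit unsigned or 32-bit float. This
# covers everything the simulator writes and what typical sSMLM raw stacks
# contain; it is not a general-purpose TIFF reader.

.TIFF_TAGS <- c(ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
                Compression = 259L, Photometric = 262L, StripOffsets = 273L,
                RowsPerStrip = 278L, StripByteCounts = 279L,
                SampleFormat = 339L)

#' Write a multi-page grayscale TIFF stack
#'
#' @param images list of numeric matrices (all same size), or one matrix.
#' @param path output path.
#' @param bits 32 (IEEE float, default) or 16 (unsigned integer, values
#'   rounded and clamped at 0..65535).
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(images, path, bits = 32L) {
  if (is.matrix(images)) images <- list(images)
  stopifnot(length(images) >= 1, bits %in% c(16L, 32L))
  con <- file(path, "wb")
  on.exit(close(con))
  wr2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  wr4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  # header
  writeBin(charToRaw("II"), con)
  wr2(42L)
  n1 <- nrow(images[[1]])
  n2 <- ncol(images[[1]])
  bytes_px <- bits / 8L
  data_len <- n1 * n2 * bytes_px
  n_entries <- length(.TIFF_TAGS)
  ifd_len <- 2L + n_entries * 12L + 4L
  # layout per page: [pixel data][IFD]
  first_ifd <- 8L + data_len
  wr4(first_ifd)
  offset <- 8L
  for (p in seq_along(images)) {
    m <- images[[p]]
    if (nrow(m) != n1 || ncol(m) != n2)
      stop("all pages must have identical dimensions")
    # pixel data, row-major (TIFF scanlines)
    v <- as.vector(t(m))
    if (bits == 16L) {
      v <- pmin(pmax(round(v), 0), 65535)
      # writeBin has no unsigned 16-bit: map to signed range
      vi <- as.integer(v)
      vi[vi > 32767L] <- vi[vi > 32767L] - 65536L
      writeBin(vi, con, size = 2, endian = "little")
    } else {
      writeBin(as.numeric(v), con, size = 4, endian = "little")
    }
    data_off <- offset
    ifd_off <- offset + data_len
    next_ifd <- if (p < length(images)) ifd_off + ifd_len + data_len else 0L
    # IFD (tags must be ascending)
    wr2(n_entries)
    entry <- function(tag, type, count, value) {
      wr2(tag); wr2(type); wr4(count); wr4(value)
    }
    entry(256L, 3L, 1L, n2)                      # width
    entry(257L, 3L, 1L, n1)                      # height
    entry(258L, 3L, 1L, bits)                    # bits per sample
    entry(259L, 3L, 1L, 1L)                      # no compression
    entry(262L, 3L, 1L, 1L)                      # BlackIsZero
    entry(273L, 4L, 1L, data_off)                # strip offset
    entry(278L, 3L, 1L, n1)                      # rows per strip
    entry(279L, 4L, 1L, data_len)                # strip byte count
    entry(339L, 3L, 1L, if (bits == 32L) 3L else 1L)  # sample format
    wr4(next_ifd)
    offset <- ifd_off + ifd_len
  }
  invisible(path)
}

#' Read a multi-page grayscale TIFF stack
#'
#' Reads baseline little- or big-endian grayscale TIFFs (uncompressed,
#' 8/16-bit unsigned or 32-bit float, any number of strips).
#'
#' @param path TIFF file.
#' @return list of numeric matrices, one per page.
#' @export
read_tiff_stack <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 8) stop("not a TIFF file: ", path)
  endian <- if (rawToChar(raw[1:2]) == "II") "little"
    else if (rawToChar(raw[1:2]) == "MM") "big" else stop("not a TIFF file")
  rd <- function(off, size, n = 1L, what = "integer", signed = TRUE) {
    readBin(raw[(off + 1):(off + size * n)], what, n = n, size = size,
            endian = endian, signed = signed)
  }
  if (rd(2, 2, signed = FALSE) != 42L) stop("bad TIFF magic")
  ifd <- rd(4, 4)
  pages <- list()
  while (ifd > 0) {
    n_ent <- rd(ifd, 2, signed = FALSE)
    tags <- list()
    for (e in seq_len(n_ent)) {
      off <- ifd + 2 + (e - 1) * 12
      tag <- rd(off, 2, signed = FALSE)
      type <- rd(off + 2, 2, signed = FALSE)
      count <- rd(off + 4, 4)
      vals <- if (type == 3L && count <= 2L) {
        rd(off + 8, 2, n = count, signed = FALSE)
      } else if (type %in% c(3L, 4L) && count > 0L) {
        if ((if (type == 3L) 2L else 4L) * count <= 4L) {
          rd(off + 8, if (type == 3L) 2L else 4L, n = count,
             signed = type != 3L)
        } else {
          voff <- rd(off + 8, 4)
          rd(voff, if (type == 3L) 2L else 4L, n = count,
             signed = type != 3L)
        }
      } else NULL
      if (!is.null(vals)) tags[[as.character(tag)]] <- vals
    }
    g <- function(t, default = NULL) tags[[as.character(t)]] %||% default
    w <- g(256L); h <- g(257L)
    bits <- g(258L, 8L)[1]
    comp <- g(259L, 1L)
    fmt <- g(339L, 1L)[1]
    if (is.null(w) || is.null(h)) stop("TIFF page missing dimensions")
    if (comp != 1L) stop("compressed TIFF not supported")
    offs <- g(273L)
    counts <- g(279L, rep(w * h * bits / 8L, length(offs)))
    vals <- numeric(0)
    for (s in seq_along(offs)) {
      nspx <- counts[s] / (bits / 8L)
      vals <- c(vals, if (bits == 32L && fmt == 3L) {
        rd(offs[s], 4, n = nspx, what = "numeric")
      } else if (bits == 16L) {
        v <- rd(offs[s], 2, n = nspx, signed = FALSE)
        as.numeric(v)
      } else if (bits == 8L) {
        as.numeric(rd(offs[s], 1, n = nspx, signed = FALSE))
      } else stop("unsupported TIFF sample layout (", bits, " bits)"))
    }
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = h, ncol = w,
                                          byrow = TRUE)
    ifd <- rd(ifd + 2 + n_ent * 12, 4)
  }
  pages
}

#' Read an sSMLM acquisition stack into frame pairs
#'
#' @param path TIFF path (side-by-side layout) or spatial-channel path.
#' @param layout `"side-by-side"` (each page holds spatial|spectral and is
#'   split at `split_column`) or `"two-files"` (`path` and `spectral_path`
#'   each hold one channel).
#' @param split_column 0-based column index at which the spectral half
#'   starts (side-by-side layout).
#' @param spectral_path second file for the two-files layout.
#' @return list of `frame_pair` objects.
#' @export
read_stack <- function(path, layout = c("side-by-side", "two-files"),
                       split_column = NULL, spectral_path = NULL) {
  layout <- match.arg(layout)
  pages <- read_tiff_stack(path)
  if (layout == "side-by-side") {
    if (is.null(split_column)) stop("split_column required for side-by-side")
    if (split_column < 1 || split_column >= ncol(pages[[1]]))
      stop("split_column outside image width")
    lapply(seq_along(pages), function(f) {
      p <- pages[[f]]
      structure(list(spatial_image = p[, seq_len(split_column), drop = FALSE],
                     spectral_image = p[, (split_column + 1):ncol(p),
                                        drop = FALSE],
                     frame_index = f), class = "frame_pair")
    })
  } else {
    if (is.null(spectral_path)) stop("spectral_path required for two-files")
    spec <- read_tiff_stack(spectral_path)
    if (length(spec) != length(pages))
      stop("spatial and spectral stacks have different frame counts")
    lapply(seq_along(pages), function(f) {
      structure(list(spatial_image = pages[[f]],
                     spectral_image = spec[[f]], frame_index = f),
                class = "frame_pair")
    })
  }
}

#' Write a simulated stack to disk
#'
#' @param stack result of [simulate_stack()] (or a list of `frame_pair`).
#' @param path output TIFF.
#' @param layout `"side-by-side"` pads the two channels to a common width
#'   and concatenates them per page; `"two-files"` writes `path` and a
#'   second file with suffix `_spectral`.
#' @param bits TIFF bit depth (16 or 32).
#' @return list with the written paths and, for side-by-side, the
#'   `split_column` to pass to [read_stack()].
#' @export
write_stack <- function(stack, path, layout = c("side-by-side", "two-files"),
                        bits = 32L) {
  layout <- match.arg(layout)
  frames <- stack$frames %||% stack
  if (layout == "side-by-side") {
    wspat <- ncol(frames[[1]]$spatial_image)
    pages <- lapply(frames, function(f) cbind(f$spatial_image,
                                              f$spectral_image))
    write_tiff_stack(pages, path, bits = bits)
    list(path = path, split_column = wspat)
  } else {
    p2 <- sub("(\\.[^.]+)?$", "_spectral\\1", path)
    write_tiff_stack(lapply(frames, `[[`, "spatial_image"), path, bits = bits)
    write_tiff_stack(lapply(frames, `[[`, "spectral_image"), p2, bits = bits)
    list(path = path, spectral_path = p2)
  }
}

#' Write a localization table
#'
#' @param locs localization data.frame.
#' @param path output CSV.
#' @param dialect `"native"` writes
#'   `frame,x_nm,y_nm,wavelength_nm,photons,merged_count,channel`;
#'   `"thunderstorm"` writes the interoperable header
#'   `"frame","x [nm]","y [nm]","intensity [photon]"` (wavelength dropped).
#' @return `path`, invisibly. Floats are fixed to 6 decimals.
#' @export
write_localizations <- function(locs, path,
                                dialect = c("native", "thunderstorm")) {
  dialect <- match.arg(dialect)
  fmt <- function(x) {
    ifelse(is.na(x), "", sprintf("%.6f", x))
  }
  if (dialect == "native") {
    d <- data.frame(
      frame = locs$frame %||% integer(nrow(locs)),
      x_nm = fmt(locs$x_nm), y_nm = fmt(locs$y_nm),
      wavelength_nm = fmt(locs$wavelength_nm %||% rep(NA_real_, nrow(locs))),
      photons = fmt(locs$photons %||% rep(NA_real_, nrow(locs))),
      merged_count = locs$merged_count %||% rep(1L, nrow(locs)),
      channel = locs$channel %||% rep("", nrow(locs)),
      stringsAsFactors = FALSE)
    write.csv(d, path, row.names = FALSE, quote = FALSE)
  } else {
    d <- data.frame(
      frame = locs$frame %||% integer(nrow(locs)),
      x = fmt(locs$x_nm), y = fmt(locs$y_nm),
      intensity = fmt(locs$photons %||% rep(NA_real_, nrow(locs))),
      stringsAsFactors = FALSE)
    names(d) <- c("frame", "x [nm]", "y [nm]", "intensity [photon]")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(sprintf('"%s"', names(d)), collapse = ","), con)
    if (nrow(d))
      writeLines(do.call(paste, c(unname(d), sep = ",")), con)
  }
  invisible(path)
}

#' Read a localization table written by [write_localizations()]
#' @param path CSV path.
#' @return localization data.frame (native column names).
#' @export
read_localizations <- function(path) {
  hdr <- readLines(path, n = 1)
  if (grepl("x \\[nm\\]", hdr)) {
    d <- read.csv(path, check.names = FALSE)
    out <- data.frame(frame = d[["frame"]], x_nm = d[["x [nm]"]],
                      y_nm = d[["y [nm]"]],
                      photons = d[["intensity [photon]"]])
  } else {
    out <- read.csv(path, stringsAsFactors = FALSE)
    if (!is.null(out$channel)) out$channel[is.na(out$channel)] <- ""
  }
  out
}

#' Write the ground-truth table of a simulated stack
#' @param truth truth data.frame from [simulate_stack()].
#' @param path CSV path (columns `frame,x_nm,y_nm,photons,dye`).
#' @export
write_truth <- function(truth, path) {
  d <- truth
  d$x_nm <- sprintf("%.6f", d$x_nm)
  d$y_nm <- sprintf("%.6f", d$y_nm)
  d$photons <- sprintf("%.6f", d$photons)
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write a pipeline configuration
#'
#' Configurations are nested lists with an `optics:` block mirroring
#' [optics_config()] plus pipeline blocks (`channels`, `filter_window`,
#' `drift`, `regression`, `render`, `seed`). YAML files require the
#' `yaml` package; JSON always works.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return nested configuration list.
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' @rdname read_config
#' @param cfg configuration list.
#' @export
write_config <- function(cfg, path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("writing YAML configs requires the 'yaml' package")
    yaml::write_yaml(cfg, path)
  } else {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
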
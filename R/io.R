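# File formats: MetaImage volumes (.mhd + .raw, uncompressed little-endian),
# pose CSV (quaternion orientation, qw first), landmark and centerline CSV,
# 4x4 transform text files, tool-configuration XML, and binary PGM frames.

#' Write a volume as MetaImage (.mhd + .raw)
#'
#' Emits an uncompressed little-endian raw payload next to the header.
#'
#' @param vol a `us_volume`.
#' @param path path to the `.mhd` header file.
#' @param element_type `"MET_FLOAT"` or `"MET_UCHAR"` (uchar values are
#'   clamped to 0-255 and rounded).
#' @return `path`, invisibly.
#' @export
write_metaimage <- function(vol, path, element_type = c("MET_FLOAT", "MET_UCHAR")) {
  stopifnot(inherits(vol, "us_volume"))
  element_type <- match.arg(element_type)
  raw_name <- sub("\\.mhd$", ".raw", basename(path))
  if (identical(raw_name, basename(path))) raw_name <- paste0(basename(path), ".raw")
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("DimSize =", paste(dim(vol$voxels), collapse = " ")),
    paste("ElementSpacing =", paste(format(vol$spacing, digits = 17), collapse = " ")),
    paste("Offset =", paste(format(vol$origin, digits = 17), collapse = " ")),
    paste("ElementType =", element_type),
    paste("ElementDataFile =", raw_name))
  writeLines(header, path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  v <- as.vector(vol$voxels)
  if (element_type == "MET_UCHAR") {
    writeBin(as.raw(pmin(pmax(round(v), 0), 255)), con)
  } else {
    writeBin(as.numeric(v), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read a MetaImage volume (.mhd + .raw)
#'
#' Supports uncompressed 3D MET_UCHAR and MET_FLOAT little-endian payloads.
#' The raw size must match `DimSize`; compressed data, missing keys and
#' other element types are rejected.
#'
#' @param path path to the `.mhd` header file.
#' @return A `us_volume` (fill and data masks all `TRUE`).
#' @export
read_metaimage <- function(path) {
  if (!file.exists(path))
    usnav_stop(paste("no such file:", path), "usnav_io_error")
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", ln))[[1L]]
    if (length(m) == 3L) kv[[m[2L]]] <- trimws(m[3L])
  }
  need <- c("DimSize", "ElementSpacing", "ElementType", "ElementDataFile")
  missing <- setdiff(need, names(kv))
  if (length(missing))
    usnav_stop(paste("MetaImage header missing key(s):",
                     paste(missing, collapse = ", ")), "usnav_io_error")
  if (!is.null(kv$CompressedData) && toupper(kv$CompressedData) == "TRUE")
    usnav_stop("compressed MetaImage payloads are not supported", "usnav_io_error")
  if (!is.null(kv$BinaryDataByteOrderMSB) && toupper(kv$BinaryDataByteOrderMSB) == "TRUE")
    usnav_stop("big-endian MetaImage payloads are not supported", "usnav_io_error")
  if (!is.null(kv$NDims) && kv$NDims != "3")
    usnav_stop("only 3D MetaImage volumes are supported", "usnav_io_error")
  dims <- as.integer(strsplit(kv$DimSize, "\\s+")[[1L]])
  if (length(dims) != 3L || any(is.na(dims)) || any(dims <= 0L))
    usnav_stop("invalid DimSize", "usnav_io_error")
  spacing <- as.numeric(strsplit(kv$ElementSpacing, "\\s+")[[1L]])
  origin <- if (!is.null(kv$Offset))
    as.numeric(strsplit(kv$Offset, "\\s+")[[1L]]) else c(0, 0, 0)
  if (kv$ElementDataFile %in% c("LIST", "LOCAL"))
    usnav_stop("multi-file/inline MetaImage payloads are not supported",
               "usnav_io_error")
  raw_path <- file.path(dirname(path), kv$ElementDataFile)
  if (!file.exists(raw_path))
    usnav_stop(paste("missing raw payload:", raw_path), "usnav_io_error")
  n <- prod(dims)
  elsize <- switch(kv$ElementType, MET_UCHAR = 1L, MET_FLOAT = 4L,
                   usnav_stop(paste("unsupported ElementType:", kv$ElementType),
                              "usnav_io_error"))
  if (file.size(raw_path) != n * elsize)
    usnav_stop(sprintf("raw payload size %d does not match DimSize (%d bytes expected)",
                       file.size(raw_path), n * elsize), "usnav_io_error")
  con <- file(raw_path, "rb")
  on.exit(close(con))
  v <- if (kv$ElementType == "MET_UCHAR")
    as.numeric(readBin(con, "raw", n = n))
  else
    readBin(con, "numeric", n = n, size = 4L, endian = "little")
  us_volume(array(v, dims), spacing, origin)
}

#' Write a pose stream as CSV
#'
#' Header `timestamp_ms,qw,qx,qy,qz,tx_mm,ty_mm,tz_mm,status`; orientation
#' as a unit quaternion (qw first).
#'
#' @param stream a `pose_stream`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pose_csv <- function(stream, path) {
  stopifnot(inherits(stream, "pose_stream"))
  df <- data.frame(timestamp_ms = format(stream$t_ms, digits = 17),
                   qw = format(stream$quat[, 1L], digits = 17),
                   qx = format(stream$quat[, 2L], digits = 17),
                   qy = format(stream$quat[, 3L], digits = 17),
                   qz = format(stream$quat[, 4L], digits = 17),
                   tx_mm = format(stream$trans[, 1L], digits = 17),
                   ty_mm = format(stream$trans[, 2L], digits = 17),
                   tz_mm = format(stream$trans[, 3L], digits = 17),
                   status = "OK")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pose stream from CSV
#'
#' `MISSING` rows carry no pose and are skipped (count reported via message
#' and the `n_missing` attribute). Quaternions are normalized on read; a
#' norm further than 1e-3 from unit is an error naming the offending row.
#'
#' @param path CSV path.
#' @param from,to frame labels for the poses (sensor -> tracker by default).
#' @return A `pose_stream`.
#' @export
read_pose_csv <- function(path, from = "sensor", to = "tracker") {
  if (!file.exists(path))
    usnav_stop(paste("no such file:", path), "usnav_io_error")
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp_ms", "qw", "qx", "qy", "qz", "tx_mm", "ty_mm", "tz_mm",
            "status")
  if (!all(need %in% names(df)))
    usnav_stop("pose CSV is missing required columns", "usnav_io_error")
  missing_rows <- which(df$status == "MISSING")
  if (length(missing_rows)) {
    message(sprintf("read_pose_csv: skipped %d MISSING row(s)", length(missing_rows)))
    df <- df[-missing_rows, , drop = FALSE]
  }
  if (nrow(df) == 0L)
    usnav_stop("pose CSV holds no usable rows", "usnav_empty_input")
  q <- as.matrix(df[, c("qw", "qx", "qy", "qz")])
  nrm <- sqrt(rowSums(q^2))
  bad <- which(abs(nrm - 1) > 1e-3)
  if (length(bad))
    usnav_stop(sprintf("quaternion in row %d has norm %.4f (not unit)",
                       bad[1L], nrm[bad[1L]]), "usnav_io_error")
  poses <- lapply(seq_len(nrow(df)), function(i)
    rigid_transform(rotation_from_quat(q[i, ] / nrm[i]),
                    c(df$tx_mm[i], df$ty_mm[i], df$tz_mm[i]), from, to))
  out <- pose_stream(df$timestamp_ms, poses)
  attr(out, "n_missing") <- length(missing_rows)
  out
}

#' Read/write landmark CSV (`name,x_mm,y_mm,z_mm`)
#'
#' @param path CSV path.
#' @param frame frame label for the returned set.
#' @return `read_landmarks_csv`: a `landmark_set`.
#' @export
read_landmarks_csv <- function(path, frame = "unknown") {
  if (!file.exists(path))
    usnav_stop(paste("no such file:", path), "usnav_io_error")
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "x_mm", "y_mm", "z_mm") %in% names(df)))
    usnav_stop("landmark CSV needs columns name,x_mm,y_mm,z_mm", "usnav_io_error")
  landmark_set(df, frame = frame)
}

#' @rdname read_landmarks_csv
#' @param landmarks a `landmark_set`.
#' @export
write_landmarks_csv <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "landmark_set"))
  df <- data.frame(name = rownames(landmarks$points),
                   x_mm = landmarks$points[, 1L],
                   y_mm = landmarks$points[, 2L],
                   z_mm = landmarks$points[, 3L])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write centerline CSV (`x_mm,y_mm,z_mm` plus optional `tx,ty,tz`)
#'
#' @param path CSV path.
#' @return `read_centerline_csv`: a `centerline`.
#' @export
read_centerline_csv <- function(path) {
  if (!file.exists(path))
    usnav_stop(paste("no such file:", path), "usnav_io_error")
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x_mm", "y_mm", "z_mm") %in% names(df)))
    usnav_stop("centerline CSV needs columns x_mm,y_mm,z_mm", "usnav_io_error")
  tang <- if (all(c("tx", "ty", "tz") %in% names(df)))
    as.matrix(df[, c("tx", "ty", "tz")]) else NULL
  centerline(as.matrix(df[, c("x_mm", "y_mm", "z_mm")]), tang)
}

#' @rdname read_centerline_csv
#' @param cl a `centerline`.
#' @export
write_centerline_csv <- function(cl, path) {
  stopifnot(inherits(cl, "centerline"))
  df <- data.frame(x_mm = cl$points[, 1L], y_mm = cl$points[, 2L],
                   z_mm = cl$points[, 3L])
  if (!is.null(cl$tangents)) {
    df$tx <- cl$tangents[, 1L]; df$ty <- cl$tangents[, 2L]
    df$tz <- cl$tangents[, 3L]
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write a transform text file (4 rows of 4 whitespace-separated floats)
#'
#' @param path file path.
#' @param from,to frame labels for the returned transform.
#' @return `read_transform_file`: a `rigid_transform`.
#' @export
read_transform_file <- function(path, from = "from", to = "to") {
  if (!file.exists(path))
    usnav_stop(paste("no such file:", path), "usnav_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != 4L)
    usnav_stop("transform file must have 4 rows", "usnav_io_error")
  m <- t(vapply(lines, function(ln) {
    v <- as.numeric(strsplit(trimws(ln), "\\s+")[[1L]])
    if (length(v) != 4L || any(is.na(v)))
      usnav_stop("transform file rows must hold 4 numbers", "usnav_io_error")
    v
  }, numeric(4)))
  from_homogeneous(m, from, to)
}

#' @rdname read_transform_file
#' @param t a `rigid_transform`.
#' @export
write_transform_file <- function(t, path) {
  stopifnot(inherits(t, "rigid_transform"))
  m <- as_homogeneous(t)
  writeLines(apply(m, 1L, function(r) paste(format(r, digits = 17), collapse = " ")),
             path)
  invisible(path)
}

#' Read/write tool-configuration XML
#'
#' Minimal schema: `<tool name="...">` with a `<tracking_system>` label and a
#' `<calibration>` element holding 16 row-major numbers (sensor -> tip
#' homogeneous matrix); optionally `<probe ref="..."/>`. A calibration whose
#' rotation is not orthonormal with determinant +1 is rejected.
#'
#' @param path XML path.
#' @return `read_tool_config_xml`: a list of class `tool_config` with
#'   `name`, `tracking_system`, `calibration` (a `rigid_transform`,
#'   sensor -> tip) and `probe_ref`.
#' @export
read_tool_config_xml <- function(path) {
  if (!file.exists(path))
    usnav_stop(paste("no such file:", path), "usnav_io_error")
  doc <- xml2::read_xml(path)
  name <- xml2::xml_attr(doc, "name")
  if (is.na(name) || !nzchar(name))
    usnav_stop("tool XML must carry a tool name", "usnav_io_error")
  ts_node <- xml2::xml_find_first(doc, "./tracking_system")
  tracking <- if (inherits(ts_node, "xml_missing")) "" else xml2::xml_text(ts_node)
  cal_node <- xml2::xml_find_first(doc, "./calibration")
  if (inherits(cal_node, "xml_missing"))
    usnav_stop("tool XML must carry a calibration matrix", "usnav_io_error")
  v <- as.numeric(strsplit(trimws(xml2::xml_text(cal_node)), "\\s+")[[1L]])
  if (length(v) != 16L || any(is.na(v)))
    usnav_stop("tool calibration must hold 16 numbers", "usnav_io_error")
  m <- matrix(v, 4L, 4L, byrow = TRUE)
  r <- m[1:3, 1:3]
  if (max(abs(crossprod(r) - diag(3))) > 1e-6 || det(r) < 0)
    usnav_stop("tool calibration is not a rigid transform", "usnav_io_error")
  cal <- from_homogeneous(m, from = "sensor", to = "tip")
  probe_node <- xml2::xml_find_first(doc, "./probe")
  probe_ref <- if (inherits(probe_node, "xml_missing")) NULL
  else xml2::xml_attr(probe_node, "ref")
  structure(list(name = name, tracking_system = tracking, calibration = cal,
                 probe_ref = probe_ref),
            class = "tool_config")
}

#' @rdname read_tool_config_xml
#' @param config a `tool_config` list (`name`, `tracking_system`,
#'   `calibration`, optional `probe_ref`).
#' @export
write_tool_config_xml <- function(config, path) {
  m <- as_homogeneous(config$calibration)
  doc <- xml2::xml_new_root("tool", name = config$name)
  xml2::xml_add_child(doc, "tracking_system", config$tracking_system)
  xml2::xml_add_child(doc, "calibration",
                      paste(format(as.vector(t(m)), digits = 17), collapse = " "))
  if (!is.null(config$probe_ref))
    xml2::xml_add_child(doc, "probe", ref = config$probe_ref)
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read/write probe-configuration XML
#'
#' Serialises a `probe_model` (geometry, pixel grid, spatial calibration as
#' 16 row-major numbers, temporal offset).
#'
#' @param path XML path.
#' @return `read_probe_xml`: a `probe_model`.
#' @export
read_probe_xml <- function(path) {
  if (!file.exists(path))
    usnav_stop(paste("no such file:", path), "usnav_io_error")
  doc <- xml2::read_xml(path)
  num <- function(xp) as.numeric(strsplit(trimws(xml2::xml_text(
    xml2::xml_find_first(doc, xp))), "\\s+")[[1L]])
  v <- num("./calibration")
  if (length(v) != 16L || any(is.na(v)))
    usnav_stop("probe calibration must hold 16 numbers", "usnav_io_error")
  probe_model(xml2::xml_attr(doc, "geometry"),
              width = num("./width_mm"),
              depth_start = num("./depth_start_mm"),
              depth_end = num("./depth_end_mm"),
              pixel_spacing = num("./pixel_spacing_mm"),
              image_size = num("./image_size"),
              origin_px = num("./origin_px"),
              calibration = from_homogeneous(matrix(v, 4L, 4L, byrow = TRUE),
                                             "image", "sensor"),
              temporal_offset = num("./temporal_offset_ms"))
}

#' @rdname read_probe_xml
#' @param probe a `probe_model`.
#' @export
write_probe_xml <- function(probe, path) {
  stopifnot(inherits(probe, "probe_model"))
  doc <- xml2::xml_new_root("probe", geometry = probe$geometry_kind)
  add <- function(tag, val) xml2::xml_add_child(doc, tag,
    paste(format(val, digits = 17), collapse = " "))
  add("width_mm", probe$width)
  add("depth_start_mm", probe$depth_start)
  add("depth_end_mm", probe$depth_end)
  add("pixel_spacing_mm", probe$pixel_spacing)
  add("image_size", probe$image_size)
  add("origin_px", probe$origin_px)
  add("calibration", as.vector(t(as_homogeneous(probe$calibration))))
  add("temporal_offset_ms", probe$temporal_offset)
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read/write binary PGM (P5) frames
#'
#' @param path PGM path.
#' @return `read_pgm`: numeric rows x cols matrix of 0-255 intensities.
#' @export
read_pgm <- function(path) {
  if (!file.exists(path))
    usnav_stop(paste("no such file:", path), "usnav_io_error")
  bytes <- readBin(path, "raw", n = file.size(path))
  is_space <- function(b) b %in% as.raw(c(9L, 10L, 13L, 32L))
  pos <- 1L
  tok <- character(0)
  n <- length(bytes)
  while (length(tok) < 4L && pos <= n) {
    if (bytes[pos] == as.raw(35L)) {            # '#' comment to end of line
      while (pos <= n && bytes[pos] != as.raw(10L)) pos <- pos + 1L
      pos <- pos + 1L
    } else if (is_space(bytes[pos])) {
      pos <- pos + 1L
    } else {
      start <- pos
      while (pos <= n && !is_space(bytes[pos])) pos <- pos + 1L
      tok <- c(tok, rawToChar(bytes[start:(pos - 1L)]))
    }
  }
  if (length(tok) < 4L || tok[1L] != "P5")
    usnav_stop("only binary (P5) PGM is supported", "usnav_io_error")
  w <- as.integer(tok[2L]); h <- as.integer(tok[3L])
  if (n < pos + w * h)
    usnav_stop("PGM payload shorter than header promises", "usnav_io_error")
  data <- bytes[(pos + 1L):(pos + w * h)]       # one whitespace after maxval
  matrix(as.numeric(data), h, w, byrow = TRUE)
}

#' @rdname read_pgm
#' @param pixels numeric matrix, clamped to 0-255 and rounded.
#' @export
write_pgm <- function(pixels, path) {
  pixels <- as.matrix(pixels)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(sprintf("P5\n%d %d\n255\n", ncol(pixels), nrow(pixels))), con)
  writeBin(as.raw(pmin(pmax(round(t(pixels)), 0), 255)), con)
  invisible(path)
}
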
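# Readers and writers for the on-disk formats: PLY (ascii and binary
# little-endian) and whitespace XYZ for clouds, 3-column CSV for
# displacement fields, JSON for landmarks, correspondences, transforms and
# configs, CSV for metric reports. Text floats use 17 significant digits so
# every round-trip is lossless.

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

#' Read a point cloud from PLY or XYZ
#'
#' Accepts ascii or binary little-endian PLY with `x`, `y`, `z` vertex
#' properties (an optional integer `label` property becomes labels), or
#' plain whitespace-separated XYZ text. Point order is preserved.
#'
#' @param path input file.
#' @return a `point_cloud`.
#' @export
read_point_cloud <- function(path) {
  if (!file.exists(path)) err(sprintf("file not found: '%s'", path), "io_error")
  head1 <- readLines(path, n = 1L, warn = FALSE)
  if (identical(trimws(head1), "ply")) read_ply(path) else read_xyz(path)
}

read_ply_header <- function(con) {
  fmt <- NULL; n_vertex <- NULL; props <- character(0); types <- character(0)
  lineno <- 1L
  in_vertex <- FALSE
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) err("unexpected end of PLY header", "parse_error")
    lineno <- lineno + 1L
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0L) next
    if (tok[1] == "format") {
      fmt <- tok[2]
    } else if (tok[1] == "element") {
      in_vertex <- tok[2] == "vertex"
      if (in_vertex) n_vertex <- as.integer(tok[3])
    } else if (tok[1] == "property" && in_vertex) {
      if (tok[2] == "list") err("list properties are not supported", "parse_error")
      types <- c(types, tok[2])
      props <- c(props, tok[3])
    } else if (tok[1] == "end_header") {
      break
    }
  }
  if (is.null(fmt) || is.null(n_vertex)) {
    err("malformed PLY header: missing format or vertex element", "parse_error")
  }
  if (!all(c("x", "y", "z") %in% props)) {
    err("PLY vertex element lacks x/y/z properties", "parse_error")
  }
  list(format = fmt, n = n_vertex, props = props, types = types, header_lines = lineno)
}

ply_type_size <- function(t) {
  switch(t,
         char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
         short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
         int = 4L, uint = 4L, int32 = 4L, uint32 = 4L, float = 4L, float32 = 4L,
         double = 8L, float64 = 8L,
         err(sprintf("unsupported PLY property type '%s'", t), "parse_error"))
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- read_ply_header(con)
  np <- length(hdr$props)
  if (hdr$format == "ascii") {
    vals <- matrix(NA_real_, hdr$n, np)
    for (i in seq_len(hdr$n)) {
      line <- readLines(con, n = 1L, warn = FALSE)
      if (length(line) == 0L) {
        err(sprintf("PLY '%s': unexpected end of data at vertex %d", path, i), "parse_error")
      }
      tok <- suppressWarnings(as.numeric(strsplit(trimws(line), "\\s+")[[1]]))
      if (length(tok) < np || anyNA(tok)) {
        err(sprintf("PLY '%s': malformed vertex row %d", path, i), "parse_error")
      }
      vals[i, ] <- tok[seq_len(np)]
    }
  } else if (hdr$format == "binary_little_endian") {
    vals <- matrix(NA_real_, hdr$n, np)
    for (i in seq_len(hdr$n)) {
      for (j in seq_len(np)) {
        t <- hdr$types[j]
        sz <- ply_type_size(t)
        what <- if (t %in% c("float", "float32", "double", "float64")) "double" else "integer"
        vals[i, j] <- readBin(con, what = what, n = 1L, size = sz,
                              endian = "little",
                              signed = !(t %in% c("uchar", "uint8", "ushort", "uint16")))
      }
    }
  } else {
    err(sprintf("unsupported PLY format '%s'", hdr$format), "parse_error")
  }
  colnames(vals) <- hdr$props
  labels <- if ("label" %in% hdr$props) as.integer(vals[, "label"]) else NULL
  point_cloud(vals[, c("x", "y", "z"), drop = FALSE], labels = labels)
}

read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) err(sprintf("XYZ '%s': no data rows", path), "parse_error")
  pts <- matrix(NA_real_, length(lines), 3)
  for (i in seq_along(lines)) {
    tok <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (length(tok) < 3L || anyNA(tok[1:3])) {
      err(sprintf("XYZ '%s': malformed row %d", path, i), "parse_error")
    }
    pts[i, ] <- tok[1:3]
  }
  point_cloud(pts)
}

#' Write a point cloud
#'
#' Ascii PLY (default, with a `label` property when labels are integer-like)
#' or whitespace XYZ.
#'
#' @param cloud a `point_cloud`.
#' @param path output file.
#' @param format `"ply"` or `"xyz"`.
#' @export
write_point_cloud <- function(cloud, path, format = c("ply", "xyz")) {
  format <- match.arg(format)
  m <- as_cloud_matrix(cloud)
  if (format == "xyz") {
    writeLines(paste(fmt_num(m[, 1]), fmt_num(m[, 2]), fmt_num(m[, 3])), path)
    return(invisible(path))
  }
  labels <- cloud$labels
  int_labels <- !is.null(labels) && (is.numeric(labels) || is.factor(labels) || is.character(labels))
  lab_codes <- if (int_labels) as.integer(factor(labels, levels = unique(labels))) else NULL
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(m)),
           "property double x", "property double y", "property double z",
           if (int_labels) "property int label",
           "end_header")
  rows <- paste(fmt_num(m[, 1]), fmt_num(m[, 2]), fmt_num(m[, 3]))
  if (int_labels) rows <- paste(rows, lab_codes)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write / read a displacement field as 3-column CSV
#'
#' Rows align with the source cloud's row order; columns `dx`, `dy`, `dz`.
#'
#' @param field a `displacement_field`.
#' @param path file path.
#' @return `read_field` returns a `displacement_field`.
#' @export
write_field <- function(field, path) {
  df <- as.data.frame(field$vectors)
  df[] <- lapply(df, fmt_num)
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  if (!file.exists(path)) err(sprintf("file not found: '%s'", path), "io_error")
  df <- read.table(path, sep = ",", header = TRUE)
  displacement_field(as.matrix(df[, c("dx", "dy", "dz")]))
}

#' Write / read landmarks as JSON
#'
#' Serialized as `{structure_id: [[x, y, z], ...], ...}` preserving structure
#' order.
#'
#' @param landmarks named list of L x 3 matrices.
#' @param path file path.
#' @return `read_landmarks` returns the named list of matrices.
#' @export
write_landmarks <- function(landmarks, path) {
  obj <- lapply(landmarks, function(L) {
    L <- as.matrix(L)
    dimnames(L) <- NULL
    L
  })
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) err(sprintf("file not found: '%s'", path), "io_error")
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(obj, function(L) matrix(as.numeric(L), ncol = 3))
}

#' Write / read a rigid transform as 4x4 row-major JSON
#' @param transform a `rigid_transform`.
#' @param path file path.
#' @return `read_transform` returns a `rigid_transform`.
#' @export
write_transform <- function(transform, path) {
  M <- rbind(cbind(transform$rotation, transform$translation), c(0, 0, 0, 1))
  jsonlite::write_json(as.vector(t(M)), path, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  if (!file.exists(path)) err(sprintf("file not found: '%s'", path), "io_error")
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(v) != 16L) err("transform JSON must hold 16 numbers", "parse_error")
  M <- matrix(as.numeric(v), 4, 4, byrow = TRUE)
  rigid_transform(M[1:3, 1:3], M[1:3, 4])
}

#' Write / read a correspondence set as JSON
#' @param sigma a `correspondence_set`.
#' @param path file path.
#' @return `read_correspondences` returns a `correspondence_set`.
#' @export
write_correspondences <- function(sigma, path) {
  m <- sigma$pairs
  dimnames(m) <- NULL
  jsonlite::write_json(m, path)
  invisible(path)
}

#' @rdname write_correspondences
#' @export
read_correspondences <- function(path) {
  if (!file.exists(path)) err(sprintf("file not found: '%s'", path), "io_error")
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  correspondence_set(matrix(as.integer(m), ncol = 2))
}

#' Write / read a metric report table as CSV
#' @param report a `metric_report` (or data.frame of stacked reports).
#' @param path file path.
#' @return `read_report` returns the data.frame.
#' @export
write_report <- function(report, path) {
  df <- as.data.frame(report)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  write.table(df, path, sep = ",", row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) err(sprintf("file not found: '%s'", path), "io_error")
  read.table(path, sep = ",", header = TRUE, stringsAsFactors = FALSE)
}

#' Read a run configuration from YAML or JSON
#'
#' Top-level keys `simulation`, `pyramid`, `stage1` (backend name + params)
#' are mapped onto [simulation_config()], [pyramid_config()] and a stage-one
#' parameter list; unspecified entries keep their defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return list with elements `simulation`, `pyramid`, `stage1`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) err(sprintf("file not found: '%s'", path), "io_error")
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  sim_args <- raw$simulation %||% list()
  if (!is.null(sim_args$n_points)) sim_args$n_points <- unlist(sim_args$n_points)
  if (!is.null(sim_args$occlusion_range)) {
    sim_args$occlusion_range <- as.numeric(unlist(sim_args$occlusion_range))
  }
  list(simulation = do.call(simulation_config, sim_args),
       pyramid = do.call(pyramid_config, raw$pyramid %||% list()),
       stage1 = list(backend = raw$stage1$backend %||% "descriptor",
                     params = raw$stage1$params %||% list()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
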
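#' Read a point cloud from ASCII PLY or delimited XYZ text
#'
#' Supports ASCII PLY files whose vertex element carries `x`, `y`, `z` and
#' optionally an `intensity` (or `scalar_*`) property, and plain text files
#' with 3 or 4 whitespace- or comma-delimited numeric columns
#' (x, y, z\[, intensity\]). Binary PLY is rejected. Points are returned in
#' file order; coordinates are millimetres.
#'
#' @param path Path to the file.
#' @param format One of `"auto"` (default; decided by the `ply` magic/extension),
#'   `"ply"` or `"xyz"`.
#' @return A point-cloud tibble (see [as_cloud()]) with `source_id` set from
#'   the file name.
#' @seealso [write_cloud()]
#' @export
read_cloud <- function(path, format = c("auto", "ply", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (length(first) && identical(trimws(first), "ply")) "ply" else "xyz"
  }
  src <- basename(path)
  if (format == "ply") read_ply(path, src) else read_xyz(path, src)
}

read_xyz <- function(path, src) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (!length(lines)) return(as_cloud(data.frame(x = double(), y = double(), z = double()), source_id = src))
  rows <- strsplit(trimws(gsub(",", " ", lines, fixed = TRUE)), "\\s+")
  ncols <- lengths(rows)
  if (any(ncols < 3 | ncols > 4)) {
    bad <- which(keep)[which(ncols < 3 | ncols > 4)[1]]
    abort(sprintf("parse error in %s line %d: expected 3 or 4 numeric columns", src, bad))
  }
  vals <- suppressWarnings(lapply(rows, as.numeric))
  isna <- vapply(vals, function(v) anyNA(v), logical(1))
  if (any(isna)) {
    bad <- which(keep)[which(isna)[1]]
    abort(sprintf("parse error in %s line %d: non-numeric value", src, bad))
  }
  m <- do.call(rbind, vals)
  as_cloud(m[, 1:3, drop = FALSE],
           intensity = if (ncol(m) == 4) m[, 4] else NULL,
           source_id = src)
}

read_ply <- function(path, src) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || trimws(lines[1]) != "ply") {
    abort(sprintf("parse error in %s line 1: not a PLY file", src))
  }
  end <- match("end_header", trimws(lines))
  if (is.na(end)) abort(sprintf("parse error in %s: missing end_header", src))
  header <- trimws(lines[seq_len(end)])
  fmt <- grep("^format ", header, value = TRUE)
  if (length(fmt) && !grepl("^format\\s+ascii", fmt[1])) {
    abort(sprintf("unsupported format in %s: binary PLY is not supported", src))
  }
  # vertex element and its properties, in declaration order
  elem_lines <- grep("^element ", header)
  vert_line <- elem_lines[grepl("^element\\s+vertex\\s", header[elem_lines])]
  if (!length(vert_line)) abort(sprintf("parse error in %s: no vertex element", src))
  vert_line <- vert_line[1]
  n_vertex <- as.integer(strsplit(header[vert_line], "\\s+")[[1]][3])
  next_elem <- elem_lines[elem_lines > vert_line]
  prop_end <- if (length(next_elem)) next_elem[1] - 1L else end - 1L
  props <- header[seq(vert_line + 1L, prop_end)]
  props <- props[grepl("^property ", props)]
  prop_names <- vapply(strsplit(props, "\\s+"), function(p) p[length(p)], character(1))
  need <- match(c("x", "y", "z"), prop_names)
  if (anyNA(need)) abort(sprintf("parse error in %s: vertex element lacks x/y/z", src))
  int_col <- which(prop_names == "intensity" | grepl("^scalar", prop_names))[1]

  body <- lines[seq(end + 1L, length.out = length(lines) - end)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n_vertex) {
    abort(sprintf("parse error in %s: %d vertex rows declared, %d found",
                  src, n_vertex, length(body)))
  }
  if (n_vertex == 0L) {
    return(as_cloud(data.frame(x = double(), y = double(), z = double()),
                    source_id = src))
  }
  rows <- strsplit(trimws(body[seq_len(n_vertex)]), "\\s+")
  vals <- suppressWarnings(lapply(rows, as.numeric))
  bad <- which(vapply(vals, function(v) anyNA(v) || length(v) < length(prop_names), logical(1)))
  if (length(bad)) {
    abort(sprintf("parse error in %s line %d: malformed vertex row", src, end + bad[1]))
  }
  m <- do.call(rbind, vals)
  as_cloud(m[, need, drop = FALSE],
           intensity = if (!is.na(int_col)) m[, int_col] else NULL,
           source_id = src)
}

#' Write a point cloud to ASCII PLY or XYZ text
#'
#' @param cloud A point-cloud tibble.
#' @param path Output path; the parent directory must exist.
#' @param format `"ply"` (ASCII, with an `intensity` property when present)
#'   or `"xyz"` (space-delimited, 3 or 4 columns).
#' @return `path`, invisibly.
#' @seealso [read_cloud()]
#' @export
write_cloud <- function(cloud, path, format = c("ply", "xyz")) {
  format <- match.arg(format)
  if (!dir.exists(dirname(path))) {
    abort(sprintf("cannot write %s: directory does not exist", path))
  }
  has_int <- "intensity" %in% names(cloud)
  cols <- if (has_int) cloud[c("x", "y", "z", "intensity")] else cloud[c("x", "y", "z")]
  body <- do.call(paste, c(lapply(cols, format_num), list(sep = " ")))
  if (format == "ply") {
    header <- c(
      "ply", "format ascii 1.0",
      sprintf("element vertex %d", nrow(cloud)),
      "property float x", "property float y", "property float z",
      if (has_int) "property float intensity",
      "end_header"
    )
    writeLines(c(header, body), path)
  } else {
    writeLines(body, path)
  }
  invisible(path)
}

format_num <- function(v) {
  formatC(v, digits = 9, format = "g")
}

#' Read bounding-box annotations (Pascal-VOC XML or CSV)
#'
#' Boxes are returned in file order as a tibble with columns `image_id`,
#' `label`, `x_min`, `y_min`, `x_max`, `y_max` and, when present in the file,
#' `score`. Coordinates use the half-open pixel convention
#' `[x_min, x_max) x [y_min, y_max)`. VOC XML carries the image size; it is
#' attached as attributes `image_width` / `image_height` and every box is
#' validated against it.
#'
#' @param path Path to a `.xml` (Pascal VOC) or `.csv` file. The CSV dialect
#'   has header `image_id,label,x_min,y_min,x_max,y_max[,score]`.
#' @param format `"auto"` (default, by extension), `"voc_xml"` or `"csv"`.
#' @return An annotation tibble of class `cc_boxes`.
#' @export
read_annotations <- function(path, format = c("auto", "voc_xml", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.xml$", path, ignore.case = TRUE)) "voc_xml" else "csv"
  }
  if (format == "voc_xml") read_voc_xml(path) else read_boxes_csv(path)
}

read_voc_xml <- function(path) {
  doc <- xml2::read_xml(path)
  image_id <- xml2::xml_text(xml2::xml_find_first(doc, "./filename"))
  w <- as.numeric(xml2::xml_text(xml2::xml_find_first(doc, "./size/width")))
  h <- as.numeric(xml2::xml_text(xml2::xml_find_first(doc, "./size/height")))
  objs <- xml2::xml_find_all(doc, "./object")
  num <- function(node, q) as.numeric(xml2::xml_text(xml2::xml_find_first(node, q)))
  boxes <- tibble::tibble(
    image_id = rep(image_id, length(objs)),
    label = vapply(objs, function(o) xml2::xml_text(xml2::xml_find_first(o, "./name")), character(1)),
    x_min = vapply(objs, num, numeric(1), q = "./bndbox/xmin"),
    y_min = vapply(objs, num, numeric(1), q = "./bndbox/ymin"),
    x_max = vapply(objs, num, numeric(1), q = "./bndbox/xmax"),
    y_max = vapply(objs, num, numeric(1), q = "./bndbox/ymax")
  )
  as_boxes(boxes, image_width = w, image_height = h)
}

read_boxes_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "label", "x_min", "y_min", "x_max", "y_max")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(sprintf("annotation CSV %s lacks columns: %s", basename(path),
                  paste(missing_cols, collapse = ", ")))
  }
  keep <- c(need, intersect("score", names(df)))
  as_boxes(tibble::as_tibble(df[keep]))
}

#' Construct or validate a bounding-box tibble
#'
#' @param boxes Data frame with columns `image_id`, `label`, `x_min`,
#'   `y_min`, `x_max`, `y_max` and optionally `score` (confidence in
#'   \[0, 1\]). Boxes are half-open pixel rectangles and must have positive
#'   area and non-empty labels.
#' @param image_width,image_height Optional image size in pixels; when given,
#'   every box must lie inside `[0, width] x [0, height]`.
#' @return The validated tibble with class `cc_boxes`.
#' @export
as_boxes <- function(boxes, image_width = NULL, image_height = NULL) {
  boxes <- tibble::as_tibble(boxes)
  need <- c("image_id", "label", "x_min", "y_min", "x_max", "y_max")
  stopifnot(all(need %in% names(boxes)))
  if (nrow(boxes)) {
    if (any(!nzchar(boxes$label))) abort("box labels must be non-empty")
    degenerate <- boxes$x_max <= boxes$x_min | boxes$y_max <= boxes$y_min
    if (any(degenerate)) {
      abort(sprintf("%d boxes have non-positive area (first at row %d)",
                    sum(degenerate), which(degenerate)[1]))
    }
    if ("score" %in% names(boxes) &&
        any(!is.na(boxes$score) & (boxes$score < 0 | boxes$score > 1))) {
      abort("scores must lie in [0, 1]")
    }
    if (!is.null(image_width) && !is.null(image_height) &&
        is.finite(image_width) && is.finite(image_height)) {
      out <- boxes$x_min < 0 | boxes$y_min < 0 |
        boxes$x_max > image_width | boxes$y_max > image_height
      if (any(out)) {
        b <- boxes[which(out)[1], ]
        abort(sprintf(
          "box (%g,%g,%g,%g) lies outside the %g x %g image",
          b$x_min, b$y_min, b$x_max, b$y_max, image_width, image_height))
      }
    }
  }
  attr(boxes, "image_width") <- image_width
  attr(boxes, "image_height") <- image_height
  if (!inherits(boxes, "cc_boxes")) class(boxes) <- c("cc_boxes", class(boxes))
  boxes
}

#' Write bounding-box annotations
#'
#' @param ann An annotation tibble ([as_boxes()]).
#' @param path Output path.
#' @param format `"csv"` (shared dialect, one row per box) or `"voc_xml"`
#'   (one image per file; requires a single `image_id` and the
#'   `image_width`/`image_height` attributes).
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path, format = c("csv", "voc_xml")) {
  format <- match.arg(format)
  if (format == "csv") {
    cols <- c("image_id", "label", "x_min", "y_min", "x_max", "y_max",
              intersect("score", names(ann)))
    write.csv(as.data.frame(ann)[cols], path, row.names = FALSE, quote = FALSE)
  } else {
    ids <- unique(ann$image_id)
    if (length(ids) > 1) abort("voc_xml holds one image per file; split by image_id first")
    w <- attr(ann, "image_width"); h <- attr(ann, "image_height")
    if (is.null(w) || is.null(h)) abort("voc_xml needs image_width/image_height attributes")
    objs <- purrr::pmap_chr(ann, function(image_id, label, x_min, y_min, x_max, y_max, ...) {
      paste0("  <object><name>", label, "</name><bndbox>",
             "<xmin>", x_min, "</xmin><ymin>", y_min, "</ymin>",
             "<xmax>", x_max, "</xmax><ymax>", y_max, "</ymax>",
             "</bndbox></object>")
    })
    writeLines(c(
      "<annotation>",
      paste0("  <filename>", if (length(ids)) ids else "", "</filename>"),
      paste0("  <size><width>", w, "</width><height>", h, "</height><depth>3</depth></size>"),
      objs,
      "</annotation>"
    ), path)
  }
  invisible(path)
}
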
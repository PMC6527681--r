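# Annotation and raster I/O: Pascal-VOC XML in the LabelImg dialect,
# dataset manifests, and the native -> detector-input resize.
#
# Internally boxes use 0-based half-open pixel intervals [xmin, xmax) x
# [ymin, ymax), so integer boxes have exact integer areas. VOC XML stores
# 1-based inclusive corners (the LabelImg convention); the conversion
# happens only at the file boundary: file xmin = internal xmin + 1,
# file xmax = internal xmax.

#' Construct an annotated image
#'
#' @param image optional grayscale raster matrix in `[0,1]` (rows = y).
#' @param width,height raster extent in pixels.
#' @param boxes box table (0-based half-open pixel coordinates) with an
#'   optional `label` column; defaults to zero boxes.
#' @param image_path,metadata provenance: source file and a list of leaflet
#'   metadata (accession, origin, position, replicate, ...).
#' @return an `annotated_image` object.
#' @export
annotated_image <- function(image = NULL, width = NULL, height = NULL,
                            boxes = NULL, image_path = NULL,
                            metadata = list()) {
  if (!is.null(image)) {
    height <- height %||% nrow(image)
    width <- width %||% ncol(image)
  }
  if (is.null(width) || is.null(height) || width <= 0 || height <= 0) {
    stopf("annotated_image needs positive width and height")
  }
  if (is.null(boxes)) {
    boxes <- data.frame(xmin = numeric(0), ymin = numeric(0),
                        xmax = numeric(0), ymax = numeric(0),
                        label = character(0))
  }
  if (nrow(boxes) > 0L) {
    m <- box_matrix(boxes)
    if (any(m[, 1] >= m[, 3]) || any(m[, 2] >= m[, 4])) {
      stopf("degenerate box in annotation")
    }
    if (any(m[, c(1, 3)] < 0) || any(m[, c(1, 3)] > width) ||
        any(m[, c(2, 4)] < 0) || any(m[, c(2, 4)] > height)) {
      stopf("box outside the image extent")
    }
    if (is.null(boxes$label)) boxes$label <- "stoma"
  }
  structure(list(image = image, image_path = image_path,
                 width = as.integer(width), height = as.integer(height),
                 boxes = boxes, metadata = metadata),
            class = "annotated_image")
}

#' @export
print.annotated_image <- function(x, ...) {
  cat(sprintf("Annotated image %dx%d px, %d box(es)%s\n", x$width, x$height,
              nrow(x$boxes),
              if (!is.null(x$image_path)) paste0(" [", x$image_path, "]")
              else ""))
  invisible(x)
}

#' Read a LabelImg-style Pascal VOC annotation
#'
#' @param xml_path path to the XML file.
#' @return an [annotated_image()] (raster not loaded; see
#'   [read_micrograph()]).
#' @export
read_voc_annotation <- function(xml_path) {
  if (!file.exists(xml_path)) stopf("annotation file not found: %s", xml_path)
  doc <- xml2::read_xml(xml_path)
  size <- xml2::xml_find_first(doc, ".//size")
  if (is.na(size)) stopf("%s: missing <size> element", xml_path)
  width <- as.integer(xml2::xml_text(xml2::xml_find_first(size, "./width")))
  height <- as.integer(xml2::xml_text(xml2::xml_find_first(size, "./height")))
  objs <- xml2::xml_find_all(doc, ".//object")
  boxes <- data.frame(xmin = numeric(0), ymin = numeric(0),
                      xmax = numeric(0), ymax = numeric(0),
                      label = character(0))
  for (k in seq_along(objs)) {
    bb <- xml2::xml_find_first(objs[[k]], "./bndbox")
    if (is.na(bb)) stopf("%s: object %d has no <bndbox>", xml_path, k)
    v <- vapply(c("xmin", "ymin", "xmax", "ymax"), function(f) {
      as.numeric(xml2::xml_text(xml2::xml_find_first(bb, paste0("./", f))))
    }, numeric(1))
    # 1-based inclusive on file -> 0-based half-open internally
    box <- c(v["xmin"] - 1, v["ymin"] - 1, v["xmax"], v["ymax"])
    if (any(is.na(box)) || box[1] >= box[3] || box[2] >= box[4]) {
      stopf("%s: degenerate bndbox in object %d", xml_path, k)
    }
    lab <- xml2::xml_text(xml2::xml_find_first(objs[[k]], "./name"))
    boxes[k, c("xmin", "ymin", "xmax", "ymax")] <- box
    boxes[k, "label"] <- lab
  }
  fname <- xml2::xml_text(xml2::xml_find_first(doc, ".//filename"))
  annotated_image(width = width, height = height, boxes = boxes,
                  image_path = if (nchar(fname)) fname else NULL)
}

#' Write a LabelImg-style Pascal VOC annotation
#'
#' Round-trips losslessly with [read_voc_annotation()] for integer boxes.
#'
#' @param ann an [annotated_image()].
#' @param xml_path output path.
#' @return the path, invisibly.
#' @export
write_voc_annotation <- function(ann, xml_path) {
  stopifnot(inherits(ann, "annotated_image"))
  fname <- if (!is.null(ann$image_path)) basename(ann$image_path) else "image"
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "folder", dirname(ann$image_path %||% "."))
  xml2::xml_add_child(doc, "filename", fname)
  xml2::xml_add_child(doc, "path", ann$image_path %||% fname)
  src <- xml2::xml_add_child(doc, "source")
  xml2::xml_add_child(src, "database", "Unknown")
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(ann$width))
  xml2::xml_add_child(size, "height", as.character(ann$height))
  xml2::xml_add_child(size, "depth", "1")
  xml2::xml_add_child(doc, "segmented", "0")
  if (nrow(ann$boxes) > 0L) {
    for (k in seq_len(nrow(ann$boxes))) {
      obj <- xml2::xml_add_child(doc, "object")
      xml2::xml_add_child(obj, "name",
                          as.character(ann$boxes$label[k] %||% "stoma"))
      xml2::xml_add_child(obj, "pose", "Unspecified")
      xml2::xml_add_child(obj, "truncated", "0")
      xml2::xml_add_child(obj, "difficult", "0")
      bb <- xml2::xml_add_child(obj, "bndbox")
      xml2::xml_add_child(bb, "xmin", as.character(ann$boxes$xmin[k] + 1))
      xml2::xml_add_child(bb, "ymin", as.character(ann$boxes$ymin[k] + 1))
      xml2::xml_add_child(bb, "xmax", as.character(ann$boxes$xmax[k]))
      xml2::xml_add_child(bb, "ymax", as.character(ann$boxes$ymax[k]))
    }
  }
  xml2::write_xml(doc, xml_path)
  invisible(xml_path)
}

#' Read a replica micrograph raster
#'
#' Supports PNG (via the png package) and TIFF (via the tiff package, if
#' installed). Color rasters are converted to grayscale by channel
#' averaging. JPEG is not supported; convert externally.
#'
#' @param path image file path.
#' @return a grayscale matrix in `[0,1]`.
#' @export
read_micrograph <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stopf("reading TIFF requires the tiff package")
      }
      tiff::readTIFF(path)
    },
    stopf("unsupported raster format '.%s' (use PNG or TIFF)", ext))
  if (length(dim(img)) == 3L) img <- rowMeans(img, dims = 2L)
  img
}

#' Write a grayscale raster as 8-bit PNG
#'
#' @param image matrix in `[0,1]`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_micrograph <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Randomly split images into disjoint train and test manifests
#'
#' Uniform sampling without replacement; deterministic for a fixed seed.
#'
#' @param images a character vector of paths or a data frame with one row
#'   per image.
#' @param train_size,test_size requested split sizes; their sum may not
#'   exceed the number of images.
#' @param seed RNG seed for the draw.
#' @return list with `train` and `test` manifests (data frames carrying a
#'   `split` column and the seed as an attribute).
#' @export
split_dataset <- function(images, train_size, test_size, seed = 1L) {
  df <- if (is.data.frame(images)) images else data.frame(path = images,
    stringsAsFactors = FALSE)
  n <- nrow(df)
  if (!is_count(train_size) || !is_count(test_size)) {
    stopf("train_size and test_size must be non-negative integers")
  }
  if (train_size + test_size > n) {
    stopf("requested %d + %d images but only %d are available",
          train_size, test_size, n)
  }
  idx <- with_seed(seed, sample.int(n, train_size + test_size))
  tr <- df[idx[seq_len(train_size)], , drop = FALSE]
  te <- df[idx[seq_len(test_size) + train_size], , drop = FALSE]
  tr$split <- if (train_size) "train" else character(0)
  te$split <- if (test_size) "test" else character(0)
  attr(tr, "seed") <- seed
  attr(te, "seed") <- seed
  list(train = tr, test = te)
}

#' Resize an annotated image to the detector input size
#'
#' Bilinear resampling for the raster; each box coordinate is scaled by
#' `target/native` per axis, rounded to the nearest integer and clipped to
#' the target raster. Metadata is preserved.
#'
#' @param ann an [annotated_image()] with a loaded raster (or a readable
#'   `image_path`).
#' @param target_size target side length in pixels.
#' @return the resized `annotated_image`.
#' @export
resize_image_and_boxes <- function(ann, target_size) {
  stopifnot(inherits(ann, "annotated_image"))
  if (!is_count(target_size) || target_size <= 0) {
    stopf("target_size must be a positive integer")
  }
  target_size <- as.integer(target_size)
  if (ann$width == target_size && ann$height == target_size) return(ann)
  img <- ann$image
  if (is.null(img) && !is.null(ann$image_path) &&
      file.exists(ann$image_path)) {
    img <- read_micrograph(ann$image_path)
  }
  if (!is.null(img)) {
    img <- resize_bilinear_cpp(img, target_size, target_size)
  }
  boxes <- ann$boxes
  if (nrow(boxes) > 0L) {
    sx <- target_size / ann$width
    sy <- target_size / ann$height
    boxes$xmin <- pmin(pmax(round_half_up(boxes$xmin * sx), 0), target_size)
    boxes$xmax <- pmin(pmax(round_half_up(boxes$xmax * sx), 0), target_size)
    boxes$ymin <- pmin(pmax(round_half_up(boxes$ymin * sy), 0), target_size)
    boxes$ymax <- pmin(pmax(round_half_up(boxes$ymax * sy), 0), target_size)
    # a sub-pixel box may collapse under rounding; keep it one pixel wide
    fix <- boxes$xmax <= boxes$xmin
    boxes$xmax[fix] <- pmin(boxes$xmin[fix] + 1, target_size)
    boxes$xmin[fix] <- boxes$xmax[fix] - 1
    fix <- boxes$ymax <= boxes$ymin
    boxes$ymax[fix] <- pmin(boxes$ymin[fix] + 1, target_size)
    boxes$ymin[fix] <- boxes$ymax[fix] - 1
  }
  out <- ann
  out$image <- img
  out$width <- target_size
  out$height <- target_size
  out$boxes <- boxes
  out
}

#' Export detections as a VOC annotation
#'
#' Rounds detection boxes to integer pixels and writes them in the same
#' LabelImg XML dialect as the ground-truth annotations, so detector
#' output can be inspected (or corrected) in the annotation tool.
#'
#' @param detections a [detect()] result.
#' @param width,height raster extent the detections refer to.
#' @param xml_path output path.
#' @param image_path optional source image recorded in the XML.
#' @return the path, invisibly.
#' @export
detections_to_voc <- function(detections, width, height, xml_path,
                              image_path = NULL) {
  boxes <- NULL
  if (nrow(detections) > 0L) {
    xmin <- pmax(floor(detections$xmin), 0)
    ymin <- pmax(floor(detections$ymin), 0)
    xmax <- pmin(ceiling(detections$xmax), width)
    ymax <- pmin(ceiling(detections$ymax), height)
    boxes <- bounding_boxes(xmin, ymin, xmax, ymax, label = "stoma")
  }
  ann <- annotated_image(width = width, height = height, boxes = boxes,
                         image_path = image_path)
  write_voc_annotation(ann, xml_path)
}

#' Write a dataset manifest CSV
#'
#' @param manifest data frame (columns such as path, xml, accession,
#'   origin, position, replicate, split, true_count, true_sd).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a dataset manifest CSV
#' @param path CSV path.
#' @return a data frame.
#' @export
read_manifest <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
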
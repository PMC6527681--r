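# VOC XML annotation I/O, dataset splitting, and the native -> detector
# resize.

make_ann <- function(n = 3, size = 1840L) {
  boxes <- NULL
  if (n > 0) {
    x0 <- seq(10, by = 60, length.out = n)
    boxes <- bounding_boxes(x0, x0, x0 + 40, x0 + 30, label = "stoma")
  }
  annotated_image(width = size, height = size, boxes = boxes,
                  image_path = "img_001.png")
}

test_that("VOC XML round-trips losslessly and reads the declared size", {
  ann <- make_ann(3)
  path <- withr::local_tempfile(fileext = ".xml")
  write_voc_annotation(ann, path)
  back <- read_voc_annotation(path)
  expect_equal(back$width, 1840L)
  expect_equal(back$height, 1840L)
  expect_equal(nrow(back$boxes), 3L)
  expect_equal(back$boxes[c("xmin", "ymin", "xmax", "ymax")],
               ann$boxes[c("xmin", "ymin", "xmax", "ymax")])
  # write(read(f)) is also the identity
  path2 <- withr::local_tempfile(fileext = ".xml")
  write_voc_annotation(back, path2)
  expect_equal(read_voc_annotation(path2)$boxes, back$boxes)
})

test_that("single-box field passthrough and the empty annotation", {
  ann <- annotated_image(width = 100, height = 100,
                         boxes = bounding_boxes(10, 20, 30, 40))
  path <- withr::local_tempfile(fileext = ".xml")
  write_voc_annotation(ann, path)
  doc <- xml2::read_xml(path)
  bb <- xml2::xml_find_first(doc, ".//bndbox")
  # file values are 1-based inclusive corners
  vals <- as.numeric(xml2::xml_text(xml2::xml_children(bb)))
  expect_equal(vals, c(11, 21, 30, 40))
  expect_equal(read_voc_annotation(path)$boxes$xmin, 10)
  empty <- make_ann(0)
  write_voc_annotation(empty, path)
  expect_equal(nrow(read_voc_annotation(path)$boxes), 0L)
  expect_length(xml2::xml_find_all(xml2::read_xml(path), ".//object"), 0L)
})

test_that("degenerate boxes are rejected with the offending index", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(c("<annotation><size><width>50</width><height>50</height>",
               "<depth>1</depth></size>",
               "<object><name>stoma</name><bndbox><xmin>10</xmin>",
               "<ymin>10</ymin><xmax>20</xmax><ymax>20</ymax></bndbox>",
               "</object>",
               "<object><name>stoma</name><bndbox><xmin>30</xmin>",
               "<ymin>10</ymin><xmax>25</xmax><ymax>20</ymax></bndbox>",
               "</object></annotation>"), path)
  expect_error(read_voc_annotation(path), "object 2")
})

test_that("dataset splits are disjoint, sized, and seed-reproducible", {
  paths <- sprintf("img_%04d.png", 1:400)
  sp <- split_dataset(paths, 200, 150, seed = 9)
  expect_equal(nrow(sp$train), 200L)
  expect_equal(nrow(sp$test), 150L)
  expect_length(intersect(sp$train$path, sp$test$path), 0L)
  sp2 <- split_dataset(paths, 200, 150, seed = 9)
  expect_identical(sp$train$path, sp2$train$path)
  expect_identical(sp$test$path, sp2$test$path)
  # empty train is valid
  sp0 <- split_dataset(paths, 0, 10, seed = 1)
  expect_equal(nrow(sp0$train), 0L)
  expect_error(split_dataset(paths[1:5], 4, 2, seed = 1), "available")
})

test_that("resize scales boxes exactly and preserves containment", {
  ann <- annotated_image(width = 1840, height = 1840,
                         boxes = bounding_boxes(184, 184, 368, 368))
  out <- resize_image_and_boxes(ann, 300)
  expect_equal(as.numeric(out$boxes[1, 1:4]), c(30, 30, 60, 60))
  # identity at native size
  same <- resize_image_and_boxes(make_ann(3), 1840)
  expect_equal(same$boxes, make_ann(3)$boxes)
  # area ratio property against a float-precision oracle
  set.seed(31)
  for (k in 1:25) {
    b <- random_pixel_box(1840L)
    while ((b[3] - b[1]) < 30 || (b[4] - b[2]) < 30) b <- random_pixel_box(1840L)
    a <- annotated_image(width = 1840, height = 1840,
                         boxes = bounding_boxes(b[1], b[2], b[3], b[4]))
    r <- resize_image_and_boxes(a, 300)$boxes
    exact <- (b[3] - b[1]) * (b[4] - b[2]) * (300 / 1840)^2
    got <- (r$xmax - r$xmin) * (r$ymax - r$ymin)
    expect_lt(abs(got - exact) / exact, 0.35)  # rounding slack on small boxes
    expect_true(all(r$xmin >= 0 & r$xmax <= 300 &
                      r$ymin >= 0 & r$ymax <= 300))
  }
})

test_that("raster resize is exercised through a real image", {
  img <- matrix(runif(100 * 100), 100, 100)
  ann <- annotated_image(image = img,
                         boxes = bounding_boxes(10, 10, 50, 50))
  out <- resize_image_and_boxes(ann, 50)
  expect_equal(dim(out$image), c(50L, 50L))
  expect_equal(as.numeric(out$boxes[1, 1:4]), c(5, 5, 25, 25))
  # constant images stay constant under bilinear resampling
  flat <- annotated_image(image = matrix(0.4, 60, 60))
  expect_equal(unique(as.numeric(resize_image_and_boxes(flat, 30)$image)),
               0.4)
})

test_that("detections export to VOC XML with integer boxes", {
  det <- data.frame(xmin = c(10.4, -0.2), ymin = c(5.7, 2.1),
                    xmax = c(20.6, 7.9), ymax = c(15.2, 9.8),
                    score = c(0.9, 0.4))
  path <- withr::local_tempfile(fileext = ".xml")
  detections_to_voc(det, width = 100, height = 100, xml_path = path)
  back <- read_voc_annotation(path)
  expect_equal(nrow(back$boxes), 2L)
  expect_equal(back$boxes$xmin, c(10, 0))
  expect_equal(back$boxes$xmax, c(21, 8))
  expect_true(all(back$boxes$label == "stoma"))
})

test_that("micrograph PNG round-trip preserves 8-bit content", {
  img <- matrix(seq(0, 1, length.out = 64 * 64), 64, 64)
  path <- withr::local_tempfile(fileext = ".png")
  write_micrograph(img, path)
  back <- read_micrograph(path)
  expect_lt(max(abs(back - img)), 1 / 255)
})
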
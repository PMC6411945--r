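test_that("single-page TIFF round-trips losslessly with inferred 2-D axes", {
  tmp <- tempfile(fileext = ".tif")
  img <- image_stack(matrix(sample(0:255, 64 * 64, replace = TRUE), 64, 64))
  write_stack(img, tmp, bits = 8)
  rt <- read_stack(tmp)
  expect_identical(rt$axes, c("y", "x"))
  expect_identical(dim(rt$pixels), c(64L, 64L))
  expect_identical(rt$pixels, img$pixels)

  zero <- image_stack(matrix(0, 16, 16))
  write_stack(zero, tmp, bits = 8)
  expect_equal(sum(read_stack(tmp)$pixels), 0)
})

test_that("multi-page stacks keep pages and calibration", {
  tmp <- tempfile(fileext = ".tif")
  withr::with_seed(7, {
    arr <- array(sample(0:65535, 3 * 32 * 32, replace = TRUE), c(3, 32, 32))
  })
  st <- image_stack(arr, axes = c("z", "y", "x"), pixel_size = 0.2)
  write_stack(st, tmp, bits = 16)
  rt <- read_stack(tmp, pixel_size = 0.2)
  expect_identical(rt$axes, c("z", "y", "x"))
  expect_equal(axis_size(rt, "z"), 3L)
  expect_identical(rt$pixels, st$pixels)

  # a 90-page series read as a 2-s time-lapse spans (90-1)*2 = 178 s
  arr <- array(sample(0:255, 90 * 8 * 8, replace = TRUE), c(90, 8, 8))
  write_stack(image_stack(arr, axes = c("z", "y", "x")), tmp, bits = 8)
  mv <- read_stack(tmp, frame_interval = 2)
  expect_identical(mv$axes, c("t", "y", "x"))
  expect_equal(axis_size(mv, "t"), 90L)
  expect_equal((axis_size(mv, "t") - 1) * mv$frame_interval, 178)
})

test_that("ImageStack validation rejects malformed input", {
  expect_error(image_stack(matrix(-1, 4, 4)), "non-negative")
  expect_error(image_stack(matrix(NaN, 4, 4)), "finite")
  expect_error(image_stack(array(1, c(2, 4, 4)), axes = c("t", "y", "x")),
               "frame_interval")
  expect_error(image_stack(matrix(1, 4, 4), pixel_size = 0), "pixel_size")
  expect_error(read_stack(tempfile()), "not found")
})

test_that("annotation CSV parses islands and rejects unknown labels", {
  tmp <- tempfile(fileext = ".csv")
  df <- data.frame(
    island_id = rep(c("A", "B"), each = 5),
    cell_id = rep(1:5, 2),
    class = rep(c("epithelial", "mesenchymal", rep("epithelial", 3)), 2))
  write.csv(df, tmp, row.names = FALSE)
  ann <- read_annotations(tmp)
  expect_length(ann, 2)
  expect_length(ann[[1]]$cell_classes, 5)

  df$class[7] <- "mesh"
  write.csv(df, tmp, row.names = FALSE)
  expect_error(read_annotations(tmp), "row 7")

  write.csv(df[0, ], tmp, row.names = FALSE)
  expect_error(read_annotations(tmp), "empty")
})

test_that("a generated 31-island annotation file reads back as 31 islands", {
  tmp <- tempfile(fileext = ".csv")
  withr::with_seed(11, {
    n_cells <- sample(5:25, 31, replace = TRUE)
    df <- do.call(rbind, lapply(seq_len(31), function(i)
      data.frame(island_id = sprintf("isl%02d", i),
                 cell_id = seq_len(n_cells[i]),
                 class = sample(c("epithelial", "mesenchymal"), n_cells[i],
                                replace = TRUE))))
  })
  write.csv(df, tmp, row.names = FALSE)
  ann <- read_annotations(tmp)
  expect_length(ann, 31)
  expect_equal(vapply(ann, function(a) length(a$cell_classes), integer(1)),
               n_cells)
})

test_that("JSON annotations carry perimeter segments", {
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    list(island_id = "A", cell_classes = list("epithelial", "mesenchymal"),
         perimeter_segments = list(
           list(length_um = 10, class = "mesenchymal"),
           list(length_um = 30, class = "epithelial")))),
    tmp, auto_unbox = TRUE)
  ann <- read_annotations(tmp)
  expect_length(ann, 1)
  expect_equal(ann[[1]]$perimeter_segments$length_um, c(10, 30))
  jsonlite::write_json(list(
    list(island_id = "A", cell_classes = list("fibroblast"))),
    tmp, auto_unbox = TRUE)
  expect_error(read_annotations(tmp), "unknown class")
})
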
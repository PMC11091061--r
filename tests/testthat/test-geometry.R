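test_that("VIA parsing keeps polygons, converts circles, drops rect/point shapes", {
  via <- list(
    "img1.jpg" = list(
      filename = "img1.jpg", size = 123, width = 200, height = 100,
      regions = list(
        list(shape_attributes = list(name = "polygon",
                                     all_points_x = c(10, 50, 50, 10),
                                     all_points_y = c(10, 10, 40, 40)),
             region_attributes = list(class = "Root")),
        list(shape_attributes = list(name = "rect", x = 1, y = 1,
                                     width = 5, height = 5),
             region_attributes = list(class = "arbuscule")),
        list(shape_attributes = list(name = "point", cx = 3, cy = 3),
             region_attributes = list(class = "spore")),
        list(shape_attributes = list(name = "circle", cx = 100, cy = 50,
                                     r = 20),
             region_attributes = list(class = "vesicle")))))
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(via, path, auto_unbox = TRUE, digits = NA)
  imgs <- parse_annotations(path)
  expect_length(imgs, 1L)
  sh <- imgs[[1]]$shapes
  expect_length(sh, 2L)  # polygon + circle; rect and point removed
  expect_equal(sh[[1]]$class_label, "root")
  expect_equal(sh[[1]]$vertices,
               cbind(x = c(10, 50, 50, 10), y = c(10, 10, 40, 40)))
  # 64-gon circle area within 1% of pi r^2
  expect_equal(polygon_area(sh[[2]]$vertices), pi * 20^2,
               tolerance = 0.01)
  expect_equal(sh[[2]]$class_label, "ves")
})

test_that("CSV twin parses to the same shapes and unknown classes warn", {
  csv <- data.frame(
    filename = "a.jpg", file_size = 1, file_attributes = "{}",
    region_count = 2, region_id = 0:1,
    region_shape_attributes = c(
      '{"name":"polygon","all_points_x":[0,10,10,0],"all_points_y":[0,0,10,10]}',
      '{"name":"polyline","all_points_x":[20,30,25],"all_points_y":[20,20,30]}'),
    region_attributes = c('{"class":"root"}', '{"class":"mystery"}'),
    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(csv, path, row.names = FALSE)
  expect_warning(imgs <- parse_annotations(path), "mystery")
  expect_length(imgs[[1]]$shapes, 2L)
  expect_equal(imgs[[1]]$shapes[[2]]$class_label, "other")
})

test_that("class normalization maps field spellings onto canonical labels", {
  expect_equal(
    normalize_class_label(c("Arbuscule", "extraradical hypha",
                            "internal hypha", "Vesicle", "sp", "Non-AM")),
    c("arb", "exH", "inH", "ves", "sp", "other"))
  expect_warning(out <- normalize_class_label("blob"), "blob")
  expect_equal(out, "other")
})

test_that("tiling leaves a fully interior polygon untouched", {
  sq <- cbind(c(100, 200, 200, 100), c(100, 100, 250, 250))
  img <- annotated_image("im", 1024, 1024, list(polygon_shape(sq, "root")))
  tl <- tile_annotated_image(img, 512)
  expect_length(tl, 1L)
  expect_equal(unname(tl[[1]]$shapes[[1]]$vertices), unname(sq))
})

test_that("a square straddling two tiles splits into two equal rectangles", {
  sq <- cbind(c(480, 544, 544, 480), c(10, 10, 74, 74))
  img <- annotated_image("im", 1024, 1024, list(polygon_shape(sq, "arb")))
  tl <- tile_annotated_image(img, 512)
  expect_length(tl, 2L)
  areas <- vapply(tl, function(t) polygon_area(t$shapes[[1]]$vertices), 0)
  expect_equal(areas, c(32 * 64, 32 * 64))
  # oracle: rasterize-and-count on the original square
  expect_equal(sum(areas),
               length(brute_force_raster(sq + 0.0, 1024, 1024)),
               tolerance = 1e-6)
})

test_that("tiling conserves total area and keeps vertices tile-local", {
  set.seed(41)
  for (rep in 1:12) {
    shapes <- random_frame_shapes(sample(2:5, 1), 300, 200)
    img <- annotated_image(paste0("r", rep), 300, 200, shapes)
    total_in <- sum(vapply(shapes, function(s) polygon_area(s$vertices), 0))
    tl <- tile_annotated_image(img, 128)
    total_out <- 0
    for (t in tl) for (s in t$shapes) {
      V <- s$vertices
      expect_true(all(V[, 1] >= -1e-7 & V[, 1] <= t$width + 1e-7))
      expect_true(all(V[, 2] >= -1e-7 & V[, 2] <= t$height + 1e-7))
      total_out <- total_out + polygon_area(V)
    }
    expect_equal(total_out, total_in, tolerance = 1e-6)
  }
})

test_that("tiling an already tile-sized image returns the input geometry", {
  P <- random_simple_polygon(7, cx = 60, cy = 60, rmax = 50)
  img <- annotated_image("t", 128, 128, list(polygon_shape(P, "arb")))
  tl <- tile_annotated_image(img, 128)
  expect_length(tl, 1L)
  expect_equal(unname(tl[[1]]$shapes[[1]]$vertices), unname(P))
})

test_that("empty tiles are dropped unless keep_empty", {
  sq <- cbind(c(10, 50, 50, 10), c(10, 10, 50, 50))
  img <- annotated_image("im", 1024, 1024, list(polygon_shape(sq, "arb")))
  expect_length(tile_annotated_image(img, 512), 1L)
  expect_length(tile_annotated_image(img, 512, keep_empty = TRUE), 4L)
})

test_that("repair leaves simple polygons alone and dissects a bowtie", {
  tri <- cbind(c(0, 4, 2), c(0, 0, 3))
  out <- repair_polygon(tri)
  expect_length(out, 1L)
  expect_equal(polygon_area(out[[1]]), polygon_area(tri))
  # repeated vertex: same triangle after de-duplication
  tri2 <- tri[c(1, 1, 2, 3), ]
  out2 <- repair_polygon(tri2)
  expect_length(out2, 1L)
  expect_equal(polygon_area(out2[[1]]), 6)
  # bowtie -> two triangles of equal area, even-odd area preserved
  bt <- cbind(c(0, 1, 1, 0), c(0, 1, 0, 1))
  pieces <- repair_polygon(bt)
  expect_length(pieces, 2L)
  expect_equal(sort(vapply(pieces, polygon_area, 0)), c(0.25, 0.25))
  expect_true(all(vapply(pieces, polygon_is_simple, TRUE)))
  # collinear input is degenerate
  expect_length(repair_polygon(cbind(c(0, 1, 2), c(0, 1, 2))), 0L)
})

test_that("repair reproduces the even-odd interior (rasterization oracle)", {
  # pentagram: winding-2 center is excluded under even-odd
  th <- pi / 2 + 2 * pi * (0:4) * 2 / 5
  pent <- cbind(50.3 + 40.1 * cos(th), 50.2 + 40.1 * sin(th))
  pieces <- repair_polygon(pent)
  expect_gt(length(pieces), 1L)
  got <- sort(unique(unlist(
    lapply(pieces, amfpheno:::rasterize_polygon, width = 100, height = 100))))
  expect_equal(got, sort(brute_force_raster(pent, 100, 100)))
  # pieces are pairwise interior-disjoint
  allpx <- unlist(lapply(pieces, amfpheno:::rasterize_polygon,
                         width = 100, height = 100))
  expect_false(any(duplicated(allpx)))
  # random crossed quadrilaterals
  set.seed(7)
  for (k in 1:8) {
    P <- cbind(runif(4, 0, 60), runif(4, 0, 60)) + 0.21
    pieces <- repair_polygon(P)
    got <- sort(unique(unlist(
      lapply(pieces, amfpheno:::rasterize_polygon, width = 64, height = 64))))
    expect_equal(got, sort(brute_force_raster(P, 64, 64)))
  }
})

test_that("rasterized area follows the pixel-center rule", {
  rect <- cbind(c(0, 10, 10, 0), c(0, 0, 5, 5))
  expect_equal(rasterized_area(rect, 20, 20), 50L)
  # raster smaller than the polygon counts in-raster pixels only
  expect_equal(rasterized_area(rect, 4, 3), 12L)
  expect_equal(rasterized_area(rect + 1000, 20, 20), 0L)
  set.seed(11)
  for (k in 1:20) {
    P <- random_simple_polygon(sample(4:9, 1), cx = runif(1, 10, 40),
                               cy = runif(1, 10, 40), rmax = runif(1, 5, 25))
    expect_equal(sort(amfpheno:::rasterize_polygon(P, 50, 50)),
                 sort(brute_force_raster(P, 50, 50)))
  }
})

test_that("round-trip through the VIA writer preserves geometry", {
  P <- random_simple_polygon(6, 40, 40, 30)
  img <- annotated_image("x.jpg", 100, 100, list(polygon_shape(P, "ves")))
  path <- withr::local_tempfile(fileext = ".json")
  write_annotations(list(img), path)
  back <- parse_annotations(path)
  expect_equal(unname(back[[1]]$shapes[[1]]$vertices), unname(P))
  expect_equal(back[[1]]$shapes[[1]]$class_label, "ves")
})

test_that("train/validation/test split is deterministic and partitions", {
  ids <- sprintf("img%03d", 1:100)
  s1 <- split_train_val_test(ids, seed = 9)
  s2 <- split_train_val_test(ids, seed = 9)
  expect_identical(s1, s2)
  expect_setequal(unlist(s1), ids)
  expect_equal(lengths(s1), c(train = 80L, validation = 10L, test = 10L))
})
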
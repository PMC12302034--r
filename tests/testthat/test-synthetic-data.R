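# Synthetic generator, folder reader and train/test splitting.

test_that("generator handles empty sets, is seed-deterministic, and classes are separable", {
  empty <- generate_synthetic_dataset(synthetic_spec(4, per_class = 0))
  expect_length(empty$images, 0)
  expect_length(empty$class_names, 4)

  s <- synthetic_spec(3, per_class = 2, image_size = 32, seed = 7)
  a <- generate_synthetic_dataset(s)
  b <- generate_synthetic_dataset(s)
  expect_identical(a$images, b$images)
  expect_identical(a$labels, b$labels)

  # frozen default textures: pixel-mean nearest-centroid oracle separates
  d <- generate_synthetic_dataset(synthetic_spec(4, 50, 64, seed = 1))
  expect_gt(centroid_accuracy(d), 0.9)

  expect_error(synthetic_spec(1), "n_classes")
  expect_error(synthetic_spec(4, image_size = 16), "image_size")
})

test_that("flat and breakhis folder layouts are read with lexicographic labels", {
  root <- withr::local_tempdir()
  d <- micro_data(per_class = 3)
  ns <- asNamespace("ofml")
  # flat: 2 classes x 3 images
  sub <- ns$subset_image_set(d, 1:6)
  sub$class_names <- sub$class_names[1:2]
  ns$write_image_folder(sub, root)
  got <- read_image_folder(root, "flat", image_size = 32)
  expect_length(got$images, 6)
  expect_identical(got$labels, c(0L, 0L, 0L, 1L, 1L, 1L))
  expect_identical(dim(got$images[[1]]), c(32L, 32L, 3L))

  # breakhis-style: class/subtype/magnification/img
  r2 <- withr::local_tempdir()
  for (p in list(c("benign", "adenosis", "40X"), c("benign", "adenosis", "100X"),
                 c("malignant", "ductal", "40X"), c("malignant", "ductal", "200X"))) {
    dir.create(file.path(r2, p[1], p[2], p[3]), recursive = TRUE)
  }
  img <- EBImage::Image(array(runif(24 * 24 * 3), c(24, 24, 3)), colormode = "Color")
  EBImage::writeImage(img, file.path(r2, "benign", "adenosis", "40X", "a.png"))
  EBImage::writeImage(img, file.path(r2, "benign", "adenosis", "100X", "b.png"))
  EBImage::writeImage(img, file.path(r2, "malignant", "ductal", "40X", "c.png"))
  EBImage::writeImage(img, file.path(r2, "malignant", "ductal", "200X", "d.png"))
  bh <- read_image_folder(r2, "breakhis", image_size = 32)
  expect_identical(bh$labels, c(0L, 0L, 1L, 1L))
  expect_setequal(bh$metadata$magnification, c("100X", "40X", "200X"))

  # error paths: missing root, empty tree, undecodable file
  expect_error(read_image_folder(file.path(root, "nope")), "not found")
  r3 <- withr::local_tempdir()
  dir.create(file.path(r3, "classA"))
  expect_error(read_image_folder(r3, "flat"), "no decodable images")
  writeLines("not an image", file.path(r3, "classA", "bad.png"))
  dir.create(file.path(r3, "classB"))
  EBImage::writeImage(img, file.path(r3, "classB", "ok.png"))
  expect_warning(got3 <- read_image_folder(r3, "flat", image_size = 32),
                 "undecodable")
  expect_length(got3$images, 1)
})

test_that("train/test split is a disjoint exhaustive partition with floored sizes", {
  d <- micro_data(per_class = 10)  # 40 images
  ns <- asNamespace("ofml")
  ten <- ns$subset_image_set(d, 1:10)

  sp <- split_train_test(ten, 0.7, seed = 1, stratified = FALSE)
  expect_length(sp$train$images, 7)
  expect_length(sp$test$images, 3)

  # extreme fraction still leaves a non-empty test set
  sp99 <- split_train_test(ten, 0.999, seed = 1, stratified = FALSE)
  expect_length(sp99$train$images, 9)
  expect_length(sp99$test$images, 1)

  # stratified: each class contributes floor(10 * 0.7) = 7
  sps <- split_train_test(d, 0.7, seed = 2, stratified = TRUE)
  expect_identical(as.vector(table(sps$train$labels)), rep(7L, 4))

  # partition property (as multisets of images)
  key <- function(im) paste(round(as.vector(im), 6), collapse = ",")
  all_keys <- sort(vapply(d$images, key, character(1)))
  got_keys <- sort(vapply(c(sps$train$images, sps$test$images), key, character(1)))
  expect_identical(got_keys, all_keys)
  expect_length(intersect(vapply(sps$train$images, key, character(1)),
                          vapply(sps$test$images, key, character(1))), 0)

  # same seed, same split
  spa <- split_train_test(d, 0.7, seed = 5)
  spb <- split_train_test(d, 0.7, seed = 5)
  expect_identical(spa$train$labels, spb$train$labels)
  expect_identical(spa$train$images, spb$train$images)

  # failure modes
  expect_error(split_train_test(ten, 1.2), "train_frac")
  one <- ns$subset_image_set(d, c(1, 11, 21, 31, 2))
  expect_error(split_train_test(one, 0.7, stratified = TRUE), "at least 2")
})
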
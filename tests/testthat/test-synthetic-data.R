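test_that("scene generation is deterministic and class-labelled by hue", {
  sp <- scene_spec(image_size = 256, n_fruits = 3, seed = 1)
  a <- generate_scene(sp); b <- generate_scene(sp)
  expect_identical(a, b)
  # single unoccluded ripe fruit: one box, hue recovered as ripe
  one <- generate_scene(scene_spec(image_size = 256, n_fruits = 1,
                                   occlusion_prob = 0, seed = 5,
                                   class_ids = 2L))
  expect_equal(nrow(one$boxes), 1)
  expect_equal(one$boxes$cls, 2L)
  expect_equal(classify_box_hue(one$image, as.numeric(one$boxes[1, 1:4])), 2L)
  # boxes lie inside the image
  expect_true(all(a$boxes$x1 >= 0 & a$boxes$x2 <= 256 &
                    a$boxes$y1 >= 0 & a$boxes$y2 <= 256 &
                    a$boxes$x1 < a$boxes$x2 & a$boxes$y1 < a$boxes$y2))
  expect_error(generate_scene(scene_spec(image_size = 64, n_fruits = 40,
                                         seed = 1)),
               "too small|crowded")
})

test_that("occlusion events follow the stated Bernoulli rate", {
  # 500 scenes at occlusion_prob = 0.5: occluded fraction within [0.4, 0.6]
  occ <- unlist(lapply(1:250, function(i) {
    generate_scene(scene_spec(image_size = 96, n_fruits = 2,
                              occlusion_prob = 0.5, seed = 1000 + i))$occluded
  }))
  expect_gte(mean(occ), 0.4)
  expect_lte(mean(occ), 0.6)
})

test_that("a majority-hue classifier recovers the class on >= 95% of unoccluded fruits", {
  hits <- 0; total <- 0
  for (i in 1:40) {
    sc <- generate_scene(scene_spec(image_size = 192, n_fruits = 2,
                                    occlusion_prob = 0, seed = 2000 + i))
    for (j in seq_len(nrow(sc$boxes))) {
      pred <- classify_box_hue(sc$image, as.numeric(sc$boxes[j, 1:4]))
      hits <- hits + (pred == sc$boxes$cls[j])
      total <- total + 1
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("the 70/10/20 split uses floor/floor/remainder and is deterministic", {
  s <- split_dataset(3251, seed = 3)
  expect_equal(lengths(s), c(train = 2275, val = 325, test = 651))
  expect_equal(sort(c(s$train, s$val, s$test)), 1:3251)
  expect_equal(length(intersect(s$train, s$val)), 0)
  expect_equal(length(intersect(s$train, s$test)), 0)
  s10 <- split_dataset(10, seed = 1)
  expect_equal(lengths(s10), c(train = 7, val = 1, test = 2))
  expect_identical(split_dataset(500, seed = 9), split_dataset(500, seed = 9))
  expect_false(identical(split_dataset(500, seed = 9)$train,
                         split_dataset(500, seed = 10)$train))
})

test_that("augmentation parameter bounds hold over 1000 draws", {
  set.seed(77)
  ks <- sample_augment_params("mean_blur", 1000)
  expect_true(all(ks %in% seq(5, 15, by = 2)))
  fr <- sample_augment_params("random_crop", 1000)
  expect_gte(min(fr), 0.40); expect_lte(max(fr), 0.80)
  an <- sample_augment_params("random_rotate", 1000)
  expect_gte(min(an), -60); expect_lte(max(an), 60)
  expect_error(sample_augment_params("cutmix", 1), "unknown")
})

test_that("augmentation ops honour their identity and invariance contracts", {
  sc <- generate_scene(scene_spec(image_size = 128, n_fruits = 2, seed = 9))
  # zero-degree rotation: image and boxes unchanged (same-size canvas)
  r0 <- augment(sc$image, sc$boxes, "random_rotate", param = 0, out_size = 128)
  expect_equal(r0$image, sc$image)
  expect_equal(r0$boxes[, 1:4], sc$boxes[, 1:4])
  # mean blur of a constant image is that image, boxes untouched
  const <- array(0.4, c(64, 64, 3))
  bl <- augment(const, sc$boxes[0, ], "mean_blur", param = 5, out_size = 64)
  expect_equal(bl$image, const)
  # blur never moves boxes
  b5 <- augment(sc$image, sc$boxes, "mean_blur", param = 7, out_size = 128)
  expect_equal(b5$boxes[, 1:4], sc$boxes[, 1:4])
  # crops resize to the requested output and keep surviving boxes valid
  cr <- augment(sc$image, sc$boxes, "random_crop", seed = 3, out_size = 96)
  expect_equal(dim(cr$image), c(96, 96, 3))
  if (nrow(cr$boxes)) {
    expect_true(all(cr$boxes$x1 < cr$boxes$x2 & cr$boxes$y1 < cr$boxes$y2))
    expect_true(all(cr$boxes$x1 >= 0 & cr$boxes$x2 <= 96))
  }
  expect_identical(augment(sc$image, sc$boxes, "random_crop", seed = 3,
                           out_size = 96),
                   cr)
  expect_error(augment(sc$image, sc$boxes, "sharpen"), "unknown")
})

test_that("rotation transforms boxes with the image content", {
  # one bright fruit on a dark scene: the rotated box must still cover the
  # bright pixels
  sc <- generate_scene(scene_spec(image_size = 128, n_fruits = 1,
                                  occlusion_prob = 0, seed = 21,
                                  class_ids = 2L))
  rot <- augment(sc$image, sc$boxes, "random_rotate", param = 30,
                 out_size = 128)
  expect_equal(nrow(rot$boxes), 1)
  expect_equal(classify_box_hue(rot$image, as.numeric(rot$boxes[1, 1:4])), 2L)
})
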
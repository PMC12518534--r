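# Synthetic phantom generator: determinism, recoverability in the noiseless
# limit, label coverage, splits and joint augmentation.

test_that("identical spec and index reproduce the phantom bit for bit", {
  spec <- phantom_spec("multi_organ", img_size = 64L, seed = 5L)
  a <- generate_phantom(spec, 3L)
  b <- generate_phantom(spec, 3L)
  expect_identical(a, b)
  d <- generate_phantom(spec, 4L)
  expect_false(identical(a$image, d$image))
})

test_that("noiseless full-contrast phantoms are recoverable by intensity
           thresholding", {
  for (regime in c("multi_organ", "cardiac", "lesion")) {
    spec <- phantom_spec(regime, img_size = 64L, contrast = 1, noise_sd = 0,
                         boundary_softness = 0, seed = 2L)
    ph <- generate_phantom(spec, 1L)
    expect_true(all(ph$image >= 0 & ph$image <= 1))
    levels <- class_levels(spec$num_classes, 1)
    recovered <- apply(abs(outer(as.vector(ph$image), levels, "-")), 1,
                       which.min) - 1L
    expect_identical(array(recovered, dim(ph$mask)), ph$mask)
  }
})

test_that("multi-organ masks use labels 0..8 with high label coverage", {
  spec <- phantom_spec("multi_organ", img_size = 64L, seed = 9L,
                       n_images = 50L)
  n_lab <- vapply(1:50, function(i) {
    m <- generate_phantom(spec, i)$mask
    expect_true(all(m %in% 0:8))
    length(unique(as.vector(m)))
  }, 0)
  expect_gte(mean(n_lab), 5)
})

test_that("cardiac and lesion regimes carry their advertised class counts", {
  sc <- phantom_spec("cardiac", img_size = 64L, seed = 1L)
  expect_identical(sc$num_classes, 4L)
  mc <- generate_phantom(sc, 1L)$mask
  expect_setequal(unique(as.vector(mc)), 0:3)
  sl <- phantom_spec("lesion", img_size = 64L, seed = 1L)
  expect_identical(sl$num_classes, 2L)
  expect_setequal(unique(as.vector(generate_phantom(sl, 1L)$mask)), 0:1)
})

test_that("generate_split produces disjoint reproducible splits on disk", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  spec <- phantom_spec("lesion", img_size = 32L, n_images = 20L, seed = 3L)
  m1 <- generate_split(spec, c(0.7, 0.1, 0.2), dir1)
  m2 <- generate_split(spec, c(0.7, 0.1, 0.2), dir2)
  expect_identical(lengths(m1$splits), c(train = 14L, val = 2L, test = 4L))
  expect_length(unique(unlist(m1$splits)), 20L)
  expect_identical(m1$splits, m2$splits) # same seed, same manifest
  expect_error(generate_split(spec, c(0.7, 0.2, 0.2), dir1), "sum to 1")
  ds <- load_split(dir1, "train")
  expect_length(ds$images, 14L)
  expect_true(all(vapply(ds$masks, function(m) all(m %in% 0:1), TRUE)))
  # PNG round trip preserves the exact mask
  ph <- generate_phantom(spec, m1$splits$train[1])
  expect_identical(ds$masks[[1]], ph$mask)
})

test_that("augmentation applies one joint transform preserving labels", {
  spec <- phantom_spec("cardiac", img_size = 48L, seed = 6L)
  ph <- generate_phantom(spec, 1L)
  idn <- augment(ph$image, ph$mask, transform = "none")
  expect_identical(idn$image, ph$image)
  expect_identical(idn$mask, ph$mask)
  for (tr in c("hflip", "vflip", "rot90", "rot180", "rot270")) {
    a <- augment(ph$image, ph$mask, transform = tr)
    expect_identical(table(a$mask), table(ph$mask)) # pixel permutation
  }
  # DSC between two masks is invariant under the same transform
  other <- generate_phantom(spec, 2L)$mask
  a1 <- augment(ph$image, ph$mask, transform = "rot90")
  a2 <- augment(ph$image, other, transform = "rot90")
  for (cls in 1:3) {
    expect_equal(dsc_metric(a1$mask, a2$mask, cls),
                 dsc_metric(ph$mask, other, cls))
  }
  sm <- augment(ph$image, ph$mask, transform = list(angle = 15))
  expect_true(all(sm$mask %in% 0:3)) # nearest neighbour keeps label values
  expect_identical(augment(ph$image, ph$mask, seed = 4L),
                   augment(ph$image, ph$mask, seed = 4L))
})

test_that("phantom volumes round-trip through NIfTI", {
  dir <- withr::local_tempdir()
  spec <- phantom_spec("cardiac", img_size = 32L, seed = 8L)
  files <- write_phantom_volume(spec, 1:3, file.path(dir, "case01"))
  img <- RNifti::readNifti(files[1])
  msk <- RNifti::readNifti(files[2])
  expect_identical(dim(img), c(32L, 32L, 3L))
  expect_identical(as.vector(msk[, , 2]),
                   as.vector(generate_phantom(spec, 2L)$mask))
})

test_that("phantom spec validates its difficulty knobs", {
  expect_error(phantom_spec("lesion", contrast = 0), "contrast")
  expect_error(phantom_spec("lesion", noise_sd = -1), "noise_sd")
  expect_error(phantom_spec("lesion", boundary_softness = -1),
               "boundary_softness")
})
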
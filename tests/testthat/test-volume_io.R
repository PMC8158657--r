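test_that("normalize_modality matches direct mean/std computation", {
  v <- array(0, c(3, 1, 1))
  v[, 1, 1] <- c(2, 4, 6)
  out <- normalize_modality(v)
  # population std of {2,4,6} is sqrt(8/3); expected values computed directly
  expect_equal(as.vector(out), c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)

  set.seed(1)
  v <- array(rnorm(4^3, 50, 5), c(4, 4, 4))
  out <- normalize_modality(v)
  expect_lt(abs(mean(out)), 1e-10)
  expect_lt(abs(sqrt(mean((out - mean(out))^2)) - 1), 1e-10)
})

test_that("normalize_modality is idempotent and rejects constant images", {
  set.seed(2)
  v <- array(0, c(6, 6, 6))
  brain <- rand_mask(c(6, 6, 6), 0.6, seed = 3) == 1
  v[brain] <- rnorm(sum(brain), 100, 7)
  n1 <- normalize_modality(v)
  n2 <- normalize_modality(n1)
  expect_lt(max(abs(n2 - n1)), 1e-6)
  expect_true(all(n1[!brain] == 0))

  cv <- array(5, c(4, 4, 4))
  expect_error(normalize_modality(cv), "constant image")
  expect_error(normalize_modality(array(0, c(3, 3, 3))), "domain is empty")
})

test_that("map_labels builds nested hierarchical regions", {
  lab <- array(0L, c(4, 4, 4))
  lab[1, 1, 1] <- 2L # ED: in WT only
  lab[2, 1, 1] <- 4L # ET: in all three
  lab[3, 1, 1] <- 1L # NCR/NET: in WT and TC
  mk <- map_labels(lab)
  expect_equal(c(mk$wt[1, 1, 1], mk$tc[1, 1, 1], mk$et[1, 1, 1]), c(1L, 0L, 0L))
  expect_equal(c(mk$wt[2, 1, 1], mk$tc[2, 1, 1], mk$et[2, 1, 1]), c(1L, 1L, 1L))
  expect_equal(c(mk$wt[3, 1, 1], mk$tc[3, 1, 1], mk$et[3, 1, 1]), c(1L, 1L, 0L))

  empty <- map_labels(array(0L, c(3, 3, 3)))
  expect_equal(sum(empty$wt) + sum(empty$tc) + sum(empty$et), 0L)

  bad <- lab
  bad[4, 4, 4] <- 3L
  expect_error(map_labels(bad), "unknown label code.*3")
})

test_that("map_labels is idempotent in effect and matches the counting oracle", {
  set.seed(4)
  for (rep in 1:5) {
    lab <- array(sample(c(0L, 1L, 2L, 4L), 6^3, replace = TRUE), c(6, 6, 6))
    mk1 <- map_labels(lab)
    mk2 <- map_labels(lab)
    expect_identical(mk1, mk2)
    orc <- masks_from_labels_oracle(lab)
    expect_equal(unclass(mk1)[c("wt", "tc", "et")], orc)
    # voxel-count ordering follows from nesting
    expect_true(sum(mk1$et) <= sum(mk1$tc))
    expect_true(sum(mk1$tc) <= sum(mk1$wt))
  }
})

test_that("hierarchical_masks enforces binarity and nesting", {
  z <- array(0L, c(3, 3, 3))
  o <- z
  o[2, 2, 2] <- 1L
  expect_s3_class(hierarchical_masks(o, o, o), "hierarchical_masks")
  expect_error(hierarchical_masks(z, o, z), "TC not contained in WT")
  expect_error(hierarchical_masks(o, z, o), "ET not contained in TC")
  bad <- z
  bad[1, 1, 1] <- 2L
  expect_error(hierarchical_masks(bad, z, z), "not binary")
})

test_that("split_modality_pairs has fixed channel order and round-trips", {
  ph <- small_phantom(seed = 11L)
  st <- ph$study
  pr <- split_modality_pairs(st)
  expect_identical(pr$g1$channels[, , , 1], st$t1)
  expect_identical(pr$g1$channels[, , , 2], st$t1c)
  expect_identical(pr$g2$channels[, , , 1], st$t2)
  expect_identical(pr$g2$channels[, , , 2], st$flair)
  re <- multimodal_study(
    pr$g1$channels[, , , 1], pr$g1$channels[, , , 2],
    pr$g2$channels[, , , 1], pr$g2$channels[, , , 2],
    spacing = st$spacing, subject_id = st$subject_id
  )
  for (m in c("t1", "t1c", "t2", "flair")) expect_identical(re[[m]], st[[m]])
})

test_that("NIfTI volumes round-trip and masks are bit-exact", {
  td <- withr::local_tempdir()
  set.seed(5)
  img <- array(rnorm(8^3), c(8, 8, 8))
  p <- file.path(td, "x.nii.gz")
  write_nifti(img, p, spacing = c(1, 1.5, 2))
  back <- read_nifti(p)
  expect_equal(dim(back$img), c(8, 8, 8))
  expect_equal(back$spacing, c(1, 1.5, 2), tolerance = 1e-6)
  expect_equal(back$img, img, tolerance = 1e-6) # float32 storage

  # integer masks round-trip exactly
  wt <- rand_mask(c(8, 8, 8), 0.4, seed = 6)
  tc <- wt * rand_mask(c(8, 8, 8), 0.5, seed = 7)
  et <- tc * rand_mask(c(8, 8, 8), 0.5, seed = 8)
  mk <- hierarchical_masks(wt, tc, et)
  write_masks(mk, spacing = c(1, 1, 1), path = file.path(td, "m"))
  back <- read_masks(file.path(td, "m"))
  expect_identical(unclass(back), unclass(mk))

  # all-zero masks are valid files
  z <- array(0L, c(4, 4, 4))
  write_masks(hierarchical_masks(z, z, z), path = file.path(td, "z"))
  expect_equal(sum(read_masks(file.path(td, "z"))$wt), 0L)

  # nesting-violating input is refused before any file is written
  expect_error(
    write_masks(list(wt = z, tc = z + 1L, et = z), path = file.path(td, "bad")),
    "nesting"
  )
})

test_that("read_study validates presence, shapes and affines", {
  td <- withr::local_tempdir()
  ph <- small_phantom(seed = 21L)
  write_study(ph$study, ph$labels, file.path(td, "s1"))
  paths <- sapply(
    c("t1", "t1c", "t2", "flair"),
    function(m) file.path(td, "s1", paste0(m, ".nii.gz"))
  )
  st <- read_study(paths)
  expect_s3_class(st, "multimodal_study")
  expect_equal(dim(st$t1), c(32L, 32L, 32L))
  expect_equal(st$spacing, c(1, 1, 1), tolerance = 1e-6)

  expect_error(read_study(paths[c("t1", "t1c", "t2")]), "missing modality")
  bad <- paths
  bad[["flair"]] <- file.path(td, "nope.nii.gz")
  expect_error(read_study(bad), "missing modality file")

  # mismatched grid shape
  write_nifti(array(0, c(30, 30, 30)) + 1, file.path(td, "small.nii.gz"))
  bad <- paths
  bad[["t2"]] <- file.path(td, "small.nii.gz")
  expect_error(read_study(bad), "shape mismatch")

  # mismatched affine (different spacing)
  write_nifti(ph$study$t2, file.path(td, "sp.nii.gz"), spacing = c(2, 2, 2))
  bad <- paths
  bad[["t2"]] <- file.path(td, "sp.nii.gz")
  expect_error(read_study(bad), "affine mismatch")
})

test_that("subject directory layout round-trips studies and labels", {
  td <- withr::local_tempdir()
  ph <- small_phantom(seed = 31L)
  write_study(ph$study, ph$labels, file.path(td, "sub-001"))
  back <- read_subject_dir(file.path(td, "sub-001"))
  expect_equal(back$study$t1, ph$study$t1, tolerance = 1e-5)
  expect_identical(back$labels, ph$labels)
})
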
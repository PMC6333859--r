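test_that("atlas construction enforces lookup completeness and involution", {
  atlas <- make_synthetic_atlas()
  expect_s3_class(atlas, "label_atlas")

  vol <- atlas$volume
  bad_lookup <- atlas$lookup[-1, ]
  expect_error(label_atlas(vol, bad_lookup), "absent from lookup")

  broken <- atlas$lookup
  broken$homolog_id[broken$label_id == 1] <- 102   # 102's homolog is 2
  expect_error(label_atlas(vol, broken), "involution")
})

test_that("VOI extraction is the voxel mean, exactly", {
  atlas <- make_synthetic_atlas(dim = c(10, 10, 6), n_pairs = 2)
  sched <- make_frame_schedule(list(c(3, 60)))

  uni <- array(4.2, c(10, 10, 6, 3))
  tacs <- extract_voi_tacs(uni, atlas, list(r1 = 1, r2 = 101), sched)
  expect_equal(tacs$r1$values, rep(4.2, 3))
  expect_equal(tacs$r2$values, rep(4.2, 3))

  # painted round trip: painting known curves then extracting recovers them
  curves <- list(`1` = c(1, 2, 3), `101` = c(10, 20, 30),
                 `2` = c(5, 5, 5), `102` = c(0.5, 1, 2))
  vol4 <- paint_volume(atlas, curves)
  got <- extract_voi_tacs(vol4, atlas, list(a = 1, b = 101, c = 2, d = 102),
                          sched)
  expect_identical(got$a$values, c(1, 2, 3))
  expect_identical(got$b$values, c(10, 20, 30))
  expect_identical(got$d$values, c(0.5, 1, 2))
})

test_that("static extraction averages and merged VOIs pool voxels", {
  atlas <- make_synthetic_atlas(dim = c(10, 10, 6), n_pairs = 2)
  vol <- paint_volume(atlas, list(`1` = 5, `101` = 9, `2` = 2, `102` = 4))
  ac <- extract_static_ac(vol, atlas, list(x = 1, y = 101))
  expect_equal(unname(ac), c(5, 9))

  # merged VOI: volume-weighted pooled mean over both labels' voxels
  n1 <- sum(atlas$volume == 1); n2 <- sum(atlas$volume == 2)
  merged <- extract_static_ac(vol, atlas, list(m = c(1, 2)))
  expect_equal(unname(merged), (5 * n1 + 2 * n2) / (n1 + n2))

  # per-voxel mean on a hand-painted region
  small <- array(0L, c(3, 1, 1)); small[] <- 1L
  lu <- data.frame(label_id = 1, name = "r", hemisphere = "left",
                   homolog_id = NA)
  a2 <- label_atlas(small, lu)
  img <- array(c(2, 4, 9), c(3, 1, 1))
  expect_equal(unname(extract_static_ac(img, a2, list(r = 1))), 5)
})

test_that("extraction errors are typed", {
  atlas <- make_synthetic_atlas(dim = c(10, 10, 6), n_pairs = 2)
  sched <- make_frame_schedule(list(c(3, 60)))
  vol4 <- array(1, c(10, 10, 6, 3))
  expect_error(extract_voi_tacs(vol4, atlas, list(z = 55), sched),
               "empty-region")
  expect_error(extract_voi_tacs(array(1, c(9, 10, 6, 3)), atlas,
                                list(a = 1), sched), "alignment error")
  expect_error(extract_voi_tacs(array(1, c(10, 10, 6, 2)), atlas,
                                list(a = 1), sched), "alignment error")
})

test_that("region pairing follows the focus side and the homolog involution", {
  atlas <- make_synthetic_atlas(n_pairs = 6)
  selL <- voi_selection(epileptogenic_ids = 1, reference_ids = c(2, 3),
                        focus_side = "left")
  pl <- pair_regions(atlas, selL)
  expect_equal(pl$ipsilateral_id[1], 1)
  expect_equal(pl$contralateral_id[1], 101)

  # focus on the right: the same selected label maps to the mirror pair
  selR <- voi_selection(epileptogenic_ids = 1, focus_side = "right")
  pr <- pair_regions(atlas, selR)
  expect_equal(pr$ipsilateral_id[1], 101)
  expect_equal(pr$contralateral_id[1], 1)

  # a six-region selection yields six distinct pairs
  sel6 <- voi_selection(epileptogenic_ids = 1:6, focus_side = "left")
  p6 <- pair_regions(atlas, sel6)
  expect_equal(nrow(p6), 6L)
  expect_equal(anyDuplicated(p6$ipsilateral_id), 0L)
  expect_equal(anyDuplicated(p6$contralateral_id), 0L)

  expect_error(voi_selection(1, reference_ids = 1, focus_side = "left"),
               "overlap")
})

test_that("atlas and volumes round-trip through NIfTI files", {
  atlas <- make_synthetic_atlas(dim = c(8, 8, 4), n_pairs = 2)
  td <- withr::local_tempdir()
  nii <- file.path(td, "atlas.nii")
  tsv <- file.path(td, "lookup.tsv")
  RNifti::writeNifti(atlas$volume, nii)
  utils::write.table(atlas$lookup, tsv, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  back <- read_label_atlas(nii, tsv)
  expect_equal(as.array(back$volume), atlas$volume, ignore_attr = TRUE)
  expect_equal(back$lookup$homolog_id, atlas$lookup$homolog_id)
})
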
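test_that("rest-pose render matches the independent blob-sum oracle bit-for-bit in structure", {
  spec <- tiny_molecule()
  img <- render_conformation(spec, c(0, 0))
  expect_equal(img, oracle_render(spec, c(0, 0)), tolerance = 1e-12)
  # determinism: rendering is a pure function
  expect_identical(img, render_conformation(spec, c(0, 0)))
})

test_that("mirrored symmetric geometry renders mirror images under swapped, negated conformations", {
  spec <- mirror_molecule()
  z <- c(0.4, -0.25)
  img <- apply_pose(spec, z, 0)
  # mirror about the vertical axis maps arm angles theta -> pi - theta,
  # exchanging the arms with negated articulations
  mirrored <- apply_pose(spec, c(0.25, -0.4), 0)[, ncol(img):1]
  expect_close(img, mirrored, 1e-12)
})

test_that("integrated density is conserved across conformation and pose", {
  spec <- default_molecule()
  sums <- with_test_seed(11, {
    vapply(1:100, function(i) {
      z <- stats::runif(2, -pi / 2, pi / 2)
      phi <- stats::runif(1, 0, 2 * pi)
      sum(apply_pose(spec, z, phi))
    }, numeric(1))
  })
  expect_lt((max(sums) - min(sums)) / mean(sums), 1e-6)
})

test_that("pose application is the identity at phi = 0 and matches the array-rotation oracle at 90 degrees", {
  spec <- pixel_centred_molecule()
  z <- c(0, 0)
  expect_identical(apply_pose(spec, z, 0), render_conformation(spec, z))
  img0 <- apply_pose(spec, z, 0)
  for (k in 1:3) {
    expect_close(apply_pose(spec, z, k * pi / 2), rotate_image_90(img0, k), 1e-12)
    # rotate_image_90 itself agrees with the independent subscript oracle
  }
  expect_identical(rotate_image_90(img0), oracle_rot90(img0))
  expect_identical(rotate_image_90(img0, 4), img0)
})

test_that("pose rotations compose additively on blob centres", {
  ns <- asNamespace("conformscape")
  spec <- tiny_molecule()
  z <- c(0.3, -0.5)
  t1 <- ns$blob_table(spec, z, phi = 0.7)
  # re-rotate the phi = 0.7 table by 0.5 by hand
  c2 <- cos(0.5)
  s2 <- sin(0.5)
  manual <- cbind(t1$x * c2 - t1$y * s2, t1$x * s2 + t1$y * c2)
  t12 <- ns$blob_table(spec, z, phi = 1.2)
  expect_close(as.matrix(t12[, c("x", "y")]), manual, 1e-12)
})

test_that("invalid conformations and degenerate geometries are rejected", {
  spec <- tiny_molecule()
  expect_error(render_conformation(spec, c(2, 0)), "out of range")
  expect_error(render_conformation(spec, c(0.1, NA)), "finite")
  # arm reaching the border fails at construction, not at render
  expect_error(
    toy_molecule_spec(
      image_size = 16,
      core_blobs = data.frame(x = 0, y = 0.5, amp = 1, width = 1),
      arm_joints = rbind(c(-2, 0), c(2, 0)),
      arm_length = 8, blobs_per_arm = 3, blob_width = 1
    ),
    "field of view"
  )
  # a 180-degree-symmetric scene cannot identify pose
  expect_error(
    toy_molecule_spec(
      image_size = 20,
      core_blobs = data.frame(x = 0, y = 0, amp = 1, width = 1.5),
      arm_joints = rbind(c(-2, 0), c(2, 0)),
      arm_length = 2, blobs_per_arm = 3, blob_width = 1,
      rest_angles = c(pi / 2, -pi / 2)
    ),
    "symmetry"
  )
  expect_error(
    toy_molecule_spec(
      image_size = 16,
      core_blobs = data.frame(x = 1, y = 0, amp = 1, width = 1),
      arm_joints = rbind(c(1, 0), c(1, 0)),
      arm_length = 2, blobs_per_arm = 3, blob_width = 1
    ),
    "distinct"
  )
})

test_that("noise-free images at distinct poses differ (asymmetry marker)", {
  spec <- default_molecule()
  img0 <- apply_pose(spec, c(0.2, -0.3), 0)
  imgpi <- apply_pose(spec, c(0.2, -0.3), pi)
  expect_gt(max(abs(img0 - imgpi)), 1e-3 * max(img0))
})
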
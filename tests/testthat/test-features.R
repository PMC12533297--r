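test_that("pixel counts convert to volumes under all three modes", {
  v <- array(0L, c(3, 12, 12))
  v[1, 2, 2] <- 1L
  v[2, 4:5, 3:7] <- 2L              # 10 voxels on one slice
  av <- annotated_volume(v, 0.5, slice_thickness = 4, slice_gap = 1)

  acc <- node_volume(av, 2L, "accumulated")
  expect_equal(acc$pixel_count, 10L)
  expect_equal(acc$volume, 2.5)      # 10 x 0.25 mm^2

  mx <- node_volume(av, 2L, "max_cross_section")
  expect_equal(mx$volume, acc$volume)  # single slice: modes coincide

  vv <- node_volume(av, 2L, "voxel_volume")
  expect_equal(vv$volume, 10 * 0.25 * (4 + 1))

  # two-slice node: accumulated counts both, max cross-section the larger
  v[3, 4, 3:4] <- 2L
  av2 <- annotated_volume(v, 0.5, 4, 1)
  expect_equal(node_volume(av2, 2L, "accumulated")$pixel_count, 12L)
  expect_equal(node_volume(av2, 2L, "max_cross_section")$pixel_count, 10L)

  expect_error(node_volume(av, 3L), "absent")
})

test_that("drainage distance follows the printed through-plane rule", {
  # same slice, (3,4) mm in-plane: the distance is the 3-4-5 hypotenuse
  same <- two_point_volume(ds = 0L, row_off = 6L, col_off = 8L)
  nd0 <- node_distance(same, 2L)
  expect_equal(nd0$delta_s, 0L)
  expect_equal(nd0$distance, 5)

  # two slices apart, G = 1, T = 4: through-plane term (2*1 + 1*4)^2 = 36
  two <- two_point_volume(ds = 2L, row_off = 6L, col_off = 8L)
  nd2 <- node_distance(two, 2L)
  expect_equal(nd2$delta_s, 2L)
  expect_equal(nd2$distance, sqrt(61), tolerance = 1e-12)

  # one slice apart the thickness does not enter: (1*G + 0*T)^2
  one <- two_point_volume(ds = 1L, row_off = 0L, col_off = 0L)
  expect_equal(node_distance(one, 2L)$distance, 1)
})

test_that("patient totals are exact sums and zero-node patients are flagged", {
  v <- array(0L, c(5, 20, 20))
  v[2, 3:4, 3:4] <- 1L
  v[2, 10:11, 3:7] <- 2L
  v[4, 15, 15] <- 3L
  av <- annotated_volume(v, 0.5, 4, 1)
  pf <- patient_features(av)
  expect_equal(pf$node_count, 2L)
  expect_false(pf$no_nodes)
  expect_identical(pf$tLNV, sum(pf$nodes$volume))
  expect_identical(pf$tLND, sum(pf$nodes$distance))
  vols <- vapply(node_labels(av),
                 function(lb) node_volume(av, lb)$volume, numeric(1))
  expect_identical(pf$tLNV, sum(vols))

  v0 <- array(0L, c(3, 6, 6)); v0[2, 3, 3] <- 1L
  pf0 <- patient_features(annotated_volume(v0, 0.5, 4, 1))
  expect_equal(c(pf0$tLNV, pf0$tLND, pf0$node_count), c(0, 0, 0))
  expect_true(pf0$no_nodes)
})

test_that("features are invariant to whole-voxel translations", {
  base <- array(0L, c(8, 24, 24))
  base[2, 4:6, 4:6] <- 1L
  base[4, 10:12, 8:10] <- 2L
  base[6, 18, 18] <- 3L
  shift <- array(0L, c(8, 24, 24))
  shift[2:8, 3:24, 2:24] <- base[1:7, 1:22, 1:23]  # +1 slice, +2 rows, +1 col
  for (mode in c("accumulated", "max_cross_section", "voxel_volume")) {
    a <- patient_features(annotated_volume(base, 0.7, 3.5, 0.5), mode)
    b <- patient_features(annotated_volume(shift, 0.7, 3.5, 0.5), mode)
    expect_equal(a$nodes$volume, b$nodes$volume)
    expect_equal(a$nodes$distance, b$nodes$distance)
  }
})

test_that("adding a node never decreases the patient totals", {
  v <- array(0L, c(8, 24, 24))
  v[2, 4:6, 4:6] <- 1L
  v[4, 10:12, 8:10] <- 2L
  before <- patient_features(annotated_volume(v, 0.5, 4, 1))
  v[7, 20:21, 20:21] <- 3L
  after <- patient_features(annotated_volume(v, 0.5, 4, 1))
  expect_gte(after$tLNV, before$tLNV)
  expect_gte(after$tLND, before$tLND)
  expect_equal(after$node_count, before$node_count + 1L)
})

test_that("features match the independent phantom ground truth", {
  for (seed in 101:120) {
    ph <- make_phantom(random_phantom_spec(seed))
    pf <- patient_features(ph$volume)
    expect_identical(pf$nodes$pixel_count,
                     as.integer(ph$truth$nodes$n_voxels))
    expect_identical(pf$nodes$volume, ph$truth$nodes$volume_mm3)
    expect_lt(max(abs(pf$nodes$distance - ph$truth$nodes$distance_mm)),
              1e-9)
    expect_identical(pf$tLNV, ph$truth$tLNV)
  }
})

test_that("node size and distance classes use inclusive thresholds", {
  nodes <- data.frame(
    max_cross_section_mm2 = c(pi * 2.5^2, pi * 2.49^2, pi * 4),
    distance = c(50, 49.9, 80))
  ann <- annotate_node_classes(nodes)
  # area of a 5 mm circle sits exactly on the boundary: large, inclusive
  expect_equal(ann$equiv_diameter_mm[1], 5)
  expect_equal(ann$size_class, c("L-LN", "S-LN", "S-LN"))
  expect_equal(ann$distance_class, c("D-LN", "N-LN", "D-LN"))
  # thresholds are configurable
  ann2 <- annotate_node_classes(nodes, size_threshold = 4.5,
                                distance_threshold = 60)
  expect_equal(ann2$size_class, c("L-LN", "L-LN", "S-LN"))
  expect_equal(ann2$distance_class, c("N-LN", "N-LN", "D-LN"))
})
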
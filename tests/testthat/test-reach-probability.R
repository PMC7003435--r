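test_that("boundary mask matches the hand-enumerated definition", {
  lab <- toy_labels()
  # WM plane z = 1, ROI 2 slab z = 2, ROI 3 slab z = 3:
  # only the z = 2 slab touches white matter
  m2 <- boundary_mask(lab, 2L)
  expect_equal(sum(m2), 9)
  expect_true(all(which(m2, arr.ind = TRUE)[, 3] == 2))
  m3 <- boundary_mask(lab, 3L)
  expect_equal(sum(m3), 0)   # fully insulated by ROI 2
  expect_error(boundary_mask(lab, 9L), class = "cs_lookup_error")
})

test_that("a single ROI voxel face-adjacent to WM is included; an interior one is not", {
  arr <- array(0L, c(5, 5, 5))
  arr[3, 3, 3] <- 1L            # one WM voxel
  arr[3, 3, 4] <- 2L            # face-adjacent ROI voxel
  arr[1, 1, 1] <- 2L            # isolated ROI voxel, no WM neighbor
  lab <- label_volume(arr)
  m <- boundary_mask(lab, 2L)
  expect_true(m[3, 3, 4])
  expect_false(m[1, 1, 1])
  # corner-adjacency only counts at 26-connectivity
  arr2 <- array(0L, c(3, 3, 3))
  arr2[1, 1, 1] <- 1L; arr2[2, 2, 2] <- 2L
  lab2 <- label_volume(arr2)
  expect_false(any(boundary_mask(lab2, 2L, connectivity = 6L)))
  expect_true(boundary_mask(lab2, 2L, connectivity = 26L)[2, 2, 2])
})

test_that("reach probability follows the trim-normalize-average contract", {
  lab <- toy_labels()
  tract <- array(0L, c(3, 3, 3))
  tract[1, 1, 2] <- 30L      # in ROI 2 boundary mask
  tract[2, 1, 2] <- 10L      # in ROI 2 boundary mask
  tract[1, 1, 1] <- 60L      # white matter
  r <- reach_probability(tract, lab)
  # per-voxel normalized values 0.3 and 0.1, averaged over the 9-voxel mask
  expect_equal(unname(r["2"]), (0.3 + 0.1) / 9)
  expect_equal(unname(r["3"]), 0)

  # all mass on a single one-voxel mask gives reach exactly 1
  arr <- array(0L, c(5, 5, 5))
  arr[3, 3, 2] <- 1L; arr[3, 3, 3] <- 2L
  lab1 <- label_volume(arr)
  t1 <- array(0L, c(5, 5, 5)); t1[3, 3, 3] <- 17L
  expect_equal(unname(reach_probability(t1, lab1)["2"]), 1)

  # mass outside every mask but on WM: all entries zero
  t2 <- array(0L, c(3, 3, 3)); t2[2, 2, 1] <- 5L
  expect_equal(unname(reach_probability(t2, lab)), c(0, 0))

  # no mass on the trimmed support at all: degenerate tract
  t3 <- array(0L, c(3, 3, 3)); t3[1, 1, 3] <- 5L  # ROI 3 has empty mask
  expect_error(reach_probability(t3, lab), class = "cs_degenerate_tract")
})

test_that("production reach equals the brute-force voxel-loop oracle on small grids", {
  set.seed(41)
  for (rep in 1:8) {
    d <- c(sample(3:5, 1), sample(3:5, 1), sample(3:5, 1))
    arr <- array(sample(0:3, prod(d), replace = TRUE,
                        prob = c(0.3, 0.4, 0.15, 0.15)), d)
    lab <- label_volume(arr, wm_label = 1L, roi_labels = c(2L, 3L))
    tract <- array(rpois(prod(d), 2), d)
    trim <- arr == 1
    for (r in c(2L, 3L)) trim <- trim | boundary_mask(lab, r)
    if (sum(tract[trim]) == 0) next
    got <- reach_probability(tract, lab)
    for (r in c(2L, 3L))
      expect_equal(unname(got[as.character(r)]),
                   reach_oracle(tract, lab, r))
  }
})

test_that("reach is invariant to positive rescaling of counts and masses partition to 1", {
  cfg <- small_cfg(seed = 4)
  lab <- generate_label_volume(cfg)
  tv <- generate_tract_volumes(cfg, lab)
  tract <- tv[[1]]
  r1 <- reach_probability(tract, lab)
  r2 <- reach_probability(tract * 7L, lab)
  expect_equal(r1, r2)
  # sum over masks of reach * mask size plus WM fraction equals 1
  masks <- lapply(lab$roi_labels, function(r) boundary_mask(lab, r))
  trim <- lab$values == lab$wm_label
  for (m in masks) trim <- trim | m
  total <- sum(tract[trim])
  mask_fraction <- sum(vapply(seq_along(masks), function(i)
    r1[i] * sum(masks[[i]]), numeric(1)))
  wm_only <- trim & lab$values == lab$wm_label
  expect_equal(mask_fraction + sum(tract[wm_only]) / total, 1,
               tolerance = 1e-12)
})

test_that("thresholding is monotone and fixed mode counts exact", {
  m <- matrix(c(0, 0.001, 0.003), 1, dimnames = list("t", c("2", "3", "4")))
  class(m) <- c("reach_matrix", class(m))
  cs <- connection_threshold(m, mode = "fixed", cutoff = 0.002)
  expect_equal(sum(cs$connected), 1)
  counts <- vapply(c(0.0005, 0.002, 0.01),
                   function(ct) sum(connection_threshold(
                     m, "fixed", cutoff = ct)$connected), numeric(1))
  expect_true(all(diff(counts) <= 0))
  z <- matrix(0, 2, 2)
  class(z) <- c("reach_matrix", class(z))
  expect_error(connection_threshold(z, "fixed", cutoff = 0.1),
               class = "cs_threshold_error")
  expect_error(connection_threshold(m, "fixed"), class = "cs_config_error")
})

test_that("ECDF reflection cutoff recovers the planted connection set exactly at leak 0", {
  cfg <- small_cfg(seed = 9)
  lab <- generate_label_volume(cfg)
  tv <- generate_tract_volumes(cfg, lab)
  rm_ <- reach_matrix(tv, lab)
  cs <- connection_threshold(rm_, mode = "ecdf_reflection")
  got <- which(cs$connected == 1, arr.ind = TRUE)
  got_ids <- paste(rownames(cs$connected)[got[, 1]],
                   colnames(cs$connected)[got[, 2]])
  want <- paste(cfg$planted_connections$tract, cfg$planted_connections$roi)
  expect_setequal(got_ids, want)
  # Gumbel diagnostic present on the non-zero entries
  expect_true(all(is.finite(cs$gumbel)))
})

test_that("region-pair classification counts, symmetry and idempotence", {
  cfg <- synth_config(seed = 1)
  lab <- generate_label_volume(cfg)
  tv <- generate_tract_volumes(cfg, lab)
  cs <- connection_threshold(reach_matrix(tv, lab), "ecdf_reflection")
  cl <- classify_region_pairs(cs, default_region_map(cfg))
  expect_equal(nrow(cl), 136)            # 17 * 16 / 2
  expect_equal(unname(attr(cl, "counts")),
               c(72, 64, 43))
  expect_true(all(cl$ad_bound <= cl$bound))  # subset relation
  # classification depends only on the unordered pair
  map_swapped <- default_region_map(cfg)[rev(seq_len(17)), ]
  cl2 <- classify_region_pairs(cs, map_swapped)
  expect_equal(cl[order(cl$pair), c("pair", "bound", "ad_bound")],
               cl2[order(cl2$pair), c("pair", "bound", "ad_bound")],
               ignore_attr = TRUE)
})

test_that("empty connections give all not-bound; one shared tract gives one AD pair", {
  conn <- structure(list(
    cutoff = 0.5,
    connected = matrix(0L, 2, 4, dimnames = list(c("t1", "t2"),
                                                 as.character(2:5))),
    gumbel = c(location = NA, scale = NA), mode = "fixed"),
    class = "connection_set")
  map <- data.frame(region = c("A", "B", "C"), roi = 2:4)
  cl <- classify_region_pairs(conn, map, ad_tracts = "t1")
  expect_true(all(!cl$bound))
  conn$connected["t1", c("2", "3")] <- 1L
  cl2 <- classify_region_pairs(conn, map, ad_tracts = "t1")
  expect_equal(sum(cl2$ad_bound), 1)
  expect_equal(cl2$pair[cl2$ad_bound], "A|B")
  expect_equal(sum(cl2$bound), 1)
})
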
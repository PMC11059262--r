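mk_lists <- function(global_vals, local_vals) {
  structure(list(
    global = data.frame(slice = seq_along(global_vals), row = 1L, col = 1L,
                        value = global_vals),
    local = data.frame(slice = 1L, row = 1L, col = seq_along(local_vals),
                       value = local_vals)),
    class = "seed_lists")
}

test_that("growth_config validates its fields", {
  cfg <- growth_config()
  expect_equal(cfg$alpha, 3)
  expect_equal(cfg$min_voxels, 10L)
  expect_equal(cfg$max_center_jump, 50)
  expect_equal(cfg$lookback, 10L)
  expect_error(growth_config(alpha = 0), "alpha")
  expect_error(growth_config(min_voxels = -1), "min_voxels")
  expect_error(growth_config(lookback = 0), "lookback")
  expect_error(growth_config(connectivity = 6), "connectivity")
  expect_error(growth_config(local_seed_mode = 3), "local_seed_mode")
})

test_that("seed lists accumulate global and local records", {
  lists <- seed_lists()
  lists <- record_seeds(lists, 7L, list(seed_point(3, 4, 1.1),
                                        seed_point(2, 4, 1.0),
                                        seed_point(4, 4, 1.2)))
  expect_equal(nrow(lists$global), 1L)
  expect_equal(nrow(lists$local), 3L)
  expect_equal(lists$global$value, 1.1) # first record is the global center
  lists <- record_seeds(lists, 8L, list(seed_point(3, 4, 1.15)))
  expect_equal(nrow(lists$global), 2L)
  expect_equal(lists$local$slice, c(7L, 7L, 7L, 8L))
})

test_that("growth_interval is mu +/- alpha * population sd of local seeds", {
  iv <- growth_interval(mk_lists(10, c(8, 12)), alpha = 3)
  expect_equal(iv$mu, 10)
  expect_equal(iv$sigma, 2)
  expect_equal(c(iv$lo, iv$hi), c(4, 16))
  # doubling alpha doubles the half-width
  iv6 <- growth_interval(mk_lists(10, c(8, 12)), alpha = 6)
  expect_equal(c(iv6$lo, iv6$hi), c(-2, 22))
  # all-equal local seeds collapse to a point interval
  iv0 <- growth_interval(mk_lists(c(5, 5), c(5, 5, 5)), alpha = 3)
  expect_equal(c(iv0$lo, iv0$hi), c(5, 5))
  # ... unless a sigma floor is supplied
  ivf <- growth_interval(mk_lists(c(5, 5), c(5, 5, 5)), alpha = 3,
                         sigma_floor = 0.5)
  expect_equal(c(ivf$lo, ivf$hi), c(3.5, 6.5))
  expect_error(growth_interval(seed_lists()), "empty")
})

test_that("grow_region captures exactly the seeded in-interval component", {
  img <- matrix(0, 8, 8)
  img[2:4, 2:4] <- 10 # one blob
  img[6:7, 6:7] <- 10 # a disjoint blob
  iv <- as_key_interval(4, 16)
  m <- grow_region(img, list(seed_point(3, 3)), iv)
  expect_equal(sum(m), 9)
  expect_true(all(m[2:4, 2:4] == 1))
  expect_true(all(m[6:7, 6:7] == 0))
  # a seed with out-of-interval intensity contributes nothing
  expect_equal(sum(grow_region(img, list(seed_point(1, 1)), iv)), 0)
  expect_error(grow_region(img, list(seed_point(9, 1)), iv), "out of bounds")
})

test_that("4-connectivity does not cross diagonal gaps, 8-connectivity does", {
  img <- matrix(0, 4, 4)
  img[1, 1] <- 10; img[2, 2] <- 10
  iv <- as_key_interval(4, 16)
  expect_equal(sum(grow_region(img, list(seed_point(1, 1)), iv,
                               connectivity = 4L)), 1)
  expect_equal(sum(grow_region(img, list(seed_point(1, 1)), iv,
                               connectivity = 8L)), 2)
})

test_that("grow_region equals the breadth-first flood-fill oracle", {
  set.seed(191)
  for (rep in 1:60) {
    img <- matrix(sample(0:4, 400, replace = TRUE), 20, 20)
    seeds <- lapply(1:3, function(i)
      seed_point(sample.int(20, 1), sample.int(20, 1)))
    conn <- sample(c(4L, 8L), 1)
    iv <- as_key_interval(1, 3)
    got <- grow_region(img, seeds, iv, connectivity = conn)
    want <- bf_flood(img, lapply(seeds, function(s) c(s$row, s$col)),
                     1, 3, conn)
    expect_identical(unname(got), want)
  }
})

test_that("growth output is an in-interval set, seeded and monotone", {
  set.seed(193)
  for (rep in 1:30) {
    img <- matrix(rnorm(400), 20, 20)
    seeds <- lapply(1:2, function(i)
      seed_point(sample.int(20, 1), sample.int(20, 1)))
    narrow <- as_key_interval(-0.5, 0.5)
    wide <- as_key_interval(-1.5, 1.5)
    m1 <- grow_region(img, seeds, narrow)
    m2 <- grow_region(img, seeds, wide)
    # subset of the in-interval pixel set
    expect_true(all(img[m1 == 1] >= narrow$lo & img[m1 == 1] <= narrow$hi))
    # monotone: widening the interval never shrinks the mask
    expect_true(all(m2[m1 == 1] == 1))
  }
})

test_that("the gradient veto bars growth across high-gradient walls", {
  img <- matrix(0.5, 6, 6)
  grad <- matrix(0, 6, 6); grad[, 3] <- 10
  iv <- as_key_interval(0, 1)
  m <- grow_region(img, list(seed_point(3, 1)), iv,
                   gradient = grad, gradient_threshold = 5)
  expect_true(all(m[, 1:2] == 1))
  expect_true(all(m[, 3:6] == 0))
  # threshold Inf disables the veto
  m2 <- grow_region(img, list(seed_point(3, 1)), iv,
                    gradient = grad, gradient_threshold = Inf)
  expect_true(all(m2 == 1))
})

test_that("extract_local_seeds returns global + part centroids", {
  intensity <- matrix(seq_len(36) / 10, 6, 6)
  m1 <- matrix(0L, 6, 6); m1[4, 5] <- 1L
  s1 <- extract_local_seeds(m1, intensity, mode = 2L)
  expect_equal(length(s1), 3L)
  for (s in s1) expect_equal(c(s$row, s$col), c(4L, 5L)) # all identical
  # 4x2 rectangle rows 1..4, cols 1..2
  m2 <- matrix(0L, 6, 6); m2[1:4, 1:2] <- 1L
  s2 <- extract_local_seeds(m2, intensity, mode = 2L)
  expect_equal(c(s2[[1]]$row, s2[[1]]$col), c(3L, 2L)) # floor(2.5+.5), floor(1.5+.5)
  expect_equal(c(s2[[2]]$row, s2[[2]]$col), c(2L, 2L)) # rows above the center
  expect_equal(c(s2[[3]]$row, s2[[3]]$col), c(4L, 2L)) # rows below the center
  expect_equal(s2[[1]]$value, intensity[3, 2])
  # one-row mask: both parts are empty and fall back to the global seed
  m3 <- matrix(0L, 6, 6); m3[2, 1:5] <- 1L
  s3 <- extract_local_seeds(m3, intensity, mode = 2L)
  expect_equal(c(s3[[1]]$row, s3[[1]]$col), c(2L, 3L))
  expect_equal(s3[[2]], s3[[1]])
  expect_equal(s3[[3]], s3[[1]])
  # modes 0 and 4
  expect_equal(length(extract_local_seeds(m2, intensity, mode = 0L)), 1L)
  s4 <- extract_local_seeds(m2, intensity, mode = 4L)
  expect_equal(length(s4), 5L)
  for (s in s4) expect_equal(m2[s$row, s$col], 1L) # snapped onto the mask
  expect_error(extract_local_seeds(matrix(0L, 3, 3), intensity), "empty mask")
})

test_that("every returned seed lies on the mask", {
  set.seed(197)
  for (rep in 1:25) {
    m <- matrix(0L, 10, 10)
    m[sample(100, sample(3:40, 1))] <- 1L
    intensity <- matrix(rnorm(100), 10, 10)
    for (mode in c(0L, 2L, 4L))
      for (s in extract_local_seeds(m, intensity, mode)) {
        expect_equal(m[s$row, s$col], 1L)
        expect_equal(s$value, intensity[s$row, s$col])
      }
  }
})

test_that("condition 1: all seeds outside the key range stops", {
  cfg <- growth_config()
  iv <- as_key_interval(0, 1)
  big <- matrix(1L, 10, 10)
  out <- check_termination(big, list(seed_point(1, 1, 5),
                                     seed_point(2, 2, -3)), iv, NULL, cfg)
  expect_equal(out, "seeds_out_of_range")
  # one in-range seed keeps going
  expect_equal(check_termination(big, list(seed_point(1, 1, 5),
                                           seed_point(2, 2, 0.5)),
                                 iv, NULL, cfg), "none")
})

test_that("condition 2: below 10 voxels stops, exactly 10 continues", {
  cfg <- growth_config()
  iv <- as_key_interval(0, 1)
  seeds <- list(seed_point(1, 1, 0.5))
  m9 <- matrix(0L, 10, 10); m9[1, 1:9] <- 1L
  m10 <- matrix(0L, 10, 10); m10[1, 1:10] <- 1L
  expect_equal(check_termination(m9, seeds, iv, NULL, cfg), "too_few_voxels")
  expect_equal(check_termination(m10, seeds, iv, NULL, cfg), "none")
})

test_that("condition 3: center jump beyond 50 px stops, exactly 50 continues", {
  cfg <- growth_config()
  iv <- as_key_interval(0, 1)
  seeds <- list(seed_point(2, 4, 0.5))
  mask <- matrix(0L, 4, 80); mask[1:2, 1:6] <- 1L # 12 voxels, center (2,4)
  expect_equal(check_termination(mask, seeds, iv, matrix(c(2, 55), 1), cfg),
               "center_jump") # distance 51
  expect_equal(check_termination(mask, seeds, iv, matrix(c(2, 54), 1), cfg),
               "none") # distance 50 exactly
  # only the last `lookback` centers count
  history <- rbind(matrix(c(2, 70), 1),
                   matrix(rep(c(2, 4), 10), 10, 2, byrow = TRUE))
  expect_equal(check_termination(mask, seeds, iv, history, cfg), "none")
})

test_that("conditions fire in order 1 -> 2 -> 3 and respect the subset", {
  iv <- as_key_interval(0, 1)
  tiny <- matrix(0L, 10, 10); tiny[1, 1] <- 1L
  bad_seeds <- list(seed_point(1, 1, 9))
  expect_equal(check_termination(tiny, bad_seeds, iv, NULL, growth_config()),
               "seeds_out_of_range") # 1 shadows 2
  expect_equal(check_termination(tiny, bad_seeds, iv, NULL,
                                 growth_config(conditions = c(2L, 3L))),
               "too_few_voxels") # 1 disabled
  expect_equal(check_termination(tiny, bad_seeds, iv, NULL,
                                 growth_config(conditions = integer(0))),
               "none") # all disabled
})

test_that("2D closing fills holes, keeps convex masks, equals the oracle", {
  m <- matrix(0L, 9, 9); m[3:7, 3:7] <- 1L; m[5, 5] <- 0L
  closed <- close_mask_2d(m, radius = 2L)
  expect_equal(closed[5, 5], 1L)
  expect_identical(unname(closed), bf_close2d(m, 2L))
  # convex solid mask unchanged
  solid <- matrix(0L, 9, 9); solid[2:6, 3:8] <- 1L
  expect_identical(unname(close_mask_2d(solid, 3L)), solid)
  # empty stays empty; radius 0 is the identity
  expect_true(all(close_mask_2d(matrix(0L, 5, 5), 3L) == 0))
  expect_identical(unname(close_mask_2d(m, 0L)), m)
  expect_error(close_mask_2d(m, -1), "radius")
})

test_that("closing is extensive and matches the dilate-erode oracle", {
  set.seed(199)
  for (rep in 1:40) {
    m <- matrix(rbinom(36, 1, 0.4), 6, 6)
    for (radius in 1:2) {
      closed <- close_mask_2d(m, radius)
      expect_true(all(closed[m == 1] == 1)) # output superset of input
      expect_identical(unname(closed), bf_close2d(m, radius))
    }
  }
})

test_that("3D closing is extensive and matches a plain-loop ball oracle", {
  bf_close3d <- function(mask, radius) {
    # true closing: embed in a zero background (pad = radius), close, crop
    d0 <- dim(mask)
    P <- array(0L, d0 + 2L * radius)
    P[radius + seq_len(d0[1]), radius + seq_len(d0[2]),
      radius + seq_len(d0[3])] <- mask
    mask <- P
    d <- dim(mask)
    off <- expand.grid(a = -radius:radius, b = -radius:radius,
                       c = -radius:radius)
    off <- off[off$a^2 + off$b^2 + off$c^2 <= radius^2, ]
    probe <- function(src, bg) {
      out <- array(0L, d)
      for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
        vals <- integer(nrow(off))
        for (t in seq_len(nrow(off))) {
          ii <- i + off$a[t]; jj <- j + off$b[t]; kk <- k + off$c[t]
          vals[t] <- if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] &&
                         kk >= 1 && kk <= d[3]) src[ii, jj, kk] else bg
        }
        out[i, j, k] <- if (bg == 0L) max(vals) else min(vals)
      }
      out
    }
    probe(probe(mask, 0L), 1L)[radius + seq_len(d0[1]),
                               radius + seq_len(d0[2]),
                               radius + seq_len(d0[3])]
  }
  set.seed(211)
  m <- array(rbinom(125, 1, 0.3), c(5, 5, 5))
  closed <- close_mask_3d(m, 1L)
  expect_true(all(closed[m == 1] == 1))
  expect_identical(unname(closed), unname(bf_close3d(m, 1L)))
  # a one-voxel interior hole in a solid block gets filled
  blk <- array(0L, c(7, 7, 7)); blk[2:6, 2:6, 2:6] <- 1L; blk[4, 4, 4] <- 0L
  expect_equal(close_mask_3d(blk, 2L)[4, 4, 4], 1L)
  expect_identical(unname(close_mask_3d(m, 0L)), unname(m))
})

test_that("segment_organ recovers a noise-free ellipsoid (DSC >= 0.99)", {
  ph <- generate_phantom(noisefree_config(), seed = 5)
  pre <- preprocess_volume(ph$volume)
  iv <- key_interval(organ_histogram(list(
    list(volume = pre, mask = ph$masks$liver))))
  tr <- ph$truth$liver
  seg <- segment_organ(pre, iv,
                       backend_oracle(tr$centroid["row"], tr$centroid["col"]),
                       slic_params(50))
  expect_s3_class(seg, "organ_segmentation")
  expect_gte(dsc(confusion(seg$mask, ph$masks$liver)), 0.99)
  expect_equal(seg$key_slice, tr$key_slice)
  expect_true(all(c("slice", "direction", "lo", "hi", "voxels", "reason")
                  %in% names(seg$report)))
})

test_that("a single-slice organ yields a single-slice mask with logged stops", {
  cfg <- phantom_config(
    shape = c(9L, 64L, 64L),
    organs = list(organ = list(center = c(5, 32, 32),
                               semiaxes = c(0.9, 12, 12), mean = 100, sd = 0)),
    background = list(mean = 40, sd = 0), noise_sigma = 0, patch = 32L)
  ph <- generate_phantom(cfg, seed = 2)
  expect_true(all(apply(ph$masks$organ, 1, sum)[-5] == 0))
  pre <- preprocess_volume(ph$volume)
  iv <- key_interval(organ_histogram(list(
    list(volume = pre, mask = ph$masks$organ))))
  tr <- ph$truth$organ
  seg <- segment_organ(pre, iv,
                       backend_oracle(tr$centroid["row"], tr$centroid["col"]),
                       slic_params(13),
                       growth_config(closing_3d = 0L))
  expect_true(sum(seg$mask[5, , ]) > 0)
  expect_true(all(seg$mask[-5, , ] == 0))
  expect_true(all(seg$termination %in%
                  c("too_few_voxels", "seeds_out_of_range")))
})

test_that("with termination disabled the engine halts at the volume edges", {
  cfg <- phantom_config(
    shape = c(9L, 32L, 32L),
    organs = list(organ = list(center = c(5, 16, 16),
                               semiaxes = c(2, 10, 10), mean = 100, sd = 0)),
    background = list(mean = 40, sd = 0), noise_sigma = 0, patch = 16L)
  ph <- generate_phantom(cfg, seed = 3)
  pre <- preprocess_volume(ph$volume)
  iv <- key_interval(organ_histogram(list(
    list(volume = pre, mask = ph$masks$organ))))
  tr <- ph$truth$organ
  seg <- segment_organ(pre, iv,
                       backend_oracle(tr$centroid["row"], tr$centroid["col"]),
                       slic_params(8),
                       growth_config(conditions = integer(0), closing_3d = 0L))
  expect_equal(unname(seg$termination), c("volume_edge", "volume_edge"))
})

test_that("segmentation is deterministic for identical inputs", {
  ph <- generate_phantom(phantom_config(), seed = 11)
  pre <- preprocess_volume(ph$volume)
  iv <- calibrate_interval("liver", n = 2, seed0 = 300)
  tr <- ph$truth$liver
  run <- function() segment_organ(
    pre, iv, backend_oracle(tr$centroid["row"], tr$centroid["col"]),
    slic_params(50))
  a <- run(); b <- run()
  expect_identical(a$mask, b$mask)
  expect_identical(a$report, b$report)
})
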
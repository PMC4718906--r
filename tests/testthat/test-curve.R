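test_that("threshold index follows its defining arithmetic", {
  expect_equal(threshold_index(200, 150), 0.25)
  expect_equal(threshold_index(100, 100), 0)
  expect_equal(threshold_index(100, 0), 1)
  expect_error(threshold_index(0, 0), "positive")
  expect_error(threshold_index(100, 101), "c_max")
})

test_that("uniform volumes give a flat single-focus curve", {
  vol <- array(50, c(6, 6, 6))
  cv <- nnufti(vol, array(TRUE, c(6, 6, 6)), grid_size = 8)
  expect_true(all(cv$rows$nuf == 1))
  expect_true(all(cv$rows$nnuf == 1))
  expect_equal(cv$c_max, 50)
  expect_equal(cv$mean_conc, 50)
})

test_that("a single hot voxel yields one focus at every threshold level", {
  vol <- array(0, c(4, 4, 4))
  vol[2, 2, 2] <- 100
  cv <- nnufti(vol, array(TRUE, c(4, 4, 4)), grid_size = 4)
  expect_equal(cv$rows$threshold, c(100, 75, 50, 25))
  expect_true(all(cv$rows$nuf == 1))
  expect_true(all(cv$rows$nnuf == 1))
})

test_that("curve invariants hold to machine precision on phantom curves", {
  for (s in c(3, 4)) {
    ph <- generate_phantom(tiny_spec(seed = s))
    cv <- nnufti(ph$volume, ph$voi, grid_size = 64)
    r <- cv$rows
    expect_true(all(diff(r$thi) > 0))                       # strictly increasing
    expect_equal(r$thi, (cv$c_max - r$threshold) / cv$c_max, tolerance = 1e-15)
    expect_identical(max(r$nnuf), 1)                        # exact normalization
    expect_true(all(r$nnuf > 0 & r$nnuf <= 1))
    expect_gte(r$nuf[r$threshold == cv$c_max], 1)
    expect_equal(cv$mean_conc, mean_concentration(ph$volume, ph$voi))
  }
})

test_that("per-threshold counts agree with the flood-fill oracle", {
  ph <- generate_phantom(tiny_spec(seed = 21))
  cv <- nnufti(ph$volume, ph$voi, grid_size = 12)
  for (i in seq_len(nrow(cv$rows)))
    expect_equal(cv$rows$nuf[i],
                 oracle_count_foci(ph$volume$values, ph$voi$mask,
                                   cv$rows$threshold[i], 26, 1))
})

test_that("branch crossings are linearly interpolated on the right row pair", {
  cv <- fixture_curve(thi = c(0.2, 0.4, 0.6, 0.8),
                      nnuf = c(0.1, 1.0, 0.4, 0.1))
  expect_equal(thi_at_nnuf(cv, 0.25, "right"),
               0.6 + 0.2 * (0.4 - 0.25) / (0.4 - 0.1))   # = 0.7
  expect_equal(thi_at_nnuf(cv, 0.25, "left"),
               0.2 + 0.2 * (0.25 - 0.1) / (1.0 - 0.1))   # ~ 0.2333
})

test_that("flat curves raise a no-crossing error naming the side", {
  cv <- fixture_curve(thi = c(0.2, 0.4, 0.6), nnuf = c(1, 1, 1))
  expect_error(thi_at_nnuf(cv, 0.25, "right"), "right branch")
  expect_error(thi_at_nnuf(cv, 0.25, "left"), "left branch")
  expect_error(thi_at_nnuf(cv, 1.5), "between 0 and 1")
})

test_that("mean concentration is the arithmetic VOI mean", {
  vol <- array(0, c(4, 4, 1))
  vol[1, 1, 1] <- 40; vol[2, 1, 1] <- 80
  voi <- array(FALSE, c(4, 4, 1)); voi[1:2, 1, 1] <- TRUE
  expect_equal(mean_concentration(vol, voi), 60)

  ph <- generate_phantom(small_spec(seed = 5, nonuniformity = 0,
                                    psf_sigma_mm = 0))
  n <- sum(ph$voi$mask)
  expect_gt(n, 1e3)
  expect_lt(abs(mean_concentration(ph$volume, ph$voi) - 60),
            3 * sqrt(60 / n))
})

test_that("tumour-free phantom curves are unimodal with an interior peak", {
  ph <- generate_phantom(small_spec(seed = 31))
  cv <- nnufti(ph$volume, ph$voi, grid_size = 128)
  pk <- which.max(cv$rows$nnuf)
  expect_gt(pk, 1)
  expect_lt(pk, nrow(cv$rows))
  # rises before the peak region and decays after it (coarse shape check)
  expect_gt(cv$rows$nnuf[pk], cv$rows$nnuf[2] + 0.2)
  expect_gt(cv$rows$nnuf[pk], cv$rows$nnuf[nrow(cv$rows) - 1] + 0.2)
})

test_that("a hot lesion shifts the right branch to higher ThI", {
  neg <- generate_phantom(small_spec(seed = 77))
  les <- list(lesion(c(82, 72, 54), radius_mm = 12, tnc = 3))
  pos <- generate_phantom(small_spec(seed = 77, lesions = les))
  thi_neg <- thi_at_nnuf(nnufti(neg$volume, neg$voi, grid_size = 128), 0.25)
  thi_pos <- thi_at_nnuf(nnufti(pos$volume, pos$voi, grid_size = 128), 0.25)
  expect_gt(thi_pos, thi_neg)
})
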
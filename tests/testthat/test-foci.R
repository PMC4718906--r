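box_voi <- function(d) array(TRUE, d)

test_that("disjoint hot voxels are counted separately at any connectivity", {
  vol <- array(0, c(3, 3, 1))
  vol[1, 1, 1] <- vol[3, 3, 1] <- 10
  for (conn in c(6, 18, 26))
    expect_equal(count_foci(vol, box_voi(c(3, 3, 1)), 5, connectivity = conn), 2)
})

test_that("corner and edge adjacency depend on the connectivity", {
  vol <- array(0, c(3, 3, 3))
  vol[1, 1, 1] <- vol[2, 2, 2] <- 10   # share only a corner
  expect_equal(count_foci(vol, box_voi(c(3, 3, 3)), 5, connectivity = 26), 1)
  expect_equal(count_foci(vol, box_voi(c(3, 3, 3)), 5, connectivity = 18), 2)
  expect_equal(count_foci(vol, box_voi(c(3, 3, 3)), 5, connectivity = 6), 2)

  vol2 <- array(0, c(3, 3, 3))
  vol2[1, 1, 1] <- vol2[2, 2, 1] <- 10  # share an edge
  expect_equal(count_foci(vol2, box_voi(c(3, 3, 3)), 5, connectivity = 18), 1)
  expect_equal(count_foci(vol2, box_voi(c(3, 3, 3)), 5, connectivity = 6), 2)
})

test_that("counts equal the brute-force flood-fill oracle on random fields", {
  set.seed(101)
  for (case in 1:12) {
    d <- sample(3:12, 3, replace = TRUE)
    vol <- array(rpois(prod(d), 6), d)
    voi <- array(runif(prod(d)) < 0.8, d)
    if (!any(voi)) voi[1, 1, 1] <- TRUE
    thr <- sample(3:9, 1)
    conn <- sample(c(6, 18, 26), 1)
    msz <- sample(1:2, 1)
    expect_equal(count_foci(vol, voi, thr, conn, msz),
                 oracle_count_foci(vol, voi, thr, conn, msz),
                 info = sprintf("case %d: %s thr %d conn %d min %d",
                                case, paste(d, collapse = "x"), thr, conn, msz))
  }
})

test_that("raising the threshold never adds a foreground voxel", {
  set.seed(7)
  d <- c(10, 10, 8)
  vol <- array(rpois(prod(d), 6), d)
  voi <- box_voi(d)
  prev <- NULL
  for (thr in c(2, 4, 6, 8, 10)) {
    fg <- label_foci(vol, voi, thr)$labels > 0
    if (!is.null(prev)) expect_true(all(prev | !fg))  # fg subset of prev
    prev <- fg
  }
})

test_that("labelling is deterministic and labels follow scan order", {
  set.seed(8)
  d <- c(9, 9, 9)
  vol <- array(rpois(prod(d), 5), d)
  a <- label_foci(vol, box_voi(d), 7)
  b <- label_foci(vol, box_voi(d), 7)
  expect_identical(a$labels, b$labels)
  if (a$count > 1) {
    first_idx <- vapply(seq_len(a$count),
                        function(k) min(which(as.vector(a$labels) == k)),
                        numeric(1))
    expect_true(all(diff(first_idx) > 0))
  }
})

test_that("min_size drops sub-threshold-size foci", {
  vol <- array(0, c(5, 5, 5))
  vol[3, 3, 3] <- 100                    # single isolated hot voxel
  expect_equal(count_foci(vol, box_voi(c(5, 5, 5)), 50, min_size = 1), 1)
  expect_equal(count_foci(vol, box_voi(c(5, 5, 5)), 50, min_size = 2), 0)
})

test_that("degenerate thresholds behave as documented", {
  set.seed(9)
  d <- c(6, 6, 6)
  vol <- array(rpois(prod(d), 20) + 1, d)  # strictly positive
  voi <- box_voi(d)
  expect_equal(count_foci(vol, voi, max(vol) + 1), 0)
  expect_equal(count_foci(vol, voi, 0), 1)  # connected VOI all merges
})

test_that("the VOI is a hard boundary for connectivity", {
  vol <- array(10, c(5, 1, 1))
  voi <- array(c(TRUE, TRUE, FALSE, TRUE, TRUE), c(5, 1, 1))
  # the middle voxel is above threshold but outside the VOI: two foci
  expect_equal(count_foci(vol, voi, 5, connectivity = 6), 2)
})

test_that("invalid parameters are rejected", {
  vol <- array(1, c(2, 2, 2))
  expect_error(count_foci(vol, box_voi(c(2, 2, 2)), 1, connectivity = 10),
               "connectivity")
  expect_error(count_foci(vol, box_voi(c(2, 2, 2)), -1), "threshold")
  expect_error(count_foci(vol, box_voi(c(2, 2, 3)), 1), "does not match")
})
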
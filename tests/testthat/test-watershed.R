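# deterministic two-pit surface with a straight vertical ridge at the
# middle column: symmetric, so ridge pixels have tied steepest routes
two_pit_surface <- function(n = 17) {
  stopifnot(n %% 2 == 1)
  mid <- (n + 1) / 2
  ci <- (n + 1) / 2
  # squared distance to the two pit centers; the ridge is the equidistant
  # middle column
  c1 <- c(ci, (mid + 1) / 2); c2 <- c(ci, n + 1 - (mid + 1) / 2)
  d1 <- outer((seq_len(n) - c1[1])^2, (seq_len(n) - c1[2])^2, "+")
  d2 <- outer((seq_len(n) - c2[1])^2, (seq_len(n) - c2[2])^2, "+")
  pmin(d1, d2)
}

test_that("a constant surface floods to one basin without divide lines", {
  lab <- watershed_flood(matrix(5, 6, 8))
  expect_equal(lab, matrix(1L, 6, 8))
})

test_that("the one-row [0,1,2,1,0] surface has two basins split at the center", {
  lab <- watershed_flood(matrix(c(0, 1, 2, 1, 0), 1))
  expect_equal(as.vector(lab), c(1L, 1L, 0L, 2L, 2L))
})

test_that("two pits separated by a straight ridge give 2 basins with the divide on the ridge", {
  s <- two_pit_surface(17)
  lab <- watershed_flood(s)
  expect_equal(max(lab), 2)
  mid <- 9
  expect_true(all(lab[, mid] == 0))          # divide on the symmetric ridge
  expect_true(all(lab[, 1:(mid - 1)] == 1))
  expect_true(all(lab[, (mid + 1):17] == 2))
  expect_error(watershed_flood(matrix(Inf, 2, 2)), "finite")
})

test_that("flooding partitions the image and seeds one basin per regional minimum", {
  set.seed(121)
  for (rep in 1:10) {
    s <- matrix(sample(0:9, 15 * 15, replace = TRUE), 15, 15)
    for (conn in c(4, 8)) {
      lab <- watershed_flood(s, conn)
      expect_true(all(lab >= 0))
      n_min <- max(label_components(regional_minima(s, conn), conn))
      expect_equal(max(lab), n_min)
      for (k in seq_len(max(lab)))           # basins connected, non-empty
        expect_equal(max(label_components(lab == k, conn)), 1)
    }
  }
})

test_that("flooding agrees with the steepest-descent drainage oracle", {
  set.seed(131)
  for (rep in 1:20) {
    s <- matrix(runif(16 * 16), 16, 16)      # continuous: plateau-free
    for (conn in c(4, 8))
      expect_equal(watershed_flood(s, conn), oracle_watershed(s, conn))
  }
})

test_that("imposing minima makes the marker components the only minima", {
  s <- matrix(runif(12 * 12, 1, 9), 12, 12)
  all_mk <- matrix(TRUE, 12, 12)
  flat <- impose_minima(s, all_mk)
  expect_equal(length(unique(as.vector(flat))), 1L)

  set.seed(141)
  for (rep in 1:25) {
    s <- matrix(runif(16 * 16, 0, 100), 16, 16)
    mk <- matrix(FALSE, 16, 16)
    for (b in seq_len(sample(1:3, 1))) {
      ci <- sample(3:14, 1); cj <- sample(3:14, 1)
      mk[ci + (-1:1), cj + (-1:1)] <- TRUE
    }
    imp <- impose_minima(s, mk)
    minima <- regional_minima(imp)
    expect_equal(minima, mk)
    expect_equal(max(label_components(minima)),
                 max(label_components(mk)))
  }
  expect_error(impose_minima(s, matrix(FALSE, 16, 16)), "at least one")
})

test_that("a marker on a hill floods a basin containing that hill", {
  s <- two_pit_surface(17)
  mk <- matrix(FALSE, 17, 17)
  mk[8:10, 9] <- TRUE                        # on the ridge crest
  mk[9, 3] <- TRUE                           # in pit 1
  lab <- marker_watershed(s, mk)
  expect_equal(max(lab), 2)
  ridge_basin <- lab[9, 9]
  expect_true(ridge_basin > 0)
  expect_true(all(lab[8:10, 9] == ridge_basin))
})

test_that("marker-controlled flooding yields exactly one basin per marker component", {
  mk1 <- matrix(FALSE, 9, 9); mk1[4:5, 4:5] <- TRUE
  s <- matrix(runif(81), 9, 9)
  expect_equal(max(marker_watershed(s, mk1)), 1)

  set.seed(151)
  mk3 <- matrix(FALSE, 20, 20)
  mk3[2:3, 2:3] <- TRUE; mk3[10:12, 8:9] <- TRUE; mk3[17, 15:17] <- TRUE
  s <- matrix(runif(400, 0, 50), 20, 20)
  lab <- marker_watershed(s, mk3)
  expect_equal(max(lab), 3)
  expect_equal(sort(unique(lab[mk3])), 1:3)
})

test_that("permuting marker labels permutes basins but not the divide set", {
  set.seed(161)
  s <- matrix(runif(18 * 18, 0, 10), 18, 18)
  mk <- matrix(FALSE, 18, 18)
  centers <- list(c(4, 4), c(9, 14), c(15, 6))
  ml <- matrix(0L, 18, 18)
  for (b in seq_along(centers)) {
    cc <- centers[[b]]
    mk[cc[1] + (-1:1), cc[2] + (-1:1)] <- TRUE
    ml[cc[1] + (-1:1), cc[2] + (-1:1)] <- b
  }
  base <- marker_watershed(s, mk)
  perm <- c(2L, 3L, 1L)
  ml_perm <- ml; ml_perm[ml > 0] <- perm[ml[ml > 0]]
  shuffled <- marker_watershed(s, mk, marker_labels = ml_perm)
  expect_equal(shuffled == 0, base == 0)               # same divide pixels
  for (b in 1:3) {                                     # same basins, relabeled
    seed_px <- ml == b
    base_id <- unique(base[seed_px])
    expect_length(base_id, 1)
    expect_equal(shuffled == perm[b], base == base_id)
  }
})

test_that("superimpose repaints exactly the divide pixels", {
  set.seed(171)
  img <- array(sample(0:255, 10 * 10 * 3, TRUE), dim = c(10, 10, 3))
  lab_none <- matrix(1L, 10, 10)
  expect_equal(superimpose(img, lab_none), img)
  lab_all <- matrix(0L, 10, 10)
  solid <- superimpose(img, lab_all, c(0, 255, 0))
  expect_true(all(solid[, , 1] == 0) && all(solid[, , 2] == 255))
  lab <- matrix(1L, 10, 10); lab[3, ] <- 0L; lab[, 7] <- 0L
  out <- superimpose(img, lab, c(255, 0, 0))
  repainted <- out[, , 1] != img[, , 1] | out[, , 2] != img[, , 2] |
    out[, , 3] != img[, , 3]
  expect_true(all(which(repainted) %in% which(lab == 0)))
  expect_equal(out[, , 1][lab == 0], rep(255, sum(lab == 0)))
  expect_error(superimpose(img, matrix(0L, 3, 3)), "shape")
})
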
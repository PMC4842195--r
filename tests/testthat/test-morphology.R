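test_that("complement maps endpoints and is an involution", {
  expect_equal(complement(matrix(0, 2, 2)), matrix(255, 2, 2))
  expect_equal(complement(matrix(255, 2, 2)), matrix(0, 2, 2))
  set.seed(11)
  img <- rand_img8(9, 13)
  expect_equal(complement(complement(img)), img)
  expect_error(complement(matrix(300, 2, 2)), "8-bit")
  expect_error(complement(matrix(0.5, 2, 2)), "8-bit")
})

test_that("structuring elements are validated", {
  expect_error(structuring_element(matrix(TRUE, 2, 2)), "odd")
  expect_error(structuring_element(matrix(FALSE, 3, 3)), "origin")
  fp <- matrix(FALSE, 3, 3); fp[1, 1] <- TRUE
  expect_error(structuring_element(fp), "origin")
  expect_equal(sum(se_disk(1)$footprint), 5)   # unit cross
  expect_equal(sum(se_square(1)$footprint), 9)
  expect_error(se_disk(0), "positive")
})

test_that("erosion and dilation match their definitions", {
  expect_equal(erode(matrix(100, 4, 6), se_disk(2)), matrix(100, 4, 6))
  expect_equal(dilate(matrix(100, 4, 6), se_disk(2)), matrix(100, 4, 6))

  img <- matrix(0, 5, 5); img[3, 3] <- 255
  expect_equal(erode(img, se_square(1)), matrix(0, 5, 5))
  d <- dilate(img, se_square(1))
  expect_equal(sum(d == 255), 9)
  expect_equal(d[2:4, 2:4], matrix(255, 3, 3))

  blk <- matrix(0, 5, 5); blk[2:4, 2:4] <- 255
  er <- erode(blk, se_square(1))
  expected <- matrix(0, 5, 5); expected[3, 3] <- 255
  expect_equal(er, expected)
})

test_that("erosion/dilation agree with the double-loop oracle and bracket the image", {
  set.seed(21)
  ses <- list(se_disk(1), se_disk(2), se_square(1), se_square(2))
  for (rep in 1:8) {
    img <- rand_img8(sample(5:12, 1), sample(5:12, 1))
    se <- ses[[sample(length(ses), 1)]]
    er <- erode(img, se); di <- dilate(img, se)
    expect_equal(er, oracle_erode(img, se))
    expect_equal(di, oracle_dilate(img, se))
    expect_true(all(er <= img) && all(img <= di))
    # duality: dilation is the complement of eroding the complement
    expect_equal(di, complement(erode(complement(img), se)))
  }
})

test_that("reconstruction by dilation restores the marked plateau only", {
  mask <- matrix(10, 9, 9)
  mask[2:4, 2:4] <- 200   # plateau A
  mask[6:8, 6:8] <- 200   # plateau B
  marker <- matrix(0, 9, 9); marker[3, 3] <- 200
  r <- reconstruct_by_dilation(marker, mask)
  expect_equal(r[2:4, 2:4], matrix(200, 3, 3))
  expect_equal(r[6:8, 6:8], matrix(10, 3, 3))
  expect_equal(r[5, 5], 10)
  expect_equal(r, oracle_reconstruct(marker, mask))

  expect_equal(reconstruct_by_dilation(mask, mask), mask)
  expect_equal(reconstruct_by_dilation(matrix(0, 9, 9), mask), matrix(0, 9, 9))
  expect_error(reconstruct_by_dilation(mask + 1, mask), "exceed")
  expect_error(reconstruct_by_dilation(matrix(0, 2, 2), mask), "dimensions")
})

test_that("reconstruction brackets marker and mask and is a fixed point", {
  set.seed(31)
  for (rep in 1:20) {
    mask <- rand_img8(16, 16)
    marker <- pmin(mask, rand_img8(16, 16))
    for (conn in c(4, 8)) {
      r <- reconstruct_by_dilation(marker, mask, conn)
      expect_true(all(marker <= r) && all(r <= mask))
      expect_equal(reconstruct_by_dilation(r, mask, conn), r)
      expect_equal(r, oracle_reconstruct(marker, mask, conn))
    }
  }
})

test_that("reconstruction by erosion is the complement dual", {
  set.seed(41)
  mask <- rand_img8(12, 12)
  marker <- pmax(mask, rand_img8(12, 12))
  r <- reconstruct_by_erosion(marker, mask)
  expect_equal(r, complement(reconstruct_by_dilation(complement(marker),
                                                     complement(mask))))
  expect_equal(reconstruct_by_erosion(mask, mask), mask)
  # an isolated spike above a flat mask erodes down to the mask; a marker
  # that is constant everywhere is already a fixed point of geodesic
  # erosion (eroding a constant changes nothing)
  spike <- matrix(7, 6, 6); spike[3, 4] <- 255
  expect_equal(reconstruct_by_erosion(spike, matrix(7, 6, 6)),
               matrix(7, 6, 6))
  expect_equal(reconstruct_by_erosion(matrix(255, 6, 6), matrix(7, 6, 6)),
               matrix(255, 6, 6))
  expect_error(reconstruct_by_erosion(mask - 1, mask), "below")
})

test_that("opening-by-reconstruction removes small specks, keeps large plateaus", {
  img <- matrix(0, 12, 12)
  img[2:9, 2:9] <- 255      # plateau bigger than the SE
  img[11, 11] <- 255        # isolated speck
  se <- se_square(1)
  op <- opening_by_reconstruction(img, se)
  expected <- img; expected[11, 11] <- 0
  expect_equal(op, expected)
  expect_equal(op, oracle_reconstruct(oracle_erode(img, se), img))
  expect_equal(opening_by_reconstruction(matrix(42, 5, 5), se),
               matrix(42, 5, 5))
})

test_that("opening-by-reconstruction is anti-extensive, increasing and idempotent", {
  set.seed(51)
  se <- se_disk(1)
  for (rep in 1:15) {
    img <- rand_img8(16, 16)
    op <- opening_by_reconstruction(img, se)
    expect_true(all(op <= img))
    expect_equal(opening_by_reconstruction(op, se), op)
    bigger <- pmin(img + rand_img8(16, 16, 0:60), 255)
    expect_true(all(op <= opening_by_reconstruction(bigger, se)))
  }
})

test_that("closing-by-reconstruction fills dark specks and is extensive + idempotent", {
  img <- matrix(255, 10, 10); img[5, 5] <- 0
  se <- se_square(1)
  expect_equal(closing_by_reconstruction(img, se), matrix(255, 10, 10))
  expect_equal(closing_by_reconstruction(matrix(9, 4, 4), se),
               matrix(9, 4, 4))
  set.seed(61)
  for (rep in 1:15) {
    img <- rand_img8(16, 16)
    cl <- closing_by_reconstruction(img, se)
    expect_true(all(cl >= img))
    expect_equal(closing_by_reconstruction(cl, se), cl)
  }
})

test_that("the printed closing form and the erosion-reconstruction dual coincide", {
  set.seed(71)
  for (se in list(se_disk(1), se_square(2))) {
    img <- rand_img8(14, 14)
    expect_equal(closing_by_reconstruction(img, se),
                 reconstruct_by_erosion(dilate(img, se), img))
  }
})

test_that("HMR equals the hand-composed complement/opening/closing chain", {
  set.seed(81)
  se <- se_disk(2)
  expect_equal(hmr_enhance(matrix(77, 8, 8), se), matrix(77, 8, 8))
  for (rep in 1:10) {
    img <- rand_img8(16, 16)
    out <- hmr_enhance(img, se)
    expect_true(all(out >= 0) && all(out <= 255))
    by_hand <- complement(
      closing_by_reconstruction(
        opening_by_reconstruction(complement(img), se), se))
    expect_equal(out, by_hand)
  }
})

test_that("HMR removes both bright and dark specks, keeps plateau boundaries", {
  img <- matrix(128, 20, 20)
  img[3:12, 3:12] <- 220    # large bright plateau
  img[16, 16] <- 255        # bright speck
  img[16, 4] <- 10          # dark speck
  out <- hmr_enhance(img, se_square(1))
  expect_equal(out[16, 16], 128)
  expect_equal(out[16, 4], 128)
  expect_equal(out[3:12, 3:12], img[3:12, 3:12])
  expect_equal(out[14, 14], 128)
})

test_that("regional maxima mark plateaus with strictly lower surroundings", {
  img <- matrix(0, 5, 5); img[3, 3] <- 9
  expect_equal(which(regional_maxima(img)), which(img == 9))
  expect_true(all(regional_maxima(matrix(7, 4, 4))))   # vacuous condition
  # plateau of 5 ringed by 3 inside background 7: the plateau is a maximum
  img <- matrix(7, 9, 9)
  img[3:7, 3:7] <- 3
  img[4:6, 4:6] <- 5
  rm8 <- regional_maxima(img)
  expect_true(all(rm8[4:6, 4:6]))
  expect_false(any(rm8[img == 3]))
  expect_error(regional_maxima(img, connectivity = 6), "connectivity")
})

test_that("regional maxima agree with the plateau-enumeration oracle", {
  set.seed(91)
  for (rep in 1:25) {
    img <- rand_img8(16, 16, 0:5)   # small range forces plateaus
    for (conn in c(4, 8))
      expect_equal(regional_maxima(img, conn),
                   oracle_regional_maxima(img, conn))
  }
})

test_that("rgb_to_gray applies luma weights with round-half-up", {
  px <- function(r, g, b) array(c(r, g, b), dim = c(1, 1, 3))
  expect_equal(rgb_to_gray(px(0, 0, 0))[1, 1], 0)
  expect_equal(rgb_to_gray(px(255, 255, 255))[1, 1], 255)
  expect_equal(rgb_to_gray(px(255, 0, 0))[1, 1], 76)
  v <- 0:255
  gray <- rgb_to_gray(array(rep(v, 3), dim = c(256, 1, 3)))
  expect_equal(as.vector(gray), v)    # (v,v,v) -> v for every v
  expect_error(rgb_to_gray(matrix(0, 3, 3)), "3 array")
})
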
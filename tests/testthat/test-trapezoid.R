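test_that("trapezoid construction enforces ordering and rejects bad input", {
  A <- trapezoid(0, 0.25, 0.75, 1)
  expect_s3_class(A, "trapezoid")
  expect_equal(unname(unclass(A)), c(0, 0.25, 0.75, 1))
  expect_error(trapezoid(1, 0, 2, 3), "a <= b <= c <= d")
  expect_error(trapezoid(c(0, 1, Inf, 2)), "finite")
  # degenerate forms are legal
  expect_s3_class(trapezoid(0, 0.5, 0.5, 1), "trapezoid")   # triangular
  expect_s3_class(trapezoid(0, 0, 1, 1), "trapezoid")       # interval
  expect_s3_class(trapezoid(0.3, 0.3, 0.3, 0.3), "trapezoid")
})

test_that("membership is piecewise linear with plateau 1 and zero outside", {
  A <- trapezoid(0, 0.25, 0.75, 1)
  expect_equal(tfn_membership(A, 0.5), 1)      # plateau
  expect_equal(tfn_membership(A, 0.125), 0.5)  # (x - a)/(b - a)
  expect_equal(tfn_membership(A, 2), 0)        # outside support
  expect_equal(tfn_membership(A, -1), 0)
  expect_equal(tfn_membership(A, c(0.25, 0.75)), c(1, 1))
  # right ramp by symmetry
  expect_equal(tfn_membership(A, 0.875), 0.5)
  expect_error(tfn_membership(A, NaN), "finite")
})

test_that("degenerate ramps behave as steps", {
  A <- trapezoid(0.2, 0.2, 0.8, 0.8)  # interval
  expect_equal(tfn_membership(A, c(0.2, 0.5, 0.8)), c(1, 1, 1))
  expect_equal(tfn_membership(A, c(0.1999, 0.8001)), c(0, 0))
})

test_that("membership is continuous across the ramps", {
  A <- trapezoid(0.1, 0.4, 0.6, 0.9)
  xs <- seq(0.1, 0.9, by = 1e-3)
  y <- tfn_membership(A, xs)
  expect_lt(max(abs(diff(y))), 0.01)
  expect_true(all(y >= 0 & y <= 1))
})

test_that("addition, multiplication and scaling are componentwise and keep ordering", {
  x <- trapezoid(0.1, 0.2, 0.3, 0.4)
  expect_equal(tfn_add(trapezoid(0, 0, 0, 0), x), x)          # identity
  expect_equal(unname(unclass(tfn_add(trapezoid(1, 2, 3, 4),
                                      trapezoid(1, 1, 1, 1)))),
               c(2, 3, 4, 5))
  expect_equal(tfn_multiply(x, trapezoid(1, 1, 1, 1)), x)     # identity
  expect_equal(unname(unclass(tfn_scale(0.5, trapezoid(0.2, 0.4, 0.6, 0.8)))),
               c(0.1, 0.2, 0.3, 0.4))
  expect_equal(tfn_scale(1, x), x)
  expect_error(tfn_scale(-1, x), "non-negative")
  # commutativity on random operands
  set.seed(11)
  for (i in 1:20) {
    a <- random_trapezoid(); b <- random_trapezoid()
    expect_equal(tfn_add(a, b), tfn_add(b, a))
    expect_equal(tfn_multiply(a, b), tfn_multiply(b, a))
  }
})

test_that("subtraction and division return signed tuples with an honest ordered flag", {
  d <- tfn_subtract(trapezoid(0, 0.5, 0.5, 1), trapezoid(0, 0, 1, 1))
  expect_s3_class(d, "signed_tuple")
  expect_equal(as.numeric(d), c(0, 0.5, -0.5, 0))
  expect_false(is_ordered(d))
  expect_true(is_ordered(tfn_subtract(trapezoid(1, 2, 3, 4),
                                      trapezoid(1, 1, 1, 1))))
  q <- tfn_divide(trapezoid(1, 2, 3, 4), trapezoid(1, 2, 3, 4))
  expect_equal(as.numeric(q), c(1, 1, 1, 1))
  expect_error(tfn_divide(trapezoid(1, 2, 3, 4), c(0, 1, 2, 3)), "zero")
})

test_that("mean of ordered tuples is ordered and componentwise", {
  x <- trapezoid(0.1, 0.2, 0.3, 0.4)
  expect_equal(tfn_mean(list(x)), x)
  expect_equal(unname(unclass(tfn_mean(list(trapezoid(0, 0, 0, 0),
                                            trapezoid(1, 1, 1, 1))))),
               rep(0.5, 4))
  # mean of encodings S3, S4, [S4,S5] on the 7-term scale
  enc <- list(encode(linguistic_value(ts7, 3)),
              encode(linguistic_value(ts7, 4)),
              encode(linguistic_value(ts7, 4, 5)))
  expect_equal(unname(unclass(tfn_mean(enc))),
               c(19, 22, 27, 30) / 39, tolerance = 1e-12)
  expect_error(tfn_mean(list()), "empty")
  set.seed(13)
  for (i in 1:20) {
    m <- tfn_mean(lapply(1:5, function(.) random_trapezoid()))
    expect_false(is.unsorted(unclass(m)))
  }
})

test_that("defuzzification is the segmentation integral and is linear", {
  expect_equal(defuzzify(trapezoid(0.643, 0.720, 0.797, 0.874)), 0.7585)
  expect_equal(round_half_up(defuzzify(trapezoid(0.643, 0.720, 0.797, 0.874)), 3),
               0.759)
  expect_equal(round_half_up(defuzzify(trapezoid(0.607, 0.684, 0.761, 0.838)), 3),
               0.723)
  expect_equal(defuzzify(trapezoid(0.3, 0.3, 0.3, 0.3)), 0.3)  # crisp fixed point
  set.seed(17)
  for (i in 1:25) {
    a <- random_trapezoid(); b <- random_trapezoid(); lam <- runif(1, 0, 3)
    expect_equal(defuzzify(tfn_add(a, b)), defuzzify(a) + defuzzify(b),
                 tolerance = 1e-12)
    expect_equal(defuzzify(tfn_scale(lam, a)), lam * defuzzify(a),
                 tolerance = 1e-12)
    v <- unclass(a)
    expect_gte(defuzzify(a), v[1])
    expect_lte(defuzzify(a), v[4])
  }
})

test_that("report rounding is half away from zero", {
  expect_equal(round_half_up(0.7225, 3), 0.723)
  expect_equal(round_half_up(-0.0255, 3), -0.026)
  expect_equal(round_half_up(0.96415, 4), 0.9642)
  expect_equal(round_half_up(c(1.5, -1.5, 2.5), 0), c(2, -2, 3))
  # boundary reached only up to float representation still rounds up
  expect_equal(round_half_up(0.675 - 0.7055, 3), -0.031)
})
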
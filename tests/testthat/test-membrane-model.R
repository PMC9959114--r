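# Pure membrane electromechanics: worked values, identities, monotonicity.

test_that("parallel-plate capacitance reproduces the 0.9 mm DOPC disc", {
  # A = 6.36e-7 m^2, d = 2.69 nm, er = 2.5 -> 5.23 nF
  c_dopc <- capacitance_planar(6.36e-7, 2.69e-9, 2.5)
  expect_equal(c_dopc, eps0 * 2.5 * 6.36e-7 / 2.69e-9)
  expect_equal(c_dopc, 5.23e-9, tolerance = 1e-3)

  # scaling structure: linear in A, reciprocal in d, A/d invariance
  expect_lt(capacitance_planar(1e-12, 2.69e-9), 1e-14)
  expect_equal(
    capacitance_planar(2 * 6.36e-7, 2 * 2.69e-9),
    c_dopc
  )
})

test_that("thickness inversion is exact and scales reciprocally", {
  d <- thickness_from_capacitance(5.2335e-9, 6.36e-7, 2.5)
  expect_equal(d, 2.69e-9, tolerance = 1e-3)

  # inversion identity over a randomized grid of valid geometries
  set.seed(11)
  for (i in 1:25) {
    a <- 10^runif(1, -8, -5)
    dd <- 10^runif(1, -9.5, -8)
    er <- runif(1, 1.5, 4)
    expect_equal(
      thickness_from_capacitance(capacitance_planar(a, dd, er), a, er),
      dd,
      tolerance = 1e-12
    )
  }

  # doubling C at fixed area halves the thickness
  c1 <- capacitance_planar(6.36e-7, 2.69e-9)
  expect_equal(
    thickness_from_capacitance(2 * c1, 6.36e-7),
    2.69e-9 / 2
  )
})

test_that("volume form of the capacitance equals the planar form", {
  set.seed(12)
  for (i in 1:25) {
    a <- 10^runif(1, -8, -5)
    d <- 10^runif(1, -9.5, -8)
    er <- runif(1, 1.5, 4)
    expect_equal(
      capacitance_from_volume(a * d, d, er),
      capacitance_planar(a, d, er),
      tolerance = 1e-12
    )
  }
  # 1/d^2 law: halving d at fixed volume quadruples C
  v <- 6.36e-7 * 2.69e-9
  expect_equal(
    capacitance_from_volume(v, 2.69e-9 / 2),
    4 * capacitance_from_volume(v, 2.69e-9)
  )
})

test_that("constant-volume capacitance reduces to C0 at the zero-field state", {
  a0 <- 6.36e-7
  d0 <- 2.69e-9
  v0 <- a0 * d0
  c0 <- capacitance_planar(a0, d0)
  expect_equal(constant_volume_capacitance(v0, d0), c0)
  # 1/d^2 scaling evaluated by hand
  expect_equal(
    constant_volume_capacitance(v0, d0 / sqrt(1.02)),
    1.02 * c0,
    tolerance = 1e-12
  )
  # DOPC volume compressed to 2.60 nm
  expect_equal(
    constant_volume_capacitance(v0, 2.60e-9),
    5.60e-9,
    tolerance = 1e-3
  )
})

test_that("legacy electrostriction modulus matches the hand-evaluated value", {
  expect_equal(
    young_modulus_hianik(8.23e-3, 0.15, 1.0e-10),
    9.26e5,
    tolerance = 1e-3
  )
  # quadratic voltage scaling at fixed compression
  expect_equal(
    young_modulus_hianik(8.23e-3, 0.30, 1.0e-10),
    4 * young_modulus_hianik(8.23e-3, 0.15, 1.0e-10)
  )
  # forward form: no field, no compression
  e <- 1e6
  psi <- 0
  expect_identical(8.23e-3 * psi^2 / (2 * e), 0)

  expect_error(
    young_modulus_hianik(8.23e-3, 0.15, -1e-10),
    class = "electrobend_domain_error"
  )
  expect_error(
    young_modulus_hianik(8.23e-3, 0, 1e-10),
    class = "electrobend_domain_error"
  )
})

test_that("alpha follows m/(slope_factor * C0)", {
  expect_equal(
    alpha_from_slope(2.733e-9, 5.233e-9),
    0.1741,
    tolerance = 1e-3
  )
  expect_identical(alpha_from_slope(0, 5.233e-9), 0)
  # with slope_factor 1 the literal quadratic-law slope C0*alpha inverts
  alpha_true <- 0.2
  c0 <- 5e-9
  expect_equal(alpha_from_slope(c0 * alpha_true, c0, slope_factor = 1),
               alpha_true)
  expect_error(alpha_from_slope(1e-9, -1e-9),
               class = "electrobend_domain_error")
})

test_that("constant-volume Young's modulus has the right value and scalings", {
  e <- young_modulus_alvarez(8.23e-3, 0.1741, 2.69e-9)
  expect_equal(e, 1.76e7, tolerance = 2e-3)
  expect_equal(
    young_modulus_alvarez(8.23e-3, 2 * 0.1741, 2.69e-9),
    e / 2
  )
  expect_error(
    young_modulus_alvarez(8.23e-3, 0, 2.69e-9),
    class = "electrobend_domain_error"
  )
  expect_error(
    young_modulus_alvarez(8.23e-3, -0.1, 2.69e-9),
    class = "electrobend_domain_error"
  )
})

test_that("thin-plate conversion reproduces DOPC and DOPG moduli", {
  expect_equal(area_expansion_modulus(1.757e7, 2.69e-9, 0.5),
               9.45e-2, tolerance = 1e-3)
  expect_equal(area_expansion_modulus(6.29e6, 2.84e-9, 0.5),
               3.57e-2, tolerance = 1e-3)
  expect_equal(area_expansion_modulus(1e7, 3e-9, 0), 1e7 * 3e-9)
  expect_error(area_expansion_modulus(1e7, 3e-9, 1),
               class = "electrobend_domain_error")

  expect_equal(bending_rigidity(9.45e-2, 2.69e-9, 0.5),
               1.9e-20, tolerance = 2e-3)
  expect_equal(bending_rigidity(3.57e-2, 2.84e-9, 0.5),
               0.80e-20, tolerance = 2e-3)
})

test_that("composed bending rigidity is E*d^3/18 at Poisson ratio 0.5", {
  kc_composed <- function(e, d, v) {
    bending_rigidity(area_expansion_modulus(e, d, v), d, v)
  }
  set.seed(13)
  for (i in 1:20) {
    e <- 10^runif(1, 5, 8)
    d <- runif(1, 2e-9, 5e-9)
    expect_equal(kc_composed(e, d, 0.5), e * d^3 / 18, tolerance = 1e-12)
  }
  # d^3 scaling
  expect_equal(
    kc_composed(1.757e7, 2 * 2.69e-9, 0.5),
    8 * kc_composed(1.757e7, 2.69e-9, 0.5)
  )
})

test_that("operations are strictly monotone in each argument", {
  set.seed(14)
  for (i in 1:20) {
    a <- 10^runif(1, -8, -5)
    d <- 10^runif(1, -9.5, -8)
    up <- 1 + runif(1, 0.01, 0.5)
    expect_gt(capacitance_planar(a * up, d), capacitance_planar(a, d))
    expect_lt(capacitance_planar(a, d * up), capacitance_planar(a, d))
    expect_lt(
      thickness_from_capacitance(capacitance_planar(a, d) * up, a),
      thickness_from_capacitance(capacitance_planar(a, d), a)
    )
    expect_gt(
      young_modulus_hianik(8e-3, 0.1 * up, 1e-10),
      young_modulus_hianik(8e-3, 0.1, 1e-10)
    )
    expect_lt(
      young_modulus_alvarez(8e-3, 0.2 * up, d),
      young_modulus_alvarez(8e-3, 0.2, d)
    )
  }
})

test_that("domain errors name the offending field", {
  expect_error(capacitance_planar(-1e-7, 2.69e-9), "area")
  expect_error(capacitance_planar(6.36e-7, 0), "thickness")
  expect_error(thickness_from_capacitance(0, 6.36e-7), "capacitance")
  expect_error(constant_volume_capacitance(-1e-15, 2.6e-9),
               "zero_field_volume")
})

test_that("model functions are pure: repeated calls are bit-identical", {
  args <- list(6.36e-7, 2.69e-9, 2.5)
  expect_identical(
    do.call(capacitance_planar, args),
    do.call(capacitance_planar, args)
  )
  expect_identical(
    young_modulus_alvarez(8.23e-3, 0.1741, 2.69e-9),
    young_modulus_alvarez(8.23e-3, 0.1741, 2.69e-9)
  )
})
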
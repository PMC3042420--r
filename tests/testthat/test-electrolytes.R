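# Solution chemistry and equilibrium electrochemistry.

test_that("Nernst potential reproduces hand values and its symmetries", {
  expect_equal(nernst_potential(150, 150, 1, 310.15), 0)
  # (RT/F) ln 10 at 310.15 K
  expect_equal(nernst_potential(150, 15, 1, 310.15), 61.5, tolerance = 1e-2)
  expect_equal(nernst_potential(15, 150, 1, 310.15),
               -nernst_potential(150, 15, 1, 310.15))
  withr::with_seed(202, {
    for (i in 1:25) {
      a <- runif(1, 0.1, 500); b <- runif(1, 0.1, 500)
      z <- sample(c(-2L, -1L, 1L, 2L), 1)
      expect_equal(nernst_potential(a, b, z), -nernst_potential(b, a, z))
      expect_equal(nernst_potential(a, b, z),
                   nernst_potential(a, b, 1L) / z)
    }
  })
  expect_error(nernst_potential(-1, 10), "c_out")
  expect_error(nernst_potential(10, 0), "c_in")
  expect_error(nernst_potential(10, 10, 0L), "z")
})

test_that("bi-ionic GHK ratio matches the printed worked value and inverts", {
  expect_equal(round(bionic_permeability_ratio(7.0, 150, 150, 1, 310.15), 1),
               1.3)
  expect_equal(bionic_permeability_ratio(0, 150, 150), 1)
  expect_equal(bionic_permeability_ratio(-7.0, 150, 150), 0.77,
               tolerance = 1e-2)
  # round trip through the forward prediction
  withr::with_seed(202, {
    for (i in 1:30) {
      r <- exp(runif(1, log(0.1), log(10)))
      ct <- runif(1, 10, 300); cr <- runif(1, 10, 300)
      dvr <- bionic_delta_vr(r, ct, cr)
      expect_equal(bionic_permeability_ratio(dvr, ct, cr), r,
                   tolerance = 1e-10)
    }
  })
  expect_error(bionic_permeability_ratio(5, -1, 150), "c_out_test")
})

test_that("Henderson LJP: zero on identity, antisymmetric, matches the
           linear-mixing integral", {
  B2 <- stock_solution("B2")
  expect_identical(henderson_ljp(B2, B2), 0)
  # independent numeric oracle: quadrature of the junction integral
  # -RT/F int_0^1 sum(z u dc) / sum(z^2 u c) dx over a linear mixing path
  planck_ljp <- function(A, B, T_K = 310.15) {
    mob <- ion_mobilities()
    sp <- union(names(A$ions), names(B$ions))
    lam <- mob$lambda0[match(sp, mob$name)]
    z <- mob$z[match(sp, mob$name)]
    cA <- ion_conc(A, sp); cB <- ion_conc(B, sp)
    f <- function(x) vapply(x, function(xx) {
      cx <- cA + xx * (cB - cA)
      -sum(sign(z) * lam * (cB - cA)) / sum(abs(z) * lam * cx)
    }, numeric(1))
    rt_over_f(T_K) * stats::integrate(f, 0, 1, rel.tol = 1e-10)$value
  }
  withr::with_seed(202, {
    for (i in 1:20) {
      A <- random_solution("A"); B <- random_solution("B")
      e <- henderson_ljp(A, B)
      expect_equal(henderson_ljp(B, A), -e, tolerance = 1e-9)
      expect_equal(e, planck_ljp(A, B), tolerance = 1e-6)
    }
  })
  # near-equal K+/Cl- mobilities force a small junction potential
  kcl150 <- make_solution("KCl150", c(K = 150, Cl = 150))
  kcl15 <- make_solution("KCl15", c(K = 15, Cl = 15))
  expect_lt(abs(henderson_ljp(kcl150, kcl15)), 2)
  # the printed correction for the low-Na/high-NMDG pipette against the
  # Na-rich bath (-6.9 mV) is reproduced by the shipped mobility table
  expect_equal(henderson_ljp(stock_solution("P4"), B2), -6.9,
               tolerance = 0.5)
  # K-rich pipette vs Na-rich bath: positive, a few millivolts
  e <- henderson_ljp(stock_solution("P3"), B2)
  expect_gt(e, 3); expect_lt(e, 8)
  # missing mobility entry is a configuration error naming the species
  odd <- make_solution("odd", c(K = 10, Cl = 10))
  odd$ions <- c(odd$ions, unobtainium = 5)
  expect_error(henderson_ljp(odd, B2), "unobtainium")
})

test_that("free calcium solves the 1:1 buffer equilibrium", {
  expect_equal(free_calcium(0, 1), 0)
  expect_equal(free_calcium(0.367, 0), 367000)
  # canonical pipette recipe is buffered to ~100 nM
  expect_equal(free_calcium(0.367, 1.0, 172.5), 100, tolerance = 0.05)
  # brute-force bisection oracle
  bisect <- function(caT, egta, kd_nM) {
    kd <- kd_nM * 1e-6
    f <- function(x) x + egta * x / (kd + x) - caT
    if (caT == 0) return(0)
    stats::uniroot(f, c(0, caT), tol = 1e-15)$root * 1e6
  }
  withr::with_seed(202, {
    for (i in 1:30) {
      caT <- runif(1, 0, 2); egta <- runif(1, 0, 5)
      kd <- runif(1, 50, 5000)
      expect_equal(free_calcium(caT, egta, kd), bisect(caT, egta, kd),
                   tolerance = 1e-6)
    }
  })
  # monotonicity
  expect_gt(free_calcium(0.5, 1), free_calcium(0.4, 1))
  expect_lt(free_calcium(0.4, 1.2), free_calcium(0.4, 1))
})

test_that("ideal osmolarity sums dissociated particles", {
  empty <- make_solution("water", c(Na = 0, Cl = 0))
  expect_equal(ideal_osmolarity(empty), 0)
  nacl <- make_solution("saline", c(Na = 150, Cl = 150))
  expect_equal(ideal_osmolarity(nacl), 300)
  # recipes land near the measured 311-318 mOsm; ideal unit-coefficient
  # sums (titrant included) run ~5-15 mOsm above the measured values
  for (lab in solution_labels()) {
    osm <- ideal_osmolarity(stock_solution(lab))
    expect_gt(osm, 305); expect_lt(osm, 335)
  }
})

test_that("canonical recipes balance charge and survive JSON round trips", {
  for (lab in solution_labels()) {
    s <- stock_solution(lab)
    expect_lt(abs(charge_imbalance(s)), 1e-9)
    path <- tempfile(fileext = ".json")
    write_solution_json(s, path)
    s2 <- read_solution_json(path)
    expect_equal(s2$ions, s$ions)
    expect_equal(s2$pH, s$pH)
  }
  # constructor rejects a grossly unbalanced inventory
  expect_error(make_solution("bad", c(Na = 100, Cl = 10)), "imbalance")
})

test_that("mobility table ships and validates", {
  tab <- ion_mobilities()
  expect_true(all(c("Na", "K", "Li", "NMDG", "Cl", "methanesulfonate",
                    "gluconate", "SO4", "Mg", "Ca", "HEPES") %in% tab$name))
  expect_true(all(tab$lambda0 > 0))
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(name = "X", z = 0, lambda0 = 50), bad,
            row.names = FALSE)
  expect_error(read_mobility_table(bad), "valence")
})
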
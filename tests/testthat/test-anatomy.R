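test_that("equivalent diameter inverts the circle area exactly", {
  expect_equal(equivalent_diameter(100 * pi), 20)
  expect_equal(equivalent_diameter(pi / 4), 1)
  expect_equal(equivalent_diameter(1000), 2 * sqrt(1000 / pi))
  expect_equal(equivalent_diameter(1000), 35.6825, tolerance = 1e-5)
  # round trip area -> diameter -> area
  a <- c(0.3, 12, 950, 8000)
  expect_equal(pi * equivalent_diameter(a)^2 / 4, a, tolerance = 1e-12)
  expect_error(equivalent_diameter(0), "positive")
  expect_error(equivalent_diameter(c(10, -1)), "positive")
})

test_that("both hydraulic diameter conventions match their closed forms", {
  expect_equal(hydraulic_diameter(c(30, 30, 30)), 30)
  expect_equal(hydraulic_diameter(c(30, 30, 30), "fourth_moment"), 30)
  expect_equal(hydraulic_diameter(c(10, 20)),
               (10^5 + 20^5) / (10^4 + 20^4))
  expect_equal(hydraulic_diameter(c(10, 20)), 19.412, tolerance = 1e-4)
  expect_equal(hydraulic_diameter(c(10, 20), "fourth_moment"),
               ((10^4 + 20^4) / 2)^0.25)
  expect_equal(hydraulic_diameter(c(10, 20), "fourth_moment"), 17.075,
               tolerance = 1e-4)
  expect_error(hydraulic_diameter(numeric(0)), "non-empty")
})

test_that("d5/d4 weighting never falls below the arithmetic mean", {
  set.seed(11)
  for (i in 1:50) {
    d <- rlnorm(sample(2:80, 1), log(40), runif(1, 0.05, 0.6))
    dh <- hydraulic_diameter(d)
    expect_gte(dh, mean(d))
    expect_gte(hydraulic_diameter(d, "fourth_moment"), mean(d))
  }
  # equality holds exactly when all diameters agree
  expect_equal(hydraulic_diameter(rep(17.3, 9)), 17.3)
})

test_that("conduit density is count per mm^2 of sector", {
  expect_equal(conduit_density(100, 1e6), 100)
  expect_equal(conduit_density(0, 1e6), 0)
  expect_equal(conduit_density(57, 0.5e6), 114)
  expect_error(conduit_density(10, 0), "positive")
})

test_that("lumen fraction is bounded and rejects impossible inputs", {
  expect_equal(lumen_fraction(c(1.2e5, 1e5), 1e6), 22)
  expect_equal(lumen_fraction(numeric(0), 1e6), 0)
  expect_equal(lumen_fraction(1e6, 1e6), 100)
  expect_error(lumen_fraction(1.1e6, 1e6), "exceeds")
})

test_that("potential conductivity follows the Hagen-Poiseuille form", {
  # independent evaluation of pi*rho*D^4 / (128*eta*A) in SI units
  manual <- pi * 998.2 * (50e-6)^4 / (128 * 1.002e-9 * 1e-6)
  expect_equal(potential_conductivity(50, 1e6), manual)
  expect_equal(potential_conductivity(50, 1e6), 0.1528, tolerance = 1e-3)
  # fourth-power scaling and additivity over conduits
  expect_equal(potential_conductivity(100, 1e6),
               16 * potential_conductivity(50, 1e6))
  expect_equal(potential_conductivity(rep(50, 100), 1e6),
               100 * potential_conductivity(50, 1e6))
  expect_error(potential_conductivity(numeric(0), 1e6), "non-empty")
  expect_error(potential_conductivity(50, 0), "positive")
})

test_that("trait bundle agrees with component-wise recomputation", {
  set.seed(21)
  d <- rlnorm(120, log(45), 0.3)
  cs <- cs_of(d)
  tr <- anatomy_traits(cs)
  expect_equal(tr$n, 120)
  expect_equal(tr$CD, conduit_density(120, cs$sector_area))
  expect_equal(tr$F, lumen_fraction(cs$lumen_areas, cs$sector_area))
  expect_equal(tr$D_mean, mean(d), tolerance = 1e-12)
  expect_equal(tr$D_h, hydraulic_diameter(d), tolerance = 1e-12)
  expect_equal(tr$KS_pot,
               potential_conductivity(d, cs$sector_area), tolerance = 1e-12)
  # KS_pot is the sum of single-conduit contributions
  per_conduit <- vapply(d, potential_conductivity,
                        numeric(1), reference_area = cs$sector_area)
  expect_equal(tr$KS_pot, sum(per_conduit), tolerance = 1e-12)
})

test_that("a uniform sector reproduces its diameter in every summary", {
  # 100 identical 61-um conduits at density 100 mm^-2
  cs <- conduit_set("u", "root", 45, sector_area = 1e6,
                    lumen_diameters = rep(61, 100))
  tr <- anatomy_traits(cs)
  expect_equal(tr$D_h, 61)
  expect_equal(tr$D_mean, 61)
  expect_equal(tr$CD, 100)
  # a single conduit degenerates the same way
  tr1 <- anatomy_traits(conduit_set("u1", "branch", 30, 1e5,
                                    lumen_diameters = 28))
  expect_equal(tr1$D_h, tr1$D_mean)
  expect_equal(tr1$D_h, 28)
})

test_that("unit audit: um inputs equal an independent SI evaluation", {
  set.seed(31)
  d_um <- rlnorm(60, log(50), 0.25)
  area_um2 <- 8e5
  from_um <- potential_conductivity(d_um, area_um2)
  # same physical geometry entered in metres through the raw equation
  d_m <- d_um * 1e-6
  area_m2 <- area_um2 * 1e-12
  from_si <- pi * 998.2 * sum(d_m^4) / (128 * 1.002e-9 * area_m2)
  expect_equal(from_um, from_si, tolerance = 1e-12)
})

test_that("sample D_h converges to the analytic lognormal moment ratio", {
  set.seed(41)
  mu <- log(40); sigma <- 0.35
  d <- rlnorm(1e4, mu, sigma)
  analytic <- exp(mu + 4.5 * sigma^2)  # E[d^5]/E[d^4] for a lognormal
  expect_equal(hydraulic_diameter(d), analytic, tolerance = 0.01)
})

test_that("the table interface reproduces per-sample trait objects", {
  set.seed(51)
  tab <- do.call(rbind, lapply(1:3, function(i) {
    d <- rlnorm(40, log(35), 0.3)
    data.frame(sample_id = paste0("s", i), organ = "branch",
               sector_angle_deg = 40, sector_area_um2 = 4e5,
               lumen_area_um2 = pi * d^2 / 4)
  }))
  out <- derive_anatomy(tab)
  expect_equal(nrow(out), 3)
  g <- tab[tab$sample_id == "s2", ]
  cs <- conduit_set("s2", "branch", 40, 4e5, lumen_areas = g$lumen_area_um2)
  tr <- anatomy_traits(cs)
  expect_equal(out$Dh_um[out$sample_id == "s2"], tr$D_h)
  expect_equal(out$KSpot_kg_m_MPa_s[out$sample_id == "s2"], tr$KS_pot)
  # diameters column is accepted as the alternative input
  tab2 <- tab
  tab2$lumen_diameter_um <- equivalent_diameter(tab2$lumen_area_um2)
  tab2$lumen_area_um2 <- NULL
  out2 <- derive_anatomy(tab2)
  expect_equal(out2$Dh_um, out$Dh_um, tolerance = 1e-12)
})

test_that("conduit sets reject inconsistent measurements", {
  expect_error(conduit_set("x", "root", 45, 100, lumen_areas = c(60, 60)),
               "exceeds")
  expect_error(conduit_set("x", "root", 45, -1, lumen_areas = 10),
               "positive")
  expect_error(conduit_set("x", "root", 45, 1e5), "exactly one")
  expect_error(conduit_set("x", "root", 45, 1e5, lumen_areas = 10,
                           lumen_diameters = 5), "exactly one")
  expect_warning(conduit_set("x", "root", 80, 1e5, lumen_areas = 10),
                 "20-70")
})
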
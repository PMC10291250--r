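test_that("axial conductivity converts instrument units correctly", {
  # 1 g/h at 2 kPa over 0.05 m: (1e-3/3600) * 0.05 / 0.002
  expect_equal(axial_conductivity(1, 2, 0.05), (1e-3 / 3600) * 0.05 / 2e-3)
  expect_equal(axial_conductivity(1, 2, 0.05), 6.944e-6, tolerance = 1e-4)
  expect_equal(axial_conductivity(0, 2, 0.05), 0)
  expect_equal(axial_conductivity(2, 2, 0.05),
               2 * axial_conductivity(1, 2, 0.05))
  expect_error(axial_conductivity(1, 0, 0.05), "positive")
})

test_that("xylem area follows the organ's end convention", {
  root <- segment_geometry("r", "root", 0.1, 4, 4, 4, 4)
  expect_equal(xylem_area(root), pi * 4 * 4 / 4 * 1e-6)
  expect_equal(xylem_area(root), 1.2566e-5, tolerance = 1e-4)
  # branch with a 1-mm circular pith: annulus
  br <- segment_geometry("b", "branch", 0.05, 4, 4, 4, 4,
                         pith_d1 = 1, pith_d2 = 1)
  expect_equal(xylem_area(br), (pi * 16 / 4 - pi / 4) * 1e-6)
  expect_equal(xylem_area(br), 1.1781e-5, tolerance = 1e-4)
  # without pith the branch uses the plain ellipse, like a root
  br2 <- segment_geometry("b2", "branch", 0.05, 4, 4, 4, 4)
  expect_equal(xylem_area(br2), xylem_area(root))
  # a root uses the distal end, a branch the basal end
  asym <- segment_geometry("a", "root", 0.1, 6, 6, 3, 3)
  expect_equal(xylem_area(asym), pi * 9 / 4 * 1e-6)
  asym_b <- segment_geometry("a2", "branch", 0.05, 6, 6, 3, 3)
  expect_equal(xylem_area(asym_b), pi * 36 / 4 * 1e-6)
  expect_error(segment_geometry("p", "branch", 0.05, 4, 4, 4, 4,
                                pith_d1 = 5, pith_d2 = 1), "smaller")
})

test_that("the plateau conductivity is picked by the stability rule", {
  sel <- select_kmax(c(4.0, 4.8, 4.85), stability_tol = 0.02)
  expect_equal(sel$kh_max, 4.85)
  expect_true(sel$stable)
  expect_equal(select_kmax(5.0)$kh_max, 5.0)
  expect_warning(sel2 <- select_kmax(c(1, 2, 4, 8)), "never stabilized")
  expect_equal(sel2$kh_max, 8)
  expect_false(sel2$stable)
  expect_error(select_kmax(numeric(0)), "at least one")
})

test_that("specific, leaf-specific conductivity and Huber value divide", {
  expect_equal(specific_conductivity(6.944e-6, 1.2566e-5), 0.5526,
               tolerance = 1e-3)
  expect_equal(specific_conductivity(0, 1), 0)
  expect_equal(specific_conductivity(3 * 2, 3 * 4),
               specific_conductivity(2, 4))
  expect_equal(leaf_specific_conductivity(6.944e-6, 0.01), 6.944e-4)
  expect_equal(leaf_specific_conductivity(1, 0.02),
               leaf_specific_conductivity(1, 0.01) / 2)
  expect_equal(leaf_specific_conductivity(0, 0.01), 0)
  expect_equal(huber_value(1.2566e-5, 0.009), 1.396e-3, tolerance = 1e-3)
  expect_equal(huber_value(2, 2), 1)
  expect_equal(huber_value(0, 1), 0)
  expect_error(specific_conductivity(1, 0), "positive")
  expect_error(leaf_specific_conductivity(1, 0), "positive")
})

test_that("conductivity chain is linear in flow and length, inverse in head and area", {
  set.seed(61)
  for (i in 1:25) {
    f <- runif(1, 0.3, 8); p <- runif(1, 0.5, 3); l <- runif(1, 0.04, 0.12)
    a <- runif(1, 5e-6, 3e-5); c <- runif(1, 1.2, 4)
    ks <- specific_conductivity(axial_conductivity(f, p, l), a)
    expect_equal(specific_conductivity(axial_conductivity(c * f, p, l), a),
                 c * ks, tolerance = 1e-12)
    expect_equal(specific_conductivity(axial_conductivity(f, p, c * l), a),
                 c * ks, tolerance = 1e-12)
    expect_equal(specific_conductivity(axial_conductivity(f, c * p, l), a),
                 ks / c, tolerance = 1e-12)
    expect_equal(specific_conductivity(axial_conductivity(f, p, l), c * a),
                 ks / c, tolerance = 1e-12)
  }
})

test_that("per-sample hydraulic traits respect stage order, not row order", {
  geom <- segment_geometry("s", "branch", 0.05, 4.5, 4.4, 4.5, 4.6,
                           pith_d1 = 1, pith_d2 = 1.1)
  rec <- data.frame(stage = c("initial", "flush_1", "flush_2", "flush_3"),
                    pressure_kPa = 2,
                    flow_g_per_h = c(1.0, 1.6, 1.97, 2.0))
  tr <- hydraulic_traits(rec, geom, leaf_area = 0.01)
  shuffled <- rec[c(3, 1, 4, 2), ]
  tr2 <- hydraulic_traits(shuffled, geom, leaf_area = 0.01)
  expect_equal(tr$KS_hydr, tr2$KS_hydr)
  expect_equal(tr$Kh_init, axial_conductivity(1.0, 2, 0.05))
  expect_equal(tr$Kh_max, axial_conductivity(2.0, 2, 0.05))
  expect_equal(tr$K_L, tr$Kh_max / 0.01)
  expect_equal(tr$HV, xylem_area(geom) / 0.01)
  expect_equal(tr$KS_hydr, tr$Kh_max / xylem_area(geom))
  # initial-only records fall back with a warning
  init_only <- rec[rec$stage == "initial", ]
  expect_warning(tr3 <- hydraulic_traits(init_only, geom), "no flush")
  expect_equal(tr3$Kh_max, tr3$Kh_init)
})

test_that("the table interface joins flow, geometry and leaf areas", {
  geom_tab <- data.frame(sample_id = c("a", "b"), organ = c("root", "branch"),
                         length_m = c(0.1, 0.05),
                         end1_d1 = 4, end1_d2 = 4, end2_d1 = 4, end2_d2 = 4,
                         pith_d1 = c(NA, 1), pith_d2 = c(NA, 1),
                         dry_mass_g = NA_real_)
  flow_tab <- rbind(
    data.frame(sample_id = "a", stage = c("flush_1", "flush_2"),
               pressure_kPa = 1, flow_g_per_h = c(2.0, 2.02)),
    data.frame(sample_id = "b", stage = c("flush_1", "flush_2"),
               pressure_kPa = 2, flow_g_per_h = c(1.0, 1.01)))
  leaf_tab <- data.frame(sample_id = "b", leaf_area_m2 = 0.012)
  out <- derive_hydraulics(flow_tab, geom_tab, leaf_tab)
  expect_equal(nrow(out), 2)
  expect_equal(out$KShydr[out$sample_id == "a"],
               axial_conductivity(2.02, 1, 0.1) / (pi * 4 * 4 / 4 * 1e-6))
  expect_true(is.finite(out$HV[out$sample_id == "b"]))
  expect_true(is.na(out$HV[out$sample_id == "a"]))
  expect_error(derive_hydraulics(flow_tab, geom_tab[1, ], leaf_tab),
               "no segment geometry")
})
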
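paper_cyl <- cylinder_section(0.25e-6, 1.4, 1.33)

test_that("axial ray transfers momentum along propagation only", {
  path <- trace_ray(incident_ray(0, power = 1e-3), paper_cyl)
  f <- ray_force(path)
  expect_gt(f["fx"], 0)
  expect_equal(unname(f["fy"]), 0, tolerance = 1e-25)
  ## first two events: front-surface reflection plus entry refraction
  expect_identical(path$events$kind[1:2],
                   c("external_reflection", "refraction_in"))
  ## at normal incidence the entry reflectance is ((n2-n1)/(n2+n1))^2
  r0 <- ((1.4 - 1.33) / (1.4 + 1.33))^2
  expect_equal(path$events$event_power[1], 1e-3 * r0, tolerance = 1e-12)
})

test_that("a miss produces an empty path and zero force", {
  path <- trace_ray(incident_ray(0.3e-6, power = 1e-3), paper_cyl)
  expect_identical(nrow(path$events), 0L)
  expect_equal(unname(ray_force(path)), c(0, 0))
  ## the full power passes by
  expect_equal(sum(path$exit_rays$power), 1e-3)
})

test_that("a single mirror event at b=0 reduces to the planar force law", {
  mirror <- cylinder_section(0.25e-6, 1.4, 1.33, perfect_mirror = TRUE)
  path <- trace_ray(incident_ray(0, power = 1e-3), mirror)
  expect_identical(nrow(path$events), 1L)
  expect_equal(unname(ray_force(path)["fx"]),
               reflection_force(beam_spec(1e-3, 0), 1.33))
})

test_that("entry at a modest offset refracts through without TIR", {
  ## ray at b = r sin(40 deg): internal angle ~37.6 deg, well below the
  ## 71.8-deg critical angle, so the dominant ray exits at the back
  b <- 0.25e-6 * sin(40 * pi / 180)
  path <- trace_ray(incident_ray(b, power = 1e-3), paper_cyl)
  theta_int <- asin((1.33 / 1.4) * sin(40 * pi / 180)) * 180 / pi
  expect_equal(theta_int, 37.62, tolerance = 1e-3)
  kinds <- path$events$kind
  expect_true("refraction_out" %in% kinds)
  ## the big exit happens at the first back-surface hit
  exit_powers <- path$events$event_power[kinds == "refraction_out"]
  expect_gt(exit_powers[1] / 1e-3, 0.99)
})

test_that("per-ray force obeys the global momentum-balance oracle", {
  cutoff <- 1e-4
  p_inc <- 1e-3
  tol <- 2 * cutoff * paper_cyl$index_inside * p_inc / C0
  for (b in c(0, 0.05e-6, 0.12e-6, 0.2e-6, 0.249e-6, -0.17e-6)) {
    for (pol in c("perpendicular", "parallel")) {
      path <- trace_ray(incident_ray(b, power = p_inc, polarization = pol),
                        paper_cyl, power_cutoff_fraction = cutoff)
      expect_lt(max(abs(ray_force(path) -
                          momentum_balance_force(path, paper_cyl))), tol)
    }
  }
})

test_that("power is conserved along every traced path", {
  for (b in c(0, 0.1e-6, 0.21e-6, 0.2499e-6)) {
    path <- trace_ray(incident_ray(b, power = 1e-3), paper_cyl)
    expect_equal(sum(path$exit_rays$power) + path$residual_power, 1e-3,
                 tolerance = 1e-15)
    expect_true(all(path$events$event_power <= 1e-3))
  }
})

test_that("per-ray forces push along propagation and mirror across the axis", {
  pos <- seq(0.04e-6, 0.24e-6, length.out = 6)
  bb <- c(-rev(pos), 0, pos)            # exactly sign-symmetric grid
  ff <- vapply(bb, function(b)
    ray_force(trace_ray(incident_ray(b, 1e-3), paper_cyl)), numeric(2))
  expect_true(all(ff[1, ] >= 0))
  rev_idx <- rev(seq_along(bb))
  expect_lt(max(abs(ff[2, ] + ff[2, rev_idx])), 1e-25)
  expect_lt(max(abs(ff[1, ] - ff[1, rev_idx])), 1e-25)
})

test_that("an index-matched cylinder feels no force", {
  matched <- cylinder_section(0.25e-6, 1.33, 1.33)
  res <- beam_force_on_cylinder(1e-3, matched, n_rays = 101)
  expect_equal(unname(res$total_force), c(0, 0), tolerance = 1e-25)
})

test_that("beam totals are symmetric, bounded, and convergent", {
  res <- beam_force_on_cylinder(15e-3, paper_cyl, n_rays = 501)
  ## mirror symmetry of a centred uniform beam kills the transverse force
  expect_lt(abs(res$total_force["fy"]), 1e-12 * abs(res$total_force["fx"]))
  ## bounded by the perfect-mirror force at normal incidence
  expect_lt(sqrt(sum(res$total_force^2)),
            2 * 15e-3 * 1.33 / C0)
  ## Richardson-style refinement: error shrinks monotonically with rays
  f1 <- beam_force_on_cylinder(1e-3, paper_cyl, n_rays = 251)$total_force[1]
  f2 <- beam_force_on_cylinder(1e-3, paper_cyl, n_rays = 1001)$total_force[1]
  f3 <- beam_force_on_cylinder(1e-3, paper_cyl, n_rays = 4001)$total_force[1]
  f4 <- beam_force_on_cylinder(1e-3, paper_cyl,
                               n_rays = 16001)$total_force[1]
  expect_lt(abs(f3 - f4), abs(f2 - f4))
  expect_lt(abs(f2 - f4), abs(f1 - f4))
  ## quadrature agreement well within 0.1%
  expect_lt(abs(f2 - f4) / abs(f4), 1e-3)
  ## a perfect-mirror cylinder integrates between n/c and 2n/c per watt
  mirror <- cylinder_section(0.25e-6, 1.4, 1.33, perfect_mirror = TRUE)
  fm <- beam_force_on_cylinder(1e-3, mirror, n_rays = 2001)$total_force[1]
  expect_gt(fm, 1.33 * 1e-3 / C0)
  expect_lt(fm, 2 * 1.33 * 1e-3 / C0)
})

test_that("gaussian beams load only their in-aperture fraction", {
  wide <- beam_force_on_cylinder(1e-3, paper_cyl, n_rays = 501,
                                 profile = "gaussian", sigma = 2.5e-6)
  narrow <- beam_force_on_cylinder(1e-3, paper_cyl, n_rays = 501,
                                   profile = "gaussian", sigma = 0.05e-6)
  uniform <- beam_force_on_cylinder(1e-3, paper_cyl, n_rays = 501)
  ## a beam much wider than the cylinder deposits little of its power
  expect_lt(wide$total_force["fx"], uniform$total_force["fx"])
  ## a tightly-focused beam acts like a single axial ray
  axial <- ray_force(trace_ray(incident_ray(0, 1e-3), paper_cyl))
  expect_equal(unname(narrow$total_force["fx"]), unname(axial["fx"]),
               tolerance = 5e-3)
})

test_that("impact parameters classify into miss and refraction regimes", {
  rmap <- regime_map(paper_cyl, n_samples = 401)
  expect_identical(
    unname(rmap$regime[abs(rmap$impact_parameter) > 0.25e-6][1]), "miss")
  expect_identical(rmap$regime[which.min(abs(rmap$impact_parameter))],
                   "refract_through")
  ## external illumination reaches TIR only in the grazing limit, so a
  ## finite grid contains no tir_chain rays
  expect_identical(sum(rmap$regime == "tir_chain"), 0L)
})

test_that("injected internal rays at the critical angle stay trapped", {
  cc <- critical_angle(1.4, 1.33)
  path <- inject_internal_ray(paper_cyl, 180, cc + 2, power = 1e-3,
                              max_internal_bounces = 7)
  expect_identical(path$terminated_by, "bounce_cap")
  expect_identical(unique(path$events$kind), "internal_reflection")
  expect_identical(nrow(path$events), 7L)
  ## trapped power never leaves
  expect_equal(path$residual_power, 1e-3)
  ## below the critical angle the ray leaks out within a few bounces
  leak <- inject_internal_ray(paper_cyl, 180, cc - 10, power = 1e-3)
  expect_identical(leak$terminated_by, "power_cutoff")
  expect_gt(sum(leak$exit_rays$power) / 1e-3, 0.999)
})
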
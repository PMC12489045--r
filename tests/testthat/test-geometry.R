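test_that("axis fitting recovers helix axes with the N-to-C sign convention", {
  h <- simulate_ideal_helix(20, orientation = c(0, 0, 1))
  fr <- fit_axis(h)
  # a finite helix's principal direction carries a sub-degree intrinsic tilt
  expect_lt(acos(min(fr$axis[3], 1)) * 180 / pi, 1)
  expect_gt(fr$collinearity, 0.5)

  # reversed residue order flips the directed axis
  fr_rev <- fit_axis(h[nrow(h):1, ])
  expect_equal(fr_rev$axis, -fr$axis, tolerance = 1e-6)

  # collinear points (radius 0) fit exactly
  rod <- simulate_ideal_helix(10, radius = 0, orientation = c(1, 0, 0))
  expect_equal(fit_axis(rod)$axis, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(fit_axis(rod)$collinearity, 1)

  expect_error(fit_axis(h[1:4, ]), "5 points")
  expect_error(fit_axis(matrix(1, nrow = 6, ncol = 3)), "Degenerate")
})

test_that("axis fitting is equivariant under known rigid motions", {
  h <- simulate_ideal_helix(25, orientation = c(0, 0, 1))
  ax0 <- fit_axis(h)$axis
  for (s in 1:5) {
    R <- random_rotation(seed = s)
    moved <- h %*% t(R)
    moved <- sweep(moved, 2, c(10, -3, 7), "+")
    expect_equal(fit_axis(moved)$axis, as.numeric(R %*% ax0), tolerance = 1e-6)
  }
})

test_that("assembly plane normal is the least-variance direction, canonically signed", {
  asm <- simulate_planar_assembly(3, c(100, 130))
  n0 <- assembly_plane_normal(asm)
  expect_equal(abs(n0), c(0, 0, 1), tolerance = 1e-9)
  expect_gte(n0[3], 0)

  R <- random_rotation(seed = 7)
  rotated <- transform_structure(asm, R, c(5, 5, 5))
  n1 <- assembly_plane_normal(rotated)
  expected <- as.numeric(R %*% c(0, 0, 1))
  if (sum(n1 * expected) < 0) expected <- -expected  # sign canonicalization
  expect_equal(n1, expected, tolerance = 1e-6)

  # two-unit minimal case: defined and stable under small jitter
  two <- simulate_planar_assembly(2, 90)
  n2 <- assembly_plane_normal(two)
  jittered <- simulate_planar_assembly(2, 90, jitter = 1e-3, seed = 3)
  n2j <- assembly_plane_normal(jittered)
  expect_lt(acos(min(abs(sum(n2 * n2j)), 1)) * 180 / pi, 0.5)

  expect_error(assembly_plane_normal(matrix(rnorm(12), 4, 3) * 0), "zero variance")
})

test_that("projected angles reproduce closed-form cases", {
  n <- c(0, 0, 1)
  expect_equal(projected_inter_unit_angle(c(1, 0, 0), c(0, 1, 0), n), 90)
  expect_equal(projected_inter_unit_angle(c(1, 0, 0), c(-1 / 2, sqrt(3) / 2, 0), n),
               120, tolerance = 1e-12)
  expect_equal(projected_inter_unit_angle(c(1, 0, 0), c(1, 0, 0), n), 0)
  # symmetric in its arguments
  a <- c(0.3, 0.8, 0.2); b <- c(-0.5, 0.4, 0.1)
  expect_equal(projected_inter_unit_angle(a, b, n),
               projected_inter_unit_angle(b, a, n))
  expect_error(projected_inter_unit_angle(c(0, 0, 1), c(1, 0, 0), n),
               "perpendicular")
})

test_that("synthetic assemblies round-trip their requested angles to 1e-6 degrees", {
  for (ang in c(60, 90, 120, 150)) {
    asm <- simulate_planar_assembly(2, ang)
    rep <- assembly_report(asm, units = list("A", "B"))
    expect_equal(rep$angles$angle_deg, ang, tolerance = 1e-6)
  }
  # arbitrary angles; the fourth (cyclic closure) pair measures 360 - 275 = 85
  asm4 <- simulate_planar_assembly(4, c(70, 110, 95), n_res = 30)
  rep4 <- assembly_report(asm4, units = list("A", "B", "C", "D"))
  expect_equal(sort(rep4$angles$angle_deg), sort(c(70, 110, 95, 85)),
               tolerance = 1e-6)
})

test_that("C3-symmetric assemblies give exactly equal 120-degree adjacent angles", {
  asm <- simulate_planar_assembly(3, c(120, 120))
  rep <- assembly_report(asm, units = list("A", "B", "C"))
  expect_equal(nrow(rep$angles), 3)
  expect_equal(rep$angles$angle_deg, rep(120, 3), tolerance = 1e-9)
  expect_equal(rep$classification, "hexamer_like")
  expect_equal(diff(range(rep$angles$angle_deg)), 0, tolerance = 1e-9)
})

test_that("angles are invariant under rigid motion and robust to coordinate noise", {
  asm <- simulate_planar_assembly(3, c(95, 115), n_res = 25)
  base_rep <- assembly_report(asm, units = list("A", "B", "C"))
  for (s in 1:3) {
    R <- random_rotation(seed = 100 + s)
    moved <- transform_structure(asm, R, rnorm(3, sd = 20))
    moved_rep <- assembly_report(moved, units = list("A", "B", "C"))
    expect_equal(sort(moved_rep$angles$angle_deg),
                 sort(base_rep$angles$angle_deg), tolerance = 1e-6)
  }
  # 0.5 A isotropic jitter changes angles by < 3 degrees
  noisy <- simulate_planar_assembly(3, c(95, 115), n_res = 25,
                                    jitter = 0.5, seed = 9)
  noisy_rep <- assembly_report(noisy, units = list("A", "B", "C"))
  expect_lt(max(abs(sort(noisy_rep$angles$angle_deg) -
                      sort(base_rep$angles$angle_deg))), 3)
})

test_that("tetramer-like and hexamer-like classification follows the windows", {
  tetra <- assembly_report(simulate_planar_assembly(2, 90), list("A", "B"))
  expect_equal(tetra$classification, "tetramer_like")
  hexa <- assembly_report(simulate_planar_assembly(3, c(120, 120)),
                          list("A", "B", "C"))
  expect_equal(hexa$classification, "hexamer_like")
  open <- assembly_report(simulate_planar_assembly(2, 150), list("A", "B"))
  expect_equal(open$classification, "other")
  g <- glance(tetra)
  expect_equal(g$median_angle_deg, 90, tolerance = 1e-9)
  expect_equal(g$n_units, 2L)
})

test_that("unit definitions parse and missing chains are named in errors", {
  u <- parse_units("A+A',B+B'")
  expect_equal(length(u), 2)
  expect_equal(u[[1]], c("A", "A'"))
  asm <- simulate_planar_assembly(2, 90)
  expect_error(assembly_report(asm, units = list("A", "Z")), "Z")
  # helix mode: explicit residue range on a designated chain
  rep_h <- assembly_report(asm, units = list("A", "B"), axis_mode = "helix",
                           helix_range = list(list(chain = "A", start = 1, end = 20),
                                              list(chain = "B", start = 1, end = 20)))
  expect_equal(rep_h$angles$angle_deg, 90, tolerance = 1e-6)
})
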
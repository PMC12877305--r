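test_that("plane fit of a hexagon obeys the traversal orientation rule", {
  hx <- hexagon_xy()
  p <- fit_plane(hx)                 # counter-clockwise seen from +z
  expect_equal(p$normal, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(p$rms_deviation, 0, tolerance = 1e-12)
  p2 <- fit_plane(hx[6:1, ])         # clockwise
  expect_equal(p2$normal, c(0, 0, -1), tolerance = 1e-12)
  expect_error(fit_plane(cbind(1:5, 2 * (1:5), -1:3 * 0)), "collinear")
})

test_that("plane fit matches a dense grid-search oracle on noisy hexagons", {
  worst_angle <- 0
  for (s in 1:50) {
    set.seed(s)
    hx <- hexagon_xy()
    hx[, 3] <- hx[, 3] + runif(6, -0.05, 0.05)
    p <- fit_plane(hx)
    o <- grid_plane_oracle(hx, step_deg = 2)
    ang <- acos(min(1, abs(sum(p$normal * o$normal)))) * 180 / pi
    worst_angle <- max(worst_angle, ang)
    # SVD solution can never be beaten by any grid normal
    expect_lte(p$rms_deviation, o$rms + 1e-12)
  }
  expect_lt(worst_angle, 2.5)        # within grid resolution of the oracle
})

test_that("torsion angles follow the standard signed convention", {
  # planar zig-zag trans chain
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                              c(1, -1, 0)), 180)
  # eclipsed cis
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                              c(1, 1, 0)), 0)
  # reversal symmetry: dihedral(p4,p3,p2,p1) == dihedral(p1,p2,p3,p4)
  for (s in 1:20) {
    set.seed(s)
    p <- matrix(rnorm(12), 4, 3)
    expect_equal(dihedral_angle(p[4, ], p[3, ], p[2, ], p[1, ]),
                 dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ]),
                 tolerance = 1e-10)
  }
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                              c(3, 1, 0)), "collinear")
})

test_that("interplanar angle folds into [0, 90] independent of orientation", {
  hx <- hexagon_xy()
  pa <- fit_plane(hx)
  expect_equal(unlist(interplanar_angle(pa, pa)),
               c(alpha_raw = 0, alpha_folded = 0))
  flipped <- pa; flipped$normal <- -pa$normal
  ang <- interplanar_angle(pa, flipped)
  expect_equal(ang$alpha_raw, 180)
  expect_equal(ang$alpha_folded, 0)
  # plane tilted by construction at 35.5 degrees about an in-plane axis
  tilted <- fit_plane(azogeom:::.rotate_about(hx, c(1, 0, 0), 35.5))
  expect_equal(interplanar_angle(pa, tilted)$alpha_folded, 35.5,
               tolerance = 1e-9)
  # fold identity is symmetric and flip-invariant
  expect_equal(interplanar_angle(tilted, pa)$alpha_folded,
               interplanar_angle(pa, tilted)$alpha_folded)
})

test_that("descriptors of ideal conformers recover the built torsions", {
  planar <- descriptor_of(build_azobenzene_residue(0, 180, 0))
  expect_equal(planar$chi_pre, 0, tolerance = 1e-9)
  expect_equal(planar$chi_azo, 180, tolerance = 1e-9)
  expect_equal(planar$chi_post, 0, tolerance = 1e-9)
  expect_equal(planar$alpha_folded, 0, tolerance = 1e-12)

  d <- descriptor_of(build_azobenzene_residue(62.9, -179.1, -28.2))
  expect_equal(c(d$chi_pre, d$chi_azo, d$chi_post),
               c(62.9, -179.1, -28.2), tolerance = 1e-6 / 62.9)
})

test_that("the ortho-selection rule reproduces symmetric planar twin twists", {
  # symmetric counter-twisted trans forms keep the ring planes parallel
  for (chi in list(c(-18.2, 180, 18.2), c(-11.2, 180, 11.2),
                   c(-11.7, 180, 11.7))) {
    d <- descriptor_of(build_azobenzene_residue(chi[1], chi[2], chi[3]))
    expect_equal(abs(d$chi_pre), abs(d$chi_post), tolerance = 1e-9)
    expect_equal(d$alpha_folded, 0, tolerance = 1e-7)
    expect_lte(abs(d$chi_pre), 90)
    expect_lte(abs(d$chi_post), 90)
  }
})

test_that("descriptors are invariant under rigid motion", {
  m <- build_azobenzene_residue(62.9, -179.1, -28.2)
  d0 <- as.data.frame(descriptor_of(m))
  for (s in 1:10) {
    set.seed(s)
    rot <- random_rotation()
    mt <- transform_model(m, rot, rnorm(3, sd = 20))
    dt <- as.data.frame(descriptor_of(mt))
    expect_lt(max(abs(dt - d0)), 1e-9)
  }
})

test_that("descriptor resolution errors name the missing atom", {
  m <- build_azobenzene_residue()
  bad_ring <- ring_spec(c("C1", "C2", "C3", "C4", "C5", "CX9"))
  expect_error(
    azo_descriptor(m, pap_sel, bad_ring, azo_nitrogens(), azo_ring2()),
    "CX9")
  expect_error(ring_spec(c("C1", "C2", "C3", "C4", "C5")), "6 unique")
  expect_error(ring_spec(rep("C1", 6)), "6 unique")
})
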
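test_that("kabsch handles identity and exact rigid-transform recovery", {
  set.seed(11)
  a <- matrix(rnorm(30, sd = 5), 10, 3)
  same <- kabsch(a, a)
  expect_equal(same$rmsd, 0, tolerance = 1e-12)
  expect_equal(same$rotation, diag(3), tolerance = 1e-9)
  expect_equal(same$n_pairs, 10)

  rot <- quat_to_mat(c(0.3, -0.5, 0.8, 0.1))
  tr <- c(4, -2, 7)
  b <- sweep(a %*% t(rot), 2, tr, "+")
  fit <- kabsch(a, b)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit$rotation, rot, tolerance = 1e-9)
  expect_equal(fit$translation, tr, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
})

test_that("kabsch rmsd is the minimum over random proper rotations", {
  set.seed(21)
  a <- matrix(rnorm(30, sd = 4), 10, 3)
  b <- a %*% t(random_rotation()) + matrix(rnorm(30, sd = 0.4), 10, 3)
  fit <- kabsch(a, b)
  a0 <- sweep(a, 2, colMeans(a)); b0 <- sweep(b, 2, colMeans(b))
  rand_best <- min(vapply(1:10000, function(i) {
    r <- random_rotation()
    sqrt(mean(rowSums((a0 %*% t(r) - b0)^2)))
  }, numeric(1)))
  expect_lte(fit$rmsd, rand_best + 1e-12)
})

test_that("kabsch agrees with a quaternion-minimisation oracle", {
  worst <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    n <- sample(6:30, 1)
    a <- matrix(rnorm(3 * n, sd = 6), n, 3)
    b <- a %*% t(random_rotation()) + matrix(rnorm(3 * n, sd = 0.5), n, 3)
    worst <- max(worst, abs(kabsch(a, b)$rmsd - quaternion_rmsd_oracle(a, b)))
  }
  expect_lt(worst, 1e-6)
})

test_that("kabsch agrees with the bio3d fitting route", {
  set.seed(5)
  a <- matrix(rnorm(60, sd = 8), 20, 3)
  b <- a %*% t(random_rotation()) + matrix(rnorm(60, sd = 0.8), 20, 3)
  ref <- bio3d::rmsd(as.vector(t(a)), as.vector(t(b)), fit = TRUE)
  expect_equal(kabsch(a, b)$rmsd, ref, tolerance = 1e-3)
})

test_that("kabsch rejects degenerate inputs", {
  expect_error(kabsch(matrix(0, 5, 3), matrix(0, 4, 3)), "pairing")
  expect_error(kabsch(matrix(0, 2, 3), matrix(0, 2, 3)), "at least 3")
  expect_error(kabsch(matrix(1, 5, 3), matrix(1, 5, 3)), "coincident")
})

test_that("kabsch rmsd is invariant under a common rigid transform", {
  set.seed(31)
  a <- matrix(rnorm(45, sd = 5), 15, 3)
  b <- a + matrix(rnorm(45, sd = 0.6), 15, 3)
  base <- kabsch(a, b)$rmsd
  rot <- random_rotation(); tr <- c(-3, 9, 2)
  again <- kabsch(sweep(a %*% t(rot), 2, tr, "+"),
                  sweep(b %*% t(rot), 2, tr, "+"))$rmsd
  expect_equal(again, base, tolerance = 1e-9)
})

test_that("range-paired C-alpha RMSD drops missing residues and is symmetric", {
  ranges <- list(c(3, 74), c(79, 227))
  pm <- poly_ala(230, chain = "A", seed = 1)
  self <- rmsd_ca_ranges(pm, pm, "A", "A", ranges)
  expect_equal(self$rmsd, 0, tolerance = 1e-12)
  expect_equal(self$n_pairs, 221)

  # chain with an unmodeled stretch 75-78 (already outside the ranges)
  # plus genuinely missing residues 100-104 within the ranges
  other <- poly_ala(230, chain = "B", seed = 2, id = "polyB")
  other$atoms <- other$atoms[!other$atoms$residue_number %in% 100:104, ]
  fit_ab <- rmsd_ca_ranges(pm, other, "A", "B", ranges)
  expect_equal(fit_ab$n_pairs, 216)
  expect_equal(attr(fit_ab, "n_dropped"), 5)
  fit_ba <- rmsd_ca_ranges(other, pm, "B", "A", ranges)
  expect_equal(fit_ab$rmsd, fit_ba$rmsd, tolerance = 1e-9)

  short <- pm
  short$atoms <- short$atoms[short$atoms$residue_number <= 2, ]
  expect_error(rmsd_ca_ranges(short, pm, "A", "A", ranges),
               "underdetermined")
})

test_that("substructure-anchored superposition transforms the whole model", {
  anchors <- lapply(c(paste0("C", 1:6), "N1"), function(nm)
    list(mobile = selector(residue_name = "PAP", atom_names = nm),
         reference = selector(residue_name = "PAP", atom_names = nm)))
  m <- build_azobenzene_residue(62.9, -179.1, -28.2)
  moved <- transform_model(m, quat_to_mat(c(1, 2, -1, 0.5)), c(10, -4, 3))
  res <- superpose_on_substructure(moved, m, anchors)
  expect_equal(res$result$rmsd, 0, tolerance = 1e-9)
  expect_lt(max(abs(coords(res$model) - coords(m))), 1e-9)

  # conformers differing only in chi_azo: anchored ring coincides,
  # the far ring diverges
  trans_form <- build_azobenzene_residue(0, 180, 0)
  cis_form <- build_azobenzene_residue(0, 0, 0)
  res2 <- superpose_on_substructure(cis_form, trans_form, anchors)
  tab <- res2$model$atoms
  ring1_err <- max(abs(coords(tab[tab$name %in% paste0("C", 1:6), ]) -
                         coords(trans_form$atoms[
                           trans_form$atoms$name %in% paste0("C", 1:6), ])))
  ring2_err <- max(abs(coords(tab[tab$name %in% paste0("C", 7:12), ]) -
                         coords(trans_form$atoms[
                           trans_form$atoms$name %in% paste0("C", 7:12), ])))
  expect_lt(ring1_err, 1e-6)
  expect_gt(ring2_err, 1)

  # permuting the anchor list leaves the transform unchanged
  res3 <- superpose_on_substructure(cis_form, trans_form,
                                    anchors[c(4, 1, 7, 2, 6, 3, 5)])
  expect_equal(res3$result$rotation, res2$result$rotation,
               tolerance = 1e-9)

  # ambiguous anchors are a cardinality error
  bad <- list(list(mobile = selector(residue_name = "PAP"),
                   reference = selector(residue_name = "PAP")),
              anchors[[1]], anchors[[2]])
  expect_error(superpose_on_substructure(cis_form, trans_form, bad),
               "cardinality")
})
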
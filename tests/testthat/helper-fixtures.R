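# shared fixtures and independent oracles

pap_sel <- selector(residue_name = "PAP")

descriptor_of <- function(model)
  azo_descriptor(model, pap_sel, azo_ring1(), azo_nitrogens(), azo_ring2())

# one-residue model from a name/coordinate table
tiny_model <- function(names, xyz, resname = "ALA", chain = "A", resno = 1L,
                       element = NULL) {
  atoms <- data.frame(
    serial = seq_along(names), name = names,
    element = if (is.null(element)) substr(gsub("[0-9]", "", names), 1, 1)
              else element,
    alt_loc = "", residue_name = resname, chain_id = chain,
    residue_number = as.integer(resno), insertion_code = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, b_factor = 0, record = "ATOM",
    stringsAsFactors = FALSE)
  structure_model(atoms, "tiny", "synthetic")
}

# poly-Ala chain with backbone atoms for range-selection and RMSD tests
poly_ala <- function(n_res = 230, chain = "A", seed = 1, id = "polyA") {
  set.seed(seed)
  atoms <- do.call(rbind, lapply(seq_len(n_res), function(i) {
    base <- c(3.8 * i, 0, 0)
    xyz <- rbind(base + c(-0.5, 0.6, 0), base, base + c(0.5, -0.6, 0.4),
                 base + c(0.6, -1.7, 0.4)) + matrix(rnorm(12, sd = 0.3), 4)
    data.frame(serial = (i - 1) * 4 + 1:4, name = c("N", "CA", "C", "O"),
               element = c("N", "C", "C", "O"), alt_loc = "",
               residue_name = "ALA", chain_id = chain,
               residue_number = i, insertion_code = "",
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               occupancy = 1, b_factor = 0, record = "ATOM",
               stringsAsFactors = FALSE)
  }))
  structure_model(atoms, id, "synthetic")
}

# random proper rotation from a uniform quaternion
quat_to_mat <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

random_rotation <- function() quat_to_mat(rnorm(4))

# independent RMSD oracle: numeric minimisation over quaternion +
# translation (never calls the Kabsch path)
quaternion_rmsd_oracle <- function(a, b) {
  obj <- function(p) {
    r <- quat_to_mat(p[1:4])
    fitted <- sweep(a %*% t(r), 2, p[5:7], "+")
    sqrt(mean(rowSums((fitted - b)^2)))
  }
  best <- Inf
  for (k in 1:8) {
    set.seed(k)
    p0 <- c(rnorm(4), colMeans(b) - colMeans(a))
    fit <- optim(p0, obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}

# brute-force plane-fit oracle: dense grid over unit normals
grid_plane_oracle <- function(xyz, step_deg = 2) {
  ctr <- colMeans(xyz)
  cen <- sweep(xyz, 2, ctr)
  th <- seq(0, 180, by = step_deg) * pi / 180
  ph <- seq(0, 358, by = step_deg) * pi / 180
  g <- expand.grid(th = th, ph = ph)
  normals <- cbind(sin(g$th) * cos(g$ph), sin(g$th) * sin(g$ph), cos(g$th))
  costs <- colMeans((cen %*% t(normals))^2)
  list(normal = normals[which.min(costs), ], rms = sqrt(min(costs)))
}

# closed-form accessible area of two intersecting solvent-extended
# spheres (radii already include the probe)
two_sphere_area <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  4 * pi * R1^2 - 2 * pi * R1 * h1 + 4 * pi * R2^2 - 2 * pi * R2 * h2
}

# regular hexagon in the z = 0 plane, counter-clockwise
hexagon_xy <- function(radius = 1.39) {
  th <- (0:5) * pi / 3
  cbind(radius * cos(th), radius * sin(th), 0)
}
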
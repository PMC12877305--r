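test_that("PDB write/read round-trips atom count, names and coordinates", {
  m <- build_azobenzene_residue(62.9, -179.1, -28.2)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, f)
  m2 <- read_structure(f)
  expect_equal(nrow(m2$atoms), nrow(m$atoms))
  expect_equal(m2$atoms$name, m$atoms$name)
  expect_equal(m2$atoms$residue_name, m$atoms$residue_name)
  expect_equal(coords(m2), coords(m), tolerance = 1e-3)

  # arbitrary 12-atom synthetic model
  set.seed(3)
  t12 <- tiny_model(paste0("C", 1:12), matrix(rnorm(36, sd = 8), 12, 3))
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(t12, f2)
  t12b <- read_structure(f2)
  expect_equal(nrow(t12b$atoms), 12)
  expect_lt(max(abs(coords(t12b) - coords(t12))), 5e-4)
})

test_that("empty model writes a file with only an END record", {
  empty <- structure_model(build_azobenzene_residue()$atoms[0, ],
                           "empty", "synthetic")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(empty, f)
  lines <- readLines(f)
  expect_true(all(grepl("^(END|HEADER|REMARK)", lines)))
})

test_that("alternate locations are retained on write and resolved on select", {
  a <- build_azobenzene_residue()$atoms
  a$alt_loc[a$name == "CB"] <- "A"
  a$occupancy[a$name == "CB"] <- 0.7
  dup <- a[a$name == "CB", ]
  dup$alt_loc <- "B"; dup$occupancy <- 0.3; dup$x <- dup$x + 0.5
  dup$serial <- max(a$serial) + 1L
  m <- structure_model(rbind(a, dup), "alt", "synthetic")

  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, f)
  recs <- grep("^(ATOM|HETATM)", readLines(f), value = TRUE)
  expect_equal(sum(substr(recs, 17, 17) %in% c("A", "B")), 2)

  m2 <- read_structure(f)
  expect_equal(nrow(m2$atoms), nrow(a) + 1)

  pick <- function(...) {
    s <- select_atoms(m2, selector(residue_name = "PAP", ...))
    s[s$name == "CB", c("alt_loc", "occupancy")]
  }
  expect_equal(pick()$alt_loc, "A")                       # highest occupancy
  expect_equal(pick(alt_loc = "first")$alt_loc, "A")
  expect_equal(pick(alt_loc = "specific", alt_id = "B")$alt_loc, "B")

  # occupancy tie breaks alphabetically
  m3 <- m
  m3$atoms$occupancy[m3$atoms$name == "CB"] <- 0.5
  s3 <- select_atoms(m3, selector(residue_name = "PAP"))
  expect_equal(s3$alt_loc[s3$name == "CB"], "A")
})

test_that("multi-interval range selection counts and composes correctly", {
  pm <- poly_ala(230)
  sel <- selector(chain = "A", ranges = list(c(3, 74), c(79, 227)),
                  atom_names = "CA")
  got <- select_atoms(pm, sel)
  expect_equal(nrow(got), 221)           # 72 + 149
  # idempotent and equal to the union of per-interval selections
  expect_identical(got, select_atoms(pm, sel))
  part1 <- select_atoms(pm, selector("A", c(3, 74), atom_names = "CA"))
  part2 <- select_atoms(pm, selector("A", c(79, 227), atom_names = "CA"))
  expect_equal(got$residue_number,
               c(part1$residue_number, part2$residue_number))
  expect_false(anyDuplicated(got$serial) > 0)
})

test_that("residue-name selection returns exactly the switch residue", {
  tc <- build_toy_complex()
  got <- select_atoms(tc, selector(residue_name = "PAP"))
  man <- attr(tc, "manifest")
  expect_equal(unique(got$residue_number), man$guest_residue)
  expect_equal(nrow(got), 19)
  expect_setequal(got$name, c("N", "CA", "C", "O", "CB",
                              paste0("C", 1:12), "N1", "N2"))
})

test_that("selectors matching nothing yield empty results or a clear error", {
  tc <- build_toy_complex()
  expect_equal(nrow(select_atoms(tc, selector(chain = "Z"))), 0)
  expect_error(select_atoms(tc, selector(chain = "Z"),
                            require_nonempty = TRUE), "no atoms")
})

test_that("malformed and unknown inputs raise informative errors", {
  f <- withr::local_tempfile(fileext = ".pdb")
  ok <- build_azobenzene_residue()
  write_pdb(ok, f)
  lines <- readLines(f)
  bad_at <- grep("^HETATM", lines)[3]
  substr(lines[bad_at], 31, 38) <- "  xx.xxx"
  fbad <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, fbad)
  expect_error(read_structure(fbad), paste0("line ", bad_at))

  fx <- withr::local_tempfile(fileext = ".xyz")
  writeLines("3", fx)
  expect_error(read_structure(fx), "format")
  expect_error(read_structure("/nonexistent/file.pdb"), "not found")

  # coordinate overflow of the fixed-width field
  big <- ok
  big$atoms$x[1] <- 123456.0
  expect_error(write_pdb(big, withr::local_tempfile(fileext = ".pdb")),
               "overflow")
})

test_that("a minimal mmCIF atom_site loop maps onto the same model", {
  cif <- c(
    "data_test", "loop_", "_atom_site.group_PDB", "_atom_site.id",
    "_atom_site.type_symbol", "_atom_site.label_atom_id",
    "_atom_site.label_alt_id", "_atom_site.label_comp_id",
    "_atom_site.label_asym_id", "_atom_site.label_entity_id",
    "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . ALA A 1 1 ? 1.000 2.000 3.000 1.00 10.00 ? 7 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 2.000 2.500 3.000 1.00 10.00 ? 7 ALA A CA 1")
  fc <- withr::local_tempfile(fileext = ".cif")
  writeLines(cif, fc)
  mc <- read_structure(fc)
  expect_equal(mc$source_format, "mmcif")
  expect_equal(nrow(mc$atoms), 2)
  expect_equal(mc$atoms$name, c("N", "CA"))
  expect_equal(mc$atoms$residue_number, c(7L, 7L))
  expect_equal(coords(mc)[, "x"], c(1, 2))
})
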
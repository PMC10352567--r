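# Composition grammar, residue-mass chemistry, and the theoretical
# light/heavy library.

test_that("composition parsing round-trips and rejects bad input", {
  comp <- parse_composition(c("H4N4F1", "H5N4Ge2Ac1"))
  expect_equal(comp$H, c(4L, 5L))
  expect_equal(comp$N, c(4L, 4L))
  expect_equal(comp$F, c(1L, 0L))
  expect_equal(comp$Ge, c(0L, 2L))
  expect_equal(comp$Ac, c(0L, 1L))
  expect_equal(comp$name, c("H4N4F1", "H5N4Ge2Ac1"))

  # round trip on random compositions and on the whole default panel
  for (name in c(random_compositions(25), default_panel())) {
    expect_identical(parse_composition(name)$name, name)
  }

  expect_error(parse_composition("H1X1"), "unknown symbol at position 3")
  expect_error(parse_composition("H4N"), "missing count")
  expect_error(parse_composition("H2N2Ac1"), "Ac count .* exceeds")
  expect_error(parse_composition("H2H3"), "repeated")
  expect_error(parse_composition(""), "empty")
})

test_that("residue mass table satisfies the derivatization chemistry", {
  m <- monosaccharide_masses()
  mass <- function(s) m$mass[m$symbol == s]
  expect_true(all(m$mass > 0))
  # Neu5Gc differs from Neu5Ac by one oxygen in both derivatized forms
  expect_equal(mass("Ge") - mass("E"), 15.9949146, tolerance = 1e-6)
  expect_equal(mass("Gl") - mass("L"), 15.9949146, tolerance = 1e-6)
  # ethyl ester vs lactone differ by C2H4 + H2O
  expect_equal(mass("E") - mass("L"), 46.0418648, tolerance = 1e-6)
  expect_equal(mass("Ge") - mass("Gl"), 46.0418648, tolerance = 1e-6)
})

test_that("neutral mass is the additive residue sum plus one water", {
  # zero-residue edge case: water only
  empty <- parse_composition("H2N2")[0, ]
  expect_equal(nrow(empty), 0)
  # hand-summed oracle for H4N4F1:
  # 4 x 162.052823 + 4 x 203.079373 + 146.057909 + 18.010565
  expect_equal(neutral_mass("H4N4F1"), 1624.5973, tolerance = 1e-4)
  # additivity: mass(A) + mass(B) - water = mass(A + B), over random pairs
  water <- 18.0105647
  a <- parse_composition(random_compositions(10, seed = 2))
  b <- parse_composition(random_compositions(10, seed = 3))
  ab <- a
  for (s in c("H", "N", "F", "E", "L", "Ge", "Gl", "Ac")) {
    ab[[s]] <- a[[s]] + b[[s]]
  }
  ab$name <- composition_name(ab)
  expect_equal(neutral_mass(a) + neutral_mass(b) - water, neutral_mass(ab),
               tolerance = 1e-9)
  # strictly increasing in every count
  base <- neutral_mass("H3N2")
  for (extra in c("H4N2", "H3N3", "H3N2F1", "H3N2E1", "H3N2L1",
                  "H3N2Ge1", "H3N2Gl1", "H3N2E1Ac1")) {
    expect_gt(neutral_mass(extra), base)
  }
})

test_that("sodiated m/z reproduces the printed calibrants within 5 ppm", {
  printed <- c(H4N4F1 = 1647.5865, H4N4Ge1 = 1836.65066,
               H5N4F1Ge2 = 2479.88342, H5N4Ge1 = 1998.70346,
               H5N4Ge1Gl1 = 2287.77848, H5N4Ge2 = 2333.82552,
               H5N4Ge2Gl1 = 2622.90054)
  calc <- sodiated_mz(names(printed))
  ppm <- abs(calc - printed) / printed * 1e6
  expect_true(all(ppm < 5))
  # the lactone-containing calibrants carry the known ~2 ppm discrepancy
  expect_lt(max(ppm[c(1:4, 6)]), 1)
  # water + Na+ for the empty-composition limit
  comp0 <- parse_composition("H2N2")
  comp0[c("H", "N")] <- 0L
  comp0$name <- ""
  expect_equal(sodiated_mz(comp0), 41.0, tolerance = 5e-4)
})

test_that("the heavy internal-standard shift is one H plus one D", {
  panel <- default_panel()
  shift <- internal_standard_mz(panel) - sodiated_mz(panel)
  expect_equal(shift, rep(3.0219268, length(panel)), tolerance = 1e-6)
  expect_equal(unique(round(shift)), 3)
  expect_equal(internal_standard_mz("H4N4F1"), 1650.6084, tolerance = 1e-3)
})

test_that("structure classification follows the composition rules", {
  cls <- classify_structure(c("H5N2", "H9N2", "H5N4Ge2", "H6N5Ge1Gl2",
                              "H5N3Ge1", "H3N4F1", "H3N2", "H4N3"))
  expect_equal(cls$class, c("high_mannose", "high_mannose", "complex",
                            "complex", "hybrid", "complex", "other",
                            "complex"))
  expect_equal(cls$antennae, c(0L, 0L, 2L, 3L, 1L, 2L, 0L, 1L))
  # biantennary disialylated: 2 galactoses, not branched
  bi <- cls[cls$name == "H5N4Ge2", ]
  expect_equal(bi$galactoses, 2L)
  expect_equal(bi$sialic, 2L)
  expect_false(bi$branched)
  # triantennary trisialylated: not branched either
  tri <- cls[cls$name == "H6N5Ge1Gl2", ]
  expect_equal(tri$sialic, 3L)
  expect_equal(tri$sialic_23, 2L)
  expect_equal(tri$sialic_26, 1L)
  expect_false(tri$branched)
  # disialylated antenna on a monoantennary glycan is branched
  expect_true(classify_structure("H4N3Ge2")$branched)
  # every random composition gets exactly one class
  all_cls <- classify_structure(random_compositions(40, seed = 5))
  expect_true(all(all_cls$class %in%
                    c("high_mannose", "hybrid", "complex", "other")))
  expect_equal(all_cls$sialic,
               all_cls$sialic_23 + all_cls$sialic_26)
  expect_error(classify_structure("H3N1"), "HexNAc count < 2")
})

test_that("the library is sorted, collision-free, and windowed", {
  lib <- build_library(calibrant_panel(), tol_ppm = 10)
  expect_equal(nrow(lib), 7)
  expect_equal(nrow(attr(lib, "collisions")), 0)
  expect_false(is.unsorted(lib$light_mz))
  expect_error(build_library(c("H5N4", "H5N4")), "duplicate")

  lib1 <- build_library("H5N4")
  expect_equal(nrow(lib1), 1)
  expect_equal(nrow(attr(lib1, "collisions")), 0)

  full <- build_library()
  expect_equal(full$heavy_mz - full$light_mz,
               rep(3.0219268, nrow(full)), tolerance = 1e-6)
  expect_true(all(full$light_mz >= 700 & full$heavy_mz <= 3500))
  # small glycans fall below the acquisition window and are excluded
  expect_warning(small <- build_library(c("H1N2", "H5N4")), "window")
  expect_equal(small$name, "H5N4")
  # exact isobars are reported: fucose+Ge weighs the same as hexose+E
  expect_warning(col <- build_library(c("H5N4F1Ge1", "H6N4E1"), tol_ppm = 10),
                 regexp = NA)
  expect_gt(nrow(attr(col, "collisions")), 0)
})

test_that("panel files and library exports round-trip", {
  panel_file <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# serum panel", "H5N4Ge2", "", "H4N4F1  # calibrant"),
             panel_file)
  expect_equal(read_panel(panel_file), c("H5N4Ge2", "H4N4F1"))

  lib <- build_library(calibrant_panel())
  out <- withr::local_tempfile(fileext = ".tsv")
  export_library(lib, out)
  back <- readr::read_tsv(out, show_col_types = FALSE)
  expect_equal(back$name, lib$name)
  expect_equal(back$light_mz, lib$light_mz)
  expect_equal(glance(lib)$n_glycans, 7)
})
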
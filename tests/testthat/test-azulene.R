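test_that("mirror permutation and canonicalization behave", {
  expect_equal(mirror_image(integer()), integer())
  expect_equal(mirror_image(c(2L, 5L, 7L)), c(2L, 5L, 7L))
  expect_equal(mirror_image(1L), 3L)
  expect_error(mirror_image(9L))
  # involution on all singletons and random subsets
  set.seed(1)
  for (i in 1:30) {
    p <- sort(sample(1:8, sample.int(8L, 1L)))
    expect_equal(mirror_image(mirror_image(p)), p)
    cp <- canonical_pattern(p)
    expect_equal(canonical_pattern(cp), cp)
  }
})

test_that("enumeration yields 144 orbits matching brute force and Burnside", {
  pats <- enumerate_core_patterns()
  expect_length(pats, 144L)
  expect_equal((2^8 + 2^5) / 2, 144)
  # independent brute force: orbit representatives of the 256 subsets
  seen <- character(0)
  orbit_sizes <- integer(0)
  for (mask in 0:255) {
    pos <- which(bitwAnd(mask, bitwShiftL(1L, 0:7)) != 0L)
    key <- pattern_key(canonical_pattern(pos))
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      orbit_sizes <- c(orbit_sizes,
                       if (identical(sort(pos), mirror_image(pos))) 1L else 2L)
    }
  }
  expect_length(seen, 144L)
  expect_setequal(vapply(pats, pattern_key, character(1)), seen)
  expect_true(all(orbit_sizes %in% c(1L, 2L)))
  expect_equal(sum(orbit_sizes), 256L)
  # exactly one nitrogen-free pattern and five single-nitrogen orbits
  sizes <- vapply(pats, length, integer(1))
  expect_equal(sum(sizes == 0L), 1L)
  expect_equal(sum(sizes == 1L), 5L)
})

test_that("patterns build valid molecules; distinct patterns are distinct", {
  expect_identical(pattern_to_molecule(integer())$smiles,
                   chem_canonical(AZULENE))
  core <- pattern_to_molecule(c(2L, 5L, 7L))
  expect_false(core$kekule_fallback)
  expect_equal(unname(structural_counts(core$smiles)["total_atoms"]), 15)
  # molecule-level dedup of some canonical patterns agrees with pattern identity
  pats <- enumerate_core_patterns()[1:40]
  smi <- vapply(pats, function(p) pattern_to_molecule(p)$smiles, character(1))
  expect_false(anyDuplicated(smi) > 0)
})

test_that("azulene-likeness is the conjugated C/N 5-7 bicycle", {
  expect_true(is_azulene_like(AZULENE))
  expect_false(is_azulene_like(NAPHTHALENE))
  expect_true(is_azulene_like(triaza_core()))
  expect_false(is_azulene_like("C1CCC2CCCCC2CC1"))       # saturated 5-7
  expect_false(is_azulene_like("C1=CC2=CC=CC2=C1"))      # pentalene
  expect_false(is_azulene_like("C1=CC2=CC=CC=C2C=C1"))   # heptalene
  expect_false(is_azulene_like("O1C=CC2=CC=CC=CC12"))    # oxygen in ring
  sub <- attach_identical_substituents(c(2L, 5L, 7L), "C#N", c(1L, 6L))
  expect_true(is_azulene_like(sub))
})

test_that("identical substituent attachment respects symmetry and valence", {
  # 4,8-diamino on the symmetric 2,5,7 core: mirror-image assembly gives the
  # identical canonical structure (plane of symmetry through the core)
  s <- attach_identical_substituents(c(2L, 5L, 7L), "N", c(4L, 8L))
  mirrored <- attach_identical_substituents(mirror_image(c(2L, 5L, 7L)), "N",
                                            c(4L, 8L))
  expect_identical(s, mirrored)
  expect_true(is_azulene_like(s))
  # position occupied by nitrogen is rejected
  expect_error(attach_identical_substituents(c(1L, 5L, 7L), "N", c(1L, 6L)),
               "nitrogen")
  # substituent with no free valence is rejected
  expect_error(attach_identical_substituents(c(2L, 5L, 7L), "N(=O)=O",
                                             c(4L, 8L)))
  # only the two supported position pairs exist
  expect_error(attach_identical_substituents(c(2L, 5L, 7L), "N", c(2L, 7L)))
})

test_that("substitution modes validate their cores", {
  m <- substitution_mode("symmetric_4_8_fixed_core")
  expect_equal(m$core_pattern, c(2L, 5L, 7L))
  expect_equal(m$attach_positions, c(4L, 8L))
  expect_error(substitution_mode("symmetric_4_8_fixed_core",
                                 core_pattern = c(1L, 5L)))
  expect_error(substitution_mode("identical_1_6", core_pattern = c(1L, 2L)))
  expect_null(substitution_mode("free")$attach_positions)
})

test_that("core library file lists all 144 cores", {
  tmp <- tempfile(fileext = ".smi")
  df <- write_core_library(tmp)
  expect_equal(nrow(df), 144L)
  expect_equal(length(unique(df$smiles)), 144L)
  lines <- readLines(tmp)
  expect_length(lines, 144L)
  expect_true(any(grepl("aza-2,5,7", lines)))
})
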
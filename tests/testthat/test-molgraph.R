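test_that("formula parsing returns exact counts and round-trips Hill order", {
  fc <- parse_formula("C19H11F4NO2")
  expect_equal(unclass(fc)[c("C", "H", "F", "N", "O")],
               c(C = 19L, H = 11L, F = 4L, N = 1L, O = 2L))
  expect_equal(unclass(parse_formula("H2O")), c(H = 2L, O = 1L))
  expect_equal(unclass(parse_formula("C")), c(C = 1L))
  # round-trip on canonical Hill strings
  for (s in c("C19H11F4NO2", "C6H6", "CH4O", "H2O"))
    expect_identical(format_formula(parse_formula(s)), s)
  expect_error(parse_formula("C19Xx2"), "Xx")
  expect_error(parse_formula(""), "empty")
})

test_that("V2000 molfile reading recovers declared structure", {
  benz <- fixture_mol("benzene.mol")
  expect_equal(nrow(benz$atoms), 6)
  expect_equal(nrow(benz$bonds), 6)
  expect_true(all(benz$atoms$element == "C"))

  nsc <- fixture_mol()
  expect_equal(nrow(nsc$atoms), 26)  # heavy atoms = C19 + F4 + N1 + O2
  expect_equal(nrow(nsc$bonds), 28)

  # count mismatch -> format error with a line reference
  lines <- readLines(system.file("extdata", "benzene.mol",
                                 package = "screenkit"))
  lines[4] <- sub("  6  6", "  7  6", lines[4])
  expect_error(read_molfile(paste(lines, collapse = "\n")), "line")
  expect_error(read_molfile(c("x", "y", "z", "  0  0  0 V3000")), "V3000")
})

test_that("implicit hydrogen assignment follows default valences", {
  benz <- fixture_mol("benzene.mol")
  expect_true(all(benz$atoms$implicit_h == 1))

  # carbonyl carbon with three heavy neighbours gets no H
  amide <- molgraph(
    data.frame(element = c("C", "O", "C", "N")),
    data.frame(a = c(1, 1, 1), b = c(2, 3, 4), order = c(2, 1, 1)))
  amide <- assign_implicit_h(amide)
  expect_equal(amide$atoms$implicit_h[1], 0L)

  # total implicit H of the structure fixture matches its printed formula
  nsc <- fixture_mol()
  expect_equal(sum(nsc$atoms$implicit_h),
               unname(unclass(parse_formula("C19H11F4NO2"))["H"]))
})

test_that("ring perception flags exactly the cyclic atoms and bonds", {
  benz <- fixture_mol("benzene.mol")
  expect_true(all(benz$atoms$in_ring))
  expect_true(all(benz$bonds$in_ring))

  # biphenyl: the inter-ring single bond is acyclic
  atoms <- data.frame(element = rep("C", 12))
  ring <- function(off) data.frame(a = off + 1:6, b = off + c(2:6, 1),
                                   order = c(2, 1, 2, 1, 2, 1))
  bonds <- rbind(ring(0), ring(6), data.frame(a = 1, b = 7, order = 1))
  bip <- perceive_rings(assign_implicit_h(molgraph(atoms, bonds)))
  expect_true(all(bip$atoms$in_ring))
  expect_false(bip$bonds$in_ring[13])
  expect_equal(sum(bip$bonds$in_ring), 12)

  hexane <- molgraph(data.frame(element = rep("C", 6)),
                     data.frame(a = 1:5, b = 2:6, order = 1))
  hexane <- perceive_rings(hexane)
  expect_false(any(hexane$atoms$in_ring))
})

test_that("ring perception is invariant under atom relabeling", {
  # naphthalene-like fused bicyclic, permuted labels
  atoms <- data.frame(element = rep("C", 10))
  bonds <- data.frame(
    a = c(1, 2, 3, 4, 5, 6, 6, 7, 8, 9, 10),
    b = c(2, 3, 4, 5, 6, 1, 7, 8, 9, 10, 1),
    order = 1)
  base <- perceive_rings(molgraph(atoms, bonds))
  ring_pairs <- function(m) {
    d <- m$bonds[m$bonds$in_ring, ]
    sort(paste(pmin(d$a, d$b), pmax(d$a, d$b)))
  }
  set.seed(11)
  for (rep in 1:5) {
    perm <- sample(10)
    pb <- data.frame(a = perm[bonds$a], b = perm[bonds$b], order = 1)
    m2 <- perceive_rings(molgraph(atoms, pb))
    d <- m2$bonds[m2$bonds$in_ring, ]
    back <- sort(paste(pmin(match(d$a, perm), match(d$b, perm)),
                       pmax(match(d$a, perm), match(d$b, perm))))
    expect_identical(back, ring_pairs(base))
  }
})

test_that("benzenoid aromaticity is perceived, aliphatics left alone", {
  expect_equal(sum(fixture_mol("benzene.mol")$atoms$aromatic), 6)
  cyclohexane <- molgraph(data.frame(element = rep("C", 6)),
                          data.frame(a = 1:6, b = c(2:6, 1), order = 1))
  cyclohexane <- perceive_aromatic(perceive_rings(cyclohexane))
  expect_equal(sum(cyclohexane$atoms$aromatic), 0)
  # three benzenoid rings in the study compound
  expect_equal(sum(fixture_mol()$atoms$aromatic), 18)
})

test_that("graph construction rejects malformed bonds", {
  atoms <- data.frame(element = c("C", "C"))
  expect_error(molgraph(atoms, data.frame(a = 1, b = 1, order = 1)), "self")
  expect_error(molgraph(atoms, data.frame(a = c(1, 2), b = c(2, 1), order = 1)),
               "duplicate")
  expect_error(molgraph(atoms, data.frame(a = 1, b = 3, order = 1)), "range")
})
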
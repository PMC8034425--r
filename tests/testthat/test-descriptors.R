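# small helper molecules built in code
mol_water <- function() assign_implicit_h(molgraph(data.frame(element = "O")))
mol_phenol <- function() {
  atoms <- data.frame(element = c(rep("C", 6), "O"))
  bonds <- rbind(data.frame(a = 1:6, b = c(2:6, 1), order = c(2, 1, 2, 1, 2, 1)),
                 data.frame(a = 1, b = 7, order = 1))
  perceive_aromatic(perceive_rings(assign_implicit_h(molgraph(atoms, bonds))))
}
mol_toluene <- function() {
  atoms <- data.frame(element = rep("C", 7))
  bonds <- rbind(data.frame(a = 1:6, b = c(2:6, 1), order = c(2, 1, 2, 1, 2, 1)),
                 data.frame(a = 1, b = 7, order = 1))
  perceive_aromatic(perceive_rings(assign_implicit_h(molgraph(atoms, bonds))))
}

test_that("molecular weight matches hand sums and the printed value", {
  expect_equal(molecular_weight(parse_formula("C19H11F4NO2")), 361.29)
  expect_equal(molecular_weight(parse_formula("H2O")), 18.02)  # 2x1.008+15.999
  expect_equal(molecular_weight(integer(0)), 0)
  expect_error(molecular_weight(c(Zz = 1)), "Zz")
})

test_that("molecular weight is additive over formula sums", {
  a <- parse_formula("C6H6"); b <- parse_formula("H2O")
  ab <- c(C = 6L, H = 8L, O = 1L)
  expect_equal(molecular_weight(ab),
               molecular_weight(a) + molecular_weight(b), tolerance = 0.011)
})

test_that("H-bond donor and acceptor counts follow the N+O convention", {
  nsc <- fixture_mol()
  expect_equal(count_hbd(nsc), 2)  # phenolic O-H + amide N-H
  expect_equal(count_hba(nsc), 3)  # 1 N + 2 O; the four F excluded
  expect_equal(count_hbd(fixture_mol("benzene.mol")), 0)
  expect_equal(count_hba(fixture_mol("benzene.mol")), 0)
  expect_equal(count_hbd(mol_water()), 2)
  # formamide: N + O
  fam <- molgraph(data.frame(element = c("C", "O", "N")),
                  data.frame(a = c(1, 1), b = c(2, 3), order = c(2, 1)))
  expect_equal(count_hba(assign_implicit_h(fam)), 2)
  # donors never exceed total implicit H on heteroatoms
  for (m in list(nsc, mol_phenol(), mol_water()))
    expect_lte(count_hbd(m),
               sum(m$atoms$implicit_h[m$atoms$element %in% c("N", "O", "S")]))
})

test_that("TPSA sums the packaged fragment contributions", {
  expect_equal(tpsa(fixture_mol()), 49.33)  # 20.23 + 17.07 + 12.03
  expect_equal(tpsa(fixture_mol("benzene.mol")), 0)
  expect_equal(tpsa(mol_phenol()), 20.23)
  # pyridine N (aromatic) and nitrile N classes
  pyridine <- molgraph(data.frame(element = c(rep("C", 5), "N")),
                       data.frame(a = 1:6, b = c(2:6, 1),
                                  order = c(2, 1, 2, 1, 2, 1)))
  pyridine <- perceive_aromatic(perceive_rings(assign_implicit_h(pyridine)))
  expect_equal(tpsa(pyridine), 12.89)
  nitrile <- molgraph(data.frame(element = c("C", "C", "N")),
                      data.frame(a = c(1, 2), b = c(2, 3), order = c(1, 3)))
  expect_equal(tpsa(assign_implicit_h(nitrile)), 23.79)
  # additive over disconnected components: two separate phenols
  ring <- function(off) data.frame(a = off + 1:6, b = off + c(2:6, 1),
                                   order = c(2, 1, 2, 1, 2, 1))
  two <- molgraph(data.frame(element = c(rep("C", 6), "O", rep("C", 6), "O")),
                  rbind(ring(0), data.frame(a = 1, b = 7, order = 1),
                        ring(7), data.frame(a = 8, b = 14, order = 1)))
  two <- perceive_aromatic(perceive_rings(assign_implicit_h(two)))
  expect_equal(tpsa(two), 2 * 20.23)
})

test_that("unclassifiable polar atoms are an error, never silently zero", {
  # cationic N with one single and one triple bond has no fragment class
  odd <- molgraph(data.frame(element = c("N", "C", "C"), charge = c(1, 0, 0)),
                  data.frame(a = c(1, 1), b = c(2, 3), order = c(1, 3)))
  expect_error(tpsa(assign_implicit_h(odd)), "fragment class")
})

test_that("fraction Csp3 counts single-bonded non-aromatic carbons", {
  expect_equal(fraction_csp3(fixture_mol()), 0)
  cyclohexane <- perceive_aromatic(perceive_rings(assign_implicit_h(
    molgraph(data.frame(element = rep("C", 6)),
             data.frame(a = 1:6, b = c(2:6, 1), order = 1)))))
  expect_equal(fraction_csp3(cyclohexane), 1)
  expect_equal(fraction_csp3(mol_toluene()), 1 / 7)
  expect_equal(fraction_csp3(mol_water()), 0)  # no carbons
})

test_that("rotatable bonds are acyclic single bonds between non-terminal atoms", {
  expect_equal(rotatable_bonds(fixture_mol()), 4)
  ethane <- molgraph(data.frame(element = c("C", "C")),
                     data.frame(a = 1, b = 2, order = 1))
  expect_equal(rotatable_bonds(perceive_rings(ethane)), 0)
  butane <- molgraph(data.frame(element = rep("C", 4)),
                     data.frame(a = 1:3, b = 2:4, order = 1))
  expect_equal(rotatable_bonds(perceive_rings(butane)), 1)
})

test_that("Lipinski verdict collects violations and degrades without inputs", {
  ok <- lipinski(361.29, 2, 3, logp = 4.8679, molar_refractivity = 87.77)
  expect_true(ok$pass)
  expect_length(ok$violations, 0)

  bad <- lipinski(600, 6, 11, logp = 6, molar_refractivity = 150)
  expect_false(bad$pass)
  expect_length(bad$violations, 5)

  expect_message(part <- lipinski(361.29, 2, 3), "skipped")
  expect_true(part$pass)
  expect_length(part$skipped, 2)
})

test_that("descriptor_set reproduces the full printed descriptor row", {
  d <- descriptor_set(fixture_mol(), logp = 4.867901,
                      molar_refractivity = 87.77)
  expect_equal(d$formula, "C19H11F4NO2")
  expect_equal(d$mw, 361.29)
  expect_equal(d$n_hbd, 2)
  expect_equal(d$n_hba, 3)
  expect_equal(d$tpsa, 49.33)
  expect_equal(d$frac_csp3, 0)
  expect_equal(d$n_rotatable, 4)
  expect_true(d$lipinski_pass)
})
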
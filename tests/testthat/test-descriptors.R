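test_that("molecular weight sums standard atomic masses with implicit H", {
  expect_equal(molecular_weight(parse_smiles("c1ccccc1")),
               6 * 12.01 + 6 * 1.01, tolerance = 0.01)
  expect_equal(molecular_weight(parse_smiles("C")), 12.01 + 4 * 1.01,
               tolerance = 0.01)
  expect_error(molecular_weight(structure(list(), class = "molgraph")))
})

test_that("Wiener index equals half-sum of brute-force shortest paths", {
  expect_identical(wiener_index(parse_smiles("CC")), 1L)
  expect_equal(wiener_index(parse_smiles("CCCC")), 10)
  expect_equal(wiener_index(parse_smiles("C1CC1")), 3)
  for (g in fixture_graphs()) {
    expect_equal(wiener_index(g), wiener_oracle(g))
  }
})

test_that("Randic index matches direct edge enumeration", {
  expect_equal(randic_index(parse_smiles("CC")), 1.0)
  expect_equal(randic_index(parse_smiles("CCCC")), 2 / sqrt(2) + 1 / 2,
               tolerance = 1e-12)
  expect_equal(randic_index(parse_smiles("CC(C)C")), 3 / sqrt(3), tolerance = 1e-12)
  expect_error(randic_index(parse_smiles("C")), "single-atom")
})

test_that("chi indices equal exhaustive subgraph enumeration on all fixtures", {
  kinds <- c("path", "cluster", "path-cluster")
  for (g in fixture_graphs()) {
    for (m in 0:4) for (kind in kinds) for (val in c(FALSE, TRUE)) {
      expect_equal(chi_index(g, m, kind, valence = val),
                   chi_oracle(g, m, kind, valence = val),
                   tolerance = 1e-12,
                   label = sprintf("chi m=%d kind=%s val=%s", m, kind, val))
    }
  }
})

test_that("chi anchor values: butane paths, star clusters", {
  but <- parse_smiles("CCCC")
  expect_equal(chi_index(but, 2, "path"), 1 / sqrt(4) + 1 / sqrt(4), tolerance = 1e-12)
  expect_equal(chi_index(but, 3, "cluster"), 0)
  expect_equal(chi_index(parse_smiles("CC(C)C"), 3, "cluster"), 1 / sqrt(3),
               tolerance = 1e-12)
})

test_that("kappa indices follow the Kier formulas with closed-form path counts", {
  but <- parse_smiles("CCCC")
  expect_equal(unname(kappa_indices(but)["kappa1"]), 4)
  # A-atom path graph has kappa1 = A exactly
  for (A in 3:8) {
    path <- parse_smiles(paste(rep("C", A), collapse = ""))
    expect_equal(unname(kappa_indices(path)["kappa1"]), A)
  }
  # alpha correction is the identity for all-sp3-carbon skeletons
  expect_equal(unname(kappa_indices(but, TRUE)), unname(kappa_indices(but)),
               tolerance = 1e-12)
  for (g in fixture_graphs()) {
    if (n_atoms(g) < 4) next
    expect_equal(unname(kappa_indices(g)), kappa_oracle(g), tolerance = 1e-10)
    expect_equal(unname(kappa_indices(g, TRUE)), kappa_oracle(g, TRUE),
                 tolerance = 1e-10)
  }
  expect_error(kappa_indices(parse_smiles("CC")), "at least 3")
})

test_that("flexibility phi is positive and drops from hexane to cyclohexane", {
  pent <- parse_smiles("CCCCC")
  k <- kappa_indices(pent, alpha_corrected = TRUE)
  expect_equal(flexibility_phi(pent), unname(k["kappa1a"] * k["kappa2a"]) / 5,
               tolerance = 1e-12)
  for (g in fixture_graphs(c("propane", "hexane", "benzene", "phenol"))) {
    expect_gt(flexibility_phi(g), 0)
  }
  expect_gt(flexibility_phi(parse_smiles("CCCCCC")),
            flexibility_phi(parse_smiles("C1CCCCC1")))
})

test_that("Balaban J matches the distance-matrix oracle", {
  expect_equal(balaban_index(parse_smiles("CC")), 1.0)
  expect_equal(balaban_index(parse_smiles("CCCC")), 1.9747, tolerance = 1e-4)
  for (g in fixture_graphs()) {
    expect_equal(balaban_index(g), balaban_oracle(g), tolerance = 1e-12)
  }
})

test_that("E-state indices follow the Kier-Hall perturbation form", {
  eth <- parse_smiles("CC")
  es <- estate_indices(eth)
  # two identical CH3 carbons: S = I with zero net perturbation
  I_ch3 <- ((2 / 2)^2 * (4 - 3) + 1) / 1
  expect_equal(es$S, rep(I_ch3, 2), tolerance = 1e-12)
  # perturbations are antisymmetric: molecular sum equals sum of intrinsics
  for (g in fixture_graphs(c("phenol", "benzonitrile", "anhydride"))) {
    dv <- qsartox:::.valence_deltas(g)
    L <- qsartox:::.element_info(g$atoms$element)$L
    delta <- pmax(tabulate(c(g$bonds$i, g$bonds$j), n_atoms(g)), 1)
    I <- ((2 / L)^2 * dv + 1) / delta
    expect_equal(estate_indices(g)$total, sum(I), tolerance = 1e-10)
  }
  # nitrile N is electron-rich: higher S than any ring carbon
  bn <- parse_smiles("N#Cc1ccccc1")
  es <- estate_indices(bn)$S
  expect_true(es[bn$atoms$element == "N"] > max(es[bn$atoms$element == "C"]))
})

test_that("atom and group counts match hand enumeration", {
  tcp <- atom_and_group_counts(parse_smiles("Oc1c(Cl)cc(Cl)cc1Cl"))
  expect_equal(unname(tcp["NHal"]), 3L)
  expect_equal(unname(tcp["n_hydroxyl"]), 1L)
  bz <- atom_and_group_counts(parse_smiles("c1ccccc1"))
  expect_true(all(bz[c("n_O", "n_N", "NHal", "n_hetero", "n_hydroxyl", "n_amino",
                       "n_nitro", "n_cyano", "n_methyl")] == 0L))
  pna <- atom_and_group_counts(parse_smiles("Nc1ccc(cc1)[N+](=O)[O-]"))
  expect_equal(unname(pna["n_nitro"]), 1L)
  expect_equal(unname(pna["n_amino"]), 1L)
  expect_equal(unname(pna["n_N"]), 2L)
  # both nitro dialects match
  expect_equal(unname(atom_and_group_counts(parse_smiles("CN(=O)=O"))["n_nitro"]), 1L)
  expect_equal(unname(atom_and_group_counts(parse_smiles("CC(=O)OC(=O)C"))["n_anhydride"]), 1L)
  expect_equal(unname(atom_and_group_counts(parse_smiles("O=Cc1ccccc1"))["n_aldehyde"]), 1L)
  expect_equal(unname(atom_and_group_counts(parse_smiles("N#Cc1ccccc1"))["n_cyano"]), 1L)
  expect_equal(unname(atom_and_group_counts(parse_smiles("CC(C)C"))["n_methyl"]), 3L)
})

test_that("hydrogen-bond counts follow the heavy-atom convention", {
  expect_equal(unname(hbond_counts(parse_smiles("c1ccccc1O"))), c(1L, 1L))
  expect_equal(unname(hbond_counts(parse_smiles("Nc1ccccc1"))["NHdon"]), 1L)
  expect_equal(unname(hbond_counts(parse_smiles("c1ccccc1"))), c(0L, 0L))
  # pyrrole-type N-H is a donor but not an acceptor
  pyrrole <- hbond_counts(parse_smiles("c1cc[nH]c1"))
  expect_equal(unname(pyrrole["NHdon"]), 1L)
  expect_equal(unname(pyrrole["NHacc"]), 0L)
  # amide N excluded from acceptors
  acet <- hbond_counts(parse_smiles("CC(=O)N"))
  expect_equal(unname(acet["NHacc"]), 1L)  # only the carbonyl O
})

test_that("all topological descriptors are invariant under atom relabelling", {
  set.seed(11)
  for (nm in c("isobutane", "cyclohexane", "phenol", "nitroaniline", "anhydride")) {
    g <- parse_smiles(FIXTURE_SMILES[[nm]])
    row0 <- qsartox:::.descriptor_row(g)
    for (r in 1:3) {
      gp <- permute_molgraph(g, sample(n_atoms(g)))
      expect_equal(qsartox:::.descriptor_row(gp), row0, tolerance = 1e-12,
                   label = paste("permuted", nm))
    }
  }
})

test_that("descriptor block assembles batches with deterministic columns", {
  tab <- compute_descriptor_block(c(ethane = "CC", benzene = "c1ccccc1"))
  expect_s3_class(tab, "descriptor_table")
  expect_equal(unname(tab$values[, "MW"]), c(30.07, 78.12), tolerance = 0.011)
  expect_equal(tab$ids, c("ethane", "benzene"))
  expect_error(compute_descriptor_block(list()), "empty")
  expect_warning(one <- compute_descriptor_block(c(ok = "CC", bad = "C1CC"),
                                                 on_error = "skip"), "skipping")
  expect_equal(nrow(one$values), 1L)
  # same batch twice: identical column order and values
  tab2 <- compute_descriptor_block(c(ethane = "CC", benzene = "c1ccccc1"))
  expect_identical(tab$values, tab2$values)
})
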
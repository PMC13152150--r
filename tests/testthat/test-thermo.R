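# Stoichiometric flowsheet: reaction builders and their balance checks,
# specified-conversion reactors, separator closure, enthalpy accounting and
# the coulombic bound.

test_that("the three reaction builders carry the balanced coefficients", {
  an <- anode_reaction()
  expect_equal(an$stoich[["glucose"]], -1)
  expect_equal(an$stoich[["water"]], -6)
  expect_equal(an$stoich[["co2"]], 6)
  expect_equal(an$stoich[["proton"]], 24)
  expect_equal(an$stoich[["electron"]], 24)
  expect_equal(an$n_electrons, 24)
  ca <- cathode_reaction()
  expect_equal(ca$stoich[["water"]], 2)
  expect_equal(ca$stoich[["oxygen"]], -1)
  expect_equal(ca$n_electrons, 4)
  ov <- overall_reaction()
  expect_equal(ov$stoich[["co2"]], 6)
  expect_equal(ov$stoich[["water"]], 6)
  expect_equal(ov$stoich[["proton"]], 0)
  expect_equal(ov$stoich[["electron"]], 0)
})

test_that("anode plus six cathode turnovers equals the overall reaction", {
  combo <- anode_reaction()$stoich + 6 * cathode_reaction()$stoich
  expect_equal(combo, overall_reaction()$stoich)
})

test_that("unbalanced or charged reactions are rejected at construction", {
  expect_error(reaction(c(glucose = -1, co2 = 5)), "element balance")
  expect_error(reaction(c(electron = 1)), "charge balance")
  expect_error(reaction(c(unobtainium = 1)), "unknown species")
})

test_that("specified-conversion reactor applies the stoichiometry to the limiting reagent", {
  feed <- stream(c(glucose = 1, water = 50))
  expect_equal(react_stream(feed, anode_reaction(), 0)$flows, feed$flows)
  out <- react_stream(feed, anode_reaction(), 1)
  expect_equal(out$flows[["co2"]], 6)
  expect_equal(out$flows[["proton"]], 24)
  expect_equal(out$flows[["glucose"]], 0)
  expect_equal(out$flows[["water"]], 44)
  # water limiting: 3 mol water supports only 0.5 mol glucose turnover
  lim <- react_stream(stream(c(glucose = 1, water = 3)), anode_reaction(), 1)
  expect_equal(attr(lim, "extent"), 0.5)
  expect_equal(lim$flows[["glucose"]], 0.5)
})

test_that("element and charge totals are conserved across random reactors", {
  set.seed(11)
  rxns <- list(anode_reaction(), cathode_reaction(), overall_reaction())
  for (k in 1:25) {
    rxn <- rxns[[sample.int(3, 1)]]
    feed <- stream(stats::setNames(stats::runif(6, 0, 10),
                                   species_table()$species))
    conv <- stats::runif(1)
    out <- react_stream(feed, rxn, conv)
    expect_equal(element_totals(out), element_totals(feed),
                 tolerance = 1e-12)
  }
})

test_that("separator splits close species-wise", {
  s <- stream(c(glucose = 0.2, water = 40, co2 = 3, proton = 12))
  pem <- separate(s, separator_spec(c(proton = 1)))
  expect_equal(pem$permeate$flows[["proton"]], 12)
  expect_equal(sum(pem$permeate$flows), 12)   # nothing else crosses
  half <- separator_spec(stats::setNames(rep(0.5, 6), species_table()$species))
  sp <- separate(s, half)
  expect_equal(sp$permeate$flows, s$flows / 2)
  set.seed(7)
  for (k in 1:10) {
    fr <- stats::setNames(stats::runif(6), species_table()$species)
    sp <- separate(s, separator_spec(fr))
    expect_equal(sp$permeate$flows + sp$retentate$flows, s$flows)
  }
})

test_that("cathode stage consumes protons, electrons and oxygen in 4:4:1", {
  perm <- stream(c(proton = 24, electron = 24))
  o2 <- stream(c(oxygen = 6))
  out <- cathode_stage(perm, o2, 1)
  expect_equal(out$flows[["water"]], 12)
  expect_equal(out$flows[["proton"]], 0)
  expect_equal(out$flows[["electron"]], 0)
  expect_equal(out$flows[["oxygen"]], 0)
  # pass-through at zero conversion
  expect_equal(cathode_stage(perm, o2, 0)$flows[["proton"]], 24)
  # oxygen short by half halves the extent
  short <- cathode_stage(perm, stream(c(oxygen = 3)), 1)
  expect_equal(short$flows[["water"]], 6)
  expect_equal(short$flows[["proton"]], 12)
})

test_that("reaction enthalpy sums coefficient times formation enthalpy", {
  zero <- reaction(c(water = 0), n_electrons = 0)
  expect_equal(reaction_enthalpy(zero), 0)
  synth <- c(glucose = 0, water = 0, co2 = -1, proton = 0, oxygen = 0,
             electron = 0)
  expect_equal(reaction_enthalpy(overall_reaction(), synth), -6)
  # hand sum over the shipped reference table
  tab <- load_formation_enthalpies()
  hand <- 6 * tab[["co2"]] + 6 * tab[["water"]] - tab[["glucose"]] -
    6 * tab[["oxygen"]]
  expect_equal(reaction_enthalpy(overall_reaction(), tab), hand)
  expect_equal(hand, -2802.74, tolerance = 1e-8)
  expect_error(reaction_enthalpy(overall_reaction(), c(co2 = -1)), "missing")
})

test_that("the coulombic bound follows the 24-electron stoichiometry", {
  feed <- stream(c(glucose = 1, water = 100))
  expect_equal(max_electron_flow(feed, 1)$electron_mol_per_h, 24)
  expect_equal(max_electron_flow(feed, 0)$current_A, 0)
  half <- max_electron_flow(stream(c(glucose = 0.5, water = 100)), 0.5)
  expect_equal(half$electron_mol_per_h, 6)
  expect_equal(half$current_A, 6 * 96485 / 3600)
})

test_that("the chained flowsheet conserves elements end-to-end and depletes glucose", {
  fs <- run_flowsheet()
  expect_equal(unname(fs$element_residuals[c("C", "H", "O")]), rep(0, 3),
               tolerance = 1e-12)
  # default 0.99 conversion leaves 1% of the glucose feed
  expect_equal(fs$retentate$flows[["glucose"]],
               0.01 * fs$feed$flows[["glucose"]], tolerance = 1e-12)
  expect_equal(fs$electron_mol_per_h, 24 * 0.99)
  set.seed(23)
  for (k in 1:8) {
    fs <- run_flowsheet(
      feed = stream(c(glucose = stats::runif(1, 0.1, 2),
                      water = stats::runif(1, 10, 100))),
      anode_conversion = stats::runif(1),
      cathode_conversion = stats::runif(1),
      separator = separator_spec(c(proton = stats::runif(1, 0.5, 1),
                                   water = stats::runif(1, 0, 0.1))))
    expect_equal(unname(fs$element_residuals[c("C", "H", "O")]), rep(0, 3),
                 tolerance = 1e-12)
  }
})

test_that("streams reject unknown species and negative flows", {
  expect_error(stream(c(helium = 1)), "unknown species")
  expect_error(stream(c(glucose = -1)), "non-negative")
  expect_error(react_stream(stream(c(glucose = 1, water = 50)),
                            anode_reaction(), 1.2), "conversion")
})
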
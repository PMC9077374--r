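test_that("default network carries the printed azide and water rate constants", {
  net <- default_network()
  rxn <- net$reactions

  r4 <- rxn[rxn$r1 == "N3-" & rxn$r2 == "H", ]
  expect_equal(nrow(r4), 1L)
  expect_equal(r4$k, 3.15e9)

  r2 <- rxn[rxn$r1 == "e_aq-" & rxn$r2 == "e_aq-", ]
  expect_equal(r2$k, 6.2e9)
  expect_equal(sort(c(r2$p1, r2$p2, r2$p3)), c("H2", "OH-", "OH-"))

  expect_equal(rxn$k[rxn$id == "R1"], 2.5e10)
  expect_equal(rxn$k[rxn$id == "R3"], 4.6e9)
  expect_equal(rxn$k[rxn$id == "R7"], 1.2e10)
  expect_equal(rxn$k[rxn$id == "R9"], 1.2e10)
  expect_equal(rxn$k[rxn$id == "R11"], 2.4e10)
  expect_equal(rxn$k[rxn$id == "R14"], 3.9e9)
  expect_equal(rxn$k[rxn$id == "R15"], 2.4e5)
  expect_equal(rxn$k[rxn$id == "R16"], 1.2e10)
  expect_equal(rxn$k[rxn$id == "R17"], 19)

  spp <- net$species
  expect_equal(spp$D_cm2s[spp$name == "N3-"], 1.84e-5)
  expect_equal(spp$D_cm2s[spp$name == "N3"], 1.84e-5)
  expect_equal(unname(net$pKa["HN3"]), 4.7)
})

test_that("every fully specified reaction balances elements and charge", {
  # validate_network() stops on imbalance; it runs inside default_network()
  expect_silent(validate_network(default_network()))
  # and a deliberately broken reaction is caught
  bad <- default_network()$reactions
  bad$p1[bad$id == "R3"] <- "H2O2"
  expect_error(irt_network(default_network()$species, bad), "unbalanced")
})

test_that("network validation catches structural defects", {
  net <- default_network()
  dup <- net$reactions
  dup$id[2] <- dup$id[1]
  expect_error(irt_network(net$species, dup), "duplicate")
  ghost <- net$reactions
  ghost$p1[ghost$id == "R3"] <- "X99"
  expect_error(irt_network(net$species, ghost), "unresolved")
  expect_error(default_network(k_overrides = c(R99 = 1)), "unknown reaction")
  over <- default_network(k_overrides = c(R5 = 7e5))
  expect_equal(over$reactions$k[over$reactions$id == "R5"], 7e5)
})

test_that("encounter radius inverts and round-trips the Smoluchowski relation", {
  D <- 1.19e-4  # cm^2/s, mutual
  R0 <- 0.5
  k <- 4 * pi * diffusion_nm2ps(D) * R0 / irtrad:::K_M1S1_TO_NM3PS
  expect_equal(encounter_radius(k, D), R0, tolerance = 1e-12)
  # linearity in k_obs
  expect_equal(encounter_radius(2 * k, D), 2 * R0, tolerance = 1e-12)
  # independent hand conversion: R[cm] = k * 1000 / (4 pi N_A D[cm^2/s])
  k1 <- 2.5e10
  R_hand_nm <- k1 * 1000 / (4 * pi * 6.02214076e23 * D) * 1e7
  expect_equal(encounter_radius(k1, D), R_hand_nm, tolerance = 1e-10)
  expect_equal(R_hand_nm, 0.27761, tolerance = 1e-4)
  # round trip at random constants
  for (kk in c(1e7, 4.6e9, 3e10)) {
    R <- encounter_radius(kk, D)
    k_back <- 4 * pi * diffusion_nm2ps(D) * R / irtrad:::K_M1S1_TO_NM3PS
    expect_equal(k_back, kk, tolerance = 1e-10)
  }
})

test_that("partially controlled encounter model obeys Collins-Kimball", {
  D <- 1e-4
  out <- encounter_radius(5e9, D, model = "partial", k_act = 2e10)
  k_diff <- 4 * pi * diffusion_nm2ps(D) * out$R / irtrad:::K_M1S1_TO_NM3PS
  expect_equal(1 / (1 / 2e10 + 1 / k_diff), 5e9, tolerance = 1e-10)
  expect_equal(out$v, k_bimolecular_nm3ps(2e10) / (4 * pi * out$R^2),
               tolerance = 1e-12)
  expect_error(encounter_radius(5e9, D, model = "partial", k_act = 4e9),
               "unphysical")
})

test_that("ionic strength factor has the Bronsted-Bjerrum limits and symmetry", {
  expect_equal(ionic_strength_factor(0, -1, 1), 1)
  expect_equal(ionic_strength_factor(-1, -1, 0), 1)
  # closed form at I = 0.1 M for a (-1,-1) pair
  f_expected <- 10^(1.02 * sqrt(0.1) / (1 + sqrt(0.1)))
  expect_equal(ionic_strength_factor(-1, -1, 0.1), f_expected)
  expect_equal(f_expected, 1.758, tolerance = 1e-3)
  # symmetry under reactant exchange, like > 1 > unlike
  for (I in c(0.01, 0.3, 2)) {
    expect_equal(ionic_strength_factor(-1, 2, I),
                 ionic_strength_factor(2, -1, I))
    expect_gt(ionic_strength_factor(1, 1, I), 1)
    expect_lt(ionic_strength_factor(1, -1, I), 1)
  }
  # continuity and monotonicity in I for like charges
  I <- seq(0, 3, by = 0.05)
  f <- ionic_strength_factor(-1, -1, I)
  expect_true(all(diff(f) > 0))
  expect_error(ionic_strength_factor(1, 1, -0.1), "negative")
})

test_that("HN3 speciation follows Henderson-Hasselbalch with pKa 4.7", {
  expect_equal(hn3_fraction(4.7), 0.5)
  expect_equal(hn3_fraction(14), 0, tolerance = 1e-9)
  expect_equal(hn3_fraction(7), 1 / (1 + 10^2.3))
  expect_equal(hn3_fraction(7), 5.0e-3, tolerance = 1e-2)
  expect_error(hn3_fraction(-1))
})

test_that("scavenging capacity is k*conc with the expected spur-lifetime scale", {
  expect_equal(scavenging_capacity(1.5e6, 0), 0)
  expect_equal(scavenging_capacity(3.15e9, 1), 3.15e9)
  # e_aq- in 5 M azide: scavenging time ~1.3e-7 s, same order as the
  # ~0.2 us lifetime of a low-LET spur
  cap <- scavenging_capacity(1.5e6, 5)
  expect_equal(cap, 7.5e6)
  expect_equal(1 / cap, 1.33e-7, tolerance = 1e-2)
})

test_that("network YAML round trip is stable", {
  net <- default_network()
  path <- tempfile(fileext = ".yml")
  write_network_yaml(net, path)
  back <- read_network_yaml(path)
  expect_equal(back$species, net$species)
  expect_equal(back$reactions, net$reactions)
  expect_equal(back$pKa, net$pKa)
})
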
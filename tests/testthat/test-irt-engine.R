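test_that("an inert particle survives untouched", {
  compiled <- compile_engine(default_network(), azide = 0, o2 = 2.5e-4)
  h <- run_history(single_particle("H2"), compiled)
  expect_equal(nrow(h$events), 0L)
  expect_equal(h$survivors, "H2")
  expect_error(run_history(single_particle("Xx"), compiled), "unknown")
})

test_that("an isolated reactive pair follows the analytic first-passage law", {
  net <- pair_network(R_nm = 0.5)
  t_end <- 500
  compiled <- compile_engine(net, azide = 0, o2 = 0, t_end = t_end)
  expect_equal(compiled$pair$R, 0.5, tolerance = 1e-12)
  r0 <- 1.5
  D <- diffusion_nm2ps(4.9e-5 + 7.0e-5)
  cfg <- list(particles = data.frame(species = c("A", "B"),
                                     x = c(0, r0), y = 0, z = 0),
              energy = 100)
  set.seed(9)
  n <- 3e4
  reacted <- vapply(seq_len(n), function(i) {
    nrow(run_history(cfg, compiled)$events) > 0
  }, logical(1))
  # events are kept only if they precede t_end, so the reacted fraction
  # estimates W(t_end - 1) = (R/r) erfc[(r-R)/sqrt(4 D (t_end-1))]
  w <- (0.5 / r0) * irtrad:::erfc_((r0 - 0.5) / sqrt(4 * D * (t_end - 1)))
  se <- sqrt(w * (1 - w) / n)
  expect_lt(abs(mean(reacted) - w), 3 * se)
})

test_that("homogeneous scavenging reproduces the exponential survival law", {
  # single H atom in 1 M azide; high pH keeps the acid fraction negligible
  compiled <- compile_engine(default_network(), azide = 1, o2 = 0, pH = 9,
                             t_end = 500)
  hi <- match("H", compiled$track) - 1L
  lam <- sum(compiled$fo$rate[compiled$fo$spec == hi])
  # R4 dominates; the residual HN3 channel contributes ~1e-6 relative
  expect_equal(lam, 3.15e9 * 1e-12 * (1 - hn3_fraction(9)), tolerance = 1e-5)
  set.seed(10)
  n <- 2e4
  surv <- vapply(seq_len(n), function(i) {
    nrow(run_history(single_particle("H"), compiled)$events) == 0
  }, logical(1))
  p <- exp(-lam * (500 - 1))
  expect_lt(abs(mean(surv) - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("event bookkeeping conserves particles, elements and charge", {
  set.seed(11)
  compiled <- compile_engine(default_network(), azide = 0.01, o2 = 2.5e-4)
  cfg <- generate_track(track_mode("gamma", segment_length_um = 5), spur_params())
  h <- run_history(cfg, compiled)
  # survivors = initial + net stoichiometry of the event log, per species
  ev_counts <- table(factor(h$events$reaction, levels = compiled$rxn_ids))
  predicted <- h$initial + as.vector(compiled$stoich %*% as.numeric(ev_counts))
  observed <- table(factor(h$survivors, levels = compiled$track))
  expect_equal(as.numeric(observed), as.numeric(predicted))
  # event times never precede the 1 ps start and never exceed the window
  expect_true(all(h$events$time >= 1))
  expect_true(all(h$events$time <= compiled$t_end))
  # element/charge conservation across the log: every executed reaction is
  # balanced (validated at network construction), so the net elemental
  # content of survivors equals initial + per-reaction balanced exchange.
  spp <- default_network()$species
  for (col in c("nH", "nO", "nN", "charge")) {
    v <- stats::setNames(spp[[col]], spp$name)
    drift <- sum(v[h$survivors]) - sum(v[names(h$initial)] * h$initial)
    # drift must be fully explained by bulk/solvent exchange of the
    # executed reactions, never by lost particles
    rxn <- compiled$reactions
    exch <- 0
    for (id in names(ev_counts)) {
      n_ev <- as.numeric(ev_counts[[id]])
      if (n_ev == 0) next
      r <- rxn[rxn$id == id, ]
      track_sp <- compiled$track
      re <- c(r$r1, r$r2); pr <- c(r$p1, r$p2, r$p3)
      re <- re[!is.na(re)]; pr <- pr[!is.na(pr)]
      w <- if (col == "nH") 2 else if (col == "nO") 1 else 0
      gain <- sum(v[pr[pr %in% track_sp]]) - sum(v[re[re %in% track_sp]])
      exch <- exch + n_ev * gain
    }
    expect_equal(drift, exch)
  }
})

test_that("ensemble yields are reproducible and monotone in their extents", {
  tm <- track_mode("gamma", segment_length_um = 3, n_histories = 15)
  y1 <- simulate_yields(tm, azide = 1e-3, seed = 123)
  y2 <- simulate_yields(tm, azide = 1e-3, seed = 123)
  expect_identical(y1$G, y2$G)
  expect_identical(y1$dG, y2$dG)
  y3 <- simulate_yields(tm, azide = 1e-3, seed = 124)
  expect_false(identical(y1$G, y3$G))

  # cumulative per-channel extents never decrease; G never negative
  expect_true(all(apply(y1$dG, 2, function(v) all(diff(v) >= -1e-12))))
  expect_true(all(y1$G >= -1e-12))
  # the 1-ps H2 yield equals the configured initialization within MC error
  # (~45 eV * 15 histories * 20 spurs -> ~45 H2 molecules, rel. sd ~15%)
  expect_lt(abs(y1$G[1, "H2"] - 0.34), 0.12)
  # empty initial configurations produce all-zero yields
  p0 <- spur_params(g = c("e_aq-" = 0, "OH" = 0, "H" = 0, "H2" = 0,
                          "OH-" = 0, "H2O2" = 0))
  y0 <- simulate_yields(track_mode("gamma", segment_length_um = 1,
                                   n_histories = 3), spur = p0, seed = 5)
  expect_true(all(y0$G == 0))
})

test_that("bookkeeping closure links species yields to channel extents", {
  tm <- track_mode("gamma", segment_length_um = 5, n_histories = 20)
  y <- simulate_yields(tm, azide = 0.01, seed = 42)
  compiled <- compile_engine(default_network(), azide = 0.01)
  S <- compiled$stoich
  for (sp in c("H2", "e_aq-", "OH", "N3")) {
    reconstructed <- y$G[1, sp] + as.vector(y$dG %*% S[sp, ])
    expect_equal(unname(y$G[, sp]), reconstructed, tolerance = 1e-10)
  }
})

test_that("plateau and chemical-stage gain obey their algebraic identities", {
  tm <- track_mode("gamma", segment_length_um = 8, n_histories = 40)
  y <- simulate_yields(tm, seed = 31)
  p <- plateau(y, "H2")
  g <- chemical_stage_gain(y, "H2")
  expect_equal(g$value + unname(y$G[1, "H2"]), p$value)  # sum rule, exact
  expect_true(is.finite(p$se) && p$se >= 0)
  # a constant series has plateau equal to the constant and no drift flag
  yc <- y
  yc$G[, "H2"] <- 0.45
  yc$G_batch[, , "H2"] <- 0.45
  pc <- plateau(yc, "H2")
  expect_equal(pc$value, 0.45)
  expect_false(pc$drifting)
  expect_equal(pc$changeover_ps, yc$time[1])
  # a series still rising at the end of the window raises the drift flag
  yr <- y
  yr$G[, "H2"] <- seq(0.1, 0.5, length.out = length(yr$time))
  expect_true(plateau(yr, "H2")$drifting)
})
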
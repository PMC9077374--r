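test_that("spur sampling reproduces the configured yields and neutrality", {
  set.seed(41)
  p <- spur_params(g = c("e_aq-" = 4.0, "OH" = 5.0, "H" = 0.6,
                         "H2" = 0.34, "OH-" = 0.5, "H2O2" = 0.2))
  expect_equal(unname(p$g["H3O+"]), 4.5)  # charge balance of the anions

  # mean e_aq- count over many 50 eV spurs: 4.0 * 50 / 100 = 2.0
  n <- 20000
  counts <- vapply(seq_len(n), function(i) {
    s <- sample_spur(50, p)
    sum(s$species == "e_aq-")
  }, numeric(1))
  se <- sqrt(2.0 / n)  # Poisson
  expect_lt(abs(mean(counts) - 2.0), 3 * se)

  # exact per-spur charge neutrality by pairing construction
  spp <- default_species()
  z <- stats::setNames(spp$charge, spp$name)
  for (i in 1:200) {
    s <- sample_spur(stats::runif(1, 10, 90), p)
    if (nrow(s)) expect_identical(sum(z[s$species]), 0L)
  }

  # all-zero yields give an empty particle list
  p0 <- spur_params(g = c("e_aq-" = 0, "OH" = 0, "H" = 0, "H2" = 0,
                          "OH-" = 0, "H2O2" = 0))
  expect_equal(nrow(sample_spur(50, p0)), 0L)
})

test_that("gamma segments deposit LET * length with spur spacing E/LET", {
  set.seed(42)
  p <- spur_params()
  tm <- track_mode("gamma", segment_length_um = 50)
  cfgs <- lapply(1:30, function(i) generate_track(tm, p))
  E <- vapply(cfgs, function(cc) cc$energy, numeric(1))
  expect_lt(abs(mean(E) - 0.3 * 5e4) / (0.3 * 5e4), 0.05)

  # mean gap between consecutive spur centres ~ mean spur energy / LET
  gaps <- unlist(lapply(cfgs, function(cc) diff(cc$spur_z)))
  expect_lt(abs(mean(gaps) - p$mean_spur_energy / 0.3) /
              (p$mean_spur_energy / 0.3), 0.1)

  # vanishing LET leaves a single spur in the segment
  tiny <- track_mode("gamma", let = 1e-7, segment_length_um = 50)
  cfg1 <- generate_track(tiny, p)
  expect_lt(diff(range(cfg1$particles$z)), 50)
})

test_that("tritium tracks deposit 7800 eV exactly over ~E/LET of path", {
  set.seed(43)
  p <- spur_params()
  tm <- track_mode("tritium")
  cfgs <- lapply(1:20, function(i) generate_track(tm, p))
  expect_true(all(vapply(cfgs, function(cc) cc$energy, numeric(1)) == 7800))
  len <- vapply(cfgs, function(cc) max(cc$particles$z) - min(cc$particles$z),
                numeric(1))
  expect_lt(abs(mean(len) - 7800 / 5.9) / (7800 / 5.9), 0.15)
})

test_that("tritium short tracks are denser than gamma spur tracks", {
  set.seed(44)
  p <- spur_params()
  nn_dist <- function(cfg, m = 400) {
    xyz <- as.matrix(cfg$particles[, c("x", "y", "z")])
    idx <- seq_len(min(m, nrow(xyz)))
    d <- as.matrix(stats::dist(xyz[idx, ]))
    diag(d) <- Inf
    mean(apply(d, 1, min))
  }
  tri <- nn_dist(generate_track(track_mode("tritium"), p))
  gam <- nn_dist(generate_track(track_mode("gamma", segment_length_um = 30), p))
  expect_lt(tri, gam)

  # pairs within 10 nm per 100 eV: the geometric driver of the higher
  # molecular yields of the short-track geometry
  pair_density <- function(cfg) {
    xyz <- as.matrix(cfg$particles[, c("x", "y", "z")])
    d <- stats::dist(xyz)
    100 * sum(d < 10) / cfg$energy
  }
  expect_gt(pair_density(generate_track(track_mode("tritium"), p)),
            pair_density(generate_track(track_mode("gamma",
                                                   segment_length_um = 30), p)))
})

test_that("ensemble 1-ps G-values reproduce the configured yields in both modes", {
  set.seed(45)
  p <- spur_params()
  for (tm in list(track_mode("gamma", segment_length_um = 20),
                  track_mode("tritium"))) {
    cfgs <- lapply(1:40, function(i) generate_track(tm, p))
    E <- sum(vapply(cfgs, function(cc) cc$energy, numeric(1)))
    tab <- table(unlist(lapply(cfgs, function(cc) cc$particles$species)))
    for (sp in names(p$g)) {
      g_hat <- 100 * as.numeric(tab[sp]) / E
      se <- 100 * sqrt(as.numeric(tab[sp])) / E
      expect_lt(abs(g_hat - p$g[[sp]]), 4 * se + 1e-9)
    }
  }
})

test_that("track CSV round trip preserves particles and energy", {
  set.seed(46)
  cfg <- generate_track(track_mode("gamma", segment_length_um = 5), spur_params())
  path <- tempfile(fileext = ".csv")
  write_track_csv(cfg, path)
  back <- read_track_csv(path)
  expect_equal(back$energy, cfg$energy, tolerance = 1e-8)
  expect_equal(back$particles$species, cfg$particles$species)
  expect_equal(back$particles$x, cfg$particles$x, tolerance = 1e-5)
  expect_equal(back$mode, "gamma")
})
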
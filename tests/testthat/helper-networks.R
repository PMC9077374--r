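# Minimal element-free test networks and fixtures shared across the suite.

# two mobile species with a single fully diffusion-controlled channel
# A + B -> C at encounter radius R_nm; rate constant derived from the
# forward Smoluchowski relation so compile_engine() recovers R_nm exactly
pair_network <- function(R_nm = 0.5, D_A = 4.9e-5, D_B = 7.0e-5) {
  spp <- data.frame(
    name = c("A", "B", "C"), charge = 0L,
    D_cm2s = c(D_A, D_B, 1e-5),
    nH = 0L, nO = 0L, nN = 0L, role = "track",
    stringsAsFactors = FALSE)
  k <- 4 * pi * diffusion_nm2ps(D_A + D_B) * R_nm / irtrad:::K_M1S1_TO_NM3PS
  rxn <- data.frame(id = "RA", r1 = "A", r2 = "B", k = k,
                    p1 = "C", p2 = NA, p3 = NA, n_water = 0L,
                    sink = FALSE, enabled = TRUE, stringsAsFactors = FALSE)
  irt_network(spp, rxn, pKa = c(HN3 = 4.7))
}

# the 6-particle validation cluster: two competing channels,
# A + B -> P1 (R = 0.5 nm) and A + A -> P2 (R = 0.35 nm), inert products
cluster_network <- function() {
  spp <- data.frame(
    name = c("A", "B", "P1", "P2"), charge = 0L,
    D_cm2s = c(4.9e-5, 7.0e-5, 1e-5, 1e-5),
    nH = 0L, nO = 0L, nN = 0L, role = "track",
    stringsAsFactors = FALSE)
  kAB <- 4 * pi * diffusion_nm2ps(4.9e-5 + 7.0e-5) * 0.5 /
    irtrad:::K_M1S1_TO_NM3PS
  kAA <- 4 * pi * diffusion_nm2ps(2 * 4.9e-5) * 0.35 /
    irtrad:::K_M1S1_TO_NM3PS
  rxn <- rbind(
    data.frame(id = "RA", r1 = "A", r2 = "B", k = kAB, p1 = "P1",
               p2 = NA, p3 = NA, n_water = 0L, sink = FALSE, enabled = TRUE,
               stringsAsFactors = FALSE),
    data.frame(id = "RB", r1 = "A", r2 = "A", k = kAA, p1 = "P2",
               p2 = NA, p3 = NA, n_water = 0L, sink = FALSE, enabled = TRUE,
               stringsAsFactors = FALSE))
  irt_network(spp, rxn, pKa = c(HN3 = 4.7))
}

cluster_fixture <- function() {
  read_track_csv(system.file("extdata", "cluster6.csv", package = "irtrad"))
}

# configuration holding a single particle of the given species
single_particle <- function(species, energy = 100) {
  list(particles = data.frame(species = species, x = 0, y = 0, z = 0,
                              stringsAsFactors = FALSE),
       energy = energy)
}
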
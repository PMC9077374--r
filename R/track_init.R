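# Synthetic 1-ps initial configurations standing in for the physical /
# physicochemical stages of track-structure simulation. Two geometries:
#   gamma   -- widely spaced spherical spurs along a straight track segment
#              (low-LET limit, 0.3 eV/nm, mimicking 60Co gamma / fast electrons
#              via a 300 MeV proton track segment)
#   tritium -- densely overlapping energy-loss events along the short
#              (~1.3 um) path of a 7.8 keV beta electron (mean LET 5.9 eV/nm)

#' Spur model parameters
#'
#' The 1-ps yields (molecules/100 eV), Gaussian spur widths, and the spur
#' energy spectrum used by the synthetic track generator. The H2 yield at
#' 1 ps (0.34 molecule/100 eV) is the physicochemical-stage contribution of
#' the sub-picosecond dry/subexcitation-electron chemistry; it is carried as
#' an initial condition, not simulated mechanistically. The hydronium yield
#' is the charge balance of the anions (g(H3O+) = g(e_aq-) + g(OH-)), so the
#' expected net charge of every spur is zero. Spur widths default to the
#' calibrated values for which the azide-free low-LET escape yield of H2
#' matches 0.45 molecule/100 eV (see the package vignette).
#'
#' @param g named yields at 1 ps, molecules/100 eV. `H3O+` is derived.
#' @param sigma_e Gaussian standard deviation for the hydrated electron, nm.
#' @param sigma_heavy Gaussian standard deviation for all other species, nm.
#' @param mean_spur_energy mean of the spur energy spectrum, eV.
#' @param energy_range truncation bounds of the spur energy spectrum, eV.
#' @return An object of class `spur_params`.
#' @export
spur_params <- function(g = c("e_aq-" = 4.2, "OH" = 5.0, "H" = 0.6,
                              "H2" = 0.34, "OH-" = 0.5, "H2O2" = 0.2),
                        sigma_e = 4.3, sigma_heavy = 1.0,
                        mean_spur_energy = 40,
                        energy_range = c(6.6, 100)) {
  stopifnot(all(g >= 0), sigma_e > 0, sigma_heavy > 0,
            mean_spur_energy > energy_range[1],
            mean_spur_energy < energy_range[2])
  g["H3O+"] <- g[["e_aq-"]] + g[["OH-"]]  # exact charge neutrality
  structure(list(g = g, sigma_e = sigma_e, sigma_heavy = sigma_heavy,
                 mean_spur_energy = mean_spur_energy,
                 energy_range = energy_range,
                 energy_rate = .trunc_exp_rate(mean_spur_energy, energy_range)),
            class = "spur_params")
}

# rate of an exponential truncated to [a,b] with the requested mean
.trunc_exp_rate <- function(m, range) {
  a <- range[1]; b <- range[2]
  f <- function(lam) {
    d <- b - a
    a + 1 / lam - d * exp(-lam * d) / (1 - exp(-lam * d)) - m
  }
  stats::uniroot(f, c(1e-6, 2), tol = 1e-12)$root
}

# sample spur energies from the truncated exponential spectrum
sample_spur_energies <- function(n, params) {
  a <- params$energy_range[1]; b <- params$energy_range[2]
  lam <- params$energy_rate
  u <- stats::runif(n)
  a - log(1 - u * (1 - exp(-lam * (b - a)))) / lam
}

#' Track mode parameters
#'
#' Irradiation geometry: `"gamma"` is a track segment of a ~300 MeV proton
#' (LET 0.3 eV/nm at 25 C, mimicking 60Co gamma / fast-electron
#' irradiation), sliced into isolated spurs; `"tritium"` is the complete
#' track of a 7.8 keV beta electron (mean LET 5.9 eV/nm), whose energy-loss
#' events overlap into a quasi-cylindrical short track.
#'
#' @param mode `"gamma"` or `"tritium"`.
#' @param let linear energy transfer, eV/nm.
#' @param segment_length_um gamma-mode track segment length, um.
#' @param electron_energy_keV tritium-mode initial electron energy, keV.
#' @param n_histories default number of stochastic track histories.
#' @return An object of class `track_mode`.
#' @export
track_mode <- function(mode = c("gamma", "tritium"),
                       let = NULL, segment_length_um = 150,
                       electron_energy_keV = 7.8, n_histories = NULL) {
  mode <- match.arg(mode)
  if (is.null(let)) let <- if (mode == "gamma") 0.3 else 5.9
  if (is.null(n_histories)) n_histories <- if (mode == "gamma") 150 else 6000
  stopifnot(let > 0, segment_length_um > 0, electron_energy_keV > 0,
            n_histories >= 1)
  structure(list(mode = mode, let = let,
                 segment_length_um = segment_length_um,
                 electron_energy_keV = electron_energy_keV,
                 n_histories = n_histories),
            class = "track_mode")
}

#' Sample the species content of one spur
#'
#' Draws the particle content of a single energy-loss event of energy
#' `energy` so that the expected count of species s is `g[s] * energy / 100`.
#' Anion counts are Poisson; every e_aq- and every OH- is created together
#' with an H3O+ partner, so each spur is exactly charge neutral. Positions
#' are isotropic 3-D Gaussians centred on `centre` with the species-class
#' standard deviation (`sigma_e` for the hydrated electron, `sigma_heavy`
#' otherwise).
#'
#' @param energy spur energy, eV (> 0).
#' @param params a [spur_params()] object.
#' @param centre spur centre, length-3 numeric (nm).
#' @return data.frame with columns `species`, `x`, `y`, `z` (nm).
#' @export
sample_spur <- function(energy, params, centre = c(0, 0, 0)) {
  stopifnot(energy > 0)
  g <- params$g
  counts <- integer(0); names(counts) <- character(0)
  n_e  <- stats::rpois(1, g[["e_aq-"]] * energy / 100)
  n_oh <- stats::rpois(1, g[["OH-"]]  * energy / 100)
  counts <- c("e_aq-" = n_e, "OH-" = n_oh, "H3O+" = n_e + n_oh)
  for (sp in setdiff(names(g), c("e_aq-", "OH-", "H3O+"))) {
    counts[sp] <- stats::rpois(1, g[[sp]] * energy / 100)
  }
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n == 0) {
    return(data.frame(species = character(0), x = numeric(0),
                      y = numeric(0), z = numeric(0)))
  }
  species <- rep(names(counts), counts)
  sd <- ifelse(species == "e_aq-", params$sigma_e, params$sigma_heavy)
  data.frame(species = species,
             x = stats::rnorm(n, centre[1], sd),
             y = stats::rnorm(n, centre[2], sd),
             z = stats::rnorm(n, centre[3], sd),
             stringsAsFactors = FALSE)
}

#' Generate one 1-ps initial track configuration
#'
#' Gamma mode: spur centres are laid along a straight line; the gap ahead of
#' each spur is exponential with mean (spur energy)/LET, so the mean energy
#' deposited per unit length equals the LET (~0.3 eV/nm gives a mean
#' inter-spur spacing of >100 nm, i.e. effectively independent spurs). The
#' first spur sits at the segment origin and placement stops at the end of
#' the segment; the deposited energy is the sum of the placed spur energies.
#'
#' Tritium mode: energy-loss events are drawn from the same spur spectrum
#' until their sum reaches the initial electron energy exactly (the last
#' event is truncated), and placed along a straight path with exponential
#' gaps of mean (event energy)/LET, giving a total path length of about
#' E/LET (~1.3 um at 7.8 keV and 5.9 eV/nm) and overlapping,
#' quasi-cylindrical species clusters. The deposited energy is exactly the
#' electron energy.
#'
#' @param mode a [track_mode()] object.
#' @param params a [spur_params()] object.
#' @return A list of class `track_config` with elements `particles`
#'   (data.frame `species`, `x`, `y`, `z` in nm), `energy` (eV), `mode`,
#'   and the energy-loss event layout `spur_z` / `spur_e` (centres in nm,
#'   energies in eV).
#' @export
generate_track <- function(mode, params) {
  if (mode$mode == "gamma") {
    L <- mode$segment_length_um * 1e3  # nm
    # draw generously, then truncate at the segment end
    n_guess <- max(16L, ceiling(1.6 * L * mode$let / params$mean_spur_energy) + 8L)
    repeat {
      e <- sample_spur_energies(n_guess, params)
      gaps <- stats::rexp(n_guess, rate = mode$let / e)
      z <- cumsum(c(0, gaps[-n_guess]))
      if (z[n_guess] > L) break
      n_guess <- n_guess * 2L
    }
    keep <- z <= L
    e <- e[keep]; z <- z[keep]
    parts <- do.call(rbind, lapply(seq_along(e), function(i) {
      sample_spur(e[i], params, centre = c(0, 0, z[i]))
    }))
    energy <- sum(e)
  } else {
    E_tot <- mode$electron_energy_keV * 1e3
    e <- numeric(0)
    while (sum(e) < E_tot) {
      e <- c(e, sample_spur_energies(
        max(8L, ceiling((E_tot - sum(e)) / params$mean_spur_energy)), params))
    }
    cum <- cumsum(e)
    k <- which(cum >= E_tot)[1]
    e <- e[seq_len(k)]
    e[k] <- e[k] - (cum[k] - E_tot)  # exact energy deposition
    e <- e[e > 0]
    gaps <- stats::rexp(length(e), rate = mode$let / e)
    z <- cumsum(c(0, gaps[-length(e)]))
    parts <- do.call(rbind, lapply(seq_along(e), function(i) {
      sample_spur(e[i], params, centre = c(0, 0, z[i]))
    }))
    energy <- E_tot
  }
  if (is.null(parts)) {
    parts <- data.frame(species = character(0), x = numeric(0),
                        y = numeric(0), z = numeric(0))
  }
  structure(list(particles = parts, energy = energy, mode = mode$mode,
                 spur_z = z, spur_e = e),
            class = "track_config")
}

#' Write / read a track configuration as a CSV table
#'
#' Plain-text interchange format (`species,x,y,z` in nm, with the deposited
#' energy recorded in a leading comment line) used for inspection and for
#' feeding fixture clusters to the Brownian-dynamics oracle.
#'
#' @param config a `track_config` (or any list with `particles` / `energy`).
#' @param path file path.
#' @export
write_track_csv <- function(config, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# energy_eV=%.9g mode=%s", config$energy,
                     if (is.null(config$mode)) "custom" else config$mode), con)
  utils::write.csv(config$particles, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_track_csv
#' @export
read_track_csv <- function(path) {
  header <- readLines(path, n = 1)
  energy <- as.numeric(sub(".*energy_eV=([0-9.eE+-]+).*", "\\1", header))
  mode <- sub(".*mode=(\\S+).*", "\\1", header)
  parts <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  structure(list(particles = parts, energy = energy, mode = mode),
            class = "track_config")
}
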
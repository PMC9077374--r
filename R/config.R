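# Configuration schema, YAML round trip, and the high-level entry points
# behind the command-line interface (exec/irtrad).

#' Full simulation configuration
#'
#' Bundles the track mode, spur parameters, scavenger composition and
#' reproducibility settings into a single validated object that can be
#' written to and read back from YAML. Defaults: air-saturated water
#' (O2 = 2.5e-4 M), neutral pH, 25 C, window 1 ps to 10 us, 150 histories
#' in gamma mode / 6000 in tritium mode.
#'
#' @param mode `"gamma"` or `"tritium"`.
#' @param azide total azide concentration, M.
#' @param o2 dissolved oxygen concentration, M.
#' @param pH solution pH.
#' @param n_histories history count (default: the mode's convention).
#' @param seed master seed (integer).
#' @param t_end end of the window, ps.
#' @param spur a [spur_params()] (default calibrated values).
#' @param segment_length_um gamma-mode segment length, um.
#' @param network_file optional YAML file overriding the reaction network.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(mode = "gamma", azide = 0, o2 = 2.5e-4, pH = 7,
                       n_histories = NULL, seed = 1L, t_end = 1e7,
                       spur = spur_params(), segment_length_um = 150,
                       network_file = NULL) {
  stopifnot(mode %in% c("gamma", "tritium"), azide >= 0, o2 >= 0,
            pH >= 0, pH <= 14, t_end > 1, seed == as.integer(seed))
  tm <- track_mode(mode, segment_length_um = segment_length_um,
                   n_histories = n_histories)
  structure(list(mode = tm, spur = spur, azide = azide, o2 = o2, pH = pH,
                 seed = as.integer(seed), t_end = t_end,
                 network_file = network_file),
            class = "sim_config")
}

#' Write / read a simulation configuration as YAML
#'
#' The round trip `read_config(write_config(cfg))` is the identity.
#'
#' @param cfg a [sim_config()].
#' @param path file path.
#' @export
write_config <- function(cfg, path) {
  obj <- list(
    mode = cfg$mode$mode,
    let = cfg$mode$let,
    segment_length_um = cfg$mode$segment_length_um,
    electron_energy_keV = cfg$mode$electron_energy_keV,
    n_histories = cfg$mode$n_histories,
    azide = cfg$azide, o2 = cfg$o2, pH = cfg$pH,
    seed = cfg$seed, t_end = cfg$t_end,
    spur = list(g = as.list(cfg$spur$g[setdiff(names(cfg$spur$g), "H3O+")]),
                sigma_e = cfg$spur$sigma_e,
                sigma_heavy = cfg$spur$sigma_heavy,
                mean_spur_energy = cfg$spur$mean_spur_energy,
                energy_range = cfg$spur$energy_range),
    network_file = cfg$network_file)
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  o <- yaml::read_yaml(path)
  required <- c("mode", "azide", "seed")
  missing <- setdiff(required, names(o))
  if (length(missing)) {
    stop("config file lacks required field(s): ", paste(missing, collapse = ", "))
  }
  sp <- if (is.null(o$spur)) spur_params() else
    spur_params(g = unlist(o$spur$g),
                sigma_e = o$spur$sigma_e,
                sigma_heavy = o$spur$sigma_heavy,
                mean_spur_energy = o$spur$mean_spur_energy,
                energy_range = as.numeric(o$spur$energy_range))
  sim_config(mode = o$mode, azide = o$azide,
             o2 = if (is.null(o$o2)) 2.5e-4 else o$o2,
             pH = if (is.null(o$pH)) 7 else o$pH,
             n_histories = o$n_histories, seed = o$seed,
             t_end = if (is.null(o$t_end)) 1e7 else o$t_end,
             spur = sp,
             segment_length_um = if (is.null(o$segment_length_um)) 150
                                 else o$segment_length_um,
             network_file = o$network_file)
}

config_network <- function(cfg) {
  if (is.null(cfg$network_file)) default_network()
  else read_network_yaml(cfg$network_file)
}

#' Run a configured simulation and write its outputs
#'
#' Executes [simulate_yields()] for a [sim_config()] and writes
#' `g_of_t.csv`, `channels.csv` and `manifest.json` to `out_dir`. Given the
#' same configuration and seed the outputs are bit-identical.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory.
#' @return The `irt_yields` object, invisibly.
#' @export
run_simulation <- function(cfg, out_dir) {
  y <- simulate_yields(cfg$mode, spur = cfg$spur, azide = cfg$azide,
                       o2 = cfg$o2, pH = cfg$pH,
                       n_histories = cfg$mode$n_histories,
                       seed = cfg$seed, net = config_network(cfg),
                       t_end = cfg$t_end)
  write_yields_csv(y, out_dir)
  write_manifest(y, out_dir)
  invisible(y)
}

#' Built-in oracle self-checks
#'
#' Runs the fast validation battery behind `irtrad validate`: the pair-time
#' sampler against its analytic first-passage law (Kolmogorov-Smirnov), the
#' ultimate-reaction frequency against R/r, the homogeneous scavenging
#' limit against the exponential law, and the IRT engine against the
#' Brownian-dynamics oracle on a two-particle system. Returns a summary
#' table; `ok` is FALSE for any check outside its tolerance.
#'
#' @param seed master seed.
#' @param n sample size for the sampler checks.
#' @return data.frame with columns `check`, `statistic`, `ok`.
#' @export
validate_oracles <- function(seed = 1L, n = 1e5) {
  set.seed(seed)
  r <- 2; R <- 1; D <- 0.01
  u <- stats::runif(n)
  t <- sample_pair_time(r, R, D, u)
  reacted <- is.finite(t)
  p_hit <- mean(reacted)
  se_hit <- sqrt((R / r) * (1 - R / r) / n)
  cdf <- function(q) erfc_((r - R) / sqrt(4 * D * q))
  ks <- stats::ks.test(t[reacted], cdf)
  rows <- data.frame(
    check = c("pair sampler KS p-value",
              "ultimate reaction frequency |p - R/r| / se"),
    statistic = c(ks$p.value, abs(p_hit - R / r) / se_hit),
    ok = c(ks$p.value > 0.01, abs(p_hit - R / r) / se_hit < 3))

  # homogeneous scavenging: single H atom in 1 M azide
  net <- default_network()
  compiled <- compile_engine(net, azide = 1, o2 = 0, pH = 9, t_end = 1e4)
  lam <- sum(compiled$fo$rate[compiled$fo$spec ==
                                (match("H", compiled$track) - 1L)])
  one <- list(particles = data.frame(species = "H", x = 0, y = 0, z = 0),
              energy = 100)
  m <- 2e4
  surv <- sum(vapply(seq_len(m), function(i) {
    nrow(run_history(one, compiled)$events) == 0
  }, logical(1)))
  p_exp <- exp(-lam * (1e4 - 1))
  z_scav <- abs(surv / m - p_exp) / sqrt(p_exp * (1 - p_exp) / m)
  rows <- rbind(rows, data.frame(check = "H scavenging exponential |z|",
                                 statistic = z_scav, ok = z_scav < 3))

  # IRT vs BD on an isolated pair
  bd <- bd_pair_survival(r, R, D, times = c(50, 200, 800), params = bd_params(
    dt = 0.15, t_end = 800, n_rep = 4000))
  irt_frac <- (R / r) * erfc_((r - R) / sqrt(4 * D * bd$time))
  zmax <- max(abs((1 - bd$S) - irt_frac) / bd$se)
  rows <- rbind(rows, data.frame(check = "BD vs analytic pair law max |z|",
                                 statistic = zmax, ok = zmax < 3))
  rows
}
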
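# R-side driver of the compiled IRT event engine: compiles an irt_network
# plus a scavenger composition into the flat channel tables the C++ core
# consumes, runs single histories, and accumulates ensemble yields.

#' Compile a reaction network for the IRT engine
#'
#' Resolves the network against a scavenger composition: reactions between
#' two track species become pair channels (encounter radius from the
#' Smoluchowski inversion of the -- ionic-strength-corrected -- rate
#' constant, mutual diffusion coefficient in nm^2/ps); reactions of a track
#' species with a bulk solute (azide, hydrazoic acid, dissolved oxygen, the
#' solvent) become pseudo-first-order channels with rate k * conc. Total
#' azide is split between N3- and HN3 by [hn3_fraction()] at the given pH.
#' The ionic strength defaults to the total azide concentration (NaN3 is a
#' 1:1 salt) and scales every channel whose two partners are both charged,
#' via [ionic_strength_factor()].
#'
#' The pair-channel interaction cutoff is the distance at which the
#' ultimate-by-t_end reaction probability (R/r) erfc[(r-R)/sqrt(4 D t_end)]
#' falls below `p_min` for every channel; pairs farther apart are never
#' assigned a channel.
#'
#' @param net an [irt_network()].
#' @param azide total azide concentration, M.
#' @param o2 dissolved oxygen concentration, M (default air-saturated,
#'   2.5e-4 M).
#' @param pH solution pH (default 7).
#' @param ionic_strength override for the ionic strength, M.
#' @param t_end end of the simulated window, ps.
#' @param p_min pair-channel probability floor defining the cutoff.
#' @return A `compiled_network` list used by [run_history()].
#' @export
compile_engine <- function(net, azide = 0, o2 = 2.5e-4, pH = 7,
                           ionic_strength = NULL, t_end = 1e7,
                           p_min = 1e-5) {
  stopifnot(inherits(net, "irt_network"), azide >= 0, o2 >= 0)
  spp <- net$species
  rxn <- net$reactions[net$reactions$enabled, , drop = FALSE]
  f_hn3 <- hn3_fraction(pH, net$pKa[["HN3"]])
  conc <- c("N3-" = azide * (1 - f_hn3), "HN3" = azide * f_hn3,
            "O2" = o2, "H2O" = WATER_MOLARITY)
  I <- if (is.null(ionic_strength)) azide else ionic_strength

  track <- spp$name[spp$role == "track"]
  sidx <- function(nm) match(nm, track) - 1L  # 0-based track index
  z <- function(nm) spp$charge[match(nm, spp$name)]
  D <- function(nm) diffusion_nm2ps(spp$D_cm2s[match(nm, spp$name)])

  pc <- list(a = integer(0), b = integer(0), R = numeric(0),
             D = numeric(0), rid = integer(0))
  fo <- list(spec = integer(0), rate = numeric(0), rid = integer(0))
  products <- vector("list", nrow(rxn))
  for (i in seq_len(nrow(rxn))) {
    r <- rxn[i, ]
    prods <- c(r$p1, r$p2, r$p3)
    prods <- prods[!is.na(prods)]
    products[[i]] <- as.integer(sidx(prods[prods %in% track]))
    k_corr <- r$k * ionic_strength_factor(z(r$r1), z(r$r2), I)
    both_track <- r$r1 %in% track && r$r2 %in% track
    if (both_track) {
      Dm <- D(r$r1) + D(r$r2)
      pc$a <- c(pc$a, sidx(r$r1)); pc$b <- c(pc$b, sidx(r$r2))
      pc$R <- c(pc$R, k_bimolecular_nm3ps(k_corr) / (4 * pi * Dm))
      pc$D <- c(pc$D, Dm)
      pc$rid <- c(pc$rid, i - 1L)
    } else {
      bulk <- if (r$r1 %in% track) r$r2 else r$r1
      ts <- if (r$r1 %in% track) r$r1 else r$r2
      if (!ts %in% track) next  # bulk-bulk: nothing to simulate
      cb <- conc[[bulk]]
      if (is.null(cb) || is.na(cb)) {
        stop("no concentration known for bulk species ", bulk)
      }
      rate <- k_corr * cb * RATE_S_TO_PS
      if (rate > 0) {
        fo$spec <- c(fo$spec, sidx(ts))
        fo$rate <- c(fo$rate, rate)
        fo$rid <- c(fo$rid, i - 1L)
      }
    }
  }

  # interaction cutoff: largest distance at which any channel can still
  # fire with probability >= p_min within the window
  cutoff <- 1
  if (length(pc$R)) {
    for (c_i in seq_along(pc$R)) {
      R <- pc$R[c_i]; Dm <- pc$D[c_i]
      fcut <- function(r) (R / r) * erfc_((r - R) / sqrt(4 * Dm * t_end)) - p_min
      hi <- R / p_min
      cut_i <- if (fcut(hi) >= 0) hi else
        stats::uniroot(fcut, c(R * (1 + 1e-9), hi), tol = 1e-6)$root
      cutoff <- max(cutoff, cut_i)
    }
  }

  # net stoichiometry of track species per reaction (for G(t) accounting)
  S <- matrix(0L, nrow = length(track), ncol = nrow(rxn),
              dimnames = list(track, rxn$id))
  for (i in seq_len(nrow(rxn))) {
    re <- c(rxn$r1[i], rxn$r2[i])
    for (sp in re[re %in% track]) S[sp, i] <- S[sp, i] - 1L
    for (p in products[[i]]) S[p + 1L, i] <- S[p + 1L, i] + 1L
  }

  list(net = net, track = track, rxn_ids = rxn$id, reactions = rxn,
       pair = pc, fo = fo, products = products,
       D_track = diffusion_nm2ps(spp$D_cm2s[match(track, spp$name)]),
       stoich = S, cutoff = cutoff, t_end = t_end,
       azide = azide, o2 = o2, pH = pH, ionic_strength = I)
}

#' Run one IRT history
#'
#' Propagates a single 1-ps initial configuration through the IRT event
#' loop: reaction times are sampled for every reactive pair (from the
#' inter-particle distances at 1 ps) and every pseudo-first-order channel;
#' the globally earliest pending event is executed, its reactants removed,
#' products created at the diffusion-weighted contact point and given fresh
#' channels against all survivors; the loop ends when no pending event
#' precedes `t_end`. Particles born closer than the encounter radius react
#' immediately (contact rule).
#'
#' @param config a `track_config` from [generate_track()], or any list with
#'   a `particles` data.frame (`species`, `x`, `y`, `z`) and `energy` (eV).
#' @param compiled a [compile_engine()] result.
#' @param t_start start of diffusion, ps (default 1).
#' @return A list of class `irt_history`: `events` (data.frame `time`,
#'   `reaction`, `x`, `y`, `z`), `survivors` (character vector of species),
#'   `initial` (named counts at 1 ps) and `energy` (eV).
#' @export
run_history <- function(config, compiled, t_start = 1) {
  stopifnot(t_start >= 1)
  parts <- config$particles
  sp <- match(parts$species, compiled$track) - 1L
  if (anyNA(sp)) {
    stop("unknown track species: ",
         paste(unique(parts$species[is.na(sp)]), collapse = ", "))
  }
  res <- .irt_run_history_cpp(
    as.matrix(parts[, c("x", "y", "z")]), as.integer(sp),
    length(compiled$track),
    compiled$pair$a, compiled$pair$b, compiled$pair$R, compiled$pair$D,
    compiled$pair$rid,
    compiled$fo$spec, compiled$fo$rate, compiled$fo$rid,
    compiled$products, compiled$D_track,
    t_start, compiled$t_end, compiled$cutoff)
  ev <- res$events
  events <- data.frame(time = ev[, 1],
                       reaction = compiled$rxn_ids[ev[, 2]],
                       x = ev[, 3], y = ev[, 4], z = ev[, 5],
                       stringsAsFactors = FALSE)
  events <- events[order(events$time), , drop = FALSE]
  initial <- table(factor(parts$species, levels = compiled$track))
  structure(list(events = events,
                 survivors = compiled$track[res$survivors],
                 initial = c(unclass(initial)), energy = config$energy),
            class = "irt_history")
}

# per-concentration / per-mode run seed, derived from the master seed and
# the run label so that scan results do not depend on evaluation order
derive_seed <- function(master, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 1009)
  as.integer((as.numeric(master) * 48271 + h) %% 2147483647)
}

#' Simulate ensemble radiation chemical yields
#'
#' Runs `n_histories` independent track histories on freshly generated
#' initial configurations and accumulates, on a log-spaced time grid over
#' \[1 ps, `t_end`\], the G-value of every track species (100 x
#' count / deposited energy) and the cumulative extent Delta-G(t) of every
#' reaction channel, with Monte Carlo standard errors estimated from
#' batch means.
#'
#' @param mode a [track_mode()].
#' @param spur a [spur_params()].
#' @param azide,o2,pH scavenger composition (see [compile_engine()]).
#' @param n_histories number of track histories (defaults to the mode's).
#' @param seed master seed; every source of randomness derives from it.
#' @param net reaction network (default [default_network()]).
#' @param t_end end of the window, ps (default 10 us).
#' @param n_times points of the log-spaced output grid (default 120).
#' @param n_batches batches for the standard-error estimate.
#' @return An object of class `irt_yields`: list with `time` (ps), `G`
#'   (time x species matrix), `G_se`, `dG` (time x channel cumulative
#'   extents), `dG_se`, batch arrays, total `energy` (eV) and a config echo.
#' @export
simulate_yields <- function(mode, spur = spur_params(), azide = 0,
                            o2 = 2.5e-4, pH = 7, n_histories = NULL,
                            seed = 1L, net = default_network(),
                            t_end = 1e7, n_times = 120L, n_batches = 20L) {
  if (is.null(n_histories)) n_histories <- mode$n_histories
  compiled <- compile_engine(net, azide = azide, o2 = o2, pH = pH,
                             t_end = t_end)
  times <- 10^seq(0, log10(t_end), length.out = n_times)
  n_batches <- min(n_batches, n_histories)
  ntr <- length(compiled$track)
  nrx <- length(compiled$rxn_ids)

  E_b <- numeric(n_batches)
  N0_b <- matrix(0, n_batches, ntr, dimnames = list(NULL, compiled$track))
  B_b <- array(0, c(n_batches, n_times, nrx))  # per-bin channel counts

  set.seed(seed)
  for (h in seq_len(n_histories)) {
    b <- ((h - 1L) %% n_batches) + 1L
    cfg <- generate_track(mode, spur)
    hist <- run_history(cfg, compiled)
    E_b[b] <- E_b[b] + cfg$energy
    N0_b[b, ] <- N0_b[b, ] + hist$initial
    if (nrow(hist$events)) {
      ri <- match(hist$events$reaction, compiled$rxn_ids)
      # an event at time t contributes to the first grid point >= t
      ti <- findInterval(hist$events$time, times, left.open = TRUE) + 1L
      ti[ti > n_times] <- n_times
      inc <- tabulate(ti + (ri - 1L) * n_times, nbins = n_times * nrx)
      B_b[b, , ] <- B_b[b, , ] + matrix(inc, n_times, nrx)
    }
  }

  S <- compiled$stoich
  G_batch <- array(0, c(n_batches, n_times, ntr),
                   dimnames = list(NULL, NULL, compiled$track))
  dG_batch <- array(0, c(n_batches, n_times, nrx),
                    dimnames = list(NULL, NULL, compiled$rxn_ids))
  for (b in seq_len(n_batches)) {
    Cb <- apply(matrix(B_b[b, , ], n_times, nrx), 2, cumsum)
    Cb <- matrix(Cb, n_times, nrx)
    counts <- matrix(N0_b[b, ], n_times, ntr, byrow = TRUE) + Cb %*% t(S)
    G_batch[b, , ] <- 100 * counts / E_b[b]
    dG_batch[b, , ] <- 100 * Cb / E_b[b]
  }
  totE <- sum(E_b)
  wb <- E_b / totE
  agg <- function(A) apply(A, c(2, 3), function(v) sum(v * wb))
  se <- function(A) apply(A, c(2, 3), stats::sd) / sqrt(n_batches)
  G <- agg(G_batch); G_se <- se(G_batch)
  dG <- agg(dG_batch); dG_se <- se(dG_batch)
  colnames(G) <- colnames(G_se) <- compiled$track
  colnames(dG) <- colnames(dG_se) <- compiled$rxn_ids

  structure(list(time = times, species = compiled$track,
                 channels = compiled$rxn_ids,
                 G = G, G_se = G_se, dG = dG, dG_se = dG_se,
                 G_batch = G_batch, dG_batch = dG_batch,
                 energy = totE, n_histories = n_histories,
                 config = list(mode = mode, spur = spur, azide = azide,
                               o2 = o2, pH = pH, seed = seed,
                               t_end = t_end, n_times = n_times)),
            class = "irt_yields")
}

#' @export
print.irt_yields <- function(x, ...) {
  cat(sprintf("IRT yield ensemble: %d histories (%s mode), %.3g eV total\n",
              x$n_histories, x$config$mode$mode, x$energy))
  cat(sprintf("  azide %.4g M, O2 %.4g M, pH %.3g, window %.4g-%.4g ps\n",
              x$config$azide, x$config$o2, x$config$pH,
              x$time[1], x$time[length(x$time)]))
  gh2 <- x$G[, "H2"]
  cat(sprintf("  G(H2): %.3f at 1 ps -> %.3f at the end of the window\n",
              gh2[1], gh2[length(gh2)]))
  invisible(x)
}
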
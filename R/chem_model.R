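# Reaction network for the radiolysis of water and aqueous azide at 25 C.
#
# Species roles:
#   "track"       -- an explicit particle followed by the IRT engine
#   "bulk"        -- a homogeneously distributed solute present at a fixed
#                    concentration; consumed/produced only as bookkeeping and
#                    reacting with track species as pseudo-first-order channels
#   "bookkeeping" -- the solvent (H2O); appears in reaction stoichiometry for
#                    balance checks only (column n_water of the reaction table)

#' Default species table
#'
#' Species of the azide / water radiolysis system with their charges,
#' diffusion coefficients at 25 C (cm^2 s^-1) and elemental composition
#' (H, O, N) used for balance checks. The azide anion and the azide
#' radical share the same diffusion coefficient, 1.84e-5 cm^2 s^-1.
#'
#' @return A data.frame with columns `name`, `charge`, `D_cm2s`,
#'   `nH`, `nO`, `nN`, `role`.
#' @export
default_species <- function() {
  s <- function(name, charge, D, nH, nO, nN, role) {
    data.frame(name = name, charge = charge, D_cm2s = D,
               nH = nH, nO = nO, nN = nN, role = role,
               stringsAsFactors = FALSE)
  }
  rbind(
    s("e_aq-", -1L, 4.90e-5, 0L, 0L, 0L, "track"),
    s("H",      0L, 7.00e-5, 1L, 0L, 0L, "track"),
    s("OH",     0L, 2.20e-5, 1L, 1L, 0L, "track"),
    s("H2",     0L, 4.80e-5, 2L, 0L, 0L, "track"),
    s("H2O2",   0L, 2.30e-5, 2L, 2L, 0L, "track"),
    s("H3O+",   1L, 9.46e-5, 3L, 1L, 0L, "track"),
    s("OH-",   -1L, 5.27e-5, 1L, 1L, 0L, "track"),
    s("O2-",   -1L, 1.75e-5, 0L, 2L, 0L, "track"),
    s("HO2",    0L, 2.30e-5, 1L, 2L, 0L, "track"),
    s("N3",     0L, 1.84e-5, 0L, 0L, 3L, "track"),
    s("HN3-",  -1L, 1.84e-5, 1L, 0L, 3L, "track"),
    s("N6-",   -1L, 1.84e-5, 0L, 0L, 6L, "track"),
    s("N2",     0L, 4.80e-5, 0L, 0L, 2L, "track"),
    s("O2",     0L, 2.40e-5, 0L, 2L, 0L, "bulk"),
    s("N3-",   -1L, 1.84e-5, 0L, 0L, 3L, "bulk"),
    s("HN3",    0L, 1.84e-5, 1L, 0L, 3L, "bulk"),
    s("H2O",    0L, 2.30e-5, 2L, 1L, 0L, "bookkeeping")
  )
}

# One reaction row. Products beyond p1..p3 are not needed; `n_water` is the
# net number of solvent molecules consumed (negative = produced), used only
# for element/charge balance. `sink = TRUE` marks channels whose products the
# literature leaves unspecified ("products (!= H2)"); they are terminal and
# excluded from balance checks.
rx <- function(id, r1, r2, k, p1 = NA, p2 = NA, p3 = NA, n_water = 0L,
               sink = FALSE, enabled = TRUE) {
  data.frame(id = id, r1 = r1, r2 = r2, k = k,
             p1 = p1, p2 = p2, p3 = p3, n_water = as.integer(n_water),
             sink = sink, enabled = enabled, stringsAsFactors = FALSE)
}

default_reactions <- function() {
  rbind(
    # H2-forming radical-radical combinations of the chemical stage
    rx("R1",  "e_aq-", "H",     2.5e10, "H2",  "OH-",          n_water = 1L),
    rx("R2",  "e_aq-", "e_aq-", 6.2e9,  "H2",  "OH-", "OH-",   n_water = 2L),
    rx("R3",  "H",     "H",     4.6e9,  "H2"),
    # azide anion chemistry (k5 is an upper bound, used as the default)
    rx("R4",  "N3-",   "H",     3.15e9, "HN3-"),
    rx("R5",  "N3-",   "e_aq-", 1.5e6,  sink = TRUE),
    # in-track proton transfer N3- + H3O+ <-> HN3; static speciation is used
    # by default, so this explicit channel ships disabled
    rx("R6",  "N3-",   "H3O+",  1.0e10, "HN3", n_water = -1L, enabled = FALSE),
    # hydrazoic acid chemistry (fed by the equilibrium HN3 fraction)
    rx("R7",  "HN3",   "e_aq-", 1.2e10, "HN3-"),
    rx("R8",  "HN3",   "H",     6.3e7,  sink = TRUE),
    rx("R9",  "N3-",   "OH",    1.2e10, "N3",  "OH-"),
    rx("R10", "HN3",   "OH",    1.0e7,  "N3",  n_water = -1L),
    # azide radical chemistry (k13 is an upper bound, used as the default)
    rx("R11", "N3",    "e_aq-", 2.4e10, "N3-"),
    rx("R12", "N3",    "H",     1.0e10, "HN3"),
    rx("R13", "N3",    "H2O2",  5.0e6,  sink = TRUE),
    rx("R14", "N3",    "N3",    3.9e9,  "N2", "N2", "N2"),
    rx("R15", "N3",    "N3-",   2.4e5,  "N6-"),
    rx("R16", "N3",    "O2-",   1.2e10, "O2", "N3-"),
    # electron + water, written bimolecular with the solvent as the partner
    rx("R17", "e_aq-", "H2O",   19,     "H",  "OH-"),
    # pure-water background set (Buxton / Elliot-Bartels 25 C compilations)
    rx("W1",  "OH",    "OH",    5.5e9,  "H2O2"),
    rx("W2",  "OH",    "e_aq-", 3.5e10, "OH-"),
    rx("W3",  "OH",    "H",     7.0e9,  n_water = -1L),
    rx("W4",  "e_aq-", "H2O2",  1.1e10, "OH", "OH-"),
    rx("W5",  "H",     "H2O2",  9.0e7,  "OH", n_water = -1L),
    rx("W6",  "e_aq-", "H3O+",  2.3e10, "H",  n_water = -1L),
    rx("W7",  "H3O+",  "OH-",   1.43e11, n_water = -2L),
    rx("W8",  "e_aq-", "O2",    1.9e10, "O2-"),
    rx("W9",  "H",     "O2",    2.1e10, "HO2"),
    rx("W10", "OH",    "H2",    4.2e7,  "H",  n_water = -1L),
    rx("W11", "OH",    "H2O2",  2.7e7,  "HO2", n_water = -1L)
  )
}

#' Construct the default azide / water reaction network
#'
#' Builds the 25 C reaction network: the three H2-forming radical-radical
#' combinations (e_aq- + H, e_aq- + e_aq-, H + H), the azide and hydrazoic
#' acid scavenging set including the azide radical chemistry, the
#' electron + water channel, and a pure-water background set. Rate constants
#' printed in the literature only as bounds (R5, R10, R13) default to the
#' bound value; the forward proton-transfer constant for N3- + H3O+ is set
#' to 1e10 M^-1 s^-1, the upper (diffusion-controlled) end of its reported
#' range. Any constant can be overridden.
#'
#' @param k_overrides optional named numeric vector of rate-constant
#'   overrides, names matching reaction ids (e.g. `c(R5 = 1e6)`).
#' @param extra_reactions optional data.frame of additional reactions in the
#'   same layout as the default table (see [default_species()] for names).
#' @param species optional replacement species table.
#' @return An object of class `irt_network`: a list with elements
#'   `species`, `reactions`, `pKa` (named, `HN3` = 4.7) and `temperature`.
#' @examples
#' net <- default_network()
#' subset(net$reactions, id == "R4")$k  # 3.15e9
#' @export
default_network <- function(k_overrides = NULL, extra_reactions = NULL,
                            species = NULL) {
  spp <- if (is.null(species)) default_species() else species
  rxn <- default_reactions()
  if (!is.null(extra_reactions)) rxn <- rbind(rxn, extra_reactions)
  if (!is.null(k_overrides)) {
    bad <- setdiff(names(k_overrides), rxn$id)
    if (length(bad)) stop("unknown reaction id(s): ", paste(bad, collapse = ", "))
    rxn$k[match(names(k_overrides), rxn$id)] <- unname(k_overrides)
  }
  net <- structure(list(species = spp, reactions = rxn,
                        pKa = c(HN3 = 4.7), temperature = 25),
                   class = "irt_network")
  validate_network(net)
  net
}

#' Build a custom reaction network
#'
#' Lower-level constructor used for test systems and model variants.
#'
#' @param species species data.frame (columns as in [default_species()]).
#' @param reactions reaction data.frame (columns as in the default network).
#' @param pKa named numeric vector of acid dissociation constants.
#' @return An `irt_network` object.
#' @export
irt_network <- function(species, reactions, pKa = c(HN3 = 4.7)) {
  net <- structure(list(species = species, reactions = reactions,
                        pKa = pKa, temperature = 25),
                   class = "irt_network")
  validate_network(net)
  net
}

#' Validate a reaction network
#'
#' Checks that every reactant/product resolves to a declared species, that
#' reaction ids are unique, that rate constants and diffusion coefficients
#' are positive, and that every reaction with fully specified products
#' conserves H, O and N atom counts and total charge (solvent molecules in
#' `n_water` included). Sink reactions are excluded from balance checks.
#'
#' @param net an `irt_network`.
#' @return `net`, invisibly; errors on any violation.
#' @export
validate_network <- function(net) {
  spp <- net$species
  rxn <- net$reactions
  if (anyDuplicated(rxn$id)) stop("duplicate reaction ids")
  if (anyDuplicated(spp$name)) stop("duplicate species names")
  if (any(spp$D_cm2s <= 0)) stop("non-positive diffusion coefficient")
  if (any(spp[c("nH", "nO", "nN")] < 0)) stop("negative element counts")
  if (any(rxn$k <= 0)) stop("non-positive rate constant")
  nm <- c(rxn$r1, rxn$r2, rxn$p1, rxn$p2, rxn$p3)
  nm <- nm[!is.na(nm)]
  unknown <- setdiff(nm, spp$name)
  if (length(unknown)) stop("unresolved species: ", paste(unknown, collapse = ", "))

  prop <- function(names, col) {
    v <- spp[[col]][match(names, spp$name)]
    sum(v[!is.na(names)], na.rm = TRUE)
  }
  for (i in seq_len(nrow(rxn))) {
    r <- rxn[i, ]
    if (isTRUE(r$sink)) next
    re <- c(r$r1, r$r2)
    pr <- c(r$p1, r$p2, r$p3)
    for (col in c("nH", "nO", "nN", "charge")) {
      w <- if (col == "nH") 2L else if (col == "nO") 1L else 0L  # H2O content
      lhs <- prop(re, col) + max(r$n_water, 0L) * w
      rhs <- prop(pr, col) + max(-r$n_water, 0L) * w
      if (lhs != rhs) {
        stop(sprintf("reaction %s unbalanced in %s (%d vs %d)",
                     r$id, col, lhs, rhs))
      }
    }
  }
  invisible(net)
}

#' Encounter distance from an observed rate constant
#'
#' Converts an observed bimolecular rate constant into the geometric
#' parameters of the IRT first-passage kernels. For a fully
#' diffusion-controlled reaction this is the Smoluchowski inversion
#' \eqn{R = k_{obs} / (4 \pi N_A D)}. For a partially diffusion-controlled
#' reaction the encounter distance is computed from the intrinsic
#' (activation-limited) constant `k_act` via the Collins-Kimball relation
#' \eqn{1/k_{obs} = 1/k_{act} + 1/k_{diff}}, and the radiation
#' boundary-condition velocity \eqn{v = k_{act} / (4 \pi R^2 N_A)} is
#' returned alongside.
#'
#' @param k_obs observed rate constant, M^-1 s^-1.
#' @param D_mutual mutual diffusion coefficient (sum over the pair), cm^2 s^-1.
#' @param model `"diffusion"` (fully diffusion-controlled, default) or
#'   `"partial"`.
#' @param k_act intrinsic rate constant, M^-1 s^-1 (required for
#'   `model = "partial"`; must exceed `k_obs`).
#' @return For `"diffusion"`, the encounter radius in nm. For `"partial"`,
#'   a list with elements `R` (nm) and `v` (nm/ps).
#' @examples
#' encounter_radius(2.5e10, 4.9e-5 + 7.0e-5)  # e_aq- + H, ~0.28 nm
#' @export
encounter_radius <- function(k_obs, D_mutual,
                             model = c("diffusion", "partial"),
                             k_act = NULL) {
  model <- match.arg(model)
  stopifnot(k_obs > 0, D_mutual > 0)
  D <- diffusion_nm2ps(D_mutual)
  if (model == "diffusion") {
    return(k_bimolecular_nm3ps(k_obs) / (4 * pi * D))
  }
  if (is.null(k_act)) stop("k_act required for the partially controlled model")
  if (k_act <= k_obs) {
    stop("unphysical: k_act must exceed k_obs (k_obs = k_act*k_diff/(k_act+k_diff))")
  }
  k_diff <- k_obs * k_act / (k_act - k_obs)
  R <- k_bimolecular_nm3ps(k_diff) / (4 * pi * D)
  v <- k_bimolecular_nm3ps(k_act) / (4 * pi * R^2)
  list(R = R, v = v)
}

#' Ionic-strength correction factor for reactions between ions
#'
#' Bronsted-Bjerrum / extended Debye-Hueckel factor at 25 C,
#' \eqn{\log_{10} f = 1.02\, z_A z_B \sqrt{I} / (1 + \sqrt{I})}, applied
#' multiplicatively to the zero-ionic-strength rate constant. Equal to 1
#' when either reactant is neutral or when I = 0; > 1 for like charges,
#' < 1 for unlike charges.
#'
#' @param zA,zB reactant charges (elementary charges).
#' @param I ionic strength, M (must be >= 0).
#' @return Dimensionless multiplier `f` such that `k(I) = f * k(0)`.
#' @export
ionic_strength_factor <- function(zA, zB, I) {
  if (any(I < 0)) stop("negative ionic strength")
  10^(1.02 * zA * zB * sqrt(I) / (1 + sqrt(I)))
}

#' Fraction of total azide present as hydrazoic acid
#'
#' Henderson-Hasselbalch speciation of the HN3 / N3- couple
#' (pKa = 4.7 in water at 25 C): fraction HN3 = 1 / (1 + 10^(pH - pKa)).
#' At neutral pH the azide is almost entirely in the anion form
#' (fraction HN3 ~ 0.5%).
#'
#' @param pH solution pH in \[0, 14\].
#' @param pKa acid dissociation constant (default 4.7).
#' @return Fraction in \[0, 1\].
#' @export
hn3_fraction <- function(pH, pKa = 4.7) {
  stopifnot(pH >= 0, pH <= 14)
  1 / (1 + 10^(pH - pKa))
}

#' Scavenging capacity of a solute
#'
#' The pseudo-first-order rate `k * conc` (s^-1) at which a homogeneously
#' distributed solute removes a track species; its reciprocal is the
#' scavenging time.
#'
#' @param k bimolecular rate constant, M^-1 s^-1.
#' @param conc solute concentration, M.
#' @return Rate in s^-1.
#' @export
scavenging_capacity <- function(k, conc) {
  stopifnot(k > 0, all(conc >= 0))
  k * conc
}

#' Write / read a reaction network as a YAML config block
#'
#' Plain-text serialization of the species and reaction tables; the
#' round trip `read(write(net))` reproduces the network.
#'
#' @param net an `irt_network`.
#' @param path file path.
#' @return `read_network_yaml()` returns an `irt_network`.
#' @export
write_network_yaml <- function(net, path) {
  obj <- list(
    temperature = net$temperature,
    pKa = as.list(net$pKa),
    species = lapply(seq_len(nrow(net$species)), function(i) as.list(net$species[i, ])),
    reactions = lapply(seq_len(nrow(net$reactions)), function(i) {
      r <- as.list(net$reactions[i, ])
      r[!vapply(r, function(x) is.na(x) || identical(x, ""), logical(1))]
    })
  )
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' @rdname write_network_yaml
#' @export
read_network_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  spp <- do.call(rbind, lapply(obj$species, function(s) {
    data.frame(name = s$name, charge = as.integer(s$charge),
               D_cm2s = s$D_cm2s, nH = as.integer(s$nH),
               nO = as.integer(s$nO), nN = as.integer(s$nN),
               role = s$role, stringsAsFactors = FALSE)
  }))
  rxn <- do.call(rbind, lapply(obj$reactions, function(r) {
    rx(r$id, r$r1, r$r2, r$k,
       p1 = if (is.null(r$p1)) NA else r$p1,
       p2 = if (is.null(r$p2)) NA else r$p2,
       p3 = if (is.null(r$p3)) NA else r$p3,
       n_water = if (is.null(r$n_water)) 0L else r$n_water,
       sink = isTRUE(r$sink), enabled = !isFALSE(r$enabled))
  }))
  irt_network(spp, rxn, pKa = unlist(obj$pKa))
}
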
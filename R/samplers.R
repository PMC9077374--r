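# First-passage samplers of the IRT method. All arguments are in
# simulation units (nm, ps, nm^2/ps); rate constants enter only through
# the encounter geometry computed by encounter_radius().

#' Sample a diffusion-controlled pair reaction time
#'
#' Inverts the Smoluchowski pair reaction-time law
#' \deqn{P(T \le t) = (R/r)\, \mathrm{erfc}\!\left[(r - R)/\sqrt{4 D t}\right].}
#' With probability \eqn{1 - R/r} the pair never reacts (`Inf` is
#' returned); otherwise the reaction time is
#' \eqn{t = (r - R)^2 / \{4 D\, [\mathrm{erfc}^{-1}(u\, r/R)]^2\}}.
#'
#' @param r initial separation, nm (must be >= R; overlapping initial
#'   placements are resolved by the caller's contact rule).
#' @param R encounter radius, nm.
#' @param D mutual diffusion coefficient, nm^2/ps.
#' @param u uniform(0,1) variate(s).
#' @return Reaction time(s) in ps; `Inf` for a non-reactive draw, `0` at
#'   contact (`r == R`).
#' @export
sample_pair_time <- function(r, R, D, u) {
  stopifnot(D > 0, all(u > 0), all(u < 1), R > 0)
  if (any(r < R)) stop("r < R: resolve overlapping pairs with the contact rule")
  n <- max(length(r), length(u))
  r <- rep_len(r, n); u <- rep_len(u, n)
  out <- rep(Inf, n)
  hit <- u < R / r
  at <- hit & r == R
  out[at] <- 0
  go <- hit & r > R
  out[go] <- (r[go] - R)^2 / (4 * D * erfcinv_(u[go] * r[go] / R)^2)
  out
}

# scaled complementary error function, stable for arbitrarily large z
erfcx_ <- function(z) {
  out <- numeric(length(z))
  big <- z > 25
  out[!big] <- pracma::erfcx(z[!big])
  zb <- z[big]  # asymptotic series: 1/(z sqrt(pi)) (1 - 1/(2z^2) + 3/(4z^4))
  out[big] <- (1 - 0.5 / zb^2 + 0.75 / zb^4) / (zb * sqrt(pi))
  out
}

# Reaction probability by time t under the radiation boundary condition
# (Collins-Kimball kernel) with encounter velocity v at radius R:
#   Q(t) = (R/r) * vR/(D+vR) * [erfc(x) - exp(-x^2) * erfcx(x + a*sqrt(Dt))]
# with x = (r-R)/sqrt(4Dt), a = (1 + vR/D)/R. The exp(-x^2)*erfcx form is
# the numerically stable rewriting of exp(a(r-R) + a^2 Dt) erfc(x + a sqrt(Dt)).
ck_reaction_prob <- function(t, r, R, v, D) {
  a <- (1 + v * R / D) / R
  amp <- (R / r) * (v * R / (D + v * R))
  x <- (r - R) / sqrt(4 * D * t)
  c2 <- x + a * sqrt(D * t)
  amp * (erfc_(x) - exp(-x^2) * erfcx_(c2))
}

#' Sample a partially diffusion-controlled pair reaction time
#'
#' Samples from the reaction-time distribution of the radiation
#' (Collins-Kimball) boundary condition with encounter velocity
#' \eqn{v = k_{act} / (4 \pi R^2 N_A)} (see [encounter_radius()] with
#' `model = "partial"`). The ultimate reaction probability is
#' \eqn{(R/r)\, vR/(D + vR) < R/r}; as \eqn{v \to \infty} the distribution
#' reduces to [sample_pair_time()]. Times are obtained by numeric inversion
#' of the closed-form kernel.
#'
#' @inheritParams sample_pair_time
#' @param v encounter (radiation boundary) velocity, nm/ps.
#' @return Reaction time(s) in ps, `Inf` for non-reactive draws.
#' @export
sample_pair_time_partial <- function(r, R, v, D, u) {
  stopifnot(D > 0, v > 0, R > 0, all(u > 0), all(u < 1))
  if (any(r < R)) stop("r < R: resolve overlapping pairs with the contact rule")
  n <- max(length(r), length(u))
  r <- rep_len(r, n); u <- rep_len(u, n)
  q_inf <- (R / r) * (v * R / (D + v * R))
  out <- rep(Inf, n)
  for (i in which(u < q_inf)) {
    f <- function(lt) ck_reaction_prob(10^lt, r[i], R, v, D) - u[i]
    lo <- -9; hi <- 15
    while (f(hi) < 0 && hi < 40) hi <- hi + 5
    out[i] <- 10^stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  }
  out
}

#' Sample a first-order (scavenging) reaction time
#'
#' Exponential law \eqn{t = -\ln(u)/\lambda}; `Inf` when the rate is zero.
#'
#' @param rate first-order rate, ps^-1 (>= 0).
#' @param u uniform(0,1) variate(s).
#' @return Time(s) in ps.
#' @export
sample_first_order_time <- function(rate, u) {
  stopifnot(rate >= 0, all(u > 0), all(u <= 1))
  if (rate == 0) return(rep(Inf, length(u)))
  -log(u) / rate
}

#' Position assigned to reaction products
#'
#' For a pair event the product is placed at the diffusion-weighted point
#' between the parents, \eqn{p = p_a + (p_b - p_a) D_a / (D_a + D_b)}: the
#' expected contact point lies closer to the slower parent because the
#' faster one covers more of the separation. For a first-order event the
#' product inherits the parent position.
#'
#' @param positions numeric matrix with 1 or 2 rows (parents), columns x,y,z.
#' @param D diffusion coefficients of the parents (same length as rows), nm^2/ps.
#' @return Length-3 numeric position (nm).
#' @export
product_position <- function(positions, D) {
  positions <- rbind(positions)
  if (nrow(positions) == 1) return(as.numeric(positions[1, ]))
  stopifnot(nrow(positions) == 2, length(D) == 2, all(D > 0))
  w <- D[1] / (D[1] + D[2])
  as.numeric(positions[1, ] + w * (positions[2, ] - positions[1, ]))
}
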
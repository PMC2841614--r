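#' Define a strain phenotype
#'
#' A strain is characterized by whether it secretes the public extracellular
#' enzyme (a cooperator) and at what specific rate `R_E`, together with the
#' social parameters of the enzyme benefit: cooperators constitutively pay a
#' fold growth-rate cost `C * R_E`, while any cell — cooperator or exploiter —
#' whose local enzyme concentration reaches the threshold `tau` has its growth
#' rate multiplied by the benefit factor. That asymmetry (cost unconditional,
#' benefit shared) is what makes exploitation possible.
#'
#' The benefit factor is `1 + B` by default ("increases growth rate by a fold
#' factor B"); set `benefit_mode = "times_b"` for the literal multiplication
#' by `B`, kept for sensitivity checks.
#'
#' @param name strain label (stored in snapshots).
#' @param cooperator logical; exploiters must have `R_E = 0`.
#' @param R_E specific enzyme production rate [g enzyme / g biomass / h].
#' @param B benefit fold factor [dimensionless]; default 3.
#' @param C cost scaling factor per unit `R_E`; default 0.3. `C * R_E` must be
#'   < 1 so the growth multiplier stays positive.
#' @param tau enzyme concentration threshold for the benefit [g/L]. The
#'   default 0.1 g/L is calibrated against the default [param_set()]
#'   geometry: a pure-cooperator film at `R_E = 1` holds about 2.4 g/L of
#'   enzyme through its active layer, and `tau` is set to a few percent of
#'   that level so that even a single clonal cooperator sector — producing
#'   enzyme over a small fraction of the domain width, at production rates
#'   down to `R_E = 0.5` — can trip its own benefit early in tower
#'   formation (see the methods vignette).
#' @param mu_max,K_G,Y optional strain-specific overrides of the growth
#'   constants; `NA` (default) inherits from the simulation [param_set()].
#' @param benefit_mode `"one_plus_b"` (default) or `"times_b"`.
#' @return an object of class `"strain_phenotype"`.
#' @examples
#' coop <- strain_phenotype("coop", cooperator = TRUE, R_E = 1)
#' expl <- strain_phenotype("expl")
#' @export
strain_phenotype <- function(name, cooperator = FALSE, R_E = 0, B = 3,
                             C = 0.3, tau = 0.1,
                             mu_max = NA_real_, K_G = NA_real_, Y = NA_real_,
                             benefit_mode = c("one_plus_b", "times_b")) {
  benefit_mode <- match.arg(benefit_mode)
  if (!is.character(name) || length(name) != 1 || !nzchar(name))
    stop("strain name must be a non-empty string")
  if (R_E < 0) stop("R_E must be non-negative")
  if (!cooperator && R_E > 0)
    stop("an exploiter (cooperator = FALSE) must have R_E = 0")
  if (C * R_E >= 1)
    stop("C * R_E must be < 1: the growth multiplier would not stay positive")
  if (tau <= 0) stop("tau must be positive")
  structure(list(name = name, cooperator = cooperator, R_E = R_E, B = B,
                 C = C, tau = tau, mu_max = mu_max, K_G = K_G, Y = Y,
                 benefit_mode = benefit_mode),
            class = "strain_phenotype")
}

#' @export
print.strain_phenotype <- function(x, ...) {
  cat(sprintf("<strain '%s'> %s  R_E=%g  B=%g  C=%g  tau=%g g/L (%s)\n",
              x$name, if (x$cooperator) "cooperator" else "exploiter",
              x$R_E, x$B, x$C, x$tau, x$benefit_mode))
  invisible(x)
}

# fill NA strain growth constants from the parameter set
resolve_strain <- function(strain, params) {
  for (nm in c("mu_max", "K_G", "Y"))
    if (is.na(strain[[nm]])) strain[[nm]] <- params[[nm]]
  strain
}

benefit_factor <- function(strain, E_local) {
  full <- if (strain$benefit_mode == "one_plus_b") 1 + strain$B else strain$B
  ifelse(E_local >= strain$tau, full, 1)
}

#' Specific growth rate under the cooperative Michaelis-Menten law
#'
#' `mu = mu_max * (1 - C*R_E) * benefit(E) * G / (K_G + G)`, where
#' `benefit(E)` is `1 + B` (or `B` under the literal mode) when the local
#' enzyme concentration is at or above `tau` and 1 otherwise. The cost is paid
#' by cooperators unconditionally; the benefit accrues to any strain above
#' threshold. Negative inputs are rejected; the result is always >= 0.
#'
#' @param strain a [strain_phenotype()] with resolved growth constants, or one
#'   with `NA`s plus a `params` to inherit from.
#' @param G_local local substrate concentration [g/L], vectorized.
#' @param E_local local enzyme concentration [g/L], vectorized.
#' @param params optional [param_set()] supplying `mu_max`, `K_G`, `Y` where
#'   the strain leaves them `NA`.
#' @return specific growth rate [1/h].
#' @examples
#' s <- strain_phenotype("wt")
#' specific_growth_rate(s, G_local = 0.0035, E_local = 0, params = param_set())
#' @export
specific_growth_rate <- function(strain, G_local, E_local = 0, params = NULL) {
  if (!is.null(params)) strain <- resolve_strain(strain, params)
  if (is.na(strain$mu_max) || is.na(strain$K_G))
    stop("strain growth constants unresolved: supply `params`")
  if (any(G_local < 0) || any(E_local < 0))
    stop("concentrations must be non-negative")
  mu <- strain$mu_max * (1 - strain$C * strain$R_E) *
    benefit_factor(strain, E_local) * G_local / (strain$K_G + G_local)
  pmax(mu, 0)
}

#' Substrate consumption rate of a biomass node
#'
#' Growth at specific rate `mu` consumes substrate at `mu * X / Y` (returned
#' as a positive magnitude; the solver applies it as a sink).
#'
#' @param mu specific growth rate [1/h], vectorized.
#' @param X_node biomass concentration at the node [g/L].
#' @param Y yield [dimensionless], > 0.
#' @return consumption rate [g/L/h].
#' @export
substrate_sink_rate <- function(mu, X_node, Y) {
  if (any(Y <= 0)) stop("yield Y must be positive")
  if (any(mu < 0) || any(X_node < 0)) stop("inputs must be non-negative")
  mu * X_node / Y
}

#' Enzyme production rate of a biomass node
#'
#' Cooperator biomass secretes enzyme constitutively at `R_E * X`; exploiter
#' biomass produces none.
#'
#' @param strain a [strain_phenotype()].
#' @param X_node biomass concentration at the node [g/L], vectorized.
#' @return source rate [g/L/h].
#' @export
enzyme_source_rate <- function(strain, X_node) {
  if (any(X_node < 0)) stop("biomass must be non-negative")
  if (strain$cooperator) strain$R_E * X_node else 0 * X_node
}
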
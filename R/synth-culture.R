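#' Parameters for the synthetic cultivation time-series generator
#'
#' Emulates a 10-day shake-flask cultivation of a secondary-metabolite
#' producer on 4 g/L glucose: logistic biomass growth that saturates around
#' day 2, glucose depletion coupled to growth through a yield coefficient,
#' and a delayed logistic product rise beginning between day 3 and 4.
#' Default product level (38 mg/L) corresponds to an unsupplemented
#' culture; raise `P_max` (about 95 mg/L) and `production_rate` to emulate
#' a glass-bead-supplemented condition.
#'
#' @param t_grid Strictly increasing sampling times in days.
#' @param X_max Biomass carrying capacity (g/L).
#' @param X0 Inoculum biomass (g/L).
#' @param growth_rate Logistic growth rate (1/d).
#' @param production_onset_day Day at which product formation starts.
#' @param P_max Final product concentration (mg/L).
#' @param production_rate Logistic steepness of the product rise (1/d).
#' @param glucose_init Initial glucose (g/L).
#' @param yield_coefficient Biomass yield on glucose (g/g).
#' @param noise_sd Named vector of per-channel Gaussian noise sds with
#'   entries `P` (mg/L), `X` (g/L), `S` (g/L); a single number is recycled.
#' @param seed Integer seed.
#' @return Parameter list of class `cultivation_gen_params`.
#' @export
cultivation_gen_params <- function(t_grid = 0:10, X_max = 3, X0 = 0.06,
                                   growth_rate = 3, production_onset_day = 3.5,
                                   P_max = 38, production_rate = 1,
                                   glucose_init = 4, yield_coefficient = 0.75,
                                   noise_sd = c(P = 1.5, X = 0.08, S = 0.08),
                                   seed = 1L) {
  if (length(noise_sd) == 1L) noise_sd <- c(P = noise_sd, X = noise_sd, S = noise_sd)
  stopifnot(all(diff(t_grid) > 0), X_max > 0, X0 > 0, X0 < X_max,
            growth_rate > 0, P_max >= 0, production_rate > 0,
            glucose_init >= 0, yield_coefficient > 0, all(noise_sd >= 0),
            all(c("P", "X", "S") %in% names(noise_sd)))
  structure(list(t_grid = as.numeric(t_grid), X_max = X_max, X0 = X0,
                 growth_rate = growth_rate,
                 production_onset_day = production_onset_day, P_max = P_max,
                 production_rate = production_rate, glucose_init = glucose_init,
                 yield_coefficient = yield_coefficient, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "cultivation_gen_params")
}

# Noise-free model curves on an arbitrary time grid.
cultivation_model <- function(params, t = params$t_grid) {
  p <- params
  X <- p$X_max / (1 + ((p$X_max - p$X0) / p$X0) * exp(-p$growth_rate * t))
  t_half <- p$production_onset_day + 2 / p$production_rate
  L <- function(tt) 1 / (1 + exp(-p$production_rate * (tt - t_half)))
  L0 <- L(p$production_onset_day)
  P <- p$P_max * pmax(0, (L(t) - L0) / (1 - L0))
  S <- pmax(0, p$glucose_init - (X - p$X0) / p$yield_coefficient)
  list(t = t, P = P, X = X, S = S)
}

#' Generate a synthetic cultivation time series
#'
#' Evaluates the logistic growth / delayed production / yield-coupled
#' glucose model on the parameter grid, adds seeded per-channel Gaussian
#' noise and clips concentrations at zero.
#'
#' @param params A [cultivation_gen_params()] list.
#' @param condition Condition label stored with the series.
#' @return A [cultivation_series()] data frame.
#' @export
generate_cultivation_series <- function(params, condition = "synthetic") {
  stopifnot(inherits(params, "cultivation_gen_params"))
  m <- cultivation_model(params)
  p <- params
  local_seed(p$seed, {
    n <- length(m$t)
    P <- pmax(0, m$P + stats::rnorm(n, 0, p$noise_sd[["P"]]))
    X <- pmax(0, m$X + stats::rnorm(n, 0, p$noise_sd[["X"]]))
    S <- pmax(0, m$S + stats::rnorm(n, 0, p$noise_sd[["S"]]))
    cultivation_series(m$t, P, X, S, condition = condition)
  })
}
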
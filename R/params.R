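#' Physical constants for Boltzmann-Arrhenius rate scaling
#'
#' Bundle of the two constants entering the temperature dependence of
#' metabolic rates: the Boltzmann constant (in eV/K, so activation energies
#' are carried in eV) and the reference absolute temperature about which
#' rates are expanded. The reference is the water freezing point, 273 K;
#' temperatures elsewhere in the package are degrees Celsius above it.
#'
#' @param boltzmann_k Boltzmann constant, eV/K.
#' @param t_a Reference absolute temperature, K.
#' @return An object of class `thermal_constants`.
#' @examples
#' thermal_constants()
#' @export
thermal_constants <- function(boltzmann_k = 8.617e-5, t_a = 273) {
  stopifnot(is.numeric(boltzmann_k), length(boltzmann_k) == 1L,
            is.finite(boltzmann_k), boltzmann_k > 0,
            is.numeric(t_a), length(t_a) == 1L, is.finite(t_a), t_a > 0)
  structure(list(boltzmann_k = boltzmann_k, t_a = t_a),
            class = "thermal_constants")
}

#' Ontogenetic growth-law parameters
#'
#' Parameters of the quarter-power growth equation
#' \deqn{dm/dt = a\, m^{z} \left[1 - (m/M)^{1-z}\right]}
#' with `z = 3/4` by default. The rate coefficient `a` carries the
#' temperature dependence through a Boltzmann factor with activation energy
#' `E` (for whole-body growth) or `E'` (for growth of the neural system).
#' Optionally `a` can be derived from its metabolic provenance
#' `a = B0 * m_c / E_c` (normalisation of the metabolic rate, cell mass,
#' energy to build a cell).
#'
#' @param base_rate Growth-rate coefficient `a` at the reference absolute
#'   temperature, in mass^(1-z) per unit time.
#' @param activation_energy Activation energy of the rate-limiting reaction,
#'   eV.
#' @param asymptotic_mass Asymptotic (adult) mass `M`.
#' @param initial_mass Mass at the start of growth, `0 <= m0 < M`.
#' @param exponent Allometric exponent `z` in (0, 1); 3/4 for the
#'   quarter-power law.
#' @param cell_mass,cell_energy,metabolic_norm Optional provenance of
#'   `base_rate`; if all three are given, `base_rate` is computed as
#'   `metabolic_norm * cell_mass / cell_energy` and must not also be supplied.
#' @return An object of class `growth_params`.
#' @examples
#' growth_params(base_rate = 1, activation_energy = 0.822, asymptotic_mass = 1)
#' @export
growth_params <- function(base_rate = NULL, activation_energy,
                          asymptotic_mass, initial_mass = 0,
                          exponent = 3 / 4,
                          cell_mass = NULL, cell_energy = NULL,
                          metabolic_norm = NULL) {
  provenance <- !vapply(list(cell_mass, cell_energy, metabolic_norm),
                        is.null, logical(1))
  if (any(provenance)) {
    if (!all(provenance))
      stop("cell_mass, cell_energy and metabolic_norm must be given together",
           call. = FALSE)
    if (!is.null(base_rate))
      stop("give either base_rate or its provenance fields, not both",
           call. = FALSE)
    base_rate <- metabolic_norm * cell_mass / cell_energy
  }
  stopifnot(is.numeric(base_rate), is.finite(base_rate), base_rate > 0,
            is.numeric(activation_energy), is.finite(activation_energy),
            activation_energy > 0,
            is.finite(asymptotic_mass), asymptotic_mass > 0,
            is.finite(initial_mass), initial_mass >= 0,
            initial_mass < asymptotic_mass,
            is.finite(exponent), exponent > 0, exponent < 1)
  structure(list(base_rate = base_rate,
                 activation_energy = activation_energy,
                 asymptotic_mass = asymptotic_mass,
                 initial_mass = initial_mass,
                 exponent = exponent,
                 cell_mass = cell_mass, cell_energy = cell_energy,
                 metabolic_norm = metabolic_norm),
            class = "growth_params")
}

#' Macroscopic scaling factors for fold-change laws
#'
#' The exponential scaling factors (per degree Celsius) governing fold
#' changes relative to a reference temperature `T0`:
#' developmental time follows \eqn{t/t_0 = e^{-\alpha (T - T_0)}} and the
#' number of synaptic partners follows \eqn{n/n_0 = e^{-\beta (T - T_0)}}.
#' The derived factor \eqn{\gamma = \alpha - \beta/4} is the scaling of the
#' brain's own growth rate and drives the temperature-cycle predictions.
#'
#' @param alpha Scaling factor of developmental time, per degree C.
#' @param beta Scaling factor of synaptic connectivity, per degree C.
#' @param ref_temp Reference temperature `T0`, degrees C, in `[10, 35]`.
#' @param constants [thermal_constants()] used to convert factors to
#'   activation energies.
#' @return An object of class `scaling_params` with fields `alpha`, `beta`,
#'   `gamma`, `ref_temp`, `delta_e` (the activation-energy difference
#'   `E - E'` in eV implied by `beta`).
#' @examples
#' scaling_params(alpha = 0.128, beta = 0.133)
#' @export
scaling_params <- function(alpha, beta, ref_temp = 25,
                           constants = thermal_constants()) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(beta), length(beta) == 1L, is.finite(beta),
            is.numeric(ref_temp), length(ref_temp) == 1L,
            ref_temp >= 10, ref_temp <= 35,
            inherits(constants, "thermal_constants"))
  kta2 <- constants$boltzmann_k * constants$t_a^2
  structure(list(alpha = alpha, beta = beta, gamma = alpha - beta / 4,
                 ref_temp = ref_temp, delta_e = beta * kta2 / 4,
                 constants = constants),
            class = "scaling_params")
}

#' @export
print.scaling_params <- function(x, ...) {
  cat(sprintf(
    "Scaling factors (per degree C): alpha = %.4g, beta = %.4g, gamma = %.4g\n",
    x$alpha, x$beta, x$gamma))
  cat(sprintf("Reference temperature T0 = %g C; delta E = %.4g eV\n",
              x$ref_temp, x$delta_e))
  invisible(x)
}

#' Read scaling parameters from a YAML or JSON config file
#'
#' The file must contain at least `alpha` and `beta`; `ref_temp`,
#' `boltzmann_k` and `t_a` are optional and default to 25 C, 8.617e-5 eV/K
#' and 273 K.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [scaling_params()] object.
#' @export
read_scaling_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$alpha) || is.null(cfg$beta))
    stop("config must provide 'alpha' and 'beta'", call. = FALSE)
  constants <- thermal_constants(
    boltzmann_k = cfg$boltzmann_k %||% 8.617e-5,
    t_a = cfg$t_a %||% 273)
  scaling_params(alpha = cfg$alpha, beta = cfg$beta,
                 ref_temp = cfg$ref_temp %||% 25, constants = constants)
}

#' Export a result with parameter provenance as JSON
#'
#' @param result A named list or one-row data frame of results.
#' @param scaling The [scaling_params()] the result was computed with.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_result_json <- function(result, scaling, path) {
  stopifnot(inherits(scaling, "scaling_params"))
  payload <- list(
    result = result,
    params = list(alpha = scaling$alpha, beta = scaling$beta,
                  gamma = scaling$gamma, ref_temp = scaling$ref_temp,
                  delta_e = scaling$delta_e,
                  boltzmann_k = scaling$constants$boltzmann_k,
                  t_a = scaling$constants$t_a),
    package_version = as.character(utils::packageVersion("thermowire")))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
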
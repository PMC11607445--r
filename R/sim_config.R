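#' Configuration for the synthetic sepsis EHR simulator
#'
#' Defines the generative model for a confounded, irregularly sampled synthetic
#' ICU cohort with known counterfactual ground truth. Latent sepsis severity
#' follows a mean-reverting (Ornstein--Uhlenbeck type) diffusion in SOFA units
#' with an additive per-treatment-option drift; side-effect labs integrate a
#' severity coupling plus antibiotic-specific toxicity drifts. Treatment is
#' assigned at fixed decision times by a softmax policy over the six candidate
#' options (three antibiotics alone or in pairs) whose score depends on the
#' current SOFA and creatinine values, which induces time-dependent
#' confounding.
#'
#' @param n_patients Number of patients to simulate.
#' @param horizon_h Simulation horizon in hours.
#' @param dt_h Euler--Maruyama step in hours.
#' @param latent_noise_sd Diffusion scale of latent severity (SOFA units per
#'   square-root hour).
#' @param lab_noise_sd Named vector of diffusion scales for the side-effect
#'   labs (lab units per square-root hour).
#' @param pathogen_class_probs Probability vector over the pathogen classes
#'   `gram_pos`, `gram_neg`, `mixed`, `fungal`, `viral`; must sum to 1.
#' @param efficacy_matrix Antibiotic-by-pathogen-class severity drift in SOFA
#'   units per hour; entries are non-positive for effective pairs and zero for
#'   the fungal/viral columns (antibiotics do not treat those pathogens).
#' @param toxicity Named list mapping an antibiotic to a named vector of lab
#'   drifts (lab units per hour) active while the antibiotic is administered.
#' @param policy_temperature Softmax temperature of the treatment-assignment
#'   policy; larger values give a more uniform (less confounded) policy.
#' @param obs_rates Named vector of expected observations per hour per
#'   variable (Poisson sampling processes).
#' @param missing_frac Fraction of drawn observations discarded at random
#'   (missingness on top of irregular sampling).
#' @param resistance_prob Probability that a bacterial culture reports
#'   resistance against one randomly chosen antibiotic.
#' @param mean_reversion Mean-reversion rate of latent severity (per hour).
#' @param severity_setpoint Severity value toward which untreated patients
#'   revert (natural recovery tendency), in SOFA units.
#' @param sev_coupling Named vector: drift of each lab per hour per SOFA unit
#'   of excess severity above `sev_coupling_ref`.
#' @param sev_coupling_ref Severity reference for the lab coupling.
#' @param class_lab_shift Named list per pathogen class of additive shifts to
#'   baseline lab levels; makes the pathogen class partially observable
#'   through admission labs.
#' @param seed Integer seed; identical configurations (including the seed)
#'   reproduce bit-identical cohorts.
#'
#' @return An object of class `sim_config` (a list).
#' @export
sim_config <- function(n_patients = 500L,
                       horizon_h = 96,
                       dt_h = 0.25,
                       latent_noise_sd = 0.35,
                       lab_noise_sd = c(creatinine = 0.012,
                                        bilirubin_total = 0.015,
                                        alanine_transaminase = 1.2),
                       pathogen_class_probs = c(gram_pos = 0.45, gram_neg = 0.25,
                                                mixed = 0.15, fungal = 0.10,
                                                viral = 0.05),
                       efficacy_matrix = default_efficacy_matrix(),
                       toxicity = list(
                         Vancomycin = c(creatinine = 0.010),
                         Ceftriaxone = c(bilirubin_total = 0.012,
                                         alanine_transaminase = 1.2)
                       ),
                       policy_temperature = 1,
                       obs_rates = c(sofa = 1, creatinine = 1 / 6,
                                     bilirubin_total = 1 / 8,
                                     alanine_transaminase = 1 / 8,
                                     anion_gap = 1 / 4, chloride = 1 / 4,
                                     lactate = 1 / 6),
                       missing_frac = 0.15,
                       resistance_prob = 0.10,
                       mean_reversion = 0.02,
                       severity_setpoint = 4,
                       sev_coupling = c(creatinine = 0.002,
                                        bilirubin_total = 0.003,
                                        alanine_transaminase = 0.30,
                                        anion_gap = 0.06,
                                        lactate = 0.015),
                       sev_coupling_ref = 8,
                       class_lab_shift = list(
                         gram_pos = c(creatinine = 0.4),
                         gram_neg = c(bilirubin_total = 0.7,
                                      alanine_transaminase = 35),
                         mixed = c(creatinine = 0.3, bilirubin_total = 0.5,
                                   alanine_transaminase = 25)
                       ),
                       seed = 1L) {
  if (!is.numeric(n_patients) || n_patients < 1) {
    stop("`n_patients` must be a positive count.", call. = FALSE)
  }
  if (!is.numeric(horizon_h) || horizon_h <= 0) {
    stop("`horizon_h` must be positive.", call. = FALSE)
  }
  if (abs(sum(pathogen_class_probs) - 1) > 1e-8) {
    stop("`pathogen_class_probs` must sum to 1.", call. = FALSE)
  }
  if (any(obs_rates <= 0)) stop("`obs_rates` must be positive.", call. = FALSE)
  if (missing_frac < 0 || missing_frac >= 1) {
    stop("`missing_frac` must be in [0, 1).", call. = FALSE)
  }
  stopifnot(identical(rownames(efficacy_matrix), antibiotics()),
            identical(colnames(efficacy_matrix), pathogen_classes()))
  structure(
    list(
      n_patients = as.integer(n_patients), horizon_h = horizon_h, dt_h = dt_h,
      latent_noise_sd = latent_noise_sd, lab_noise_sd = lab_noise_sd,
      pathogen_class_probs = pathogen_class_probs,
      efficacy_matrix = efficacy_matrix, toxicity = toxicity,
      policy_temperature = policy_temperature, obs_rates = obs_rates,
      missing_frac = missing_frac, resistance_prob = resistance_prob,
      mean_reversion = mean_reversion, severity_setpoint = severity_setpoint,
      sev_coupling = sev_coupling, sev_coupling_ref = sev_coupling_ref,
      class_lab_shift = class_lab_shift, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' The three candidate antibiotics
#' @return Character vector, lexicographic order.
#' @export
antibiotics <- function() c("Ceftriaxone", "Piperacillin/Tazobactam", "Vancomycin")

#' Pathogen classes known to the simulator
#' @return Character vector.
#' @export
pathogen_classes <- function() c("gram_pos", "gram_neg", "mixed", "fungal", "viral")

#' Default antibiotic-by-pathogen-class severity drift matrix
#'
#' Entries are SOFA units per hour added to the latent severity drift while
#' the antibiotic is given to a patient infected with that pathogen class
#' (negative = effective). Fungal and viral columns are zero: antibiotics are
#' ineffective there, which exercises the selector's physician-notification
#' path.
#'
#' @return A 3 x 5 numeric matrix with antibiotics as rows.
#' @export
default_efficacy_matrix <- function() {
  m <- rbind(
    Ceftriaxone                = c(gram_pos = -0.02, gram_neg = -0.10, mixed = -0.05, fungal = 0, viral = 0),
    `Piperacillin/Tazobactam`  = c(gram_pos = -0.06, gram_neg = -0.06, mixed = -0.07, fungal = 0, viral = 0),
    Vancomycin                 = c(gram_pos = -0.10, gram_neg = -0.01, mixed = -0.06, fungal = 0, viral = 0)
  )
  m[antibiotics(), pathogen_classes()]
}

#' Candidate treatment options: single antibiotics and unordered pairs
#'
#' @param available Character vector of usable antibiotics.
#' @return A list of character vectors (each of length 1 or 2), in
#'   deterministic lexicographic order; option labels join members with " + ".
#' @export
treatment_options <- function(available = antibiotics()) {
  available <- sort(available)
  singles <- as.list(available)
  pairs <- if (length(available) >= 2) utils::combn(available, 2, simplify = FALSE) else list()
  opts <- c(singles, pairs)
  opts[order(vapply(opts, paste, "", collapse = " + "))]
}

#' @rdname treatment_options
#' @param option A character vector of antibiotics.
#' @return `option_label()`: a single string.
#' @export
option_label <- function(option) paste(sort(option), collapse = " + ")
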
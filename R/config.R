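#' Default bifactor measurement model for ten psychiatric diagnoses
#'
#' The default calibration of the synthetic-data generator: ten register-style
#' psychiatric diagnoses loading on one general psychopathology (p) factor and
#' three specific factors (internalizing, substance misuse,
#' neurodevelopmental).  General and specific loadings follow published
#' register-based bifactor estimates for these ten diagnoses; prevalences are
#' set so that the diagnostic sum score is strongly right-skewed with a
#' population mean close to 0.2, as observed in national-register birth
#' cohorts.
#'
#' @return A list with elements `conditions` (character), `loadings_general`
#'   (numeric vector), `loadings_specific` (numeric matrix, one column per
#'   specific factor) and `prevalences` (numeric vector).
#' @export
#' @examples
#' m <- default_measurement_model()
#' round(m$loadings_general, 2)
default_measurement_model <- function() {
  conditions <- c("anxiety", "depression", "bipolar", "eating",
                  "drug_misuse", "alcohol_abuse", "adhd", "autism",
                  "tics", "schizophrenia")
  lg <- c(0.67, 0.68, 0.61, 0.35, 0.68, 0.47, 0.67, 0.52, 0.42, 0.49)
  ls <- cbind(
    internalizing      = c(0.51, 0.62, 0.42, 0.56, 0.13, 0.14, 0.00, 0.12, -0.01, 0.30),
    substance_misuse   = c(0.10, 0.02, 0.12, -0.09, 0.60, 0.42, 0.11, -0.15, -0.10, 0.11),
    neurodevelopmental = c(0.05, 0.03, 0.07, -0.12, -0.05, -0.09, 0.56, 0.55, 0.53, 0.08))
  rownames(ls) <- conditions
  prev <- c(0.050, 0.050, 0.005, 0.010, 0.030, 0.025, 0.030, 0.010, 0.003, 0.004)
  names(prev) <- conditions
  names(lg) <- conditions
  list(conditions = conditions, loadings_general = lg,
       loadings_specific = ls, prevalences = prev)
}

default_id_params <- function() {
  list(
    # register-style diagnosis prevalences by severity class (strictly decreasing)
    prevalence     = c(mild = 0.005, moderate = 0.002, severe_profound = 0.001),
    # share of cases in each class arising from familial (heritable) liability;
    # the remainder are de-novo, non-familial cases
    familial_share = c(mild = 1.0, moderate = 0.3, severe_profound = 0.15),
    # correlation between the additive-genetic parts of the cognitive (g-like)
    # trait and the general psychopathology liability (inverse association)
    gp_cor         = -0.5,
    # heritability of the latent g-like trait used for familial ID cases
    g_h2           = 0.8)
}

#' Configuration for the synthetic family-data generator
#'
#' Defines the generative liability-threshold model: each person's liability
#' for condition *i* is
#' \deqn{L_i = \sqrt{1-b^2}\,(\lambda_{g,i} G + \Sigma_j \lambda_{s,ij} S_j +
#'   \sqrt{1-h_i}\,\epsilon_i) + b\, z_{age},}
#' where the general factor \eqn{G} and each specific factor \eqn{S_j} are
#' standard-normal with cross-member correlations determined by their ACE
#' triples (MZ twins share the additive component fully, DZ twins and full
#' siblings share half; the shared-environment component is common to both
#' members), \eqn{h_i} is the communality, and a diagnosis is assigned when
#' \eqn{L_i} exceeds the threshold \eqn{\tau_i = \Phi^{-1}(1 - \pi_i)} for
#' prevalence \eqn{\pi_i}.
#'
#' In `extreme_mode = "discontinuous"` each person independently receives an
#' additive non-familial shock of `discontinuity_shift` liability SD on the
#' general factor with probability `discontinuity_rate`, uncorrelated across
#' family members.  This creates a qualitatively distinct, non-familial route
#' into the extreme tail, the alternative hypothesis that the downstream
#' linearity and group-heritability analyses are designed to detect.
#'
#' @param n_sib_pairs,n_mz_pairs,n_dz_pairs numbers of full-sibling,
#'   monozygotic and dizygotic twin pairs (non-negative; at least one positive).
#'   Defaults mirror a national-register study design (580,891 sibling pairs;
#'   5133 MZ and 12,037 DZ twin pairs).
#' @param conditions character vector of condition names.
#' @param loadings_general general-factor loading per condition, each in
#'   `[0, 1)`.
#' @param loadings_specific matrix of specific-factor loadings
#'   (condition x factor).
#' @param prevalences per-condition diagnosis prevalence, each in (0, 0.5).
#' @param ace_general,ace_specific ACE variance proportions `(a2, c2, e2)` for
#'   the general factor, and one triple per specific factor (matrix rows);
#'   each triple must be non-negative and sum to 1.
#' @param extreme_mode `"homogeneous"` (one continuous etiology) or
#'   `"discontinuous"` (adds non-familial liability shocks).
#' @param discontinuity_rate target share of shock-origin persons among those
#'   whose general liability exceeds `discontinuity_threshold` (discontinuous
#'   mode).  The generator converts this to the implied per-person shock
#'   probability under the normal liability model, so small rates of large
#'   shocks concentrate in the extreme tail rather than distorting the bulk
#'   of the distribution.
#' @param discontinuity_shift shock size in liability SD units.
#' @param discontinuity_threshold liability z-score defining the "extreme"
#'   region whose shock-origin share `discontinuity_rate` controls
#'   (default 3).
#' @param id_params list controlling the intellectual-disability negative
#'   control (see [simulate_id_negative_control()]); missing entries filled
#'   with defaults.
#' @param age_range ages are drawn uniformly over this range (years).
#' @param age_beta standardized linear effect of age on every liability
#'   (variance-preserving, so marginal prevalences are unaffected).
#' @param keep_truth retain latent ground truth columns (`latent_general`,
#'   `latent_specific_*`, `latent_additive_general`) for parameter-recovery
#'   testing.
#' @param seed integer RNG seed; all generator output is deterministic given
#'   the config.
#' @return An object of class `generator_config`.
#' @seealso [simulate_families()]
#' @export
#' @examples
#' cfg <- generator_config(n_sib_pairs = 100, n_mz_pairs = 20, n_dz_pairs = 40)
#' cfg$prevalences
generator_config <- function(n_sib_pairs = 580891L,
                             n_mz_pairs = 5133L,
                             n_dz_pairs = 12037L,
                             conditions = NULL,
                             loadings_general = NULL,
                             loadings_specific = NULL,
                             prevalences = NULL,
                             ace_general = c(0.45, 0, 0.55),
                             ace_specific = NULL,
                             extreme_mode = c("homogeneous", "discontinuous"),
                             discontinuity_rate = 0.6,
                             discontinuity_shift = 3,
                             discontinuity_threshold = 3,
                             id_params = list(),
                             age_range = c(14.1, 34.0),
                             age_beta = 0.05,
                             keep_truth = TRUE,
                             seed = 1L) {
  dm <- default_measurement_model()
  conditions <- conditions %||% dm$conditions
  p <- length(conditions)
  loadings_general <- loadings_general %||% dm$loadings_general[seq_len(min(p, 10))]
  loadings_specific <- loadings_specific %||% dm$loadings_specific[seq_len(min(p, 10)), , drop = FALSE]
  prevalences <- prevalences %||% dm$prevalences[seq_len(min(p, 10))]
  loadings_specific <- as.matrix(loadings_specific)
  s <- ncol(loadings_specific)
  ace_specific <- ace_specific %||%
    matrix(rep(c(0.35, 0, 0.65), each = s), nrow = s,
           dimnames = list(colnames(loadings_specific), c("a2", "c2", "e2")))
  ace_specific <- matrix(as.numeric(ace_specific), nrow = s,
                         dimnames = dimnames(ace_specific))
  extreme_mode <- match.arg(extreme_mode)

  counts <- c(n_sib_pairs, n_mz_pairs, n_dz_pairs)
  if (any(counts < 0) || sum(counts) <= 0)
    stop("pair counts must be non-negative with a positive total")
  if (length(loadings_general) != p || nrow(loadings_specific) != p ||
      length(prevalences) != p)
    stop("loadings and prevalences must have one entry per condition")
  if (any(loadings_general < 0 | loadings_general >= 1))
    stop("general loadings must lie in [0, 1)")
  comm <- loadings_general^2 + rowSums(loadings_specific^2)
  if (any(comm >= 1))
    stop("communality bound violated for condition(s): ",
         paste(conditions[comm >= 1], collapse = ", "))
  if (any(prevalences <= 0 | prevalences >= 0.5))
    stop("prevalences must lie in (0, 0.5)")
  check_ace <- function(x, what) {
    if (any(x < -1e-8) || abs(sum(x) - 1) > 1e-8)
      stop(what, " ACE proportions must be non-negative and sum to 1")
  }
  check_ace(ace_general, "general")
  for (j in seq_len(s)) check_ace(ace_specific[j, ], paste("specific", j))
  if (discontinuity_rate < 0 || discontinuity_rate >= 1)
    stop("discontinuity_rate must lie in [0, 1)")
  if (discontinuity_shift < 0 || discontinuity_threshold <= 0)
    stop("discontinuity shift must be >= 0 and threshold > 0")
  stopifnot(length(age_range) == 2, age_range[2] > age_range[1],
            abs(age_beta) < 1)

  idp <- utils::modifyList(default_id_params(), id_params)
  if (any(diff(idp$prevalence) >= 0))
    warning("ID severity prevalences are not strictly decreasing; proceeding")

  structure(list(
    n_sib_pairs = as.integer(n_sib_pairs),
    n_mz_pairs = as.integer(n_mz_pairs),
    n_dz_pairs = as.integer(n_dz_pairs),
    conditions = conditions,
    loadings_general = unname(loadings_general),
    loadings_specific = unname(loadings_specific),
    specific_names = colnames(loadings_specific) %||% paste0("S", seq_len(s)),
    prevalences = unname(prevalences),
    thresholds = stats::qnorm(1 - unname(prevalences)),
    ace_general = unname(ace_general),
    ace_specific = unname(ace_specific),
    extreme_mode = extreme_mode,
    discontinuity_rate = discontinuity_rate,
    discontinuity_shift = discontinuity_shift,
    discontinuity_threshold = discontinuity_threshold,
    id_params = idp,
    age_range = age_range,
    age_beta = age_beta,
    keep_truth = isTRUE(keep_truth),
    seed = as.integer(seed)), class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat(sprintf("  pairs: %d sib / %d MZ / %d DZ\n",
              x$n_sib_pairs, x$n_mz_pairs, x$n_dz_pairs))
  cat(sprintf("  %d conditions, %d specific factors, mode = %s, seed = %d\n",
              length(x$conditions), ncol(x$loadings_specific),
              x$extreme_mode, x$seed))
  cat(sprintf("  general ACE = (%.2f, %.2f, %.2f); expected sum-score mean = %.3f\n",
              x$ace_general[1], x$ace_general[2], x$ace_general[3],
              sum(x$prevalences)))
  invisible(x)
}

#' Read / write a generator or run configuration as JSON
#'
#' @param config a `generator_config` or `run_config`.
#' @param path JSON file path.
#' @return `config_to_json` returns `path` invisibly; `config_from_json`
#'   returns a rebuilt `generator_config`.
#' @export
config_to_json <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname config_to_json
#' @export
config_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  generator_config(
    n_sib_pairs = raw$n_sib_pairs, n_mz_pairs = raw$n_mz_pairs,
    n_dz_pairs = raw$n_dz_pairs, conditions = raw$conditions,
    loadings_general = raw$loadings_general,
    loadings_specific = matrix(unlist(raw$loadings_specific),
                               nrow = length(raw$conditions)),
    prevalences = raw$prevalences, ace_general = raw$ace_general,
    ace_specific = matrix(unlist(raw$ace_specific), ncol = 3),
    extreme_mode = raw$extreme_mode,
    discontinuity_rate = raw$discontinuity_rate,
    discontinuity_shift = raw$discontinuity_shift,
    discontinuity_threshold = raw$discontinuity_threshold,
    id_params = raw$id_params, age_range = raw$age_range,
    age_beta = raw$age_beta, keep_truth = raw$keep_truth, seed = raw$seed)
}
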
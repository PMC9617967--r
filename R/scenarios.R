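#' Isotype concentration triple
#'
#' Free concentrations (uM) of Tubb3-containing dimers, Tubb4-containing
#' dimers and the pooled remaining beta-tubulin dimers.
#'
#' @param c_tubb3,c_tubb4,c_other Concentrations in uM, each >= 0.
#' @return An object of class `isotype_concentrations`.
#' @export
isotype_concentrations <- function(c_tubb3, c_tubb4, c_other) {
  v <- c(c_tubb3, c_tubb4, c_other)
  if (!all(is.finite(v)) || any(v < 0)) {
    stop("concentrations must be finite and >= 0 uM", call. = FALSE)
  }
  structure(list(c_tubb3 = as.numeric(c_tubb3),
                 c_tubb4 = as.numeric(c_tubb4),
                 c_other = as.numeric(c_other)),
            class = "isotype_concentrations")
}

#' @export
print.isotype_concentrations <- function(x, ...) {
  cat(sprintf("<isotype_concentrations> Tubb3 %g, Tubb4 %g, other %g uM\n",
              x$c_tubb3, x$c_tubb4, x$c_other))
  invisible(x)
}

#' Concentrations from expression fractions
#'
#' Splits a total soluble tubulin pool across the three isotype classes by
#' their expression fractions: c_i = fraction_i * total.
#'
#' @param fractions Numeric length-3 vector (Tubb3, Tubb4, other), each >= 0.
#' @param total Total soluble tubulin concentration in uM (default 7).
#' @return An `isotype_concentrations`.
#' @examples
#' # neuronal cytoplasm estimate: 14% Tubb3, 28% Tubb4, 58% remaining Tubbs
#' concentrations_from_fractions(c(0.14, 0.28, 0.58), total = 7)
#' @export
concentrations_from_fractions <- function(fractions, total = 7) {
  stopifnot(length(fractions) == 3, total >= 0)
  if (any(!is.finite(fractions)) || any(fractions < 0)) {
    stop("fractions must be >= 0", call. = FALSE)
  }
  isotype_concentrations(fractions[1] * total, fractions[2] * total,
                         fractions[3] * total)
}

#' Control-condition concentrations
#'
#' 14% Tubb3, 28% Tubb4 and 58% remaining isotypes of a 7 uM soluble pool:
#' 0.98, 1.96 and 4.06 uM.
#'
#' @return An `isotype_concentrations`.
#' @export
control_concentrations <- function() {
  concentrations_from_fractions(c(0.14, 0.28, 0.58), total = 7)
}

#' Tubb3-knockdown concentrations from expression scaling
#'
#' Under Tubb3 knockdown, Tubb3 expression drops to `tubb3_scale` (43%) of
#' control and Tubb4 rises to `tubb4_scale` (133%); the remaining isotypes
#' absorb the difference so the total pool is conserved:
#' c_other = total - c_tubb3 - c_tubb4.
#'
#' @param control Control `isotype_concentrations`.
#' @param tubb3_scale,tubb4_scale Expression scaling factors (>= 0).
#' @param total Conserved total pool, uM.
#' @return An `isotype_concentrations` (0.42, 2.61, 3.97 uM with defaults,
#'   to two decimals).
#' @export
knockdown_concentrations <- function(control = control_concentrations(),
                                     tubb3_scale = 0.43, tubb4_scale = 1.33,
                                     total = 7) {
  stopifnot(inherits(control, "isotype_concentrations"),
            tubb3_scale >= 0, tubb4_scale >= 0)
  c3 <- control$c_tubb3 * tubb3_scale
  c4 <- control$c_tubb4 * tubb4_scale
  rest <- total - c3 - c4
  if (rest < 0) {
    stop("scaled Tubb3 + Tubb4 exceed the total pool", call. = FALSE)
  }
  isotype_concentrations(c3, c4, rest)
}

#' Named concentration presets
#'
#' The six modeled conditions.  Control and knockdown derive from expression
#' levels; scenarios I-IV probe hypothetical isotype expression changes and
#' are stored literally (their totals are not all 7 uM):
#' \describe{
#'   \item{control}{0.98 / 1.96 / 4.06 uM}
#'   \item{tubb3_kd}{0.42 / 2.61 / 3.97 uM}
#'   \item{scenario_I}{high Tubb3, low Tubb4: 2.1 / 0.84 / 4.06 uM}
#'   \item{scenario_II}{low Tubb4, more others: 0.98 / 0.84 / 5.18 uM}
#'   \item{scenario_III}{high Tubb4: 0.98 / 2.61 / 4.06 uM}
#'   \item{scenario_IV}{high Tubb3: 2.1 / 1.96 / 4.06 uM}
#' }
#'
#' @return Named list of `scenario_preset` objects, each with fields `name`
#'   and `concentrations`.
#' @export
scenario_presets <- function() {
  mk <- function(name, c3, c4, co) {
    structure(list(name = name,
                   concentrations = isotype_concentrations(c3, c4, co)),
              class = "scenario_preset")
  }
  list(
    control = mk("control", 0.98, 1.96, 4.06),
    tubb3_kd = mk("tubb3_kd", 0.42, 2.61, 3.97),
    scenario_I = mk("scenario_I", 2.1, 0.84, 4.06),
    scenario_II = mk("scenario_II", 0.98, 0.84, 5.18),
    scenario_III = mk("scenario_III", 0.98, 2.61, 4.06),
    scenario_IV = mk("scenario_IV", 2.1, 1.96, 4.06))
}

#' Look up a preset's concentrations by name
#'
#' Accepts the canonical names of [scenario_presets()] plus the short
#' aliases used on the command line (`"I"`..`"IV"`, `"tubb3-kd"`).
#'
#' @param name Preset name.
#' @return An `isotype_concentrations`.
#' @export
scenario_concentrations <- function(name) {
  alias <- c(I = "scenario_I", II = "scenario_II", III = "scenario_III",
             IV = "scenario_IV", "tubb3-kd" = "tubb3_kd")
  if (name %in% names(alias)) name <- alias[[name]]
  ps <- scenario_presets()
  if (!name %in% names(ps)) {
    stop(sprintf("unknown scenario '%s' (known: %s)", name,
                 paste(names(ps), collapse = ", ")), call. = FALSE)
  }
  ps[[name]]$concentrations
}

#' Compare two velocity samples
#'
#' Group summary and a two-sample t test between two sets of replicate
#' velocities.  Simulated velocities are means over thousands of elementary
#' events and are close to normal, so Student's t (equal variances) is the
#' default; `welch = TRUE` switches to the unequal-variance form.
#'
#' @param velocities_a,velocities_b Numeric vectors (n >= 2 each).
#' @param welch Use Welch's unequal-variance t test.
#' @return List with per-group `mean`, `sem`, `n`, plus `t`, `df`, `p_value`.
#' @export
compare_groups <- function(velocities_a, velocities_b, welch = FALSE) {
  stopifnot(length(velocities_a) >= 2, length(velocities_b) >= 2)
  if (stats::sd(velocities_a) == 0 && stats::sd(velocities_b) == 0) {
    if (isTRUE(all.equal(mean(velocities_a), mean(velocities_b)))) {
      return(list(mean = c(a = mean(velocities_a), b = mean(velocities_b)),
                  sem = c(a = 0, b = 0),
                  n = c(a = length(velocities_a), b = length(velocities_b)),
                  t = 0, df = NA_real_, p_value = 1))
    }
    stop("both groups have zero variance but different means", call. = FALSE)
  }
  tt <- stats::t.test(velocities_a, velocities_b, var.equal = !welch)
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  list(mean = c(a = mean(velocities_a), b = mean(velocities_b)),
       sem = c(a = sem(velocities_a), b = sem(velocities_b)),
       n = c(a = length(velocities_a), b = length(velocities_b)),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}
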
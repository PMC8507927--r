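# Logit transforms diverge at fa = 0 or 1; observed fractions are clamped
# strictly inside (0,1).
FA_EPS <- 0.005

.clampFa <- function(fa, eps = FA_EPS) pmin(pmax(fa, eps), 1 - eps)

#' Fraction affected from viability signals
#'
#' `fa = 1 - treated/control` (signals normalized to the untreated
#' control), clamped into `[0.005, 0.995]` so the logit transform of the
#' median-effect fit stays finite.
#'
#' @param treated Nonnegative treated-well signal(s).
#' @param control Positive untreated-control signal.
#' @return Fraction(s) affected in (0, 1).
#' @examples
#' fractionAffected(0.4, 1)   # 0.6
#' @export
fractionAffected <- function(treated, control) {
  if (any(treated < 0) || any(control <= 0)) {
    stop("signals must be nonnegative and control > 0", call. = FALSE)
  }
  .clampFa(1 - treated / control)
}

#' Construct a DoseResponseCurve
#'
#' @param doses Positive, strictly increasing concentrations (nM).
#' @param fa Fractions affected; clamped into (0, 1).
#' @param drugLabel Drug name.
#' @return A [DoseResponseCurve-class].
#' @export
DoseResponseCurve <- function(doses, fa, drugLabel = "") {
  obj <- new("DoseResponseCurve", doses = as.numeric(doses),
             fa = .clampFa(as.numeric(fa)), drugLabel = drugLabel)
  validObject(obj)
  obj
}

#' Fit the median-effect equation to a dose-response curve
#'
#' Ordinary least squares of `log10(fa/(1-fa))` on `log10(D)`: the slope is
#' `m`, and `Dm = 10^(-intercept/m)` is the dose producing fa = 0.5.  A
#' non-positive slope is returned flagged (`status = "nonpositive_slope"`)
#' with a warning rather than an error.
#'
#' @param curve A [DoseResponseCurve-class] with at least 3 distinct doses.
#' @return A [MedianEffectFit-class].
#' @examples
#' cv <- simulateDoseResponse(m = 2, Dm = 50, doses = seq(10, 100, 10))
#' fitMedianEffect(cv)
#' @export
fitMedianEffect <- function(curve) {
  stopifnot(is(curve, "DoseResponseCurve"))
  if (length(unique(curve@doses)) < 3L) {
    stop("at least 3 points with distinct doses are required", call. = FALSE)
  }
  x <- log10(curve@doses)
  y <- log10(curve@fa / (1 - curve@fa))
  fit <- lm(y ~ x)
  m <- unname(coef(fit)[2L])
  b <- unname(coef(fit)[1L])
  status <- "ok"
  if (m <= 0) {
    warning("non-positive median-effect slope for '", curve@drugLabel,
            "'; fit flagged")
    status <- "nonpositive_slope"
  }
  Dm <- if (m != 0) 10^(-b / m) else NA_real_
  new("MedianEffectFit", m = m, Dm = Dm, r = unname(cor(x, y)),
      drugLabel = curve@drugLabel, status = status,
      n = length(curve@doses))
}

setMethod("show", "MedianEffectFit", function(object) {
  cat(sprintf("MedianEffectFit '%s': m = %.4g, Dm = %.4g nM, r = %.4f (%s, n = %d)\n",
              object@drugLabel, object@m, object@Dm, object@r,
              object@status, object@n))
})

#' Dose producing a given fraction affected
#'
#' Inverts the median-effect equation: `Dx = Dm * (fa/(1-fa))^(1/m)`.
#' Strictly increasing and continuous in `fa`.
#'
#' @param fit A [MedianEffectFit-class] with `m > 0`.
#' @param fa Fraction affected, strictly inside (0, 1).
#' @return Dose(s) in the fit's concentration units.
#' @examples
#' fit <- new("MedianEffectFit", m = 2, Dm = 10, r = 1, drugLabel = "x",
#'            status = "ok", n = 3L)
#' doseForEffect(fit, 0.9)  # 30
#' @export
doseForEffect <- function(fit, fa) {
  stopifnot(is(fit, "MedianEffectFit"))
  if (fit@m <= 0 || !is.finite(fit@Dm)) {
    stop("degenerate median-effect fit (m <= 0)", call. = FALSE)
  }
  if (any(fa <= 0 | fa >= 1)) {
    stop("fa must lie strictly inside (0, 1)", call. = FALSE)
  }
  fit@Dm * (fa / (1 - fa))^(1 / fit@m)
}

#' IC50 under the median-effect model
#'
#' The half-maximal inhibitory concentration equals `Dm`, the dose at
#' fa = 0.5.
#'
#' @param fit A [MedianEffectFit-class].
#' @return IC50 in the fit's concentration units.
#' @export
ic50 <- function(fit) {
  stopifnot(is(fit, "MedianEffectFit"))
  fit@Dm
}

#' Chou-Talalay combination index
#'
#' For a combination achieving fraction affected `faCombo` at doses
#' `(dose1, dose2)`, `CI = dose1/Dx1 + dose2/Dx2` where `Dxi` is the
#' single-agent dose of drug i producing `faCombo` (mutually exclusive,
#' Loewe-type two-term form).  CI < 1 indicates synergism, CI around 1
#' additivity, CI > 1 antagonism.
#'
#' @param faCombo Observed fraction affected of the combination, in (0, 1).
#' @param dose1,dose2 Combination doses of drugs 1 and 2.
#' @param fit1,fit2 Single-agent [MedianEffectFit-class] objects.
#' @return The combination index (positive real).
#' @export
combinationIndex <- function(faCombo, dose1, dose2, fit1, fit2) {
  .assertFraction(faCombo, "faCombo", 0, 1)
  if (faCombo <= 0 || faCombo >= 1) {
    stop("faCombo must lie strictly inside (0, 1)", call. = FALSE)
  }
  dose1 / doseForEffect(fit1, faCombo) + dose2 / doseForEffect(fit2, faCombo)
}

#' Qualitative classification of a combination index
#'
#' Standard Chou bands, e.g. CI in \[0.3, 0.7) is "synergism" and
#' \[0.7, 0.85) "moderate synergism".
#'
#' @param ci Positive combination index (vectorized).
#' @return Character label(s).
#' @examples
#' classifyCI(c(0.56, 0.78, 1.0))
#' @export
classifyCI <- function(ci) {
  if (any(ci <= 0)) stop("ci must be > 0", call. = FALSE)
  # synergism bands are right-open, antagonism bands right-closed, so that
  # CI = 1.10 still counts as nearly additive
  ifelse(ci < 0.1, "very strong synergism",
  ifelse(ci < 0.3, "strong synergism",
  ifelse(ci < 0.7, "synergism",
  ifelse(ci < 0.85, "moderate synergism",
  ifelse(ci < 0.90, "slight synergism",
  ifelse(ci <= 1.10, "nearly additive",
  ifelse(ci <= 1.20, "slight antagonism",
  ifelse(ci <= 1.45, "moderate antagonism",
  ifelse(ci <= 3.3, "antagonism",
  ifelse(ci <= 10, "strong antagonism", "very strong antagonism"))))))))))
}

#' Simulate a dose-response curve from median-effect parameters
#'
#' `fa(D) = (D/Dm)^m / (1 + (D/Dm)^m)` plus optional Gaussian noise on the
#' fa scale, clamped strictly inside (0, 1).
#'
#' @param m,Dm Median-effect parameters (slope; median-effect dose).
#' @param doses Positive, strictly increasing doses.
#' @param noiseSd Gaussian noise sd on fa (default 0).
#' @param seed Integer seed (ignored when `noiseSd = 0`).
#' @param drugLabel Drug name.
#' @return A [DoseResponseCurve-class].
#' @export
simulateDoseResponse <- function(m, Dm, doses, noiseSd = 0, seed = 1L,
                                 drugLabel = "simulated") {
  stopifnot(m > 0, Dm > 0, noiseSd >= 0)
  fa <- (doses / Dm)^m / (1 + (doses / Dm)^m)
  if (noiseSd > 0) {
    fa <- withSeed(seed, fa + rnorm(length(fa), 0, noiseSd))
  }
  DoseResponseCurve(doses, fa, drugLabel = drugLabel)
}
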
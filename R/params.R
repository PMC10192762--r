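#' Biomarker interaction parameters
#'
#' Rate constants of the mutually inhibitory IGF-1/IL-6 subsystem. Each
#' biomarker is produced at a constant rate, inhibited by a Hill-type function
#' of the other biomarker, and degraded first-order:
#' \deqn{dG/dt = kp_G / (1 + ks_I I^n) - kd_G G}
#' \deqn{dI/dt = kp_I / (1 + ks_G G^n) - kd_I I}
#' where \eqn{G} is IGF-1 (ng/ml) and \eqn{I} is IL-6 (pg/ml), time in months.
#'
#' @param kp_IGF1 IGF-1 production rate (ng/ml per month).
#' @param ks_IL6 inhibition scaling of IL-6 on IGF-1 production
#'   ((pg/ml)^-hill_n); non-negative, 0 uncouples the pair.
#' @param kd_IGF1 IGF-1 first-order degradation rate (per month).
#' @param kp_IL6 IL-6 production rate (pg/ml per month).
#' @param ks_IGF1 inhibition scaling of IGF-1 on IL-6 production ((ng/ml)^-hill_n).
#' @param kd_IL6 IL-6 degradation rate (per month).
#' @param hill_n Hill coefficient on the inhibitor concentration; the model's
#'   default is 2 (cooperative inhibition, required for bistability). Kept as
#'   a parameter so sensitivity runs can set it to 1.
#' @return An object of class `biomarker_params` (named list).
#' @seealso [outcome_params()], [pin_production_ratios()], [find_steady_states()]
#' @export
biomarker_params <- function(kp_IGF1, ks_IL6, kd_IGF1,
                             kp_IL6, ks_IGF1, kd_IL6, hill_n = 2) {
  p <- list(kp_IGF1 = kp_IGF1, ks_IL6 = ks_IL6, kd_IGF1 = kd_IGF1,
            kp_IL6 = kp_IL6, ks_IGF1 = ks_IGF1, kd_IL6 = kd_IL6,
            hill_n = hill_n)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a finite numeric scalar")
  }
  if (kp_IGF1 <= 0 || kd_IGF1 <= 0 || kp_IL6 <= 0 || kd_IL6 <= 0)
    stop("production and degradation rates must be strictly positive")
  if (ks_IL6 < 0 || ks_IGF1 < 0)
    stop("inhibition scalings must be non-negative")
  if (p$hill_n < 1) stop("hill_n must be >= 1")
  structure(p, class = "biomarker_params")
}

#' Clinical outcome (prevalence score) parameters
#'
#' Rate constants coupling the biomarkers to the mobility (M), mobility
#' disability (MD) and death (D) prevalence scores:
#' \deqn{dM/dt  = -k_{loss} I M + k_{gain} G\, MD - k_{mort} e^{k_{longevity} t} M}
#' \deqn{dMD/dt = +k_{loss} I M - k_{gain} G\, MD - k_{extra} k_{mort} e^{k_{longevity} t} MD}
#' \deqn{dD/dt  = k_{mort} e^{k_{longevity} t} (M + k_{extra}\, MD)}
#'
#' @param k_loss M to MD transition coefficient (per pg/ml IL-6 per month).
#' @param k_gain MD to M recovery coefficient (per ng/ml IGF-1 per month).
#' @param k_mort baseline mortality rate (per month).
#' @param k_longevity exponential mortality acceleration (per month).
#' @param k_extra dimensionless mortality amplifier for the disabled
#'   compartment; must be >= 1. Default 2.5 (literature-derived).
#'
#' @details Rates must be non-negative; a zero rate switches the
#'   corresponding pathway off (useful for frozen-dynamics checks and for
#'   reducing the mortality submodel to its closed form).
#' @return An object of class `outcome_params` (named list).
#' @export
outcome_params <- function(k_loss, k_gain, k_mort, k_longevity, k_extra = 2.5) {
  p <- list(k_loss = k_loss, k_gain = k_gain, k_mort = k_mort,
            k_longevity = k_longevity, k_extra = k_extra)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a finite numeric scalar")
  }
  if (any(unlist(p) < 0))
    stop("outcome rates must be non-negative")
  if (p$k_extra < 1) stop("k_extra must be >= 1")
  structure(p, class = "outcome_params")
}

#' Pin production rates to physiological maxima
#'
#' The uninhibited steady state of each biomarker equals kp/kd, so fixing the
#' physiological maximum (the level the biomarker would reach with the other
#' one absent) determines the production rate given a degradation rate:
#' `kp = max * kd`. Defaults are the literature ceilings of 400 ng/ml (IGF-1)
#' and 25 pg/ml (IL-6).
#'
#' @param max_IGF1,max_IL6 physiological maxima (ng/ml, pg/ml).
#' @param kd_IGF1,kd_IL6 degradation rates (per month).
#' @return Named list with `kp_IGF1` and `kp_IL6`.
#' @export
pin_production_ratios <- function(max_IGF1 = 400, max_IL6 = 25,
                                  kd_IGF1, kd_IL6) {
  if (max_IGF1 <= 0 || max_IL6 <= 0)
    stop("physiological maxima must be strictly positive")
  if (kd_IGF1 <= 0 || kd_IL6 <= 0)
    stop("degradation rates must be strictly positive")
  list(kp_IGF1 = max_IGF1 * kd_IGF1, kp_IL6 = max_IL6 * kd_IL6)
}

#' Bundle biomarker and outcome parameters into a model object
#'
#' @param biomarker a [biomarker_params()] object.
#' @param outcome an [outcome_params()] object, or `NULL` for the biomarker
#'   subsystem alone.
#' @return An object of class `frailty_model`.
#' @export
frailty_model <- function(biomarker, outcome = NULL) {
  stopifnot(inherits(biomarker, "biomarker_params"))
  if (!is.null(outcome)) stopifnot(inherits(outcome, "outcome_params"))
  structure(list(biomarker = biomarker, outcome = outcome),
            class = "frailty_model")
}

#' @export
print.biomarker_params <- function(x, ...) {
  cat("Biomarker toggle-switch parameters (time unit: month)\n")
  cat(sprintf("  IGF-1: kp = %.6g ng/ml/mo, kd = %.6g /mo, ks_IL6 = %.6g (pg/ml)^-%g\n",
              x$kp_IGF1, x$kd_IGF1, x$ks_IL6, x$hill_n))
  cat(sprintf("  IL-6 : kp = %.6g pg/ml/mo, kd = %.6g /mo, ks_IGF1 = %.6g (ng/ml)^-%g\n",
              x$kp_IL6, x$kd_IL6, x$ks_IGF1, x$hill_n))
  cat(sprintf("  uninhibited maxima: IGF-1 %.4g ng/ml, IL-6 %.4g pg/ml; Hill n = %g\n",
              x$kp_IGF1 / x$kd_IGF1, x$kp_IL6 / x$kd_IL6, x$hill_n))
  invisible(x)
}

#' @export
print.outcome_params <- function(x, ...) {
  cat("Mobility/mortality parameters (time unit: month)\n")
  cat(sprintf("  k_loss = %.6g, k_gain = %.6g, k_mort = %.6g, k_longevity = %.6g, k_extra = %.3g\n",
              x$k_loss, x$k_gain, x$k_mort, x$k_longevity, x$k_extra))
  invisible(x)
}

#' @export
print.frailty_model <- function(x, ...) {
  cat("Bistable frailty model\n\n")
  print(x$biomarker)
  if (!is.null(x$outcome)) {
    cat("\n")
    print(x$outcome)
  } else cat("\n  (no outcome parameters: biomarker subsystem only)\n")
  invisible(x)
}

#' @export
coef.frailty_model <- function(object, ...) {
  b <- object$biomarker
  o <- object$outcome
  out <- c(kp_IGF1 = b$kp_IGF1, ks_IL6 = b$ks_IL6, kd_IGF1 = b$kd_IGF1,
           kp_IL6 = b$kp_IL6, ks_IGF1 = b$ks_IGF1, kd_IL6 = b$kd_IL6)
  if (!is.null(o))
    out <- c(out, k_loss = o$k_loss, k_gain = o$k_gain, k_mort = o$k_mort,
             k_longevity = o$k_longevity, k_extra = o$k_extra)
  out
}

#' Serialize model parameters to JSON
#'
#' Writes (or returns) a JSON document with explicit unit annotations so
#' parameter sets round-trip losslessly between sessions.
#'
#' @param model a [frailty_model()] (or fitted `frailty_fit`).
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_params_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "frailty_model"))
  doc <- list(
    units = list(time = "month", IGF1 = "ng/ml", IL6 = "pg/ml"),
    biomarker = unclass(model$biomarker),
    outcome = if (!is.null(model$outcome)) unclass(model$outcome)
  )
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read model parameters from JSON
#'
#' @param path file path or JSON string produced by [write_params_json()].
#' @return A [frailty_model()].
#' @export
read_params_json <- function(path) {
  doc <- jsonlite::fromJSON(path)
  bm <- do.call(biomarker_params, doc$biomarker)
  oc <- if (!is.null(doc$outcome)) do.call(outcome_params, doc$outcome)
  frailty_model(bm, oc)
}
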
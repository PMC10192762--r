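## ODE right-hand sides, numerical integration, trajectory container.

# lsoda may probe a few ulps*scale below zero on stiff decays; clamp those,
# error on anything larger (model error, not roundoff).
.NEG_CLAMP <- 1e-6

.clamp_nonneg <- function(x, what = "state") {
  bad <- x < -.NEG_CLAMP
  if (any(bad))
    stop("negative ", what, " encountered (", paste(signif(x[bad], 4), collapse = ", "),
         "); magnitude exceeds the roundoff guard")
  pmax(x, 0)
}

#' Biomarker subsystem right-hand side
#'
#' Time derivatives of the mutually inhibitory IGF-1/IL-6 pair. Production of
#' each biomarker is divided by `1 + ks * inhibitor^hill_n`; degradation is
#' first order.
#'
#' @param state numeric, named or positional `c(IGF1, IL6)` (a longer state
#'   vector is accepted and the first two components used).
#' @param p a [biomarker_params()] object.
#' @return Named numeric `c(dIGF1, dIL6)` (ng/ml and pg/ml per month).
#' @export
biomarker_rhs <- function(state, p) {
  stopifnot(inherits(p, "biomarker_params"))
  G <- if (!is.null(names(state)) && "IGF1" %in% names(state)) state[["IGF1"]] else state[[1L]]
  I <- if (!is.null(names(state)) && "IL6" %in% names(state)) state[["IL6"]] else state[[2L]]
  if (G < 0 || I < 0) stop("concentrations must be non-negative")
  c(dIGF1 = p$kp_IGF1 / (1 + p$ks_IL6 * I^p$hill_n) - p$kd_IGF1 * G,
    dIL6  = p$kp_IL6 / (1 + p$ks_IGF1 * G^p$hill_n) - p$kd_IL6 * I)
}

#' Outcome compartment right-hand side
#'
#' Time derivatives of the mobility (M), mobility-disability (MD) and death (D)
#' prevalence scores at time `t`, driven by the current biomarker levels.
#' The death derivative is the negated sum of the other two, so the three
#' derivatives sum to zero identically and total prevalence is conserved.
#'
#' @param state named numeric with components `IGF1`, `IL6`, `M`, `MD` (and
#'   optionally `D`), plus `t` or a separate `t` argument.
#' @param bp a [biomarker_params()] object (unused by the rates themselves but
#'   kept for interface symmetry with [biomarker_rhs()]).
#' @param op an [outcome_params()] object.
#' @param t time since baseline (months); defaults to `state[["t"]]` if present,
#'   else 0.
#' @return Named numeric `c(dM, dMD, dD)`; always sums to zero.
#' @export
outcome_rhs <- function(state, bp, op, t = NULL) {
  stopifnot(inherits(op, "outcome_params"))
  if (is.null(t)) t <- if ("t" %in% names(state)) state[["t"]] else 0
  G <- state[["IGF1"]]; I <- state[["IL6"]]
  M <- state[["M"]]; MD <- state[["MD"]]
  haz <- op$k_mort * exp(op$k_longevity * t)
  dM  <- -op$k_loss * I * M + op$k_gain * G * MD - haz * M
  dMD <- op$k_loss * I * M - op$k_gain * G * MD - op$k_extra * haz * MD
  c(dM = dM, dMD = dMD, dD = -(dM + dMD))
}

# deSolve derivative function for the full system. State ordering:
# (IGF1, IL6[, M, MD, D[, D_M, D_MD]]). parms carries bp, op, split flag.
.frailty_deriv <- function(t, y, parms) {
  y <- .clamp_nonneg(y)
  bp <- parms$bp
  G <- y[1L]; I <- y[2L]
  dG <- bp$kp_IGF1 / (1 + bp$ks_IL6 * I^bp$hill_n) - bp$kd_IGF1 * G
  dI <- bp$kp_IL6 / (1 + bp$ks_IGF1 * G^bp$hill_n) - bp$kd_IL6 * I
  if (is.null(parms$op)) return(list(c(dG, dI)))
  op <- parms$op
  M <- y[3L]; MD <- y[4L]
  haz <- op$k_mort * exp(op$k_longevity * t)
  dM  <- -op$k_loss * I * M + op$k_gain * G * MD - haz * M
  dMD <- op$k_loss * I * M - op$k_gain * G * MD - op$k_extra * haz * MD
  dD <- -(dM + dMD)
  out <- c(dG, dI, dM, dMD, dD)
  if (isTRUE(parms$split_death))
    out <- c(out, haz * M, op$k_extra * haz * MD)
  if (isTRUE(parms$track_phi)) {
    # mobile fraction among survivors; its dynamics are independent of the
    # absolute survival level, so it stays well-conditioned long after M and
    # MD have decayed below solver tolerances. The last term is survivorship
    # enrichment: disabled survivors die k_extra times faster.
    phi <- y[length(y)]
    dphi <- -op$k_loss * I * phi + op$k_gain * G * (1 - phi) +
      (op$k_extra - 1) * haz * phi * (1 - phi)
    out <- c(out, dphi)
  }
  list(out)
}

#' Simulate a frailty trajectory
#'
#' Integrates the coupled biomarker + prevalence-score system (or the
#' biomarker subsystem alone when no outcome parameters are given) with a
#' stiff-capable adaptive integrator.
#'
#' @param initial named numeric: `IGF1`, `IL6` and, for the full system, `M`,
#'   `MD` (and optionally `D`; it defaults to `1 - M - MD`).
#' @param bp a [biomarker_params()] object.
#' @param op an [outcome_params()] object or `NULL`.
#' @param times strictly increasing output time grid (months), starting at the
#'   initial time.
#' @param rtol,atol solver tolerances.
#' @param split_death also track the cumulative death inflow from the mobile
#'   (`D_M`) and disabled (`D_MD`) compartments separately.
#' @param track_conditional also integrate the mobile fraction among
#'   survivors, `M/(M+MD)`, as its own state (`M_cond`); unlike the ratio of
#'   the integrated compartments it remains numerically meaningful at
#'   horizons where survival has decayed below solver tolerances.
#' @return A `frailty_trajectory`: data frame with columns `time`, `IGF1`,
#'   `IL6` and, for the full system, `M`, `MD`, `D` (plus `D_M`, `D_MD` when
#'   requested), carrying the parameters and solver settings as attributes.
#' @examples
#' bp <- biomarker_params(kp_IGF1 = 1, ks_IL6 = 10, kd_IGF1 = 1,
#'                        kp_IL6 = 1, ks_IGF1 = 10, kd_IL6 = 1)
#' tr <- simulate_frailty(c(IGF1 = 0.9, IL6 = 0.2), bp, times = seq(0, 50, 1))
#' @export
simulate_frailty <- function(initial, bp, op = NULL, times = 0:240,
                             rtol = 1e-8, atol = 1e-10, split_death = FALSE,
                             track_conditional = FALSE) {
  stopifnot(inherits(bp, "biomarker_params"))
  if (!is.null(op)) stopifnot(inherits(op, "outcome_params"))
  if (length(times) < 2L || any(diff(times) <= 0))
    stop("'times' must be strictly increasing with at least two points")
  if (any(c("IGF1", "IL6") %in% names(initial) == FALSE))
    stop("'initial' must name IGF1 and IL6")
  G0 <- initial[["IGF1"]]; I0 <- initial[["IL6"]]
  if (G0 < 0 || I0 < 0) stop("initial concentrations must be non-negative")
  if (is.null(op)) {
    y0 <- c(IGF1 = G0, IL6 = I0)
  } else {
    M0 <- if ("M" %in% names(initial)) initial[["M"]] else 1
    MD0 <- if ("MD" %in% names(initial)) initial[["MD"]] else 0
    D0 <- if ("D" %in% names(initial)) initial[["D"]] else max(0, 1 - M0 - MD0)
    if (min(M0, MD0, D0) < -1e-12 || max(M0, MD0, D0) > 1 + 1e-12)
      stop("prevalence scores must lie in [0, 1]")
    if (abs(M0 + MD0 + D0 - 1) > 1e-8)
      stop("initial prevalence scores must sum to 1")
    y0 <- c(IGF1 = G0, IL6 = I0, M = M0, MD = MD0, D = D0)
    if (split_death) y0 <- c(y0, D_M = 0, D_MD = 0)
    if (track_conditional)
      y0 <- c(y0, M_cond = if (M0 + MD0 > 0) M0 / (M0 + MD0) else 1)
  }
  sol <- deSolve::lsoda(y = y0, times = times, func = .frailty_deriv,
                        parms = list(bp = bp, op = op, split_death = split_death,
                                     track_phi = !is.null(op) && track_conditional),
                        rtol = rtol, atol = atol, maxsteps = 50000)
  diagn <- attributes(sol)[c("istate", "rstate")]
  if (utils::tail(sol[, "time"], 1L) < utils::tail(times, 1L))
    stop("solver did not reach the end of the time grid; last good time = ",
         utils::tail(sol[, "time"], 1L))
  out <- as.data.frame(sol)
  # integration can leave prevalence scores a hair outside [0,1]; keep raw
  # values (conservation is asserted, not imposed) but clamp tiny negatives
  for (cn in intersect(c("M", "MD", "D"), names(out)))
    out[[cn]] <- ifelse(out[[cn]] > -.NEG_CLAMP & out[[cn]] < 0, 0, out[[cn]])
  structure(out,
            class = c("frailty_trajectory", "data.frame"),
            bp = bp, op = op, initial = y0,
            solver = list(method = "lsoda", rtol = rtol, atol = atol,
                          istate = diagn$istate),
            split_death = split_death)
}

#' Check trajectory invariants
#'
#' Verifies strictly increasing time, non-negative concentrations, prevalence
#' scores in `[0, 1]`, non-decreasing death prevalence and conservation of
#' total prevalence.
#'
#' @param traj a `frailty_trajectory`.
#' @param conservation_tol maximum allowed `|M + MD + D - 1|`.
#' @return `TRUE` invisibly; errors describing the violated invariant otherwise.
#' @export
validate_trajectory <- function(traj, conservation_tol = 1e-6) {
  stopifnot(inherits(traj, "frailty_trajectory"))
  if (any(diff(traj$time) <= 0)) stop("time grid not strictly increasing")
  if (min(traj$IGF1, traj$IL6) < 0) stop("negative biomarker concentration")
  if ("M" %in% names(traj)) {
    sc <- c(traj$M, traj$MD, traj$D)
    if (min(sc) < -conservation_tol || max(sc) > 1 + conservation_tol)
      stop("prevalence score outside [0, 1]")
    drift <- max(abs(traj$M + traj$MD + traj$D - 1))
    if (drift > conservation_tol)
      stop(sprintf("conservation violated: max |M+MD+D-1| = %.3g", drift))
    if (any(diff(traj$D) < -conservation_tol))
      stop("death prevalence decreased along the trajectory")
  }
  invisible(TRUE)
}

#' @export
print.frailty_trajectory <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("Frailty trajectory: %d points over t = [%g, %g] months\n",
              n, x$time[1L], x$time[n]))
  cat(sprintf("  IGF-1: %.4g -> %.4g ng/ml; IL-6: %.4g -> %.4g pg/ml\n",
              x$IGF1[1L], x$IGF1[n], x$IL6[1L], x$IL6[n]))
  if ("M" %in% names(x))
    cat(sprintf("  endpoint prevalence: M = %.4g, MD = %.4g, D = %.4g\n",
                x$M[n], x$MD[n], x$D[n]))
  invisible(x)
}

#' @export
plot.frailty_trajectory <- function(x, which = c("outcomes", "biomarkers"), ...) {
  which <- match.arg(which)
  if (which == "biomarkers" || !("M" %in% names(x))) {
    graphics::matplot(x$time, cbind(x$IGF1, x$IL6), type = "l", lty = 1,
                      col = c("steelblue", "firebrick"),
                      xlab = "time (months)", ylab = "concentration", ...)
    graphics::legend("right", legend = c("IGF-1 (ng/ml)", "IL-6 (pg/ml)"),
                     col = c("steelblue", "firebrick"), lty = 1, bty = "n")
  } else {
    graphics::matplot(x$time, cbind(x$M, x$MD, x$D), type = "l", lty = 1,
                      col = c("forestgreen", "orange", "grey30"),
                      xlab = "time (months)", ylab = "prevalence score",
                      ylim = c(0, 1), ...)
    graphics::legend("right", legend = c("M", "MD", "D"),
                     col = c("forestgreen", "orange", "grey30"), lty = 1, bty = "n")
  }
  invisible(x)
}

#' Simulate method for frailty models
#'
#' `simulate()` wrapper around [simulate_frailty()]; the model is
#' deterministic, so `nsim`/`seed` are accepted for generic compatibility but
#' every replicate is identical.
#'
#' @param object a [frailty_model()] or fitted `frailty_fit`.
#' @param nsim number of trajectories (all identical; kept for the generic).
#' @param seed ignored (deterministic model); kept for the generic.
#' @param initial,times,... passed to [simulate_frailty()].
#' @return A `frailty_trajectory` (or a list of them when `nsim > 1`).
#' @export
simulate.frailty_model <- function(object, nsim = 1, seed = NULL,
                                   initial, times = 0:240, ...) {
  one <- simulate_frailty(initial, object$biomarker, object$outcome,
                          times = times, ...)
  if (nsim == 1) one else replicate(nsim, one, simplify = FALSE)
}

#' Closed-form single-compartment survival under a Gompertz hazard
#'
#' With disability transitions frozen (`k_loss = k_gain = 0`) and everyone
#' starting mobile, mobility prevalence obeys
#' \eqn{M(t) = M_0 \exp(-(k_{mort}/k_{longevity})(e^{k_{longevity} t} - 1))};
#' the limit `k_longevity = 0` is simple exponential decay. Serves as an
#' analytic cross-check of the mortality submodel and as the defining equation
#' for [calibrate_longevity()].
#'
#' @param t time (months), vectorised.
#' @param k_mort baseline mortality rate (per month).
#' @param k_longevity mortality acceleration (per month); may be 0.
#' @param M0 initial prevalence.
#' @return Survival prevalence at `t`.
#' @export
closed_form_survival <- function(t, k_mort, k_longevity, M0 = 1) {
  stopifnot(all(t >= 0), k_mort > 0, k_longevity >= 0)
  if (k_longevity == 0) return(M0 * exp(-k_mort * t))
  M0 * exp(-(k_mort / k_longevity) * expm1(k_longevity * t))
}
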
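## Basin-of-attraction scans, separatrix detection and switch-like mobility
## curves over initial biomarker conditions.

# log-spaced output grid reaching t_max; trajectories settle long before the
# 240-month clinical horizon matters, but attractor classification integrates
# far beyond it.
.logtimes <- function(t_max, n = 48) c(0, exp(seq(log(0.1), log(t_max), length.out = n)))

# relative distance in log-concentration space (scale-free across the
# 25 pg/ml vs 400 ng/ml disparity): RMS of component-wise log-ratios
.log_dist <- function(G, I, ss, eps = 1e-12) {
  sqrt(((log(G + eps) - log(ss$IGF1 + eps))^2 +
          (log(I + eps) - log(ss$IL6 + eps))^2) / 2)
}

# integrate one initial condition and return the index of the stable state it
# reaches (NA when unassigned), plus the first output time within tol of it
.attractor_of <- function(G0, I0, bp, stable, t_max = 1e4, tol = 0.01,
                          times = NULL) {
  if (is.null(times)) times <- .logtimes(t_max)
  tr <- simulate_frailty(c(IGF1 = G0, IL6 = I0), bp, op = NULL, times = times)
  n <- nrow(tr)
  d_end <- vapply(seq_len(nrow(stable)), function(k)
    .log_dist(tr$IGF1[n], tr$IL6[n], stable[k, ]), 0)
  k <- which.min(d_end)
  if (d_end[k] > tol) return(list(label = NA_integer_, t_converge = NA_real_))
  d_path <- .log_dist(tr$IGF1, tr$IL6, stable[k, ])
  first <- which(d_path <= tol)[1L]
  list(label = k, t_converge = times[first])
}

#' Initial-condition grid for attractor scans
#'
#' Defaults reproduce the published scan ranges: initial IGF-1 from 40 to
#' 300 ng/ml and initial IL-6 from 1 to 10 pg/ml (0.001-0.01 mcg/L in mass
#' units).
#'
#' @param igf1_range,il6_range axis ranges (ng/ml, pg/ml).
#' @param n length-2 grid resolution `c(IGF1, IL6)` (scalar recycled).
#' @return An object of class `initial_grid`.
#' @export
initial_grid <- function(igf1_range = c(40, 300), il6_range = c(1, 10),
                         n = c(60, 60)) {
  if (length(n) == 1L) n <- rep(n, 2L)
  stopifnot(igf1_range[1] > 0, il6_range[1] > 0,
            igf1_range[1] < igf1_range[2], il6_range[1] < il6_range[2],
            all(n >= 2))
  structure(list(IGF1 = seq(igf1_range[1], igf1_range[2], length.out = n[1]),
                 IL6 = seq(il6_range[1], il6_range[2], length.out = n[2]),
                 igf1_range = igf1_range, il6_range = il6_range, n = n),
            class = "initial_grid")
}

#' Scan basins of attraction over an initial-condition grid
#'
#' Integrates the biomarker subsystem from every grid node far past the
#' clinical horizon and assigns each node to the nearest stable steady state
#' (relative log-concentration distance below `tol`); nodes that fail the
#' assignment test are flagged, never silently dropped.
#'
#' @param grid an [initial_grid()].
#' @param bp a [biomarker_params()] object.
#' @param t_max integration horizon for steady-state classification (months).
#' @param tol relative assignment tolerance (default 1%).
#' @return An object of class `phase_diagram`: data frame `IGF1_0`, `IL6_0`,
#'   `attractor` (index into the stable-state table, ordered by increasing
#'   IGF-1: 1 = frail attractor, 2 = resilient), `t_converge`; stable states
#'   and unassigned nodes as attributes.
#' @export
scan_attractors <- function(grid, bp, t_max = 1e4, tol = 0.01) {
  stopifnot(inherits(grid, "initial_grid"), inherits(bp, "biomarker_params"))
  stable <- .stable_states(bp)
  if (nrow(stable) == 0L) stop("no stable steady state found")
  nodes <- expand.grid(IGF1_0 = grid$IGF1, IL6_0 = grid$IL6)
  times <- .logtimes(t_max)
  res <- lapply(seq_len(nrow(nodes)), function(i)
    .attractor_of(nodes$IGF1_0[i], nodes$IL6_0[i], bp, stable,
                  t_max = t_max, tol = tol, times = times))
  nodes$attractor <- vapply(res, function(r) r$label, 0L)
  nodes$t_converge <- vapply(res, function(r) r$t_converge, 0)
  structure(nodes, class = c("phase_diagram", "data.frame"),
            steady_states = stable, grid = grid, tol = tol, t_max = t_max,
            unassigned = which(is.na(nodes$attractor)))
}

#' @export
print.phase_diagram <- function(x, ...) {
  tab <- table(factor(x$attractor, levels = seq_len(nrow(attr(x, "steady_states")))),
               useNA = "ifany")
  cat(sprintf("Phase diagram: %d nodes, %d attractor label(s) present\n",
              nrow(x), length(unique(stats::na.omit(x$attractor)))))
  for (k in seq_along(tab))
    cat(sprintf("  attractor %s: %d nodes\n", names(tab)[k], tab[k]))
  un <- attr(x, "unassigned")
  if (length(un)) cat(sprintf("  unassigned (flagged): %d\n", length(un)))
  invisible(x)
}

#' @export
plot.phase_diagram <- function(x, ...) {
  g <- attr(x, "grid")
  z <- matrix(x$attractor, nrow = length(g$IGF1))
  graphics::image(g$IGF1, g$IL6, z, col = c("#fdcc8a", "#a6d96a"),
                  xlab = "initial IGF-1 (ng/ml)", ylab = "initial IL-6 (pg/ml)",
                  ...)
  ss <- attr(x, "steady_states")
  graphics::points(ss$IGF1, ss$IL6, pch = 19)
  invisible(x)
}

#' Locate the separatrix between the two basins
#'
#' For each scan line (fixed IL-6), bisects over initial IGF-1 between the
#' range ends until the interval bracketing the basin boundary is narrower
#' than `tol` (a fraction of the axis range); the midpoint is reported. Scan
#' lines whose two endpoints fall in the same basin are omitted and logged.
#'
#' @param bp a bistable [biomarker_params()] object.
#' @param igf1_range,il6_range search ranges (defaults match the published
#'   scan box).
#' @param n_lines number of IL-6 scan lines.
#' @param tol bisection tolerance as a fraction of the IGF-1 range.
#' @param t_max classification horizon (months).
#' @return An object of class `separatrix`: data frame `IL6`, `IGF1_crit`,
#'   with omitted lines, tolerance and ranges as attributes.
#' @export
find_separatrix <- function(bp, igf1_range = c(40, 300), il6_range = c(1, 10),
                            n_lines = 25, tol = 0.001, t_max = 1e4) {
  stopifnot(inherits(bp, "biomarker_params"))
  stable <- .stable_states(bp)
  if (nrow(stable) < 2L) stop("separatrix undefined: system is not bistable")
  times <- .logtimes(t_max)
  cls <- function(G, I) .attractor_of(G, I, bp, stable, times = times)$label
  tol_abs <- tol * diff(igf1_range)
  il6 <- seq(il6_range[1], il6_range[2], length.out = n_lines)
  crit <- rep(NA_real_, n_lines)
  omitted <- integer(0)
  for (j in seq_len(n_lines)) {
    lo <- igf1_range[1]; hi <- igf1_range[2]
    a <- cls(lo, il6[j]); b <- cls(hi, il6[j])
    if (is.na(a) || is.na(b) || a == b) {
      omitted <- c(omitted, j)
      next
    }
    while (hi - lo > tol_abs) {
      mid <- (lo + hi) / 2
      m <- cls(mid, il6[j])
      if (is.na(m)) break
      if (m == a) lo <- mid else hi <- mid
    }
    crit[j] <- (lo + hi) / 2
  }
  out <- data.frame(IL6 = il6[!is.na(crit)], IGF1_crit = crit[!is.na(crit)])
  structure(out, class = c("separatrix", "data.frame"),
            tol = tol, tol_abs = tol_abs, igf1_range = igf1_range,
            il6_range = il6_range, omitted_IL6 = il6[omitted],
            steady_states = stable)
}

#' @export
print.separatrix <- function(x, ...) {
  cat(sprintf("Separatrix: %d boundary points, IL-6 in [%.3g, %.3g] pg/ml\n",
              nrow(x), min(x$IL6), max(x$IL6)))
  cat(sprintf("  critical IGF-1 from %.4g to %.4g ng/ml (tol %.3g ng/ml)\n",
              min(x$IGF1_crit), max(x$IGF1_crit), attr(x, "tol_abs")))
  om <- attr(x, "omitted_IL6")
  if (length(om)) cat(sprintf("  %d single-basin scan line(s) omitted\n", length(om)))
  invisible(x)
}

#' @export
plot.separatrix <- function(x, add = FALSE, ...) {
  if (add) graphics::lines(x$IGF1_crit, x$IL6, lwd = 2, col = "grey40", ...)
  else graphics::plot(x$IGF1_crit, x$IL6, type = "l", lwd = 2, col = "grey40",
                      xlab = "IGF-1 (ng/ml)", ylab = "IL-6 (pg/ml)", ...)
  invisible(x)
}

#' Interpolated critical IGF-1 at a given IL-6 level
#'
#' Linear interpolation along the separatrix; outside the computed IL-6 span
#' the end segments are extended linearly (the curve is monotone, so a point
#' far above the span has a critical IGF-1 beyond the physiological range and
#' classifies frail for any scanned IGF-1, and symmetrically below).
#'
#' @param sep a [find_separatrix()] result.
#' @param il6 IL-6 levels (pg/ml), vectorised.
#' @return Critical initial IGF-1 values (ng/ml).
#' @export
separatrix_critical_igf1 <- function(sep, il6) {
  stopifnot(inherits(sep, "separatrix"), nrow(sep) >= 2L)
  out <- stats::approx(sep$IL6, sep$IGF1_crit, xout = il6, rule = 2)$y
  n <- nrow(sep)
  lo_slope <- (sep$IGF1_crit[2] - sep$IGF1_crit[1]) / (sep$IL6[2] - sep$IL6[1])
  hi_slope <- (sep$IGF1_crit[n] - sep$IGF1_crit[n - 1]) /
    (sep$IL6[n] - sep$IL6[n - 1])
  below <- il6 < sep$IL6[1]
  above <- il6 > sep$IL6[n]
  out[below] <- sep$IGF1_crit[1] + lo_slope * (il6[below] - sep$IL6[1])
  out[above] <- sep$IGF1_crit[n] + hi_slope * (il6[above] - sep$IL6[n])
  out
}

#' Switch-like mobility curves over initial biomarker levels
#'
#' Sweeps the initial level of one biomarker (the other fixed, by default at
#' its population mean), simulates the full model, and records the mobility
#' prevalence score M and its survival-conditioned counterpart `M/(M+MD)` at
#' each horizon. The per-horizon critical value is the midpoint of the
#' steepest-transition interval; transition steepness is amplitude-normalised
#' (`max |dm/dx| / (max m - min m)`).
#'
#' Threshold detection uses the survival-conditioned score by default: at
#' horizons at or beyond the longevity horizon nearly the whole cohort has
#' died, so the raw score M decays across many orders of magnitude within
#' both basins and its steepest gradient no longer marks the basin boundary,
#' whereas mobility among the (few) survivors switches cleanly at the
#' critical initial level.
#'
#' @param vary `"IGF1"` or `"IL6"`: the biomarker whose initial level is swept.
#' @param bp,op calibrated parameters.
#' @param fixed_value initial level of the other biomarker; defaults to the
#'   population means 3.14 pg/ml (IL-6) / 107.8 ng/ml (IGF-1).
#' @param horizons evaluation horizons in months (default 5, 20, 30 years).
#' @param range sweep range; defaults to the published scan ranges.
#' @param n sweep resolution.
#' @param initial_M,initial_MD baseline prevalence scores.
#' @param measure score used for threshold detection: `"conditional"`
#'   (mobile fraction among survivors, default) or `"raw"` (M itself).
#' @return An object of class `switch_curve`: data frame `value`, `horizon`,
#'   `M` (raw), `M_cond` (survival-conditioned), with per-horizon critical
#'   values and normalised steepness in attribute `thresholds`.
#' @export
mobility_switch_curve <- function(vary = c("IGF1", "IL6"), bp, op,
                                  fixed_value = NULL,
                                  horizons = c(60, 240, 360), range = NULL,
                                  n = 400, initial_M = 1, initial_MD = 0,
                                  measure = c("conditional", "raw")) {
  vary <- match.arg(vary)
  measure <- match.arg(measure)
  stopifnot(inherits(bp, "biomarker_params"), inherits(op, "outcome_params"))
  if (is.null(fixed_value)) fixed_value <- if (vary == "IGF1") 3.14 else 107.8
  if (is.null(range)) range <- if (vary == "IGF1") c(40, 300) else c(1, 10)
  horizons <- sort(horizons)
  vals <- seq(range[1], range[2], length.out = n)
  times <- sort(unique(c(0, horizons)))
  M <- Mc <- matrix(NA_real_, nrow = n, ncol = length(horizons))
  for (i in seq_len(n)) {
    ini <- if (vary == "IGF1") c(IGF1 = vals[i], IL6 = fixed_value)
    else c(IGF1 = fixed_value, IL6 = vals[i])
    tr <- simulate_frailty(c(ini, M = initial_M, MD = initial_MD), bp, op,
                           times = times, track_conditional = TRUE)
    idx <- match(horizons, tr$time)
    M[i, ] <- tr$M[idx]
    Mc[i, ] <- tr$M_cond[idx]
  }
  score <- if (measure == "conditional") Mc else M
  bistable <- is_bistable(bp)
  thr <- do.call(rbind, lapply(seq_along(horizons), function(h) {
    m <- score[, h]
    amp <- max(m) - min(m)
    dm <- abs(diff(m))
    dx <- diff(vals)[1]
    # interior gradient only: a boundary-hugging gradient is exposure
    # attenuation at the sweep edge, not the switch
    int <- seq(3, length(dm) - 2)
    steep <- max(dm[int]) / dx
    # a threshold needs two basins, a meaningful amplitude and a localised jump
    if (!bistable || amp < 0.05 || max(dm[int]) < 2 * stats::median(dm))
      return(data.frame(horizon = horizons[h], critical = NA_real_,
                        steepness = if (amp < 1e-12) 0 else steep))
    k <- int[which.max(dm[int])]
    data.frame(horizon = horizons[h], critical = (vals[k] + vals[k + 1]) / 2,
               steepness = steep)
  }))
  out <- data.frame(value = rep(vals, times = length(horizons)),
                    horizon = rep(horizons, each = n),
                    M = as.vector(M), M_cond = as.vector(Mc))
  structure(out, class = c("switch_curve", "data.frame"),
            vary = vary, fixed_value = fixed_value, thresholds = thr,
            range = range, n = n, measure = measure)
}

#' @export
print.switch_curve <- function(x, ...) {
  cat(sprintf("Switch curve: initial %s swept over [%.4g, %.4g] (%s fixed at %.4g)\n",
              attr(x, "vary"), attr(x, "range")[1], attr(x, "range")[2],
              if (attr(x, "vary") == "IGF1") "IL-6" else "IGF-1",
              attr(x, "fixed_value")))
  print(attr(x, "thresholds"), row.names = FALSE)
  invisible(x)
}

#' @export
plot.switch_curve <- function(x, normalise = TRUE, ...) {
  hs <- unique(x$horizon)
  cols <- grDevices::hcl.colors(length(hs), "Zissou 1")
  graphics::plot(NA, xlim = range(x$value), ylim = c(0, 1),
                 xlab = paste("initial", attr(x, "vary")),
                 ylab = if (normalise) "M / max M" else "M", ...)
  for (i in seq_along(hs)) {
    m <- if (identical(attr(x, "measure"), "conditional"))
      x$M_cond[x$horizon == hs[i]] else x$M[x$horizon == hs[i]]
    if (normalise && max(m, na.rm = TRUE) > 0) m <- m / max(m, na.rm = TRUE)
    graphics::lines(x$value[x$horizon == hs[i]], m, col = cols[i])
  }
  graphics::legend("topleft", legend = paste(hs, "mo"), col = cols, lty = 1,
                   bty = "n")
  invisible(x)
}

#' Critical initial biomarker value at a horizon
#'
#' Extracts the per-horizon critical value detected by
#' [mobility_switch_curve()]; `NA` (an explicit no-threshold result) when the
#' sweep showed no localised transition.
#'
#' @param curve a `switch_curve`.
#' @param horizon one of the curve's horizons (months).
#' @return The critical initial value, or `NA_real_`.
#' @export
critical_threshold <- function(curve, horizon) {
  stopifnot(inherits(curve, "switch_curve"))
  thr <- attr(curve, "thresholds")
  i <- match(horizon, thr$horizon)
  if (is.na(i)) stop("horizon ", horizon, " not present in the curve")
  thr$critical[i]
}
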
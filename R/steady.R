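## Steady-state enumeration and stability classification for the 2-D
## biomarker toggle switch.

# Nullclines: G = f(I) = (kp_G/kd_G)/(1 + ks_I I^n)
#             I = g(G) = (kp_I/kd_I)/(1 + ks_G G^n)
# Fixed points are roots of h(G) = G - f(g(G)) on [0, kp_G/kd_G].

.null_G <- function(I, p) (p$kp_IGF1 / p$kd_IGF1) / (1 + p$ks_IL6 * I^p$hill_n)
.null_I <- function(G, p) (p$kp_IL6 / p$kd_IL6) / (1 + p$ks_IGF1 * G^p$hill_n)

#' Jacobian of the biomarker subsystem
#'
#' @param G,I evaluation point (ng/ml, pg/ml).
#' @param p a [biomarker_params()] object.
#' @return 2x2 matrix, rows/cols ordered (IGF1, IL6).
#' @export
biomarker_jacobian <- function(G, I, p) {
  n <- p$hill_n
  dG_dI <- -p$kp_IGF1 * p$ks_IL6 * n * I^(n - 1) / (1 + p$ks_IL6 * I^n)^2
  dI_dG <- -p$kp_IL6 * p$ks_IGF1 * n * G^(n - 1) / (1 + p$ks_IGF1 * G^n)^2
  matrix(c(-p$kd_IGF1, dG_dI, dI_dG, -p$kd_IL6), nrow = 2, byrow = TRUE,
         dimnames = list(c("IGF1", "IL6"), c("IGF1", "IL6")))
}

#' Enumerate biomarker steady states
#'
#' Substitutes one nullcline into the other, reducing the fixed-point problem
#' to a scalar root-find in the IGF-1 coordinate; sign changes are bracketed
#' on a dense grid and polished with Brent's method, then each fixed point is
#' classified by the eigenvalues of the 2x2 Jacobian. With cooperative
#' inhibition (Hill n = 2) and strong enough coupling the system has two
#' stable states separated by a saddle; weak coupling or n = 1 gives a single
#' stable state.
#'
#' @param p a [biomarker_params()] object.
#' @param grid_n number of grid points used to bracket sign changes.
#' @param tol root residual tolerance (on the composed scalar equation,
#'   relative to the IGF-1 scale).
#' @return A data frame of class `frailty_steady_states` with columns `IGF1`,
#'   `IL6`, `stability` (`"stable"`, `"saddle"` or `"unstable"`), `eig1`,
#'   `eig2` (real parts), ordered by increasing IGF-1.
#' @examples
#' p <- biomarker_params(1, 10, 1, 1, 10, 1)
#' find_steady_states(p)
#' @export
find_steady_states <- function(p, grid_n = 800, tol = 1e-10) {
  stopifnot(inherits(p, "biomarker_params"))
  Gmax <- p$kp_IGF1 / p$kd_IGF1
  h <- function(G) G - .null_G(.null_I(G, p), p)
  xs <- seq(0, Gmax * (1 + 1e-9), length.out = grid_n)
  hs <- h(xs)
  roots <- xs[hs == 0]
  idx <- which(hs[-1] * hs[-length(hs)] < 0)
  for (i in idx) {
    r <- stats::uniroot(h, lower = xs[i], upper = xs[i + 1L],
                        tol = tol * max(1, Gmax))$root
    roots <- c(roots, r)
  }
  roots <- sort(unique(roots))
  if (length(roots) > 1L)  # dedupe near-coincident polished roots
    roots <- roots[c(TRUE, diff(roots) > 1e-8 * max(1, Gmax))]
  out <- do.call(rbind, lapply(roots, function(G) {
    I <- .null_I(G, p)
    J <- biomarker_jacobian(G, I, p)
    ev <- eigen(J, only.values = TRUE)$values
    re <- sort(Re(ev))
    stab <- if (max(re) < 0) "stable" else if (min(re) < 0 && max(re) > 0)
      "saddle" else "unstable"
    data.frame(IGF1 = G, IL6 = I, stability = stab, eig1 = re[1], eig2 = re[2])
  }))
  # residual check against the raw RHS
  for (i in seq_len(nrow(out))) {
    r <- biomarker_rhs(c(IGF1 = out$IGF1[i], IL6 = out$IL6[i]), p)
    scale <- max(p$kp_IGF1, p$kp_IL6)
    if (max(abs(r)) > 1e-6 * scale)
      stop("steady-state residual check failed at (",
           signif(out$IGF1[i], 6), ", ", signif(out$IL6[i], 6), ")")
  }
  structure(out, class = c("frailty_steady_states", "data.frame"))
}

#' @export
print.frailty_steady_states <- function(x, ...) {
  cat(sprintf("%d biomarker fixed point(s):\n", nrow(x)))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  IGF-1 = %9.4g ng/ml, IL-6 = %9.4g pg/ml  [%s]\n",
                x$IGF1[i], x$IL6[i], x$stability[i]))
  invisible(x)
}

#' Is the biomarker subsystem bistable?
#'
#' @param p a [biomarker_params()] object (or a [frailty_model()]).
#' @param ... passed to [find_steady_states()].
#' @return `TRUE` when exactly two stable fixed points exist.
#' @export
is_bistable <- function(p, ...) {
  if (inherits(p, "frailty_model")) p <- p$biomarker
  ss <- find_steady_states(p, ...)
  sum(ss$stability == "stable") == 2L
}

# Stable states sorted by IGF1 (frail attractor first: low IGF-1/high IL-6).
.stable_states <- function(p, ...) {
  ss <- find_steady_states(p, ...)
  ss <- ss[ss$stability == "stable", , drop = FALSE]
  ss[order(ss$IGF1), , drop = FALSE]
}
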
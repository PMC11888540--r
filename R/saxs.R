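# Vacuum Debye scattering and Guinier analysis. The hydration-layer and
# excluded-volume corrections of crystallographic SAXS predictors are
# deliberately not modelled: curves here are for self-consistent R_g
# extraction and method testing, and differ systematically from
# experimental solution curves.

# Coarse single-Gaussian atomic form factors: f(q) = Z exp(-b q^2), with
# q in nm^-1. b is a per-element width giving a plausible small-angle
# fall-off; adequate for Guinier-region work, not for wide-angle fits.
.FORM_FACTORS <- data.frame(
  element = c("H", "C", "N", "O", "S", "P"),
  Z = c(1, 6, 7, 8, 16, 15),
  b = c(2.3e-3, 1.0e-3, 8.0e-4, 6.5e-4, 4.0e-4, 4.5e-4))

#' Tabulated single-Gaussian atomic form factors
#'
#' @param elements Character vector of element symbols (H, C, N, O, S, P).
#' @param q Numeric vector of momentum transfer values (nm^-1).
#' @return length(elements) x length(q) matrix of f(q).
#' @export
atomic_form_factors <- function(elements, q) {
  i <- match(toupper(elements), .FORM_FACTORS$element)
  if (anyNA(i)) stop("no form factor for element(s): ",
                     paste(unique(elements[is.na(i)]), collapse = ", "))
  outer(seq_along(i), seq_along(q), function(a, b)
    .FORM_FACTORS$Z[i[a]] * exp(-.FORM_FACTORS$b[i[a]] * q[b]^2))
}

#' Debye scattering curve of one frame
#'
#' Orientationally averaged intensity
#' `I(q) = sum_i sum_j f_i f_j sin(q r_ij)/(q r_ij)`, with the q -> 0
#' and i = j limits handled analytically (`sinc -> 1`), so
#' `I(0) = (sum f_i)^2` for constant form factors.
#'
#' @param xyz N x 3 coordinates (nm) or an [ff_frame()].
#' @param q Numeric vector of q values (nm^-1, >= 0).
#' @param f Form factors: a scalar, a per-atom vector, or an
#'   N x length(q) matrix (e.g. from [atomic_form_factors()]).
#' @return data.frame of class `saxs_curve` with columns `q`, `I`.
#' @export
debye_saxs <- function(xyz, q, f = 1) {
  if (inherits(xyz, "ff_frame")) xyz <- xyz$xyz
  xyz <- as.matrix(xyz)
  if (any(q < 0)) stop("q must be >= 0")
  n <- nrow(xyz)
  fq <- if (is.matrix(f)) f else matrix(rep_len(f, n), nrow = n, ncol = length(q))
  if (nrow(fq) != n || ncol(fq) != length(q))
    stop("form factors must be scalar, length-N, or N x length(q)")
  D <- as.matrix(stats::dist(xyz))
  ut <- which(upper.tri(D))
  rij <- D[ut]
  I <- numeric(length(q))
  for (k in seq_along(q)) {
    fk <- fq[, k]
    self <- sum(fk^2)
    ff <- outer(fk, fk)[ut]
    s <- if (q[k] == 0) rep(1, length(rij)) else {
      x <- q[k] * rij
      ifelse(x == 0, 1, sin(x) / x)
    }
    I[k] <- self + 2 * sum(ff * s)
  }
  structure(data.frame(q = q, I = I), class = c("saxs_curve", "data.frame"))
}

#' Guinier analysis of a scattering curve
#'
#' Linear fit of `ln I` against `q^2` in the low-q window, giving
#' `R_g = sqrt(-3 * slope)` and `I0 = exp(intercept)`. The window is
#' found self-consistently: an initial fit on the smallest-q points
#' yields an R_g estimate, the window is re-cut at `q * R_g <= qrg_max`,
#' and the fit is repeated until the window stabilizes.
#'
#' @param curve A `saxs_curve` (or data.frame with `q`, `I`).
#' @param qrg_max Upper limit of `q * R_g` for the fit window
#'   (default 1.3, the conventional Guinier validity bound).
#' @param min_points Minimum points required in the window.
#' @return List of class `guinier_fit`: `rg`, `i0`, `window` (q-range
#'   used), `n_points`, `slope`.
#' @export
guinier_rg <- function(curve, qrg_max = 1.3, min_points = 5) {
  q <- curve$q; I <- curve$I
  keep <- q > 0
  q <- q[keep]; I <- I[keep]
  o <- order(q); q <- q[o]; I <- I[o]
  if (length(q) < min_points) stop("too few points for Guinier analysis")

  fit_window <- function(idx) {
    if (any(I[idx] <= 0))
      stop("non-positive intensities in Guinier window")
    fit <- stats::lm(log(I[idx]) ~ I(q[idx]^2))
    slope <- unname(stats::coef(fit)[2])
    if (slope >= 0) stop("non-decreasing intensity: Guinier fit undefined")
    list(rg = sqrt(-3 * slope), i0 = exp(unname(stats::coef(fit)[1])),
         slope = slope)
  }

  idx <- seq_len(min_points)
  res <- fit_window(idx)
  for (iter in 1:50) {
    new_idx <- which(q * res$rg <= qrg_max)
    if (length(new_idx) < min_points) new_idx <- seq_len(min_points)
    if (identical(new_idx, idx)) break
    idx <- new_idx
    res <- fit_window(idx)
  }
  structure(list(rg = res$rg, i0 = res$i0, window = range(q[idx]),
                 n_points = length(idx), slope = res$slope),
            class = "guinier_fit")
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf("<guinier_fit> Rg = %.4f nm, I0 = %.4g (%d pts, q in [%.3g, %.3g])\n",
              x$rg, x$i0, x$n_points, x$window[1], x$window[2]))
  invisible(x)
}
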
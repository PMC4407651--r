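#' Convert matric potential (kPa) to hydraulic head (cm) and back
#'
#' Uses the same water density and gravitational acceleration as the flow
#' module (`rho` = 1000 kg m^-3, `g` = 9.8 m s^-2), giving 10.2041 cm of
#' water column per kPa.
#'
#' @param potential_kpa Matric potential (kPa, <= 0).
#' @param head_cm Hydraulic head (cm, >= 0).
#' @return Head in cm (or potential in kPa for the inverse).
#' @export
#' @examples
#' head_from_potential(-75)
#' potential_from_head(head_from_potential(-75))
head_from_potential <- function(potential_kpa) {
  abs(potential_kpa) * water_constants()$kpa_to_cm
}

#' @rdname head_from_potential
#' @export
potential_from_head <- function(head_cm) {
  -head_cm / water_constants()$kpa_to_cm
}

#' Van Genuchten parameter set
#'
#' @param theta_s Saturated volumetric water content (fraction).
#' @param alpha Inverse air-entry scale (cm^-1), > 0.
#' @param n Shape parameter, > 1; `m = 1 - 1/n` is derived, never free.
#' @param theta_r Residual water content (taken as 0 here).
#' @param Ksat Saturated hydraulic conductivity (cm/s), optional.
#' @return Object of class `vg_params`.
#' @export
vg_params <- function(theta_s, alpha, n, theta_r = 0, Ksat = NA_real_) {
  if (!(alpha > 0)) stop("alpha must be positive")
  if (!(n > 1)) stop("n must exceed 1")
  if (!(theta_r >= 0 && theta_r < theta_s && theta_s <= 1))
    stop("need 0 <= theta_r < theta_s <= 1")
  structure(list(theta_s = theta_s, theta_r = theta_r, alpha = alpha,
                 n = n, m = 1 - 1 / n, Ksat = Ksat),
            class = "vg_params")
}

#' @export
print.vg_params <- function(x, ...) {
  cat(sprintf("vg_params: theta_s %.3f, theta_r %.3f, alpha %.4g /cm, n %.3f (m %.3f)",
              x$theta_s, x$theta_r, x$alpha, x$n, x$m))
  if (!is.na(x$Ksat)) cat(sprintf(", Ksat %.4g cm/s", x$Ksat))
  cat("\n")
  invisible(x)
}

#' Van Genuchten water retention curve
#'
#' `theta(h) = (theta_s - theta_r) * (1 + (alpha h)^n)^(-m) + theta_r`.
#'
#' @param h Hydraulic head (cm, >= 0); vectorised.
#' @param p A [vg_params()].
#' @return Volumetric water content.
#' @export
#' @examples
#' vg_theta(0, vg_params(0.458, 0.052, 1.65))
vg_theta <- function(h, p) {
  stopifnot(inherits(p, "vg_params"))
  if (any(h < 0)) stop("head must be non-negative")
  (p$theta_s - p$theta_r) * (1 + (p$alpha * h)^p$n)^(-p$m) + p$theta_r
}

#' Van Genuchten relative hydraulic conductivity
#'
#' `k_r(h) = {1 - (alpha h)^(n-1) [1 + (alpha h)^n]^(-m)}^2 /
#'           [1 + (alpha h)^n]^(m/2)`, with `K = Ksat * k_r`.
#'
#' @inheritParams vg_theta
#' @return Relative conductivity in \[0, 1\] (values outside by less than
#'   1e-12 are clipped).
#' @export
vg_relative_k <- function(h, p) {
  stopifnot(inherits(p, "vg_params"))
  if (any(h < 0)) stop("head must be non-negative")
  ah_n <- (p$alpha * h)^p$n
  num <- (1 - (p$alpha * h)^(p$n - 1) * (1 + ah_n)^(-p$m))^2
  kr <- num / (1 + ah_n)^(p$m / 2)
  kr[kr > 1 & kr < 1 + 1e-12] <- 1
  kr[kr < 0 & kr > -1e-12] <- 0
  kr
}

# residual vector for the joint WRC + relative-conductivity fit
vg_joint_residuals <- function(par, h_theta, theta, h_k, logkr) {
  theta_s <- par[1]; alpha <- exp(par[2]); n <- 1 + exp(par[3])
  p <- list(theta_s = theta_s, theta_r = 0, alpha = alpha, n = n,
            m = 1 - 1 / n)
  class(p) <- "vg_params"
  res <- (vg_theta(h_theta, p) - theta) / max(mean(theta), 1e-6) /
    sqrt(length(theta))
  if (length(h_k)) {
    kr <- pmax(vg_relative_k(h_k, p), 1e-300)
    sc <- max(diff(range(logkr)), 1)
    res <- c(res, (log10(kr) - logkr) / sc / sqrt(length(logkr)))
  }
  res
}

#' Fit the van Genuchten model to retention (and conductivity) data
#'
#' Joint nonlinear least squares for `theta_s`, `alpha` and `n`
#' (`theta_r` fixed at 0, `m = 1 - 1/n`), minimising normalised water
#' content residuals plus, when conductivity points are supplied,
#' normalised log10 relative-conductivity residuals with equal aggregate
#' weight per dataset. `Ksat` is the supplied conductivity at saturation
#' (h = 0), not a fitted shape parameter. Levenberg-Marquardt iterations
#' are multistarted from a coarse (alpha, n) grid.
#'
#' @param wrc Data frame with columns `head_cm` and `theta` (at least 4
#'   distinct heads).
#' @param k Optional data frame with columns `head_cm` and `K_cm_s`
#'   (positive; the h = 0 row, if present, supplies `Ksat`).
#' @param alpha_grid,n_grid Multistart grids.
#' @return A [vg_params()] with attributes `rss` (residual sum of squares)
#'   and `fit` (the winning `nls.lm` object).
#' @export
#' @examples
#' truth <- vg_params(0.494, 0.032, 1.75)
#' h <- head_from_potential(c(0, -5, -10, -20, -40, -60, -75))
#' fit <- fit_vg(data.frame(head_cm = h, theta = vg_theta(h, truth)))
#' c(fit$theta_s, fit$alpha, fit$n)
fit_vg <- function(wrc, k = NULL,
                   alpha_grid = exp(seq(log(0.005), log(0.5), length.out = 6)),
                   n_grid = seq(1.1, 3.5, length.out = 6)) {
  stopifnot(is.data.frame(wrc), all(c("head_cm", "theta") %in% names(wrc)))
  if (length(unique(wrc$head_cm)) < 4)
    stop("need at least 4 distinct heads to fit theta_s, alpha and n")
  if (diff(range(wrc$theta)) <= 0)
    stop("degenerate flat water-content data")
  h_k <- numeric(0); logkr <- numeric(0); Ksat <- NA_real_
  if (!is.null(k) && nrow(k)) {
    stopifnot(all(c("head_cm", "K_cm_s") %in% names(k)))
    if (any(k$K_cm_s <= 0)) stop("conductivities must be positive")
    sat <- k$head_cm == 0
    if (any(sat)) Ksat <- mean(k$K_cm_s[sat])
    kk <- k[!sat, , drop = FALSE]
    if (is.na(Ksat)) Ksat <- max(k$K_cm_s)
    if (nrow(kk)) {
      h_k <- kk$head_cm
      logkr <- log10(kk$K_cm_s / Ksat)
    }
  }
  best <- NULL
  best_rss <- Inf
  for (a0 in alpha_grid)
    for (n0 in n_grid) {
      start <- c(max(wrc$theta), log(a0), log(n0 - 1))
      fit <- tryCatch(
        minpack.lm::nls.lm(par = start, fn = vg_joint_residuals,
                           h_theta = wrc$head_cm, theta = wrc$theta,
                           h_k = h_k, logkr = logkr,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
        error = function(e) NULL)
      if (is.null(fit)) next
      rss <- sum(fit$fvec^2)
      if (is.finite(rss) && rss < best_rss) { best_rss <- rss; best <- fit }
    }
  if (is.null(best))
    stop("van Genuchten fit failed to converge from every start")
  par <- best$par
  out <- vg_params(theta_s = par[1], alpha = exp(par[2]),
                   n = 1 + exp(par[3]), Ksat = Ksat)
  attr(out, "rss") <- best_rss
  attr(out, "fit") <- best
  out
}

#' Reference van Genuchten parameter sets for repacked sand and clay loam
#'
#' Representative saturated conductivities and retention parameters for
#' bulk and rhizosphere variants of a loamy sand and a clay loam, used as
#' generator truths in round-trip validation.
#'
#' @return Data frame: soil, Ksat_cm_s, theta_s, alpha_cm, n.
#' @export
soil_presets <- function() {
  data.frame(
    soil = c("bulk_sand", "rhizosphere_sand", "bulk_clay", "rhizosphere_clay"),
    Ksat_cm_s = c(0.00215, 0.00246, 0.00321, 0.00109),
    theta_s = c(0.458, 0.450, 0.494, 0.446),
    alpha_cm = c(0.052, 0.064, 0.032, 0.051),
    n = c(1.65, 1.77, 1.75, 1.98))
}

#' REV convergence statistics of conductivity results
#'
#' Mean and standard deviation of hydraulic conductivity per dyadic level,
#' with nominal REV volume and a convergence flag comparing successive
#' level means.
#'
#' @param results List of `conductivity_result`-like rows: a data frame
#'   with columns `j`, `K_h_cm_s` and optionally `volume_mm3`.
#' @param direction Unused label kept for bookkeeping.
#' @param rel_tol Convergence threshold: level j is converged when
#'   `|mean(j) - mean(j-1)| < rel_tol * |mean(j)|`.
#' @return Data frame of class `convergence_series`: j, n, mean, sd,
#'   volume_mm3, converged.
#' @export
convergence_stats <- function(results, direction = "z", rel_tol = 0.1) {
  stopifnot(is.data.frame(results), all(c("j", "K_h_cm_s") %in% names(results)))
  levels_j <- sort(unique(results$j))
  rows <- lapply(levels_j, function(j) {
    x <- results$K_h_cm_s[results$j == j]
    if (length(x) < 2) {
      warning(sprintf("level j = %d has fewer than 2 results; skipped", j))
      return(NULL)
    }
    vol <- if ("volume_mm3" %in% names(results))
      mean(results$volume_mm3[results$j == j]) else NA_real_
    data.frame(j = j, n = length(x), mean_K_h = mean(x), sd_K_h = sd(x),
               volume_mm3 = vol)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0)
    stop("no level has at least 2 results")
  rows <- rows[order(rows$j), ]
  rows$converged <- FALSE
  # walk from the largest REV (smallest j) downward in volume
  for (i in seq_len(nrow(rows))[-1]) {
    dm <- abs(rows$mean_K_h[i] - rows$mean_K_h[i - 1])
    rows$converged[i] <- is.finite(dm) &&
      dm < rel_tol * max(abs(rows$mean_K_h[i]), .Machine$double.eps)
  }
  class(rows) <- c("convergence_series", "data.frame")
  attr(rows, "direction") <- direction
  rows
}
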
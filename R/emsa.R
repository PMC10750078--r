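#' Background-correct band intensities
#'
#' Subtracts blank-region background from bound and unbound band
#' intensities, clamping negative results to zero (blank-region noise
#' routinely exceeds faint bands); clamping events are reported in the
#' `n_clamped` attribute and a warning.
#'
#' @param bound_raw,unbound_raw,background numeric vectors of raw
#'   intensities (all >= 0)
#' @return list with `bound` and `unbound` corrected intensities
#' @export
correct_background <- function(bound_raw, unbound_raw, background) {
  if (any(c(bound_raw, unbound_raw) < 0))
    stop("raw intensities must be non-negative")
  b <- bound_raw - background
  u <- unbound_raw - background
  n_clamped <- sum(b < 0) + sum(u < 0)
  if (n_clamped > 0)
    warning(n_clamped, " corrected intensit(ies) clamped to zero")
  out <- list(bound = pmax(b, 0), unbound = pmax(u, 0))
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Fraction of DNA bound
#'
#' `bound / (bound + unbound)`, per lane.  Lanes where both intensities are
#' zero are undefined and returned as `NA` with their indices in the
#' `undefined` attribute.
#'
#' @param bound,unbound corrected intensities (>= 0)
#' @return numeric vector in `[0, 1]` (NA where undefined)
#' @export
fraction_bound <- function(bound, unbound) {
  tot <- bound + unbound
  y <- ifelse(tot > 0, bound / tot, NA_real_)
  und <- which(tot == 0)
  if (length(und))
    warning("fraction bound undefined (both bands zero) for lane(s): ",
            paste(und, collapse = ", "))
  attr(y, "undefined") <- und
  y
}

#' Build binding points from a lane table
#'
#' Applies background correction and the bound/(bound+unbound) ratio to a
#' lane quantification table.
#'
#' @param lanes data.table with `concentration_nM`, `bound`, `unbound`,
#'   `background` (and optionally `replicate`)
#' @return data.table with `concentration`, `fraction`, `replicate`
#' @export
binding_points <- function(lanes) {
  lanes <- as.data.table(lanes)
  corr <- correct_background(lanes$bound, lanes$unbound, lanes$background)
  y <- fraction_bound(corr$bound, corr$unbound)
  data.table(concentration = lanes$concentration_nM,
             fraction = as.numeric(y),
             replicate = lanes$replicate %||% 1L)
}

#' Fit the one-site specific-binding model
#'
#' Least-squares fit of `Y = Bmax * X / (Kd + X)` to (concentration,
#' fraction bound) points.  Replicates are pooled into one fit by default
#' (preserving the error structure); `average_replicates = TRUE` first
#' averages fractions per concentration, mirroring curves drawn through
#' mean points.  Initialization: `Bmax0 = max(Y)`, `Kd0 =` the
#' concentration whose Y is nearest `Bmax0 / 2`.  Standard errors come
#' from the curvature of the least-squares surface at the optimum.
#'
#' @param points data.table from [binding_points()] (columns
#'   `concentration`, `fraction`; NA fractions are dropped)
#' @param constrain_bmax constrain `Bmax <= 1`
#' @param average_replicates average fractions per concentration before
#'   fitting
#' @return object of class `binding_fit`: `bmax`, `kd`, `se_bmax`,
#'   `se_kd`, `rss`, `converged`, `n_points`
#' @export
fit_one_site <- function(points, constrain_bmax = FALSE,
                         average_replicates = FALSE) {
  pts <- as.data.table(points)[!is.na(fraction)]
  if (average_replicates)
    pts <- pts[, .(fraction = mean(fraction)), by = concentration]
  if (length(unique(pts$concentration)) < 3)
    stop("need at least 3 distinct concentrations")
  if (var(pts$fraction) == 0)
    stop("all fraction-bound values equal: Kd is unidentifiable")
  bmax0 <- max(pts$fraction)
  kd0 <- pts$concentration[which.min(abs(pts$fraction - bmax0 / 2))]
  if (kd0 <= 0) kd0 <- min(pts$concentration)
  upper <- if (constrain_bmax) c(Bmax = 1, Kd = Inf) else
    c(Bmax = Inf, Kd = Inf)
  fit <- tryCatch(
    minpack.lm::nlsLM(fraction ~ Bmax * concentration / (Kd + concentration),
                      data = pts,
                      start = list(Bmax = bmax0, Kd = kd0),
                      lower = c(Bmax = 1e-12, Kd = 1e-12), upper = upper,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) stop("one-site fit failed to converge: ",
                             conditionMessage(e)))
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(NA_real_, NA_real_))
  structure(list(bmax = unname(est["Bmax"]), kd = unname(est["Kd"]),
                 se_bmax = unname(se[1]), se_kd = unname(se[2]),
                 rss = sum(stats::resid(fit)^2),
                 converged = fit$convInfo$isConv %||% TRUE,
                 n_points = nrow(pts)),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("one-site fit: Bmax = %.3f (SE %.3g), Kd = %.1f nM (SE %.3g), RSS = %.3g\n",
              x$bmax, x$se_bmax, x$kd, x$se_kd, x$rss))
  invisible(x)
}

#' Compare reference- and alternate-allele binding fits
#'
#' Direction is `"increased"` (binding affinity up) when the alternate Kd
#' is below the reference Kd by more than the combined standard error,
#' `"decreased"` for the reverse, and `"unchanged"` otherwise.
#'
#' @param fit_ref,fit_alt `binding_fit` objects
#' @return list with `delta_kd` (alt - ref), `kd_ratio` (alt / ref),
#'   `direction`
#' @export
compare_alleles <- function(fit_ref, fit_alt) {
  if (!isTRUE(fit_ref$converged) || !isTRUE(fit_alt$converged))
    stop("both fits must have converged")
  se_comb <- sqrt(fit_ref$se_kd^2 + fit_alt$se_kd^2)
  dk <- fit_alt$kd - fit_ref$kd
  direction <- if (is.na(se_comb)) "unchanged"
  else if (dk < -se_comb) "increased"
  else if (dk > se_comb) "decreased"
  else "unchanged"
  list(delta_kd = dk, kd_ratio = fit_alt$kd / fit_ref$kd,
       direction = direction)
}
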
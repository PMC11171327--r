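#' Four-parameter logistic response function
#'
#' `signal = bottom + (top - bottom) / (1 + (conc/ic50)^hill)`.  At zero
#' concentration the power term vanishes and the signal equals `top`; at
#' `conc == ic50` the signal is the midpoint `(top + bottom)/2`.
#'
#' @param conc Concentration vector (>= 0).
#' @param top,bottom,hill,ic50 Curve parameters; `hill > 0`, `ic50 > 0`.
#' @return Predicted signal vector.
#' @export
four_pl <- function(conc, top, bottom, hill, ic50) {
  pw <- ifelse(conc > 0, (conc / ic50)^hill, 0)
  bottom + (top - bottom) / (1 + pw)
}

#' Fit a four-parameter logistic concentration-response curve
#'
#' Least-squares fit of the 4PL model by bounded quasi-Newton optimization
#' over (top, bottom, log ic50, log hill).  Initialization: top and bottom
#' from the max/min of dose-averaged signals; ic50 by log-linear
#' interpolation of the dose pair bracketing the half-maximal signal; a
#' multi-start over hill in {0.5, 1, 2} guards against the hill/ic50
#' trade-off.  Constraints: bottom >= 0, hill in (0.1, 10]; a fit that ends
#' on a bound or on degenerate (flat) data is flagged `converged = FALSE`.
#' Zero-concentration wells anchor the top asymptote and enter the residuals
#' but contribute nothing to the power term.
#'
#' @param concentrations Dose vector; at least 4 distinct positive values.
#' @param signals Measured response, same length.
#' @return List of class `"dose_response_fit"`: `top`, `bottom`, `hill`,
#'   `ic50`, `rss`, `converged`.
#' @examples
#' d <- simulate_dose_response(top = 1, bottom = 0, hill = 1, ic50 = 100)
#' fit_4pl(d$concentration, d$signal)$ic50
#' @export
fit_4pl <- function(concentrations, signals) {
  conc <- as.numeric(concentrations)
  y <- as.numeric(signals)
  if (length(conc) != length(y))
    stop("concentrations and signals must have equal length", call. = FALSE)
  if (anyNA(conc) || anyNA(y) || any(!is.finite(y)))
    stop("signals and concentrations must be finite", call. = FALSE)
  if (length(unique(conc[conc > 0])) < 4L)
    stop("need at least 4 distinct positive concentrations", call. = FALSE)

  mu_t <- tapply(y, conc, mean)
  doses <- as.numeric(names(mu_t))
  mu <- unname(mu_t)
  flat_result <- structure(
    list(top = max(y), bottom = min(y), hill = NA_real_, ic50 = NA_real_,
         rss = sum((y - mean(y))^2), converged = FALSE),
    class = "dose_response_fit")
  if (diff(range(y)) <= .Machine$double.eps * max(1, abs(mean(y))) * 100)
    return(flat_result)

  top0 <- max(mu); bot0 <- min(mu)
  half <- (top0 + bot0) / 2
  pos <- doses > 0
  dmu <- mu[pos]; dd <- doses[pos]
  # log-linear interpolation of the dose bracketing the half signal
  ic0 <- exp(mean(log(range(dd))))
  below <- which(dmu <= half)
  if (length(below) && below[1] > 1L) {
    i <- below[1]
    f <- (dmu[i - 1] - half) / (dmu[i - 1] - dmu[i])
    ic0 <- exp(log(dd[i - 1]) + f * (log(dd[i]) - log(dd[i - 1])))
  }

  obj <- function(par) {
    pred <- four_pl(conc, top = par[1], bottom = par[2],
                    hill = exp(par[4]), ic50 = exp(par[3]))
    sum((y - pred)^2)
  }
  lower <- c(-Inf, 0, log(min(dd)) - log(1e4), log(0.1))
  upper <- c(Inf, Inf, log(max(dd)) + log(1e4), log(10))
  best <- NULL
  for (h0 in c(0.5, 1, 2)) {
    start <- c(top0, max(bot0, 0), log(ic0), log(h0))
    fit <- tryCatch(
      stats::optim(start, obj, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) return(flat_result)

  hill <- exp(best$par[4]); ic50 <- exp(best$par[3])
  on_bound <- best$par[4] <= log(0.1) + 1e-8 || best$par[4] >= log(10) - 1e-8 ||
    best$par[3] <= lower[3] + 1e-8 || best$par[3] >= upper[3] - 1e-8
  structure(
    list(top = best$par[1], bottom = best$par[2], hill = hill, ic50 = ic50,
         rss = best$value,
         converged = best$convergence == 0 && !on_bound),
    class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (!x$converged && is.na(x$ic50)) {
    cat("4PL fit: not converged (flat or degenerate data)\n")
  } else {
    cat(sprintf("4PL fit: top %.4g, bottom %.4g, hill %.3g, IC50 %.4g (rss %.3g%s)\n",
                x$top, x$bottom, x$hill, x$ic50, x$rss,
                if (x$converged) "" else "; NOT converged"))
  }
  invisible(x)
}

#' Fold-potentiation between two dose-response fits
#'
#' Sensitization of a drug by a fixed-concentration partner is summarized as
#' the ratio of IC50s: `fold = ic50_single / ic50_combo`.  A fold above 1
#' means the combination is more potent.
#'
#' @param fit_single 4PL fit of the drug alone.
#' @param fit_combo 4PL fit of the drug plus the sensitizer.
#' @param label Arm label (e.g. the sensitizer name) carried on the result.
#' @return List of class `"potentiation_result"`: `ic50_single`,
#'   `ic50_combo`, `fold`, `label`.
#' @export
potentiation_fold <- function(fit_single, fit_combo, label = "combination") {
  stopifnot(inherits(fit_single, "dose_response_fit"),
            inherits(fit_combo, "dose_response_fit"))
  if (is.na(fit_single$ic50) || is.na(fit_combo$ic50))
    stop("both fits must have a defined IC50", call. = FALSE)
  structure(list(ic50_single = fit_single$ic50, ic50_combo = fit_combo$ic50,
                 fold = fit_single$ic50 / fit_combo$ic50, label = label),
            class = "potentiation_result")
}

#' Further potentiation by a resistance-pathway modulator
#'
#' Same ratio contract as [potentiation_fold()], labeled for a modulator arm:
#' e.g. how much an MGMT inhibitor (O6-benzylguanine) lowers the IC50 of an
#' already-sensitized combination.
#'
#' @param fit_combo 4PL fit of the combination alone.
#' @param fit_combo_plus_modulator 4PL fit with the modulator added.
#' @param label Modulator label.
#' @return A `"potentiation_result"` with `fold =
#'   ic50(combo) / ic50(combo + modulator)`.
#' @export
potentiation_with_modulator <- function(fit_combo, fit_combo_plus_modulator,
                                        label = "modulator") {
  potentiation_fold(fit_combo, fit_combo_plus_modulator, label = label)
}

#' @export
print.potentiation_result <- function(x, ...) {
  cat(sprintf("Potentiation (%s): IC50 %.4g -> %.4g, fold %.3g\n",
              x$label, x$ic50_single, x$ic50_combo, x$fold))
  invisible(x)
}
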
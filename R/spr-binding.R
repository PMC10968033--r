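# SPR equilibrium analysis: double referencing, equilibrium response
# extraction, sorption-isotherm construction and 1:1 (Langmuir) binding
# model fitting with saturation-adequacy diagnostics.

#' Construct a sorption isotherm
#'
#' Equilibrium SPR responses as a function of analyte concentration.
#' Duplicate concentrations are allowed (and enter a fit as independent
#' residuals).
#'
#' @param concentration analyte concentrations (mM Eq Gly), all > 0.
#' @param response equilibrium responses (RU).
#' @param sample_id optional label.
#' @return Data.frame of class `isotherm`.
#' @export
isotherm <- function(concentration, response, sample_id = "") {
  if (length(concentration) != length(response)) {
    stop("concentration and response must have equal length")
  }
  if (any(concentration <= 0)) stop("concentrations must be > 0")
  structure(
    data.frame(concentration = as.numeric(concentration),
               response = as.numeric(response)),
    class = c("isotherm", "data.frame"), sample_id = sample_id
  )
}

#' Read an isotherm CSV (columns: concentration_mM_eq_gly, response_RU)
#' @param path CSV path.
#' @param sample_id optional label.
#' @export
read_isotherm <- function(path, sample_id = "") {
  df <- utils::read.csv(path)
  for (col in c("concentration_mM_eq_gly", "response_RU")) {
    if (!col %in% names(df)) {
      stop(sprintf("format error: missing column '%s'", col))
    }
  }
  isotherm(df$concentration_mM_eq_gly, df$response_RU, sample_id)
}

#' Write an isotherm CSV
#' @param iso an [isotherm()].
#' @param path output path.
#' @export
write_isotherm <- function(iso, path) {
  utils::write.csv(
    data.frame(concentration_mM_eq_gly = iso$concentration,
               response_RU = iso$response),
    path, row.names = FALSE)
  invisible(path)
}

#' Double referencing of SPR series
#'
#' Subtracts the reference flow cell pointwise and the average of the two
#' buffer-blank runs (each itself reference-subtracted) bracketing the
#' sample series: `corrected = (active - reference) -
#' mean(blank_before - its reference, blank_after - its reference)`.
#'
#' @param active,reference time-aligned RU series of equal length.
#' @param blank_before,blank_after buffer-blank RU series (active channel).
#' @param blank_before_reference,blank_after_reference reference-channel
#'   series for the blanks; default 0 (blanks already referenced).
#' @return Corrected RU series.
#' @export
double_reference <- function(active, reference, blank_before, blank_after,
                             blank_before_reference = 0,
                             blank_after_reference = 0) {
  n <- length(active)
  series <- list(reference, blank_before, blank_after)
  if (any(vapply(series, length, integer(1)) != n)) {
    stop("all series must have equal length")
  }
  bb <- blank_before - blank_before_reference
  ba <- blank_after - blank_after_reference
  (active - reference) - (bb + ba) / 2
}

#' Equilibrium response from a corrected sensorgram
#'
#' Mean corrected response over the final `tail_seconds` of the association
#' window (default 10 s of a 270 s injection).
#'
#' @param time time points (s).
#' @param response corrected RU series.
#' @param window association window `c(start, end)` in seconds.
#' @param tail_seconds averaging window at the end of association.
#' @return Scalar RU.
#' @export
equilibrium_response <- function(time, response, window,
                                 tail_seconds = 10) {
  if (length(time) != length(response)) {
    stop("time and response must have equal length")
  }
  if (tail_seconds <= 0) stop("tail_seconds must be > 0")
  if (tail_seconds > diff(window)) {
    stop("tail longer than association window")
  }
  sel <- time >= window[2] - tail_seconds & time <= window[2]
  if (!any(sel)) stop("no samples in equilibrium tail")
  mean(response[sel])
}

langmuir_response <- function(conc, rmax, kd, offset = 0) {
  rmax * conc / (kd + conc) + offset
}

#' Fit the 1:1 (Langmuir) binding model to an isotherm
#'
#' Nonlinear least squares of `R(C) = R_max * C / (K_D + C)` on the linear
#' response scale with unweighted residuals, via Levenberg-Marquardt.
#' Initialization: `R_max0 = 1.1 * max(response)`, `K_D0` = the
#' concentration whose response is nearest `R_max0 / 2`. Convergence when
#' the relative parameter change drops below 1e-10 (at most 500
#' iterations). Standard errors come from the residual-variance-scaled
#' inverse curvature (Gauss-Newton approximation) at the optimum.
#'
#' @param iso an [isotherm()] with >= 4 distinct concentrations (plus one
#'   extra distinct point when fitting an offset).
#' @param fit_offset also fit a constant response offset (sensitivity
#'   analysis; by default offsets are assumed already subtracted during
#'   isotherm construction).
#' @return Object of class `binding_fit` with `kd`, `rmax`, `se_kd`,
#'   `se_rmax`, `residual_sse`, `cmax`, `saturation_flag` (set by
#'   [saturation_check()], `NA` here), and `offset` if fitted.
#' @export
fit_langmuir <- function(iso, fit_offset = FALSE) {
  stopifnot(inherits(iso, "isotherm"))
  conc <- iso$concentration
  resp <- iso$response
  n_par <- if (fit_offset) 3L else 2L
  if (length(unique(conc)) < n_par + 2L) {
    stop(sprintf("need >= %d distinct concentrations", n_par + 2L))
  }
  if (all(resp <= 0)) stop("no binding signal: all responses <= 0")

  rmax0 <- 1.1 * max(resp)
  kd0 <- conc[which.min(abs(resp - rmax0 / 2))]
  theta <- c(rmax = rmax0, kd = kd0)
  if (fit_offset) theta <- c(theta, offset = 0)

  model <- function(th) {
    langmuir_response(conc, th[["rmax"]], th[["kd"]],
                      if (fit_offset) th[["offset"]] else 0)
  }
  jacobian <- function(th) {
    denom <- th[["kd"]] + conc
    J <- cbind(rmax = conc / denom,
               kd = -th[["rmax"]] * conc / denom^2)
    if (fit_offset) J <- cbind(J, offset = rep(1, length(conc)))
    J
  }

  lambda <- 1e-3
  sse <- sum((resp - model(theta))^2)
  converged <- FALSE
  for (iter in seq_len(500L)) {
    J <- jacobian(theta)
    r <- resp - model(theta)
    A <- crossprod(J)
    g <- crossprod(J, r)
    step_ok <- FALSE
    for (try in seq_len(60L)) {
      delta <- tryCatch(
        drop(solve(A + lambda * diag(diag(A), nrow = nrow(A)), g)),
        error = function(e) NULL)
      if (!is.null(delta)) {
        cand <- theta + stats::setNames(delta, names(theta))
        if (cand[["kd"]] > 0 && cand[["rmax"]] >= 0) {
          sse_new <- sum((resp - model(cand))^2)
          if (sse_new <= sse) {
            rel_change <- max(abs(delta) / pmax(abs(theta), 1e-12))
            theta <- cand
            sse <- sse_new
            lambda <- max(lambda / 3, 1e-12)
            step_ok <- TRUE
            if (rel_change < 1e-10) converged <- TRUE
            break
          }
        }
      }
      lambda <- lambda * 5
    }
    if (!step_ok || converged) break
  }
  if (!converged && !step_ok) {
    # stalled without meeting the relative-change criterion: accept only if
    # the gradient is numerically flat, else report non-convergence
    grad <- drop(crossprod(jacobian(theta), resp - model(theta)))
    if (max(abs(grad)) > 1e-6 * max(1, sse)) {
      stop(sprintf(
        "1:1 binding fit did not converge (iter %d, sse %.4g, kd %.4g)",
        iter, sse, theta[["kd"]]))
    }
  }

  J <- jacobian(theta)
  dof <- length(resp) - n_par
  sigma2 <- if (dof > 0) sse / dof else NA_real_
  cov <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) {
    matrix(NA_real_, n_par, n_par)
  })
  se <- sqrt(pmax(diag(cov), 0))
  structure(list(
    kd = theta[["kd"]],
    rmax = theta[["rmax"]],
    offset = if (fit_offset) theta[["offset"]] else NULL,
    se_kd = se[2],
    se_rmax = se[1],
    residual_sse = sse,
    n_points = length(resp),
    cmax = max(conc),
    saturation_flag = NA,
    sample_id = attr(iso, "sample_id")
  ), class = "binding_fit")
}

#' Saturation-adequacy check for a binding fit
#'
#' When the fitted dissociation constant exceeds half the maximum assayed
#' concentration, the isotherm did not approach saturation and the fitted
#' K_D is likely an underestimation of the true value; such fits are
#' flagged. Strict inequality: `kd > cmax / 2`.
#'
#' @param fit a [fit_langmuir()] result.
#' @return The fit with `saturation_flag` set and, when flagged, an
#'   `annotation` field.
#' @export
saturation_check <- function(fit) {
  stopifnot(inherits(fit, "binding_fit"))
  fit$saturation_flag <- fit$kd > fit$cmax / 2
  fit$annotation <- if (fit$saturation_flag) {
    "likely underestimation of true K_D: no saturation within assayed range"
  } else {
    NULL
  }
  fit
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit>%s K_D = %.3g +/- %.3g mM Eq Gly, R_max = %.3g RU\n",
              if (nzchar(x$sample_id %||% "")) paste0(" ", x$sample_id) else "",
              x$kd, x$se_kd, x$rmax))
  if (isTRUE(x$saturation_flag)) cat("  [!]", x$annotation, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
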
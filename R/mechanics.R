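# Spherical Hertzian contact fitting of AFM force-indentation curves.

#' Construct a ForceCurve
#'
#' @param depth indentation depths (m), non-decreasing, >= 10 points.
#' @param force forces (N), same length.
#' @param probeRadius spherical probe radius (m; default 0.75 um).
#' @param springConstant cantilever spring constant (N/m; metadata).
#' @param label sample label.
#' @return a validated [ForceCurve-class].
#' @export
ForceCurve <- function(depth, force, probeRadius = 0.75e-6,
                       springConstant = 0.1, label = "") {
  new("ForceCurve", depth = as.numeric(depth), force = as.numeric(force),
      probeRadius = as.numeric(probeRadius),
      springConstant = as.numeric(springConstant),
      label = as.character(label))
}

#' Convert a raw deflection-vs-piezo record to indentation
#'
#' For a cantilever of spring constant k, the indentation is the piezo
#' travel minus the cantilever deflection: \eqn{\delta = z - F/k} with
#' \eqn{F = k d}. Spring-constant calibration itself (thermal noise method)
#' is out of scope; k is taken as given.
#'
#' @param zPiezo piezo displacement (m).
#' @param deflection cantilever deflection (m).
#' @param springConstant spring constant k (N/m).
#' @return list with \code{depth} (m) and \code{force} (N).
#' @export
deflectionToIndentation <- function(zPiezo, deflection, springConstant) {
  force <- springConstant * deflection
  list(depth = zPiezo - deflection, force = force)
}

#' Fit the spherical Hertzian contact model to a force curve
#'
#' Least-squares fit of
#' \eqn{F = (4/3) (E/(1-\nu^2)) \sqrt{R} (\delta - \delta_0)^{3/2}} over the
#' window \eqn{\delta - \delta_0 \in (0, \delta_{cut}]}. By default the
#' contact point is taken at \eqn{\delta_0 = 0}; with
#' \code{estimateContact = TRUE}, \eqn{\delta_0} is a free parameter bounded
#' within the pre-contact region. Initialization comes from the linearized
#' form (\eqn{F^{2/3}} is linear in \eqn{\delta}); the final estimate is a
#' Levenberg-Marquardt nonlinear least-squares fit on the native force
#' scale, so the result is robustly started but not linearization-biased.
#'
#' @param curve a [ForceCurve-class].
#' @param nu Poisson ratio assumed (default 0.5, incompressible hydrogel).
#' @param depthCutoff maximum indentation depth used (m; default 200 nm).
#' @param estimateContact fit the contact-point offset as a free parameter.
#' @return a [HertzFit-class].
#' @export
fitHertz <- function(curve, nu = 0.5, depthCutoff = 200e-9,
                     estimateContact = FALSE) {
  validObject(curve)
  R <- curve@probeRadius
  pref <- (4 / 3) / (1 - nu^2) * sqrt(R)   # F = pref * E * (d - d0)^1.5

  selectWindow <- function(d0) {
    eff <- curve@depth - d0
    which(eff > 0 & eff <= depthCutoff)
  }

  linearInit <- function() {
    # F^(2/3) = (pref*E)^(2/3) * (d - d0): slope/intercept give E0, d0
    use <- curve@force > 0 & curve@depth <= depthCutoff * 1.5
    if (sum(use) < 5L) use <- curve@force > 0
    if (sum(use) < 2L) return(c(E = 1, d0 = 0))
    y <- curve@force[use]^(2 / 3)
    x <- curve@depth[use]
    co <- stats::coef(stats::lm(y ~ x))
    slope <- max(co[[2L]], .Machine$double.eps)
    E0 <- slope^(3 / 2) / pref
    d0 <- -co[[1L]] / slope
    c(E = max(E0, .Machine$double.eps), d0 = d0)
  }

  init <- linearInit()
  if (!estimateContact) {
    idx <- selectWindow(0)
    if (length(idx) < 5L)
      stop("insufficient points: fewer than 5 depths in (0, cutoff]")
    d <- curve@depth[idx]; f <- curve@force[idx]
    fit <- try(minpack.lm::nlsLM(
      f ~ pref * E * d^1.5,
      start = list(E = init[["E"]]),
      lower = c(E = .Machine$double.eps),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error"))
      stop("Hertz fit did not converge: ", attr(fit, "condition")$message,
           " (initial E = ", signif(init[["E"]], 4), " Pa, ",
           length(idx), " points)")
    E <- stats::coef(fit)[["E"]]
    d0 <- 0
    res <- f - pref * E * d^1.5
    nUsed <- length(idx)
  } else {
    # contact offset bounded within the pre-contact region
    d0lo <- min(curve@depth)
    d0hi <- max(min(init[["d0"]] + depthCutoff / 2,
                    max(curve@depth) - depthCutoff / 2), d0lo)
    d0start <- min(max(init[["d0"]], d0lo), d0hi)
    dAll <- curve@depth; fAll <- curve@force
    fit <- try(minpack.lm::nlsLM(
      fAll ~ pref * E * pmax(dAll - d0, 0)^1.5,
      start = list(E = init[["E"]], d0 = d0start),
      lower = c(E = .Machine$double.eps, d0 = d0lo),
      upper = c(E = Inf, d0 = d0hi),
      control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
    if (inherits(fit, "try-error"))
      stop("Hertz fit did not converge: ", attr(fit, "condition")$message)
    co <- stats::coef(fit)
    d0 <- co[["d0"]]
    idx <- selectWindow(d0)
    if (length(idx) < 5L)
      stop("insufficient points: fewer than 5 depths in (0, cutoff] ",
           "after contact-offset correction")
    d <- curve@depth[idx]; f <- curve@force[idx]
    # refit E on the windowed data at the fitted contact point
    fit2 <- try(minpack.lm::nlsLM(
      f ~ pref * E * pmax(d - d0, 0)^1.5,
      start = list(E = co[["E"]]),
      lower = c(E = .Machine$double.eps),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit2, "try-error"))
      stop("Hertz fit did not converge in the windowed refit")
    E <- stats::coef(fit2)[["E"]]
    res <- f - pref * E * pmax(d - d0, 0)^1.5
    nUsed <- length(idx)
  }
  new("HertzFit", E = E, nu = nu, contactOffset = d0,
      depthCutoff = depthCutoff,
      rmsResidual = sqrt(mean(res^2)), nPointsUsed = as.integer(nUsed))
}

#' Summarize Young's moduli over replicate fits
#'
#' @param fits list of [HertzFit-class] objects (>= 2), or a numeric vector
#'   of moduli.
#' @return list with \code{meanE} (Pa), \code{sem} (sd / sqrt(n)) and
#'   \code{n}.
#' @export
summarizeModulus <- function(fits) {
  E <- if (is.numeric(fits)) fits
       else vapply(fits, function(f) f@E, numeric(1))
  if (length(E) < 2L)
    stop("summarizeModulus needs at least 2 fits")
  list(meanE = mean(E), sem = sd(E) / sqrt(length(E)), n = length(E))
}

#' Read a force curve from a two-column table
#'
#' Expects a CSV/TSV with columns \code{depth_m} and \code{force_N}
#' (header required). Probe radius and spring constant come from an
#' optional JSON sidecar (\code{<path>.json} with keys
#' \code{probe_radius_m}, \code{spring_constant_n_per_m}) or from the
#' arguments, which take precedence.
#'
#' @param path file path.
#' @param probeRadius,springConstant overrides for the sidecar values.
#' @param sep field separator (default ",").
#' @return a [ForceCurve-class].
#' @export
readForceCurve <- function(path, probeRadius = NULL, springConstant = NULL,
                           sep = ",") {
  tab <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  if (!all(c("depth_m", "force_N") %in% names(tab)))
    stop("force-curve table needs columns depth_m and force_N")
  side <- paste0(path, ".json")
  meta <- if (file.exists(side))
    jsonlite::read_json(side, simplifyVector = TRUE) else list()
  R <- if (!is.null(probeRadius)) probeRadius
       else if (!is.null(meta$probe_radius_m)) meta$probe_radius_m
       else stop("probe radius missing (argument or sidecar)")
  k <- if (!is.null(springConstant)) springConstant
       else if (!is.null(meta$spring_constant_n_per_m))
         meta$spring_constant_n_per_m else 0.1
  ForceCurve(tab$depth_m, tab$force_N, probeRadius = R, springConstant = k,
             label = basename(path))
}
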
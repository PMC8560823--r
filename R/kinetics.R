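# 1:1 Langmuir binding kinetics: closed-form simulation and global
# multi-concentration fitting of sensorgrams.
#
# Model: dR/dt = kon * C * (Rmax - R) - koff * R, giving
# association R(t) = C kon Rmax / (C kon + koff) * (1 - exp(-(C kon + koff) t))
# and dissociation R(t) = R0 * exp(-koff t). KD = koff / kon.

#' Kinetic parameter set for the 1:1 binding model
#'
#' @param kon association rate constant (M^-1 s^-1, > 0).
#' @param koff dissociation rate constant (s^-1, > 0).
#' @param rmax maximal response (RU, > 0).
#' @return list of class `kinetic_params` with the derived `kd = koff/kon`.
#' @export
kinetic_params <- function(kon, koff, rmax) {
  stopifnot(kon > 0, koff > 0, rmax > 0)
  structure(list(kon = kon, koff = koff, rmax = rmax, kd = koff / kon),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("kon  = %.4g M^-1 s^-1\nkoff = %.4g s^-1\nrmax = %.4g RU\n",
              x$kon, x$koff, x$rmax))
  cat(sprintf("KD   = %.4g M (%.2g M at 2 s.f.)\n", x$kd, signif(x$kd, 2)))
  invisible(x)
}

#' Closed-form association-phase response
#'
#' @param params a [kinetic_params()].
#' @param conc analyte concentration in M (>= 0).
#' @param times times in s from injection start (>= 0).
#' @return responses in RU; 0 throughout for `conc = 0`.
#' @export
simulate_association <- function(params, conc, times) {
  stopifnot(inherits(params, "kinetic_params"), conc >= 0)
  if (any(times < 0)) stop("negative time")
  if (conc == 0) return(numeric(length(times)))
  kobs <- conc * params$kon + params$koff
  req <- conc * params$kon * params$rmax / kobs
  req * (1 - exp(-kobs * times))
}

#' Closed-form dissociation-phase response
#'
#' @param params a [kinetic_params()].
#' @param r_start response at the start of dissociation (RU, >= 0).
#' @param times times in s from dissociation start (>= 0).
#' @return responses in RU; half-life is `log(2)/koff`.
#' @export
simulate_dissociation <- function(params, r_start, times) {
  stopifnot(inherits(params, "kinetic_params"), r_start >= 0)
  if (any(times < 0)) stop("negative time")
  r_start * exp(-params$koff * times)
}

#' Simulate a multi-concentration sensorgram series
#'
#' One trace per analyte concentration, with an association phase followed by
#' a dissociation phase, plus optional i.i.d. Gaussian noise. The
#' zero-concentration trace is the blank. Reproducible for a fixed seed.
#'
#' @param params a [kinetic_params()].
#' @param concs analyte concentrations in M (the study ladder: 0, 2, 4, 8, 16,
#'   32, 64 nM).
#' @param t_assoc,t_dissoc phase durations in s (default 300/300).
#' @param dt sampling interval in s (default 1).
#' @param noise_sd noise standard deviation in RU (default 0).
#' @param seed optional RNG seed.
#' @return list of data.frames (one per concentration) with columns `time`,
#'   `response`, `conc`, `phase`.
#' @export
simulate_series <- function(params, concs = c(0, 2, 4, 8, 16, 32, 64) * 1e-9,
                            t_assoc = 300, t_dissoc = 300, dt = 1,
                            noise_sd = 0, seed = NULL) {
  stopifnot(all(concs >= 0), t_assoc > 0, t_dissoc >= 0, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  ta <- seq(0, t_assoc, by = dt)
  td <- if (t_dissoc > 0) seq(dt, t_dissoc, by = dt) else numeric()
  out <- lapply(concs, function(cc) {
    ra <- simulate_association(params, cc, ta)
    r0 <- ra[length(ra)]
    rd <- simulate_dissociation(params, r0, td)
    resp <- c(ra, rd)
    if (noise_sd > 0) resp <- resp + stats::rnorm(length(resp), 0, noise_sd)
    data.frame(time = c(ta, t_assoc + td), response = resp, conc = cc,
               phase = c(rep("association", length(ta)),
                         rep("dissociation", length(td))),
               stringsAsFactors = FALSE)
  })
  names(out) <- format(concs, scientific = TRUE)
  out
}

#' @keywords internal
model_response <- function(kon, koff, rmax, conc, time, t_assoc) {
  kobs <- conc * kon + koff
  req <- ifelse(kobs > 0, conc * kon * rmax / kobs, 0)
  r_end <- req * (1 - exp(-kobs * t_assoc))
  ifelse(time <= t_assoc,
         req * (1 - exp(-kobs * time)),
         r_end * exp(-koff * (time - t_assoc)))
}

#' Global 1:1 fit of a sensorgram series
#'
#' Fits a single (kon, koff, Rmax) across all non-blank traces by
#' Levenberg-Marquardt least squares on log-scale parameters. A blank
#' (zero-concentration) trace, when present, is subtracted point-wise from
#' every trace before fitting. Initial values: koff from the log-slope of the
#' dissociation tail, kon from the observed-rate/concentration relation, Rmax
#' from 1.2x the maximal response; bounds kon in [1e2, 1e9], koff in [1e-6, 1].
#'
#' @param series list of sensorgram data.frames as from [simulate_series()]
#'   (columns `time`, `response`, `conc`).
#' @param t_assoc association-phase end in s; defaults to the maximal
#'   association-phase time found in the traces (the boundary is supplied, not
#'   detected).
#' @return list with `params` ([kinetic_params()]), `kd`, `residual_sd`,
#'   `se` (approximate standard errors of kon/koff/rmax), `niter`.
#' @export
fit_1to1_global <- function(series, t_assoc = NULL) {
  stopifnot(is.list(series), length(series) >= 1)
  concs <- vapply(series, function(s) s$conc[1], numeric(1))
  if (is.null(t_assoc)) {
    if (!is.null(series[[1]]$phase))
      t_assoc <- max(series[[1]]$time[series[[1]]$phase == "association"])
    else stop("t_assoc must be supplied when traces carry no phase column")
  }
  blank <- which(concs == 0)
  traces <- series[concs > 0]
  if (length(traces) < 2)
    stop("need >= 2 non-zero analyte concentrations for a global fit")
  if (length(blank)) {
    bl <- series[[blank[1]]]
    traces <- lapply(traces, function(s) {
      s$response <- s$response -
        stats::approx(bl$time, bl$response, xout = s$time, rule = 2)$y
      s
    })
  }
  time <- unlist(lapply(traces, `[[`, "time"))
  resp <- unlist(lapply(traces, `[[`, "response"))
  conc <- unlist(lapply(traces, function(s) rep(s$conc[1], nrow(s))))
  if (all(abs(resp) < .Machine$double.eps))
    stop("all-zero responses: nothing to fit")
  # initial values
  rmax0 <- max(resp) * 1.2
  tail_fit <- local({
    s <- traces[[length(traces)]]
    dd <- s[s$time > t_assoc, ]
    dd <- dd[dd$response > max(dd$response, 1e-9) * 0.05, ]
    if (nrow(dd) >= 3 && all(dd$response > 0))
      -stats::coef(stats::lm(log(dd$response) ~ dd$time))[2]
    else 1e-3
  })
  koff0 <- min(max(tail_fit, 1e-6), 1)
  # kobs ~ kon * C + koff from the early association of the top trace
  kon0 <- local({
    s <- traces[[length(traces)]]
    aa <- s[s$time <= t_assoc & s$time > 0, ]
    plateau <- max(aa$response)
    y <- 1 - aa$response / (plateau * 1.05)
    ok <- y > 0.05
    if (sum(ok) >= 3) {
      kobs <- -stats::coef(stats::lm(log(y[ok]) ~ aa$time[ok]))[2]
      max((kobs - koff0) / s$conc[1], 1e2)
    } else 1e5
  })
  kon0 <- min(kon0, 1e9)
  fn <- function(p) {
    model_response(exp(p[1]), exp(p[2]), exp(p[3]), conc, time, t_assoc) - resp
  }
  fit <- minpack.lm::nls.lm(
    par = log(c(kon0, koff0, rmax0)), fn = fn,
    lower = log(c(1e2, 1e-6, 1e-12)), upper = log(c(1e9, 1, Inf)),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14))
  if (fit$info %in% c(0, 5))
    stop("global fit did not converge (", fit$message, "); last iterate: ",
         paste(signif(exp(fit$par), 4), collapse = ", "),
         ". Check phase boundary and concentration units.")
  est <- exp(fit$par)
  dof <- length(resp) - 3
  rsd <- sqrt(sum(fit$fvec^2) / max(dof, 1))
  se <- tryCatch({
    cov_log <- rsd^2 * solve(t(fit$jacobian) %*% fit$jacobian)
    est * sqrt(pmax(diag(cov_log), 0))   # delta method back to linear scale
  }, error = function(e) rep(NA_real_, 3))
  list(params = kinetic_params(est[1], est[2], est[3]),
       kd = est[2] / est[1], residual_sd = rsd,
       se = stats::setNames(se, c("kon", "koff", "rmax")),
       niter = fit$niter)
}

#' Equilibrium dissociation constant from rate constants
#'
#' @param kon association rate (M^-1 s^-1, > 0).
#' @param koff dissociation rate (s^-1).
#' @return list with the exact quotient `kd` and `kd_2sf` rounded to 2
#'   significant figures (the precision of printed kinetic tables).
#' @export
kd_of <- function(kon, koff) {
  if (kon <= 0) stop("kon must be positive")
  kd <- koff / kon
  list(kd = kd, kd_2sf = signif(kd, 2))
}
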
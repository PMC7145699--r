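# One-site ITC binding isotherm: forward simulation (Wiseman cumulative-heat
# expression with displacement correction) and nonlinear least-squares
# fitting, plus fold-change and c-value helpers.
#
# Units: concentrations in uM, volumes in ul, molar enthalpy dH in cal/mol,
# heats in ucal (uM * ul * cal/mol = 1e-6 ucal).

#' Titration protocol
#'
#' Defaults mirror a standard iTC200 experiment: 24 x 1.6 ul injections of
#' 400 uM titrant (the protein) into 20 uM macromolecule (the DNA duplex) in
#' a 200 ul cell at 25 C.
#'
#' @param n_injections Number of injections.
#' @param injection_ul Volume per injection (ul); scalar or vector of length
#'   `n_injections`.
#' @param syringe_conc Titrant concentration in the syringe (uM).
#' @param cell_conc Macromolecule concentration in the cell (uM).
#' @param cell_volume Working cell volume V0 (ul).
#' @param temperature Temperature (C); recorded, not used by the isotherm.
#' @return List of class `"itc_protocol"`.
#' @export
itc_protocol <- function(n_injections = 24L, injection_ul = 1.6,
                         syringe_conc = 400, cell_conc = 20,
                         cell_volume = 200, temperature = 25) {
  vols <- rep_len(injection_ul, n_injections)
  stopifnot(all(vols > 0), syringe_conc > 0, cell_conc > 0, cell_volume > 0)
  structure(list(n_injections = as.integer(n_injections),
                 injection_volumes = vols, syringe_conc = syringe_conc,
                 cell_conc = cell_conc, cell_volume = cell_volume,
                 temperature = temperature),
            class = "itc_protocol")
}

#' One-site binding parameters
#'
#' @param n Stoichiometry (sites per macromolecule), > 0.
#' @param Kd Dissociation constant in uM, > 0.
#' @param dH Molar enthalpy of injectant binding (cal/mol).
#' @param q0 Per-injection baseline heat (ucal), e.g. dilution heat.
#' @return List of class `"binding_params"`.
#' @export
binding_params <- function(n = 1, Kd, dH, q0 = 0) {
  if (!is.numeric(n) || n <= 0) stop("n must be > 0")
  if (!is.numeric(Kd) || Kd <= 0) stop("Kd must be > 0 (uM)")
  structure(list(n = n, Kd = Kd, dH = dH, q0 = q0), class = "binding_params")
}

# Deterministic per-injection heats (ucal) of the one-site model.
one_site_heats <- function(n, Kd, dH, q0, protocol) {
  V0 <- protocol$cell_volume
  dV <- protocol$injection_volumes
  v <- cumsum(dV)
  Mt <- protocol$cell_conc * (1 - v / (2 * V0)) / (1 + v / (2 * V0))
  Xt <- protocol$syringe_conc * (v / V0) / (1 + v / (2 * V0))
  r <- Xt / (n * Mt)
  s <- 1 + r + Kd / (n * Mt)
  Q <- (n * Mt * dH * V0 / 2) * (s - sqrt(s^2 - 4 * r))   # uM*ul*cal/mol
  Qp <- c(0, Q[-length(Q)])
  dQ <- Q - Qp + (dV / V0) * (Q + Qp) / 2
  list(heat = dQ * 1e-6 + q0, ratio = Xt / Mt, Mt = Mt, Xt = Xt,
       Q_ucal = Q * 1e-6)
}

#' Simulate a one-site ITC thermogram
#'
#' Forward-simulates per-injection heats under the one-site (Wiseman)
#' isotherm with the symmetric displacement correction
#' `Mt = M0 (1 - v/2V0)/(1 + v/2V0)` and optional Gaussian noise.
#'
#' @param params [binding_params()].
#' @param protocol [itc_protocol()].
#' @param noise_sd Gaussian noise s.d. per injection (ucal).
#' @param seed Optional RNG seed (local to this call).
#' @return `data.frame` of class `"thermogram"`: `injection`, `volume_ul`,
#'   `molar_ratio` (Xt/Mt in the cell), `heat_ucal`.
#' @examples
#' tg <- simulate_titration(binding_params(1, Kd = 0.051, dH = -8000),
#'                          itc_protocol())
#' @export
simulate_titration <- function(params, protocol = itc_protocol(),
                               noise_sd = 0, seed = NULL) {
  stopifnot(inherits(params, "binding_params"),
            inherits(protocol, "itc_protocol"))
  h <- one_site_heats(params$n, params$Kd, params$dH, params$q0, protocol)
  heat <- h$heat
  if (noise_sd > 0)
    heat <- heat + with_seed(seed, rnorm(length(heat), 0, noise_sd))
  out <- data.frame(injection = seq_along(heat),
                    volume_ul = protocol$injection_volumes,
                    molar_ratio = h$ratio, heat_ucal = heat)
  class(out) <- c("thermogram", "data.frame")
  out
}

#' Fit the one-site binding model to a thermogram
#'
#' Nonlinear least squares (Levenberg-Marquardt via
#' [minpack.lm::nlsLM()]) of the one-site forward model over
#' `(n, Kd, dH, q0)`.  Default starting values: `n = 1`,
#' `Kd = cell_conc/10`, `dH = 5000 * sign(largest-|heat| injection)`,
#' `q0 = mean of the last 3 heats`.  Non-convergence is reported via
#' `$converged` with best-effort parameters, never silently.
#'
#' @param thermogram A `"thermogram"` (or data.frame with `heat_ucal`).
#' @param protocol The [itc_protocol()] the data were collected under.
#' @param init Optional named list overriding any of `n`, `Kd`, `dH`, `q0`.
#' @param drop_first If `TRUE`, ignore the first injection (common
#'   first-injection artifact handling); default keeps it.
#' @return Object of class `"itc_fit"` with methods `print`, `summary`,
#'   `coef`, `vcov`, `predict`, `fitted`, `residuals`, `plot`, `simulate`.
#' @examples
#' tg <- simulate_titration(binding_params(1, 0.051, -8000), itc_protocol())
#' fit <- fit_one_site(tg, itc_protocol())
#' coef(fit)
#' @export
fit_one_site <- function(thermogram, protocol = itc_protocol(), init = NULL,
                         drop_first = FALSE) {
  stopifnot(inherits(protocol, "itc_protocol"))
  heat <- thermogram$heat_ucal
  if (length(heat) < 6L) stop("need at least 6 injections to fit")
  use <- seq_along(heat)
  if (drop_first) use <- use[-1L]
  start <- list(
    n = 1,
    Kd = protocol$cell_conc / 10,
    dH = 5000 * sign(heat[which.max(abs(heat))] + .Machine$double.eps),
    q0 = mean(tail(heat, 3L))
  )
  start[names(init)] <- init
  # Internal parameterization (log Kd, dH in kcal/mol) equalizes the scale of
  # the Jacobian columns; estimates and SEs are mapped back afterwards.
  model_heat <- function(n, lKd, dHk, q0)
    one_site_heats(n, exp(lKd), dHk * 1000, q0, protocol)$heat[use]
  obs <- heat[use]
  tstart <- list(n = start$n, lKd = log(start$Kd), dHk = start$dH / 1000,
                 q0 = start$q0)
  back <- function(tcf)
    c(n = unname(tcf[["n"]]), Kd = exp(unname(tcf[["lKd"]])),
      dH = unname(tcf[["dHk"]]) * 1000, q0 = unname(tcf[["q0"]]))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      obs ~ model_heat(n, lKd, dHk, q0),
      start = tstart,
      lower = c(n = 1e-3, lKd = log(1e-9), dHk = -Inf, q0 = -Inf),
      upper = c(n = 1e3, lKd = log(1e6), dHk = Inf, q0 = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    cf <- back(unlist(tstart))
    se <- setNames(rep(NA_real_, 4L), names(cf))
    res <- obs - one_site_heats(cf[["n"]], cf[["Kd"]], cf[["dH"]],
                                cf[["q0"]], protocol)$heat[use]
    out <- list(coefficients = cf, se = se, vcov = NULL,
                fitted = obs - res, residuals = res,
                rss = sum(res^2), converged = FALSE,
                message = conditionMessage(fit))
  } else {
    tcf <- coef(fit)
    cf <- back(tcf)
    sm <- tryCatch(summary(fit), error = function(e) NULL)
    tse <- if (!is.null(sm)) sm$coefficients[names(tcf), "Std. Error"] else
      setNames(rep(NA_real_, length(tcf)), names(tcf))
    # delta method back to (n, Kd, dH, q0)
    jac <- c(1, cf[["Kd"]], 1000, 1)
    se <- setNames(unname(tse) * jac, names(cf))
    vc <- tryCatch({
      v <- vcov(fit)
      v <- diag(jac) %*% v %*% diag(jac)
      dimnames(v) <- list(names(cf), names(cf))
      v
    }, error = function(e) NULL)
    out <- list(coefficients = cf, se = se, vcov = vc,
                fitted = as.numeric(fitted(fit)),
                residuals = as.numeric(residuals(fit)),
                rss = sum(residuals(fit)^2),
                converged = fit$convInfo$isConv %||% TRUE,
                message = fit$convInfo$stopMessage %||% "")
  }
  out$identifiable <- isTRUE(out$converged) && all(is.finite(out$se)) &&
    is.finite(out$se[["Kd"]]) &&
    out$se[["Kd"]] <= abs(out$coefficients[["Kd"]])
  out$protocol <- protocol
  out$data <- thermogram
  out$use <- use
  class(out) <- "itc_fit"
  out
}

#' @export
coef.itc_fit <- function(object, ...) object$coefficients

#' @export
vcov.itc_fit <- function(object, ...) object$vcov

#' @export
fitted.itc_fit <- function(object, ...) object$fitted

#' @export
residuals.itc_fit <- function(object, ...) object$residuals

#' @rdname fit_one_site
#' @param object,x An `"itc_fit"`.
#' @param ... Unused.
#' @export
print.itc_fit <- function(x, ...) {
  cf <- x$coefficients
  cat("One-site ITC fit\n")
  cat(sprintf("  n  = %.3f\n  Kd = %.4g uM (%.1f nM)\n  dH = %.0f cal/mol\n",
              cf[["n"]], cf[["Kd"]], cf[["Kd"]] * 1000, cf[["dH"]]))
  cat(sprintf("  q0 = %.3f ucal;  RSS = %.4g ucal^2;  %s\n", cf[["q0"]],
              x$rss,
              if (x$converged) "converged" else
                paste0("NOT converged (", x$message, ")")))
  if (!x$identifiable)
    cat("  warning: parameters poorly identified (wide or undefined SEs)\n")
  invisible(x)
}

#' @export
summary.itc_fit <- function(object, ...) {
  cf <- object$coefficients
  tab <- data.frame(estimate = unname(cf), std_error = unname(object$se),
                    row.names = names(cf))
  cv <- c_value(binding_params(cf[["n"]], cf[["Kd"]], cf[["dH"]], cf[["q0"]]),
                object$protocol)
  out <- list(coefficients = tab, rss = object$rss,
              converged = object$converged,
              identifiable = object$identifiable,
              Kd_nM = cf[["Kd"]] * 1000, c_value = cv$c,
              fittable_window = cv$fittable,
              n_injections = length(object$use))
  class(out) <- "summary.itc_fit"
  out
}

#' @export
print.summary.itc_fit <- function(x, ...) {
  cat("One-site ITC fit summary\n")
  print(round(x$coefficients, 4))
  cat(sprintf("Kd = %.1f nM;  c = %.1f (%s);  RSS = %.4g over %d injections\n",
              x$Kd_nM, x$c_value,
              if (x$fittable_window) "inside fittable window 1-1000"
              else "OUTSIDE fittable window 1-1000",
              x$rss, x$n_injections))
  if (!x$converged) cat("fit did NOT converge\n")
  invisible(x)
}

#' @export
predict.itc_fit <- function(object, protocol = NULL, ...) {
  protocol <- protocol %||% object$protocol
  cf <- object$coefficients
  one_site_heats(cf[["n"]], cf[["Kd"]], cf[["dH"]], cf[["q0"]],
                 protocol)$heat
}

#' @export
simulate.itc_fit <- function(object, nsim = 1, seed = NULL, noise_sd = NULL,
                             ...) {
  noise_sd <- noise_sd %||% stats::sd(object$residuals)
  cf <- object$coefficients
  p <- binding_params(cf[["n"]], cf[["Kd"]], cf[["dH"]], cf[["q0"]])
  with_seed(seed, lapply(seq_len(nsim), function(i)
    simulate_titration(p, object$protocol, noise_sd = noise_sd)))
}

#' @export
plot.itc_fit <- function(x, ...) {
  ratio <- x$data$molar_ratio[x$use]
  graphics::plot(ratio, x$data$heat_ucal[x$use], pch = 16,
                 xlab = "molar ratio (titrant/macromolecule)",
                 ylab = "heat per injection (ucal)",
                 main = "One-site ITC isotherm", ...)
  graphics::lines(ratio, x$fitted, col = "red3", lwd = 2)
  invisible(x)
}

#' Kd fold change between two binding measurements
#'
#' @param kd_variant,kd_reference Dissociation constants (same units, > 0).
#' @return `kd_variant / kd_reference`.
#' @examples
#' fold_change(2.336, 0.051)  # 5mC-modified vs unmodified site
#' @export
fold_change <- function(kd_variant, kd_reference) {
  if (any(kd_variant <= 0) || any(kd_reference <= 0))
    stop("Kd values must be positive")
  kd_variant / kd_reference
}

#' Wiseman c-value of a titration design
#'
#' `c = n * cell_conc / Kd`; isotherms with `1 <= c <= 1000` are generally
#' fittable.
#'
#' @param params [binding_params()].
#' @param protocol [itc_protocol()].
#' @return List with `c` and logical `fittable`.
#' @export
c_value <- function(params, protocol = itc_protocol()) {
  c_val <- params$n * protocol$cell_conc / params$Kd
  list(c = c_val, fittable = c_val >= 1 && c_val <= 1000)
}

#' Write / read a thermogram as TSV
#'
#' Columns: `injection`, `volume_ul`, `molar_ratio`, `heat_ucal`.
#'
#' @param thermogram A `"thermogram"` data frame.
#' @param path File path.
#' @return `path` (write) or the thermogram (read).
#' @export
write_thermogram <- function(thermogram, path) {
  write.table(as.data.frame(thermogram), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_thermogram
#' @export
read_thermogram <- function(path) {
  out <- read.table(path, sep = "\t", header = TRUE)
  class(out) <- c("thermogram", "data.frame")
  out
}
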
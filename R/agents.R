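#' Shell parameters of an encapsulated microbubble agent
#'
#' Physicochemical constants of the stabilizing shell and core gas used by
#' the modified Rayleigh-Plesset model: shell stiffness \eqn{\chi} (the
#' elastic modulus in the restoring term \eqn{2\chi(1/R_0 - 1/R)}), the
#' specific heat ratio \eqn{\gamma} of the core gas (polytropic exponent
#' \eqn{3\gamma}), and the gas-liquid interfacial tension \eqn{\sigma}.
#' The gas compressibility \eqn{\kappa} is carried as metadata only; it does
#' not enter the model equations.
#'
#' @param name agent label (free text).
#' @param chi shell stiffness, N/m; must be >= 0.
#' @param gamma specific heat ratio of the core gas, dimensionless; >= 1.
#' @param sigma interfacial tension, N/m; >= 0.
#' @param kappa gas compressibility, m^2/N (informational, may be `NA`).
#' @return An object of class `shell_params`.
#' @examples
#' shell_params("SonoVue", chi = 0.22, gamma = 1.0934, sigma = 0.052)
#' @seealso [default_agents()] for the three shipped clinical agents.
#' @export
shell_params <- function(name, chi, gamma, sigma, kappa = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(chi) || chi < 0) stop("shell stiffness `chi` must be >= 0")
  if (!is.finite(gamma) || gamma < 1) stop("specific heat ratio `gamma` must be >= 1")
  if (!is.finite(sigma) || sigma < 0) stop("interfacial tension `sigma` must be >= 0")
  structure(
    list(name = name, chi = chi, gamma = gamma, sigma = sigma, kappa = kappa),
    class = "shell_params"
  )
}

#' @export
print.shell_params <- function(x, ...) {
  cat(sprintf("<shell_params> %s: chi = %g N/m, gamma = %g, sigma = %g N/m\n",
              x$name, x$chi, x$gamma, x$sigma))
  invisible(x)
}

#' Properties of the fluid surrounding the bubble
#'
#' Density, dynamic viscosity, sound speed, ambient pressure and vapour
#' pressure of the host liquid.  The defaults describe mouse blood at 37 C
#' with standard atmospheric pressure; every value can be overridden.
#'
#' @param rho fluid density, kg/m^3.
#' @param mu dynamic viscosity, Pa s.
#' @param c sound speed, m/s.
#' @param p0 ambient pressure, Pa.
#' @param pv vapour pressure, Pa.
#' @return An object of class `medium`.
#' @examples
#' mouse_blood()
#' medium(rho = 1000, mu = 1e-3, c = 1480) # water-like
#' @export
medium <- function(rho = 1057, mu = 5.996e-3, c = 1570,
                   p0 = 101325, pv = 6267) {
  vals <- c(rho = rho, mu = mu, c = c, p0 = p0, pv = pv)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all medium properties must be finite and strictly positive")
  }
  structure(as.list(vals), class = "medium")
}

#' @rdname medium
#' @export
mouse_blood <- function() medium()

#' @export
print.medium <- function(x, ...) {
  cat(sprintf(
    "<medium> rho = %g kg/m^3, mu = %g Pa s, c = %g m/s, p0 = %g Pa, pv = %g Pa\n",
    x$rho, x$mu, x$c, x$p0, x$pv))
  invisible(x)
}

#' Shell parameters of the three clinical contrast agents
#'
#' Literature shell constants for SonoVue (SF6, lipid shell), Sonazoid
#' (C4F10, lipid shell) and Optison (C3F8, albumin shell), as used by the
#' simulation examples throughout the package.  The same values ship as
#' plain JSON in `inst/extdata/agents.json`.
#'
#' @param path optional path to an agent parameter JSON file; the default
#'   reads the file shipped with the package.
#' @return A named list of [shell_params()] objects.
#' @examples
#' default_agents()$SonoVue
#' @export
default_agents <- function(path = system.file("extdata", "agents.json",
                                              package = "sonosim")) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(seq_len(nrow(raw)), function(i) {
    shell_params(raw$name[i], chi = raw$chi_n_m[i], gamma = raw$gamma[i],
                 sigma = raw$sigma_n_m[i], kappa = raw$kappa_m2_n[i])
  })
  names(out) <- raw$name
  out
}
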
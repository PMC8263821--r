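#' BCR model parameters
#'
#' Complete generative specification of the biased and correlated random
#' walk: three non-negative behavioural weights on top of the 8 isotropic
#' diffusion quadrants, a log-normal step-length law, an attractor ("den")
#' and the immobility distance cutoff.
#'
#' The normalising constant is `chi = 8 + p_I + p_s + p_F`: each simulated
#' step draws `x ~ U[0, chi)` and the branch (diffusion, inertia, immobile,
#' attraction) is read off the partition of `[0, chi)` for the current state.
#'
#' @param p_I inertia weight: extra probability mass on repeating the
#'   previous step's direction exactly.
#' @param p_s immobility weight: probability mass on a zero-displacement
#'   step (rest behaviour and GPS noise below `d_min`).
#' @param p_F attraction weight: extra mass on heading exactly toward the
#'   den `X_F`.
#' @param mu,sigma mean and standard deviation of the log step length
#'   (step lengths in metres are log-normal).
#' @param X_F the attractor, length-2 numeric (metres).
#' @param d_min distance cutoff (metres) below which a displacement is
#'   treated as no movement; 10 m is the typical GPS error magnitude.
#' @param T_bar nominal duration of one simulated step, minutes.
#' @return An object of class `bcr_params`.
#' @examples
#' p <- bcr_params(p_I = 0.22, p_s = 1.66, p_F = 0.24, mu = 3.03, sigma = 1.06)
#' chi_value(p)
#' @export
bcr_params <- function(p_I = 0, p_s = 0, p_F = 0, mu = 3, sigma = 1,
                       X_F = c(0, 0), d_min = 10, T_bar = 10) {
  for (w in c(p_I = p_I, p_s = p_s, p_F = p_F)) {
    if (!is.finite(w) || w < 0)
      stopf("weights p_I, p_s, p_F must be finite and non-negative (negative estimates must not feed the simulator)")
  }
  if (!is.finite(sigma) || sigma <= 0) stopf("sigma must be positive")
  if (!is.finite(mu)) stopf("mu must be finite")
  if (length(X_F) != 2 || anyNA(X_F)) stopf("X_F must be a length-2 point")
  if (d_min < 0) stopf("d_min must be non-negative")
  if (T_bar <= 0) stopf("T_bar must be positive")
  structure(list(p_I = p_I, p_s = p_s, p_F = p_F, mu = mu, sigma = sigma,
                 X_F = as.numeric(X_F), d_min = d_min, T_bar = T_bar),
            class = "bcr_params")
}

#' @rdname bcr_params
#' @param params a `bcr_params` object.
#' @export
chi_value <- function(params) 8 + params$p_I + params$p_s + params$p_F

#' @export
print.bcr_params <- function(x, ...) {
  cat(sprintf(
    "<bcr_params: p_I=%.3g p_s=%.3g p_F=%.3g (chi=%.3g), step ~ lnN(%.3g, %.3g), X_F=(%.6g, %.6g), d_min=%g m, T_bar=%g min>\n",
    x$p_I, x$p_s, x$p_F, chi_value(x), x$mu, x$sigma,
    x$X_F[1], x$X_F[2], x$d_min, x$T_bar))
  invisible(x)
}

#' Reference red-deer parameter sets
#'
#' Published parameter estimates for five GPS-collared female red deer
#' (*Cervus elaphus*) tracked at ~10-minute intervals over 5-7 months.
#' These rows serve as realistic generative truths for simulation studies
#' and for the package's parameter-recovery checks; the underlying GPS
#' tracks themselves are not public.
#'
#' @return A data.frame with columns `animal`, `p_I`, `p_F`, `p_s`, `mu`,
#'   `sigma`.
#' @export
deer_reference_params <- function() {
  data.frame(
    animal = paste0("deer", 1:5),
    p_I = c(0.01, 0.06, 0.12, 0.10, 0.22),
    p_F = c(0.01, 0.13, 0.05, 0.06, 0.24),
    p_s = c(2.01, 1.44, 1.70, 1.52, 1.66),
    mu = c(2.94, 3.15, 3.07, 3.10, 3.03),
    sigma = c(1.01, 0.97, 1.04, 0.98, 1.06)
  )
}

# bcr_params from one row of deer_reference_params()
deer_params_row <- function(animal = "deer5", X_F = c(0, 0), d_min = 10,
                            T_bar = 10) {
  tab <- deer_reference_params()
  row <- tab[tab$animal == animal, ]
  if (nrow(row) != 1) stopf("unknown reference animal '%s'", animal)
  bcr_params(p_I = row$p_I, p_s = row$p_s, p_F = row$p_F,
             mu = row$mu, sigma = row$sigma,
             X_F = X_F, d_min = d_min, T_bar = T_bar)
}
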
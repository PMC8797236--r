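## 1-D spatial structure: Gaussian connection kernel, all-to-all mixing,
## potassium diffusion and the AMPA strength gradient.

#' Gaussian connection kernel matrix
#'
#' Row-normalized kernel \code{K[i, j] ~ exp(-(x_i - x_j)^2 / lambda^2)}
#' over the truncated domain (the normalization integral is taken over the
#' finite segment, not by reflection), so each row sums to 1 and a
#' spatially uniform rate field is left unchanged. \code{lambda = 0}
#' degenerates to the identity.
#'
#' @param x node positions (um).
#' @param lambda connection length (um), nonnegative.
#' @return an \code{nx} by \code{nx} matrix.
#' @export
connection_kernel <- function(x, lambda) {
  n <- length(x)
  if (lambda <= 0) return(diag(n))
  K <- exp(-outer(x, x, "-")^2 / lambda^2)
  K / rowSums(K)
}

#' Presynaptic rate field from somatic rates
#'
#' Convolution of the somatic firing-rate field with the row-normalized
#' Gaussian kernel: \code{phi(x) = sum_j K[x, j] nu(j)}.
#'
#' @param nu somatic firing rates per node (1/ms).
#' @param lambda connection length (um).
#' @param x node positions (um).
#' @return presynaptic rate field, same length as \code{nu}.
#' @export
presynaptic_rate_field <- function(nu, lambda, x) {
  stopifnot(length(nu) == length(x), lambda >= 0)
  drop(connection_kernel(x, lambda) %*% nu)
}

#' Mix a fraction of all-to-all (domain-mean) drive into the rate field
#'
#' \code{phi' = (1 - fraction) phi + fraction * mean(nu)}; the mean is
#' taken over the somatic rates.
#'
#' @param phi presynaptic rate field (1/ms).
#' @param nu somatic rate field (1/ms).
#' @param fraction all-to-all fraction in [0, 1].
#' @return mixed rate field.
#' @export
mix_long_range <- function(phi, nu, fraction) {
  stopifnot(fraction >= 0, fraction <= 1)
  (1 - fraction) * phi + fraction * mean(nu)
}

#' Discrete diffusion operator with zero-flux boundaries
#'
#' Conservative second-difference Laplacian scaled by \code{D}: interior
#' nodes get \code{D (K[i-1] - 2 K[i] + K[i+1]) / dx^2}; boundary fluxes
#' are zero (Neumann), so the total over nodes vanishes to machine
#' precision.
#'
#' @param K_o field values per node (mM).
#' @param D diffusion coefficient (um2/ms).
#' @param dx node spacing (um).
#' @return rate field (mM/ms).
#' @export
diffusion_operator <- function(K_o, D, dx) {
  stopifnot(D >= 0, dx > 0)
  n <- length(K_o)
  flux <- diff(K_o) / dx              # n-1 interface fluxes
  (c(flux, 0) - c(0, flux)) * D / dx
}

#' Linear spatial profile of the maximal AMPA conductance onto E-cells
#'
#' \code{g(x) = g_max x / L}: zero at x = 0, maximal at x = L.
#'
#' @param x node positions (um).
#' @param g_max maximal conductance (mS/cm2).
#' @param L domain length (um); defaults to \code{max(x)}.
#' @return per-node maximal conductance.
#' @export
ampa_gradient_profile <- function(x, g_max, L = max(x)) {
  stopifnot(g_max >= 0, L > 0)
  g_max * x / L
}
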
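#' Time-basis specification for random regression curves
#'
#' Defines the family of basis functions used for every time-dependent term
#' of the test-day model: the fixed mean curves, the per-SNP effect curve,
#' and the additive-genetic and permanent-environmental random regressions.
#'
#' Two families are supported. `"legendre"` evaluates classical Legendre
#' polynomials on days-in-milk standardized to \eqn{[-1, 1]}; with
#' `normalized = TRUE` (the convention in dairy random-regression work) the
#' k-th function is \eqn{\sqrt{(2k+1)/2}\,P_k(s)}. `"wilmink"` is the
#' three-parameter lactation curve basis \eqn{[1, t, e^{-\lambda t}]};
#' it always has exactly 3 functions and ignores `order`.
#'
#' @param family `"legendre"` or `"wilmink"`.
#' @param order Highest polynomial index k, so a Legendre basis has
#'   `order + 1` functions. Ignored by the Wilmink family.
#' @param t_min,t_max Time domain in days (days in milk). Defaults cover a
#'   standard 305-day lactation starting at day 5.
#' @param normalized Logical; use the orthonormal Legendre scaling
#'   \eqn{\sqrt{(2k+1)/2}}. Normalization only reparameterizes the
#'   coefficient covariances and leaves Wald p-values unchanged.
#' @param wilmink_rate Exponential decay constant \eqn{\lambda} (1/days) of
#'   the Wilmink term.
#' @return An object of class `basis_spec`.
#' @examples
#' sp <- basis_spec("legendre", order = 2)
#' evaluate_basis(155, sp)
#' @export
basis_spec <- function(family = c("legendre", "wilmink"), order = 2,
                       t_min = 5, t_max = 305, normalized = TRUE,
                       wilmink_rate = 0.05) {
  family <- match.arg(family)
  if (length(order) != 1L || is.na(order) || order < 0 || order != floor(order))
    stop("`order` must be a single non-negative integer")
  if (!is.finite(t_min) || !is.finite(t_max) || t_min >= t_max)
    stop("time domain requires t_min < t_max")
  if (family == "wilmink" && (!is.finite(wilmink_rate) || wilmink_rate <= 0))
    stop("`wilmink_rate` must be a positive real")
  structure(
    list(family = family, order = as.integer(order),
         t_min = as.numeric(t_min), t_max = as.numeric(t_max),
         normalized = isTRUE(normalized),
         wilmink_rate = as.numeric(wilmink_rate)),
    class = "basis_spec")
}

#' @export
print.basis_spec <- function(x, ...) {
  cat(sprintf("<basis_spec> %s, %d function(s) on [%g, %g] days%s\n",
              x$family, n_basis(x), x$t_min, x$t_max,
              if (x$family == "legendre" && x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Number of basis functions of a spec
#'
#' `order + 1` for Legendre; always 3 for Wilmink.
#' @param spec A [basis_spec()].
#' @return Integer count of basis functions.
#' @export
n_basis <- function(spec) {
  if (spec$family == "wilmink") 3L else spec$order + 1L
}

#' Standardize days-in-milk to the Legendre interval
#'
#' Affine map of a time point onto \eqn{[-1, 1]}:
#' \eqn{s = 2(t - t_{min})/(t_{max} - t_{min}) - 1}.
#'
#' @param t Numeric vector of times (days).
#' @param domain Length-2 numeric `c(t_min, t_max)`.
#' @return Numeric vector in \eqn{[-1, 1]}.
#' @export
standardize_time <- function(t, domain) {
  t_min <- domain[[1]]; t_max <- domain[[2]]
  if (t_min >= t_max) stop("time domain requires t_min < t_max")
  bad <- which(t < t_min | t > t_max | !is.finite(t))
  if (length(bad))
    stop(sprintf("time(s) outside domain [%g, %g] at position(s) %s: %s",
                 t_min, t_max, paste(utils::head(bad, 5L), collapse = ", "),
                 paste(utils::head(t[bad], 5L), collapse = ", ")))
  2 * (t - t_min) / (t_max - t_min) - 1
}

# Classical Legendre polynomials P_0..P_order at standardized s via the
# three-term recurrence (k+1)P_{k+1} = (2k+1) s P_k - k P_{k-1}.
legendre_values <- function(s, order, normalized = TRUE) {
  n <- length(s)
  out <- matrix(0, n, order + 1L)
  out[, 1L] <- 1
  if (order >= 1L) out[, 2L] <- s
  if (order >= 2L) {
    for (k in 1L:(order - 1L)) {
      out[, k + 2L] <- ((2 * k + 1) * s * out[, k + 1L] - k * out[, k]) / (k + 1)
    }
  }
  if (normalized) {
    scl <- sqrt((2 * (0:order) + 1) / 2)
    out <- sweep(out, 2L, scl, `*`)
  }
  out
}

#' Evaluate the basis functions at one time point
#'
#' @param t A single time (days) inside the spec's domain.
#' @param spec A [basis_spec()].
#' @return Numeric vector of length [n_basis()]: \eqn{\varphi_k(t)} for
#'   k = 0..order (Legendre) or `c(1, t, exp(-rate * t))` (Wilmink).
#' @export
evaluate_basis <- function(t, spec) {
  drop(basis_matrix(t, spec))
}

#' Evaluate the basis at many time points
#'
#' Row r is the basis evaluated at `times[r]`; this is the \eqn{\Phi} block
#' used in the fixed and random regression design matrices.
#'
#' @param times Numeric vector of times (days), all inside the domain.
#' @param spec A [basis_spec()].
#' @return Numeric matrix `length(times) x n_basis(spec)`.
#' @export
basis_matrix <- function(times, spec) {
  stopifnot(inherits(spec, "basis_spec"))
  if (length(times) == 0L)
    return(matrix(0, 0L, n_basis(spec)))
  if (spec$family == "legendre") {
    s <- standardize_time(times, c(spec$t_min, spec$t_max))
    legendre_values(s, spec$order, spec$normalized)
  } else {
    # domain check kept for wilmink too: records outside lactation are errors
    standardize_time(times, c(spec$t_min, spec$t_max))
    cbind(1, times, exp(-spec$wilmink_rate * times), deparse.level = 0)
  }
}
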
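#' Normalized Hill activation function
#'
#' Builds the saturating transfer function used by logic-based differential
#' equation (LDE) models. The function has the form
#' \deqn{f(x) = B x^n / (K^n + x^n)}
#' with the gain \eqn{B} and half-saturation \eqn{K} derived from the Hill
#' coefficient `n` and half-activation `ec50` so that the three
#' normalization constraints hold: \eqn{f(0) = 0}, \eqn{f(EC_{50}) = 0.5},
#' and \eqn{f(1) = 1}. Closed forms (the Kraeutler/Netflux convention):
#' \eqn{B = (EC_{50}^n - 1) / (2 EC_{50}^n - 1)} and \eqn{K^n = B - 1}.
#'
#' When \eqn{2\,EC_{50}^n = 1} the derivation is singular (the denominator
#' vanishes; at `n = 1`, `ec50 = 0.5` for example) and the constrained
#' family degenerates to the identity \eqn{f(x) = x}, which is returned as
#' the limit case.
#'
#' Evaluated activities are clipped to `[0, 1]` before the Hill form is
#' applied and the output is clipped to `[0, 1]`, so that gate operands
#' remain valid even when a perturbation raises a species' `y_max` above 1.
#'
#' @param hill_n Hill coefficient \eqn{n > 0}.
#' @param ec50 Half-maximal input activity, strictly between 0 and 1.
#' @return An object of class `activation_function`: a list with fields
#'   `hill_n`, `ec50`, `beta` (the gain B), `k` (half-saturation K),
#'   `identity` (TRUE for the singular limit case) and `fn`, the vectorized
#'   transfer function.
#' @examples
#' f <- normalize_hill(1.4, 0.5)
#' f$fn(c(0, 0.5, 1))   # 0, 0.5, 1
#' normalize_hill(1, 0.5)$identity  # TRUE: singular case, f(x) = x
#' @export
normalize_hill <- function(hill_n, ec50) {
  stopifnot(is.numeric(hill_n), length(hill_n) == 1L, is.finite(hill_n),
            is.numeric(ec50), length(ec50) == 1L, is.finite(ec50))
  if (hill_n <= 0) stop("hill_n must be > 0, got ", hill_n)
  if (ec50 <= 0 || ec50 >= 1) stop("ec50 must lie strictly in (0, 1), got ", ec50)
  e <- ec50^hill_n
  den <- 2 * e - 1
  if (abs(den) < 1e-12) {
    # singular case: the constraint system forces f(x) = x
    fn <- function(x) pmin(pmax(x, 0), 1)
    out <- list(hill_n = hill_n, ec50 = ec50, beta = NA_real_, k = NA_real_,
                identity = TRUE, fn = fn)
    class(out) <- "activation_function"
    return(out)
  }
  beta <- (e - 1) / den
  kn <- beta - 1
  n <- hill_n
  fn <- function(x) {
    x <- pmin(pmax(x, 0), 1)
    pmin(pmax(beta * x^n / (kn + x^n), 0), 1)
  }
  out <- list(hill_n = hill_n, ec50 = ec50, beta = beta,
              k = if (kn > 0) kn^(1 / n) else NA_real_,
              identity = FALSE, fn = fn)
  class(out) <- "activation_function"
  out
}

#' @export
print.activation_function <- function(x, ...) {
  if (x$identity) {
    cat(sprintf("<normalized Hill: n=%g, EC50=%g (singular limit, f(x)=x)>\n",
                x$hill_n, x$ec50))
  } else {
    cat(sprintf("<normalized Hill: n=%g, EC50=%g, B=%.4g, K^n=%.4g>\n",
                x$hill_n, x$ec50, x$beta, x$beta - 1))
  }
  invisible(x)
}

check_unit_interval <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(what, " must lie in [0, 1]; got ", paste(signif(x, 6), collapse = ", "))
  invisible(x)
}

#' Continuous AND gate
#'
#' Combines activation values under "every input necessary" semantics:
#' the product of the operands. The n-ary form is the product over all
#' arguments; 1 is the identity element and 0 the annihilator.
#'
#' @param ... Activation values in `[0, 1]` (scalars or equal-length vectors).
#' @return Elementwise product.
#' @examples
#' gate_and(0.5, 0.5)  # 0.25
#' @export
gate_and <- function(...) {
  args <- list(...)
  if (length(args) == 0L) stop("gate_and needs at least one operand")
  for (a in args) check_unit_interval(a, "AND gate operand")
  Reduce(`*`, args)
}

#' Continuous OR gate
#'
#' Combines activation values under "any input sufficient" semantics:
#' `a + b - a*b` for two operands, folded pairwise for more. Equivalent to
#' `1 - prod(1 - x_i)`, hence commutative and associative; 0 is the
#' identity element and 1 the annihilator.
#'
#' @param ... Activation values in `[0, 1]` (scalars or equal-length vectors).
#' @return Elementwise OR-combination.
#' @examples
#' gate_or(0.5, 0.5)  # 0.75
#' @export
gate_or <- function(...) {
  args <- list(...)
  if (length(args) == 0L) stop("gate_or needs at least one operand")
  for (a in args) check_unit_interval(a, "OR gate operand")
  Reduce(function(a, b) a + b - a * b, args)
}
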
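# Independent oracles, derived directly from the defining constraints and
# the model tables; they never call the package's compiled-model machinery.

# Solve the normalized-Hill constraints f(ec50) = 0.5, f(1) = 1 for the
# gain/half-saturation numerically (f(0) = 0 is automatic). From f(1) = 1,
# B = Kn + 1; the remaining constraint is solved for Kn with uniroot.
oracle_hill_params <- function(n, ec50) {
  e <- ec50^n
  if (abs(2 * e - 1) < 1e-12) return(list(identity = TRUE))
  h <- function(kn) (kn + 1) * e / (kn + e) - 0.5
  interval <- if (e < 0.5) c(1e-9, 1e9) else c(-1e9, -1 - 1e-9)
  kn <- stats::uniroot(h, interval, tol = 1e-14)$root
  list(identity = FALSE, B = kn + 1, Kn = kn, n = n)
}

oracle_hill_eval <- function(par, x) {
  if (isTRUE(par$identity)) return(pmin(pmax(x, 0), 1))
  x <- pmin(pmax(x, 0), 1)
  pmin(pmax(par$B * x^par$n / (par$Kn + x^par$n), 0), 1)
}

# Damped fixed-point solver working straight off the model tables: the
# drive of each reaction is w * prod(f or 1 - f of its operands), drives
# on one target OR-fold as 1 - prod(1 - a), and y <- (1-a)y + a*ymax*g(y).
oracle_steady_state <- function(model, alpha = 0.5, tol = 1e-12,
                                max_iter = 50000L) {
  sp <- model$species
  rx <- model$reactions
  idx <- stats::setNames(seq_len(nrow(sp)), sp$id)
  pars <- lapply(seq_len(nrow(rx)),
                 function(i) oracle_hill_params(rx$hill_n[i], rx$ec50[i]))
  y <- sp$y_init
  clamped <- which(!is.na(sp$clamp))
  y[clamped] <- sp$clamp[clamped]
  for (iter in seq_len(max_iter)) {
    a <- vapply(seq_len(nrow(rx)), function(i) {
      v <- rx$weight[i]
      ops <- rx$operands[[i]]
      if (length(ops)) {
        f <- oracle_hill_eval(pars[[i]], y[idx[ops]])
        f[rx$inhibitor[[i]]] <- 1 - f[rx$inhibitor[[i]]]
        v <- v * prod(f)
      }
      v
    }, numeric(1))
    g <- vapply(sp$id, function(s) {
      k <- which(rx$target == s)
      if (!length(k)) 0 else 1 - prod(1 - a[k])
    }, numeric(1))
    target <- sp$y_max * g
    target[clamped] <- sp$clamp[clamped]
    y_new <- (1 - alpha) * y + alpha * target
    if (max(abs(y_new - y)) < tol)
      return(stats::setNames(y_new, sp$id))
    y <- y_new
  }
  stop("oracle fixed-point iteration did not converge")
}

# Iterated-Hill steady state for an input-driven linear chain at the
# default parameters: Y_1 = w_in, then Y_k = 0.9 * f(Y_{k-1}).
oracle_chain_states <- function(w_in, k) {
  par <- oracle_hill_params(1.4, 0.5)
  y <- numeric(k)
  y[1] <- w_in
  for (i in seq_len(k - 1L))
    y[i + 1L] <- 0.9 * oracle_hill_eval(par, y[i])
  y
}

expect_steady_state_matches_oracle <- function(model, tol = 1e-6) {
  ss <- steady_state(model)
  or <- oracle_steady_state(model)
  expect_lt(max(abs(ss - or[names(ss)])), tol)
}
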
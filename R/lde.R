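#' Solver configuration
#'
#' @param atol,rtol Absolute/relative integration tolerances passed to
#'   [deSolve::ode()].
#' @param method Integration method (default `"lsoda"`, stiff-safe).
#' @param t_cap Time cap for steady-state runs, in units of the model time
#'   constants (default 40; with `tau = 1` transients decay as `exp(-t)`).
#' @param ss_atol Steady-state convergence threshold on the maximum
#'   absolute rate (default 1e-8).
#' @return A list of class `solver_config`.
#' @export
solver_config <- function(atol = 1e-8, rtol = 1e-8, method = "lsoda",
                          t_cap = 40, ss_atol = 1e-8) {
  structure(list(atol = atol, rtol = rtol, method = method,
                 t_cap = t_cap, ss_atol = ss_atol),
            class = "solver_config")
}

#' Compile a network model into its LDE right-hand side
#'
#' For each species \eqn{c} the logic-based differential equation is
#' \deqn{dY_c/dt = (Y_{max,c}\, g_c(Y) - Y_c) / \tau_c}
#' where \eqn{g_c} OR-combines the drives of all reactions targeting
#' \eqn{c}; a reaction's drive is its weight times the product of the
#' normalized-Hill transfer \eqn{f(Y_i)} of its activating operands and
#' \eqn{1 - f(Y_j)} of its inhibitory operands (AND with negation); input
#' reactions contribute their weight directly. Species with no incoming
#' reaction decay to zero. Clamped species are held at their clamp value.
#'
#' @param model A valid `network_model`.
#' @return An object of class `compiled_model` with the state order, node
#'   parameter vectors, per-reaction structure and the vectorized `rhs`
#'   function used by the integrator.
#' @export
compile_model <- function(model) {
  check_model(model, warn_orphans = FALSE, perturbed = TRUE)
  sp <- model$species
  rx <- model$reactions
  ids <- sp$id
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)

  rxs <- lapply(seq_len(nrow(rx)), function(i) {
    act <- normalize_hill(rx$hill_n[i], rx$ec50[i])
    list(target = idx[[rx$target[i]]],
         weight = rx$weight[i],
         op_idx = unname(idx[rx$operands[[i]]]),
         op_inh = rx$inhibitor[[i]],
         fn = act$fn)
  })
  by_target <- lapply(seq_len(n), function(j)
    which(vapply(rxs, `[[`, integer(1), "target") == j))

  clamped <- which(!is.na(sp$clamp))
  clamp_val <- sp$clamp[clamped]
  y_max <- sp$y_max
  tau <- sp$tau

  drive <- function(y) {
    a <- vapply(rxs, function(r) {
      v <- r$weight
      if (length(r$op_idx)) {
        f <- r$fn(y[r$op_idx])
        f[r$op_inh] <- 1 - f[r$op_inh]
        v <- v * prod(f)
      }
      v
    }, numeric(1))
    vapply(by_target, function(k) {
      if (!length(k)) 0 else 1 - prod(1 - a[k])
    }, numeric(1))
  }

  rhs <- function(t, y, parms) {
    if (length(clamped)) y[clamped] <- clamp_val
    dy <- (y_max * drive(y) - y) / tau
    if (length(clamped)) dy[clamped] <- 0
    list(dy)
  }

  y0 <- sp$y_init
  if (length(clamped)) y0[clamped] <- clamp_val

  structure(list(ids = ids, n = n, y_init = y0, y_max = y_max, tau = tau,
                 clamped = clamped, clamp_val = clamp_val,
                 reactions = rxs, by_target = by_target,
                 drive = drive, rhs = rhs),
            class = "compiled_model")
}

as_compiled <- function(x) {
  if (inherits(x, "compiled_model")) x else compile_model(x)
}

#' Simulate a network model
#'
#' Integrates the LDE system from the initial state, optionally restarting
#' at event times with a modified model (e.g. stepping up the stretch input
#' at 20 minutes, adding an inhibitor later).
#'
#' @param model A `network_model`.
#' @param t_end End time (> 0).
#' @param events Optional list of events, each a list with fields `time`
#'   and `perturbation` (a [perturbation()]), sorted by time.
#' @param times Output time grid (default 201 points over `[0, t_end]`;
#'   event times are inserted).
#' @param config A [solver_config()].
#' @return An `lde_trajectory`: list with `time`, `states` (time x species
#'   matrix), `converged` (final rates below `config$ss_atol`) and
#'   `steady_state` (final state when converged, else NULL).
#' @examples
#' m <- toy_motifs()$chain
#' tr <- simulate_model(m, t_end = 10)
#' tail(as.data.frame(tr), 1)
#' @export
simulate_model <- function(model, t_end, events = NULL, times = NULL,
                           config = solver_config()) {
  stopifnot(t_end > 0)
  if (is.null(times)) times <- seq(0, t_end, length.out = 201L)
  ev_times <- vapply(events, `[[`, numeric(1), "time")
  if (is.unsorted(ev_times)) stop("events must be sorted by time")
  times <- sort(unique(c(times, ev_times, 0, t_end)))
  breaks <- c(0, ev_times[ev_times > 0 & ev_times < t_end], t_end)

  comp <- compile_model(model)
  state <- stats::setNames(comp$y_init, comp$ids)
  out_t <- numeric(0)
  out_y <- NULL
  cur <- model
  for (seg in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[seg]; t1 <- breaks[seg + 1L]
    if (seg > 1L) {
      ev <- events[[which(ev_times == t0)[1]]]
      cur <- apply_perturbation(cur, ev$perturbation)
      comp <- compile_model(cur)
      if (length(comp$clamped)) state[comp$clamped] <- comp$clamp_val
    }
    seg_times <- unique(c(t0, times[times > t0 & times < t1], t1))
    sol <- deSolve::ode(y = state, times = seg_times, func = comp$rhs,
                        parms = NULL, method = config$method,
                        atol = config$atol, rtol = config$rtol)
    if (attr(sol, "istate")[1] < 0)
      stop("integrator failure at t = ", utils::tail(sol[, 1], 1),
           "; last valid state retained in trajectory")
    y <- sol[, -1, drop = FALSE]
    keep <- if (seg < length(breaks) - 1L) seq_len(nrow(y) - 1L) else seq_len(nrow(y))
    out_t <- c(out_t, sol[keep, 1])
    out_y <- rbind(out_y, y[keep, , drop = FALSE])
    state <- stats::setNames(y[nrow(y), ], comp$ids)
  }
  colnames(out_y) <- comp$ids
  rate <- comp$rhs(t_end, state, NULL)[[1]]
  converged <- max(abs(rate)) < config$ss_atol
  structure(list(time = out_t, states = out_y, converged = converged,
                 steady_state = if (converged) state else NULL),
            class = "lde_trajectory")
}

#' @export
as.data.frame.lde_trajectory <- function(x, ...) {
  data.frame(time = x$time, x$states, check.names = FALSE)
}

#' @export
print.lde_trajectory <- function(x, ...) {
  cat(sprintf("<LDE trajectory: %d species, t in [%g, %g], %s>\n",
              ncol(x$states), min(x$time), max(x$time),
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Plot method for LDE trajectories
#' @param x An `lde_trajectory`.
#' @param species Optional subset of species ids to draw.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.lde_trajectory <- function(x, species = NULL, ...) {
  y <- x$states
  if (!is.null(species)) y <- y[, species, drop = FALSE]
  graphics::matplot(x$time, y, type = "l", lty = 1,
                    xlab = "time", ylab = "normalized activity", ...)
  graphics::legend("topleft", legend = colnames(y), lty = 1, bty = "n",
                   col = seq_len(ncol(y)), cex = 0.7)
  invisible(x)
}

#' Steady state of a network model
#'
#' Integrates the LDE system until the maximum absolute rate drops below
#' `config$ss_atol`, checking at intervals up to the time cap
#' `config$t_cap`. Non-convergence within the cap raises an error (the
#' model may be oscillatory or multistable) rather than returning the last
#' state silently.
#'
#' @param model A `network_model` or `compiled_model`.
#' @param config A [solver_config()].
#' @return Named numeric vector of converged activities.
#' @examples
#' m <- toy_motifs()$chain
#' steady_state(m)
#' @export
steady_state <- function(model, config = solver_config()) {
  comp <- as_compiled(model)
  state <- stats::setNames(comp$y_init, comp$ids)
  n_chunk <- 8L
  t_edges <- seq(0, config$t_cap, length.out = n_chunk + 1L)
  for (i in seq_len(n_chunk)) {
    sol <- deSolve::ode(y = state, times = c(t_edges[i], t_edges[i + 1L]),
                        func = comp$rhs, parms = NULL,
                        method = config$method,
                        atol = config$atol, rtol = config$rtol)
    if (attr(sol, "istate")[1] < 0)
      stop("integrator failure during steady-state run")
    state <- stats::setNames(sol[nrow(sol), -1], comp$ids)
    rate <- comp$rhs(t_edges[i + 1L], state, NULL)[[1]]
    if (max(abs(rate)) < config$ss_atol) return(state)
  }
  stop("steady state did not converge within t_cap = ", config$t_cap,
       " (max |dY/dt| = ", signif(max(abs(rate)), 3),
       "); the system may be oscillatory or multistable")
}

#' Steady state by damped fixed-point iteration
#'
#' Solves \eqn{Y = Y_{max}\, g(Y)} by the damped iteration
#' \eqn{y \leftarrow (1-\alpha) y + \alpha\, Y_{max} g(y)}. Kept as an
#' independent route to the fixed point for cross-checking the ODE solver;
#' plain iteration can fail to settle on feedback cycles, which the
#' damping mitigates.
#'
#' @param model A `network_model` or `compiled_model`.
#' @param alpha Damping factor in (0, 1], default 0.5.
#' @param tol Convergence tolerance on the update step (default 1e-10).
#' @param max_iter Iteration cap.
#' @return Named numeric vector, or an error on non-convergence.
#' @export
fixed_point_state <- function(model, alpha = 0.5, tol = 1e-10,
                              max_iter = 20000L) {
  comp <- as_compiled(model)
  y <- comp$y_init
  for (i in seq_len(max_iter)) {
    target <- comp$y_max * comp$drive(y)
    if (length(comp$clamped)) target[comp$clamped] <- comp$clamp_val
    y_new <- (1 - alpha) * y + alpha * target
    if (max(abs(y_new - y)) < tol)
      return(stats::setNames(y_new, comp$ids))
    y <- y_new
  }
  stop("fixed-point iteration did not converge in ", max_iter, " steps")
}
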
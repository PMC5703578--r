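#' Perturbation contexts
#'
#' A `perturbation` is an ordered set of actions applied to a model before
#' simulation: setting an input-reaction weight (e.g. stretch = 0.7),
#' scaling or setting a species' maximal activity `y_max` (knockdown /
#' overexpression), or clamping a species at a fixed activity. Each action
#' kind takes a named numeric vector (names are species ids); at most one
#' action per species per kind. A clamp overrides all dynamics for that
#' species.
#'
#' @param set_input Named vector of input levels in `[0, 1]`.
#' @param scale_ymax Named vector of non-negative `y_max` multipliers
#'   (0.5 = 50\% knockdown, 1.5 = 50\% increase).
#' @param set_ymax Named vector of non-negative absolute `y_max` values.
#' @param clamp Named vector of clamp values in `[0, y_max]`.
#' @return An object of class `perturbation`.
#' @examples
#' stretch <- perturbation(set_input = c(Stretch = 0.7))
#' block <- perturbation(scale_ymax = c(AT1R = 0))
#' merge_perturbations(stretch, block)
#' @export
perturbation <- function(set_input = NULL, scale_ymax = NULL,
                         set_ymax = NULL, clamp = NULL) {
  chk <- function(x, what, lo = 0, hi = Inf) {
    if (is.null(x)) return(stats::setNames(numeric(0), character(0)))
    if (is.null(names(x)) || any(names(x) == ""))
      stop(what, " actions must be a named numeric vector (names = species ids)")
    if (anyDuplicated(names(x)))
      stop("at most one ", what, " action per species")
    if (any(!is.finite(x)) || any(x < lo) || any(x > hi))
      stop(what, " values must lie in [", lo, ", ",
           if (is.finite(hi)) hi else "Inf", "]")
    x
  }
  structure(list(set_input = chk(set_input, "set_input", 0, 1),
                 scale_ymax = chk(scale_ymax, "scale_ymax"),
                 set_ymax = chk(set_ymax, "set_ymax"),
                 clamp = chk(clamp, "clamp")),
            class = "perturbation")
}

#' @export
print.perturbation <- function(x, ...) {
  parts <- unlist(lapply(names(x), function(k) {
    if (length(x[[k]]))
      sprintf("%s(%s=%g)", k, names(x[[k]]), x[[k]])
  }))
  cat("<perturbation:", if (length(parts)) paste(parts, collapse = " ")
      else "empty", ">\n")
  invisible(x)
}

#' Merge perturbations acting on disjoint species
#'
#' Applying the merged perturbation equals applying the two in sequence
#' when their species sets are disjoint per action kind.
#' @param ... `perturbation` objects.
#' @return A single `perturbation`.
#' @export
merge_perturbations <- function(...) {
  ps <- list(...)
  out <- perturbation()
  for (p in ps) {
    stopifnot(inherits(p, "perturbation"))
    for (k in names(out)) {
      if (any(names(p[[k]]) %in% names(out[[k]])))
        stop("cannot merge: duplicate ", k, " action on ",
             paste(intersect(names(p[[k]]), names(out[[k]])), collapse = ", "))
      out[[k]] <- c(out[[k]], p[[k]])
    }
  }
  out
}

#' Apply a perturbation to a model
#'
#' Returns a modified copy; the input model is never mutated. `set_input`
#' rewrites the weight of the target's input reaction(s) and errors if the
#' species has none; `scale_ymax`/`set_ymax` rewrite `y_max` (a factor of
#' 0 is a full block and is allowed here even though unperturbed models
#' require `y_max > 0`); `clamp` pins the species at a fixed activity.
#'
#' @param model A `network_model`.
#' @param p A [perturbation()].
#' @return A new `network_model`.
#' @export
apply_perturbation <- function(model, p) {
  stopifnot(inherits(model, "network_model"), inherits(p, "perturbation"))
  sp <- model$species
  rx <- model$reactions
  sp_idx <- function(id) {
    j <- match(id, sp$id)
    if (is.na(j)) stop("perturbation refers to unknown species ", sQuote(id))
    j
  }
  for (id in names(p$set_input)) {
    sp_idx(id)
    k <- which(rx$target == id & lengths(rx$operands) == 0L)
    if (!length(k))
      stop("set_input: species ", sQuote(id), " has no input reaction")
    rx$weight[k] <- p$set_input[[id]]
  }
  for (id in names(p$scale_ymax))
    sp$y_max[sp_idx(id)] <- sp$y_max[sp_idx(id)] * p$scale_ymax[[id]]
  for (id in names(p$set_ymax))
    sp$y_max[sp_idx(id)] <- p$set_ymax[[id]]
  for (id in names(p$clamp)) {
    j <- sp_idx(id)
    if (p$clamp[[id]] > sp$y_max[j] + 1e-12)
      stop("clamp value for ", sQuote(id), " exceeds its y_max")
    sp$clamp[j] <- p$clamp[[id]]
  }
  out <- model
  out$species <- sp
  out$reactions <- rx
  out
}

add_input_reaction <- function(model, species, weight) {
  if (!species %in% model$species$id)
    stop("unknown species ", sQuote(species))
  rx <- model$reactions
  k <- which(rx$target == species & lengths(rx$operands) == 0L)
  if (length(k)) {
    rx$weight[k] <- weight
  } else {
    new <- data.frame(id = paste0("input_", species),
                      rule = paste("=>", species),
                      target = species,
                      weight = weight,
                      hill_n = .default_params$hill_n,
                      ec50 = .default_params$ec50,
                      stringsAsFactors = FALSE)
    new$operands <- I(list(character()))
    new$inhibitor <- I(list(logical()))
    rx <- rbind(rx, new[, names(rx)])
  }
  model$reactions <- rx
  model
}

#' Steady-state dose-response curve
#'
#' Sweeps a fractional dose on one target in a fixed base context (for
#' example steady-state stretch) and records steady-state readouts.
#' `mode = "inhibit"` scales the target's `y_max` by `1 - level`
#' (level 1 = full block); `mode = "activate"` drives the target through
#' an input reaction with weight equal to the level (added if the target
#' has none), leaving downstream gate semantics intact.
#'
#' @param model A `network_model`.
#' @param target Species id to dose.
#' @param mode `"inhibit"` or `"activate"`.
#' @param levels Numeric vector of fractional doses in `[0, 1]`.
#' @param readouts Species ids to report.
#' @param base Optional [perturbation()] defining the context.
#' @param config A [solver_config()].
#' @return Data frame with column `level` and one column per readout,
#'   holding steady-state activities.
#' @export
dose_response <- function(model, target, mode = c("inhibit", "activate"),
                          levels, readouts, base = NULL,
                          config = solver_config()) {
  mode <- match.arg(mode)
  if (any(levels < 0 | levels > 1)) stop("levels must lie in [0, 1]")
  bad <- setdiff(c(target, readouts), model$species$id)
  if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
  ctx <- if (is.null(base)) model else apply_perturbation(model, base)
  rows <- lapply(levels, function(lv) {
    m <- dose_model(ctx, target, mode, lv)
    ss <- steady_state(m, config)
    c(level = lv, ss[readouts])
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("level", readouts)
  out
}

dose_model <- function(ctx, target, mode, level) {
  if (mode == "inhibit") {
    apply_perturbation(ctx, perturbation(
      scale_ymax = stats::setNames(1 - level, target)))
  } else {
    add_input_reaction(ctx, target, level)
  }
}

#' Two-target dose-response surface
#'
#' Joint sweep over a grid of fractional doses on two targets (e.g.
#' AT1R inhibition crossed with sGC-axis activation), each with its own
#' mode, in a shared base context.
#'
#' @param model A `network_model`.
#' @param targets Character vector of two species ids.
#' @param modes Character vector of two modes (`"inhibit"`/`"activate"`).
#' @param levels1,levels2 Dose grids for the first and second target.
#' @param readouts Species ids to report.
#' @param base Optional [perturbation()] context.
#' @param config A [solver_config()].
#' @return Long data frame: `level1`, `level2`, one column per readout.
#' @export
dose_response_grid <- function(model, targets, modes, levels1, levels2,
                               readouts, base = NULL,
                               config = solver_config()) {
  stopifnot(length(targets) == 2L, length(modes) == 2L)
  ctx <- if (is.null(base)) model else apply_perturbation(model, base)
  grid <- expand.grid(level1 = levels1, level2 = levels2,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    m <- dose_model(ctx, targets[1], modes[1], grid$level1[i])
    m <- dose_model(m, targets[2], modes[2], grid$level2[i])
    ss <- steady_state(m, config)
    c(level1 = grid$level1[i], level2 = grid$level2[i], ss[readouts])
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("level1", "level2", readouts)
  out
}

#' Read a perturbation from YAML
#'
#' Expects a YAML list of `{action, species, value}` entries where action
#' is one of `set_input`, `scale_ymax`, `set_ymax`, `clamp`.
#' @param path Path to a YAML file (or a YAML string).
#' @return A [perturbation()].
#' @export
perturbation_from_yaml <- function(path) {
  spec <- if (file.exists(path)) yaml::read_yaml(path) else yaml::yaml.load(path)
  args <- list(set_input = NULL, scale_ymax = NULL, set_ymax = NULL,
               clamp = NULL)
  for (entry in spec) {
    act <- entry$action
    if (!act %in% names(args))
      stop("unknown perturbation action ", sQuote(act))
    args[[act]] <- c(args[[act]],
                     stats::setNames(as.numeric(entry$value), entry$species))
  }
  do.call(perturbation, args)
}
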
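#' Validation configuration
#'
#' @param threshold Change threshold for calling a direction (default 0.05,
#'   i.e. a 5\% change in normalized activity).
#' @param threshold_mode `"absolute"` (default) compares the raw delta to
#'   the threshold; `"relative"` divides the delta by the reference
#'   activity first (falling back to absolute, with a flag, when the
#'   reference is zero).
#' @param stretch_level Input level of the stretched context (default 0.7).
#' @param inhibition_depth `y_max` scale factor applied to simulated
#'   inhibitors (default 0 = full block; the sensitivity analysis'
#'   half-knockdown corresponds to 0.5).
#' @param input Species id carrying the stretch input (default "Stretch").
#' @return A list of class `validation_config`.
#' @export
validation_config <- function(threshold = 0.05,
                              threshold_mode = c("absolute", "relative"),
                              stretch_level = 0.7, inhibition_depth = 0,
                              input = "Stretch") {
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(threshold > 0, stretch_level >= 0, stretch_level <= 1,
            inhibition_depth >= 0)
  structure(list(threshold = threshold, threshold_mode = threshold_mode,
                 stretch_level = stretch_level,
                 inhibition_depth = inhibition_depth, input = input),
            class = "validation_config")
}

#' Build an observation table
#'
#' One row per literature observation: the measured species, the
#' observation category (`input-output` and `input-intermediate` compare
#' stretch against no stretch; `inhibition` compares stretch plus an
#' inhibitor against stretch alone), and the observed direction
#' (`increase`, `decrease`, `no-change`). Inhibition rows must name the
#' inhibited species.
#'
#' @param measured Character vector of measured species ids.
#' @param category Character vector of categories (recycled).
#' @param direction Character vector of observed directions.
#' @param inhibit Inhibited species id per row (NA outside the inhibition
#'   category).
#' @param source Optional citation tokens.
#' @return A data frame of class `observation_table`.
#' @export
observation_table <- function(measured, category, direction,
                              inhibit = NA_character_,
                              source = NA_character_) {
  df <- data.frame(measured = as.character(measured),
                   category = as.character(category),
                   direction = as.character(direction),
                   inhibit = as.character(inhibit),
                   source = as.character(source),
                   stringsAsFactors = FALSE)
  df$inhibit[!is.na(df$inhibit) & df$inhibit == ""] <- NA_character_
  bad_cat <- setdiff(df$category,
                     c("input-output", "input-intermediate", "inhibition"))
  if (length(bad_cat)) stop("unknown category: ", paste(bad_cat, collapse = ", "))
  bad_dir <- setdiff(df$direction, c("increase", "decrease", "no-change"))
  if (length(bad_dir)) stop("unknown direction: ", paste(bad_dir, collapse = ", "))
  if (any(df$category == "inhibition" & is.na(df$inhibit)))
    stop("inhibition observations must name the inhibited species")
  class(df) <- c("observation_table", "data.frame")
  df
}

#' Read an observation table from CSV or workbook
#'
#' Expects columns `measured`, `category`, `direction` and optionally
#' `inhibit`, `source` (the layout of a validation-relationships sheet).
#' @param path CSV or `.xlsx` path.
#' @param col_map Optional named character vector remapping canonical
#'   column names to the file's headers.
#' @return An `observation_table`.
#' @export
read_observations <- function(path, col_map = NULL) {
  df <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading workbooks requires the 'readxl' package")
    as.data.frame(readxl::read_excel(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  df <- remap_columns(df, col_map)
  observation_table(df$measured, df$category, df$direction,
                    inhibit = if ("inhibit" %in% names(df)) df$inhibit else NA,
                    source = if ("source" %in% names(df)) df$source else NA)
}

#' Classify an activity change as a qualitative direction
#'
#' Strict inequalities: a delta exactly at the threshold is `no-change`
#' (a conservative claim of change).
#'
#' @param delta Numeric vector of activity changes.
#' @param config A [validation_config()].
#' @param reference Reference activities (required for relative mode).
#' @return Character vector in `increase` / `decrease` / `no-change`. In
#'   relative mode, rows with zero reference are classified on the
#'   absolute scale and flagged in the `"absolute_fallback"` attribute.
#' @export
classify_change <- function(delta, config = validation_config(),
                            reference = NULL) {
  stopifnot(all(is.finite(delta)))
  eff <- delta
  fallback <- rep(FALSE, length(delta))
  if (config$threshold_mode == "relative") {
    if (is.null(reference))
      stop("relative threshold mode needs reference activities")
    fallback <- reference == 0
    eff[!fallback] <- delta[!fallback] / reference[!fallback]
  }
  out <- ifelse(eff > config$threshold, "increase",
                ifelse(eff < -config$threshold, "decrease", "no-change"))
  if (any(fallback)) attr(out, "absolute_fallback") <- which(fallback)
  out
}

# Steady states needed to evaluate a set of observations, computed once.
validation_contexts <- function(model, observations, config,
                                solver = solver_config()) {
  base_p <- perturbation(set_input = stats::setNames(0, config$input))
  stretch_p <- perturbation(set_input = stats::setNames(config$stretch_level,
                                                        config$input))
  safe_ss <- function(m) tryCatch(steady_state(m, solver),
                                  error = function(e) NULL)
  ss0 <- safe_ss(apply_perturbation(model, base_p))
  ss1 <- safe_ss(apply_perturbation(model, stretch_p))
  inhibitors <- unique(stats::na.omit(observations$inhibit))
  ss_inh <- lapply(inhibitors, function(i) {
    p <- merge_perturbations(stretch_p, perturbation(
      scale_ymax = stats::setNames(config$inhibition_depth, i)))
    safe_ss(apply_perturbation(model, p))
  })
  names(ss_inh) <- inhibitors
  list(ss0 = ss0, ss1 = ss1, ss_inh = ss_inh)
}

#' Predict the activity change for one observation
#'
#' Input-output and input-intermediate deltas are stretch minus no-stretch;
#' inhibition deltas are stretch-plus-inhibitor minus stretch alone (i.e.
#' relative to steady-state stretch activation, not to baseline).
#'
#' @param model A `network_model`.
#' @param record One observation (a one-row [observation_table()] or list
#'   with fields `measured`, `category`, `inhibit`).
#' @param config A [validation_config()].
#' @param solver A [solver_config()].
#' @return List with `delta`, `reference` and `direction`.
#' @export
predict_observation <- function(model, record, config = validation_config(),
                                solver = solver_config()) {
  obs <- observation_table(record$measured, record$category,
                           if (!is.null(record$direction)) record$direction
                           else "no-change",
                           inhibit = if (is.null(record$inhibit)) NA
                                     else record$inhibit)
  rep <- validate_observations(model, obs, config, solver)
  row <- rep$records[1, ]
  list(delta = row$delta, reference = row$reference,
       direction = row$predicted)
}

#' Validate a model against an observation table
#'
#' Simulates each observation's context, classifies predicted deltas with
#' [classify_change()], and tabulates per-category and overall accuracy
#' plus a taxonomy of disagreements: `below_threshold` (predicted change
#' in the observed direction but under the threshold), `missing_connection`
#' (observed change, predicted flat at zero), `spurious_prediction`
#' (predicted change, observed none), and `sign_flip`. Records whose
#' steady state fails to converge are flagged unevaluable and excluded
#' from all denominators with a warning.
#'
#' @param model A `network_model`.
#' @param observations An [observation_table()].
#' @param config A [validation_config()].
#' @param solver A [solver_config()].
#' @param zero_tol Deltas below this magnitude count as exactly zero for
#'   the missing-connection class (default 1e-6, the solver tolerance).
#' @return A `validation_report`.
#' @examples
#' m <- mini_mechano_network()
#' obs <- observation_table("BNP", "input-output", "increase")
#' validate_observations(m, obs)
#' @export
validate_observations <- function(model, observations,
                                  config = validation_config(),
                                  solver = solver_config(),
                                  zero_tol = 1e-6) {
  stopifnot(nrow(observations) > 0)
  bad <- setdiff(c(observations$measured,
                   stats::na.omit(observations$inhibit)),
                 model$species$id)
  if (length(bad)) stop("observations refer to unknown species: ",
                        paste(unique(bad), collapse = ", "))
  ctx <- validation_contexts(model, observations, config, solver)
  n <- nrow(observations)
  delta <- reference <- rep(NA_real_, n)
  evaluable <- rep(TRUE, n)
  for (i in seq_len(n)) {
    m <- observations$measured[i]
    if (observations$category[i] == "inhibition") {
      ssA <- ctx$ss_inh[[observations$inhibit[i]]]
      ssB <- ctx$ss1
    } else {
      ssA <- ctx$ss1
      ssB <- ctx$ss0
    }
    if (is.null(ssA) || is.null(ssB)) {
      evaluable[i] <- FALSE
    } else {
      delta[i] <- ssA[[m]] - ssB[[m]]
      reference[i] <- ssB[[m]]
    }
  }
  if (any(!evaluable))
    warning(sum(!evaluable), " record(s) unevaluable (steady state did not",
            " converge); excluded from accuracy", call. = FALSE)
  predicted <- rep(NA_character_, n)
  predicted[evaluable] <- classify_change(delta[evaluable], config,
                                          reference[evaluable])
  match_flag <- evaluable & predicted == observations$direction

  records <- data.frame(observations,
                        delta = delta, reference = reference,
                        predicted = predicted, match = match_flag,
                        evaluable = evaluable,
                        stringsAsFactors = FALSE)

  cats <- c("input-output", "input-intermediate", "inhibition")
  by_cat <- do.call(rbind, lapply(cats, function(ct) {
    sel <- records$category == ct & records$evaluable
    data.frame(category = ct, matches = sum(records$match[sel]),
               total = sum(sel),
               accuracy = if (sum(sel)) sum(records$match[sel]) / sum(sel)
                          else NA_real_,
               stringsAsFactors = FALSE)
  }))

  mism <- records[records$evaluable & !records$match, , drop = FALSE]
  sgn <- function(d) ifelse(d > 0, "increase", ifelse(d < 0, "decrease",
                                                      "no-change"))
  cls <- character(nrow(mism))
  for (i in seq_len(nrow(mism))) {
    obs_dir <- mism$direction[i]; pred <- mism$predicted[i]; d <- mism$delta[i]
    cls[i] <- if (obs_dir != "no-change" && pred == "no-change") {
      if (abs(d) <= zero_tol) "missing_connection"
      else if (sgn(d) == obs_dir) "below_threshold"
      else "sign_flip"
    } else if (obs_dir == "no-change" && pred != "no-change") {
      "spurious_prediction"
    } else "sign_flip"
  }
  taxonomy <- c(below_threshold = sum(cls == "below_threshold"),
                missing_connection = sum(cls == "missing_connection"),
                spurious_prediction = sum(cls == "spurious_prediction"),
                sign_flip = sum(cls == "sign_flip"))

  structure(list(records = records, by_category = by_cat,
                 overall = list(matches = sum(records$match[records$evaluable]),
                                total = sum(records$evaluable),
                                accuracy = sum(records$match[records$evaluable]) /
                                  max(1L, sum(records$evaluable))),
                 disagreements = taxonomy, config = config),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation: %d/%d observations matched (%.1f%%)\n",
              x$overall$matches, x$overall$total,
              100 * x$overall$accuracy))
  for (i in seq_len(nrow(x$by_category))) {
    r <- x$by_category[i, ]
    if (r$total > 0)
      cat(sprintf("  %-18s %d/%d (%.0f%%)\n", r$category, r$matches,
                  r$total, 100 * r$accuracy))
  }
  if (sum(x$disagreements) > 0) {
    cat("Disagreements:",
        paste(names(x$disagreements), x$disagreements, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Convert activating AND reactions to OR
#'
#' Every reaction with two or more operands, all of them activating, is
#' split into one single-operand reaction per operand (inheriting weight,
#' Hill coefficient and EC50), which the LDE semantics OR-combine on the
#' shared target. Reactions containing inhibitory operands are left
#' intact. Used to probe how much validation accuracy depends on AND
#' logic.
#'
#' @param model A `network_model`.
#' @return A new `network_model` with the same species.
#' @export
strip_and_gates <- function(model) {
  rx <- model$reactions
  rows <- list()
  for (i in seq_len(nrow(rx))) {
    ops <- rx$operands[[i]]
    inh <- rx$inhibitor[[i]]
    if (length(ops) >= 2L && !any(inh)) {
      for (j in seq_along(ops)) {
        rows[[length(rows) + 1L]] <- data.frame(
          id = paste0(rx$id[i], letters[j]),
          rule = paste(ops[j], "=>", rx$target[i]),
          weight = rx$weight[i], hill_n = rx$hill_n[i], ec50 = rx$ec50[i],
          stringsAsFactors = FALSE)
      }
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        id = rx$id[i], rule = rx$rule[i], weight = rx$weight[i],
        hill_n = rx$hill_n[i], ec50 = rx$ec50[i], stringsAsFactors = FALSE)
    }
  }
  suppressWarnings(network_model(model$species, do.call(rbind, rows),
                                 metadata = c(model$metadata,
                                              list(variant = "and_to_or"))))
}

#' Parameter robustness of validation accuracy
#'
#' For each half-width `h`, draws `n_sets` parameter vectors in which every
#' instance of the chosen parameter is resampled uniformly from
#' `[p(1-h), p(1+h)]` (clipped to its validity range), revalidates the
#' model, and records the accuracy. `tau` and `y_init` do not move steady
#' states, so their scans should return the unperturbed accuracy at every
#' half-width. For `w`, input-reaction weights are left alone: the
#' validation contexts overwrite them via `set_input`, so varying them
#' would be a no-op by construction.
#'
#' @param model A `network_model`.
#' @param observations An [observation_table()].
#' @param config A [validation_config()].
#' @param parameter One of `"y_max"`, `"w"`, `"n"`, `"ec50"`, `"tau"`,
#'   `"y_init"`.
#' @param half_widths Numeric vector of non-negative half-widths.
#' @param n_sets Parameter sets per half-width (default 100).
#' @param seed Optional integer seed; same seed gives identical draws.
#' @param solver A [solver_config()].
#' @return Data frame with columns `half_width`, `set`, `accuracy`.
#' @export
robustness_scan <- function(model, observations, config = validation_config(),
                            parameter = c("y_max", "w", "n", "ec50", "tau",
                                          "y_init"),
                            half_widths = c(0.1, 0.2, 0.3), n_sets = 100,
                            seed = NULL, solver = solver_config()) {
  parameter <- match.arg(parameter)
  stopifnot(all(half_widths >= 0), n_sets >= 1)
  if (!is.null(seed)) set.seed(seed)
  eps <- 1e-6
  is_input <- lengths(model$reactions$operands) == 0L
  draw_model <- function(h) {
    m <- model
    jitter <- function(p) stats::runif(length(p), p * (1 - h), p * (1 + h))
    switch(parameter,
      y_max = { m$species$y_max <- pmax(jitter(m$species$y_max), eps) },
      tau = { m$species$tau <- pmax(jitter(m$species$tau), eps) },
      y_init = {
        m$species$y_init <- pmin(pmax(jitter(m$species$y_init), 0),
                                 m$species$y_max)
      },
      w = {
        w <- m$reactions$weight
        w[!is_input] <- pmin(pmax(jitter(w[!is_input]), 0), 1)
        m$reactions$weight <- w
      },
      n = { m$reactions$hill_n <- pmax(jitter(m$reactions$hill_n), eps) },
      ec50 = {
        m$reactions$ec50 <- pmin(pmax(jitter(m$reactions$ec50), eps), 1 - eps)
      })
    m
  }
  out <- expand.grid(half_width = half_widths, set = seq_len(n_sets),
                     KEEP.OUT.ATTRS = FALSE)
  out <- out[order(out$half_width, out$set), , drop = FALSE]
  out$accuracy <- vapply(seq_len(nrow(out)), function(i) {
    m <- draw_model(out$half_width[i])
    suppressWarnings(
      validate_observations(m, observations, config, solver)$overall$accuracy)
  }, numeric(1))
  rownames(out) <- NULL
  out
}

#' Fraction of nodes activated inside a band
#'
#' Steady-state calibration diagnostic: the fraction of non-input species
#' (species not driven by an input reaction) whose steady-state activity
#' under a given input level lies inside a band. The published calibration
#' picks the input level and default weight that maximize the fraction in
#' [0.5, 0.95], avoiding under- and over-saturation.
#'
#' @param model A `network_model`.
#' @param input_level Input level to apply.
#' @param band Length-2 numeric interval inside `[0, 1]`.
#' @param input Species id carrying the input (default "Stretch" when
#'   present, else the first input species).
#' @param config A [solver_config()].
#' @return Fraction in `[0, 1]`.
#' @export
activation_band <- function(model, input_level, band = c(0.5, 0.95),
                            input = NULL, config = solver_config()) {
  stopifnot(length(band) == 2L, band[1] <= band[2],
            band[1] >= 0, band[2] <= 1)
  inputs <- input_species(model)
  if (is.null(input))
    input <- if ("Stretch" %in% inputs) "Stretch" else inputs[1]
  m <- apply_perturbation(model, perturbation(
    set_input = stats::setNames(input_level, input)))
  ss <- steady_state(m, config)
  consider <- setdiff(model$species$id, inputs)
  if (!length(consider)) return(NA_real_)
  mean(ss[consider] >= band[1] & ss[consider] <= band[2])
}
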
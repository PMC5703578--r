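#' @title Network model container
#' @description
#' A `network_model` holds a signed logic network in the Netflux-style
#' two-table layout: a species table (`id`, `name`, `y_init`, `y_max`,
#' `tau`) and a reactions table (`id`, `rule`, `weight`, `hill_n`, `ec50`).
#' Reaction rules follow the grammar
#' \preformatted{
#'   => C            input reaction (constant drive w onto C)
#'   A => C          single activating edge
#'   !A => C         inhibitory edge
#'   A & !B & C => D AND of the listed operands ("!" marks inhibitors)
#' }
#' OR gating is implicit: several reactions sharing a target are
#' OR-combined. Species order is preserved from the input table.
#' @name network_model
NULL

.default_params <- list(y_init = 0, y_max = 1, tau = 1,
                        weight = 0.9, hill_n = 1.4, ec50 = 0.5,
                        input_weight = 0.7)

#' Parse a reaction rule string
#'
#' @param rule Rule string, e.g. `"A & !B => C"`.
#' @return List with `target` (character scalar), `operands` (character
#'   vector, possibly empty for input reactions) and `inhibitor` (logical
#'   vector parallel to `operands`).
#' @export
parse_rule <- function(rule) {
  stopifnot(is.character(rule), length(rule) == 1L)
  parts <- strsplit(rule, "=>", fixed = TRUE)[[1]]
  if (length(parts) > 2L || !grepl("=>", rule, fixed = TRUE))
    stop("rule must contain exactly one '=>': ", sQuote(rule))
  lhs <- trimws(if (length(parts) >= 1L) parts[1] else "")
  rhs <- trimws(if (length(parts) == 2L) parts[2] else "")
  if (rhs == "" || grepl("[&![:space:]]", rhs))
    stop("rule must name exactly one target species right of '=>': ", sQuote(rule))
  if (lhs == "") {
    return(list(target = rhs, operands = character(), inhibitor = logical()))
  }
  ops <- trimws(strsplit(lhs, "&", fixed = TRUE)[[1]])
  n_amp <- lengths(regmatches(lhs, gregexpr("&", lhs, fixed = TRUE)))
  if (any(ops == "") || length(ops) != n_amp + 1L)
    stop("empty operand in rule ", sQuote(rule))
  inhib <- startsWith(ops, "!")
  ops <- trimws(sub("^!", "", ops))
  if (any(ops == "") || any(grepl("[&![:space:]]", ops)))
    stop("malformed operand in rule ", sQuote(rule))
  list(target = rhs, operands = ops, inhibitor = inhib)
}

deparse_rule <- function(target, operands, inhibitor) {
  if (length(operands) == 0L) return(paste("=>", target))
  lhs <- paste0(ifelse(inhibitor, "!", ""), operands, collapse = " & ")
  paste(lhs, "=>", target)
}

#' Construct a network model
#'
#' @param species Data frame with columns `id`, `name`, `y_init`, `y_max`,
#'   `tau` (missing parameter columns are filled with defaults
#'   `y_init = 0`, `y_max = 1`, `tau = 1`).
#' @param reactions Data frame with columns `id`, `rule`, `weight`,
#'   `hill_n`, `ec50` (missing parameter columns filled with defaults
#'   `weight = 0.9` for non-input reactions, `hill_n = 1.4`, `ec50 = 0.5`;
#'   input reactions default to weight 0).
#' @param metadata Optional list of free-form provenance annotations.
#' @param check Run invariant checks (default TRUE).
#' @return An object of class `network_model`.
#' @export
network_model <- function(species, reactions, metadata = list(), check = TRUE) {
  species <- as.data.frame(species, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (!"id" %in% names(species)) stop("species table needs an 'id' column")
  if (!all(c("id", "rule") %in% names(reactions)))
    stop("reactions table needs 'id' and 'rule' columns")
  if (!"name" %in% names(species)) species$name <- species$id
  species$name[is.na(species$name)] <- species$id[is.na(species$name)]
  for (col in c("y_init", "y_max", "tau")) {
    if (!col %in% names(species)) species[[col]] <- NA_real_
    species[[col]] <- as.numeric(species[[col]])
    species[[col]][is.na(species[[col]])] <- .default_params[[col]]
  }
  if (!"clamp" %in% names(species)) species$clamp <- NA_real_
  species <- species[, c("id", "name", "y_init", "y_max", "tau", "clamp")]

  parsed <- lapply(as.character(reactions$rule), parse_rule)
  reactions$target <- vapply(parsed, `[[`, character(1), "target")
  reactions$operands <- I(lapply(parsed, `[[`, "operands"))
  reactions$inhibitor <- I(lapply(parsed, `[[`, "inhibitor"))
  is_input <- lengths(reactions$operands) == 0L
  for (col in c("weight", "hill_n", "ec50")) {
    if (!col %in% names(reactions)) reactions[[col]] <- NA_real_
    reactions[[col]] <- as.numeric(reactions[[col]])
  }
  reactions$weight[is.na(reactions$weight)] <-
    ifelse(is_input[is.na(reactions$weight)], 0, .default_params$weight)
  reactions$hill_n[is.na(reactions$hill_n)] <- .default_params$hill_n
  reactions$ec50[is.na(reactions$ec50)] <- .default_params$ec50
  reactions <- reactions[, c("id", "rule", "target", "operands", "inhibitor",
                             "weight", "hill_n", "ec50")]

  model <- structure(list(species = species, reactions = reactions,
                          metadata = metadata),
                     class = "network_model")
  if (check) check_model(model)
  model
}

#' Check network model invariants
#'
#' Verifies uniqueness of ids, parameter ranges, and that every operand and
#' target in a rule resolves to a declared species. Emits a warning listing
#' species with neither an incoming reaction nor an input reaction (these
#' decay to zero).
#'
#' @param model A `network_model`.
#' @param warn_orphans Warn about undriven species (default TRUE).
#' @param perturbed Relax the node checks for perturbed models: a full
#'   knockdown sets `y_max = 0`, which unperturbed models may not carry.
#' @return The model, invisibly; stops on violation.
#' @export
check_model <- function(model, warn_orphans = TRUE, perturbed = FALSE) {
  sp <- model$species
  rx <- model$reactions
  if (nrow(sp) == 0L) stop("model has no species")
  if (anyDuplicated(sp$id))
    stop("duplicate species id: ",
         paste(unique(sp$id[duplicated(sp$id)]), collapse = ", "))
  if (any(!is.finite(sp$y_max)) || any(sp$y_max < 0) ||
      (!perturbed && any(sp$y_max == 0)))
    stop("y_max must be > 0 for all species")
  if (any(!is.finite(sp$tau)) || any(sp$tau <= 0))
    stop("tau must be > 0 for all species")
  if (any(!is.finite(sp$y_init)) || any(sp$y_init < 0) ||
      (!perturbed && any(sp$y_init > sp$y_max)))
    stop("y_init must satisfy 0 <= y_init <= y_max")
  if (nrow(rx) > 0L) {
    if (anyDuplicated(rx$id))
      stop("duplicate reaction id: ",
           paste(unique(rx$id[duplicated(rx$id)]), collapse = ", "))
    if (any(rx$weight < 0 | rx$weight > 1))
      stop("reaction weight must lie in [0, 1]")
    if (any(rx$ec50 <= 0 | rx$ec50 >= 1))
      stop("reaction ec50 must lie strictly in (0, 1)")
    if (any(rx$hill_n <= 0))
      stop("reaction hill_n must be > 0")
    for (i in seq_len(nrow(rx))) {
      toks <- c(rx$target[i], rx$operands[[i]])
      bad <- setdiff(toks, sp$id)
      if (length(bad))
        stop("reaction ", sQuote(rx$id[i]), ": unknown species token ",
             paste(sQuote(bad), collapse = ", "))
    }
  }
  if (warn_orphans) {
    driven <- unique(rx$target)
    orphans <- setdiff(sp$id, driven)
    if (length(orphans))
      warning("species with no incoming reaction (will decay to 0): ",
              paste(orphans, collapse = ", "), call. = FALSE)
  }
  invisible(model)
}

#' Species ids of a model, in sheet order
#' @param model A `network_model`.
#' @return Character vector.
#' @export
species_ids <- function(model) model$species$id

#' Species driven by an input reaction
#' @param model A `network_model`.
#' @return Character vector of species that are the target of at least one
#'   zero-operand (input) reaction.
#' @export
input_species <- function(model) {
  rx <- model$reactions
  unique(rx$target[lengths(rx$operands) == 0L])
}

#' Summarize a network model
#'
#' @param model A `network_model`.
#' @return A list with `n_species`, `n_reactions`, `n_inputs` (reactions
#'   with zero operands), `n_and` (reactions with two or more operands) and
#'   `n_inhibitor_edges` (inhibitory operand occurrences).
#' @examples
#' m <- toy_motifs()$fanin_and
#' model_summary(m)
#' @export
model_summary <- function(model) {
  rx <- model$reactions
  nop <- lengths(rx$operands)
  out <- list(
    n_species = nrow(model$species),
    n_reactions = nrow(rx),
    n_inputs = sum(nop == 0L),
    n_and = sum(nop >= 2L),
    n_inhibitor_edges = sum(vapply(rx$inhibitor, sum, integer(1)))
  )
  class(out) <- "network_model_summary"
  out
}

#' @export
print.network_model_summary <- function(x, ...) {
  cat(sprintf(paste0("LDE network: %d species, %d reactions ",
                     "(%d input, %d AND, %d inhibitory edges)\n"),
              x$n_species, x$n_reactions, x$n_inputs, x$n_and,
              x$n_inhibitor_edges))
  invisible(x)
}

#' @export
print.network_model <- function(x, ...) {
  s <- model_summary(x)
  print(s)
  print(utils::head(x$species[, c("id", "y_init", "y_max", "tau")], 5))
  cat("rules:\n")
  cat(paste0("  ", utils::head(x$reactions$rule, 8), collapse = "\n"), "\n")
  if (nrow(x$reactions) > 8) cat("  ...\n")
  invisible(x)
}

#' Structural equality of two models
#'
#' Compares species tables, reaction tables (parsed structure and numeric
#' parameters) and ignores metadata. Used by the serialization round-trip
#' property and the perturbation purity checks.
#' @param a,b `network_model` objects.
#' @return TRUE/FALSE.
#' @export
models_identical <- function(a, b) {
  strip <- function(m) {
    rx <- m$reactions
    rx$operands <- lapply(rx$operands, as.character)
    rx$inhibitor <- lapply(rx$inhibitor, as.logical)
    list(species = m$species, reactions = rx)
  }
  isTRUE(all.equal(strip(a), strip(b), tolerance = 0))
}
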
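#' Random signed logic network
#'
#' Generates a seeded random network for desk-scale testing: `n_inputs`
#' source nodes carry input reactions (default weight 0.7, the stretch
#' level used throughout), every remaining node receives at least one
#' incoming reaction where the reaction budget allows (operands drawn from
#' lower-index nodes, so the default topology is acyclic), and surplus
#' reactions add random crosstalk. Operands are inhibitory with
#' probability `p_inhibitor`; reactions have two AND-ed operands with
#' probability `p_and`. All kinetic parameters sit at the framework
#' defaults.
#'
#' @param n_nodes Number of species.
#' @param n_reactions Total reactions including the input reactions.
#' @param p_inhibitor Probability an operand is inhibitory.
#' @param p_and Probability a non-input reaction has two operands.
#' @param n_inputs Number of input-driven source nodes (>= 1).
#' @param seed Optional integer seed (calls [set.seed()]).
#' @param allow_cycles Sample operands from all other nodes rather than
#'   lower-index nodes only (default FALSE).
#' @param input_weight Weight of the input reactions (default 0.7).
#' @return A `network_model`.
#' @examples
#' m <- random_network(10, 14, seed = 1)
#' model_summary(m)
#' @export
random_network <- function(n_nodes, n_reactions, p_inhibitor = 0.15,
                           p_and = 0.2, n_inputs = 1, seed = NULL,
                           allow_cycles = FALSE, input_weight = 0.7) {
  stopifnot(p_inhibitor >= 0, p_inhibitor <= 1, p_and >= 0, p_and <= 1)
  if (n_inputs < 1 || n_inputs > n_nodes)
    stop("need 1 <= n_inputs <= n_nodes")
  if (n_reactions < n_inputs)
    stop("n_reactions must be >= n_inputs")
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("N%02d", seq_len(n_nodes))
  rules <- paste("=>", ids[seq_len(n_inputs)])
  weights <- rep(input_weight, n_inputs)

  draw_ops <- function(target_idx) {
    pool <- if (allow_cycles) setdiff(seq_len(n_nodes), target_idx)
            else seq_len(target_idx - 1L)
    k <- if (stats::runif(1) < p_and && length(pool) >= 2L) 2L else 1L
    ops <- sample(pool, k)
    inh <- stats::runif(k) < p_inhibitor
    paste0(ifelse(inh, "!", ""), ids[ops], collapse = " & ")
  }

  n_extra <- n_reactions - n_inputs
  targets_cover <- setdiff(seq_len(n_nodes), seq_len(n_inputs))
  targets_cover <- utils::head(targets_cover, n_extra)
  for (j in targets_cover) {
    rules <- c(rules, paste(draw_ops(j), "=>", ids[j]))
    weights <- c(weights, NA_real_)
  }
  n_left <- n_extra - length(targets_cover)
  if (n_left > 0) {
    pool <- setdiff(seq_len(n_nodes), seq_len(n_inputs))
    if (!length(pool)) stop("no non-input nodes available for extra reactions")
    for (r in seq_len(n_left)) {
      j <- if (length(pool) == 1L) pool else sample(pool, 1L)
      rules <- c(rules, paste(draw_ops(j), "=>", ids[j]))
      weights <- c(weights, NA_real_)
    }
  }
  species <- data.frame(id = ids, stringsAsFactors = FALSE)
  reactions <- data.frame(id = sprintf("r%02d", seq_along(rules)),
                          rule = rules, weight = weights,
                          stringsAsFactors = FALSE)
  suppressWarnings(network_model(species, reactions,
                                 metadata = list(generator = "random_network",
                                                 seed = seed)))
}

#' Toy network motifs with known steady states
#'
#' Small fixtures whose steady states follow from iterating the normalized
#' Hill transfer by hand:
#' \describe{
#'   \item{chain}{Input-driven linear chain `S -> A -> B -> ...`
#'     (input 0.7): `Y_S = 0.7`, then `Y = 0.9 f(Y_upstream)` down the
#'     chain.}
#'   \item{fanin_or}{Two driven inputs converging on one target through
#'     separate reactions (implicit OR).}
#'   \item{fanin_and}{Same geometry but one AND reaction.}
#'   \item{inhibitor}{`!A => B`: B driven when A is inactive,
#'     `Y_B = 0.9 (1 - f(Y_A))`.}
#'   \item{negfb}{Negative-feedback 2-cycle: `S & !B => A`, `A => B`.}
#' }
#' @param chain_len Number of nodes in the chain motif (default 3).
#' @return Named list of `network_model` objects.
#' @export
toy_motifs <- function(chain_len = 3) {
  stopifnot(chain_len >= 2, chain_len <= 15)
  mk <- function(ids, rules, weights = NULL) {
    rx <- data.frame(id = sprintf("r%d", seq_along(rules)), rule = rules,
                     stringsAsFactors = FALSE)
    if (!is.null(weights)) rx$weight <- weights
    network_model(data.frame(id = ids, stringsAsFactors = FALSE), rx)
  }
  chain_ids <- c("S", LETTERS[seq_len(chain_len - 1L)])
  chain_rules <- c(paste("=>", "S"),
                   paste(chain_ids[-chain_len], "=>", chain_ids[-1L]))
  list(
    chain = mk(chain_ids, chain_rules,
               c(0.7, rep(NA_real_, chain_len - 1L))),
    fanin_or = mk(c("I1", "I2", "T"),
                  c("=> I1", "=> I2", "I1 => T", "I2 => T"),
                  c(0.7, 0.7, NA, NA)),
    fanin_and = mk(c("I1", "I2", "T"),
                   c("=> I1", "=> I2", "I1 & I2 => T"),
                   c(0.7, 0.7, NA)),
    inhibitor = mk(c("A", "B"), c("=> A", "!A => B"), c(0.7, NA)),
    negfb = mk(c("S", "A", "B"),
               c("=> S", "S & !B => A", "A => B"),
               c(0.7, NA, NA))
  )
}

#' Curated mini mechano-signaling network
#'
#' A ~30-node cardiomyocyte mechano-signaling subnetwork assembled from
#' pathway connections commonly described for stretch signaling: a stretch
#' input fans out to the mechano-sensors (AT1R, the L-type calcium channel
#' LTCC, the TRP channel, integrin, dystroglycan, gp130); AT1R signals
#' through G-alpha-q/11 to Ras and PI3K/Akt (driving CREB, FoxO, GATA4);
#' Ras/Raf1/MEK1-2/ERK1-2 drives cFos; the calcium channels raise Ca2+,
#' calmodulin, calcineurin and NFAT; gp130 activates JAK/STAT; the
#' cytoskeletal sensors drive actin and FAK (FAK closing onto Ras); and an
#' sGC/cGMP/PKG1 axis inhibits the stretch-sensitive calcium channels and
#' the calcineurin step. BNP transcription is the AND of five
#' transcription factors (NFAT, CREB, GATA4, STAT, cFos), reflecting that
#' each is necessary but not individually sufficient. Gate choices at
#' other convergence points default to OR and are fixture choices.
#'
#' This is a desk-scale test fixture, not the full published 94-node
#' curation; both the stretch input and the sGC input default to weight 0
#' and are driven via [perturbation()] / [dose_response()].
#'
#' @return A `network_model`.
#' @examples
#' m <- mini_mechano_network()
#' model_summary(m)
#' @export
mini_mechano_network <- function() {
  ids <- c("Stretch", "AT1R", "Gaq11", "LTCC", "TRP", "Ca", "CaM", "CaN",
           "NFAT", "Ras", "Raf1", "MEK12", "ERK12", "cFos", "PI3K", "Akt",
           "CREB", "FoxO", "GATA4", "gp130", "JAK", "STAT", "Integrin",
           "Dysgl", "Actin", "FAK", "sGC", "cGMP", "PKG1", "BNP")
  rules <- c(
    "=> Stretch",
    "=> sGC",
    "Stretch => AT1R",
    "Stretch & !PKG1 => LTCC",
    "Stretch & !PKG1 => TRP",
    "Stretch => Integrin",
    "Stretch => Dysgl",
    "Stretch => gp130",
    "AT1R => Gaq11",
    "Gaq11 => Ras",
    "FAK => Ras",
    "Ras => Raf1",
    "Raf1 => MEK12",
    "MEK12 => ERK12",
    "ERK12 => cFos",
    "Gaq11 => PI3K",
    "Ras => PI3K",
    "PI3K => Akt",
    "Akt => CREB",
    "Akt => FoxO",
    "Akt => GATA4",
    "LTCC => Ca",
    "TRP => Ca",
    "Ca => CaM",
    "CaM & !PKG1 => CaN",
    "CaN => NFAT",
    "gp130 => JAK",
    "JAK => STAT",
    "Integrin => Actin",
    "Dysgl => Actin",
    "Integrin => FAK",
    "sGC => cGMP",
    "cGMP => PKG1",
    "NFAT & CREB & GATA4 & STAT & cFos => BNP"
  )
  species <- data.frame(id = ids, stringsAsFactors = FALSE)
  reactions <- data.frame(id = sprintf("r%02d", seq_along(rules)),
                          rule = rules, stringsAsFactors = FALSE)
  network_model(species, reactions,
                metadata = list(fixture = "mini_mechano_network",
                                note = paste("text-derived subnetwork fixture;",
                                             "not the full curated model")))
}
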
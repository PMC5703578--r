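chain_ctx <- function() {
  list(model = toy_motifs()$chain, context = NULL)
}

test_that("knockdown matrix: locality, null factor, diagonal sign", {
  m <- toy_motifs()$chain
  sm <- knockdown_matrix(m, factor = 0.5)
  # B has no outgoing edges: its knockdown only moves its own row
  expect_lt(sm$delta["B", "B"], 0)
  expect_equal(unname(sm$delta[c("S", "A"), "B"]), c(0, 0),
               tolerance = 1e-8)
  # factor 1 is the null perturbation
  sm1 <- knockdown_matrix(m, factor = 1)
  expect_true(all(abs(sm1$delta) < 1e-7))
  # knocked-down node's own delta is never positive
  expect_true(all(diag(sm$delta) <= 1e-8))
})

test_that("knockdown deltas match the fixed-point oracle on the chain", {
  m <- toy_motifs()$chain
  sm <- knockdown_matrix(m, factor = 0.5)
  m_kd <- apply_perturbation(m, perturbation(scale_ymax = c(A = 0.5)))
  or <- oracle_steady_state(m_kd) - oracle_steady_state(m)
  expect_equal(unname(sm$delta[, "A"]), unname(or), tolerance = 1e-6)
  expect_lt(sm$delta["A", "A"], 0)
  expect_lt(sm$delta["B", "A"], 0)  # propagates downstream
})

test_that("knockdown deltas vary continuously with the factor", {
  m <- toy_motifs()$chain
  fs <- c(0.25, 0.5, 0.75)
  d <- vapply(fs, function(f)
    knockdown_matrix(m, factor = f)$delta["B", "A"], numeric(1))
  expect_true(all(diff(d) > 0))  # milder knockdown, smaller deficit
  expect_true(all(d < 0))
})

test_that("influence ranking finds the dominant column and ignores order", {
  m <- mini_mechano_network()
  sm <- knockdown_matrix(m, perturbation(set_input = c(Stretch = 0.7)))
  tfs <- c("NFAT", "CREB", "FoxO", "GATA4", "STAT", "cFos")
  r1 <- influence_ranking(sm, tfs, k = 5)
  r2 <- influence_ranking(sm, rev(tfs), k = 5)
  expect_equal(r1, r2)  # permutation invariance over rows
  # a single nonzero column ranks first
  sm_toy <- sm
  sm_toy$delta[] <- 0
  sm_toy$delta["BNP", "Ras"] <- -0.4
  expect_equal(influence_ranking(sm_toy, "BNP", k = 1)$species, "Ras")
  expect_warning(influence_ranking(sm_toy, "BNP", k = 1e4), "k exceeds")
})

test_that("hub clustering cuts the UPGMA tree at the criterion", {
  m <- mini_mechano_network()
  sm <- knockdown_matrix(m, perturbation(set_input = c(Stretch = 0.7)))
  # constructed geometry: two identical columns, one distant
  sm2 <- sm
  sm2$delta[, "LTCC"] <- sm2$delta[, "TRP"]
  rows <- c("Ca", "CaN", "NFAT", "BNP")
  gap_cut <- cluster_hubs(sm2, c("LTCC", "TRP", "PI3K"), rows,
                          criterion = 0.05)
  expect_equal(gap_cut$n_clusters, 2)
  expect_equal(gap_cut$labels[["LTCC"]], gap_cut$labels[["TRP"]])
  # criterion above the root merge joins everything
  one <- cluster_hubs(sm, c("LTCC", "TRP", "PI3K", "Ras"), rows,
                      criterion = 10)
  expect_equal(one$n_clusters, 1)
  # near-zero criterion separates distinct columns
  all_sep <- cluster_hubs(sm, c("LTCC", "PI3K", "Ras"), rows,
                          criterion = 1e-9)
  expect_equal(all_sep$n_clusters, 3)
  # invariance to column ordering
  a <- cluster_hubs(sm, c("LTCC", "TRP", "PI3K", "Ras"), rows, 0.3)
  b <- cluster_hubs(sm, c("Ras", "PI3K", "TRP", "LTCC"), rows, 0.3)
  expect_equal(a$n_clusters, b$n_clusters)
  expect_equal(a$labels[names(b$labels)] |> unname() |> table() |> sort(),
               b$labels |> unname() |> table() |> sort())
})

test_that("pairwise screen: AND convergence is synergistic, chains are not", {
  # two independent input branches feeding one output through an AND gate
  and_motif <- suppressWarnings(network_model(
    data.frame(id = c("I1", "I2", "U1", "U2", "T")),
    data.frame(id = paste0("r", 1:5),
               rule = c("=> I1", "=> I2", "I1 => U1", "I2 => U2",
                        "U1 & U2 => T"),
               weight = c(0.7, 0.7, NA, NA, NA))))
  res <- pairwise_screen(and_motif, outputs = "T", factor = 0.5,
                         nodes = c("U1", "U2"), directions = "decrease")
  expect_equal(nrow(res), 1)
  expect_lt(res$additional_benefit, 0)            # super-additive suppression
  expect_lt(res$combined, min(res$single_a, res$single_b))
  # oracle recomputation of the combined delta
  ctx_ss <- oracle_steady_state(and_motif)
  both <- apply_perturbation(and_motif, perturbation(
    scale_ymax = c(U1 = 0.5, U2 = 0.5)))
  or_comb <- oracle_steady_state(both)[["T"]] - ctx_ss[["T"]]
  expect_equal(res$combined, or_comb, tolerance = 1e-6)

  # a node and its sole descendant: full joint block adds nothing
  chain <- toy_motifs()$chain
  res_chain <- pairwise_screen(chain, outputs = "B", factor = 1,
                               nodes = c("A", "B"), directions = "decrease")
  expect_equal(res_chain$additional_benefit, 0, tolerance = 1e-6)
  # at partial knockdown the residual equals the oracle-computed one
  res_half <- pairwise_screen(chain, outputs = "B", factor = 0.5,
                              nodes = c("A", "B"), directions = "decrease")
  both_half <- apply_perturbation(chain, perturbation(
    scale_ymax = c(A = 0.5, B = 0.5)))
  singles <- lapply(c("A", "B"), function(n)
    oracle_steady_state(apply_perturbation(chain, perturbation(
      scale_ymax = stats::setNames(0.5, n))))[["B"]])
  ref <- oracle_steady_state(chain)[["B"]]
  deltas <- unlist(singles) - ref
  or_resid <- (oracle_steady_state(both_half)[["B"]] - ref) -
    deltas[which.max(abs(deltas))]
  expect_equal(res_half$additional_benefit, unname(or_resid),
               tolerance = 1e-6)
})

test_that("pairwise screen is symmetric in pair order and direction-aware", {
  m <- toy_motifs()$fanin_or
  res <- pairwise_screen(m, outputs = "T", factor = 0.5,
                         nodes = c("I1", "I2"))
  expect_equal(sort(unique(res$direction)), c("decrease", "increase"))
  # unordered pairs: one row per direction, symmetric singles
  dec <- res[res$direction == "decrease", ]
  expect_equal(dec$single_a, dec$single_b, tolerance = 1e-6)
  # increase direction pushes the output up
  inc <- res[res$direction == "increase", ]
  expect_gt(inc$combined, 0)
  expect_lt(dec$combined, 0)
})

test_that("top_overlap agrees on identical lists and disjoint rankings", {
  df <- data.frame(node_a = letters[1:6], node_b = letters[7:12],
                   direction = "decrease",
                   additional_benefit = seq(-0.6, -0.1, by = 0.1))
  expect_equal(top_overlap(df, df, k = 5), 1)
  df2 <- df
  df2$additional_benefit <- rev(df$additional_benefit)
  expect_equal(top_overlap(df, df2, k = 3), 0)
  expect_warning(ov <- top_overlap(df, df, k = 50), "fewer than k")
  expect_equal(ov, 1)
})
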
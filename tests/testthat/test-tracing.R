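# Cross-compartment clone tracing and spanning analyses.

# small handmade clone-state world
toy_tracing <- function() {
  assignment <- list(assignment = data.frame(
    barcode = paste0("b", 1:8),
    clone_id = c(1L, 1L, 1L, 1L, 1L, 2L, 3L, 3L)))
  states <- c(b1 = "PC-Tigit", b2 = "PC-Tigit", b3 = "PC-Tigit",
              b4 = "PC-Tigit", b5 = "PC-Tigit", b6 = "PC-progenitor",
              b7 = "PC-Slpi", b8 = "PC-Slpi")
  compartments <- c(b1 = "spleen", b2 = "spleen", b3 = "spleen",
                    b4 = "bone_marrow", b5 = "bone_marrow", b6 = "spleen",
                    b7 = "spleen", b8 = "bone_marrow")
  list(assignment = assignment, states = states,
       compartments = compartments)
}

test_that("clone-state table aggregates and conserves counts", {
  tt <- toy_tracing()
  tab <- build_clone_state_table(tt$assignment, tt$states, tt$compartments)
  # clone 1: 3 spleen PC-Tigit + 2 BM PC-Tigit -> two rows, counts 3 and 2
  c1 <- tab[tab$clone_id == 1L, ]
  expect_equal(nrow(c1), 2L)
  expect_setequal(c1$n_cells, c(3L, 2L))
  expect_equal(sum(tab$n_cells), 8L)
  # specificity filter removes other labels from totals
  spec <- setNames(rep(c("NP", "KLH"), each = 4), paste0("b", 1:8))
  np <- build_clone_state_table(tt$assignment, tt$states, tt$compartments,
                                specificity = spec, filter = "NP")
  expect_equal(sum(np$n_cells), 4L)
})

test_that("spanning clones honor min_nodes and shrink monotonically", {
  tt <- toy_tracing()
  tab <- build_clone_state_table(tt$assignment, tt$states, tt$compartments)
  all_clones <- spanning_clones(tab, min_nodes = 1L)
  expect_setequal(all_clones$clone_id, c(1L, 2L, 3L))
  sp2 <- spanning_clones(tab, min_nodes = 2L)
  expect_setequal(sp2$clone_id, c(1L, 3L))  # clone 2 sits in one node
  sp3 <- spanning_clones(tab, min_nodes = 3L)
  expect_equal(nrow(sp3), 0L)
  expect_true(all(sp3$clone_id %in% sp2$clone_id) &&
                all(sp2$clone_id %in% all_clones$clone_id))
})

test_that("span matrix counts clones per state pair, with normalization", {
  tt <- toy_tracing()
  tab <- build_clone_state_table(tt$assignment, tt$states, tt$compartments)
  m <- span_frequency_matrix(tab)
  expect_equal(m["PC-Tigit", "PC-Tigit"], 1)
  expect_equal(m["PC-Slpi", "PC-Slpi"], 1)
  expect_equal(sum(m), 2)
  mn <- span_frequency_matrix(tab, normalize = TRUE)
  expect_equal(unname(rowSums(mn)[rowSums(m) > 0]),
               rep(1, sum(rowSums(m) > 0)))
})

test_that("span matrix equals a brute-force recount on simulated data", {
  sim <- small_sim()
  ca <- call_clones(sim$paired)
  states <- truth_lookup(sim$truth, "state")
  comps <- truth_lookup(sim$truth, "compartment")
  tab <- build_clone_state_table(ca, states, comps)
  m <- span_frequency_matrix(tab)
  # brute force over raw per-cell labels
  bc <- ca$assignment$barcode
  df <- data.frame(clone = ca$assignment$clone_id,
                   state = states[bc], comp = comps[bc])
  brute <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  for (cl in unique(df$clone)) {
    s_sp <- unique(df$state[df$clone == cl & df$comp == "spleen"])
    s_bm <- unique(df$state[df$clone == cl & df$comp == "bone_marrow"])
    for (i in intersect(s_sp, rownames(brute)))
      for (j in intersect(s_bm, colnames(brute)))
        brute[i, j] <- brute[i, j] + 1
  }
  expect_equal(m, brute)
  # unnormalized entries sum to the total pair incidences counted above
  expect_equal(sum(m), sum(brute))
})

test_that("PC clones seed the marrow in their own state; progenitors never", {
  sim <- small_sim()
  ca <- call_clones(sim$paired)
  tab <- build_clone_state_table(ca, truth_lookup(sim$truth, "state"),
                                 truth_lookup(sim$truth, "compartment"))
  m <- span_frequency_matrix(
    tab, states_a = names(sim$cfg$state_proportions))
  expect_equal(sum(m["PC-progenitor", ]), 0)
  for (st in intersect(sim$cfg$bm_states, colnames(m))) {
    row <- m[st, ]
    expect_gt(sum(row), 0)
    expect_equal(names(which.max(row)), st)
  }
})

test_that("programmed seeding rates order the span-matrix row masses", {
  wins <- 0L
  for (s in 1:10) {
    cfg <- sim_config(n_cells = 600L, n_clones = 60L,
                      bm_seeding_prob = c("PC-Tigit" = 0.9,
                                          "PC-Slpi" = 0.3,
                                          "PC-Lag3" = 0.3),
                      seed = 500L + s)
    sim <- simulate_repertoire(cfg)
    paired <- suppressMessages(pair_cell_chains(sim$contigs))
    ca <- call_clones(paired)
    tab <- build_clone_state_table(ca, truth_lookup(sim$truth, "state"),
                                   truth_lookup(sim$truth, "compartment"))
    m <- span_frequency_matrix(tab,
                               states_a = names(cfg$state_proportions))
    wins <- wins + (sum(m["PC-Tigit", ]) > max(sum(m["PC-Slpi", ]),
                                               sum(m["PC-Lag3", ])))
  }
  expect_gte(wins, 9L)
})

test_that("tracing outputs are invariant to barcode order and relabeling", {
  sim <- small_sim()
  ca <- call_clones(sim$paired)
  states <- truth_lookup(sim$truth, "state")
  comps <- truth_lookup(sim$truth, "compartment")
  tab1 <- build_clone_state_table(ca, states, comps)
  # permute assignment rows and relabel clone ids
  perm <- ca
  set.seed(4)
  o <- sample(nrow(ca$assignment))
  perm$assignment <- ca$assignment[o, ]
  relab <- ca
  map <- sample(max(ca$assignment$clone_id))
  relab$assignment$clone_id <- map[ca$assignment$clone_id]
  tab2 <- build_clone_state_table(perm, states, comps)
  expect_equal(tab1, tab2, ignore_attr = TRUE)
  m1 <- span_frequency_matrix(tab1)
  m3 <- span_frequency_matrix(
    build_clone_state_table(relab, states, comps))
  expect_equal(m1, m3)
})

test_that("chord adjacency export round-trips node sets and weights", {
  tt <- toy_tracing()
  tab <- build_clone_state_table(tt$assignment, tt$states, tt$compartments)
  f <- withr::local_tempfile(fileext = ".csv")
  adj <- export_chord_adjacency(tab, f)
  back <- utils::read.csv(f, stringsAsFactors = FALSE)
  expect_equal(back, as.data.frame(adj))
  # node sets reconstruct the spanning clones
  sp <- spanning_clones(tab)
  for (k in seq_len(nrow(sp))) {
    nodes <- sort(unique(c(back$source_node[back$clone_id == sp$clone_id[k]],
                           back$target_node[back$clone_id == sp$clone_id[k]])))
    expect_equal(paste(nodes, collapse = ","), sp$nodes[k])
  }
  # weights sum to total spanning incidences (one per clone-node-pair)
  expect_equal(sum(back$weight),
               sum(choose(sp$n_nodes, 2)))
  # empty spanning set -> header-only file
  f2 <- withr::local_tempfile(fileext = ".csv")
  empty <- tab[tab$clone_id == 2L, ]
  export_chord_adjacency(empty, f2)
  expect_equal(nrow(utils::read.csv(f2)), 0L)
})
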
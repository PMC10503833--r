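# Cross-compartment clonal tracing: clone x (compartment, state) tables,
# spanning clones, span-frequency matrices, chord-diagram adjacency export.

#' Aggregate clones over compartments and genomic states
#'
#' Joins a clone assignment with per-barcode state and compartment labels
#' into a long table of cell counts per (clone, compartment, state) — the
#' substrate for all spanning analyses. Cells lacking either label are
#' excluded and counted; the table can be restricted to NP- or KLH-specific
#' cells.
#'
#' @param assignment a `clone_assignment` from [call_clones()].
#' @param states,compartments named character vectors, barcode -> label.
#' @param specificity optional named vector, barcode -> label, required when
#'   `filter != "all"`.
#' @param filter `"all"`, `"NP"` or `"KLH"`.
#' @return data.frame (clone_id, compartment, state, n_cells) with attribute
#'   `n_unlabeled`; summing `n_cells` gives the number of labeled, filtered
#'   cells.
#' @export
build_clone_state_table <- function(assignment, states, compartments,
                                    specificity = NULL,
                                    filter = c("all", "NP", "KLH")) {
  filter <- match.arg(filter)
  a <- assignment$assignment
  st <- states[a$barcode]
  cp <- compartments[a$barcode]
  keep <- !is.na(st) & !is.na(cp)
  n_unlabeled <- sum(!keep)
  if (filter != "all") {
    if (is.null(specificity))
      stop("parameter error: specificity labels required for filter")
    sp <- specificity[a$barcode]
    keep <- keep & !is.na(sp) & sp == filter
  }
  if (!any(keep))
    stop("empty output: no labeled cells after filtering")
  agg <- stats::aggregate(
    list(n_cells = rep(1L, sum(keep))),
    by = list(clone_id = a$clone_id[keep], compartment = cp[keep],
              state = st[keep]),
    FUN = sum)
  agg <- agg[order(agg$clone_id, agg$compartment, agg$state), , drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "n_unlabeled") <- n_unlabeled
  agg
}

#' Clones spanning multiple (compartment, state) nodes
#'
#' A node is one (compartment, state) combination; a clone spans when it has
#' cells in at least `min_nodes` distinct nodes. `min_nodes = 1` returns all
#' clones; the output shrinks weakly as `min_nodes` grows.
#'
#' @param table a clone-state table from [build_clone_state_table()].
#' @param min_nodes minimum number of distinct nodes (default 2).
#' @return data.frame (clone_id, n_nodes, nodes) where `nodes` is a
#'   comma-separated, sorted list of `compartment:state` node names.
#' @export
spanning_clones <- function(table, min_nodes = 2L) {
  if (min_nodes < 1L) stop("parameter error: min_nodes must be >= 1")
  node <- paste(table$compartment, table$state, sep = ":")
  per_clone <- split(node, table$clone_id)
  n_nodes <- vapply(per_clone, function(x) length(unique(x)), 0L)
  keep <- n_nodes >= min_nodes
  out <- data.frame(
    clone_id = as.integer(names(per_clone))[keep],
    n_nodes = unname(n_nodes[keep]),
    nodes = vapply(per_clone[keep],
                   function(x) paste(sort(unique(x)), collapse = ","), ""),
    stringsAsFactors = FALSE)
  out <- out[order(out$clone_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-compartment span-frequency matrix
#'
#' Entry (i, j) counts the clones (or cells) with at least one cell in state
#' i of compartment A (rows, e.g. spleen) and at least one cell in state j
#' of compartment B (columns, e.g. bone marrow). A clone touching several
#' states contributes to every touched (i, j) pair (all-pairs convention).
#' With `normalize = TRUE` rows are scaled to sum 1; rows with zero mass are
#' left at zero.
#'
#' @param table a clone-state table.
#' @param compartment_a,compartment_b row / column compartments.
#' @param states_a,states_b state sets defining the axes; defaults to the
#'   states observed in each compartment.
#' @param normalize row-normalize to frequencies.
#' @param count `"clones"` (default) or `"cells"`; for cells, the pair
#'   weight is the smaller of the clone's two cell counts.
#' @return numeric matrix states_a x states_b.
#' @export
span_frequency_matrix <- function(table, compartment_a = "spleen",
                                  compartment_b = "bone_marrow",
                                  states_a = NULL, states_b = NULL,
                                  normalize = FALSE,
                                  count = c("clones", "cells")) {
  count <- match.arg(count)
  ta <- table[table$compartment == compartment_a, , drop = FALSE]
  tb <- table[table$compartment == compartment_b, , drop = FALSE]
  if (is.null(states_a)) states_a <- sort(unique(ta$state))
  if (is.null(states_b)) states_b <- sort(unique(tb$state))
  m <- matrix(0, length(states_a), length(states_b),
              dimnames = list(states_a, states_b))
  shared <- intersect(ta$clone_id, tb$clone_id)
  for (cl in shared) {
    ra <- ta[ta$clone_id == cl & ta$state %in% states_a, , drop = FALSE]
    rb <- tb[tb$clone_id == cl & tb$state %in% states_b, , drop = FALSE]
    for (i in seq_len(nrow(ra))) for (j in seq_len(nrow(rb))) {
      w <- if (count == "clones") 1 else min(ra$n_cells[i], rb$n_cells[j])
      m[ra$state[i], rb$state[j]] <- m[ra$state[i], rb$state[j]] + w
    }
  }
  if (normalize) {
    rs <- rowSums(m)
    nz <- rs > 0
    m[nz, ] <- m[nz, , drop = FALSE] / rs[nz]
  }
  m
}

#' Export spanning-clone adjacency for chord diagrams
#'
#' Writes a long-format CSV (`source_node`, `target_node`, `clone_id`,
#' `weight`) with one row per (clone, unordered node pair) incidence among
#' spanning clones; nodes are named `compartment:state`. Consumable by
#' standard chord/Circos tooling; rendering itself is out of scope.
#'
#' @param table a clone-state table.
#' @param out_path output CSV path.
#' @param min_nodes passed to [spanning_clones()].
#' @return the written data.frame, invisibly.
#' @export
export_chord_adjacency <- function(table, out_path, min_nodes = 2L) {
  sp <- spanning_clones(table, min_nodes = min_nodes)
  rows <- list()
  for (k in seq_len(nrow(sp))) {
    nodes <- strsplit(sp$nodes[k], ",", fixed = TRUE)[[1L]]
    if (length(nodes) < 2L) next
    pairs <- utils::combn(sort(nodes), 2L)
    rows[[length(rows) + 1L]] <- data.frame(
      source_node = pairs[1L, ], target_node = pairs[2L, ],
      clone_id = sp$clone_id[k], weight = 1L, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source_node = character(), target_node = character(),
               clone_id = integer(), weight = integer())
  utils::write.csv(out, out_path, row.names = FALSE, quote = FALSE)
  invisible(out)
}
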
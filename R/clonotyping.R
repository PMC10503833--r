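# Clone calling by exact V(D)J identity of the resolved heavy/light pair.

#' Clonotype identity keys
#'
#' The clonal identity of a cell is the tuple (heavy V, heavy D, heavy J,
#' heavy CDR3 amino-acid sequence, light V, light J): cells are clone-mates
#' iff they carry identical V(D)J rearrangements in their heavy and light
#' chain loci, including the identical heavy CDR3 amino-acid sequence.
#' Light-chain CDR3 identity is additionally required only under
#' `strict = TRUE`.
#'
#' @param cells paired-cell table from [pair_cell_chains()].
#' @param granularity V/J gene granularity, `"allele"` or `"gene"`.
#' @param strict also require identical light CDR3 amino acids.
#' @return data.frame of key fields aligned to `cells` rows, plus a `key`
#'   string column; cells with a missing/empty heavy CDR3 get `NA` keys.
#' @export
clonotype_key <- function(cells, granularity = c("allele", "gene"),
                          strict = FALSE) {
  granularity <- match.arg(granularity)
  g <- function(x) .v_at_granularity(x, granularity)
  k <- data.frame(
    heavy_v = g(cells$heavy_v), heavy_d = cells$heavy_d,
    heavy_j = g(cells$heavy_j), heavy_cdr3_aa = cells$heavy_cdr3_aa,
    light_v = g(cells$light_v), light_j = g(cells$light_j),
    stringsAsFactors = FALSE)
  if (strict) k$light_cdr3_aa <- cells$light_cdr3_aa
  bad <- is.na(k$heavy_cdr3_aa) | k$heavy_cdr3_aa == ""
  key <- do.call(paste, c(unname(as.list(k)), sep = "|"))
  key[bad] <- NA_character_
  k$key <- key
  k
}

#' Partition cells into clones
#'
#' Groups paired cells by exact clonotype-key equality. Clone ids are stable
#' integers ordered by descending clone size, then lexicographically by key,
#' so the numbering is invariant to input row order. Cells without a usable
#' heavy CDR3 are excluded and counted.
#'
#' @inheritParams clonotype_key
#' @param min_clone_size clones below this size are kept but flagged.
#' @return object of class `clone_assignment`: list with `assignment`
#'   (barcode, clone_id), `clones` (clone_id, key fields, n_cells,
#'   is_singleton, below_min_size) and `n_excluded`.
#' @export
call_clones <- function(cells, min_clone_size = 1L,
                        granularity = c("allele", "gene"), strict = FALSE) {
  keys <- clonotype_key(cells, granularity, strict)
  ok <- !is.na(keys$key)
  n_excluded <- sum(!ok)
  cells_ok <- cells[ok, , drop = FALSE]
  keys_ok <- keys[ok, , drop = FALSE]
  sizes <- table(keys_ok$key)
  ord <- order(-as.integer(sizes), names(sizes))
  key_levels <- names(sizes)[ord]
  clone_id <- match(keys_ok$key, key_levels)

  assignment <- data.frame(barcode = cells_ok$barcode, clone_id = clone_id,
                           stringsAsFactors = FALSE)
  assignment <- assignment[order(assignment$barcode), , drop = FALSE]
  rownames(assignment) <- NULL

  first <- match(key_levels, keys_ok$key)
  kf <- keys_ok[first, setdiff(names(keys_ok), "key"), drop = FALSE]
  clones <- cbind(data.frame(clone_id = seq_along(key_levels)), kf,
                  data.frame(n_cells = as.integer(sizes)[ord]))
  clones$is_singleton <- clones$n_cells == 1L
  clones$below_min_size <- clones$n_cells < min_clone_size
  rownames(clones) <- NULL

  out <- list(assignment = assignment, clones = clones,
              n_excluded = n_excluded)
  class(out) <- "clone_assignment"
  out
}

#' @export
print.clone_assignment <- function(x, ...) {
  cat("Clone assignment: ", nrow(x$assignment), " cells in ",
      nrow(x$clones), " clones (", sum(x$clones$is_singleton),
      " singletons, ", x$n_excluded, " cells excluded)\n", sep = "")
  invisible(x)
}

#' Summarize clone sizes per genomic state
#'
#' Tabulates, for each (state, clone) with at least one member cell in that
#' state, the number of member cells — the substrate for comparing clone
#' sizes across PC progenitors and PC clusters. Cells lacking a state label
#' fall into an `"unlabeled"` bucket; totals conserve cell counts.
#'
#' @param assignment a `clone_assignment`.
#' @param states named character vector, barcode -> state.
#' @param specificity optional named vector, barcode -> label; with
#'   `filter != "all"` only cells with that label are counted.
#' @param filter `"all"`, `"NP"` or `"KLH"`.
#' @return data.frame (state, clone_id, n_cells).
#' @export
clone_sizes_by_state <- function(assignment, states, specificity = NULL,
                                 filter = c("all", "NP", "KLH")) {
  filter <- match.arg(filter)
  a <- assignment$assignment
  st <- states[a$barcode]
  st[is.na(st)] <- "unlabeled"
  keep <- rep(TRUE, nrow(a))
  if (filter != "all") {
    if (is.null(specificity))
      stop("parameter error: specificity labels required for filter")
    keep <- !is.na(specificity[a$barcode]) &
      specificity[a$barcode] == filter
  }
  if (!any(keep))
    return(data.frame(state = character(), clone_id = integer(),
                      n_cells = integer()))
  agg <- stats::aggregate(
    list(n_cells = rep(1L, sum(keep))),
    by = list(state = st[keep], clone_id = a$clone_id[keep]), FUN = sum)
  agg <- agg[order(agg$state, agg$clone_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
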
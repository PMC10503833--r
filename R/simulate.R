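# Synthetic paired repertoire + expression generator with full ground truth.

.AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
           "T","W","Y","V")
.BASES <- c("A", "C", "G", "T")

# random CDR3 amino-acid string anchored C...W
.random_cdr3 <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste0("C", paste(sample(.AA20, len - 2L, replace = TRUE), collapse = ""),
           "W"), "")
}

.random_nt <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(.BASES, len, replace = TRUE), collapse = ""), "")
}

# codon encoding `aa` with minimal Hamming distance from `codon` (3 chars)
.nearest_codon <- function(codon, aa) {
  cands <- .codons_by_aa()[[aa]]
  d <- vapply(cands, function(cc)
    sum(strsplit(cc, "")[[1L]] != strsplit(codon, "")[[1L]]), 0L)
  cands[order(d, cands)][1L]
}

#' Simulate a single-cell BCR repertoire with ground truth
#'
#' Generates a contig table (one heavy and at least one light chain per cell)
#' together with a truth table recording, per barcode, the clone, antigen
#' specificity, genomic state, anatomical compartment, timepoint, the exact
#' number of V-segment nucleotide substitutions applied, and whether the
#' clone carries the designated high-affinity substitution.
#'
#' Clone structure: each clone draws a heavy V gene from `ighv_usage` (its
#' truth specificity is NP or KLH when the gene belongs to the configured
#' sets), a primary genomic state, and a size from power-law weights
#' (`clone_size_exponent`), boosted by `pc_size_boost` for PC-cluster
#' clones. Clones whose primary state is in `bm_states` may seed the bone
#' marrow; their bone-marrow cells retain the primary state and their
#' within-spleen spread is restricted to PC states. PC-progenitor clones
#' spread into PC states within the spleen but never reach the bone marrow;
#' all other clones stay in their primary state. Per-cell substitution
#' counts are Poisson with mean `mutation_rate_per_timepoint` times the
#' 1-based timepoint index; substitutions fall uniformly on the V segment
#' outside the affinity codon, which is rewritten (to the nearest codon of
#' the target residue) only in clones carrying the affinity flag.
#'
#' @param config a [sim_config()].
#' @param germline a [germline_set()] covering every gene in
#'   `config$ighv_usage`.
#' @return list with elements `contigs` (data.frame of chain contigs) and
#'   `truth` (data.frame, one row per barcode).
#' @export
simulate_repertoire <- function(config, germline = default_germline(config)) {
  validate_sim_config(config)
  validate_germline_set(germline)
  if (!all(names(config$ighv_usage) %in% germline$gene))
    stop("germline does not cover all genes in ighv_usage")
  set.seed(config$seed)

  nclo <- config$n_clones
  ncel <- config$n_cells
  states <- names(config$state_proportions)
  lp <- .light_pool()

  ## clone-level draws
  heavy_v <- sample(names(config$ighv_usage), nclo, replace = TRUE,
                    prob = config$ighv_usage)
  heavy_d <- sample(.heavy_d_pool(), nclo, replace = TRUE)
  heavy_j <- sample(.heavy_j_pool(), nclo, replace = TRUE)
  heavy_cdr3 <- .random_cdr3(nclo, config$cdr3_length)
  heavy_cdr3_nt <- .random_nt(nclo, 3L * config$cdr3_length)
  light_idx <- sample(nrow(lp), nclo, replace = TRUE)
  light_cdr3 <- .random_cdr3(nclo, 9L)
  primary <- sample(states, nclo, replace = TRUE,
                    prob = config$state_proportions)
  specificity <- ifelse(heavy_v %in% config$np_genes, "NP",
                        ifelse(heavy_v %in% config$klh_genes, "KLH", "other"))
  affinity_flag <- stats::runif(nclo) < config$affinity_mutation_prob

  ## clone sizes: power-law weights, PC clones boosted, every clone >= 1
  w <- seq_len(nclo)^(-config$clone_size_exponent)
  w <- w * ifelse(primary %in% config$bm_states, config$pc_size_boost, 1)
  sizes <- rep(1L, nclo)
  extra <- ncel - nclo
  if (extra > 0L)
    sizes <- sizes + stats::rmultinom(1L, extra, prob = w)[, 1L]
  clone_of <- rep(seq_len(nclo), sizes)
  clone_ids <- sprintf("simclone%04d", seq_len(nclo))

  ## per-cell draws
  barcodes <- sprintf("cell%06d-1", seq_len(ncel))
  timepoint <- sample(config$timepoints, ncel, replace = TRUE,
                      prob = config$timepoint_proportions)
  tp_index <- match(timepoint, config$timepoints)

  seed_prob <- config$bm_seeding_prob
  if (is.null(names(seed_prob))) {
    seed_prob <- stats::setNames(rep(seed_prob[1L],
                                     length(config$bm_states)),
                                 config$bm_states)
  } else {
    full <- stats::setNames(rep(0, length(config$bm_states)),
                            config$bm_states)
    full[names(seed_prob)] <- seed_prob
    seed_prob <- full
  }
  seeds_bm <- primary %in% config$bm_states &
    stats::runif(nclo) < seed_prob[primary]
  p_bm <- unname(config$compartment_proportions["bone_marrow"])
  if (is.na(p_bm)) p_bm <- 0
  is_bm <- seeds_bm[clone_of] & stats::runif(ncel) < p_bm
  compartment <- ifelse(is_bm, "bone_marrow", "spleen")

  state <- primary[clone_of]
  wander <- which(!is_bm & stats::runif(ncel) > config$state_fidelity)
  if (length(wander)) {
    state[wander] <- vapply(wander, function(i) {
      p <- primary[clone_of[i]]
      pool <- if (p %in% config$bm_states) {
        setdiff(config$bm_states, p)
      } else if (identical(p, "PC-progenitor")) {
        intersect(config$bm_states, states)
      } else character(0)
      if (length(pool)) sample(pool, 1L) else p
    }, "")
  }

  ## somatic hypermutation on the heavy V segment
  germ_chars <- lapply(germline$nt, function(s) strsplit(s, "")[[1L]])
  names(germ_chars) <- germline$gene
  ap_list <- lapply(seq_len(nrow(germline)), function(i)
    (germline$affinity_position[i] - 1L) * 3L + 1:3)
  names(ap_list) <- germline$gene
  target_codon <- vapply(seq_len(nrow(germline)), function(i) {
    ap <- ap_list[[i]]
    .nearest_codon(substr(germline$nt[i], ap[1L], ap[3L]),
                   germline$affinity_to[i])
  }, "")
  names(target_codon) <- germline$gene

  k_draw <- stats::rpois(ncel, config$mutation_rate_per_timepoint * tp_index)
  v_seq <- character(ncel)
  n_mut <- integer(ncel)
  for (i in seq_len(ncel)) {
    g <- heavy_v[clone_of[i]]
    ref <- germ_chars[[g]]
    x <- ref
    ap <- ap_list[[g]]
    avail <- setdiff(seq_along(x), ap)
    k <- min(k_draw[i], length(avail))
    if (k > 0L) {
      pos <- sample(avail, k)
      x[pos] <- vapply(x[pos],
                       function(b) sample(setdiff(.BASES, b), 1L), "")
    }
    if (affinity_flag[clone_of[i]])
      x[ap] <- strsplit(target_codon[[g]], "")[[1L]]
    v_seq[i] <- paste(x, collapse = "")
    n_mut[i] <- sum(x != ref)
  }
  germ_nt_of <- germline$nt[match(heavy_v[clone_of], germline$gene)]

  truth <- data.frame(
    barcode = barcodes, clone_id = clone_ids[clone_of],
    specificity = specificity[clone_of], state = state,
    compartment = compartment, timepoint = timepoint,
    n_v_mutations = n_mut,
    has_affinity_mutation = affinity_flag[clone_of],
    stringsAsFactors = FALSE)

  ## contig rows: one heavy, one productive light, optional decoy light
  heavy <- data.frame(
    barcode = barcodes, locus = "IGH",
    v_call = heavy_v[clone_of], d_call = heavy_d[clone_of],
    j_call = heavy_j[clone_of], cdr3_aa = heavy_cdr3[clone_of],
    cdr3_nt = heavy_cdr3_nt[clone_of], productive = TRUE,
    umi_count = stats::rpois(ncel, 3) + 1L,
    v_sequence_nt = v_seq, germline_v_nt = germ_nt_of,
    stringsAsFactors = FALSE)
  light <- data.frame(
    barcode = barcodes, locus = lp$locus[light_idx[clone_of]],
    v_call = lp$v_call[light_idx[clone_of]],
    d_call = "", j_call = lp$j_call[light_idx[clone_of]],
    cdr3_aa = light_cdr3[clone_of],
    cdr3_nt = .random_nt(ncel, 27L), productive = TRUE,
    umi_count = stats::rpois(ncel, 3) + 1L,
    v_sequence_nt = NA_character_, germline_v_nt = NA_character_,
    stringsAsFactors = FALSE)
  decoy_cells <- which(stats::runif(ncel) < config$decoy_light_prob)
  decoy <- NULL
  if (length(decoy_cells)) {
    alt <- vapply(decoy_cells, function(i) {
      used <- light$v_call[i]
      sample(setdiff(lp$v_call, used), 1L)
    }, "")
    alt_row <- match(alt, lp$v_call)
    decoy <- data.frame(
      barcode = barcodes[decoy_cells], locus = lp$locus[alt_row],
      v_call = alt, d_call = "", j_call = lp$j_call[alt_row],
      cdr3_aa = .random_cdr3(length(decoy_cells), 9L),
      cdr3_nt = .random_nt(length(decoy_cells), 27L), productive = FALSE,
      umi_count = 1L, v_sequence_nt = NA_character_,
      germline_v_nt = NA_character_, stringsAsFactors = FALSE)
  }
  contigs <- rbind(heavy, light, decoy)
  contigs <- contigs[order(contigs$barcode, contigs$locus, contigs$v_call), ]
  rownames(contigs) <- NULL
  list(contigs = contigs, truth = truth)
}

#' Simulate a cell-by-gene count matrix with planted marker structure
#'
#' Draws UMI counts from a negative-binomial (or Poisson) model in which each
#' genomic state's marker genes have their relative abundance elevated by
#' `marker_fold` in cells of that state. Gene relative abundances are
#' gamma-distributed; per-cell library sizes are Poisson around
#' `library_size_mean`.
#'
#' @param truth truth table from [simulate_repertoire()] (only `barcode` and
#'   `state` are used, so a hand-built table works too).
#' @param config a [sim_config()].
#' @return list with `counts` (sparse gene x cell `dgCMatrix`, columns in
#'   truth barcode order) and `marker_map` (named list state -> gene names).
#' @export
simulate_expression <- function(truth, config) {
  validate_sim_config(config)
  if (nrow(truth) == 0L) stop("truth table is empty")
  set.seed(config$seed + 1L)
  states <- names(config$state_proportions)
  if (!all(truth$state %in% states))
    stop("truth contains states absent from config$state_proportions")
  ng <- config$n_genes
  m <- config$n_marker_genes_per_state
  genes <- sprintf("gene%05d", seq_len(ng))
  marker_map <- stats::setNames(lapply(seq_along(states), function(i)
    genes[((i - 1L) * m + 1L):(i * m)]), states)

  rel <- stats::rgamma(ng, shape = 0.5, rate = 1) + 1e-4
  lib <- stats::rpois(nrow(truth), config$library_size_mean)

  blocks <- vector("list", length(states))
  col_order <- integer(0)
  for (si in seq_along(states)) {
    idx <- which(truth$state == states[si])
    if (!length(idx)) next
    p <- rel
    p[match(marker_map[[states[si]]], genes)] <-
      p[match(marker_map[[states[si]]], genes)] * config$marker_fold
    p <- p / sum(p)
    mu <- outer(p, lib[idx])
    cnt <- if (config$count_model == "nb") {
      stats::rnbinom(length(mu), mu = mu, size = config$dispersion)
    } else {
      stats::rpois(length(mu), mu)
    }
    blk <- matrix(cnt, nrow = ng)
    blocks[[si]] <- methods::as(Matrix::Matrix(blk, sparse = TRUE),
                                "CsparseMatrix")
    col_order <- c(col_order, idx)
  }
  counts <- do.call(cbind, blocks[!vapply(blocks, is.null, TRUE)])
  counts <- counts[, order(col_order), drop = FALSE]
  dimnames(counts) <- list(genes, truth$barcode)
  list(counts = counts, marker_map = marker_map)
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Emits the eight artifacts consumed by the pipeline readers — a 10x-dialect
#' contig CSV, an AIRR Rearrangement TSV, the MatrixMarket triplet
#' (matrix.mtx, barcodes.tsv, features.tsv), germline nucleotide and
#' amino-acid FASTA files, and the truth TSV — plus `manifest.tsv` listing
#' each file's MD5 checksum and size.
#'
#' @param contigs,truth from [simulate_repertoire()].
#' @param counts sparse matrix from [simulate_expression()].
#' @param germline the [germline_set()] used.
#' @param out_dir output directory (created if absent).
#' @return data.frame manifest (file, md5, bytes), invisibly.
#' @export
write_fixture_bundle <- function(contigs, counts, truth, germline, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("I/O error: cannot create output directory ", out_dir)
  p <- function(f) file.path(out_dir, f)

  write_contigs_tenx(contigs, p("contigs_10x.csv"))
  write_contigs_airr(contigs, p("contigs_airr.tsv"))
  Matrix::writeMM(counts, p("matrix.mtx"))
  writeLines(colnames(counts), p("barcodes.tsv"))
  writeLines(rownames(counts), p("features.tsv"))
  write_germline_fasta(germline, p("germline_nt.fasta"),
                       p("germline_aa.fasta"))
  utils::write.table(truth, p("truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  files <- c("contigs_10x.csv", "contigs_airr.tsv", "matrix.mtx",
             "barcodes.tsv", "features.tsv", "germline_nt.fasta",
             "germline_aa.fasta", "truth.tsv")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    bytes = unname(file.size(file.path(out_dir, files))),
    stringsAsFactors = FALSE)
  utils::write.table(manifest, p("manifest.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(manifest)
}
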
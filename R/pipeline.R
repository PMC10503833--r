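# File-based pipeline orchestration: composable subcommands, run reports,
# and a one-shot end-to-end demo on generated fixtures.

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.read_label_tsv <- function(path, value_col) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("barcode", value_col) %in% names(df)))
    stop("format error: ", path, " needs columns barcode, ", value_col)
  stats::setNames(df[[value_col]], df$barcode)
}

.run_report <- function(out_dir, subcommand, params, inputs, outputs) {
  report <- list(
    subcommand = subcommand,
    package_version = as.character(utils::packageVersion("pctrace")),
    parameters = params,
    input_md5 = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    outputs = outputs)
  path <- file.path(out_dir, paste0("report_", subcommand, ".json"))
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  report
}

.require_keys <- function(config, required, optional = character()) {
  miss <- setdiff(required, names(config))
  if (length(miss))
    stop("invalid config: missing key(s): ", paste(miss, collapse = ", "))
  unknown <- setdiff(names(config), c(required, optional))
  if (length(unknown))
    stop("invalid config: unknown key(s): ", paste(unknown, collapse = ", "))
  invisible(config)
}

#' Run one pipeline subcommand
#'
#' Executes a single stage of the analysis against files on disk, writing
#' the stage's TSV/CSV artifacts plus a JSON run report (parameters, input
#' checksums, outputs) into `config$out_dir`. Stages communicate via files
#' only, so each is independently reproducible from its report. On failure,
#' files created by the failing stage are removed.
#'
#' Subcommands and their config keys:
#' \describe{
#'   \item{simulate}{`out_dir`, optional `sim` (argument list for
#'     [sim_config()]); writes the full fixture bundle.}
#'   \item{pair}{`contigs`, `dialect`, `out_dir`, optional `heavy_policy`;
#'     writes `paired.tsv`.}
#'   \item{clones}{`paired`, `out_dir`, optional `granularity`, `strict`;
#'     writes `clone_assignment.tsv`, `clones.tsv`.}
#'   \item{specificity}{`paired_reference`, `paired_a`, `paired_b`,
#'     `paired_query`, `out_dir`, optional `top_n_reference` (25),
#'     `top_n_sample` (50), `granularity`; writes `specificity_sets.tsv`,
#'     `specificity_labels.tsv`.}
#'   \item{shm}{`paired`, `germline_nt`, `germline_aa`, `out_dir`; writes
#'     `mutation_profiles.tsv`.}
#'   \item{states}{`reference_mtx`, `reference_labels`, `marker_genes`,
#'     `query_mtx`, `out_dir`, optional `min_correlation` (0.7); writes
#'     `state_labels.tsv`.}
#'   \item{score}{`mtx`, `genes`, `out_dir`, optional `seed`, `n_bins`,
#'     `bg_per_gene`; writes `signature_scores.tsv`.}
#'   \item{deg}{`mtx_a`, `mtx_b`, `out_dir`, optional `fold_threshold`
#'     (1.2), `alpha` (0.05); writes `deg.tsv`.}
#'   \item{trace}{`clone_assignment`, `states`, `compartments`, `out_dir`,
#'     optional `specificity`, `filter`, `min_nodes` (2), `normalize`;
#'     writes `clone_state_table.tsv`, `spanning_clones.tsv`,
#'     `span_matrix.tsv`, `chord_adjacency.csv`.}
#'   \item{demo}{`out_dir`, optional `seed`; runs [run_demo()].}
#' }
#'
#' @param name subcommand name.
#' @param config named list of paths and parameters for the subcommand.
#' @return the run report (for `demo`, the demo report), invisibly.
#' @export
run_subcommand <- function(name = c("simulate", "pair", "clones",
                                    "specificity", "shm", "states", "score",
                                    "deg", "trace", "demo"),
                           config = list()) {
  name <- match.arg(name)
  if (is.null(config$out_dir)) stop("invalid config: missing key(s): out_dir")
  out_dir <- config$out_dir
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  made <- character()
  on_fail_cleanup <- function(e) {
    unlink(made[file.exists(made)])
    stop(e)
  }
  tryCatch({
    report <- switch(
      name,
      simulate = {
        .require_keys(config, "out_dir", "sim")
        cfg <- do.call(sim_config, if (is.null(config$sim)) list() else
          config$sim)
        gl <- default_germline(cfg)
        rep_ <- simulate_repertoire(cfg, gl)
        expr <- simulate_expression(rep_$truth, cfg)
        manifest <- write_fixture_bundle(rep_$contigs, expr$counts,
                                         rep_$truth, gl, out_dir)
        made <- file.path(out_dir, manifest$file)
        .run_report(out_dir, "simulate",
                    params = unclass(cfg)[c("n_cells", "n_clones", "seed")],
                    inputs = character(), outputs = as.list(manifest$md5))
      },
      pair = {
        .require_keys(config, c("contigs", "dialect", "out_dir"),
                      "heavy_policy")
        contigs <- read_contigs(config$contigs, config$dialect)
        hp <- if (is.null(config$heavy_policy)) "drop" else
          config$heavy_policy
        paired <- pair_cell_chains(contigs, heavy_policy = hp)
        made <- .write_tsv(paired, file.path(out_dir, "paired.tsv"))
        .run_report(out_dir, "pair",
                    params = list(dialect = config$dialect,
                                  heavy_policy = hp,
                                  exclusions = as.list(
                                    attr(paired, "exclusions"))),
                    inputs = config$contigs,
                    outputs = as.list(tools::md5sum(made)))
      },
      clones = {
        .require_keys(config, c("paired", "out_dir"),
                      c("granularity", "strict"))
        paired <- utils::read.delim(config$paired, stringsAsFactors = FALSE)
        gran <- if (is.null(config$granularity)) "allele" else
          config$granularity
        strict <- isTRUE(config$strict)
        ca <- call_clones(paired, granularity = gran, strict = strict)
        made <- c(
          .write_tsv(merge(ca$assignment,
                           ca$clones[, c("clone_id", "heavy_v", "heavy_d",
                                         "heavy_j", "heavy_cdr3_aa",
                                         "light_v", "light_j")],
                           by = "clone_id"),
                     file.path(out_dir, "clone_assignment.tsv")),
          .write_tsv(ca$clones, file.path(out_dir, "clones.tsv")))
        .run_report(out_dir, "clones",
                    params = list(granularity = gran, strict = strict,
                                  n_clones = nrow(ca$clones),
                                  n_excluded = ca$n_excluded),
                    inputs = config$paired,
                    outputs = as.list(tools::md5sum(made)))
      },
      specificity = {
        .require_keys(config, c("paired_reference", "paired_a", "paired_b",
                                "paired_query", "out_dir"),
                      c("top_n_reference", "top_n_sample", "granularity"))
        tn_ref <- if (is.null(config$top_n_reference)) 25L else
          config$top_n_reference
        tn_s <- if (is.null(config$top_n_sample)) 50L else
          config$top_n_sample
        gran <- if (is.null(config$granularity)) "allele" else
          config$granularity
        rd <- function(p) utils::read.delim(p, stringsAsFactors = FALSE)
        rl_ref <- ighv_rank_list(rd(config$paired_reference), tn_ref, gran)
        rl_a <- ighv_rank_list(rd(config$paired_a), tn_s, gran)
        rl_b <- ighv_rank_list(rd(config$paired_b), tn_s, gran)
        sets <- derive_specificity_sets(rl_ref, rl_a, rl_b)
        query <- rd(config$paired_query)
        labels <- assign_specificity(query, sets, gran)
        made <- c(
          .write_tsv(data.frame(
            gene = c(sets$np_genes, sets$klh_genes),
            specificity = c(rep("NP", length(sets$np_genes)),
                            rep("KLH", length(sets$klh_genes)))),
            file.path(out_dir, "specificity_sets.tsv")),
          .write_tsv(data.frame(barcode = query$barcode,
                                specificity = labels),
                     file.path(out_dir, "specificity_labels.tsv")))
        .run_report(out_dir, "specificity",
                    params = list(top_n_reference = tn_ref,
                                  top_n_sample = tn_s, granularity = gran),
                    inputs = c(config$paired_reference, config$paired_a,
                               config$paired_b, config$paired_query),
                    outputs = as.list(tools::md5sum(made)))
      },
      shm = {
        .require_keys(config, c("paired", "germline_nt", "germline_aa",
                                "out_dir"))
        paired <- utils::read.delim(config$paired, stringsAsFactors = FALSE)
        gl <- read_germline_fasta(config$germline_nt, config$germline_aa)
        prof <- mutation_profiles(paired, gl)
        made <- .write_tsv(prof, file.path(out_dir,
                                           "mutation_profiles.tsv"))
        .run_report(out_dir, "shm", params = list(n_profiles = nrow(prof)),
                    inputs = c(config$paired, config$germline_nt,
                               config$germline_aa),
                    outputs = as.list(tools::md5sum(made)))
      },
      states = {
        .require_keys(config, c("reference_mtx", "reference_labels",
                                "marker_genes", "query_mtx", "out_dir"),
                      "min_correlation")
        minr <- if (is.null(config$min_correlation)) 0.7 else
          config$min_correlation
        ref <- read_expression(config$reference_mtx, "mtx_dir")
        labels <- .read_label_tsv(config$reference_labels, "state")
        markers <- readLines(config$marker_genes)
        sr <- build_centroids(ref, labels, markers,
                              min_correlation = minr)
        query <- read_expression(config$query_mtx, "mtx_dir")
        cls <- classify_cells(query, sr)
        made <- .write_tsv(cls, file.path(out_dir, "state_labels.tsv"))
        .run_report(out_dir, "states",
                    params = list(min_correlation = minr,
                                  n_states = ncol(sr$centroids)),
                    inputs = c(config$reference_labels,
                               config$marker_genes),
                    outputs = as.list(tools::md5sum(made)))
      },
      score = {
        .require_keys(config, c("mtx", "genes", "out_dir"),
                      c("seed", "n_bins", "bg_per_gene"))
        m <- read_expression(config$mtx, "mtx_dir")
        genes <- readLines(config$genes)
        seed <- if (is.null(config$seed)) 1L else config$seed
        sc <- signature_score(
          m, genes,
          n_background_bins = if (is.null(config$n_bins)) 25L else
            config$n_bins,
          background_size_per_gene = if (is.null(config$bg_per_gene)) 50L
          else config$bg_per_gene,
          seed = seed)
        made <- .write_tsv(data.frame(barcode = names(sc), score = sc),
                           file.path(out_dir, "signature_scores.tsv"))
        .run_report(out_dir, "score", params = list(seed = seed),
                    inputs = config$genes,
                    outputs = as.list(tools::md5sum(made)))
      },
      deg = {
        .require_keys(config, c("mtx_a", "mtx_b", "out_dir"),
                      c("fold_threshold", "alpha"))
        ft <- if (is.null(config$fold_threshold)) 1.2 else
          config$fold_threshold
        al <- if (is.null(config$alpha)) 0.05 else config$alpha
        a <- read_expression(config$mtx_a, "mtx_dir")
        b <- read_expression(config$mtx_b, "mtx_dir")
        deg <- differential_expression(a, b, fold_threshold = ft,
                                       alpha = al)
        made <- .write_tsv(deg, file.path(out_dir, "deg.tsv"))
        .run_report(out_dir, "deg",
                    params = list(fold_threshold = ft, alpha = al,
                                  n_deg = sum(deg$is_deg)),
                    inputs = character(),
                    outputs = as.list(tools::md5sum(made)))
      },
      trace = {
        .require_keys(config, c("clone_assignment", "states",
                                "compartments", "out_dir"),
                      c("specificity", "filter", "min_nodes", "normalize"))
        adf <- utils::read.delim(config$clone_assignment,
                                 stringsAsFactors = FALSE)
        ca <- list(assignment = adf[, c("barcode", "clone_id")])
        st <- .read_label_tsv(config$states, "state")
        cp <- .read_label_tsv(config$compartments, "compartment")
        sp <- if (!is.null(config$specificity))
          .read_label_tsv(config$specificity, "specificity") else NULL
        filt <- if (is.null(config$filter)) "all" else config$filter
        mn <- if (is.null(config$min_nodes)) 2L else config$min_nodes
        cst <- build_clone_state_table(ca, st, cp, specificity = sp,
                                       filter = filt)
        spn <- spanning_clones(cst, min_nodes = mn)
        m <- span_frequency_matrix(cst,
                                   normalize = isTRUE(config$normalize))
        made <- c(
          .write_tsv(cst, file.path(out_dir, "clone_state_table.tsv")),
          .write_tsv(spn, file.path(out_dir, "spanning_clones.tsv")),
          .write_tsv(data.frame(spleen_state = rownames(m),
                                as.data.frame(m), check.names = FALSE),
                     file.path(out_dir, "span_matrix.tsv")))
        export_chord_adjacency(cst, file.path(out_dir,
                                              "chord_adjacency.csv"),
                               min_nodes = mn)
        made <- c(made, file.path(out_dir, "chord_adjacency.csv"))
        .run_report(out_dir, "trace",
                    params = list(filter = filt, min_nodes = mn,
                                  n_spanning = nrow(spn)),
                    inputs = c(config$clone_assignment, config$states,
                               config$compartments),
                    outputs = as.list(tools::md5sum(made)))
      },
      demo = {
        .require_keys(config, "out_dir", "seed")
        run_demo(out_dir, seed = if (is.null(config$seed)) 1L else
          config$seed)
      })
    invisible(report)
  }, error = on_fail_cleanup)
}

#' End-to-end demo on generated fixtures
#'
#' Simulates a paired repertoire + expression dataset, writes the fixture
#' bundle, then runs the full pipeline from the files on disk: read and pair
#' contigs, call clones, derive specificity sets, quantify somatic
#' hypermutation and affinity maturation, transfer state labels by centroid
#' correlation, and trace clones across compartments. Asserts the
#' synthetic-recovery invariants (clone-calling ARI of 1 against truth,
#' exact per-cell mutation recovery, zero progenitor-to-bone-marrow links)
#' and writes `demo_report.json`.
#'
#' @param out_dir output directory for fixtures, artifacts and the report.
#' @param seed integer seed for the simulation.
#' @return the report, a named list, invisibly.
#' @export
run_demo <- function(out_dir, seed = 1L) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- sim_config(seed = seed)
  gl <- default_germline(cfg)
  sim <- simulate_repertoire(cfg, gl)
  expr <- simulate_expression(sim$truth, cfg)
  write_fixture_bundle(sim$contigs, expr$counts, sim$truth, gl, out_dir)
  truth <- sim$truth

  contigs <- read_contigs(file.path(out_dir, "contigs_airr.tsv"), "airr_tsv")
  paired <- pair_cell_chains(contigs)
  ca <- call_clones(paired)

  idx <- match(ca$assignment$barcode, truth$barcode)
  ari <- mclust::adjustedRandIndex(ca$assignment$clone_id,
                                   truth$clone_id[idx])
  if (ari < 1)
    stop("demo: clone recovery ARI ", signif(ari, 4), " < 1")

  tp <- stats::setNames(truth$timepoint, truth$barcode)[paired$barcode]
  spec_truth <- stats::setNames(truth$specificity,
                                truth$barcode)[paired$barcode]
  rl_ref <- ighv_rank_list(paired[spec_truth == "NP", , drop = FALSE], 25L,
                           sample_id = "NP-reference")
  rl_a <- ighv_rank_list(paired[tp == cfg$timepoints[1L], , drop = FALSE],
                         50L, sample_id = cfg$timepoints[1L])
  rl_b <- ighv_rank_list(paired[tp == cfg$timepoints[2L], , drop = FALSE],
                         50L, sample_id = cfg$timepoints[2L])
  sets <- derive_specificity_sets(rl_ref, rl_a, rl_b)
  planted <- intersect(cfg$np_genes, paired$heavy_v)
  np_precision <- if (length(sets$np_genes))
    mean(sets$np_genes %in% planted) else NA_real_
  np_recall <- mean(planted %in% sets$np_genes)
  labels <- assign_specificity(paired, sets)

  prof <- mutation_profiles(paired, gl)
  tr_mut <- stats::setNames(truth$n_v_mutations, truth$barcode)
  shm_exact <- mean(prof$n_mutations == tr_mut[prof$barcode])
  aff <- affinity_maturation_proportions(prof, rep("all", nrow(prof)))

  ref <- build_centroids(expr$counts,
                         stats::setNames(truth$state, truth$barcode),
                         unlist(expr$marker_map))
  cls <- classify_cells(expr$counts, ref)
  acc <- mean(cls$label == truth$state[match(cls$barcode, truth$barcode)])

  cst <- build_clone_state_table(
    ca, stats::setNames(truth$state, truth$barcode),
    stats::setNames(truth$compartment, truth$barcode))
  spn <- spanning_clones(cst)
  m <- span_frequency_matrix(cst)
  prog_bm <- if ("PC-progenitor" %in% rownames(m))
    sum(m["PC-progenitor", ]) else 0
  if (prog_bm > 0)
    stop("demo: expected zero progenitor-to-bone-marrow links, found ",
         prog_bm)
  export_chord_adjacency(cst, file.path(out_dir, "chord_adjacency.csv"))

  report <- list(
    seed = seed, n_cells = cfg$n_cells, n_clones = cfg$n_clones,
    clone_ari = ari, n_called_clones = nrow(ca$clones),
    np_precision = np_precision, np_recall = np_recall,
    n_np_cells = sum(labels == "NP"), n_klh_cells = sum(labels == "KLH"),
    shm_exact_fraction = shm_exact,
    affinity_fraction = aff$proportion[1L],
    state_accuracy = acc,
    n_spanning_clones = nrow(spn),
    progenitor_bm_links = prog_bm)
  jsonlite::write_json(report, file.path(out_dir, "demo_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}
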
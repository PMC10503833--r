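# Shared fixtures: small simulations reused across test files.

small_config <- function(...) {
  sim_config(n_cells = 300L, n_clones = 40L, n_genes = 400L,
             n_marker_genes_per_state = 8L, library_size_mean = 800,
             seed = 42L, ...)
}

# one small paired dataset, built once per test run
.fixture_env <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    cfg <- small_config()
    gl <- default_germline(cfg)
    sim <- simulate_repertoire(cfg, gl)
    paired <- suppressMessages(pair_cell_chains(sim$contigs))
    .fixture_env$sim <- list(cfg = cfg, germline = gl,
                             contigs = sim$contigs, truth = sim$truth,
                             paired = paired)
  }
  .fixture_env$sim
}

truth_lookup <- function(truth, col) {
  stats::setNames(truth[[col]], truth$barcode)
}

# minimal hand-built contig table for unit tests
tiny_contigs <- function() {
  data.frame(
    barcode = c("bc1", "bc1", "bc2", "bc2", "bc2", "bc3", "bc3", "bc3"),
    locus = c("IGH", "IGK", "IGH", "IGK", "IGK", "IGH", "IGH", "IGL"),
    v_call = c("IGHV1-72*01", "IGKV1-110*01", "IGHV1-72*01", "IGKV3-2*01",
               "IGKV1-110*01", "IGHV1-53*01", "IGHV9-3*01", "IGLV1*01"),
    d_call = c("IGHD1-1*01", "", "IGHD1-1*01", "", "", "IGHD2-4*01",
               "IGHD2-4*01", ""),
    j_call = c("IGHJ2*01", "IGKJ1*01", "IGHJ2*01", "IGKJ2*01", "IGKJ1*01",
               "IGHJ1*03", "IGHJ1*03", "IGLJ1*01"),
    cdr3_aa = c("CARWGGDYW", "CQQYNSYPW", "CARWGGDYW", "CLQYDNLPW",
                "CQQYNSYPW", "CTRDYYGW", "CARNNWDYW", "CALWYSNHW"),
    cdr3_nt = NA_character_,
    productive = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE),
    umi_count = c(5L, 4L, 6L, 3L, 2L, 7L, 2L, 3L),
    v_sequence_nt = NA_character_,
    germline_v_nt = NA_character_,
    stringsAsFactors = FALSE)
}

# exhaustive enumeration oracle for the two-sided rank-sum p-value
brute_wilcox <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  all_w <- apply(utils::combn(n, na), 2L,
                 function(idx) sum(r[idx]) - na * (na + 1) / 2)
  p <- 2 * min(mean(all_w <= w_obs), mean(all_w >= w_obs))
  list(statistic = w_obs, p_value = min(1, p))
}

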
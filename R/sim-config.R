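# Simulation configuration: the study conditions the generator emulates.

#' Default genomic-state proportions
#'
#' Nine genomic states spanning the B-cell-to-plasma-cell continuum: naive,
#' marginal-zone and activated B cells, light-zone and dark-zone germinal
#' center (GC) B cells, the plasma-cell (PC) progenitor, and the three PC
#' clusters distinguished by Tigit, Slpi and Lag3 expression.
#'
#' @return named numeric vector summing to 1.
#' @export
default_state_proportions <- function() {
  c("B-naive" = 0.06, "B-MZ" = 0.05, "B-activated" = 0.05,
    "GC-LZ" = 0.08, "GC-DZ" = 0.08, "PC-progenitor" = 0.18,
    "PC-Tigit" = 0.20, "PC-Slpi" = 0.16, "PC-Lag3" = 0.14)
}

#' Default IGHV usage weights for an NP-KLH response
#'
#' Sampling weights for clone heavy-chain V genes. The NP (hapten) response
#' is dominated by a Vh186.2-like gene (IGHV1-72) with IGHV1-53 and IGHV9-3
#' as recurrent secondary genes; a set of carrier (KLH)-reactive genes is
#' present at intermediate frequency; the remainder are rare bystanders.
#'
#' @return list with elements `usage` (named weights), `np_genes`,
#'   `klh_genes`.
#' @export
default_ighv_usage <- function() {
  usage <- c("IGHV1-72*01" = 30, "IGHV1-53*01" = 10, "IGHV9-3*01" = 6,
             "IGHV5-17*01" = 8, "IGHV1-82*01" = 6, "IGHV14-3*01" = 5,
             "IGHV6-6*01" = 4,
             "IGHV2-2*01" = 2, "IGHV3-6*01" = 2, "IGHV8-8*01" = 1.5,
             "IGHV10-1*01" = 1, "IGHV4-1*01" = 1)
  list(usage = usage,
       np_genes = c("IGHV1-72*01", "IGHV1-53*01", "IGHV9-3*01"),
       klh_genes = c("IGHV5-17*01", "IGHV1-82*01", "IGHV14-3*01",
                     "IGHV6-6*01"))
}

# Light-chain V/J pool (kappa and lambda); one row is a plausible VJ pair.
.light_pool <- function() {
  data.frame(
    locus = c(rep("IGK", 6), rep("IGL", 2)),
    v_call = c("IGKV1-110*01", "IGKV3-2*01", "IGKV4-57*01", "IGKV6-15*01",
               "IGKV8-30*01", "IGKV10-96*01", "IGLV1*01", "IGLV2*01"),
    j_call = c("IGKJ1*01", "IGKJ2*01", "IGKJ4*01", "IGKJ5*01", "IGKJ1*01",
               "IGKJ2*01", "IGLJ1*01", "IGLJ2*01"),
    stringsAsFactors = FALSE)
}

.heavy_d_pool <- function() c("IGHD1-1*01", "IGHD2-4*01", "IGHD3-2*02", "")
.heavy_j_pool <- function() c("IGHJ1*03", "IGHJ2*01", "IGHJ3*01", "IGHJ4*01")

#' Simulation configuration
#'
#' Assembles and validates the parameters of the paired repertoire +
#' expression simulation. Defaults encode the study conditions the package's
#' validation suite assumes: nine genomic states across spleen and bone
#' marrow, an IGHV1-72-dominated NP response, per-timepoint somatic
#' hypermutation, and a 0.4 per-clone probability of the designated
#' high-affinity substitution.
#'
#' @param n_cells,n_clones number of cells and clones (`n_clones <= n_cells`).
#' @param state_proportions named fractions over genomic states (sum 1).
#' @param compartment_proportions named fractions, `spleen` and `bone_marrow`
#'   (sum 1); the bone-marrow fraction applies to cells of clones eligible to
#'   seed the bone marrow (see `bm_states`).
#' @param ighv_usage named sampling weights for clone heavy V genes.
#' @param np_genes,klh_genes IGHV names deemed NP- / KLH-specific in truth.
#' @param timepoints,timepoint_proportions sample labels (days
#'   post-immunization) and per-cell sampling fractions.
#' @param mutation_rate_per_timepoint expected V-segment nucleotide
#'   substitutions per timepoint index (Poisson mean increment).
#' @param affinity_mutation_prob probability a clone's lineage acquires the
#'   designated high-affinity substitution.
#' @param n_genes,n_marker_genes_per_state,marker_fold,library_size_mean
#'   expression-model size, marker structure and depth; `marker_fold` > 1
#'   elevates a state's markers in that state.
#' @param dispersion negative-binomial size parameter; `count_model`
#'   chooses `"nb"` or `"poisson"`.
#' @param clone_size_exponent power-law exponent for clone-size weights.
#' @param pc_size_boost multiplicative size weight for clones whose primary
#'   state is a PC cluster (PC clones are larger than progenitor clones).
#' @param state_fidelity probability a spleen cell keeps its clone's
#'   primary state; clones are strongly state-coherent.
#' @param bm_states states whose clones may seed the bone marrow.
#' @param bm_seeding_prob probability that an eligible clone seeds the bone
#'   marrow; a scalar, or a named vector over `bm_states` to give states
#'   different seeding rates.
#' @param decoy_light_prob probability a cell carries a second,
#'   nonproductive light chain.
#' @param cdr3_length heavy CDR3 length in residues (anchored C...W).
#' @param seed integer seed; all generator output is a pure function of
#'   (config, germline, seed).
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 2000L, n_clones = 150L,
                       state_proportions = default_state_proportions(),
                       compartment_proportions = c(spleen = 0.7,
                                                   bone_marrow = 0.3),
                       ighv_usage = default_ighv_usage()$usage,
                       np_genes = default_ighv_usage()$np_genes,
                       klh_genes = default_ighv_usage()$klh_genes,
                       timepoints = c("21", "35"),
                       timepoint_proportions = c(0.5, 0.5),
                       mutation_rate_per_timepoint = 3,
                       affinity_mutation_prob = 0.4,
                       n_genes = 2000L, n_marker_genes_per_state = 20L,
                       marker_fold = 8, library_size_mean = 2000,
                       dispersion = 10, count_model = c("nb", "poisson"),
                       clone_size_exponent = 1, pc_size_boost = 3,
                       state_fidelity = 0.95,
                       bm_states = c("PC-Tigit", "PC-Slpi", "PC-Lag3"),
                       bm_seeding_prob = 1,
                       decoy_light_prob = 0.1, cdr3_length = 13L,
                       seed = 1L) {
  count_model <- match.arg(count_model)
  cfg <- list(n_cells = as.integer(n_cells), n_clones = as.integer(n_clones),
              state_proportions = state_proportions,
              compartment_proportions = compartment_proportions,
              ighv_usage = ighv_usage, np_genes = np_genes,
              klh_genes = klh_genes, timepoints = timepoints,
              timepoint_proportions = timepoint_proportions,
              mutation_rate_per_timepoint = mutation_rate_per_timepoint,
              affinity_mutation_prob = affinity_mutation_prob,
              n_genes = as.integer(n_genes),
              n_marker_genes_per_state = as.integer(n_marker_genes_per_state),
              marker_fold = marker_fold,
              library_size_mean = library_size_mean,
              dispersion = dispersion, count_model = count_model,
              clone_size_exponent = clone_size_exponent,
              pc_size_boost = pc_size_boost, state_fidelity = state_fidelity,
              bm_states = bm_states, bm_seeding_prob = bm_seeding_prob,
              decoy_light_prob = decoy_light_prob,
              cdr3_length = as.integer(cdr3_length), seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' @rdname sim_config
#' @param cfg configuration to validate.
#' @export
validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_cells < 1L || n_clones < 1L)
      stop("n_cells and n_clones must be positive")
    if (n_clones > n_cells)
      stop("configuration error: n_clones (", n_clones,
           ") exceeds n_cells (", n_cells, ")")
    if (length(state_proportions) == 0L)
      stop("configuration error: state_proportions is empty")
    if (length(compartment_proportions) == 0L)
      stop("configuration error: compartment_proportions is empty")
    if (abs(sum(state_proportions) - 1) > 1e-9)
      stop("state_proportions must sum to 1")
    if (abs(sum(compartment_proportions) - 1) > 1e-9)
      stop("compartment_proportions must sum to 1")
    if (is.null(names(state_proportions)) ||
        is.null(names(compartment_proportions)))
      stop("proportion vectors must be named")
    probs <- c(affinity_mutation_prob, timepoint_proportions,
               state_fidelity, decoy_light_prob, bm_seeding_prob)
    if (!is.null(names(bm_seeding_prob)) &&
        !all(names(bm_seeding_prob) %in% bm_states))
      stop("bm_seeding_prob names must be bm_states")
    if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
    if (mutation_rate_per_timepoint < 0)
      stop("mutation_rate_per_timepoint must be non-negative")
    if (length(ighv_usage) == 0L || any(ighv_usage <= 0))
      stop("ighv_usage must be a non-empty positive weight vector")
    if (n_marker_genes_per_state * length(state_proportions) > n_genes)
      stop("configuration error: marker genes exceed n_genes")
    if (marker_fold <= 0) stop("marker_fold must be positive")
  })
  invisible(cfg)
}

#' Germline references covering a configuration's IGHV genes
#'
#' @param cfg a `sim_config`.
#' @param ... passed to [germline_set()].
#' @return a `germline_set` with one record per gene in `cfg$ighv_usage`.
#' @export
default_germline <- function(cfg, ...) {
  germline_set(names(cfg$ighv_usage), seed = cfg$seed, ...)
}
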
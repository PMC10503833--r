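# Somatic hypermutation quantification and high-affinity substitution calls.

#' Count V-segment nucleotide mutations against germline
#'
#' Compares a gap-padded observed V sequence with its germline alignment.
#' Positions where either string carries a gap (`-` or `.`) or an ambiguous
#' base (`N`) are excluded from both numerator and denominator. The count is
#' symmetric in its two arguments.
#'
#' @param observed_nt,germline_nt equal-length aligned nucleotide strings.
#' @return list with `n_mutations`, `aligned_length` and
#'   `mutation_frequency` (= n_mutations / aligned_length).
#' @export
count_v_mutations <- function(observed_nt, germline_nt) {
  if (nchar(observed_nt) != nchar(germline_nt))
    stop("format error: aligned strings have unequal length")
  a <- strsplit(toupper(observed_nt), "")[[1L]]
  b <- strsplit(toupper(germline_nt), "")[[1L]]
  excluded <- a %in% c("-", ".", "N") | b %in% c("-", ".", "N")
  comp <- !excluded
  if (!any(comp)) stop("record error: zero comparable positions")
  n_mut <- sum(a[comp] != b[comp])
  len <- sum(comp)
  list(n_mutations = n_mut, aligned_length = len,
       mutation_frequency = n_mut / len)
}

#' Detect the designated high-affinity substitution
#'
#' Checks whether the observed amino-acid sequence carries the configured
#' substitution (e.g. W33L in IGHV1-72/Vh186.2: tryptophan 33 replaced by
#' leucine). Only the designated target residue counts; any other
#' replacement at the position returns `FALSE`. The germline must carry the
#' expected source residue at the position, otherwise the numbering is
#' mis-specified and a record error is raised.
#'
#' @param observed_aa,germline_aa amino-acid strings.
#' @param spec list with `position` (1-based), `from_aa`, `to_aa`.
#' @return logical scalar.
#' @export
detect_affinity_mutation <- function(observed_aa, germline_aa, spec) {
  stopifnot(all(c("position", "from_aa", "to_aa") %in% names(spec)),
            spec$from_aa != spec$to_aa)
  p <- spec$position
  if (nchar(observed_aa) < p || nchar(germline_aa) < p)
    stop("record error: sequence shorter than affinity position")
  if (substr(germline_aa, p, p) != spec$from_aa)
    stop("record error: germline residue at position ", p, " is '",
         substr(germline_aa, p, p), "', expected '", spec$from_aa, "'")
  substr(observed_aa, p, p) == spec$to_aa
}

#' Per-cell mutation profiles from paired cells and a germline set
#'
#' Convenience wrapper: for every paired cell carrying an aligned V sequence,
#' counts nucleotide mutations against its germline and calls the
#' high-affinity substitution from the translated observed V segment using
#' that gene's configured site.
#'
#' @param cells paired-cell table with `heavy_v_sequence_nt` and
#'   `heavy_germline_v_nt` (as produced by the generator or read from AIRR
#'   `sequence_alignment`/`germline_alignment` columns).
#' @param germline a [germline_set()] (used for affinity-site annotation).
#' @return data.frame (barcode, v_gene, n_mutations, aligned_length,
#'   mutation_frequency, has_affinity_mutation); cells without alignments
#'   are omitted.
#' @export
mutation_profiles <- function(cells, germline) {
  ok <- !is.na(cells$heavy_v_sequence_nt) & !is.na(cells$heavy_germline_v_nt)
  cells <- cells[ok, , drop = FALSE]
  if (nrow(cells) == 0L)
    return(data.frame(barcode = character(), v_gene = character(),
                      n_mutations = integer(), aligned_length = integer(),
                      mutation_frequency = numeric(),
                      has_affinity_mutation = logical()))
  gi <- match(cells$heavy_v, germline$gene)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    m <- count_v_mutations(cells$heavy_v_sequence_nt[i],
                           cells$heavy_germline_v_nt[i])
    aff <- NA
    if (!is.na(gi[i])) {
      obs_aa <- .translate_nt(cells$heavy_v_sequence_nt[i])
      aff <- detect_affinity_mutation(
        obs_aa, germline$aa[gi[i]],
        list(position = germline$affinity_position[gi[i]],
             from_aa = germline$affinity_from[gi[i]],
             to_aa = germline$affinity_to[gi[i]]))
    }
    data.frame(barcode = cells$barcode[i], v_gene = cells$heavy_v[i],
               n_mutations = m$n_mutations,
               aligned_length = m$aligned_length,
               mutation_frequency = m$mutation_frequency,
               has_affinity_mutation = aff, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Compare mutation-frequency distributions between two groups
#'
#' Two-sided Wilcoxon rank-sum test: exact when the combined sample size is
#' at most 20 and there are no ties, normal approximation with continuity
#' correction otherwise.
#'
#' @param group_a,group_b numeric vectors of mutation frequencies.
#' @return list with `statistic` (rank-sum W for group_a) and `p_value`.
#' @export
compare_mutation_distributions <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("parameter error: empty group")
  exact <- (length(group_a) + length(group_b)) <= 20L &&
    !anyDuplicated(c(group_a, group_b))
  wt <- stats::wilcox.test(group_a, group_b, alternative = "two.sided",
                           exact = exact, correct = TRUE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Per-group proportion of sequences with the high-affinity substitution
#'
#' @param profiles data.frame from [mutation_profiles()].
#' @param group factor/character vector aligned to `profiles` rows (e.g.
#'   timepoint); profiles should be restricted to the V gene of interest
#'   beforehand.
#' @return data.frame (group, n_affinity, n_total, proportion); empty groups
#'   are reported with `NA` proportion, never 0.
#' @export
affinity_maturation_proportions <- function(profiles, group) {
  stopifnot(length(group) == nrow(profiles))
  levs <- unique(group)
  out <- do.call(rbind, lapply(levs, function(g) {
    sel <- group == g & !is.na(profiles$has_affinity_mutation)
    n <- sum(sel)
    data.frame(group = g, n_affinity = sum(profiles$has_affinity_mutation[sel]),
               n_total = n,
               proportion = if (n > 0L)
                 sum(profiles$has_affinity_mutation[sel]) / n else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
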
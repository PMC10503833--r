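# Germline V-segment references: synthetic construction, FASTA I/O, validation.

# All 61 sense codons grouped by encoded residue, from the standard code.
.codons_by_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  gc <- gc[gc != "*"]
  split(names(gc), unname(gc))
}

.translate_nt <- function(nt) {
  as.character(Biostrings::translate(Biostrings::DNAStringSet(nt),
                                     no.init.codon = TRUE))
}

#' Construct a germline V-segment reference set
#'
#' Builds a table of germline heavy-chain V segments, one per gene name, each
#' carrying a designated high-affinity substitution site: a 1-based residue
#' position whose germline amino acid (`affinity_from`) can mutate to a
#' higher-affinity residue (`affinity_to`). This mirrors the canonical W33L
#' substitution of the NP-specific Vh186.2 (IGHV1-72) heavy chain, where a
#' tryptophan-to-leucine change at residue 33 confers a ~10-fold affinity
#' increase for the NP hapten.
#'
#' @param gene_names character vector of V gene names with allele suffix,
#'   e.g. `"IGHV1-72*01"`.
#' @param nt,aa optional explicit sequences (recycled checks apply); when
#'   `NULL`, random in-frame sequences of `n_codons` codons are generated
#'   with `affinity_from` planted at `affinity_position`.
#' @param n_codons V-segment length in codons for generated sequences.
#' @param affinity_position 1-based residue index of the affinity site.
#' @param affinity_from,affinity_to single amino-acid letters; the germline
#'   must carry `affinity_from` at the site.
#' @param seed integer seed for generated sequences.
#' @return A `data.frame` of class `germline_set` with columns `gene`, `nt`,
#'   `aa`, `affinity_position`, `affinity_from`, `affinity_to`.
#' @export
germline_set <- function(gene_names, nt = NULL, aa = NULL, n_codons = 98L,
                         affinity_position = 33L, affinity_from = "W",
                         affinity_to = "L", seed = 1L) {
  stopifnot(length(gene_names) >= 1L, !anyDuplicated(gene_names),
            affinity_position >= 1L, affinity_position <= n_codons,
            affinity_from != affinity_to)
  if (is.null(nt)) {
    set.seed(seed)
    cba <- .codons_by_aa()
    aas <- names(cba)
    nt <- vapply(gene_names, function(g) {
      res <- sample(aas, n_codons, replace = TRUE)
      res[affinity_position] <- affinity_from
      paste(vapply(res, function(a) sample(cba[[a]], 1L), ""), collapse = "")
    }, "")
    aa <- .translate_nt(nt)
  } else if (is.null(aa)) {
    aa <- .translate_nt(nt)
  }
  gs <- data.frame(gene = gene_names, nt = unname(nt), aa = unname(aa),
                   affinity_position = as.integer(affinity_position),
                   affinity_from = affinity_from, affinity_to = affinity_to,
                   stringsAsFactors = FALSE)
  validate_germline_set(gs)
  class(gs) <- c("germline_set", "data.frame")
  gs
}

#' @rdname germline_set
#' @param gs object to validate.
#' @export
validate_germline_set <- function(gs) {
  stopifnot(is.data.frame(gs),
            all(c("gene", "nt", "aa", "affinity_position", "affinity_from",
                  "affinity_to") %in% names(gs)))
  if (any(nchar(gs$nt) %% 3L != 0L))
    stop("germline nt length must be divisible by 3")
  tr <- .translate_nt(gs$nt)
  if (!all(tr == gs$aa))
    stop("germline aa is not the translation of nt")
  at <- substr(gs$aa, gs$affinity_position, gs$affinity_position)
  if (!all(at == gs$affinity_from))
    stop("germline residue at affinity_position does not match affinity_from")
  invisible(gs)
}

#' Write / read germline references as FASTA
#'
#' `write_germline_fasta()` emits two FASTA files (nucleotide and amino acid);
#' headers are `gene|pos=<i>|from=<X>|to=<Y>` so the affinity-site annotation
#' round-trips. `read_germline_fasta()` reconstructs the `germline_set`.
#'
#' @param gs a `germline_set`.
#' @param nt_path,aa_path output/input FASTA paths.
#' @return `write_germline_fasta()` returns the two paths invisibly;
#'   `read_germline_fasta()` returns a `germline_set`.
#' @export
write_germline_fasta <- function(gs, nt_path, aa_path) {
  hdr <- sprintf("%s|pos=%d|from=%s|to=%s", gs$gene, gs$affinity_position,
                 gs$affinity_from, gs$affinity_to)
  nt <- Biostrings::DNAStringSet(gs$nt); names(nt) <- hdr
  aa <- Biostrings::AAStringSet(gs$aa);  names(aa) <- hdr
  Biostrings::writeXStringSet(nt, nt_path)
  Biostrings::writeXStringSet(aa, aa_path)
  invisible(c(nt = nt_path, aa = aa_path))
}

#' @rdname write_germline_fasta
#' @export
read_germline_fasta <- function(nt_path, aa_path) {
  nt <- Biostrings::readDNAStringSet(nt_path)
  aa <- Biostrings::readAAStringSet(aa_path)
  parse_hdr <- function(h) {
    parts <- strsplit(h, "|", fixed = TRUE)[[1L]]
    kv <- strsplit(parts[-1L], "=", fixed = TRUE)
    out <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
    c(gene = parts[1L], out)
  }
  if (!identical(names(nt), names(aa)))
    stop("nt and aa FASTA records disagree in names or order")
  meta <- do.call(rbind, lapply(names(nt), parse_hdr))
  gs <- data.frame(gene = meta[, "gene"], nt = as.character(nt),
                   aa = as.character(aa),
                   affinity_position = as.integer(meta[, "pos"]),
                   affinity_from = meta[, "from"], affinity_to = meta[, "to"],
                   stringsAsFactors = FALSE)
  rownames(gs) <- NULL
  validate_germline_set(gs)
  class(gs) <- c("germline_set", "data.frame")
  gs
}
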
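# Repertoire and expression I/O plus heavy/light chain resolution per barcode.

.CONTIG_COLS <- c("barcode", "locus", "v_call", "d_call", "j_call", "cdr3_aa",
                  "cdr3_nt", "productive", "umi_count", "v_sequence_nt",
                  "germline_v_nt")

.IG_LOCI <- c("IGH", "IGK", "IGL")

#' Write contig tables in 10x or AIRR dialect
#'
#' @param contigs canonical contig data.frame (see [read_contigs()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_contigs_tenx <- function(contigs, path) {
  out <- data.frame(
    barcode = contigs$barcode, is_cell = "True", high_confidence = "True",
    chain = contigs$locus, v_gene = contigs$v_call, d_gene = contigs$d_call,
    j_gene = contigs$j_call, cdr3 = contigs$cdr3_aa,
    cdr3_nt = contigs$cdr3_nt,
    productive = ifelse(contigs$productive, "True", "False"),
    umis = contigs$umi_count, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_contigs_tenx
#' @export
write_contigs_airr <- function(contigs, path) {
  out <- data.frame(
    cell_id = contigs$barcode, locus = contigs$locus,
    v_call = contigs$v_call, d_call = contigs$d_call,
    j_call = contigs$j_call, junction_aa = contigs$cdr3_aa,
    junction = contigs$cdr3_nt,
    productive = ifelse(contigs$productive, "T", "F"),
    duplicate_count = contigs$umi_count,
    sequence_alignment = ifelse(is.na(contigs$v_sequence_nt), "",
                                contigs$v_sequence_nt),
    germline_alignment = ifelse(is.na(contigs$germline_v_nt), "",
                                contigs$germline_v_nt),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.parse_logical <- function(x) {
  tolower(trimws(as.character(x))) %in% c("true", "t", "1")
}

#' Read immunoglobulin contig annotations
#'
#' Parses single-cell V(D)J contig tables in either the 10x
#' `filtered_contig_annotations.csv` dialect or the AIRR Rearrangement TSV
#' schema into a canonical contig table. Rows whose locus is not IGH/IGK/IGL
#' (e.g. TR chains), or flagged not-a-cell / low-confidence when those
#' columns exist, are dropped; drop counts are reported via a message and the
#' `"skipped"` attribute.
#'
#' @param path input file.
#' @param dialect `"tenx_csv"` or `"airr_tsv"`.
#' @return data.frame with columns `barcode, locus, v_call, d_call, j_call,
#'   cdr3_aa, cdr3_nt, productive, umi_count, v_sequence_nt, germline_v_nt`;
#'   attribute `skipped` holds named drop counts.
#' @export
read_contigs <- function(path, dialect = c("tenx_csv", "airr_tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  skipped <- c(not_cell = 0L, low_confidence = 0L, unknown_locus = 0L)

  if (dialect == "tenx_csv") {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character")
    req <- c("barcode", "chain", "v_gene", "d_gene", "j_gene", "cdr3",
             "productive", "umis")
    miss <- setdiff(req, names(raw))
    if (length(miss))
      stop("format error: missing required column(s): ",
           paste(miss, collapse = ", "))
    if (nrow(raw) && "is_cell" %in% names(raw)) {
      bad <- !.parse_logical(raw$is_cell)
      skipped["not_cell"] <- sum(bad)
      raw <- raw[!bad, , drop = FALSE]
    }
    if (nrow(raw) && "high_confidence" %in% names(raw)) {
      bad <- !.parse_logical(raw$high_confidence)
      skipped["low_confidence"] <- sum(bad)
      raw <- raw[!bad, , drop = FALSE]
    }
    out <- data.frame(
      barcode = raw$barcode, locus = raw$chain, v_call = raw$v_gene,
      d_call = raw$d_gene, j_call = raw$j_gene, cdr3_aa = raw$cdr3,
      cdr3_nt = if ("cdr3_nt" %in% names(raw)) raw$cdr3_nt else
        rep(NA_character_, nrow(raw)),
      productive = .parse_logical(raw$productive),
      umi_count = as.integer(raw$umis),
      v_sequence_nt = if ("sequence_alignment" %in% names(raw))
        raw$sequence_alignment else rep(NA_character_, nrow(raw)),
      germline_v_nt = if ("germline_alignment" %in% names(raw))
        raw$germline_alignment else rep(NA_character_, nrow(raw)),
      stringsAsFactors = FALSE)
  } else {
    raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
    req <- c("cell_id", "locus", "v_call", "d_call", "j_call", "junction_aa",
             "productive")
    miss <- setdiff(req, names(raw))
    if (length(miss))
      stop("format error: missing required column(s): ",
           paste(miss, collapse = ", "))
    out <- data.frame(
      barcode = raw$cell_id, locus = raw$locus, v_call = raw$v_call,
      d_call = raw$d_call, j_call = raw$j_call, cdr3_aa = raw$junction_aa,
      cdr3_nt = if ("junction" %in% names(raw)) raw$junction else
        rep(NA_character_, nrow(raw)),
      productive = .parse_logical(raw$productive),
      umi_count = if ("duplicate_count" %in% names(raw))
        as.integer(raw$duplicate_count) else rep(NA_integer_, nrow(raw)),
      v_sequence_nt = if ("sequence_alignment" %in% names(raw))
        raw$sequence_alignment else rep(NA_character_, nrow(raw)),
      germline_v_nt = if ("germline_alignment" %in% names(raw))
        raw$germline_alignment else rep(NA_character_, nrow(raw)),
      stringsAsFactors = FALSE)
  }
  bad <- !(out$locus %in% .IG_LOCI)
  skipped["unknown_locus"] <- sum(bad)
  out <- out[!bad, , drop = FALSE]
  if (nrow(out)) {
    out$v_sequence_nt[!is.na(out$v_sequence_nt) &
                        out$v_sequence_nt == ""] <- NA_character_
    out$germline_v_nt[!is.na(out$germline_v_nt) &
                        out$germline_v_nt == ""] <- NA_character_
  }
  rownames(out) <- NULL
  if (sum(skipped) > 0L)
    message("read_contigs: skipped ", sum(skipped), " row(s) [",
            paste(names(skipped), skipped, sep = "=", collapse = ", "), "]")
  attr(out, "skipped") <- skipped
  out
}

#' Resolve each barcode into a single heavy/light chain pair
#'
#' Cells with exactly one IGH contig and one light contig pair uniquely.
#' Among multiple light chains the productively rearranged one is used; if
#' several are productive the highest-UMI chain wins, ties broken
#' lexicographically by `v_call`. Barcodes with multiple IGH contigs are
#' dropped under `heavy_policy = "drop"` (default, conservative doublet
#' handling) or resolved to the highest-UMI heavy under `"max_umi"`.
#' Barcodes lacking a heavy or a light chain are excluded; all exclusion
#' counts are returned in the `"exclusions"` attribute.
#'
#' @param contigs contig table from [read_contigs()].
#' @param heavy_policy `"drop"` or `"max_umi"`.
#' @return data.frame of paired cells, one row per retained barcode, with
#'   `heavy_*` and `light_*` columns and a `resolution_note` in
#'   `unique`, `productive_selected`, `umi_selected`.
#' @export
pair_cell_chains <- function(contigs, heavy_policy = c("drop", "max_umi")) {
  heavy_policy <- match.arg(heavy_policy)
  excl <- c(no_heavy = 0L, no_light = 0L, multi_heavy_dropped = 0L)
  if (nrow(contigs) == 0L) {
    out <- data.frame()
    attr(out, "exclusions") <- excl
    return(out)
  }
  pick_by_umi <- function(df) {
    df <- df[order(-df$umi_count, df$v_call, df$cdr3_aa), , drop = FALSE]
    df[1L, , drop = FALSE]
  }
  rows <- lapply(split(contigs, contigs$barcode), function(cc) {
    hv <- cc[cc$locus == "IGH", , drop = FALSE]
    lt <- cc[cc$locus %in% c("IGK", "IGL"), , drop = FALSE]
    if (nrow(hv) == 0L) return("no_heavy")
    if (nrow(lt) == 0L) return("no_light")
    note <- "unique"
    if (nrow(hv) > 1L) {
      if (heavy_policy == "drop") return("multi_heavy_dropped")
      hv <- pick_by_umi(hv)
      note <- "umi_selected"
    }
    if (nrow(lt) > 1L) {
      prod <- lt[lt$productive, , drop = FALSE]
      if (nrow(prod) == 1L) {
        lt <- prod
        note <- "productive_selected"
      } else {
        if (nrow(prod) > 1L) lt <- prod
        lt <- pick_by_umi(lt)
        note <- "umi_selected"
      }
    }
    data.frame(
      barcode = hv$barcode, heavy_v = hv$v_call, heavy_d = hv$d_call,
      heavy_j = hv$j_call, heavy_cdr3_aa = hv$cdr3_aa,
      heavy_cdr3_nt = hv$cdr3_nt, heavy_umi = hv$umi_count,
      heavy_v_sequence_nt = hv$v_sequence_nt,
      heavy_germline_v_nt = hv$germline_v_nt,
      light_locus = lt$locus, light_v = lt$v_call, light_j = lt$j_call,
      light_cdr3_aa = lt$cdr3_aa, light_umi = lt$umi_count,
      resolution_note = note, stringsAsFactors = FALSE)
  })
  reasons <- vapply(rows, function(r) if (is.character(r)) r else "", "")
  for (rn in names(excl)) excl[rn] <- sum(reasons == rn)
  kept <- rows[reasons == ""]
  out <- if (length(kept)) do.call(rbind, kept) else data.frame()
  if (nrow(out)) {
    out <- out[order(out$barcode), , drop = FALSE]
    rownames(out) <- NULL
  }
  if (sum(excl) > 0L)
    message("pair_cell_chains: excluded ", sum(excl), " barcode(s) [",
            paste(names(excl), excl, sep = "=", collapse = ", "), "]")
  attr(out, "exclusions") <- excl
  out
}

#' Read a cell-by-gene count matrix
#'
#' @param path for `"mtx_dir"`, a directory holding `matrix.mtx`,
#'   `barcodes.tsv` and `features.tsv`; for `"dense_tsv"`, a TSV with gene
#'   rows (first column = gene name) and barcode columns.
#' @param format input layout.
#' @return sparse `dgCMatrix`, genes x cells, with dimnames.
#' @export
read_expression <- function(path, format = c("mtx_dir", "dense_tsv")) {
  format <- match.arg(format)
  if (format == "mtx_dir") {
    mf <- file.path(path, "matrix.mtx")
    bf <- file.path(path, "barcodes.tsv")
    ff <- file.path(path, "features.tsv")
    for (f in c(mf, bf, ff))
      if (!file.exists(f)) stop("file not found: ", f)
    m <- methods::as(Matrix::readMM(mf), "CsparseMatrix")
    bc <- readLines(bf)
    ft <- readLines(ff)
    if (nrow(m) != length(ft) || ncol(m) != length(bc))
      stop("format error: matrix dimensions (", nrow(m), " x ", ncol(m),
           ") do not match features (", length(ft), ") / barcodes (",
           length(bc), ")")
    if (anyDuplicated(bc))
      stop("format error: duplicate barcode in barcodes file")
    if (anyDuplicated(ft))
      stop("format error: duplicate feature in features file")
    dimnames(m) <- list(ft, bc)
  } else {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            check.names = FALSE)
    if (anyDuplicated(df[[1L]]))
      stop("format error: duplicate gene name in dense TSV")
    m <- Matrix::Matrix(as.matrix(df[, -1L, drop = FALSE]), sparse = TRUE)
    m <- methods::as(m, "CsparseMatrix")
    rownames(m) <- df[[1L]]
    if (anyDuplicated(colnames(m)))
      stop("format error: duplicate barcode in dense TSV")
  }
  if (any(m@x < 0)) stop("format error: negative counts")
  zero_cols <- sum(Matrix::colSums(m) == 0)
  if (zero_cols > 0L)
    message("read_expression: ", zero_cols, " all-zero column(s)")
  m
}

#' Library-size normalize and log2-transform counts
#'
#' Scales each cell to `target` total counts (default: median library size)
#' and returns `log2(1 + scaled)`. Sparsity is preserved.
#'
#' @param counts sparse or dense gene x cell matrix.
#' @param target normalization target; default median column sum.
#' @return `dgCMatrix` of log2-scaled values.
#' @export
lognorm <- function(counts, target = NULL) {
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE),
                        "CsparseMatrix")
  libs <- Matrix::colSums(counts)
  if (is.null(target)) target <- stats::median(libs[libs > 0])
  sf <- ifelse(libs > 0, target / libs, 0)
  out <- counts %*% Matrix::Diagonal(x = sf)
  out <- methods::as(out, "CsparseMatrix")
  out@x <- log2(1 + out@x)
  dimnames(out) <- dimnames(counts)
  out
}
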
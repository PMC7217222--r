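#' Read a gene annotation from GFF3 or BED
#'
#' GFF3 records of type "gene" (or all records when none are typed) are
#' read via \pkg{rtracklayer}; BED input is detected by extension and its
#' 0-based half-open coordinates are converted. Genes are returned with
#' 1-based inclusive coordinates; downstream window overlap treats window
#' intervals as half-open `[start, end)`.
#'
#' @param path GFF3 (`.gff`, `.gff3`) or BED (`.bed`) file
#' @return data.frame: `gene_id`, `symbol`, `chrom`, `start`, `end`,
#'   `strand`
#' @export
read_gene_annotation <- function(path) {
  ext <- tolower(tools::file_ext(path))
  gr <- if (ext == "bed") rtracklayer::import(path, format = "bed") else
    rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  if ("type" %in% names(df) && any(df$type == "gene"))
    df <- df[df$type == "gene", , drop = FALSE]
  id <- if (!is.null(df$ID)) df$ID else if (!is.null(df$gene_id))
    df$gene_id else if (!is.null(df$name)) df$name else
      paste0("gene", seq_len(nrow(df)))
  sym <- if (!is.null(df$Name)) df$Name else if (!is.null(df$name))
    df$name else id
  out <- data.frame(gene_id = as.character(id), symbol = as.character(sym),
                    chrom = as.character(df$seqnames),
                    start = df$start, end = df$end,
                    strand = as.character(df$strand),
                    stringsAsFactors = FALSE)
  if (any(out$start > out$end)) stop("malformed annotation: start > end")
  out
}

#' Genes overlapping candidate windows
#'
#' Windows are treated as half-open `[start_bp, end_bp)`; genes are
#' 1-based inclusive intervals. A gene is reported for a window when the
#' two intervals share at least one bp; strand is ignored. A gene whose
#' start coincides with the window's `end_bp` is therefore excluded.
#'
#' @param windows data.frame with `chrom`, `start_bp`, `end_bp` (e.g.
#'   from [candidate_windows()])
#' @param annotation data.frame from [read_gene_annotation()]
#' @param dedup drop genes already reported for an earlier window
#' @return data.frame: one row per (window, gene) overlap with the
#'   window's coordinates and the gene's `gene_id`, `symbol`, `start`,
#'   `end`
#' @export
genes_in_windows <- function(windows, annotation, dedup = FALSE) {
  stopifnot(all(c("chrom", "start_bp", "end_bp") %in% names(windows)))
  unmatched <- setdiff(unique(as.character(windows$chrom)),
                       unique(as.character(annotation$chrom)))
  if (length(unmatched))
    stop("window chromosomes absent from the annotation: ",
         paste(unmatched, collapse = ", "))
  win_gr <- GenomicRanges::GRanges(
    as.character(windows$chrom),
    IRanges::IRanges(start = windows$start_bp,
                     end = pmax(windows$start_bp, windows$end_bp - 1)))
  gene_gr <- GenomicRanges::GRanges(
    as.character(annotation$chrom),
    IRanges::IRanges(start = annotation$start, end = annotation$end))
  hits <- GenomicRanges::findOverlaps(win_gr, gene_gr)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  out <- cbind(windows[qi, c("chrom", "start_bp", "end_bp"), drop = FALSE],
               annotation[si, c("gene_id", "symbol", "start", "end"),
                          drop = FALSE])
  rownames(out) <- NULL
  if (dedup) out <- out[!duplicated(out$gene_id), , drop = FALSE]
  out
}

#' Read gene sets from a GMT file
#'
#' One set per line: term id, description, then member genes, tab
#' separated.
#'
#' @param path GMT file
#' @return named list of character vectors (names = term ids)
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' Hypergeometric gene-set enrichment with BH adjustment
#'
#' For each term, the one-sided upper-tail hypergeometric probability of
#' drawing at least the observed overlap when sampling the candidate list
#' from the background universe. P-values are BH-adjusted across all
#' tested terms; by convention only terms with at least `min_overlap`
#' candidate genes are reported.
#'
#' @param candidate_genes character vector of candidate gene ids (must be
#'   a subset of `background`)
#' @param gene_sets named list of character vectors (e.g. [read_gmt()])
#' @param background character vector: the gene universe
#' @param min_overlap minimum candidate genes in a term for it to be
#'   reported (default 4)
#' @return data.frame: `term`, `term_size`, `overlap`, `overlap_genes`
#'   (comma separated), `p_value`, `p_adjusted`, sorted by `p_value`
#' @export
enrichment <- function(candidate_genes, gene_sets, background,
                       min_overlap = 4L) {
  background <- unique(background)
  if (length(background) == 0) stop("empty background gene universe")
  candidate_genes <- unique(candidate_genes)
  if (!all(candidate_genes %in% background))
    stop("candidate genes outside the background universe: ",
         paste(utils::head(setdiff(candidate_genes, background), 5),
               collapse = ", "))
  N <- length(background)
  n <- length(candidate_genes)
  rows <- lapply(names(gene_sets), function(term) {
    set <- intersect(unique(gene_sets[[term]]), background)
    K <- length(set)
    ov <- intersect(candidate_genes, set)
    k <- length(ov)
    p <- if (K == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, term_size = K, overlap = k,
               overlap_genes = paste(sort(ov), collapse = ","),
               p_value = min(p, 1), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[res$overlap >= min_overlap, , drop = FALSE]
  res <- res[order(res$p_value), , drop = FALSE]
  rownames(res) <- NULL
  res
}
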
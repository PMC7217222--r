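#' Pairwise linkage disequilibrium (r^2) within a sliding bp window
#'
#' r^2 is the squared Pearson correlation of dosage vectors (genotypic
#' LD; no phasing required), computed for every pair of markers on the
#' same chromosome whose distance is at most `window_bp`. Monomorphic
#' markers cannot be correlated and their pairs are skipped.
#'
#' @param genotypes a `genotype_set`
#' @param chrom restrict to one chromosome (default: all)
#' @param from_bp,to_bp restrict to a bp interval on `chrom`
#' @param window_bp maximum pair distance (default 200000)
#' @return an `ld_result`: list with `pairs` (data.frame `snp_i`,
#'   `snp_j`, `chrom`, `distance_bp`, `r2`), `map` (markers considered)
#'   and `n_monomorphic_skipped`
#' @export
pairwise_r2 <- function(genotypes, chrom = NULL, from_bp = NULL,
                        to_bp = NULL, window_bp = 200000) {
  map <- genotypes$map
  keep <- rep(TRUE, nrow(map))
  if (!is.null(chrom)) keep <- keep & map$chrom %in% chrom
  if (!is.null(from_bp)) keep <- keep & map$bp >= from_bp
  if (!is.null(to_bp)) keep <- keep & map$bp <= to_bp
  if (!any(keep)) stop("region contains no markers")
  map <- map[keep, , drop = FALSE]
  M <- genotypes$dosage[, keep, drop = FALSE]
  v <- apply(M, 2, stats::var)
  mono <- v == 0
  pairs <- list()
  ord <- order(map$chrom, map$bp)
  map <- map[ord, , drop = FALSE]
  M <- M[, ord, drop = FALSE]
  mono <- mono[ord]
  m <- nrow(map)
  for (i in seq_len(m - 1)) {
    if (mono[i]) next
    j <- i + 1L
    js <- integer(0)
    while (j <= m && map$chrom[j] == map$chrom[i] &&
           map$bp[j] - map$bp[i] <= window_bp) {
      if (!mono[j]) js <- c(js, j)
      j <- j + 1L
    }
    if (length(js) == 0) next
    r <- drop(stats::cor(M[, i], M[, js, drop = FALSE]))
    pairs[[length(pairs) + 1L]] <-
      data.frame(snp_i = map$snp[i], snp_j = map$snp[js],
                 chrom = map$chrom[i],
                 distance_bp = map$bp[js] - map$bp[i], r2 = r^2)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(snp_i = integer(), snp_j = integer(), chrom = integer(),
               distance_bp = integer(), r2 = numeric())
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, map = map,
                 n_monomorphic_skipped = sum(mono)),
            class = "ld_result")
}

#' Call LD blocks as threshold runs of adjacent-pair r^2
#'
#' A block is a maximal run of physically consecutive markers in which
#' every adjacent pair has r^2 >= `r2_threshold`; runs of at least two
#' markers are reported. (Confidence-interval block definitions need
#' phased haplotypes, which this pipeline does not produce.)
#'
#' @param ld an `ld_result` from [pairwise_r2()]
#' @param r2_threshold adjacent-pair r^2 cutoff (default 0.7)
#' @return data.frame: `block`, `chrom`, `snp_from`, `snp_to`, `n_snp`,
#'   `start_bp`, `end_bp`, `span_bp`, `min_adjacent_r2`, `mean_r2`
#' @export
find_blocks <- function(ld, r2_threshold = 0.7) {
  map <- ld$map
  m <- nrow(map)
  # adjacent-pair r2 in map order (NA where skipped/monomorphic)
  adj <- rep(NA_real_, max(m - 1, 0))
  if (m >= 2) {
    key_i <- map$snp[-m]
    key_j <- map$snp[-1]
    same_chr <- map$chrom[-m] == map$chrom[-1]
    idx <- match(paste(key_i, key_j), paste(ld$pairs$snp_i, ld$pairs$snp_j))
    adj <- ifelse(same_chr, ld$pairs$r2[idx], NA_real_)
  }
  good <- !is.na(adj) & adj >= r2_threshold
  blocks <- list()
  i <- 1L
  while (i <= length(good)) {
    if (good[i]) {
      j <- i
      while (j < length(good) && good[j + 1L]) j <- j + 1L
      sel <- i:(j + 1L)           # marker positions in the run
      r2s <- adj[i:j]
      blocks[[length(blocks) + 1L]] <-
        data.frame(chrom = map$chrom[sel[1]],
                   snp_from = map$snp[sel[1]],
                   snp_to = map$snp[sel[length(sel)]],
                   n_snp = length(sel),
                   start_bp = map$bp[sel[1]],
                   end_bp = map$bp[sel[length(sel)]],
                   span_bp = map$bp[sel[length(sel)]] - map$bp[sel[1]],
                   min_adjacent_r2 = min(r2s), mean_r2 = mean(r2s))
      i <- j + 2L
    } else i <- i + 1L
  }
  out <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(chrom = integer(), snp_from = integer(), snp_to = integer(),
               n_snp = integer(), start_bp = integer(), end_bp = integer(),
               span_bp = integer(), min_adjacent_r2 = numeric(),
               mean_r2 = numeric())
  if (nrow(out)) out <- cbind(block = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}
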
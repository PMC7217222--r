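#' Read and write the pipeline's delimited tables
#'
#' Plain-text interchange: pedigree CSV (`animal,sire,dam`), test-day CSV
#' (`animal,parity,dim,milk_kg`), a TSV dosage matrix with its marker
#' map, and PLINK-style `.ped`/`.map` text genotypes (alleles coded 1/2).
#' All writers round-trip through the matching readers.
#'
#' @param ped,records,genotypes objects to write
#' @param path,prefix file path (or path prefix for PLINK pairs)
#' @name lactgwas-io
NULL

#' @rdname lactgwas-io
#' @export
write_pedigree <- function(ped, path) {
  utils::write.csv(ped[, c("animal", "sire", "dam")], path,
                   row.names = FALSE, quote = FALSE)
}

#' @rdname lactgwas-io
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.csv(path)
  stopifnot(all(c("animal", "sire", "dam") %in% names(ped)))
  .check_ordered_pedigree(ped)
  ped
}

#' @rdname lactgwas-io
#' @export
write_testday <- function(records, path) {
  utils::write.csv(records[, c("animal", "parity", "dim", "milk_kg")],
                   path, row.names = FALSE, quote = FALSE)
}

#' @rdname lactgwas-io
#' @export
read_testday <- function(path) {
  rec <- utils::read.csv(path)
  stopifnot(all(c("animal", "parity", "dim", "milk_kg") %in% names(rec)))
  rec
}

#' @rdname lactgwas-io
#' @export
write_dosage <- function(genotypes, prefix) {
  m <- cbind(animal = rownames(genotypes$dosage),
             as.data.frame(genotypes$dosage))
  utils::write.table(m, paste0(prefix, "_dosage.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(genotypes$map, paste0(prefix, "_map.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
}

#' @rdname lactgwas-io
#' @export
read_dosage <- function(prefix) {
  m <- utils::read.delim(paste0(prefix, "_dosage.tsv"),
                         check.names = FALSE)
  map <- utils::read.delim(paste0(prefix, "_map.tsv"))
  dosage <- as.matrix(m[, -1, drop = FALSE])
  storage.mode(dosage) <- "integer"
  rownames(dosage) <- as.character(m$animal)
  structure(list(dosage = dosage, map = map,
                 allele_freq = colMeans(dosage) / 2,
                 founder_freq = rep(NA_real_, ncol(dosage))),
            class = "genotype_set")
}

#' @rdname lactgwas-io
#' @export
write_plink <- function(genotypes, prefix) {
  M <- genotypes$dosage
  al <- matrix("1 1", nrow(M), ncol(M))
  al[M == 1] <- "1 2"
  al[M == 2] <- "2 2"
  ped_lines <- paste(rownames(M), rownames(M), 0, 0, 0, -9,
                     apply(al, 1, paste, collapse = " "))
  writeLines(ped_lines, paste0(prefix, ".ped"))
  map <- genotypes$map
  writeLines(paste(map$chrom, paste0("snp", map$snp), 0, map$bp,
                   sep = "\t"), paste0(prefix, ".map"))
}

#' @rdname lactgwas-io
#' @export
read_plink <- function(prefix) {
  map_raw <- utils::read.delim(paste0(prefix, ".map"), header = FALSE)
  map <- data.frame(snp = seq_len(nrow(map_raw)), chrom = map_raw[[1]],
                    bp = map_raw[[4]])
  lines <- readLines(paste0(prefix, ".ped"))
  parts <- strsplit(lines, "[ \t]+")
  m <- nrow(map)
  dosage <- t(vapply(parts, function(f) {
    a <- as.integer(f[-(1:6)])
    a[seq(1, 2 * m, 2)] + a[seq(2, 2 * m, 2)] - 2L
  }, integer(m)))
  rownames(dosage) <- vapply(parts, `[[`, character(1), 2)
  colnames(dosage) <- paste0("snp", map$snp)
  structure(list(dosage = dosage, map = map,
                 allele_freq = colMeans(dosage) / 2,
                 founder_freq = rep(NA_real_, m)),
            class = "genotype_set")
}

#' @rdname lactgwas-io
#' @export
write_matrix_txt <- function(x, path) {
  utils::write.table(cbind(id = rownames(x), as.data.frame(x)), path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
}

#' @rdname lactgwas-io
#' @export
read_matrix_txt <- function(path) {
  m <- utils::read.delim(path, check.names = FALSE)
  out <- as.matrix(m[, -1, drop = FALSE])
  rownames(out) <- as.character(m$id)
  out
}
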
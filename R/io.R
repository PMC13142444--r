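## Readers and writers for the external formats the pipeline touches.
##
## Coordinate conventions, used everywhere in the package:
##   * regions are BED-style 0-based half-open [start, end)
##   * variant positions are VCF-style 1-based
##   * a variant at position pos falls in region [start, end) iff
##     pos - 1 is in [start, end), i.e. start < pos <= end.

#' Construct a cell-by-region count matrix
#'
#' Bundles a sparse non-negative integer count matrix (cells in rows, regions
#' in columns) with its region coordinates and cell barcodes, validating the
#' dimensions and the count invariants.
#'
#' @param counts A cells x regions matrix (base or [Matrix::Matrix]) of
#'   non-negative integers.
#' @param regions A data frame with columns `chrom`, `start`, `end` (BED
#'   0-based half-open) and optionally `gc` (fraction of G/C bases in
#'   \[0, 1\]).
#' @param barcodes Character vector of cell labels, one per row of `counts`.
#' @return An object of class `scads_counts`: a list with elements `counts`
#'   (a `dgCMatrix`), `regions` (a tibble) and `barcodes`.
#' @export
cell_region_matrix <- function(counts, regions, barcodes) {
  counts <- as(as(as(Matrix(counts, sparse = TRUE), "dMatrix"),
                  "generalMatrix"), "CsparseMatrix")
  regions <- as_tibble(regions)
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  if (nrow(counts) != length(barcodes))
    stop_format("counts has %d rows but %d barcodes given",
                nrow(counts), length(barcodes))
  if (ncol(counts) != nrow(regions))
    stop_format("counts has %d columns but %d regions given",
                ncol(counts), nrow(regions))
  if (any(counts@x < 0))
    stop_format("negative entries in count matrix")
  if (!is_count_like(counts))
    stop_format("non-integer entries in count matrix")
  if (any(regions$start < 0) || any(regions$start >= regions$end))
    stop_format("regions must satisfy 0 <= start < end")
  if ("gc" %in% names(regions) &&
      any(!is.na(regions$gc) & (regions$gc < 0 | regions$gc > 1)))
    stop_format("gc must lie in [0, 1]")
  structure(list(counts = counts, regions = regions,
                 barcodes = as.character(barcodes)),
            class = "scads_counts")
}

#' @export
print.scads_counts <- function(x, ...) {
  cat(sprintf("scads_counts: %d cells x %d regions, %d non-zero entries\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  invisible(x)
}

#' @export
dim.scads_counts <- function(x) dim(x$counts)

#' Read regions from a BED file
#'
#' Columns beyond the third are optional; a numeric 4th column in \[0, 1\] is
#' interpreted as per-region GC content, so that a genome FASTA is not
#' required.
#'
#' @param path BED file (optionally gzipped).
#' @return Tibble with columns `chrom`, `start`, `end` and, when present,
#'   `gc`.
#' @export
read_regions <- function(path) {
  bed <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         show_col_types = FALSE, progress = FALSE)
  if (ncol(bed) < 3) stop_format("BED file needs at least 3 columns: %s", path)
  out <- tibble(chrom = as.character(bed[[1]]),
                start = as.numeric(bed[[2]]),
                end = as.numeric(bed[[3]]))
  if (ncol(bed) >= 4 && is.numeric(bed[[4]]) &&
      all(bed[[4]] >= 0 & bed[[4]] <= 1, na.rm = TRUE)) {
    out$gc <- as.numeric(bed[[4]])
  }
  if (any(out$start < 0) || any(out$start >= out$end))
    stop_format("BED intervals must satisfy 0 <= start < end")
  out
}

#' Read a sparse cell-by-region count matrix
#'
#' Loads a Matrix Market count matrix together with BED region coordinates
#' and a barcode list. Orientation (cells in rows vs. columns) is
#' auto-detected from the dimensions; square matrices are ambiguous and
#' require `cells_as`.
#'
#' @param matrix_path Matrix Market (.mtx, optionally .gz) coordinate file.
#' @param regions_path BED file of region coordinates (see [read_regions()]).
#' @param barcodes_path Text file with one cell barcode per line.
#' @param cells_as `"auto"` (default), `"rows"` or `"columns"`: orientation
#'   of the stored matrix.
#' @return A [cell_region_matrix()] object with cells in rows.
#' @export
read_counts <- function(matrix_path, regions_path, barcodes_path,
                        cells_as = c("auto", "rows", "columns")) {
  cells_as <- match.arg(cells_as)
  m <- Matrix::readMM(matrix_path)
  regions <- read_regions(regions_path)
  barcodes <- readr::read_lines(barcodes_path, progress = FALSE)
  barcodes <- barcodes[nzchar(barcodes)]
  nb <- length(barcodes); nr <- nrow(regions)
  if (cells_as == "auto") {
    if (nb == nr && nrow(m) == ncol(m))
      stop_format(paste("square matrix with equally many barcodes and",
                        "regions is ambiguous; pass cells_as explicitly"))
    if (nrow(m) == nb && ncol(m) == nr) {
      cells_as <- "rows"
    } else if (nrow(m) == nr && ncol(m) == nb) {
      cells_as <- "columns"
    } else {
      stop_format("matrix is %d x %d but there are %d barcodes and %d regions",
                  nrow(m), ncol(m), nb, nr)
    }
  }
  if (cells_as == "columns") m <- Matrix::t(m)
  if (nrow(m) != nb || ncol(m) != nr)
    stop_format("matrix is %d x %d but there are %d barcodes and %d regions",
                nrow(m), ncol(m), nb, nr)
  cell_region_matrix(m, regions, barcodes)
}

#' Write a cell-by-region count matrix
#'
#' Writes the Matrix Market matrix (cells in rows), the BED region file (with
#' a GC 4th column when available) and the barcode list.
#'
#' @param x A `scads_counts` object.
#' @param matrix_path,regions_path,barcodes_path Output paths.
#' @return Invisibly, `x`.
#' @export
write_counts <- function(x, matrix_path, regions_path, barcodes_path) {
  stopifnot(inherits(x, "scads_counts"))
  Matrix::writeMM(x$counts, matrix_path)
  bed <- x$regions[, c("chrom", "start", "end")]
  if ("gc" %in% names(x$regions)) bed$gc <- x$regions$gc
  readr::write_tsv(bed, regions_path, col_names = FALSE, progress = FALSE)
  readr::write_lines(x$barcodes, barcodes_path)
  invisible(x)
}

#' Read LDSC-style GWAS summary statistics
#'
#' Whitespace-delimited file with header columns `SNP`, `A1`, `A2`, `N`, `Z`.
#' Rows with missing or non-finite Z are dropped; the number dropped is
#' reported in a message and stored in the `n_dropped` attribute.
#'
#' @param path Sumstats file (optionally gzipped).
#' @return Tibble with columns `SNP`, `A1`, `A2`, `N`, `Z`.
#' @export
read_sumstats <- function(path) {
  tab <- readr::read_table(path, show_col_types = FALSE, progress = FALSE,
                           na = c("NA", "NaN", "", "."))
  req <- c("SNP", "A1", "A2", "N", "Z")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop_format("sumstats file missing required column(s): %s",
                paste(miss, collapse = ", "))
  tab <- tab[, req]
  tab$N <- as.numeric(tab$N)
  tab$Z <- as.numeric(tab$Z)
  bad <- !is.finite(tab$Z)
  if (any(bad))
    message(sprintf("read_sumstats: dropped %d row(s) with missing Z",
                    sum(bad)))
  out <- as_tibble(tab[!bad, ])
  attr(out, "n_dropped") <- sum(bad)
  out
}

#' Write GWAS summary statistics
#'
#' @param sumstats Tibble with columns `SNP`, `A1`, `A2`, `N`, `Z`.
#' @param path Output path.
#' @return Invisibly, `sumstats`.
#' @export
write_sumstats <- function(sumstats, path) {
  readr::write_tsv(sumstats[, c("SNP", "A1", "A2", "N", "Z")], path,
                   progress = FALSE)
  invisible(sumstats)
}

#' Read a genotype dosage panel
#'
#' The panel is stored as two files sharing a prefix: `<prefix>.dosage.tsv`
#' holds the individuals x variants dosage matrix (entries in \{0, 1, 2\},
#' no header) and `<prefix>.vars.tsv` the variant sidecar with columns
#' `id`, `chrom`, `pos` (1-based), `a1`, `a2` in the same variant order.
#'
#' @param prefix Path prefix of the two files.
#' @return A list of class `scads_genotypes` with elements `X` (integer
#'   matrix, individuals x variants) and `variants` (tibble).
#' @export
read_genotypes <- function(prefix) {
  dpath <- paste0(prefix, ".dosage.tsv")
  vpath <- paste0(prefix, ".vars.tsv")
  if (!file.exists(dpath) || !file.exists(vpath))
    stop_format("genotype panel files not found for prefix %s", prefix)
  vars <- readr::read_tsv(vpath, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("id", "chrom", "pos") %in% names(vars)))
  X <- as.matrix(readr::read_tsv(dpath, col_names = FALSE,
                                 show_col_types = FALSE, progress = FALSE))
  if (length(X) == 0L || nrow(X) == 0L)
    stop_format("empty genotype dosage file: %s", dpath)
  dimnames(X) <- NULL
  if (ncol(X) != nrow(vars))
    stop_format("dosage matrix has %d variants but sidecar lists %d",
                ncol(X), nrow(vars))
  if (!all(X %in% c(0, 1, 2)))
    stop_format("dosages must be 0, 1 or 2")
  storage.mode(X) <- "integer"
  genotype_panel(X, vars)
}

#' Construct a genotype panel object
#'
#' @param X Integer dosage matrix, individuals x variants, entries in
#'   \{0, 1, 2\}.
#' @param variants Tibble with columns `id`, `chrom`, `pos` (1-based) and
#'   optionally `a1`, `a2`, one row per column of `X`.
#' @return A list of class `scads_genotypes`.
#' @export
genotype_panel <- function(X, variants) {
  variants <- as_tibble(variants)
  stopifnot(ncol(X) == nrow(variants),
            all(c("id", "chrom", "pos") %in% names(variants)),
            all(variants$pos >= 1))
  if (is.null(variants$a1)) variants$a1 <- "A"
  if (is.null(variants$a2)) variants$a2 <- "G"
  structure(list(X = X, variants = variants), class = "scads_genotypes")
}

#' @export
print.scads_genotypes <- function(x, ...) {
  cat(sprintf("scads_genotypes: %d individuals x %d variants\n",
              nrow(x$X), ncol(x$X)))
  invisible(x)
}

#' Write a genotype dosage panel
#'
#' @param panel A `scads_genotypes` object.
#' @param prefix Path prefix (see [read_genotypes()]).
#' @return Invisibly, `panel`.
#' @export
write_genotypes <- function(panel, prefix) {
  stopifnot(inherits(panel, "scads_genotypes"))
  readr::write_tsv(as.data.frame(panel$X), paste0(prefix, ".dosage.tsv"),
                   col_names = FALSE, progress = FALSE)
  readr::write_tsv(panel$variants[, c("id", "chrom", "pos", "a1", "a2")],
                   paste0(prefix, ".vars.tsv"), progress = FALSE)
  invisible(panel)
}

#' Write a variant annotation matrix as an annot-style TSV
#'
#' One row per variant with columns `SNP`, `CHR`, `BP` followed by one 0/1
#' column per annotation, in a deterministic column order.
#'
#' @param annotation Binary matrix or vector, variants x annotations.
#' @param variants Tibble with columns `id`, `chrom`, `pos`.
#' @param path Output path.
#' @return Invisibly, the written tibble.
#' @export
write_annotation <- function(annotation, variants, path) {
  A <- as.matrix(annotation)
  if (nrow(A) != nrow(variants))
    stop_format("annotation has %d rows but %d variants given",
                nrow(A), nrow(variants))
  if (ncol(A) > 0L && is.null(colnames(A)))
    colnames(A) <- paste0("topic", seq_len(ncol(A)))
  out <- tibble(SNP = variants$id, CHR = variants$chrom, BP = variants$pos)
  out <- dplyr::bind_cols(out, as_tibble(A))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(out)
}

#' Read an annot-style TSV back into a binary matrix
#'
#' @param path File written by [write_annotation()].
#' @return List with `annotation` (integer matrix) and `variants` (tibble).
#' @export
read_annotation <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("SNP", "CHR", "BP") %in% names(tab)))
  ann <- as.matrix(tab[, setdiff(names(tab), c("SNP", "CHR", "BP")),
                       drop = FALSE])
  list(annotation = ann,
       variants = tibble(id = tab$SNP, chrom = as.character(tab$CHR),
                         pos = tab$BP))
}

#' Write a per-cell score table
#'
#' @param table Tibble with columns `barcode`, `score`, `variance`, `z`, `p`,
#'   `fdr` (extra columns are preserved after these).
#' @param path Output path.
#' @return Invisibly, `table`.
#' @export
write_cell_scores <- function(table, path) {
  req <- c("barcode", "score", "variance", "z", "p", "fdr")
  miss <- setdiff(req, names(table))
  if (length(miss))
    stop_format("cell score table missing column(s): %s",
                paste(miss, collapse = ", "))
  readr::write_tsv(table[, c(req, setdiff(names(table), req))], path,
                   progress = FALSE)
  invisible(table)
}

#' Compute per-region GC content from a genome FASTA
#'
#' @param regions Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param fasta_path FASTA file whose sequence names match `chrom`.
#' @return The regions tibble with a `gc` column.
#' @export
region_gc_from_fasta <- function(regions, fasta_path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop_format("Biostrings is required for FASTA-based GC computation")
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gc <- vapply(seq_len(nrow(regions)), function(i) {
    chrom <- regions$chrom[i]
    if (!chrom %in% names(seqs))
      stop_format("chromosome %s not found in FASTA", chrom)
    s <- Biostrings::subseq(seqs[[chrom]], start = regions$start[i] + 1L,
                            end = regions$end[i])
    sum(Biostrings::letterFrequency(s, c("G", "C"))) / length(s)
  }, numeric(1))
  regions$gc <- gc
  regions
}

## GRanges helpers implementing the 0-based/1-based conversion rule:
## region [start, end) <-> IRanges(start + 1, end); variant pos <-> IRanges(pos, pos)
regions_to_granges <- function(regions) {
  GenomicRanges::GRanges(regions$chrom,
                         IRanges::IRanges(start = regions$start + 1L,
                                          end = regions$end))
}

variants_to_granges <- function(variants) {
  GenomicRanges::GRanges(variants$chrom,
                         IRanges::IRanges(start = variants$pos,
                                          end = variants$pos))
}
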
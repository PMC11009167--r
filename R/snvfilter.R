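#' Per-cell variant call matrix
#'
#' Container for scSNV-style sparse output: cells x sites matrices of
#' alternative- and reference-allele UMI counts, with barcode and site
#' annotations. The two matrices must be congruent and counts non-negative.
#'
#' @param alt_umis,ref_umis sparse (or coercible) cells x sites matrices of
#'   UMI counts.
#' @param barcodes character vector of unique cell identifiers (rows).
#' @param sites data frame with columns `chrom`, `pos`, `ref`, `alt` (columns).
#' @return A `variant_call_matrix` object.
#' @examples
#' a <- Matrix::Matrix(c(0, 9, 0, 0, 8, 0), 3, 2, sparse = TRUE)
#' r <- Matrix::Matrix(c(5, 0, 4, 6, 0, 7), 3, 2, sparse = TRUE)
#' sites <- tibble::tibble(chrom = c("chr1", "chr2"), pos = c(100L, 200L),
#'                         ref = c("A", "C"), alt = c("T", "G"))
#' m <- variant_call_matrix(a, r, c("b1", "b2", "b3"), sites)
#' @export
variant_call_matrix <- function(alt_umis, ref_umis, barcodes, sites) {
  alt_umis <- methods::as(methods::as(alt_umis, "CsparseMatrix"), "generalMatrix")
  ref_umis <- methods::as(methods::as(ref_umis, "CsparseMatrix"), "generalMatrix")
  if (!identical(dim(alt_umis), dim(ref_umis)))
    tc_abort("alt and ref matrices must have identical dimensions", "dims")
  if (nrow(alt_umis) != length(barcodes))
    tc_abort(sprintf("matrix has %d rows but %d barcodes",
                     nrow(alt_umis), length(barcodes)), "dims")
  if (ncol(alt_umis) != nrow(sites))
    tc_abort(sprintf("matrix has %d columns but %d site records",
                     ncol(alt_umis), nrow(sites)), "dims")
  if (anyDuplicated(barcodes))
    tc_abort("duplicate barcodes", "dims")
  sites <- tibble::as_tibble(sites)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(sites)))
    tc_abort("sites must have columns chrom, pos, ref, alt", "sites")
  if (anyDuplicated(sites[need]))
    tc_abort("duplicate variant sites", "sites")
  if (any(sites$pos < 1)) tc_abort("positions are 1-based (pos >= 1)", "sites")
  if (any(sites$ref == sites$alt)) tc_abort("site with ref == alt", "sites")
  if (min(alt_umis@x, 0) < 0 || min(ref_umis@x, 0) < 0)
    tc_abort("negative UMI counts", "counts")
  structure(list(alt_umis = alt_umis, ref_umis = ref_umis,
                 barcodes = as.character(barcodes), sites = sites),
            class = "variant_call_matrix")
}

#' @exportS3Method base::print
print.variant_call_matrix <- function(x, ...) {
  cat("<variant_call_matrix> ", length(x$barcodes), " cells x ",
      nrow(x$sites), " sites; ", length(x$alt_umis@x),
      " alt / ", length(x$ref_umis@x), " ref nonzero entries\n", sep = "")
  invisible(x)
}

#' @export
dim.variant_call_matrix <- function(x) dim(x$alt_umis)

#' Load a variant call matrix from MatrixMarket files
#'
#' Reads scSNV/CellRanger-style sparse output: two MTX files (alternative and
#' reference UMI counts, cells as rows), a barcode list (one per line) and a
#' variant annotation CSV with columns chrom, pos, ref, alt (1-based
#' positions). Row/column counts are validated against the annotation files.
#'
#' @param mtx_alt_path,mtx_ref_path paths to MatrixMarket files.
#' @param barcodes_path path to barcodes.tsv(.gz), one barcode per line.
#' @param variants_path path to variants CSV.
#' @return A [variant_call_matrix()] with file order preserved.
#' @export
load_call_matrix <- function(mtx_alt_path, mtx_ref_path, barcodes_path,
                             variants_path) {
  for (p in c(mtx_alt_path, mtx_ref_path, barcodes_path, variants_path))
    if (!file.exists(p)) tc_abort(paste0("file not found: ", p), "io")
  alt <- tryCatch(Matrix::readMM(mtx_alt_path),
                  error = function(e) tc_abort(
                    paste0("malformed MatrixMarket file ", mtx_alt_path,
                           ": ", conditionMessage(e)), "io"))
  ref <- tryCatch(Matrix::readMM(mtx_ref_path),
                  error = function(e) tc_abort(
                    paste0("malformed MatrixMarket file ", mtx_ref_path,
                           ": ", conditionMessage(e)), "io"))
  barcodes <- readLines(barcodes_path)
  barcodes <- barcodes[nzchar(barcodes)]
  sites <- utils::read.csv(variants_path, stringsAsFactors = FALSE)
  variant_call_matrix(alt, ref, barcodes, sites)
}

#' Write a variant call matrix as MatrixMarket files
#'
#' Inverse of [load_call_matrix()]: writes `alt.mtx`, `ref.mtx`,
#' `barcodes.tsv` and `variants.csv` into `dir`.
#'
#' @param m a [variant_call_matrix()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_call_matrix <- function(m, dir) {
  stopifnot(inherits(m, "variant_call_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) tc_abort(paste0("cannot create directory: ", dir), "io")
  Matrix::writeMM(m$alt_umis, file.path(dir, "alt.mtx"))
  Matrix::writeMM(m$ref_umis, file.path(dir, "ref.mtx"))
  writeLines(m$barcodes, file.path(dir, "barcodes.tsv"))
  utils::write.csv(m$sites, file.path(dir, "variants.csv"), row.names = FALSE)
  invisible(dir)
}

#' Load a germline exclusion set from a VCF
#'
#' Reads a population VCF (e.g. 1000 Genomes) and returns the set of variant
#' keys whose minor allele frequency exceeds `maf_threshold`, for removal of
#' likely germline variants from somatic call matrices. The allele frequency
#' is taken from the INFO field (`af_key`, default `"AF"`); multi-allelic
#' records are expanded per alternative allele. MAF is folded as
#' `min(AF, 1 - AF)`, so a site with AF = 0.995 has MAF 0.005 and is kept
#' below a 1% threshold. Records lacking the AF key are skipped; their count
#' is reported in a warning.
#'
#' @param vcf_path path to a VCF or VCF.gz file.
#' @param maf_threshold exclusion threshold on minor allele frequency
#'   (default 0.01, i.e. common variants over 1% MAF are excluded).
#' @param af_key INFO key holding per-alt allele frequencies.
#' @param normalize_chrom drop a leading "chr" prefix so "chr1" and "1" match
#'   (default `TRUE`).
#' @return A `germline_set` object wrapping the excluded keys.
#' @export
load_germline_vcf <- function(vcf_path, maf_threshold = 0.01, af_key = "AF",
                              normalize_chrom = TRUE) {
  if (!file.exists(vcf_path))
    tc_abort(paste0("file not found: ", vcf_path), "io")
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  info <- vcfR::extract.info(v, element = af_key)
  n_skipped <- sum(is.na(info) | !nzchar(info))
  keys <- character(0)
  for (i in seq_len(nrow(fix))) {
    if (is.na(info[i]) || !nzchar(info[i])) next
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    afs <- suppressWarnings(as.numeric(strsplit(info[i], ",", fixed = TRUE)[[1]]))
    if (length(afs) == 1 && length(alts) > 1) afs <- rep(afs, length(alts))
    for (k in seq_along(alts)) {
      af <- afs[min(k, length(afs))]
      if (is.na(af)) next
      maf <- min(af, 1 - af)
      if (maf > maf_threshold)
        keys <- c(keys, variant_key(fix[i, "CHROM"], fix[i, "POS"],
                                    fix[i, "REF"], alts[k], normalize_chrom))
    }
  }
  if (n_skipped > 0)
    warning(sprintf("%d VCF record(s) lacked INFO/%s and were skipped",
                    n_skipped, af_key))
  structure(list(keys = unique(keys), normalize_chrom = normalize_chrom),
            class = "germline_set")
}

variant_key <- function(chrom, pos, ref, alt, normalize_chrom = TRUE) {
  if (normalize_chrom) chrom <- sub("^chr", "", chrom)
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Apply germline removal and the consecutive false-positive filters
#'
#' Three steps, in order: (1) sites matching the germline exclusion set on
#' (chrom, pos, ref, alt) are dropped; (2) a cell supports a site only if its
#' alternative-allele UMI count reaches `min_umis` — sub-threshold alt counts
#' are zeroed so downstream encoding sees clean presence/absence; (3) sites
#' supported by fewer than `min_barcodes` cells are dropped. Barcode order is
#' unchanged and the input is not modified. An empty result is legal.
#'
#' @param m a [variant_call_matrix()].
#' @param germ optional `germline_set` from [load_germline_vcf()] (or `NULL`).
#' @param min_umis minimum alt UMIs within one cell for a detection
#'   (default 8).
#' @param min_barcodes minimum number of detecting cells for a site to
#'   survive (default 4).
#' @return A filtered [variant_call_matrix()].
#' @examples
#' a <- Matrix::Matrix(matrix(c(8, 8, 8, 8, 0), 5, 1), sparse = TRUE)
#' r <- Matrix::Matrix(matrix(0, 5, 1), sparse = TRUE)
#' m <- variant_call_matrix(a, r, paste0("b", 1:5),
#'   tibble::tibble(chrom = "chr1", pos = 1L, ref = "A", alt = "T"))
#' nrow(filter_variants(m)$sites)  # retained: 4 cells at >= 8 UMIs
#' @export
filter_variants <- function(m, germ = NULL, min_umis = 8, min_barcodes = 4) {
  stopifnot(inherits(m, "variant_call_matrix"))
  keep <- rep(TRUE, nrow(m$sites))
  if (!is.null(germ)) {
    stopifnot(inherits(germ, "germline_set"))
    keys <- variant_key(m$sites$chrom, m$sites$pos, m$sites$ref, m$sites$alt,
                        germ$normalize_chrom)
    keep <- !(keys %in% germ$keys)
  }
  alt <- m$alt_umis[, keep, drop = FALSE]
  ref <- m$ref_umis[, keep, drop = FALSE]
  sites <- m$sites[keep, , drop = FALSE]
  # zero sub-threshold detections
  if (length(alt@x)) alt@x[alt@x < min_umis] <- 0
  alt <- Matrix::drop0(alt)
  support <- Matrix::colSums(alt >= min_umis)
  keep2 <- support >= min_barcodes
  variant_call_matrix(alt[, keep2, drop = FALSE],
                      ref[, keep2, drop = FALSE],
                      m$barcodes, sites[keep2, , drop = FALSE])
}
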
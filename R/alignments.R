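#' Cell pseudo-alignment
#'
#' A cells x sites character matrix over the three-letter alphabet
#' `A` (alternative allele detected), `R` (reference observed, no detection)
#' and `?` (no information), the input to p-distance computation.
#'
#' @param states character matrix with entries in `{A, R, ?}`; rownames are
#'   barcodes.
#' @param sites data frame of site annotations, one row per column.
#' @return A `cell_alignment` object.
#' @export
cell_alignment <- function(states, sites) {
  if (!is.matrix(states) || is.null(rownames(states)))
    tc_abort("states must be a matrix with barcode rownames", "alignment")
  if (!all(states %in% c("A", "R", "?")))
    tc_abort("alignment states must be 'A', 'R' or '?'", "alignment")
  sites <- tibble::as_tibble(sites)
  if (nrow(sites) != ncol(states))
    tc_abort("one site record per alignment column required", "dims")
  if (anyDuplicated(rownames(states))) tc_abort("duplicate barcodes", "dims")
  structure(list(cells = rownames(states), sites = sites, states = states),
            class = "cell_alignment")
}

#' @exportS3Method base::print
print.cell_alignment <- function(x, ...) {
  cat("<cell_alignment> ", length(x$cells), " cells x ", ncol(x$states),
      " sites\n", sep = "")
  invisible(x)
}

#' @export
dim.cell_alignment <- function(x) dim(x$states)

#' Encode a filtered call matrix as a pseudo-alignment
#'
#' Per cell and site: `A` if the alternative-allele UMI count reaches
#' `min_umis` (a confirmed detection), `R` if not but at least one
#' reference-allele UMI was seen, and `?` when the site carries no usable
#' information for that cell. Expects a matrix already passed through
#' [filter_variants()] with the same `min_umis`.
#'
#' @param m a [variant_call_matrix()].
#' @param min_umis detection threshold on alt UMIs, matching the filter.
#' @return A [cell_alignment()].
#' @export
encode_alignment <- function(m, min_umis = 8) {
  stopifnot(inherits(m, "variant_call_matrix"))
  alt <- as.matrix(m$alt_umis)
  ref <- as.matrix(m$ref_umis)
  states <- matrix("?", nrow(alt), ncol(alt))
  states[ref >= 1] <- "R"
  states[alt >= min_umis] <- "A"
  rownames(states) <- m$barcodes
  cell_alignment(states, m$sites)
}

#' Draw pseudo-replicate cell subsets
#'
#' Draws `n_reps` independent uniform without-replacement subsets of
#' `cells_per_rep` cells (subsets may overlap — hence pseudo-replicates) and
#' prunes, per replicate, columns left with no `A` state, which carry no
#' signal for distances within that replicate.
#'
#' @param a a [cell_alignment()].
#' @param n_reps number of pseudo-replicates (default 5).
#' @param cells_per_rep cells per replicate (default 700).
#' @param seed integer seed making the draws reproducible.
#' @param sample_id optional label used in error messages.
#' @return List of `n_reps` [cell_alignment()] objects.
#' @export
subsample_pseudoreplicates <- function(a, n_reps = 5, cells_per_rep = 700,
                                       seed = 1L, sample_id = NULL) {
  stopifnot(inherits(a, "cell_alignment"))
  n <- length(a$cells)
  if (n < cells_per_rep)
    tc_abort(sprintf("sample %s has %d cells, fewer than cells_per_rep = %d",
                     sample_id %||% "<unnamed>", n, cells_per_rep),
             "subsample")
  set.seed(seed)
  lapply(seq_len(n_reps), function(r) {
    idx <- sort(sample.int(n, cells_per_rep))
    st <- a$states[idx, , drop = FALSE]
    keep <- colSums(st == "A") > 0
    cell_alignment(st[, keep, drop = FALSE], a$sites[keep, , drop = FALSE])
  })
}

#' Write / read a pseudo-alignment as FASTA
#'
#' One record per cell: id is the barcode, sequence the state string. The
#' native alphabet is `{A, R, ?}`; `alphabet = "nuc"` maps it onto
#' `{a, t, N}` for nucleotide-only downstream tools, and [read_fasta()]
#' recognizes either dialect.
#'
#' @param a a [cell_alignment()].
#' @param path output file.
#' @param alphabet `"native"` (default) or `"nuc"`.
#' @return `path` invisibly for the writer; a [cell_alignment()] for the
#'   reader (site annotations are synthesized placeholders, as FASTA does not
#'   carry them).
#' @export
write_fasta <- function(a, path, alphabet = c("native", "nuc")) {
  stopifnot(inherits(a, "cell_alignment"))
  alphabet <- match.arg(alphabet)
  seqs <- apply(a$states, 1, paste0, collapse = "")
  if (length(seqs) == 0) seqs <- setNames(character(0), character(0))
  if (alphabet == "nuc")
    seqs <- chartr("AR?", "atN", seqs)
  x <- Biostrings::BStringSet(seqs)
  names(x) <- a$cells
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  seqs <- as.character(x)
  if (length(seqs) && length(unique(nchar(seqs))) > 1)
    tc_abort("ragged sequence lengths in FASTA", "fasta")
  if (any(grepl("[atN]", seqs))) seqs <- chartr("atN", "AR?", seqs)
  nc <- if (length(seqs)) nchar(seqs[1]) else 0L
  states <- matrix("?", length(seqs), nc, dimnames = list(names(x), NULL))
  if (nc > 0 && length(seqs) > 0)
    states[] <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  cell_alignment(states, synth_sites(nc))
}
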
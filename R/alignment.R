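#' Nucleotide alignment objects
#'
#' An `nt_alignment` stores an aligned set of nucleotide sequences as a
#' character matrix (taxa in rows, sites in columns) together with an
#' optional partition map. All site coordinates in this package are
#' 0-based half-open intervals `[start, end)`.
#'
#' @param seqs named character vector of equal-length sequences, or a
#'   character matrix with one row per taxon and rownames set to taxon ids.
#' @param partitions optional data.frame with columns `label`, `start`,
#'   `end` (0-based half-open, disjoint, in increasing order).
#' @return an object of class `nt_alignment` with elements `ids`, `mat`
#'   (character matrix of single uppercase residues) and `partitions`.
#' @export
nt_alignment <- function(seqs, partitions = NULL) {
  if (is.matrix(seqs)) {
    mat <- seqs
    ids <- rownames(seqs)
  } else {
    ids <- names(seqs)
    if (is.null(ids)) stop("sequences must be named")
    n <- unique(nchar(seqs))
    if (length(n) > 1L) stop("ragged alignment: sequences differ in length")
    mat <- do.call(rbind, strsplit(as.character(seqs), ""))
    rownames(mat) <- ids
  }
  if (is.null(ids) || any(!nzchar(ids))) stop("all sequence ids must be non-empty")
  if (anyDuplicated(ids)) stop("duplicate id in alignment")
  if (nrow(mat) < 2L) stop("alignment needs at least 2 records")
  mat[] <- toupper(mat)
  if (!is.null(partitions)) check_partitions(partitions, ncol(mat))
  structure(list(ids = ids, mat = mat, partitions = partitions),
            class = "nt_alignment")
}

check_partitions <- function(p, n_sites) {
  stopifnot(is.data.frame(p), all(c("label", "start", "end") %in% names(p)))
  if (any(p$start < 0) || any(p$end > n_sites) || any(p$start >= p$end))
    stop("invalid partition interval")
  if (nrow(p) > 1L) {
    o <- order(p$start)
    if (any(p$end[o][-nrow(p)] > p$start[o][-1L]))
      stop("partition intervals overlap")
  }
  invisible(p)
}

#' @export
print.nt_alignment <- function(x, ...) {
  cat(sprintf("nt_alignment: %d taxa x %d sites", n_taxa(x), n_sites(x)))
  if (!is.null(x$partitions))
    cat(sprintf(", %d partitions", nrow(x$partitions)))
  cat("\n")
  invisible(x)
}

#' @rdname nt_alignment
#' @param aln an `nt_alignment`.
#' @export
n_taxa <- function(aln) nrow(aln$mat)

#' @rdname nt_alignment
#' @export
n_sites <- function(aln) ncol(aln$mat)

#' Sequences of an alignment as a named character vector
#' @param aln an `nt_alignment`.
#' @export
alignment_strings <- function(aln) {
  s <- apply(aln$mat, 1L, paste0, collapse = "")
  names(s) <- aln$ids
  s
}

#' Read an aligned FASTA file
#'
#' @param path path to a FASTA file with >= 2 equal-length records.
#' @return an `nt_alignment`; record order is preserved and residues are
#'   uppercased.
#' @export
load_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in ", path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  nt_alignment(seqs)
}

#' Write an alignment to FASTA
#' @param aln an `nt_alignment`.
#' @param path output file path.
#' @export
write_alignment <- function(aln, path) {
  set <- Biostrings::BStringSet(alignment_strings(aln))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Remove gap-rich alignment columns
#'
#' A column is removed iff its gap fraction (count of `-` divided by the
#' number of taxa) is greater than or equal to `max_gap_fraction`. With
#' `max_gap_fraction` small enough that a single gap reaches it (e.g.
#' `1e-9`), every column containing any gap is removed (strict mode).
#'
#' @param aln an `nt_alignment`.
#' @param max_gap_fraction threshold in `[0, 1]`; the comparison is
#'   inclusive (`>=`).
#' @return list with `alignment` (filtered) and `kept_columns`, the
#'   original 0-based indices of the retained columns (strictly increasing).
#' @export
filter_gap_columns <- function(aln, max_gap_fraction = 0.5) {
  stopifnot(max_gap_fraction >= 0, max_gap_fraction <= 1)
  gap_frac <- colMeans(aln$mat == "-")
  keep <- gap_frac < max_gap_fraction
  if (!any(keep)) stop("empty alignment after filtering")
  out <- nt_alignment(aln$mat[, keep, drop = FALSE])
  list(alignment = out, kept_columns = which(keep) - 1L)
}

#' Concatenate per-gene alignments
#'
#' All alignments must share exactly the same taxon set (order may
#' differ); rows are matched by id and joined in input order. The result
#' carries a partition map recording each input's interval.
#'
#' @param alignments named list of `nt_alignment` objects; names become
#'   partition labels.
#' @return an `nt_alignment` with a `partitions` data.frame.
#' @export
concatenate_alignments <- function(alignments) {
  stopifnot(length(alignments) >= 1L, !is.null(names(alignments)))
  ids <- alignments[[1L]]$ids
  mats <- lapply(alignments, function(a) {
    if (!setequal(a$ids, ids)) stop("taxon mismatch between alignments")
    a$mat[ids, , drop = FALSE]
  })
  lens <- vapply(mats, ncol, 0L)
  ends <- cumsum(lens)
  parts <- data.frame(label = names(alignments),
                      start = ends - lens, end = ends,
                      stringsAsFactors = FALSE)
  nt_alignment(do.call(cbind, mats), partitions = parts)
}

#' Extract a partition from a concatenated alignment
#' @param aln an `nt_alignment` with a partition map.
#' @param label partition label.
#' @export
extract_partition <- function(aln, label) {
  p <- aln$partitions
  if (is.null(p) || !label %in% p$label) stop("unknown partition: ", label)
  i <- match(label, p$label)
  nt_alignment(aln$mat[, (p$start[i] + 1L):p$end[i], drop = FALSE])
}

#' Frame-check an alignment as a codon alignment
#'
#' @param aln an `nt_alignment` whose length is divisible by 3.
#' @param stop_policy what to do with internal (non-terminal) stop codons
#'   in any ungapped sequence: `"error"` aborts, `"mask"` replaces the
#'   offending codon by a gap triplet, `"allow"` leaves them.
#' @return object of class `codon_alignment`: the alignment plus
#'   `n_codons` and `masked_count`.
#' @export
codonize <- function(aln, stop_policy = c("error", "mask", "allow")) {
  stop_policy <- match.arg(stop_policy)
  if (n_sites(aln) %% 3L != 0L) stop("frame error: length not divisible by 3")
  mat <- aln$mat
  n_codons <- ncol(mat) %/% 3L
  masked <- 0L
  if (stop_policy != "allow") {
    for (r in seq_len(nrow(mat))) {
      cod <- apply(matrix(mat[r, ], nrow = 3L), 2L, paste0, collapse = "")
      internal <- which(cod %in% STOP_CODONS)
      # a stop in the last ungapped codon of a sequence is terminal, not internal
      internal <- internal[internal != last_ungapped_codon(cod)]
      if (length(internal)) {
        if (stop_policy == "error")
          stop("premature stop codon in sequence ", aln$ids[r])
        for (ci in internal) mat[r, (3L * ci - 2L):(3L * ci)] <- "-"
        masked <- masked + length(internal)
      }
    }
  }
  out <- nt_alignment(mat, partitions = aln$partitions)
  structure(c(out, list(n_codons = n_codons, masked_count = masked,
                        stop_policy = stop_policy)),
            class = c("codon_alignment", "nt_alignment"))
}

last_ungapped_codon <- function(codons) {
  ok <- which(!grepl("-", codons, fixed = TRUE))
  if (length(ok)) max(ok) else 0L
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon_alignment: %d taxa x %d codons (%d masked)\n",
              length(x$ids), x$n_codons, x$masked_count))
  invisible(x)
}

#' Write a partition map as TSV
#' @param aln an `nt_alignment` with partitions.
#' @param path output path.
#' @export
write_partition_map <- function(aln, path) {
  if (is.null(aln$partitions)) stop("alignment has no partition map")
  utils::write.table(aln$partitions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
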
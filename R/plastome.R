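# Quadripartite plastome structure: inverted-repeat detection,
# composition statistics and gene classification.

#' Plastome record
#'
#' @param seq nucleotide sequence (single string).
#' @param features data.frame with columns `gene`, `start`, `end`
#'   (0-based half-open), `strand` (`"+"`/`"-"`), `kind`
#'   (`"CDS"`/`"rRNA"`/`"tRNA"`).
#' @param circular logical; plastomes are circular molecules.
#' @param id sequence identifier.
#' @return object of class `plastome`.
#' @export
plastome <- function(seq, features, circular = TRUE, id = "plastome") {
  seq <- toupper(seq)
  stopifnot(is.data.frame(features),
            all(c("gene", "start", "end", "strand", "kind") %in%
                  names(features)))
  n <- nchar(seq)
  if (nrow(features)) {
    if (any(features$start < 0) || any(features$end > n) ||
        any(features$start >= features$end))
      stop("feature interval outside [0, len)")
    if (any(!nzchar(features$gene))) stop("empty gene name")
  }
  structure(list(id = id, seq = seq, circular = circular,
                 features = features),
            class = "plastome")
}

#' @export
print.plastome <- function(x, ...) {
  cat(sprintf("plastome %s: %d bp, %d features, %s\n", x$id, nchar(x$seq),
              nrow(x$features), if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Read a 4/5-column feature table (gene, start, end, strand[, kind])
#' @param path TSV path with a header line.
#' @export
read_feature_table <- function(path) {
  ft <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"kind" %in% names(ft)) ft$kind <- "CDS"
  ft
}

#' GC and AT content of a sequence
#'
#' Ambiguity codes and gaps are excluded from the denominator; values are
#' percentages rounded to 2 decimals and sum to 100.
#'
#' @param seq nucleotide string.
#' @return named numeric: `gc`, `at`.
#' @export
composition_stats <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1L]]
  gc <- sum(ch %in% c("G", "C"))
  at <- sum(ch %in% c("A", "T", "U"))
  if (gc + at == 0L) stop("no countable bases")
  c(gc = round(100 * gc / (gc + at), 2),
    at = round(100 * at / (gc + at), 2))
}

#' Detect the inverted repeat and quadripartite partition
#'
#' Seed-and-extend search for the longest pair of reverse-complementary
#' segments: exact k-mer seeds (default 25-mers) shared between the
#' sequence and its reverse complement are extended outwards allowing a
#' mismatch rate up to `max_mismatch_rate`. The two single-copy regions
#' between the repeat copies are labelled LSC (the longer one) and SSC.
#'
#' @param rec a `plastome` (circular).
#' @param min_len minimum IR length to report (bp).
#' @param max_mismatch_rate tolerated mismatch fraction during extension.
#' @param k seed length.
#' @return object of class `plastome_partition` with intervals `ira`,
#'   `irb`, `lsc`, `ssc` (0-based half-open, `ssc`/`lsc` may wrap), and
#'   lengths `ir_len`, `lsc_len`, `ssc_len`, `total_len`, plus
#'   `gc_content` of the full sequence. `ir_len = 0` when no repeat of
#'   `min_len` is found.
#' @export
detect_ir <- function(rec, min_len = 1000L, max_mismatch_rate = 0.01,
                      k = 25L) {
  s <- rec$seq
  n <- nchar(s)
  if (n < 2L * min_len) stop("sequence shorter than 2 * min_len")
  gc <- composition_stats(s)[["gc"]]
  hit <- best_inverted_repeat(s, k, max_mismatch_rate)
  if (is.null(hit) || hit$len < min_len) {
    return(structure(list(ira = NULL, irb = NULL,
                          lsc = c(0L, n), ssc = NULL,
                          ir_len = 0L, lsc_len = n, ssc_len = 0L,
                          total_len = n, gc_content = gc),
                     class = "plastome_partition"))
  }
  # hit: copy A = [a1, a2), copy B = [b1, b2), both 0-based, a2 <= b1
  a1 <- hit$a1; a2 <- hit$a2; b1 <- hit$b1; b2 <- hit$b2
  sc1 <- c(a2, b1)                      # between the copies
  sc2_len <- n - b2 + a1                # wraps around the origin
  sc1_len <- b1 - a2
  if (sc1_len >= sc2_len) {
    lsc <- sc1; lsc_len <- sc1_len
    ssc <- c(b2 %% n, a1); ssc_len <- sc2_len
  } else {
    lsc <- c(b2 %% n, a1); lsc_len <- sc2_len
    ssc <- sc1; ssc_len <- sc1_len
  }
  structure(list(ira = c(a1, a2), irb = c(b1, b2),
                 lsc = lsc, ssc = ssc,
                 ir_len = as.integer(a2 - a1),
                 lsc_len = as.integer(lsc_len),
                 ssc_len = as.integer(ssc_len),
                 total_len = as.integer(n), gc_content = gc),
            class = "plastome_partition")
}

#' @export
print.plastome_partition <- function(x, ...) {
  cat(sprintf("plastome partition: total %d bp = LSC %d + SSC %d + 2 x IR %d; GC %.2f%%\n",
              x$total_len, x$lsc_len, x$ssc_len, x$ir_len, x$gc_content))
  invisible(x)
}

# Longest pair of reverse-complementary segments via k-mer seeds between
# s and revcomp(s), extended with a mismatch budget.
best_inverted_repeat <- function(s, k, max_mm) {
  n <- nchar(s)
  ch <- strsplit(s, "")[[1L]]
  rc <- rev(comp_base(ch))
  skmers <- substring(s, 1:(n - k + 1L), k:n)
  rcs <- paste0(rc, collapse = "")
  rkmers <- substring(rcs, 1:(n - k + 1L), k:n)
  m <- match(skmers, rkmers)
  seeds <- which(!is.na(m))
  if (!length(seeds)) return(NULL)
  # seed at i (0-based i0 = i-1) matches revcomp(s)[m[i] .. ]; the source
  # window on s is [n - m[i] + 1 - k + 1, ...], 0-based j0:
  best <- NULL
  covered_a <- rep(FALSE, n)
  # order seeds so that long repeats are found early; dedupe by coverage
  for (i in seeds) {
    i0 <- i - 1L
    j0 <- n - (m[i] - 1L) - k
    if (j0 <= i0) next                    # keep copy A before copy B
    if (covered_a[i0 + 1L]) next
    ext <- extend_ir(ch, i0, j0, k, max_mm)
    if (is.null(best) || ext$len > best$len) best <- ext
    covered_a[(ext$a1 + 1L):ext$a2] <- TRUE
  }
  best
}

# Extend an exact seed (A = [i0, i0+k), B = [j0, j0+k), revcomp match,
# pairing A-left with B-right and A-right with B-left) allowing a total
# mismatch rate <= max_mm.
extend_ir <- function(ch, i0, j0, k, max_mm) {
  n <- length(ch)
  a1 <- i0; a2 <- i0 + k; b1 <- j0; b2 <- j0 + k
  mm <- 0L
  repeat {
    grew <- FALSE
    # grow A right / B left (keep the copies from overlapping)
    if (b1 - a2 >= 2L) {
      mmn <- mm + (ch[a2 + 1L] != comp_base(ch[b1]))
      if (mmn / (a2 - a1 + 1L) <= max_mm) {
        a2 <- a2 + 1L; b1 <- b1 - 1L; mm <- mmn; grew <- TRUE
      }
    }
    # grow A left / B right
    if (a1 > 0L && b2 < n) {
      mmn <- mm + (ch[a1] != comp_base(ch[b2 + 1L]))
      if (mmn / (a2 - a1 + 1L) <= max_mm) {
        a1 <- a1 - 1L; b2 <- b2 + 1L; mm <- mmn; grew <- TRUE
      }
    }
    if (!grew) break
  }
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, len = a2 - a1, mismatches = mm)
}

feature_seq <- function(rec, feature) {
  s <- substr(rec$seq, feature$start + 1L, feature$end)
  if (feature$strand == "-") s <- revcomp(s)
  s
}

#' Classify a gene as intact, pseudogene or absent
#'
#' A CDS is intact iff its ORF starts with ATG (or ACG for genes in
#' `editing_whitelist`, where RNA editing restores the AUG start), ends
#' with a stop codon, and contains no internal stop. Internal stops or a
#' missing usable start make it a pseudogene. rRNA/tRNA features are
#' intact when their length reaches `rna_length_frac` of the reference
#' length (when one is supplied). A gene with no feature in the
#' annotation is absent.
#'
#' @param rec a `plastome`.
#' @param gene gene name.
#' @param editing_whitelist genes whose ACG start is rescued by RNA
#'   editing (e.g. `rpl2`).
#' @param reference_lengths optional named vector of reference rRNA/tRNA
#'   lengths.
#' @param rna_length_frac intactness threshold for RNA genes.
#' @return one of `"intact"`, `"pseudogene"`, `"absent"`.
#' @export
classify_gene <- function(rec, gene, editing_whitelist = "rpl2",
                          reference_lengths = NULL,
                          rna_length_frac = 0.7) {
  i <- which(rec$features$gene == gene)
  if (!length(i)) return("absent")
  f <- rec$features[i[1L], ]
  s <- feature_seq(rec, f)
  if (f$kind != "CDS") {
    if (!is.null(reference_lengths) && gene %in% names(reference_lengths)) {
      ok <- nchar(s) >= rna_length_frac * reference_lengths[[gene]]
      return(if (ok) "intact" else "pseudogene")
    }
    return("intact")
  }
  if (nchar(s) < 6L || nchar(s) %% 3L != 0L) return("pseudogene")
  codons <- substring(s, seq(1L, nchar(s) - 2L, 3L), seq(3L, nchar(s), 3L))
  start_ok <- codons[1L] == "ATG" ||
    (gene %in% editing_whitelist && codons[1L] == "ACG")
  nc <- length(codons)
  internal_stop <- any(codons[-nc] %in% STOP_CODONS)
  terminal_stop <- codons[nc] %in% STOP_CODONS
  if (start_ok && terminal_stop && !internal_stop) "intact" else "pseudogene"
}

#' Build a gene matrix from annotated plastomes
#'
#' @param records named list of `plastome` objects.
#' @param genes gene names (columns); default: union of annotated genes.
#' @param partial_taxa taxa whose assemblies are partial; their
#'   unannotated genes become `"unsampled"` rather than `"absent"`.
#' @param ... passed to [classify_gene()].
#' @return a `gene_matrix`.
#' @export
build_gene_matrix <- function(records, genes = NULL,
                              partial_taxa = character(0), ...) {
  stopifnot(length(records) >= 1L, !is.null(names(records)))
  if (is.null(genes))
    genes <- sort(unique(unlist(lapply(records, function(r) r$features$gene))))
  st <- matrix("absent", length(records), length(genes),
               dimnames = list(names(records), genes))
  for (tx in names(records)) {
    for (g in genes) {
      cl <- classify_gene(records[[tx]], g, ...)
      if (cl == "absent" && tx %in% partial_taxa) cl <- "unsampled"
      st[tx, g] <- cl
    }
  }
  gene_matrix(st, partial_taxa = partial_taxa)
}

#' Infer gene absence in a partial assembly from synteny
#'
#' Plastomes of the study group are collinear, so a gene that is
#' unsampled in a partial assembly can be called absent when both of its
#' immediate flanking genes in the shared reference gene order are
#' observed contiguously on one contig with the gene missing between
#' them. Genes at contig ends (one flank unobserved) stay unsampled.
#'
#' @param matrix a `gene_matrix`.
#' @param taxon partial-assembly taxon (a row).
#' @param observed_order character vector: the gene order actually
#'   observed on one contig of the partial assembly.
#' @param reference_order the shared collinear gene order.
#' @return the updated `gene_matrix`.
#' @export
infer_absence_by_synteny <- function(matrix, taxon, observed_order,
                                     reference_order) {
  stopifnot(taxon %in% rownames(matrix$states))
  row <- matrix$states[taxon, ]
  for (g in names(row)[row == "unsampled"]) {
    i <- match(g, reference_order)
    if (is.na(i) || i == 1L || i == length(reference_order)) next
    left <- reference_order[i - 1L]
    right <- reference_order[i + 1L]
    li <- match(left, observed_order)
    ri <- match(right, observed_order)
    if (is.na(li) || is.na(ri)) next
    if (abs(ri - li) == 1L)   # flanks contiguous, gene absent between them
      matrix$states[taxon, g] <- "absent"
  }
  matrix
}
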
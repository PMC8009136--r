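# Frequencies of synonymous substitutions in trinucleotide contexts,
# summed over the branches of a clade and normalized by opportunity
# counts (synonymous single-base changes that could have happened).

#' Synonymous substitution spectrum in nucleotide contexts
#'
#' For every branch in `branches` and every protein-coding site, an
#' observed event is a parent-to-child base change that is synonymous
#' when substituted alone into the parent codon (the other two codon
#' positions taken from the parent). An opportunity is any (site, target
#' base) pair that would be synonymous in the same sense, counted
#' whether or not the change occurred, on that branch's parent sequence.
#' The context is the 5' and 3' neighbor of the site on the annotated
#' coding strand of the parent. Codons differing at more than one
#' position between the branch endpoints are excluded from both counts
#' (reported in `excluded_codons`), as are sites lacking a neighbor or
#' with gaps/ambiguity in the parent codon or neighbors. Counts are
#' summed over branches, then `frequency = observed / opportunities`.
#'
#' @param recon an `ancestral_recon` built from a coding alignment whose
#'   sites are in frame (partitions, if present, must each be in frame).
#' @param branches edge indices (or child-node names) of the clade's
#'   branches; see [clade_branches()].
#' @param strand_merged also report classes merged with their reverse
#'   complements.
#' @return object of class `context_spectrum`: data.frame `table` with
#'   columns ctx5, from, ctx3, to, observed, opportunities, frequency;
#'   `excluded_codons`; optionally `merged`.
#' @export
synonymous_context_frequencies <- function(recon, branches,
                                           strand_merged = FALSE) {
  tree <- recon$tree
  eids <- vapply(branches, function(b) resolve_branch(tree, b), 0L)
  S <- ncol(recon$node_seq)
  if (S %% 3L != 0L) stop("frame unknown: sites not a multiple of 3")
  keys <- character(0)
  obs <- integer(0)
  opp <- integer(0)
  excluded <- 0L
  acc <- new.env(parent = emptyenv())
  bump <- function(key, dobs, dopp) {
    cur <- acc[[key]]
    if (is.null(cur)) cur <- c(0L, 0L)
    acc[[key]] <- cur + c(dobs, dopp)
  }
  for (e in eids) {
    par <- tree$edge[e, 1L]; chd <- tree$edge[e, 2L]
    p <- recon$node_seq[par, ]
    ch <- recon$node_seq[chd, ]
    pres <- recon$indel_presence[par, ] & recon$indel_presence[chd, ]
    for (cod in seq_len(S %/% 3L)) {
      idx <- (3L * cod - 2L):(3L * cod)
      pc <- p[idx]; cc <- ch[idx]
      if (!all(pres[idx])) next
      if (!all(pc %in% NT_STATES) || !all(cc %in% NT_STATES)) next
      ndiff <- sum(pc != cc)
      if (ndiff > 1L) { excluded <- excluded + 1L; next }
      paa <- GENETIC_CODE_STD[paste0(pc, collapse = "")]
      if (paa == "*") next
      for (pos in 1:3) {
        site <- idx[pos]
        if (site == 1L || site == S) next      # no neighbor
        n5 <- p[site - 1L]; n3 <- p[site + 1L]
        if (!(n5 %in% NT_STATES) || !(n3 %in% NT_STATES)) next
        if (!pres[site - 1L] || !pres[site + 1L]) next
        from <- pc[pos]
        for (to in setdiff(NT_STATES, from)) {
          mut <- pc
          mut[pos] <- to
          maa <- GENETIC_CODE_STD[paste0(mut, collapse = "")]
          if (maa != paa || maa == "*") next
          happened <- cc[pos] == to
          bump(paste(n5, from, n3, to, sep = "|"), as.integer(happened), 1L)
        }
      }
    }
  }
  ks <- ls(acc)
  if (length(ks)) {
    parts <- do.call(rbind, strsplit(ks, "|", fixed = TRUE))
    vals <- do.call(rbind, lapply(ks, function(k) acc[[k]]))
    tab <- data.frame(ctx5 = parts[, 1L], from = parts[, 2L],
                      ctx3 = parts[, 3L], to = parts[, 4L],
                      observed = vals[, 1L], opportunities = vals[, 2L],
                      stringsAsFactors = FALSE)
  } else {
    tab <- data.frame(ctx5 = character(0), from = character(0),
                      ctx3 = character(0), to = character(0),
                      observed = integer(0), opportunities = integer(0),
                      stringsAsFactors = FALSE)
  }
  tab$frequency <- ifelse(tab$opportunities > 0,
                          tab$observed / tab$opportunities, NA)
  tab <- tab[order(tab$from, tab$to, tab$ctx5, tab$ctx3), ]
  rownames(tab) <- NULL
  out <- list(table = tab, excluded_codons = excluded,
              strand_merged = strand_merged)
  if (strand_merged) out$merged <- merge_strands(tab)
  structure(out, class = "context_spectrum")
}

# add each class to its reverse complement: (n5, X->Y, n3) with
# (revcomp(n3), comp(X)->comp(Y), revcomp(n5))
merge_strands <- function(tab) {
  key <- function(c5, fr, c3, to) paste(c5, fr, c3, to, sep = "|")
  rckey <- key(comp_base(tab$ctx3), comp_base(tab$from),
               comp_base(tab$ctx5), comp_base(tab$to))
  own <- key(tab$ctx5, tab$from, tab$ctx3, tab$to)
  j <- match(rckey, own)
  pj <- ifelse(is.na(j), seq_along(own), j)
  obs <- tab$observed + ifelse(is.na(j), 0L, tab$observed[pj])
  opp <- tab$opportunities + ifelse(is.na(j), 0L, tab$opportunities[pj])
  # keep the lexicographically smaller member of each pair (classes are
  # never their own reverse complement: a base never equals its
  # complement); a class whose partner is unobserved keeps its own key
  keep <- own <= rckey | is.na(j)
  out <- tab[keep, c("ctx5", "from", "ctx3", "to")]
  out$observed <- obs[keep]
  out$opportunities <- opp[keep]
  out$frequency <- ifelse(out$opportunities > 0,
                          out$observed / out$opportunities, NA)
  rownames(out) <- NULL
  out
}

#' @export
print.context_spectrum <- function(x, ...) {
  cat(sprintf("context spectrum: %d context classes, %d observed / %d opportunities (%d codons excluded)\n",
              nrow(x$table), sum(x$table$observed),
              sum(x$table$opportunities), x$excluded_codons))
  invisible(x)
}

#' Aggregate a context spectrum by substitution class
#'
#' Sums observed and opportunity counts over contexts, giving one row
#' per from->to base change.
#'
#' @param spectrum a `context_spectrum`.
#' @return data.frame with from, to, observed, opportunities, frequency.
#' @export
substitution_class_summary <- function(spectrum) {
  tab <- spectrum$table
  agg <- stats::aggregate(cbind(observed, opportunities) ~ from + to,
                          data = tab, FUN = sum)
  agg$frequency <- agg$observed / agg$opportunities
  agg[order(-agg$frequency), ]
}

#' Edge indices of all branches inside a clade
#'
#' @param tree ape `phylo`.
#' @param tips tip labels spanning the clade.
#' @param include_stem include the clade's stem branch.
#' @return integer edge indices.
#' @export
clade_branches <- function(tree, tips, include_stem = FALSE) {
  painting <- paint_branches(tree, tips, transition = TRUE)
  which(painting == "ingroup" | (include_stem & painting == "transition"))
}
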
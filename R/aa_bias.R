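# Amino-acid composition bias: per-taxon frequency profiles, the
# AT-tendency correlation, and single- vs two-regime Ornstein-Uhlenbeck
# tests for composition shifts on the phylogeny.

#' Amino-acid frequency profile of one taxon
#'
#' Translates the taxon's codons under the standard code; gap codons,
#' ambiguous codons and stops are excluded, and counts are normalized to
#' frequencies over the 20 amino acids.
#'
#' @param codon_aln a `codon_alignment`.
#' @param taxon taxon id.
#' @return named numeric(20) summing to 1 (class `aa_profile`).
#' @export
amino_acid_frequencies <- function(codon_aln, taxon) {
  i <- match(taxon, codon_aln$ids)
  if (is.na(i)) stop("unknown taxon: ", taxon)
  row <- codon_aln$mat[i, ]
  cods <- apply(matrix(row, nrow = 3L), 2L, paste0, collapse = "")
  aa <- GENETIC_CODE_STD[cods]
  aa <- aa[!is.na(aa) & aa != "*"]
  if (!length(aa)) stop("no countable codons for taxon ", taxon)
  cnt <- table(factor(aa, levels = AA_LEVELS))
  structure(as.numeric(cnt) / sum(cnt), names = AA_LEVELS,
            class = "aa_profile", taxon = taxon)
}

#' @export
print.aa_profile <- function(x, ...) {
  cat(sprintf("amino-acid profile of %s\n", attr(x, "taxon")))
  print(round(unclass(x), 4))
  invisible(x)
}

#' Codon usage counts per taxon
#'
#' Raw counts of each sense codon in a taxon's sequence (gap, ambiguous
#' and stop codons excluded).
#'
#' @param codon_aln a `codon_alignment`.
#' @param taxa taxon ids (default: all).
#' @return data.frame, one row per codon, one count column per taxon,
#'   plus the encoded amino acid.
#' @export
codon_usage <- function(codon_aln, taxa = codon_aln$ids) {
  out <- data.frame(codon = SENSE_CODONS,
                    aa = unname(GENETIC_CODE_STD[SENSE_CODONS]),
                    stringsAsFactors = FALSE)
  for (tx in taxa) {
    i <- match(tx, codon_aln$ids)
    if (is.na(i)) stop("unknown taxon: ", tx)
    cods <- apply(matrix(codon_aln$mat[i, ], nrow = 3L), 2L, paste0,
                  collapse = "")
    out[[tx]] <- as.integer(table(factor(cods, levels = SENSE_CODONS)))
  }
  out
}

#' AT-tendency statistic
#'
#' Spearman correlation between the 20 amino-acid frequencies of a taxon
#' and the average AT content of the codons encoding each amino acid
#' (average-rank ties). Large positive values indicate a proteome biased
#' toward AT-rich codons (Lys, Phe, Ile, ...).
#'
#' @param profile an `aa_profile` (or any named numeric over the 20
#'   amino acids).
#' @return list of class `at_tendency`: `rho`, `codon_at`.
#' @export
at_tendency <- function(profile) {
  at <- codon_at_content()
  f <- unclass(profile)[names(at)]
  stopifnot(length(f) == 20L, !anyNA(f))
  if (length(unique(rank(f))) < 3L || length(unique(rank(at))) < 3L)
    stop("tendency undefined: fewer than 3 distinct ranks")
  rho <- stats::cor(f, at, method = "spearman")
  structure(list(rho = rho, codon_at = at,
                 taxon = attr(profile, "taxon")),
            class = "at_tendency")
}

#' @export
print.at_tendency <- function(x, ...) {
  cat(sprintf("AT tendency (Spearman rho): %.4f\n", x$rho))
  invisible(x)
}

# --- Ornstein-Uhlenbeck regime models ----------------------------------

# Tip expectations and covariance of an OU process on a (possibly
# non-ultrametric) tree. The root state is fixed at the optimum of the
# ancestral regime; regime changes apply from the painted branch onward.
# E[x_tip] = sum_r w_r * theta_r with weights from the decay recursion;
# Cov(i, j) = sigma2 * exp(-a (d_i + d_j - 2 m_ij)) (1 - exp(-2 a m_ij)) / (2a),
# which tends to the Brownian covariance sigma2 * m_ij as a -> 0.

# Precompute the tree geometry shared by all likelihood evaluations
ou_tree_cache <- function(tree, painting) {
  nt <- length(tree$tip.label)
  po <- postorder_edges(tree)
  pre <- po[rev(seq_len(nrow(po))), , drop = FALSE]
  eid <- match(paste(pre[, 1L], pre[, 2L]),
               paste(tree$edge[, 1L], tree$edge[, 2L]))
  depth <- ape::node.depth.edgelength(tree)
  M <- ape::mrca(tree)
  md <- matrix(depth[M], nt, nt)
  list(tree = tree, painting = painting, nt = nt,
       regimes = sort(unique(painting)),
       anc = ancestral_regime(tree, painting),
       pre = pre, eid = eid, elen = tree$edge.length[eid],
       ecls = painting[eid],
       depth_sum = outer(depth[seq_len(nt)], depth[seq_len(nt)], `+`),
       md = md)
}

ou_design <- function(cache, alpha) {
  nn <- n_nodes(cache$tree)
  W <- matrix(0, nn, length(cache$regimes),
              dimnames = list(NULL, cache$regimes))
  W[root_node(cache$tree), cache$anc] <- 1
  dec <- exp(-alpha * cache$elen)
  for (j in seq_len(nrow(cache$pre))) {
    par <- cache$pre[j, 1L]; chd <- cache$pre[j, 2L]
    W[chd, ] <- W[par, ] * dec[j]
    W[chd, cache$ecls[j]] <- W[chd, cache$ecls[j]] + (1 - dec[j])
  }
  W[seq_len(cache$nt), , drop = FALSE]
}

# regime of (a branch incident to) the root: the ancestral regime
ancestral_regime <- function(tree, painting) {
  root <- root_node(tree)
  e <- which(tree$edge[, 1L] == root)
  cls <- painting[e]
  non_trans <- setdiff(cls, "transition")
  if (length(non_trans)) non_trans[1L] else cls[1L]
}

ou_covariance <- function(cache, alpha) {
  if (alpha < 1e-12) return(cache$md)
  exp(-alpha * (cache$depth_sum - 2 * cache$md)) *
    (1 - exp(-2 * alpha * cache$md)) / (2 * alpha)
}

ou_profile_loglik <- function(cache, trait, alpha, single_regime = FALSE) {
  nt <- length(trait)
  X <- ou_design(cache, alpha)
  if (single_regime) X <- matrix(rowSums(X), nt, 1L)
  C <- ou_covariance(cache, alpha)
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) return(list(loglik = -Inf))
  y <- as.numeric(trait)
  Xi <- backsolve(ch, X, transpose = TRUE)
  yi <- backsolve(ch, y, transpose = TRUE)
  fit <- stats::lm.fit(Xi, yi)
  theta <- fit$coefficients
  r <- fit$residuals
  sigma2 <- sum(r^2) / nt
  if (sigma2 <= 0) sigma2 <- 1e-12
  ll <- -nt / 2 * log(2 * pi) - nt / 2 * log(sigma2) -
    sum(log(diag(ch))) - nt / 2
  list(loglik = ll, theta = theta, sigma2 = sigma2)
}

#' Fit an Ornstein-Uhlenbeck model with regime-specific optima
#'
#' Maximum-likelihood fit of an OU process on the tree: `"OU1"` has a
#' single optimum theta, `"OUM"` one optimum per painted regime (the
#' branch carrying the regime shift belongs to the derived regime).
#' alpha (selection strength) and sigma2 (diffusion variance) are shared
#' across regimes; the root state sits at the ancestral regime's
#' optimum. theta and sigma2 are profiled out analytically (GLS), so
#' the optimization is one-dimensional in log(alpha) over a fixed grid
#' of starting intervals -- deterministic.
#'
#' @param tree ape `phylo` with positive branch lengths.
#' @param trait named numeric, one value per tip.
#' @param painting per-edge regime labels (see [paint_branches()]); the
#'   `"transition"` label, if present, is merged into the derived
#'   (`"ingroup"`) regime.
#' @param model `"OU1"` or `"OUM"`.
#' @param cache optional precomputed tree geometry (internal use, lets
#'   repeated fits on one tree skip the MRCA computation).
#' @return object of class `ou_fit`: `theta` (per regime), `alpha`,
#'   `sigma2`, `loglik`, `model`.
#' @export
fit_ou <- function(tree, trait, painting, model = c("OU1", "OUM"),
                   cache = NULL) {
  model <- match.arg(model)
  stopifnot(all(tree$tip.label %in% names(trait)))
  y <- trait[tree$tip.label]
  stopifnot(all(is.finite(y)), all(tree$edge.length > 0))
  painting <- ifelse(painting == "transition", "ingroup", painting)
  if (model == "OUM" && length(unique(painting)) < 2L)
    stop("OUM needs at least two regimes in the painting")
  if (is.null(cache)) cache <- ou_tree_cache(tree, painting)
  single <- model == "OU1"
  obj <- function(la) -ou_profile_loglik(cache, y, exp(la),
                                         single_regime = single)$loglik
  # deterministic search: dense fixed grid in log(alpha), then a local
  # refinement around the best grid point
  grid <- seq(log(1e-6), log(75), length.out = 41L)
  vals <- vapply(grid, obj, 0)
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  o <- stats::optimize(obj, c(lo, hi), tol = 1e-8)
  alpha <- if (o$objective < vals[i]) exp(o$minimum) else exp(grid[i])
  pl <- ou_profile_loglik(cache, y, alpha, single_regime = single)
  theta <- pl$theta
  names(theta) <- if (single) "all" else sort(unique(painting))
  flat <- alpha <= 1.5e-6 && model == "OUM"
  structure(list(model = model, theta = theta, alpha = alpha,
                 sigma2 = pl$sigma2, loglik = pl$loglik,
                 flat_likelihood = flat, painting = painting),
            class = "ou_fit")
}

#' @export
print.ou_fit <- function(x, ...) {
  cat(sprintf("OU fit (%s): logLik %.4f, alpha %.4g, sigma2 %.4g\n",
              x$model, x$loglik, x$alpha, x$sigma2))
  for (r in names(x$theta))
    cat(sprintf("  theta[%s] = %.4f\n", r, x$theta[[r]]))
  if (isTRUE(x$flat_likelihood))
    cat("  note: alpha at lower bound; regime optima weakly identified\n")
  invisible(x)
}

#' @export
logLik.ou_fit <- function(object, ...) {
  structure(object$loglik, class = "logLik",
            df = length(object$theta) + 2L)
}

#' @export
coef.ou_fit <- function(object, ...) {
  c(object$theta, alpha = unname(object$alpha),
    sigma2 = unname(object$sigma2))
}

#' Single- vs two-regime OU likelihood-ratio test
#'
#' Fits OU1 and OUM on the same trait and painting and refers
#' `2 (lnL_OUM - lnL_OU1)` to a chi-square with df 1 (OUM adds one
#' optimum). If the nested inequality is violated numerically, OUM is
#' refit; a persistent violation raises an error.
#'
#' @param tree ape `phylo`.
#' @param trait named numeric per tip.
#' @param painting per-edge regime labels.
#' @param cache optional precomputed tree geometry (internal use).
#' @return list of class `ou_test`: `fit_ou1`, `fit_oum`, `lrt`,
#'   `p_value`.
#' @export
regime_shift_test <- function(tree, trait, painting, cache = NULL) {
  painting <- ifelse(painting == "transition", "ingroup", painting)
  if (is.null(cache)) cache <- ou_tree_cache(tree, painting)
  f1 <- fit_ou(tree, trait, painting, "OU1", cache = cache)
  f2 <- fit_ou(tree, trait, painting, "OUM", cache = cache)
  if (f2$loglik < f1$loglik - 1e-6)
    stop("optimizer failure: OUM likelihood below OU1")
  lrt <- max(0, 2 * (f2$loglik - f1$loglik))
  structure(list(fit_ou1 = f1, fit_oum = f2, lrt = lrt, df = 1L,
                 p_value = stats::pchisq(lrt, 1L, lower.tail = FALSE)),
            class = "ou_test")
}

#' @export
print.ou_test <- function(x, ...) {
  cat(sprintf("OU regime-shift LRT: 2*dlnL = %.4f, p = %.3g\n",
              x$lrt, x$p_value))
  invisible(x)
}

#' Batch OU regime tests with FDR correction
#'
#' Runs [regime_shift_test()] for each column of a trait matrix (e.g.
#' the 20 amino-acid frequencies) and applies Benjamini-Hochberg across
#' the tests.
#'
#' @param tree ape `phylo`.
#' @param traits numeric matrix, tips x variables, with rownames.
#' @param painting per-edge regime labels.
#' @return data.frame: variable, theta estimates, alpha, sigma2, lrt,
#'   p_value, q_value.
#' @export
regime_shift_batch <- function(tree, traits, painting) {
  stopifnot(is.matrix(traits), !is.null(rownames(traits)))
  painting <- ifelse(painting == "transition", "ingroup", painting)
  cache <- ou_tree_cache(tree, painting)
  rows <- lapply(colnames(traits), function(v) {
    tt <- regime_shift_test(tree, traits[, v], painting, cache = cache)
    th <- tt$fit_oum$theta
    data.frame(variable = v,
               theta_ancestral = th[[setdiff(names(th), "ingroup")[1L]]],
               theta_derived = th[["ingroup"]],
               alpha = tt$fit_oum$alpha, sigma2 = tt$fit_oum$sigma2,
               lrt = tt$lrt, p_value = tt$p_value)
  })
  out <- do.call(rbind, rows)
  out$q_value <- benjamini_hochberg(out$p_value)
  out
}
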
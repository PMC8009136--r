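# Branch-model codon substitution analysis (GY94-style): branch-class
# dN/dS (omega) contrasts between heterotrophic and photosynthetic
# lineages, likelihood-ratio tests and FDR control.

# Single-nucleotide-difference structure of the 61 sense codons
codon_pair_info <- local({
  n <- length(SENSE_CODONS)
  split_c <- strsplit(SENSE_CODONS, "")
  single <- matrix(FALSE, n, n)
  is_ts <- matrix(FALSE, n, n)
  is_syn <- matrix(FALSE, n, n)
  aa <- GENETIC_CODE_STD[SENSE_CODONS]
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- which(split_c[[i]] != split_c[[j]])
    if (length(d) != 1L) next
    single[i, j] <- TRUE
    is_ts[i, j] <- purine[split_c[[i]][d]] == purine[split_c[[j]][d]]
    is_syn[i, j] <- aa[i] == aa[j]
  }
  list(single = single, ts = is_ts, syn = is_syn)
})

#' Branch-class codon model
#'
#' GY94-style codon model over the 61 sense codons of the standard code:
#' rates between codons differing at one position are
#' `pi_j * kappa^[transition] * omega^[nonsynonymous]`, zero otherwise.
#' Each branch class has its own omega; every class rate matrix is
#' rescaled to one expected substitution per codon site per unit branch
#' length.
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega_map named numeric vector: omega per branch class.
#' @param codon_freqs numeric(61) over `SENSE_CODONS`, e.g. from
#'   [f3x4_frequencies()].
#' @return object of class `codon_model`.
#' @export
codon_model <- function(kappa, omega_map, codon_freqs) {
  stopifnot(kappa > 0, all(omega_map >= 0), length(codon_freqs) == 61L,
            !is.null(names(omega_map)))
  codon_freqs <- codon_freqs / sum(codon_freqs)
  names(codon_freqs) <- SENSE_CODONS
  structure(list(kappa = kappa, omega_map = omega_map,
                 codon_freqs = codon_freqs),
            class = "codon_model")
}

#' F3x4 codon frequencies from a codon alignment
#'
#' Position-specific nucleotide frequencies (codon positions 1-3) are
#' estimated from the data and multiplied per codon, then renormalized
#' over the 61 sense codons (PAML's `CodonFreq = 2`).
#'
#' @param codon_aln a `codon_alignment`.
#' @return numeric(61) over `SENSE_CODONS`.
#' @export
f3x4_frequencies <- function(codon_aln) {
  mat <- codon_aln$mat
  pos <- (seq_len(ncol(mat)) - 1L) %% 3L + 1L
  f <- sapply(1:3, function(p) {
    cnt <- vapply(NT_STATES, function(s) sum(mat[, pos == p] == s), 0)
    cnt <- cnt + 0.5
    cnt / sum(cnt)
  })
  freqs <- vapply(strsplit(SENSE_CODONS, ""), function(cd) {
    f[match(cd[1], NT_STATES), 1] * f[match(cd[2], NT_STATES), 2] *
      f[match(cd[3], NT_STATES), 3]
  }, 0)
  freqs / sum(freqs)
}

codon_rate_matrix <- function(kappa, omega, pi) {
  cp <- codon_pair_info
  Q <- matrix(0, 61L, 61L)
  fac <- ifelse(cp$ts, kappa, 1) * ifelse(cp$syn, 1, omega)
  Q[cp$single] <- (rep(pi, each = 61L) * fac)[cp$single]
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  if (mu <= 0) stop("degenerate codon rate matrix")
  Q / mu
}

codon_tip_partials <- function(mat_row) {
  S <- length(mat_row) %/% 3L
  cods <- apply(matrix(mat_row, nrow = 3L), 2L, paste0, collapse = "")
  L <- matrix(0, 61L, S)
  known <- match(cods, SENSE_CODONS)
  L[cbind(known[!is.na(known)], which(!is.na(known)))] <- 1
  L[, is.na(known)] <- 1   # gap/ambiguous/stop codons: missing data
  L
}

#' Codon log-likelihood under a branch-class model
#'
#' Felsenstein pruning over 61 codon states with per-site rescaling.
#' Codons containing gaps, ambiguity codes or stops are treated as
#' missing data.
#'
#' @param codon_aln a `codon_alignment`.
#' @param tree ape `phylo` (rooted or unrooted; the likelihood is
#'   root-invariant for this reversible model).
#' @param model a `codon_model`.
#' @param painting character vector per edge of `tree$edge`, with values
#'   naming entries of `model$omega_map`; default: single class.
#' @param site_weights optional pattern weights.
#' @param per_site return per-site values.
#' @return log-likelihood.
#' @export
codon_loglik <- function(codon_aln, tree, model, painting = NULL,
                         site_weights = NULL, per_site = FALSE) {
  check_tree_aln(tree, codon_aln)
  if (is.null(painting))
    painting <- rep(names(model$omega_map)[1L], nrow(tree$edge))
  stopifnot(length(painting) == nrow(tree$edge),
            all(painting %in% names(model$omega_map)))
  ord <- match(tree$tip.label, codon_aln$ids)
  tipL <- lapply(ord, function(i) codon_tip_partials(codon_aln$mat[i, ]))
  pi <- model$codon_freqs
  eds <- lapply(model$omega_map, function(w)
    reversible_eigen(codon_rate_matrix(model$kappa, w, pi), pi))
  Plist <- lapply(seq_len(nrow(tree$edge)), function(e)
    prob_matrix(eds[[painting[e]]], tree$edge.length[e]))
  site_ll <- prune_engine(tree, tipL, Plist, pi)$site_ll
  if (any(!is.finite(site_ll))) stop("numerical underflow in codon likelihood")
  if (per_site) return(site_ll)
  if (is.null(site_weights)) sum(site_ll) else sum(site_ll * site_weights)
}

# omega parameter sharing per configuration: list mapping omega
# parameters to painting classes
omega_groups_for <- function(config, classes) {
  switch(config,
    three_ratio = stats::setNames(lapply(classes, identity), classes),
    null_equal = {
      other <- setdiff(classes, "transition")
      c(list(pooled = other),
        if ("transition" %in% classes) list(transition = "transition"))
    },
    two_ratio = {
      if (!"transition" %in% classes)
        stop("two_ratio needs a 'transition' class in the painting")
      list(transition = "transition",
           other = setdiff(classes, "transition"))
    },
    one_ratio = list(all = classes),
    stop("unknown class configuration: ", config)
  )
}

#' Fit a branch-model codon likelihood
#'
#' Joint maximum-likelihood estimation of kappa, one omega per branch
#' class, and all branch lengths on a fixed topology (bounded L-BFGS-B
#' on log parameters, deterministic warm-started restarts). Class
#' configurations: `"three_ratio"` (one omega per painting class, e.g.
#' heterotrophic clade / transition branch / photosynthetic rest),
#' `"null_equal"` (heterotrophic and photosynthetic share one omega,
#' transition free -- the null for the dN/dS contrast), `"two_ratio"`
#' (transition branch vs all others), `"one_ratio"`.
#'
#' @param codon_aln a `codon_alignment`.
#' @param tree ape `phylo` topology.
#' @param painting per-edge class labels (see [paint_branches()]).
#' @param config class configuration, see above.
#' @param init optional named list with `kappa`, `omega`, `bl` start
#'   values.
#' @return object of class `codon_fit`: `model`, `tree` (fitted branch
#'   lengths), `loglik`, `omega` (per class), `kappa`, `config`.
#' @export
fit_branch_model <- function(codon_aln, tree, painting,
                             config = c("three_ratio", "null_equal",
                                        "two_ratio", "one_ratio"),
                             init = NULL) {
  config <- match.arg(config)
  check_tree_aln(tree, codon_aln)
  stopifnot(length(painting) == nrow(tree$edge))
  classes <- unique(painting)
  groups <- omega_groups_for(config, classes)
  pi <- f3x4_frequencies(codon_aln)

  cp <- compress_patterns(codon_aln, block = 3L)
  paln <- structure(c(cp$alignment,
                      list(n_codons = n_sites(cp$alignment) %/% 3L,
                           masked_count = 0L, stop_policy = "allow")),
                    class = c("codon_alignment", "nt_alignment"))
  w <- rep(cp$weights, each = 1L)

  nb <- nrow(tree$edge)
  ng <- length(groups)
  class_to_group <- vapply(painting, function(cl) {
    which(vapply(groups, function(g) cl %in% g, TRUE))[1L]
  }, 0L)

  build <- function(th) {
    kappa <- exp(th[1L])
    omg <- exp(th[2L:(1L + ng)])
    om_map <- stats::setNames(omg[class_to_group], painting)
    om_map <- om_map[!duplicated(names(om_map))]
    bl <- exp(th[(2L + ng):(1L + ng + nb)])
    tr <- tree
    tr$edge.length <- bl
    list(model = codon_model(kappa, om_map, pi), tree = tr,
         omega = stats::setNames(omg, names(groups)), kappa = kappa)
  }
  nll <- function(th) {
    b <- build(th)
    ll <- tryCatch(codon_loglik(paln, b$tree, b$model, painting,
                                site_weights = cp$weights),
                   error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  bl0 <- if (!is.null(init$bl)) init$bl
         else if (!is.null(tree$edge.length) && any(tree$edge.length > 0))
           pmax(tree$edge.length, 1e-4)
         else rep(0.1, nb)
  k0 <- if (!is.null(init$kappa)) init$kappa else 2.0
  om0 <- if (!is.null(init$omega)) rep_len(init$omega, ng) else rep(0.5, ng)
  th0 <- c(log(k0), log(om0), log(bl0))
  lower <- c(log(0.1), rep(log(1e-4), ng), rep(-18, nb))
  upper <- c(log(50), rep(log(10), ng), rep(log(20), nb))
  o <- stats::optim(th0, nll, method = "L-BFGS-B", lower = lower,
                    upper = upper,
                    control = list(maxit = 1000, factr = 1e8))
  # one deterministic restart from the first optimum (escapes flat spots)
  o2 <- stats::optim(o$par, nll, method = "L-BFGS-B", lower = lower,
                     upper = upper,
                     control = list(maxit = 1000, factr = 1e7))
  if (o2$value < o$value) o <- o2
  b <- build(o$par)
  structure(list(model = b$model, tree = b$tree, loglik = -o$value,
                 omega = b$omega, kappa = b$kappa, config = config,
                 painting = painting, convergence = o$convergence),
            class = "codon_fit")
}

#' @export
print.codon_fit <- function(x, ...) {
  cat(sprintf("codon branch-model fit (%s)\n", x$config))
  cat(sprintf("  log-likelihood: %.4f\n", x$loglik))
  cat(sprintf("  kappa: %.3f\n", x$kappa))
  for (g in names(x$omega))
    cat(sprintf("  omega[%s]: %.4f\n", g, x$omega[[g]]))
  invisible(x)
}

#' @export
logLik.codon_fit <- function(object, ...) {
  structure(object$loglik, class = "logLik",
            df = 1L + length(object$omega) + nrow(object$tree$edge))
}

#' @export
coef.codon_fit <- function(object, ...) {
  c(kappa = unname(object$kappa), object$omega)
}

#' Likelihood-ratio test for a dN/dS contrast
#'
#' Compares an alternative fit against a nested null (one fewer omega),
#' e.g. `three_ratio` vs `null_equal`; the statistic `2 (lnL_alt -
#' lnL_null)` is referred to a chi-square with df 1. If the alternative
#' likelihood falls below the null's, the alternative is refit
#' warm-started from the null (the models are nested, so this can only
#' be an optimizer failure).
#'
#' @param fit_alt,fit_null `codon_fit` objects on the same data.
#' @param codon_aln,tree,painting the shared inputs, needed only for the
#'   refit protocol.
#' @return object of class `dnds_test`: `lnL_alt`, `lnL_null`, `lrt`,
#'   `p_value`, `df`.
#' @export
lrt_dnds <- function(fit_alt, fit_null, codon_aln = NULL, tree = NULL,
                     painting = NULL) {
  if (fit_alt$loglik < fit_null$loglik - 1e-6 && !is.null(codon_aln)) {
    fit_alt <- fit_branch_model(codon_aln, fit_null$tree, painting,
                                config = fit_alt$config,
                                init = list(kappa = fit_null$kappa,
                                            omega = mean(fit_null$omega),
                                            bl = fit_null$tree$edge.length))
  }
  lrt <- max(0, 2 * (fit_alt$loglik - fit_null$loglik))
  if (fit_alt$loglik < fit_null$loglik - 1e-4)
    stop("optimizer failure: alternative likelihood below null after refit")
  structure(list(lnL_alt = fit_alt$loglik, lnL_null = fit_null$loglik,
                 lrt = lrt, df = 1L,
                 p_value = stats::pchisq(lrt, df = 1L, lower.tail = FALSE),
                 fit_alt = fit_alt, fit_null = fit_null),
            class = "dnds_test")
}

#' @export
print.dnds_test <- function(x, ...) {
  cat(sprintf("dN/dS LRT: 2*dlnL = %.4f (df %d), p = %.3g\n",
              x$lrt, x$df, x$p_value))
  invisible(x)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment of a vector of p-values (delegates to
#' `stats::p.adjust(method = "BH")`).
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (length(p_values) == 0L) stop("empty p-value vector")
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH")
}
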
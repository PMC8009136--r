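#' GTR+Gamma substitution model
#'
#' General time-reversible nucleotide model with discrete-gamma rate
#' variation across sites. Exchangeabilities are given in the order
#' AC, AG, AT, CG, CT, GT and are scaled relative to GT = 1. The rate
#' matrix is rescaled so that the expected substitution rate at
#' stationarity is 1, i.e. branch lengths are in expected substitutions
#' per site.
#'
#' @param exchangeabilities numeric(6), non-negative, order AC, AG, AT,
#'   CG, CT, GT.
#' @param base_freqs numeric(4) summing to 1 (order A, C, G, T), each > 0.
#' @param gamma_shape positive shape of the gamma rate distribution;
#'   `Inf` means a single rate class.
#' @param n_categories number of equal-probability discrete categories.
#' @return object of class `gtr_model`.
#' @export
gtr_model <- function(exchangeabilities = rep(1, 6),
                      base_freqs = rep(0.25, 4),
                      gamma_shape = Inf, n_categories = 4L) {
  stopifnot(length(exchangeabilities) == 6L, all(exchangeabilities >= 0),
            length(base_freqs) == 4L, all(base_freqs > 0),
            gamma_shape > 0)
  base_freqs <- base_freqs / sum(base_freqs)
  names(base_freqs) <- NT_STATES
  if (is.infinite(gamma_shape)) n_categories <- 1L
  structure(list(exchangeabilities = exchangeabilities,
                 base_freqs = base_freqs,
                 gamma_shape = gamma_shape,
                 n_categories = as.integer(n_categories)),
            class = "gtr_model")
}

#' @export
print.gtr_model <- function(x, ...) {
  cat("GTR+Gamma model\n")
  cat("  exchangeabilities (AC AG AT CG CT GT):",
      sprintf("%.4g", x$exchangeabilities), "\n")
  cat("  base freqs (A C G T):", sprintf("%.4f", x$base_freqs), "\n")
  cat(sprintf("  gamma shape: %s (%d categories)\n",
              format(x$gamma_shape, digits = 4), x$n_categories))
  invisible(x)
}

# Normalized GTR rate matrix (mean rate 1 at stationarity)
gtr_rate_matrix <- function(model) {
  s <- model$exchangeabilities
  pi <- model$base_freqs
  R <- matrix(0, 4, 4, dimnames = list(NT_STATES, NT_STATES))
  R["A", "C"] <- R["C", "A"] <- s[1]
  R["A", "G"] <- R["G", "A"] <- s[2]
  R["A", "T"] <- R["T", "A"] <- s[3]
  R["C", "G"] <- R["G", "C"] <- s[4]
  R["C", "T"] <- R["T", "C"] <- s[5]
  R["G", "T"] <- R["T", "G"] <- s[6]
  Q <- R %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q / mu
}

# Equal-probability discrete gamma category rates (category means), the
# standard discretization used with GTR+Gamma.
discrete_gamma_rates <- function(shape, k) {
  if (is.infinite(shape) || k == 1L) return(1)
  q <- stats::qgamma(seq(0, 1, length.out = k + 1L), shape = shape, rate = shape)
  p <- stats::pgamma(q, shape = shape + 1, rate = shape)
  r <- k * diff(p)      # category means of the unit-mean gamma
  r / mean(r)           # exact unit mean after truncation error
}

# Eigen decomposition of a reversible rate matrix via the symmetrizing
# similarity transform; returns functions to build P(t) cheaply.
reversible_eigen <- function(Q, pi) {
  sp <- sqrt(pi)
  B <- Q * outer(sp, 1 / sp)           # diag(sp) Q diag(1/sp), symmetric
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(values = e$values,
       left = e$vectors * (1 / sp),    # diag(1/sp) U  -> rows scaled
       right = t(e$vectors) * rep(sp, each = length(pi)))  # U^T diag(sp)
}

prob_matrix <- function(ed, t) {
  P <- ed$left %*% (exp(ed$values * t) * ed$right)
  P[P < 0] <- 0
  P / rowSums(P)
}
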
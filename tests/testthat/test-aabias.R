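test_that("amino-acid profiles translate, normalize and ignore junk codons", {
  aln <- codonize(nt_alignment(c(a = "ATGAAAAAA", b = "ATGAAAAAA")), "allow")
  p <- amino_acid_frequencies(aln, "a")
  expect_equal(p[["M"]], 1 / 3)
  expect_equal(p[["K"]], 2 / 3)
  expect_equal(sum(p), 1)
  # duplication leaves the profile unchanged
  aln2 <- codonize(nt_alignment(c(a = strrep("ATGAAAAAA", 2),
                                  b = strrep("ATGAAAAAA", 2))), "allow")
  expect_equal(unclass(amino_acid_frequencies(aln2, "a")), unclass(p))
  # gap codons and stops excluded
  aln3 <- codonize(nt_alignment(c(a = "ATG---AAATAA", b = "ATGAAAAAATAA")),
                   "allow")
  p3 <- amino_acid_frequencies(aln3, "a")
  expect_equal(p3[["M"]], 1 / 2)
  expect_equal(p3[["K"]], 1 / 2)
})

test_that("codon usage counts codons per taxon and skips junk", {
  aln <- codonize(nt_alignment(c(a = "ATGAAA---TAA", b = "ATGAAGAAATAA")),
                  "allow")
  cu <- codon_usage(aln)
  expect_equal(cu$a[cu$codon == "ATG"], 1L)
  expect_equal(cu$a[cu$codon == "AAA"], 1L)
  expect_equal(sum(cu$a), 2L)   # gap codon and stop excluded
  expect_equal(sum(cu$b), 3L)
  expect_error(codon_usage(aln, "zz"), "unknown taxon")
})

test_that("the AT-tendency statistic matches a direct rank computation", {
  at <- codon_at_content()
  # perfect monotone profiles
  up <- structure(rank(at) / sum(rank(at)), names = names(at))
  expect_equal(at_tendency(up)$rho, 1)
  down <- structure((21 - rank(at)) / sum(21 - rank(at)), names = names(at))
  expect_equal(at_tendency(down)$rho, -1)
  # hand-built profile with ties: compare against the average-rank
  # Pearson-on-ranks formula computed independently
  set.seed(4)
  f <- structure(round(runif(20), 1), names = names(at))
  f <- f / sum(f)
  rho <- at_tendency(f)$rho
  rf <- rank(f); ra <- rank(at)
  oracle <- sum((rf - mean(rf)) * (ra - mean(ra))) /
    sqrt(sum((rf - mean(rf))^2) * sum((ra - mean(ra))^2))
  expect_equal(rho, oracle, tolerance = 1e-12)
  # scaling before normalization changes nothing
  expect_equal(at_tendency(f * 7 / sum(f * 7))$rho, rho)
  # degenerate ranks
  flat <- structure(rep(1 / 20, 20), names = names(at))
  expect_error(at_tendency(flat), "tendency undefined")
})

test_that("OU fits honour closed forms and limits", {
  # all tip values equal: theta equals that value, tiny sigma2
  tr <- balanced_tree(8, 1, "t")
  y <- stats::setNames(rep(2.5, 8), tr$tip.label)
  pnt <- rep("other", nrow(tr$edge))
  f <- fit_ou(tr, y, pnt, "OU1")
  expect_equal(unname(f$theta), 2.5, tolerance = 1e-6)
  expect_lt(f$sigma2, 1e-6)
  # star tree, strong pull: iid normal ML log-likelihood
  st <- ape::stree(20)
  st$tip.label <- paste0("s", 1:20)
  st$edge.length <- rep(1, 20)
  set.seed(9)
  ys <- stats::setNames(rnorm(20, 3, 0.4), st$tip.label)
  fst <- fit_ou(st, ys, rep("other", 20), "OU1")
  lliid <- sum(dnorm(ys, mean(ys), sqrt(mean((ys - mean(ys))^2)), log = TRUE))
  expect_equal(fst$loglik, lliid, tolerance = 1e-4)
  # alpha -> 0: OU covariance approaches the Brownian covariance
  cache <- plastevol:::ou_tree_cache(tr, pnt)
  C_ou <- plastevol:::ou_covariance(cache, 1e-6)
  C_bm <- ape::vcv(tr)[tr$tip.label, tr$tip.label]
  expect_lt(max(abs(C_ou - C_bm)), 1e-4)
})

test_that("OUM never falls below OU1 and recovers simulated optima", {
  tr <- balanced_tree(32, 0, "t")
  set.seed(3)
  tr$edge.length <- runif(nrow(tr$edge), 0.3, 1)
  painting <- paint_branches(tr, paste0("t", 1:8))
  # nesting on arbitrary data
  for (i in 1:5) {
    s <- simulate_ou_traits(tr, painting, c(ingroup = 0.3, other = 0),
                            alpha = 1, sigma2 = 0.4, seed = 400 + i)
    tt <- regime_shift_test(tr, s$trait, painting)
    expect_gte(tt$fit_oum$loglik, tt$fit_ou1$loglik - 1e-9)
    expect_gte(tt$lrt, 0)
    expect_true(tt$p_value >= 0 && tt$p_value <= 1)
  }
  # recovery of a clear shift (theta 0 vs 1, alpha 2, sigma2 0.5)
  hits <- 0
  for (i in 1:10) {
    s <- simulate_ou_traits(tr, painting, c(ingroup = 1, other = 0),
                            alpha = 2, sigma2 = 0.5, seed = 900 + i)
    f2 <- fit_ou(tr, s$trait, painting, "OUM")
    if (abs(f2$theta[["ingroup"]] - 1) < 0.25 &&
        abs(f2$theta[["other"]] - 0) < 0.25) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("batch regime tests return BH-adjusted q-values", {
  tr <- balanced_tree(16, 0.5, "t")
  painting <- paint_branches(tr, paste0("t", 1:4))
  set.seed(12)
  traits <- sapply(1:4, function(j)
    simulate_ou_traits(tr, painting, c(ingroup = j / 4, other = 0),
                       alpha = 2, sigma2 = 0.3, seed = 50 + j)$trait)
  colnames(traits) <- paste0("v", 1:4)
  out <- regime_shift_batch(tr, traits, painting)
  expect_equal(out$q_value, benjamini_hochberg(out$p_value))
  expect_true(all(out$q_value >= out$p_value - 1e-12))
})
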
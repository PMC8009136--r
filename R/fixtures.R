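# Packaged worked-example data for the Thismia plastome survey: the
# published tree topology (transcribed from the described clades), the
# gene presence/pseudogene/absence pattern, and the printed dN/dS test
# table.

#' Worked-example phylogeny of the Thismia survey
#'
#' The rooted topology of the heterotrophic clade used by the worked
#' examples (unit branch lengths; parsimony only uses the topology).
#'
#' @return an ape `phylo`.
#' @export
thismia_example_tree <- function() {
  ape::read.tree(system.file("extdata", "thismia_fig_tree.nwk",
                             package = "plastevol"))
}

#' Worked-example gene state matrix
#'
#' Gene states (intact / pseudogene / absent / unsampled) for the survey
#' taxa: rps2 is absent in T. hawkesii and T. thaithongiana and
#' pseudogenized in T. hongkongensis; rps18 is absent in T. filiformis,
#' T. alba and T. hexagona and pseudogenized in T. neptunis; rps8 is
#' unobserved in the partial assembly of T. kelabitiana.
#'
#' @return a `gene_matrix`.
#' @export
thismia_gene_states <- function() {
  tab <- utils::read.delim(system.file("extdata",
                                       "thismia_gene_states.tsv",
                                       package = "plastevol"),
                           stringsAsFactors = FALSE)
  st <- as.matrix(tab[, -1L])
  rownames(st) <- tab$taxon
  partial <- c("Thismia_hongkongensis", "Thismia_neptunis",
               "Thismia_kelabitiana", "Thismia_alba", "Thismia_hexagona")
  gene_matrix(st, partial_taxa = partial)
}

#' Taxa with complete plastome assemblies in the worked example
#' @return character vector of 7 taxa.
#' @export
thismia_complete_taxa <- function() {
  c("Thismia_filiformis", "Thismia_gardneriana", "Thismia_hawkesii",
    "Thismia_lanternata", "Thismia_mucronata", "Thismia_puberula",
    "Thismia_thaithongiana")
}

#' Published per-gene dN/dS contrasts and test results
#'
#' The printed branch-model dN/dS estimates for the heterotrophic clade
#' versus its photosynthetic relatives, with the reported p- and
#' q-values (11 tests). Three p-values were printed as 0.00 and carry no
#' recoverable precision; they are `NA` here.
#'
#' @return data.frame: gene, label, omega_thismia, omega_photo, p_value,
#'   q_printed.
#' @export
thismia_dnds_table <- function() {
  utils::read.delim(system.file("extdata", "thismia_dnds_table.tsv",
                                package = "plastevol"),
                    stringsAsFactors = FALSE,
                    colClasses = c(rep("character", 2L),
                                   rep("numeric", 3L), "character"))
}

#' Benjamini-Hochberg worked example on the published p-values
#'
#' Recomputes q-values for the 11 published tests. The three p-values
#' printed as 0.00 are unrecoverable; they enter as synthetic stand-in
#' values chosen only to preserve the published rank order (larger than
#' every recoverable small p-value, smaller than 0.24), which leaves the
#' q-values of all recoverable entries unaffected.
#'
#' Two q columns are reported: `q_value` is the proper step-up adjusted
#' p-value (`min_{j >= i} p_(j) m / j`), and `q_rank` is the per-rank
#' product `p m / rank` before the step-up minimization. They differ
#' only for the smallest p-value of this table (rank 1), where the
#' published table prints the per-rank product.
#'
#' @return the table of [thismia_dnds_table()] with columns `p_used`
#'   (stand-ins marked by `p_standin`), `q_value` and `q_rank`.
#' @export
thismia_bh_worked_example <- function() {
  tab <- thismia_dnds_table()
  standin <- c(accD = 2e-3, rps12 = 1e-5, rps18 = 2e-5)
  tab$p_standin <- is.na(tab$p_value)
  tab$p_used <- ifelse(tab$p_standin, standin[tab$gene], tab$p_value)
  tab$q_value <- benjamini_hochberg(tab$p_used)
  tab$q_rank <- tab$p_used * length(tab$p_used) / rank(tab$p_used)
  tab
}
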
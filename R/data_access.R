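## Accessors for the packaged reference tables: class A GPCR subgroup
## membership with ligand annotations, and the 7TM MSA column map with the
## ten key binding-cavity positions (Ballesteros-Weinstein indexed).

#' Packaged class A GPCR subgroup membership table
#'
#' One row per receptor per subgroup: gene label, natural ligand, its
#' chemical class (`small`, `lipid`, `peptide`, `ion`; `NA` for orphans),
#' orphan status, subgroup-level flags (`N`: fails max pairwise dN < 1;
#' `S`: fails max dS < 3; `o`: contains orphans), and whether the subgroup
#' counts toward the 45 standard subgroups (the derived free-fatty-acid
#' subgroup `13b` does not).
#'
#' @return data.frame as from [read_subgroups()].
#' @export
gpcr_subgroups <- function() {
  read_subgroups(system.file("extdata", "gpcr_subgroups.tsv",
                             package = "siteomega", mustWork = TRUE))
}

#' Packaged 7TM key-position map
#'
#' MSA codon columns with known Ballesteros-Weinstein indices; the ten
#' binding-cavity key positions are flagged (`is_key`).
#'
#' @return data.frame as from [read_position_map()].
#' @export
gpcr_key_positions <- function() {
  read_position_map(system.file("extdata", "key_positions.tsv",
                                package = "siteomega", mustWork = TRUE))
}
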
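## Alignment I/O and assembly: protein MSA reading, back-translation to a codon
## alignment, position maps (Ballesteros-Weinstein labels + key flags), and
## subgroup membership tables with ligand-category classification.

#' Read a protein multiple sequence alignment from FASTA
#'
#' All records must share the aligned length. Residues are upper-cased and the
#' gap character `-` is preserved.
#'
#' @param path Path to an aligned protein FASTA file.
#' @return A character matrix (sequences x columns) of single residues, with
#'   row names taken from the FASTA headers.
#' @export
read_protein_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) stop("alignment-format error: no records in ", path)
  w <- Biostrings::width(aa)
  if (length(unique(w)) != 1)
    stop("alignment-format error: ragged record lengths (",
         paste(unique(w), collapse = ", "), ")")
  labels <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(labels))
    stop("duplicate FASTA labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  m <- do.call(rbind, strsplit(toupper(as.character(aa)), ""))
  rownames(m) <- labels
  bad <- setdiff(unique(as.vector(m)), c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-", "X"))
  if (length(bad))
    stop("content error: non-amino-acid symbol(s): ", paste(bad, collapse = ", "))
  m
}

#' Read unaligned coding sequences from FASTA
#'
#' @param path Path to a nucleotide FASTA file.
#' @return Named character vector of uppercase nucleotide sequences.
#' @export
read_cds <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dna <- Biostrings::readDNAStringSet(path)
  labels <- sub("\\s.*$", "", names(dna))
  if (anyDuplicated(labels))
    stop("duplicate FASTA labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  out <- toupper(as.character(dna))
  names(out) <- labels
  out
}

#' Assemble a codon alignment by back-translating a protein alignment
#'
#' Each residue column of the protein alignment is replaced by the codon that
#' encodes it in the corresponding coding sequence. A translation cross-check
#' is enforced: the CDS must translate (standard code) to the ungapped protein
#' row, otherwise a back-translation error names the label and position.
#' Codons containing ambiguous nucleotides become gaps (missing data).
#'
#' @param aa_alignment Character matrix from [read_protein_alignment()].
#' @param cds_records Named nucleotide sequences from [read_cds()]; names must
#'   cover the alignment row names.
#' @return A `codon_alignment`: list with `codons` (character matrix of codon
#'   triplets, `"---"` for gaps), `labels`, and `column_count`.
#' @export
build_codon_alignment <- function(aa_alignment, cds_records) {
  if (is.character(aa_alignment) && is.null(dim(aa_alignment)))
    aa_alignment <- matrix(aa_alignment, nrow = 1,
                           dimnames = list(names(aa_alignment), NULL))
  labels <- rownames(aa_alignment)
  if (is.null(labels)) stop("aa_alignment must have row names (labels)")
  missing <- setdiff(labels, names(cds_records))
  if (length(missing)) stop("no CDS for: ", paste(missing, collapse = ", "))
  tabs <- codon_tables()
  ncol_aln <- ncol(aa_alignment)
  codons <- matrix("---", nrow = length(labels), ncol = ncol_aln,
                   dimnames = list(labels, NULL))
  for (lab in labels) {
    row <- aa_alignment[lab, ]
    cds <- cds_records[[lab]]
    if (nchar(cds) %% 3 != 0)
      stop("content error: CDS length of ", lab, " not a multiple of 3")
    cvec <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    ## trailing stop codon is tolerated and dropped
    if (length(cvec) && cvec[length(cvec)] %in% tabs$stop_codons)
      cvec <- cvec[-length(cvec)]
    idx <- which(row != "-")
    if (length(cvec) != length(idx))
      stop("back-translation error: ", lab, ": CDS encodes ", length(cvec),
           " residues but protein row has ", length(idx))
    if (length(idx) == 0) next
    aa_from_cds <- translate_codons(cvec)
    ambiguous <- is.na(aa_from_cds) & !(cvec %in% tabs$stop_codons)
    internal_stop <- cvec %in% tabs$stop_codons
    if (any(internal_stop))
      stop("content error: internal stop codon in ", lab,
           " at aligned column ", idx[which(internal_stop)[1]])
    ok <- ambiguous | aa_from_cds == row[idx] |
      (row[idx] == "X" & !internal_stop)
    if (!all(ok))
      stop("back-translation error: ", lab, " at aligned column ",
           idx[which(!ok)[1]], ": codon ", cvec[which(!ok)[1]],
           " encodes ", aa_from_cds[which(!ok)[1]], " not ", row[idx][which(!ok)[1]])
    cvec[ambiguous] <- "---"
    codons[lab, idx] <- cvec
  }
  structure(list(codons = codons, labels = labels, column_count = ncol_aln),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment:", length(x$labels), "sequences x", x$column_count,
      "codon columns\n")
  gaps <- mean(x$codons == "---")
  cat(sprintf("  gap fraction %.3f; labels: %s%s\n", gaps,
              paste(utils::head(x$labels, 4), collapse = ", "),
              if (length(x$labels) > 4) ", ..." else ""))
  invisible(x)
}

## Validate a codon_alignment for model fitting: >=3 sequences, all non-gap
## cells sense codons.
validate_codon_alignment <- function(x, min_seq = 3) {
  stopifnot(inherits(x, "codon_alignment"))
  if (length(x$labels) < min_seq)
    stop("alignment has ", length(x$labels), " sequences; need >= ", min_seq)
  cells <- unique(as.vector(x$codons))
  bad <- setdiff(cells, c(codon_tables()$codons, "---"))
  if (length(bad))
    stop("content error: non-sense-codon cell(s): ", paste(bad, collapse = ", "))
  invisible(x)
}

#' Read a position map (MSA column to Ballesteros-Weinstein index)
#'
#' @param path TSV with header columns `column_index` (1-based MSA codon
#'   column), `bw_index` (Ballesteros-Weinstein label such as "3.29", may be
#'   empty), `is_key` (logical/0-1).
#' @return data.frame with those columns, `is_key` logical.
#' @export
read_position_map <- function(path) {
  pm <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(bw_index = "character"))
  need <- c("column_index", "bw_index", "is_key")
  if (!all(need %in% names(pm)))
    stop("position map must have columns: ", paste(need, collapse = ", "))
  pm$is_key <- as.logical(pm$is_key) | pm$is_key == 1
  bw <- pm$bw_index[!is.na(pm$bw_index) & nzchar(pm$bw_index)]
  if (anyDuplicated(bw))
    stop("duplicate Ballesteros-Weinstein indices in position map")
  pm
}

#' Key columns of a position map
#' @param position_map data.frame from [read_position_map()].
#' @return Integer vector of 1-based MSA codon columns flagged as key.
#' @export
key_columns <- function(position_map) {
  sort(position_map$column_index[position_map$is_key])
}

#' Read a subgroup membership table
#'
#' @param path TSV with header columns `subgroup_id`, `label`, `ligand`,
#'   `class` (chemical class of the member's natural ligand; empty for
#'   orphans), `orphan` (0/1), and optionally `flags` and `included`.
#' @return data.frame, one row per member.
#' @export
read_subgroups <- function(path) {
  sg <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("subgroup_id", "label", "class", "orphan")
  if (!all(need %in% names(sg)))
    stop("subgroup table must have columns: ", paste(need, collapse = ", "))
  sg$orphan <- as.logical(sg$orphan) | sg$orphan == 1
  if (is.null(sg$included)) sg$included <- TRUE else
    sg$included <- as.logical(sg$included) | sg$included == 1
  sg
}

#' Classify a subgroup by the chemical class of its natural ligands
#'
#' Rules, applied in order: if every member is an orphan the subgroup is
#' `orphan`; if more than two members are orphans, or the non-orphan members'
#' ligand chemical classes are not unanimous, it is `divergent`; otherwise the
#' unanimous class is returned.
#'
#' @param classes Character vector of per-member ligand chemical classes
#'   (e.g. "small", "lipid", "peptide", "ion"); `NA` for orphans.
#' @param orphan Logical vector, same length: is the member an orphan?
#' @return One of `"small"`, `"lipid"`, `"peptide"`, `"divergent"`, `"orphan"`.
#' @export
classify_subgroup <- function(classes, orphan = is.na(classes)) {
  stopifnot(length(classes) == length(orphan))
  if (any(!orphan & is.na(classes)))
    stop("classification error: non-orphan member without ligand annotation")
  if (all(orphan)) return("orphan")
  if (sum(orphan) > 2) return("divergent")
  cls <- unique(classes[!orphan])
  if (length(cls) > 1) return("divergent")
  cls
}

#' Ligand-category table over a subgroup membership table
#'
#' @param subgroups data.frame from [read_subgroups()].
#' @return data.frame with one row per included subgroup: `subgroup_id`,
#'   `n_members`, `n_orphans`, `category`.
#' @export
classify_subgroups <- function(subgroups) {
  sg <- subgroups[subgroups$included, , drop = FALSE]
  ids <- unique(sg$subgroup_id)
  out <- lapply(ids, function(id) {
    rows <- sg[sg$subgroup_id == id, , drop = FALSE]
    data.frame(subgroup_id = id, n_members = nrow(rows),
               n_orphans = sum(rows$orphan),
               category = classify_subgroup(rows$class, rows$orphan),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Translate a codon alignment back to a protein alignment
#' @param x A `codon_alignment`.
#' @return Character matrix of residues with `-` gaps.
#' @export
translate_alignment <- function(x) {
  stopifnot(inherits(x, "codon_alignment"))
  m <- x$codons
  out <- matrix("-", nrow(m), ncol(m), dimnames = dimnames(m))
  nz <- m != "---"
  out[nz] <- translate_codons(m[nz])
  out
}

#' Write sequences to FASTA
#' @param seqs Named character vector of sequences (one string per record).
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    cat(">", nm, "\n", sep = "", file = con)
    s <- seqs[[nm]]
    starts <- seq(1, max(nchar(s), 1), width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}
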
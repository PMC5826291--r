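# FG-domain sequence handling: built-in Nsp1 / Nsp1-S constructs, FASTA I/O,
# the serine (SG) mutation, segment extraction and composition metrics.

.aa_codes <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# average (isotopically averaged) residue masses, Da; water added once per chain
.aa_residue_mass <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
.water_mass <- 18.0153

#' Construct a protein sequence object
#'
#' A `nup_sequence` holds an ordered string of one-letter amino-acid codes plus
#' the terminus used for surface attachment (Nsp1 constructs anchor through a
#' C-terminal cysteine).
#'
#' @param residues character scalar of one-letter codes (whitespace stripped,
#'   uppercased)
#' @param id short label
#' @param anchor_terminus `"C"` or `"N"`
#' @return an object of class `nup_sequence`
#' @export
nup_sequence <- function(residues, id = "seq", anchor_terminus = c("C", "N")) {
  anchor_terminus <- match.arg(anchor_terminus)
  residues <- toupper(gsub("[[:space:]]", "", residues))
  if (nchar(residues) < 1L) abort("sequence must contain at least one residue")
  chars <- strsplit(residues, "")[[1]]
  bad <- which(!chars %in% .aa_codes)
  if (length(bad) > 0L) {
    abort(sprintf(
      "illegal residue code '%s' at position %d (only the 20 canonical one-letter codes are allowed)",
      chars[bad[1]], bad[1]
    ))
  }
  structure(
    list(id = id, residues = residues, anchor_terminus = anchor_terminus),
    class = "nup_sequence"
  )
}

#' @export
print.nup_sequence <- function(x, ...) {
  cat(sprintf(
    "<nup_sequence> %s: %d aa, %s-terminal anchor, MW %.1f kDa\n",
    x$id, seq_length(x), x$anchor_terminus, molecular_weight(x) / 1000
  ))
  invisible(x)
}

#' @export
length.nup_sequence <- function(x) nchar(x$residues)

#' Sequence length (number of residues)
#' @param seq a [nup_sequence()]
#' @return integer length
#' @export
seq_length <- function(seq) nchar(seq$residues)

seq_chars <- function(seq) strsplit(seq$residues, "")[[1]]

#' Molecular weight from summed average residue masses
#'
#' @param seq a [nup_sequence()]
#' @return molecular weight in Da (one water added for the chain termini)
#' @export
molecular_weight <- function(seq) {
  sum(.aa_residue_mass[seq_chars(seq)]) + .water_mass
}

#' Load a built-in FG-domain construct
#'
#' Returns the wildtype Nsp1 purification construct (637 aa: His-tag/TEV
#' leader, FG domain, C-terminal cysteine for maleimide attachment) or the
#' Nsp1-S serine mutant (638 aa; the mutant retains the leader unmutated and
#' carries one extra serine at position 635, a gene-synthesis artefact).
#'
#' @param name `"Nsp1"` or `"Nsp1-S"`
#' @return a [nup_sequence()] with a C-terminal anchor
#' @export
load_builtin <- function(name = c("Nsp1", "Nsp1-S")) {
  name <- match.arg(name)
  res <- switch(name, "Nsp1" = .nsp1_residues, "Nsp1-S" = .nsp1s_residues)
  nup_sequence(res, id = name, anchor_terminus = "C")
}

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readAAStringSet()]; records are uppercased
#' and validated against the 20 canonical codes.
#'
#' @param path FASTA file path
#' @param anchor_terminus anchor terminus assigned to every record
#' @return list of [nup_sequence()] objects, input order preserved
#' @export
read_fasta <- function(path, anchor_terminus = "C") {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) abort(sprintf("no FASTA records found in '%s'", path))
  purrr::map2(
    as.character(set), names(set),
    function(res, nm) nup_sequence(res, id = nm, anchor_terminus = anchor_terminus)
  ) |> unname()
}

#' Write sequences to a FASTA file
#'
#' @param seqs a [nup_sequence()] or list of them
#' @param path output file
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "nup_sequence")) seqs <- list(seqs)
  set <- Biostrings::AAStringSet(vapply(seqs, function(s) s$residues, character(1)))
  names(set) <- vapply(seqs, function(s) s$id, character(1))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Replace the hydrophobic residues F, I, L, V by serine
#'
#' The SG mutation converts FG/FxFG motifs to SG/SxSG by replacing every
#' phenylalanine, isoleucine, leucine and valine with serine. `from` restricts
#' the mutation to positions `>= from`; the engineered Nsp1-S construct keeps
#' its 33-residue purification leader (His-tag and TEV site) unmutated, which
#' corresponds to `from = 34`.
#'
#' @param seq a [nup_sequence()]
#' @param from first 1-based position subject to mutation (default 1: whole
#'   sequence)
#' @return mutated [nup_sequence()] of identical length
#' @export
sg_mutate <- function(seq, from = 1L) {
  head <- if (from > 1L) substr(seq$residues, 1L, from - 1L) else ""
  tail <- substr(seq$residues, from, seq_length(seq))
  mutated <- paste0(head, chartr("FILV", "SSSS", tail))
  nup_sequence(mutated, id = paste0(seq$id, "-SG"), anchor_terminus = seq$anchor_terminus)
}

#' Extract a contiguous segment of a sequence
#'
#' @param seq a [nup_sequence()]
#' @param first,last 1-based inclusive bounds
#' @return a [nup_sequence()] labelled `id[first-last]`
#' @export
seq_segment <- function(seq, first, last) {
  n <- seq_length(seq)
  if (first < 1L || last > n || first > last) {
    abort(sprintf("invalid segment [%d, %d] for sequence of length %d", first, last, n))
  }
  nup_sequence(
    substr(seq$residues, first, last),
    id = sprintf("%s[%d-%d]", seq$id, first, last),
    anchor_terminus = seq$anchor_terminus
  )
}

#' Default residue classification sets
#'
#' Charged: D, E, K, R (histidine treated neutral at pH 7.4). Hydrophobic:
#' A, C, F, I, L, M, V, W, Y. Both sets are arguments of [seq_composition()]
#' and can be overridden.
#'
#' @name residue_sets
#' @export
charged_residues <- c("D", "E", "K", "R")

#' @rdname residue_sets
#' @export
hydrophobic_residues <- c("A", "C", "F", "I", "L", "M", "V", "W", "Y")

#' Residue composition metrics
#'
#' Per-residue counts, charged and hydrophobic totals, their ratio, and the
#' molecular weight. The charged/hydrophobic ratio distinguishes cohesive
#' low-charge FG domains (Nup98-like, ~0.2) from Nsp1 (~0.9) and its serine
#' mutant (higher still).
#'
#' @param seq a [nup_sequence()]
#' @param charged_set,hydrophobic_set residue code character vectors; the two
#'   sets must be disjoint
#' @return a one-row tibble: `id`, `length`, `n_charged`, `n_hydrophobic`,
#'   `ratio_charged_over_hydrophobic` (NA when no hydrophobic residues),
#'   `molecular_weight`, and a `counts` list-column (named integer vector over
#'   the 20 codes)
#' @export
seq_composition <- function(seq,
                            charged_set = charged_residues,
                            hydrophobic_set = hydrophobic_residues) {
  if (length(intersect(charged_set, hydrophobic_set)) > 0L) {
    abort("charged_set and hydrophobic_set must be disjoint")
  }
  chars <- seq_chars(seq)
  counts <- table(factor(chars, levels = .aa_codes))
  counts <- stats::setNames(as.integer(counts), .aa_codes)
  n_ch <- sum(counts[charged_set])
  n_hp <- sum(counts[hydrophobic_set])
  ratio <- if (n_hp > 0L) n_ch / n_hp else NA_real_
  if (n_hp == 0L) warn(sprintf("'%s' has no hydrophobic residues: ratio undefined", seq$id))
  tibble(
    id = seq$id,
    length = length(chars),
    n_charged = n_ch,
    n_hydrophobic = n_hp,
    ratio_charged_over_hydrophobic = ratio,
    molecular_weight = molecular_weight(seq),
    counts = list(counts)
  )
}
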
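#' Extract non-tryptic cleavage sites from peptide evidence
#'
#' In a tryptic digest every peptide boundary should follow Lys/Arg not
#' followed by Pro; a boundary violating that specificity is evidence of
#' another protease's action (semi-/non-tryptic terminus). For each peptide
#' located in its protein, both termini are examined: an N-terminal boundary
#' at protein position `j` (peptide starts at `j + 1`) is non-tryptic iff
#' `j >= 1` and NOT (`sequence[j]` in `{K, R}` and `sequence[j + 1] != P`);
#' a C-terminal boundary at position `e` (peptide ends at `e`) is
#' non-tryptic iff `e <= L - 1` and NOT (`sequence[e]` in `{K, R}` and
#' `sequence[e + 1] != P`). Protein N/C termini are never sites. A Lys/Arg
#' boundary followed by Pro counts as non-tryptic (literal application of
#' the trypsin rule).
#'
#' Peptides not found in their named protein, or matching at multiple
#' positions, are excluded and recorded in the `"skipped"` attribute.
#'
#' @param peptide_hits `data.frame` with columns `protein_id`, `peptide`.
#' @param proteins Named list of [protein_record()]s.
#' @param protease Protease identifier assigned to the emitted annotations
#'   (default `"MMP9"`, the enzyme such semi-tryptic evidence is typically
#'   attributed to in an MMP9 digest).
#' @return Deduplicated annotation `data.frame` with `source =
#'   "experiment"`; attribute `"skipped"` reports excluded peptides with a
#'   reason (`not_found` / `ambiguous` / `unknown_protein`).
#' @examples
#' prot <- list(p = protein_record("p", "MAKSLNGFAR"))
#' hits <- data.frame(protein_id = "p", peptide = "LNGFAR")
#' nontryptic_sites(hits, prot)$p1  # 4: the boundary after Ser4 is not tryptic
#' @export
nontryptic_sites <- function(peptide_hits, proteins, protease = "MMP9") {
  out <- empty_annotations()
  skipped <- data.frame(protein_id = character(0), peptide = character(0),
                        reason = character(0), stringsAsFactors = FALSE)
  skip <- function(pid, pep, why) {
    skipped[nrow(skipped) + 1L, ] <<- list(pid, pep, why)
  }
  tryptic_boundary <- function(res, pos, L) {
    res[pos] %in% c("K", "R") && pos + 1L <= L && res[pos + 1L] != "P"
  }
  sites <- list()
  for (i in seq_len(nrow(peptide_hits))) {
    pid <- peptide_hits$protein_id[i]
    pep <- peptide_hits$peptide[i]
    if (!pid %in% names(proteins)) { skip(pid, pep, "unknown_protein"); next }
    p <- proteins[[pid]]
    # matchPattern reports overlapping occurrences, which gregexpr would miss
    m <- Biostrings::start(Biostrings::matchPattern(pep, p$sequence))
    if (length(m) == 0L) { skip(pid, pep, "not_found"); next }
    if (length(m) > 1L) { skip(pid, pep, "ambiguous"); next }
    s <- as.integer(m)
    e <- s + nchar(pep) - 1L
    res <- residues(p)
    j <- s - 1L
    if (j >= 1L && !tryptic_boundary(res, j, p$length)) {
      sites[[length(sites) + 1L]] <- c(pid, j)
    }
    if (e <= p$length - 1L && !tryptic_boundary(res, e, p$length)) {
      sites[[length(sites) + 1L]] <- c(pid, e)
    }
  }
  if (length(sites) > 0L) {
    df <- unique(data.frame(protein_id = vapply(sites, `[`, character(1), 1L),
                            p1 = as.integer(vapply(sites, `[`, character(1), 2L)),
                            stringsAsFactors = FALSE))
    out <- data.frame(protease = protease, protein_id = df$protein_id,
                      p1 = df$p1, source = "experiment", score = NA_real_,
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Cleavage-density map
#'
#' Counts annotated sites per fixed-width residue window along the protein
#' (default 50 residues), the representation used for cleavage-density heat
#' maps. Bin `b` counts sites with P1 in `[(b-1)*window + 1, b*window]`; the
#' last bin is truncated at `L - 1`.
#'
#' @param annotations Annotation `data.frame` (rows for other proteins are
#'   ignored).
#' @param protein A [protein_record()].
#' @param window Bin width in residues (default 50).
#' @return Integer vector of per-bin site counts covering `1 .. L - 1`.
#' @examples
#' p <- generate_protein(150, seed = 1, id = "p")
#' ann <- data.frame(protein_id = "p", p1 = c(10, 60, 70))
#' cleavage_density(ann, p)  # 1 2 0
#' @export
cleavage_density <- function(annotations, protein, window = 50L) {
  stopifnot(window >= 1L)
  p1 <- annotations$p1[annotations$protein_id == protein$id]
  if (any(p1 < 1L | p1 > protein$length - 1L)) {
    stop("annotation p1 outside [1, L-1] for protein '", protein$id, "'")
  }
  n_bins <- max(1L, as.integer(ceiling((protein$length - 1L) / window)))
  tabulate(ceiling(p1 / window), nbins = n_bins)
}
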
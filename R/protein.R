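#' Protein record
#'
#' Container for one protein: identifier, amino-acid sequence, optional
#' disulfide pairs and optional per-residue structural features. Residue
#' coordinates are 1-based; a cleavage site is named by the index of its P1
#' residue, so the scissile bond lies between residues `p1` and `p1 + 1`.
#'
#' Non-standard residue letters (B, J, O, U, X, Z, ...) are retained in the
#' sequence but flagged in `$nonstandard`; the encoder maps them to an
#' all-zero amino-acid block, the same convention used for terminal padding.
#'
#' @param id Identifier (first whitespace-delimited token is used when read
#'   from FASTA headers).
#' @param sequence Amino-acid sequence string; uppercased on construction.
#' @param disulfide_pairs Optional two-column matrix or data.frame of 1-based
#'   residue index pairs; both members of a pair must be cysteines and no
#'   residue may appear in two pairs.
#' @param features Optional per-residue structural feature `data.frame` as
#'   returned by [simulate_structure()] or read with [read_feature_table()]:
#'   columns `pos`, `ss` (coil/strand/helix), `exposure` (exposed/buried),
#'   `disorder` (logical), `x`, `y`, `z`.
#' @return An object of class `protein_record` with fields `id`, `sequence`,
#'   `length`, `disulfide_pairs`, `features`, `nonstandard`.
#' @examples
#' p <- protein_record("P1", "MKWCAC", disulfide_pairs = cbind(4, 6))
#' p$length
#' @export
protein_record <- function(id, sequence, disulfide_pairs = NULL, features = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L < 1L) stop("protein '", id, "': sequence must have at least one residue")
  if (grepl("[^A-Z]", sequence)) {
    stop("protein '", id, "': sequence contains non-letter characters")
  }
  res <- strsplit(sequence, "")[[1]]
  nonstd <- which(!res %in% AA_STANDARD)

  if (!is.null(disulfide_pairs)) {
    dp <- as.matrix(disulfide_pairs)
    if (ncol(dp) != 2L) stop("disulfide_pairs must have two columns")
    storage.mode(dp) <- "integer"
    if (nrow(dp) > 0L) {
      idx <- as.vector(dp)
      if (any(idx < 1L | idx > L)) {
        stop("protein '", id, "': disulfide index outside [1, ", L, "]")
      }
      if (any(res[idx] != "C")) {
        stop("protein '", id, "': disulfide index does not point at a cysteine")
      }
      if (anyDuplicated(idx)) {
        stop("protein '", id, "': a residue appears in two disulfide pairs")
      }
      # canonical order: smaller index first, rows sorted
      dp <- t(apply(dp, 1L, sort))
      dp <- dp[order(dp[, 1L]), , drop = FALSE]
    }
    colnames(dp) <- c("cys_a", "cys_b")
    disulfide_pairs <- dp
  }

  rec <- structure(
    list(id = id, sequence = sequence, length = L,
         disulfide_pairs = disulfide_pairs, features = NULL,
         nonstandard = nonstd),
    class = "protein_record"
  )
  if (!is.null(features)) rec$features <- validate_features(rec, features)
  rec
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record> ", x$id, ": ", x$length, " aa",
      if (!is.null(x$disulfide_pairs)) paste0(", ", nrow(x$disulfide_pairs), " disulfide pair(s)"),
      if (!is.null(x$features)) ", structural features attached",
      "\n", sep = "")
  invisible(x)
}

# check a structural feature table covers every residue with legal values
validate_features <- function(protein, features) {
  req <- c("pos", "ss", "exposure", "disorder", "x", "y", "z")
  if (!all(req %in% names(features))) {
    stop("feature table must have columns: ", paste(req, collapse = ", "))
  }
  features <- features[order(features$pos), req]
  if (!identical(as.integer(features$pos), seq_len(protein$length))) {
    stop("protein '", protein$id, "': features must cover every residue exactly once")
  }
  if (!all(features$ss %in% c("coil", "strand", "helix"))) {
    stop("ss values must be coil, strand or helix")
  }
  if (!all(features$exposure %in% c("exposed", "buried"))) {
    stop("exposure values must be exposed or buried")
  }
  features$disorder <- as.logical(features$disorder)
  if (anyNA(features$disorder)) stop("disorder values must be logical")
  rownames(features) <- NULL
  features
}

#' Residue characters of a protein
#' @param protein A [protein_record()].
#' @return Character vector of length `protein$length`.
#' @export
residues <- function(protein) strsplit(protein$sequence, "")[[1]]

#' Candidate cleavage sites of a protein
#'
#' Every inter-residue bond is a candidate site: P1 indices `1 .. L - 1`.
#' The negative class for a protease is this set minus its annotated
#' positives.
#'
#' @param protein A [protein_record()].
#' @return Integer vector of candidate P1 indices (empty when `L < 2`).
#' @examples
#' candidate_sites(protein_record("p", "MKWSA"))  # 1 2 3 4
#' @export
candidate_sites <- function(protein) {
  if (protein$length < 2L) return(integer(0))
  seq_len(protein$length - 1L)
}
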
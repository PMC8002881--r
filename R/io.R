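#' Read protein sequences from a FASTA file
#'
#' Parses with Biostrings and returns one [protein_record()] per entry, in
#' file order. The record id is the first whitespace-delimited token of the
#' header; sequences are uppercased. A header with no sequence is a parse
#' error naming the offending line.
#'
#' @param path Path to a FASTA file.
#' @return Named list of [protein_record()] objects.
#' @seealso [write_fasta()], [attach_disulfides()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no FASTA records in ", path)
  # a header immediately followed by another header (or EOF) has no sequence
  nxt <- c(hdr[-1L], length(lines) + 1L)
  bad <- hdr[nxt - hdr <= 1L |
               vapply(seq_along(hdr),
                      function(i) all(!nzchar(trimws(lines[seq(hdr[i] + 1L, nxt[i] - 1L)]))),
                      logical(1))]
  if (length(bad) > 0L) {
    stop("FASTA parse error in ", path, ": record without sequence at line ", bad[1L])
  }
  seqs <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  recs <- lapply(seq_along(seqs), function(i) {
    protein_record(ids[i], as.character(seqs[[i]]))
  })
  names(recs) <- ids
  recs
}

#' Write protein sequences to a FASTA file
#'
#' @param proteins List of [protein_record()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  set <- Biostrings::AAStringSet(vapply(proteins, function(p) p$sequence, character(1)))
  names(set) <- vapply(proteins, function(p) p$id, character(1))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(path, ": missing required column(s): ", paste(missing, collapse = ", "))
  }
  df
}

#' Read a cleavage-site annotation table
#'
#' Loads a normalized three-column TSV of experimentally validated cleavage
#' sites (the shape used for MEROPS- and Eckhard-style substrate exports):
#' `protease`, `protein_id`, `p1` (1-based P1 residue index; the scissile
#' bond lies between `p1` and `p1 + 1`). Rows whose protease is not in the
#' registry are rejected and reported via the `"rejected"` attribute;
#' duplicate `(protease, protein_id, p1)` rows are deduplicated. When
#' `proteins` is supplied every `p1` is validated against `1 .. L - 1`.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param registry Protease registry (default [protease_registry()]).
#' @param proteins Optional named list of [protein_record()]s for index
#'   validation.
#' @param source Source tag stored on the annotations (default `"database"`).
#' @return A `data.frame` with columns `protease`, `protein_id`, `p1`,
#'   `source`, `score`; attribute `"rejected"` holds rejected rows.
#' @export
read_cleavage_table <- function(path, registry = protease_registry(),
                                proteins = NULL, source = "database") {
  df <- read_tsv_checked(path, c("protease", "protein_id", "p1"))
  df$p1 <- as.integer(df$p1)
  known <- df$protease %in% registry$protease
  rejected <- df[!known, , drop = FALSE]
  if (nrow(rejected) > 0L) {
    message(nrow(rejected), " row(s) rejected: protease not in registry (",
            paste(unique(rejected$protease), collapse = ", "), ")")
  }
  df <- df[known, , drop = FALSE]
  df <- df[!duplicated(df[, c("protease", "protein_id", "p1")]), , drop = FALSE]
  if (!is.null(proteins)) {
    len <- vapply(proteins, function(p) p$length, integer(1))
    L <- len[df$protein_id]
    bad <- which(is.na(L) | df$p1 < 1L | df$p1 > L - 1L)
    if (length(bad) > 0L) {
      stop("invalid cleavage annotations (p1 outside [1, L-1] or unknown protein) ",
           "in rows: ", paste(head(bad, 20L), collapse = ", "))
    }
  }
  ann <- data.frame(protease = df$protease, protein_id = df$protein_id,
                    p1 = df$p1, source = source, score = NA_real_,
                    stringsAsFactors = FALSE)
  rownames(ann) <- NULL
  attr(ann, "rejected") <- rejected
  ann
}

#' Write a cleavage-site annotation table
#' @param annotations Annotation `data.frame` (columns `protease`,
#'   `protein_id`, `p1` at minimum).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cleavage_table <- function(annotations, path) {
  cols <- intersect(c("protease", "protein_id", "p1", "source", "score"),
                    names(annotations))
  write.table(annotations[, cols, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read disulfide-pair annotations and attach them to proteins
#'
#' The TSV has columns `protein_id`, `cys_a`, `cys_b` (1-based cysteine
#' indices of each disulfide bond).
#'
#' @param path Path to the TSV.
#' @return A `data.frame` of pairs.
#' @export
read_disulfide_table <- function(path) {
  df <- read_tsv_checked(path, c("protein_id", "cys_a", "cys_b"))
  df$cys_a <- as.integer(df$cys_a)
  df$cys_b <- as.integer(df$cys_b)
  df
}

#' @rdname read_disulfide_table
#' @param proteins Named list of [protein_record()]s.
#' @param pairs `data.frame` from `read_disulfide_table()`.
#' @return `attach_disulfides()`: the protein list with validated
#'   `disulfide_pairs` set.
#' @export
attach_disulfides <- function(proteins, pairs) {
  for (id in unique(pairs$protein_id)) {
    if (!id %in% names(proteins)) stop("disulfide table names unknown protein: ", id)
    sub <- pairs[pairs$protein_id == id, c("cys_a", "cys_b")]
    p <- proteins[[id]]
    proteins[[id]] <- protein_record(p$id, p$sequence,
                                     disulfide_pairs = as.matrix(sub),
                                     features = p$features)
  }
  proteins
}

#' Read a peptide-identification table
#'
#' Columns `protein_id`, `peptide`: peptides identified (e.g. by LC-MS/MS
#' database search) and assigned to a protein. Used for non-tryptic
#' cleavage-site extraction.
#'
#' @param path Path to the TSV.
#' @return A `data.frame` with columns `protein_id`, `peptide`.
#' @export
read_peptide_table <- function(path) {
  df <- read_tsv_checked(path, c("protein_id", "peptide"))
  if (any(!nzchar(df$peptide))) stop(path, ": empty peptide sequence")
  df[, c("protein_id", "peptide")]
}

#' Read a per-residue structural feature table
#'
#' File-backed counterpart of the structure simulator: one row per residue
#' with secondary-structure class, burial, disorder flag and 3D coordinates
#' (the shape produced by running PSIPRED/DISOPRED2/ACCPRO/SCRATCH-style
#' annotators externally). Columns: `protein_id`, `pos`, `ss`, `exposure`,
#' `disorder`, `x`, `y`, `z`.
#'
#' @param path Path to the TSV.
#' @return A `data.frame` of per-residue features.
#' @export
read_feature_table <- function(path) {
  df <- read_tsv_checked(path, c("protein_id", "pos", "ss", "exposure",
                                 "disorder", "x", "y", "z"))
  df$pos <- as.integer(df$pos)
  df$disorder <- as.logical(df$disorder)
  df
}

#' Read / write cleavage-score tables
#'
#' Score tables carry one row per scored candidate site: `protein_id`, `p1`,
#' `score` in \[0, 1\]. The same shape is used for this package's ensemble
#' predictions and for external predictor exports, so any such file can be
#' evaluated with [evaluate_predictor()].
#'
#' @param path Path to the TSV.
#' @return `read_score_table()`: a `data.frame` with columns `protein_id`,
#'   `p1`, `score`.
#' @export
read_score_table <- function(path) {
  df <- read_tsv_checked(path, c("protein_id", "p1", "score"))
  df$p1 <- as.integer(df$p1)
  df$score <- as.numeric(df$score)
  df[, c("protein_id", "p1", "score")]
}

#' @rdname read_score_table
#' @param scores Score `data.frame`.
#' @return `write_score_table()`: `path`, invisibly.
#' @export
write_score_table <- function(scores, path) {
  write.table(scores[, c("protein_id", "p1", "score")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
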
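#' Feature providers
#'
#' A feature provider is a function `protein -> per-residue feature
#' data.frame` (or `NULL` for no structural information). Three
#' implementations are supplied:
#'
#' * `zero_provider()` - no structural information; the secondary-structure,
#'   exposure, disorder and coordinate blocks of every window are all zero.
#' * `stored_provider()` - uses the features already attached to the
#'   [protein_record()] (as produced by [generate_dataset()]); errors when a
#'   protein has none.
#' * `file_provider(x)` - backed by a precomputed per-residue feature table
#'   (path or `data.frame`, see [read_feature_table()]), the route for
#'   externally computed structure annotations.
#' * `simulated_provider(seed, ...)` - simulates features on the fly with
#'   [simulate_structure()], deterministically per protein id.
#'
#' @return A provider function.
#' @name feature_providers
NULL

#' @rdname feature_providers
#' @export
zero_provider <- function() {
  function(protein) NULL
}

#' @rdname feature_providers
#' @export
stored_provider <- function() {
  function(protein) {
    if (is.null(protein$features)) {
      stop("protein '", protein$id, "' has no stored structural features")
    }
    protein$features
  }
}

#' @rdname feature_providers
#' @param x Path to a feature TSV or a `data.frame` from
#'   [read_feature_table()].
#' @export
file_provider <- function(x) {
  tab <- if (is.character(x)) read_feature_table(x) else x
  function(protein) {
    sub <- tab[tab$protein_id == protein$id, , drop = FALSE]
    if (nrow(sub) == 0L) {
      stop("feature table has no rows for protein '", protein$id, "'")
    }
    validate_features(protein, sub[, c("pos", "ss", "exposure", "disorder",
                                       "x", "y", "z")])
  }
}

#' @rdname feature_providers
#' @param seed Base seed; each protein uses `seed` offset by a hash of its
#'   id so features are deterministic per protein.
#' @param ... Passed to [simulate_structure()].
#' @export
simulated_provider <- function(seed = 0L, ...) {
  args <- list(...)
  function(protein) {
    off <- sum(utf8ToInt(protein$id) * seq_along(utf8ToInt(protein$id)))
    s <- (as.integer(seed) + off) %% (.Machine$integer.max - 1L)
    do.call(simulate_structure, c(list(protein = protein, seed = s), args))
  }
}

# feature block layout: 20 AA one-hot + 3 ss + 2 exposure + 2 disorder +
# 3 standardized coordinates = 30 columns per window row
feature_names <- function() {
  c(AA_STANDARD,
    paste0("ss_", c("coil", "strand", "helix")),
    paste0("acc_", c("exposed", "buried")),
    paste0("dis_", c("disordered", "ordered")),
    paste0("coord_", c("x", "y", "z")))
}

N_FEATURES <- 30L
WINDOW_POSITIONS <- c("P4", "P3", "P2", "P1", "P1'", "P2'", "P3'", "P4'")

# L x 30 per-residue feature matrix; non-standard residues get an all-zero
# AA block; coordinates are z-scored per protein per axis
residue_feature_matrix <- function(protein, provider) {
  L <- protein$length
  M <- matrix(0, nrow = L, ncol = N_FEATURES,
              dimnames = list(NULL, feature_names()))
  res <- residues(protein)
  aa_idx <- match(res, AA_STANDARD)
  ok <- !is.na(aa_idx)
  M[cbind(which(ok), aa_idx[ok])] <- 1
  feats <- provider(protein)
  if (!is.null(feats)) {
    feats <- validate_features(protein, feats)
    M[cbind(seq_len(L), 20L + match(feats$ss, c("coil", "strand", "helix")))] <- 1
    M[cbind(seq_len(L), 23L + match(feats$exposure, c("exposed", "buried")))] <- 1
    M[cbind(seq_len(L), 25L + ifelse(feats$disorder, 1L, 2L))] <- 1
    for (k in 1:3) {
      v <- feats[[c("x", "y", "z")[k]]]
      s <- sd(v)
      M[, 27L + k] <- if (is.na(s) || s == 0) 0 else (v - mean(v)) / s
    }
  }
  M
}

#' Encode one candidate cleavage site as a numeric window
#'
#' Builds the fixed-size matrix the recurrent classifier consumes: 8 window
#' rows (residues P4..P1 upstream and P1'..P4' downstream of the scissile
#' bond; the bond itself lies between rows 4 and 5) by 30 features (20-dim
#' amino-acid one-hot, 3-dim secondary-structure one-hot, 2-dim
#' exposed/buried, 2-dim disordered/ordered, 3-dim per-protein standardized
#' coordinates). Window positions beyond either terminus are all-zero rows,
#' and non-standard residues get an all-zero amino-acid block.
#'
#' @param protein A [protein_record()].
#' @param p1 P1 index of the candidate site, in `1 .. L - 1`.
#' @param provider A feature provider (see [feature_providers]).
#' @return An 8 x 30 numeric matrix with window-position rownames.
#' @examples
#' w <- encode_site(protein_record("p", "MKWSALNGFA"), p1 = 2)
#' dim(w)  # 8 30
#' @export
encode_site <- function(protein, p1, provider = zero_provider()) {
  if (p1 < 1L || p1 > protein$length - 1L) {
    stop("p1 must lie in [1, ", protein$length - 1L, "]")
  }
  M <- residue_feature_matrix(protein, provider)
  pos <- p1 + (-3L:4L)
  W <- matrix(0, nrow = 8L, ncol = N_FEATURES,
              dimnames = list(WINDOW_POSITIONS, feature_names()))
  inr <- pos >= 1L & pos <= protein$length
  W[inr, ] <- M[pos[inr], , drop = FALSE]
  W
}

# core encoder: one labeled window per candidate site of every protein,
# positives given as a (protein_id, p1) data.frame
encode_windows <- function(proteins, positives, provider) {
  ids <- sort(vapply(proteins, function(p) p$id, character(1)), method = "radix")
  proteins <- proteins[match(ids, vapply(proteins, function(p) p$id, character(1)))]
  n_per <- vapply(proteins, function(p) max(p$length - 1L, 0L), integer(1))
  n_tot <- sum(n_per)
  x <- array(0, dim = c(n_tot, 8L, N_FEATURES))
  label <- integer(n_tot)
  protein_id <- character(n_tot)
  p1 <- integer(n_tot)
  off <- 0L
  for (p in proteins) {
    nc <- max(p$length - 1L, 0L)
    if (nc == 0L) next
    M <- residue_feature_matrix(p, provider)
    Mpad <- rbind(M, 0)  # row L+1 is the all-zero padding row
    cand <- seq_len(nc)
    idx <- outer(cand, -3L:4L, "+")
    idx[idx < 1L | idx > p$length] <- p$length + 1L
    x[off + cand, , ] <- array(Mpad[as.vector(idx), ], dim = c(nc, 8L, N_FEATURES))
    pos <- positives$p1[positives$protein_id == p$id]
    label[off + cand] <- as.integer(cand %in% pos)
    protein_id[off + cand] <- p$id
    p1[off + cand] <- cand
    off <- off + nc
  }
  structure(list(x = x, label = label, protein_id = protein_id, p1 = p1),
            class = "encoded_windows")
}

#' Encode every candidate site of a protein set for one protease
#'
#' Produces one labeled window per candidate site of every protein, in a
#' stable deterministic order (protein id, then P1). A window is labeled 1
#' iff `(protease, protein, p1)` is annotated.
#'
#' @param proteins Named list of [protein_record()]s.
#' @param annotations Annotation `data.frame`.
#' @param protease Protease identifier; must be in `registry`.
#' @param provider A feature provider (see [feature_providers]).
#' @param registry Protease registry.
#' @return An `encoded_windows` object: list with `x` (n x 8 x 30 array),
#'   `label` (0/1), `protein_id`, `p1`.
#' @export
encode_dataset <- function(proteins, annotations, protease,
                           provider = zero_provider(),
                           registry = protease_registry()) {
  if (!protease %in% registry$protease) {
    stop("protease '", protease, "' is not in the registry")
  }
  pos <- annotations[annotations$protease == protease, c("protein_id", "p1")]
  encode_windows(proteins, pos, provider)
}

#' Encode pooled windows for a protease group
#'
#' Pools the positive class over every protease of one registry group: a
#' window is labeled 1 iff any group member cleaves there. This is the
#' training set for the group-generic model that seeds transfer learning.
#'
#' @inheritParams encode_dataset
#' @param group Registry group tag (`"MMP"` or `"other"`).
#' @return An `encoded_windows` object.
#' @export
encode_group <- function(proteins, annotations, group,
                         provider = zero_provider(),
                         registry = protease_registry()) {
  members <- registry_group(registry, group)
  if (length(members) == 0L) stop("no registry proteases in group '", group, "'")
  pos <- annotations[annotations$protease %in% members, c("protein_id", "p1")]
  pos <- pos[!duplicated(pos), , drop = FALSE]
  encode_windows(proteins, pos, provider)
}

#' @export
print.encoded_windows <- function(x, ...) {
  cat("<encoded_windows> ", length(x$label), " windows (",
      sum(x$label), " positive) over ", length(unique(x$protein_id)),
      " protein(s)\n", sep = "")
  invisible(x)
}

#' Subset an encoded window set
#'
#' @param enc An `encoded_windows` object.
#' @param i Logical or integer index over windows.
#' @return The subsetted `encoded_windows` object.
#' @export
windows_subset <- function(enc, i) {
  structure(list(x = enc$x[i, , , drop = FALSE], label = enc$label[i],
                 protein_id = enc$protein_id[i], p1 = enc$p1[i]),
            class = "encoded_windows")
}
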
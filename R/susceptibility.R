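#' Amino-acid composition profile
#'
#' Counts the photo- and oxidation-sensitive residues of a protein: Trp and
#' Tyr (UV chromophores), Met, Cys and His (oxidation-sensitive), and the
#' number of cysteines engaged in annotated disulfide bonds (cystine,
#' `[Cys=Cys]`; two per bond).
#'
#' @param protein A [protein_record()].
#' @return List with `trp`, `tyr`, `met`, `cys`, `his`, `n_bonded_cys`,
#'   `length`.
#' @export
composition_profile <- function(protein) {
  res <- residues(protein)
  n_bonded <- if (is.null(protein$disulfide_pairs)) 0L else
    2L * nrow(protein$disulfide_pairs)
  list(trp = sum(res == "W"), tyr = sum(res == "Y"), met = sum(res == "M"),
       cys = sum(res == "C"), his = sum(res == "H"),
       n_bonded_cys = n_bonded, length = protein$length)
}

#' Susceptibility scores from composition and predicted cleavage sites
#'
#' Per-protein percentages quantifying vulnerability to three proteolysis
#' mechanisms:
#'
#' * UV susceptibility: `(Trp + Tyr + [Cys=Cys]/2) / L * 100` - the UV
#'   chromophore residues per length, counting each disulfide bond once.
#' * ROS susceptibility: `(Trp + Tyr + Met + Cys + His) / L * 100` - the
#'   oxidation-sensitive residues per length; Cys counts all cysteines
#'   regardless of bonding.
#' * UV-ROS susceptibility: `(Trp + Tyr + Met + Cys + His + [Cys=Cys]/2) /
#'   L * 100`. As printed, a disulfide-bonded cysteine contributes to both
#'   the Cys term and the `[Cys=Cys]/2` term; set
#'   `double_count_bonded_cys = FALSE` to count bonded cysteines only once
#'   (via the cystine term).
#' * Protease susceptibility: `100 * |{sites with score > threshold}| / L`,
#'   the density of highly confident (default score > 0.8) predicted
#'   cleavage sites.
#'
#' With no disulfide annotation UV-ROS reduces exactly to ROS. All
#' composition scores are invariant under sequence duplication.
#'
#' @param protein A [protein_record()].
#' @name susceptibility
#' @return Each scalar scorer returns a percentage.
#' @examples
#' p <- protein_record("p", "WYACCAGGHM", disulfide_pairs = cbind(4, 5))
#' uv_susceptibility(p)      # (1+1+1)/10*100 = 30
#' ros_susceptibility(p)     # (1+1+1+2+1)/10*100 = 60
#' uv_ros_susceptibility(p)  # 70
NULL

#' @rdname susceptibility
#' @export
uv_susceptibility <- function(protein) {
  cp <- composition_profile(protein)
  (cp$trp + cp$tyr + cp$n_bonded_cys / 2) / cp$length * 100
}

#' @rdname susceptibility
#' @export
ros_susceptibility <- function(protein) {
  cp <- composition_profile(protein)
  (cp$trp + cp$tyr + cp$met + cp$cys + cp$his) / cp$length * 100
}

#' @rdname susceptibility
#' @param double_count_bonded_cys Count disulfide-bonded cysteines in both
#'   the Cys and the cystine term (default TRUE, the formula as printed).
#' @export
uv_ros_susceptibility <- function(protein, double_count_bonded_cys = TRUE) {
  cp <- composition_profile(protein)
  cys_term <- if (double_count_bonded_cys) cp$cys else cp$cys - cp$n_bonded_cys
  (cp$trp + cp$tyr + cp$met + cys_term + cp$his + cp$n_bonded_cys / 2) /
    cp$length * 100
}

#' @rdname susceptibility
#' @param predictions Annotation `data.frame` with `score` covering this
#'   protein's candidate sites for one protease.
#' @param threshold Confidence threshold; only sites with
#'   `score > threshold` are counted (default 0.8).
#' @export
protease_susceptibility <- function(protein, predictions, threshold = 0.8) {
  if (!(threshold > 0 && threshold < 1)) stop("threshold must be in (0, 1)")
  sub <- predictions[predictions$protein_id == protein$id, , drop = FALSE]
  100 * sum(sub$score > threshold, na.rm = TRUE) / protein$length
}

#' Classify UV/ROS susceptibility from composition thresholds
#'
#' A protein is called UV-susceptible when more than 5% of its residues are
#' UV chromophores and ROS-susceptible when more than 10% are
#' oxidation-sensitive (strict inequalities); both cut-offs are
#' configurable.
#'
#' @param uv,ros Percentages from [uv_susceptibility()] /
#'   [ros_susceptibility()].
#' @param uv_threshold,ros_threshold Classification thresholds in percent
#'   (defaults 5 and 10).
#' @return List with `uv_class`, `ros_class`
#'   (`"susceptible"`/`"resistant"`).
#' @examples
#' classify_uv_ros(uv = 7, ros = 12)  # susceptible, susceptible
#' classify_uv_ros(uv = 5, ros = 10)  # resistant, resistant (strict >)
#' @export
classify_uv_ros <- function(uv, ros, uv_threshold = 5, ros_threshold = 10) {
  list(uv_class = if (uv > uv_threshold) "susceptible" else "resistant",
       ros_class = if (ros > ros_threshold) "susceptible" else "resistant")
}

#' Full susceptibility score set for one protein
#'
#' @inheritParams susceptibility
#' @inheritParams classify_uv_ros
#' @param predictions Optional scored annotation `data.frame`; when it has
#'   a `protease` column one score per protease is computed.
#' @param threshold Cleavage-score confidence threshold (default 0.8).
#' @param double_count_bonded_cys See [uv_ros_susceptibility()].
#' @return Object of class `susceptibility_scores`.
#' @export
susceptibility_scores <- function(protein, predictions = NULL, threshold = 0.8,
                                  uv_threshold = 5, ros_threshold = 10,
                                  double_count_bonded_cys = TRUE) {
  uv <- uv_susceptibility(protein)
  ros <- ros_susceptibility(protein)
  prot_scores <- numeric(0)
  if (!is.null(predictions) && nrow(predictions) > 0L) {
    prots <- unique(predictions$protease)
    prot_scores <- vapply(prots, function(pr) {
      protease_susceptibility(protein,
                              predictions[predictions$protease == pr, , drop = FALSE],
                              threshold)
    }, numeric(1))
    names(prot_scores) <- prots
  }
  cls <- classify_uv_ros(uv, ros, uv_threshold, ros_threshold)
  structure(list(protein_id = protein$id, length = protein$length,
                 uv = uv, ros = ros,
                 uv_ros = uv_ros_susceptibility(protein, double_count_bonded_cys),
                 protease_scores = prot_scores, threshold = threshold,
                 uv_class = cls$uv_class, ros_class = cls$ros_class),
            class = "susceptibility_scores")
}

#' @export
print.susceptibility_scores <- function(x, ...) {
  cat("<susceptibility_scores>", x$protein_id, "(", x$length, "aa )\n",
      sprintf("  UV %.2f%% (%s)  ROS %.2f%% (%s)  UV-ROS %.2f%%\n",
              x$uv, x$uv_class, x$ros, x$ros_class, x$uv_ros))
  for (pr in names(x$protease_scores)) {
    cat(sprintf("  %s: %.2f sites > %.2g per 100 aa\n", pr,
                x$protease_scores[[pr]], x$threshold))
  }
  invisible(x)
}

#' Proteome-wide susceptibility report
#'
#' One row per protein with length, UV/ROS/UV-ROS percentages, the
#' threshold classifications, and one protease-susceptibility column per
#' protease present in `predictions`. Rows are ordered by descending UV-ROS
#' susceptibility (ties broken by id) so the most vulnerable proteins rank
#' first.
#'
#' @param proteins Named list of [protein_record()]s.
#' @param predictions Optional scored annotation `data.frame` covering the
#'   proteins (e.g. from [predict_sites()]).
#' @inheritParams susceptibility_scores
#' @return A `data.frame` report.
#' @export
proteome_report <- function(proteins, predictions = NULL, threshold = 0.8,
                            uv_threshold = 5, ros_threshold = 10,
                            double_count_bonded_cys = TRUE) {
  stopifnot(length(proteins) >= 1L)
  rows <- lapply(proteins, function(p) {
    s <- susceptibility_scores(p, predictions, threshold, uv_threshold,
                               ros_threshold, double_count_bonded_cys)
    base <- data.frame(protein_id = s$protein_id, length = s$length,
                       uv = s$uv, ros = s$ros, uv_ros = s$uv_ros,
                       uv_class = s$uv_class, ros_class = s$ros_class,
                       stringsAsFactors = FALSE)
    for (pr in names(s$protease_scores)) {
      base[[paste0("susc_", pr)]] <- s$protease_scores[[pr]]
    }
    base
  })
  rep <- do.call(rbind, rows)
  rep <- rep[order(-rep$uv_ros, rep$protein_id, method = "radix"), , drop = FALSE]
  rownames(rep) <- NULL
  rep
}

#' Compare susceptibility between two protein groups
#'
#' Pooled-variance two-sample t-test on one report column between two id
#' sets, e.g. proteins with vs without experimentally detected cleavage
#' sites.
#'
#' @param report A [proteome_report()] `data.frame`.
#' @param column Report column to compare (e.g. `"susc_MMP9"`).
#' @param ids_a,ids_b Protein id character vectors.
#' @return See [compare_groups()].
#' @export
compare_susceptibility <- function(report, column, ids_a, ids_b) {
  if (!column %in% names(report)) stop("no report column '", column, "'")
  compare_groups(report[[column]][report$protein_id %in% ids_a],
                 report[[column]][report$protein_id %in% ids_b])
}
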
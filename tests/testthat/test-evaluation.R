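test_that("MCC matches hand-derived values and the 0/0 convention", {
  expect_equal(mcc(confusion_counts(5, 5, 0, 0)), 1.0)
  expect_equal(mcc(confusion_counts(1, 1, 1, 1)), 0.0)
  expect_equal(mcc(confusion_counts(2, 3, 1, 1)), 5 / 12)
  expect_equal(mcc(confusion_counts(0, 5, 0, 3)), 0)  # zero marginal factor
  expect_error(mcc(confusion_counts(0, 0, 0, 0)), "zero")
  expect_error(confusion_counts(-1, 0, 0, 0), "nonnegative")
})

test_that("F1 matches hand-derived values", {
  expect_equal(f1_score(confusion_counts(5, 0, 0, 0)), 1.0)
  expect_equal(f1_score(confusion_counts(0, 1, 3, 2)), 0.0)
  expect_equal(f1_score(confusion_counts(2, 0, 1, 1)), 2 / 3)
  expect_equal(f1_score(confusion_counts(0, 4, 0, 0)), 0)  # defined 0
})

test_that("MCC equals the Pearson correlation of the binary vectors", {
  # independent oracle: expand each confusion matrix into label/prediction
  # vectors and correlate
  set.seed(1)
  for (rep in 1:50) {
    cts <- sample(0:6, 4, replace = TRUE)
    if (sum(cts) == 0) next
    truth <- rep(c(1, 0, 0, 1), cts)
    pred <- rep(c(1, 0, 1, 0), cts)
    oracle <- suppressWarnings(cor(truth, pred))
    got <- mcc(confusion_counts(cts[1], cts[2], cts[3], cts[4]))
    if (is.na(oracle)) expect_equal(got, 0) else expect_equal(got, oracle)
  }
})

test_that("ROC/AUC match hand-enumerated pair counting and handle ties", {
  r <- roc_auc(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0), n_boot = 0)
  expect_equal(r$auc, 0.75)  # 3 of 4 positive-negative pairs concordant
  expect_equal(roc_auc(c(1, 1, 0, 0), c(1, 1, 0, 0), n_boot = 0)$auc, 1.0)
  expect_equal(roc_auc(rep(0.3, 10), rep(0:1, 5), n_boot = 0)$auc, 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("ROC curves run (0,0) to (1,1) and are monotone", {
  set.seed(2)
  s <- runif(40)
  y <- rbinom(40, 1, 0.4)
  cur <- roc_curve(s, y)
  expect_equal(cur$fpr[1], 0)
  expect_equal(cur$tpr[1], 0)
  expect_equal(cur$fpr[nrow(cur)], 1)
  expect_equal(cur$tpr[nrow(cur)], 1)
  expect_true(all(diff(cur$fpr) >= 0))
  expect_true(all(diff(cur$tpr) >= 0))
})

test_that("trapezoidal and Mann-Whitney AUC agree, and match an external implementation", {
  set.seed(3)
  for (rep in 1:25) {
    n <- sample(6:20, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), 2)  # coarse scores force ties
    a_mw <- roc_auc(s, y, n_boot = 0)$auc
    expect_equal(auc_trapezoid(roc_curve(s, y)), a_mw, tolerance = 1e-12)
    a_ext <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                            direction = "<")))
    expect_equal(a_mw, a_ext, tolerance = 1e-12)
  }
})

test_that("bootstrap CI brackets the AUC and is seed-deterministic", {
  set.seed(4)
  s <- c(runif(30, 0.4, 1), runif(40, 0, 0.6))
  y <- rep(c(1, 0), c(30, 40))
  r1 <- roc_auc(s, y, n_boot = 300, seed = 9)
  r2 <- roc_auc(s, y, n_boot = 300, seed = 9)
  expect_identical(r1$ci, r2$ci)
  expect_lte(r1$ci[1], r1$auc)
  expect_gte(r1$ci[2], r1$auc)
})

test_that("non-tryptic extraction applies the trypsin specificity to both termini", {
  prots <- list(p = protein_record("p", "MAKSLNGFAR"))
  # N-boundary after K3 is tryptic, C-boundary is the protein terminus
  none <- nontryptic_sites(data.frame(protein_id = "p", peptide = "SLNGFAR"),
                           prots)
  expect_equal(nrow(none), 0L)
  # boundary after S4 is non-tryptic
  one <- nontryptic_sites(data.frame(protein_id = "p", peptide = "LNGFAR"),
                          prots)
  expect_equal(one$p1, 4L)
  expect_equal(one$source, "experiment")
  expect_equal(one$protease, "MMP9")
  # empty input, empty output
  expect_equal(nrow(nontryptic_sites(data.frame(protein_id = character(0),
                                                peptide = character(0)),
                                     prots)), 0L)
})

test_that("K/R before Pro counts as non-tryptic and shared sites deduplicate", {
  prots <- list(p = protein_record("p", "MAKPSLNGFAR"))
  # boundary after K3 is followed by P, so it violates trypsin specificity
  hits <- data.frame(protein_id = "p", peptide = c("PSLNGFAR", "MAK"))
  got <- nontryptic_sites(hits, prots)
  expect_equal(got$p1, 3L)  # both termini name position 3; deduplicated
})

test_that("unmatched and ambiguous peptides are skipped with a report", {
  prots <- list(p = protein_record("p", "ABABA"))
  hits <- data.frame(protein_id = c("p", "p", "q"),
                     peptide = c("ZZZ", "ABA", "AAA"))
  got <- nontryptic_sites(hits, prots)
  expect_equal(nrow(got), 0L)
  skipped <- attr(got, "skipped")
  expect_setequal(skipped$reason, c("not_found", "ambiguous", "unknown_protein"))
})

test_that("pure tryptic digests yield zero non-tryptic sites; planted boundaries are recovered", {
  for (seed in 1:4) {
    p <- generate_protein(300, seed = seed, id = "p")
    hits <- tryptic_digest(p)
    got <- nontryptic_sites(hits, stats::setNames(list(p), "p"))
    expect_equal(nrow(got), 0L)
  }
  # cut a tryptic peptide internally: the planted boundary is recovered
  # exactly (SLN starts after the tryptic K3; the SLN|GFAR boundary at 6 is
  # non-tryptic; GFAR ends at the tryptic R10)
  p <- protein_record("p", "MAKSLNGFARTTWQEK")
  hits <- data.frame(protein_id = "p", peptide = c("SLN", "GFAR"))
  got <- nontryptic_sites(hits, list(p = p))
  expect_equal(got$p1, 6L)
})

test_that("cleavage density bins sites per 50-residue window", {
  p <- generate_protein(150, seed = 1, id = "p")
  ann <- data.frame(protein_id = "p", p1 = c(10L, 60L, 70L))
  expect_equal(cleavage_density(ann, p), c(1L, 2L, 0L))
  expect_equal(cleavage_density(ann[0, ], p), c(0L, 0L, 0L))
  short <- generate_protein(30, seed = 2, id = "s")
  expect_equal(cleavage_density(data.frame(protein_id = "s", p1 = c(3L, 29L)),
                                short), 2L)
  expect_error(cleavage_density(data.frame(protein_id = "p", p1 = 150L), p),
               "outside")
})

test_that("predictor evaluation scores a table against the candidate universe", {
  ds <- tiny_dataset(n = 8)
  truth <- ds$annotations
  # oracle scores equal to labels: perfect metrics
  scores <- do.call(rbind, lapply(ds$proteins, function(p) {
    data.frame(protein_id = p$id, p1 = candidate_sites(p), stringsAsFactors = FALSE)
  }))
  key <- paste(scores$protein_id, scores$p1)
  scores$score <- as.numeric(key %in% paste(truth$protein_id, truth$p1))
  rep <- evaluate_predictor(scores, truth, ds$proteins, "trypsin", n_boot = 50)
  expect_equal(rep$mcc, 1.0)
  expect_equal(rep$f1, 1.0)
  expect_equal(rep$auc, 1.0)
  # label-shuffled scores: AUC near one half
  shuf <- scores
  shuf$score <- protcleave:::with_seed(13, sample(scores$score))
  rep2 <- evaluate_predictor(shuf, truth, ds$proteins, "trypsin", n_boot = 0)
  expect_lt(abs(rep2$auc - 0.5), 0.05)
  # missing candidates are scored zero with a warning
  expect_warning(
    rep3 <- evaluate_predictor(scores[-(1:5), ], truth, ds$proteins, "trypsin",
                               n_boot = 0),
    "missing")
  expect_error(evaluate_predictor(scores, truth[0, ], ds$proteins, "trypsin"),
               "no truth positives")
})

test_that("group comparison is a pooled two-sample t-test", {
  r <- compare_groups(c(1, 2, 3, 4), c(3, 4, 5, 6))
  expect_equal(r$t, -2.190890, tolerance = 1e-6)
  # closed form: 2 * pt(-2/sqrt(5/3 * 1/2), df = 6)
  expect_equal(r$p, 2 * pt(-2 / sqrt(5 / 6), df = 6))
  expect_equal(r$df, 6)
  same <- compare_groups(c(1, 2, 3), c(2, 1, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1.0)
  swapped <- compare_groups(c(3, 4, 5, 6), c(1, 2, 3, 4))
  expect_equal(swapped$t, 2.190890, tolerance = 1e-6)
  expect_equal(swapped$p, r$p)
  expect_error(compare_groups(c(1, 1), c(1, 1)), "variance")
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})
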
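test_that("UV susceptibility counts chromophores and half the bonded cysteines", {
  p <- make_protein(100, trp = 3, tyr = 2, cys = 4, n_bonds = 2)
  expect_equal(uv_susceptibility(p), 7.0)
  expect_equal(uv_susceptibility(protein_record("p", "GGGG")), 0.0)
  expect_equal(uv_susceptibility(protein_record("p", "WY")), 100.0)
})

test_that("ROS susceptibility counts all five oxidation-sensitive residues", {
  expect_equal(ros_susceptibility(protein_record("p", "WYMCH")), 100.0)
  expect_equal(ros_susceptibility(protein_record("p", "GGGGG")), 0.0)
  p <- make_protein(50, trp = 1, tyr = 1, met = 1, cys = 1, his = 1)
  expect_equal(ros_susceptibility(p), 10.0)
  # bonded or not, every cysteine counts
  pb <- make_protein(50, trp = 1, tyr = 1, met = 1, cys = 2, his = 1,
                     n_bonds = 1)
  expect_equal(ros_susceptibility(pb), 12.0)
})

test_that("UV-ROS susceptibility follows the printed formula, double counting bonded Cys", {
  p <- make_protein(20, trp = 1, met = 1, cys = 2, n_bonds = 1)
  expect_equal(uv_ros_susceptibility(p), 25.0)  # (1+1+2+1)/20*100
  # escape hatch: bonded pair counts once, as a single cystine unit
  expect_equal(uv_ros_susceptibility(p, double_count_bonded_cys = FALSE), 15.0)
  expect_equal(uv_ros_susceptibility(protein_record("p", "GGGG")), 0.0)
  # with no disulfides the UV-ROS score reduces exactly to the ROS score
  free <- make_protein(40, trp = 2, cys = 3, his = 1)
  expect_equal(uv_ros_susceptibility(free), ros_susceptibility(free))
})

test_that("protease susceptibility is the density of confident predicted sites", {
  p <- make_protein(200, id = "p")
  pred <- data.frame(protein_id = "p", p1 = 1:199,
                     score = c(rep(0.9, 6), rep(0.1, 193)))
  expect_equal(protease_susceptibility(p, pred), 3.0)
  expect_equal(protease_susceptibility(p, pred, threshold = 0.95), 0.0)
  p2 <- make_protein(101, id = "q")
  allhi <- data.frame(protein_id = "q", p1 = 1:100, score = 0.99)
  expect_equal(protease_susceptibility(p2, allhi), 100 * 100 / 101)
  # a score exactly at the threshold does not count (strict >)
  exact <- data.frame(protein_id = "p", p1 = 1:199, score = 0.8)
  expect_equal(protease_susceptibility(p, exact), 0.0)
})

test_that("UV/ROS classification uses strict 5% and 10% thresholds", {
  expect_equal(classify_uv_ros(7, 12),
               list(uv_class = "susceptible", ros_class = "susceptible"))
  expect_equal(classify_uv_ros(0, 0),
               list(uv_class = "resistant", ros_class = "resistant"))
  expect_equal(classify_uv_ros(5, 10),
               list(uv_class = "resistant", ros_class = "resistant"))
  expect_equal(classify_uv_ros(5.0001, 10.0001),
               list(uv_class = "susceptible", ros_class = "susceptible"))
})

test_that("composition invariants hold on random synthetic proteins", {
  set.seed(17)
  for (i in 1:200) {
    p <- generate_protein(sample(10:300, 1), seed = i, id = "p")
    # attach disulfides on a random subset of cysteine pairs
    cpos <- which(residues(p) == "C")
    if (length(cpos) >= 2) {
      k <- sample(0:(length(cpos) %/% 2), 1)
      if (k > 0) {
        p <- protein_record(p$id, p$sequence,
                            disulfide_pairs = matrix(cpos[seq_len(2 * k)],
                                                     ncol = 2, byrow = TRUE))
      }
    }
    uv <- uv_susceptibility(p)
    ros <- ros_susceptibility(p)
    uvros <- uv_ros_susceptibility(p)
    expect_gte(uv, 0); expect_lte(uv, 100)
    expect_gte(ros, 0); expect_lte(ros, 100)
    expect_lte(uv, uvros + 1e-12)
    expect_lte(ros, uvros + 1e-12)
    # duplication invariance: doubling sequence and annotations changes nothing
    dp <- if (is.null(p$disulfide_pairs)) NULL else
      rbind(p$disulfide_pairs, p$disulfide_pairs + p$length)
    p2 <- protein_record(p$id, paste0(p$sequence, p$sequence),
                         disulfide_pairs = dp)
    expect_equal(uv_susceptibility(p2), uv)
    expect_equal(ros_susceptibility(p2), ros)
    expect_equal(uv_ros_susceptibility(p2), uvros)
  }
})

test_that("raising the confidence threshold never raises a protease score", {
  set.seed(23)
  p <- make_protein(150, id = "p")
  pred <- data.frame(protein_id = "p", p1 = 1:149, score = runif(149))
  scores <- vapply(seq(0.05, 0.95, by = 0.05), function(th) {
    protease_susceptibility(p, pred, threshold = th)
  }, numeric(1))
  expect_true(all(diff(scores) <= 0))
})

test_that("the proteome report ranks by UV-ROS and carries per-protease columns", {
  prots <- list(
    a = make_protein(50, trp = 5, cys = 2, n_bonds = 1, id = "a"),
    b = make_protein(50, id = "b"),
    c = make_protein(50, tyr = 5, met = 3, id = "c"))
  pred <- rbind(
    data.frame(protease = "trypsin", protein_id = "a", p1 = 1:49, score = 0.9),
    data.frame(protease = "trypsin", protein_id = "b", p1 = 1:49, score = 0.1),
    data.frame(protease = "trypsin", protein_id = "c", p1 = 1:49, score = 0.9))
  rep <- proteome_report(prots, pred)
  # a and c tie on uv_ros at 16%, broken by id; b trails
  expect_equal(rep$protein_id, c("a", "c", "b"))
  expect_true("susc_trypsin" %in% names(rep))
  expect_equal(rep$susc_trypsin[rep$protein_id == "b"], 0)
  expect_equal(rep$susc_trypsin[rep$protein_id == "a"], 100 * 49 / 50)
  expect_equal(rep$uv_class[rep$protein_id == "a"], "susceptible")
  expect_equal(rep$ros_class[rep$protein_id == "b"], "resistant")

  # the t-test delegate refuses single-member groups
  expect_error(compare_susceptibility(rep, "susc_trypsin", c("a", "c"), "b"),
               "at least 2")
  expect_error(compare_susceptibility(rep, "nope", c("a", "c"), "b"),
               "no report column")
})

test_that("protease susceptibility correlates with cleavable-residue content under the rule oracle", {
  ds <- tiny_dataset(n = 40, seed = 19)
  # oracle predictor: score 1 at rule sites, 0 elsewhere
  pred <- do.call(rbind, lapply(ds$proteins, function(p) {
    cs <- candidate_sites(p)
    data.frame(protease = "trypsin", protein_id = p$id, p1 = cs,
               score = as.numeric(cs %in% rule_sites(p, trypsin_rule())),
               stringsAsFactors = FALSE)
  }))
  rep <- proteome_report(ds$proteins, pred)
  kr_density <- vapply(ds$proteins, function(p) {
    mean(residues(p) %in% c("K", "R"))
  }, numeric(1))
  rho <- cor(kr_density[rep$protein_id], rep$susc_trypsin, method = "spearman")
  expect_gt(rho, 0)
})

test_that("two groups with disjoint score distributions separate at p < 0.01", {
  prots <- c(lapply(1:6, function(i) make_protein(60, trp = 6, id = paste0("hi", i))),
             lapply(1:6, function(i) make_protein(60, id = paste0("lo", i))))
  names(prots) <- vapply(prots, `[[`, character(1), "id")
  pred <- do.call(rbind, lapply(names(prots), function(id) {
    hi <- startsWith(id, "hi")
    set.seed(nchar(id) + utf8ToInt(substr(id, 3, 3)))
    data.frame(protease = "trypsin", protein_id = id, p1 = 1:59,
               score = if (hi) runif(59, 0.7, 1) else runif(59, 0, 0.3),
               stringsAsFactors = FALSE)
  }))
  rep <- proteome_report(prots, pred)
  cmp <- compare_susceptibility(rep, "susc_trypsin",
                                paste0("hi", 1:6), paste0("lo", 1:6))
  expect_lt(cmp$p, 0.01)
})
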
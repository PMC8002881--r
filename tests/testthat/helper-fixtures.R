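# Shared fixtures: everything is generated in code, no data files.

# a small seeded synthetic dataset (trypsin rule unless overridden)
tiny_dataset <- function(n = 30L, lengths = c(60L, 120L), seed = 101L,
                         rule = trypsin_rule()) {
  generate_dataset(sim_config(n_proteins = n, length_range = lengths,
                              seed = seed, rule = rule))
}

# a fast model configuration for unit tests of the training machinery
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_bilstm_layers = 2L, hidden_units = 6L, dense_units = 6L,
                   learning_rate = 3e-3, batch_size = 128L, max_epochs = 3L,
                   patience = 20L, seed = 7L)
  do.call(model_config, utils::modifyList(defaults, args))
}

# encoded windows + split for a tiny dataset
tiny_training_setup <- function(n = 30L, seed = 101L, rule = trypsin_rule(),
                                provider = zero_provider()) {
  ds <- tiny_dataset(n = n, seed = seed, rule = rule)
  enc <- encode_dataset(ds$proteins, ds$annotations, rule$name, provider,
                        registry = rule_registry(rule))
  split <- split_proteins(names(ds$proteins), seed = seed)
  list(dataset = ds, windows = enc, split = split)
}

# held-out AUC of a model/ensemble against a truth annotation table
heldout_auc <- function(model, windows, split, truth) {
  te <- which(windows$protein_id %in% partition_ids(split, "test"))
  sub <- windows_subset(windows, te)
  key <- paste(sub$protein_id, sub$p1)
  labels <- as.integer(key %in% paste(truth$protein_id, truth$p1))
  roc_auc(predict_windows(model, sub), labels, n_boot = 0)$auc
}

# deterministic rule-site truth table over a protein list
rule_truth <- function(proteins, rule) {
  do.call(rbind, lapply(proteins, function(p) {
    s <- rule_sites(p, rule)
    if (length(s) == 0L) return(NULL)
    data.frame(protease = rule$name, protein_id = p$id, p1 = s,
               stringsAsFactors = FALSE)
  }))
}

# helper: protein with prescribed counts of the sensitive residues, padded
# with glycine, plus optional disulfide pairs among the first cysteines
make_protein <- function(L, trp = 0, tyr = 0, met = 0, cys = 0, his = 0,
                         n_bonds = 0, id = "p") {
  stopifnot(trp + tyr + met + cys + his <= L, 2 * n_bonds <= cys)
  seqchr <- c(rep("W", trp), rep("Y", tyr), rep("M", met), rep("C", cys),
              rep("H", his))
  seqchr <- c(seqchr, rep("G", L - length(seqchr)))
  pairs <- NULL
  if (n_bonds > 0) {
    cpos <- which(seqchr == "C")
    pairs <- matrix(cpos[seq_len(2 * n_bonds)], ncol = 2, byrow = TRUE)
  }
  protein_record(id, paste(seqchr, collapse = ""), disulfide_pairs = pairs)
}
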
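#' Protease registry
#'
#' The set of proteases the package models. The default registry holds the 14
#' tissue proteases covered by the cleavage-site models: eight matrix
#' metalloproteinases (group `"MMP"`) and six other proteases (group
#' `"other"`: cathepsins K, G, B and D, elastase-2 and granzyme B). The
#' registry gates which protease identifiers are accepted in annotation
#' tables and which windows are pooled when pretraining a group-generic
#' model.
#'
#' @param extra Optional `data.frame` with columns `protease` and `group`
#'   appended to the default entries (used e.g. for synthetic rule-based
#'   proteases such as trypsin).
#' @return A `data.frame` with columns `protease` (character identifier) and
#'   `group` (`"MMP"` or `"other"`).
#' @examples
#' reg <- protease_registry()
#' nrow(reg)  # 14
#' table(reg$group)
#' @export
protease_registry <- function(extra = NULL) {
  reg <- data.frame(
    protease = c("MMP1", "MMP2", "MMP3", "MMP7", "MMP8", "MMP9", "MMP12",
                 "MMP13", "CTSK", "CTSG", "CTSB", "CTSD", "ELANE", "GZMB"),
    group = c(rep("MMP", 8), rep("other", 6)),
    stringsAsFactors = FALSE
  )
  if (!is.null(extra)) {
    if (!all(c("protease", "group") %in% names(extra))) {
      stop("`extra` must have columns `protease` and `group`")
    }
    if (!all(extra$group %in% c("MMP", "other"))) {
      stop("registry group tags must be 'MMP' or 'other'")
    }
    reg <- rbind(reg, extra[, c("protease", "group")])
  }
  if (anyDuplicated(reg$protease)) stop("duplicate protease identifiers in registry")
  reg
}

#' Registry for a synthetic cleavage rule
#'
#' Wraps one or more rule-based synthetic proteases in a registry so the
#' encoding and evaluation machinery can be exercised on simulated data
#' without the real protease entries.
#'
#' @param rules A [cleavage_rule()] or list of them.
#' @param group Group tag assigned to every rule (default `"other"`).
#' @return A registry `data.frame` (see [protease_registry()]).
#' @export
rule_registry <- function(rules, group = "other") {
  if (inherits(rules, "cleavage_rule")) rules <- list(rules)
  data.frame(protease = vapply(rules, function(r) r$name, character(1)),
             group = group, stringsAsFactors = FALSE)
}

#' @rdname protease_registry
#' @param registry A registry `data.frame`.
#' @param group Group tag to select.
#' @return `registry_group()`: the protease identifiers in `group`.
#' @export
registry_group <- function(registry, group) {
  registry$protease[registry$group == group]
}
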
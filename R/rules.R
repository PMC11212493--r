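# Variable-modification rules.
#
# A rule either replaces a residue's mass outright (sequence variants such as
# K->C) or adds a mass shift (chemical modifications such as phosphorylation).
# Each rule contributes one "red" (modified) edge per matching position of the
# proteoform mass graph.

#' Construct a table of variable-modification rules
#'
#' @param rule_id Character vector of rule identifiers (need not be unique;
#'   a multi-residue modification is expressed as one row per target residue).
#' @param target One-letter code of the residue the rule applies to.
#' @param mode `"replace"` (the rule's `mass_da` is the full modified residue
#'   mass) or `"shift"` (`mass_da` is added to the unmodified residue mass).
#' @param mass_da Numeric mass in Da; interpreted according to `mode`.
#' @param label Free-text label, conventionally a UNIMOD accession.
#' @return A data.frame of class `mod_rules`.
#' @seealso [read_rules()], [builtin_rules()]
#' @export
modification_rules <- function(rule_id, target, mode, mass_da,
                               label = rep(NA_character_, length(rule_id))) {
  rules <- data.frame(
    rule_id = as.character(rule_id), target = as.character(target),
    mode = as.character(mode), mass_da = as.numeric(mass_da),
    label = as.character(label), stringsAsFactors = FALSE
  )
  validate_rules(rules)
}

validate_rules <- function(rules) {
  stopifnot(is.data.frame(rules))
  needed <- c("rule_id", "target", "mode", "mass_da", "label")
  missing_cols <- setdiff(needed, names(rules))
  if (length(missing_cols) > 0) {
    stop("rules table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!all(rules$mode %in% c("replace", "shift"))) {
    stop("rule mode must be 'replace' or 'shift'", call. = FALSE)
  }
  if (!all(nchar(rules$target) == 1L)) {
    stop("rule targets must be single residue letters", call. = FALSE)
  }
  if (any(is.na(rules$mass_da))) stop("rule masses must be numeric", call. = FALSE)
  class(rules) <- c("mod_rules", "data.frame")
  rules
}

#' Modified residue mass implied by a rule (Da)
#'
#' @param rules A `mod_rules` table.
#' @param table Residue mass table, see [residue_masses()].
#' @return Numeric vector of modified residue masses in Da, one per rule row.
#' @keywords internal
modified_masses <- function(rules, table = residue_masses()) {
  base <- unname(table[rules$target])
  ifelse(rules$mode == "replace", rules$mass_da, base + rules$mass_da)
}

#' Bundled modification rule sets
#'
#' Two small rule files ship with the package:
#' \describe{
#'   \item{`"common_ptms"`}{Oxidation (M, UNIMOD:35), Deamidation (N/Q,
#'     UNIMOD:7), Phosphorylation (S/T/Y, UNIMOD:21) and Carbamidomethylation
#'     (C, UNIMOD:4), all as additive shifts.}
#'   \item{`"mutations"`}{Sequence variants K->C (UNIMOD:1132), T->A
#'     (UNIMOD:659) and V->G (UNIMOD:672), as replacements.}
#' }
#'
#' @param set Which rule set to load.
#' @return A `mod_rules` table.
#' @export
builtin_rules <- function(set = c("common_ptms", "mutations")) {
  set <- match.arg(set)
  path <- system.file("extdata", paste0("rules_", set, ".tsv"),
                      package = "mgalign", mustWork = TRUE)
  read_rules(path)
}
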
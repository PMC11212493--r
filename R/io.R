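# File formats.
#
# FASTA goes through Biostrings.  The rules file is tab-separated text
# (rule_id, target_residue, mode, mass_Da, label; '#' comments).  The
# spectrum file is plain text: a "PRECURSOR_MASS=<Da>" header line, then one
# peak mass (Da) per line; '#' comments and blank lines ignored.

#' Read protein sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences; names are the first
#'   whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a variable-modification rules file
#'
#' Tab-separated columns `rule_id`, `target_residue`, `mode`
#' (`replace`|`shift`), `mass_Da`, `label`; lines starting with `#` are
#' comments.
#'
#' @param path Path to the rules file.
#' @return A `mod_rules` table, see [modification_rules()].
#' @export
read_rules <- function(path) {
  raw <- tryCatch(
    read.delim(path, header = FALSE, comment.char = "#",
               stringsAsFactors = FALSE,
               col.names = c("rule_id", "target", "mode", "mass_da", "label")),
    error = function(e) {
      stop("malformed rules file '", path, "': ", conditionMessage(e),
           call. = FALSE)
    })
  if (!is.numeric(raw$mass_da)) {
    bad <- which(is.na(suppressWarnings(as.numeric(raw$mass_da))))[1]
    stop(sprintf("malformed rules file '%s': non-numeric mass at data line %d",
                 path, bad), call. = FALSE)
  }
  validate_rules(raw)
}

#' Write a variable-modification rules file
#'
#' @param rules A `mod_rules` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rules <- function(rules, path) {
  rules <- validate_rules(rules)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# columns: rule_id\ttarget_residue\tmode\tmass_Da\tlabel", con)
  write.table(rules, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a deconvoluted peak-list file
#'
#' @param path Path to a spectrum file (format above).
#' @return `list(peaks = <numeric Da>, precursor = <Da or NA>)`.
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  precursor <- NA_real_
  peaks <- numeric(0)
  for (ln in seq_along(lines)) {
    s <- trimws(sub("#.*$", "", lines[ln]))
    if (nchar(s) == 0) next
    if (grepl("^PRECURSOR_MASS=", s)) {
      precursor <- suppressWarnings(as.numeric(sub("^PRECURSOR_MASS=", "", s)))
      if (is.na(precursor)) {
        stop(sprintf("malformed spectrum file '%s': bad precursor at line %d",
                     path, ln), call. = FALSE)
      }
      next
    }
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v)) {
      stop(sprintf("malformed spectrum file '%s': non-numeric peak at line %d",
                   path, ln), call. = FALSE)
    }
    peaks <- c(peaks, v)
  }
  list(peaks = peaks, precursor = precursor)
}

#' Write a deconvoluted peak-list file
#'
#' @param peaks Numeric vector of peak masses (Da).
#' @param precursor Precursor mass (Da) or `NA` to omit the header.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(peaks, precursor, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.na(precursor)) {
    writeLines(sprintf("PRECURSOR_MASS=%.6f", precursor), con)
  }
  writeLines(sprintf("%.6f", peaks), con)
  invisible(path)
}

#' Write an alignment report (TSV + JSON summary)
#'
#' The TSV holds one row per matched triple (node, 1-based residue index of
#' the step end, peak, raw mass, corrected mass, correction k, sub-path mass,
#' residues spanned); the JSON summary holds score, MME, AME, the
#' residue-match histogram, the signed consecutive errors and the effective
#' configuration.
#'
#' @param alignment An `mg_alignment`.
#' @param metrics Output of [alignment_metrics()] for it.
#' @param config A named list recorded verbatim under `config` (provenance).
#' @param path_prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @return Character vector of the two paths, invisibly.
#' @export
write_report <- function(alignment, metrics, config, path_prefix) {
  stopifnot(inherits(alignment, "mg_alignment"))
  tr <- alignment$triples
  tsv <- data.frame(node = tr$node, residue = tr$node, peak = tr$peak,
                    raw_mass = tr$peak_mass, corrected = tr$corrected,
                    k = tr$k, subpath_mass = tr$subpath_mass,
                    residues_spanned = tr$span)
  tsv_path <- paste0(path_prefix, ".tsv")
  json_path <- paste0(path_prefix, ".json")
  write.table(tsv, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    tool = "mgalign", version = as.character(utils::packageVersion("mgalign")),
    mode = alignment$mode, score = metrics$score, mme = metrics$mme,
    ame = metrics$ame, matches_1 = metrics$matches_1,
    matches_2 = metrics$matches_2, matches_3plus = metrics$matches_3plus,
    consecutive_errors = metrics$consecutive_errors, config = config)
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(tsv = tsv_path, json = json_path))
}

#' Read a YAML run configuration
#'
#' Optional convenience for the command-line driver: a flat YAML map of the
#' documented configuration keys (`tolerance.mode`, `tolerance.delta`,
#' `tolerance.ppm`, `preprocess.add_complementary`,
#' `preprocess.satellite_threshold_da`, `caps.max_gap_residues`,
#' `caps.max_red_edges`, `mode`, `seed`).
#'
#' @param path Path to a YAML file.
#' @return A named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read YAML configs", call. = FALSE)
  }
  yaml::read_yaml(path)
}
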
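#' Read RNA records from a FASTA file
#'
#' Multi-line sequences are supported; sequences are canonicalized
#' (uppercase, `T` to `U`) and records keep file order. Duplicate ids and
#' illegal characters are rejected with explicit errors.
#'
#' @param path FASTA file path.
#' @return Tibble with columns `id`, `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("FASTA file not found: %s", path),
                 class = "mirboost_io_error")
  }
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) {
                    rlang::abort(sprintf("could not parse FASTA %s: %s",
                                         path, conditionMessage(e)),
                                 class = "mirboost_io_error")
                  })
  if (!length(set)) {
    rlang::abort(sprintf("FASTA file is empty: %s", path),
                 class = "mirboost_io_error")
  }
  ids <- sub("\\s.*$", "", names(set))
  records <- tibble::tibble(id = unname(ids),
                            sequence = unname(as.character(set)))
  validate_records(records)
}

#' Write RNA records to a FASTA file
#'
#' @param records Data frame with `id` and `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  records <- validate_records(records)
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, width = 20000L)
  invisible(path)
}

#' Read dot-bracket structure triples
#'
#' Plain-text records of three lines each: `>id`, the sequence, then the
#' dot-bracket (optionally followed by an energy in parentheses, as printed
#' by RNAfold).
#'
#' @param path Input file path.
#' @return Tibble with `id`, `sequence`, `structure`, `energy` (`NA` when no
#'   energy is present) and `backend = "file"`.
#' @export
read_dotbracket <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("structure file not found: %s", path),
                 class = "mirboost_io_error")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || length(lines) %% 3 != 0) {
    rlang::abort("structure file must hold >id / sequence / structure triples",
                 class = "mirboost_io_error")
  }
  starts <- seq(1, length(lines), by = 3)
  if (any(!startsWith(lines[starts], ">"))) {
    rlang::abort("malformed structure file: expected '>' header every 3 lines",
                 class = "mirboost_io_error")
  }
  ids <- sub("\\s.*$", "", sub("^>", "", lines[starts]))
  seqs <- canonicalize_rna(trimws(lines[starts + 1]))
  sline <- trimws(lines[starts + 2])
  m <- regmatches(sline, regexec("^([().]+)(\\s+\\(\\s*(-?[0-9.]+)\\s*\\))?$", sline))
  if (any(lengths(m) == 0)) {
    rlang::abort("malformed dot-bracket line in structure file",
                 class = "mirboost_io_error")
  }
  structure_s <- vapply(m, `[`, "", 2)
  energy <- suppressWarnings(as.numeric(vapply(m, `[`, "", 4)))
  bad <- which(nchar(structure_s) != nchar(seqs))
  if (length(bad)) {
    rlang::abort(sprintf("structure length mismatch for record '%s'", ids[bad[1]]),
                 class = "mirboost_io_error")
  }
  validate_records(tibble::tibble(id = ids, sequence = seqs)) |>
    dplyr::mutate(structure = structure_s, energy = energy, backend = "file")
}

#' Write dot-bracket structure triples
#'
#' @param folded Data frame with `id`, `sequence`, `structure` and
#'   optionally `energy` columns (as from [fold_rna()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dotbracket <- function(folded, path) {
  stopifnot(all(c("id", "sequence", "structure") %in% names(folded)))
  sline <- if ("energy" %in% names(folded)) {
    sprintf("%s (%.2f)", folded$structure, folded$energy)
  } else {
    folded$structure
  }
  writeLines(paste0(">", folded$id, "\n", folded$sequence, "\n", sline), path)
  invisible(path)
}

#' Read a label manifest (TSV)
#'
#' Tab-separated with a header; requires `id` and `label` columns, keeps any
#' others (e.g. `species`). Lines starting with `#` are provenance comments
#' and are skipped.
#'
#' @param path TSV path.
#' @return Tibble of labels.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("label file not found: %s", path),
                 class = "mirboost_io_error")
  }
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (!all(c("id", "label") %in% names(out))) {
    rlang::abort("label file needs 'id' and 'label' columns",
                 class = "mirboost_io_error")
  }
  out$id <- as.character(out$id)
  out
}

#' Write a label manifest (TSV)
#'
#' @param labels Data frame with at least `id` and `label`.
#' @param path Output path.
#' @param provenance Optional named list written as leading `#` comment
#'   lines (tool version, seed, config hash).
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path, provenance = NULL) {
  stopifnot(all(c("id", "label") %in% names(labels)))
  header <- provenance_lines(provenance)
  body <- format_tsv_lines(labels)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a feature table (CSV)
#'
#' Header equals `id` plus the frozen [feature_schema()]; one record per
#' row. Optional provenance is embedded as leading `#` comment lines.
#'
#' @param features Tibble from [hairpin_features()].
#' @param path Output path.
#' @param provenance Optional named list of provenance fields.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path, provenance = NULL) {
  feature_matrix(features)  # validates the schema
  header <- provenance_lines(provenance)
  body <- readr::format_csv(features)
  writeLines(c(header, sub("\n$", "", body)), path, sep = "\n")
  invisible(path)
}

#' Read a feature table (CSV)
#'
#' @param path CSV written by [write_features()].
#' @return Feature tibble (schema-checked).
#' @export
read_features <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("feature file not found: %s", path),
                 class = "mirboost_io_error")
  }
  out <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  feature_matrix(out)
  out$id <- as.character(out$id)
  out
}

provenance_lines <- function(provenance) {
  base <- list(tool = "mirboost",
               version = as.character(utils::packageVersion("mirboost")))
  all <- utils::modifyList(base, as.list(provenance %||% list()))
  sprintf("# %s: %s", names(all), vapply(all, function(v)
    paste(format(v), collapse = " "), ""))
}

format_tsv_lines <- function(df) {
  sub("\n$", "", readr::format_tsv(df)) |>
    strsplit("\n") |>
    unlist()
}

#' Hash of a configuration object for provenance stamps
#' @param x Any serializable R object.
#' @return Short hex digest string.
#' @export
config_hash <- function(x) {
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  # small FNV-1a over the serialized config; provenance only, not cryptographic
  bytes <- utf8ToInt(as.character(json))
  h <- 2166136261
  for (b in bytes) {
    # xor and modular multiply in 16-bit halves so doubles stay exact
    lo <- bitwXor(h %% 65536, b %% 65536)
    hi <- bitwXor(h %/% 65536, b %/% 65536)
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
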
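TRIPLET_PATTERNS <- c("(((", "((.", "(.(", "(..", ".((", ".(.", "..(", "...")

FEATURE_SCHEMA_VERSION <- "98/1"

kmer_names <- function(n = 3) {
  g <- expand.grid(rep(list(RNA_ALPHABET), n), stringsAsFactors = FALSE)
  # reverse column order so the last position varies fastest => lexicographic
  do.call(paste0, rev(g))
}

triplet_names <- function() {
  paste0(rep(RNA_ALPHABET, each = length(TRIPLET_PATTERNS)),
         rep(TRIPLET_PATTERNS, times = length(RNA_ALPHABET)))
}

#' The frozen 98-column feature schema
#'
#' Column order is fixed and version-stamped: 64 trinucleotide frequencies
#' (`AAA` ... `UUU`, lexicographic), 32 triplet structure-sequence codes
#' (nucleotide major, bracket pattern minor: `(((`, `((.`, `(.(`, `(..`,
#' `.((`, `.(.`, `..(`, `...`), then `MFE` and `GU_pairs`.
#'
#' @return Character vector of the 98 feature names, with attribute
#'   `"version"`.
#' @export
feature_schema <- function() {
  structure(c(kmer_names(3), triplet_names(), "MFE", "GU_pairs"),
            version = FEATURE_SCHEMA_VERSION)
}

#' Overlapping n-gram frequencies of a sequence
#'
#' Counts every overlapping window of length `n` and divides by the number
#' of windows `L - n + 1`, so the block sums to one for any sequence of
#' length at least `n`.
#'
#' @param seq One canonical RNA sequence.
#' @param n Window length (3 gives the 64 trinucleotide features).
#' @return Named numeric vector of length `4^n` in lexicographic key order.
#' @examples
#' ngram_frequencies("ACGU")[c("ACG", "CGU")]
#' @export
ngram_frequencies <- function(seq, n = 3) {
  seq <- canonicalize_rna(seq)
  L <- nchar(seq)
  if (L < n) {
    rlang::abort(sprintf("sequence of length %d is too short for %d-grams", L, n),
                 class = "mirboost_input_error")
  }
  starts <- seq_len(L - n + 1)
  kmers <- substring(seq, starts, starts + n - 1)
  counts <- table(factor(kmers, levels = kmer_names(n)))
  stats::setNames(as.numeric(counts) / length(starts), kmer_names(n))
}

#' Unify dot-bracket orientation
#'
#' Replaces every `)` by `(`, so each position carries only a paired /
#' unpaired state. Idempotent.
#'
#' @param dotbracket Dot-bracket string(s).
#' @return String(s) over `{'(', '.'}` of the same length.
#' @export
unify_brackets <- function(dotbracket) {
  chartr(")", "(", dotbracket)
}

#' Triplet structure-sequence counts
#'
#' For every window of three consecutive positions the code combines the
#' window's first nucleotide with its three-position paired/unpaired pattern
#' (brackets unified), giving 4 x 8 = 32 codes. Raw window counts are
#' returned; they sum to `L - 2`.
#'
#' @param seq Canonical RNA sequence.
#' @param structure Dot-bracket of the same length (unified internally).
#' @return Named numeric vector of length 32 in schema order.
#' @examples
#' triplet_structure_counts("ACGU", "((..")
#' @export
triplet_structure_counts <- function(seq, structure) {
  seq <- canonicalize_rna(seq)
  L <- nchar(seq)
  if (nchar(structure) != L) {
    rlang::abort("sequence and structure lengths differ",
                 class = "mirboost_input_error")
  }
  if (L < 3) {
    rlang::abort("sequence shorter than 3 cannot be featurized",
                 class = "mirboost_input_error")
  }
  unified <- unify_brackets(structure)
  starts <- seq_len(L - 2)
  codes <- paste0(substring(seq, starts, starts),
                  substring(unified, starts, starts + 2))
  counts <- table(factor(codes, levels = triplet_names()))
  stats::setNames(as.numeric(counts), triplet_names())
}

#' Count G-U wobble pairs
#'
#' @param seq Canonical RNA sequence.
#' @param pairs Two-column 1-based base-pair matrix (as from
#'   [pairs_from_dotbracket()]).
#' @return Number of pairs whose partners are `{G, U}` in either order.
#' @export
gu_pair_count <- function(seq, pairs) {
  seq <- canonicalize_rna(seq)
  if (!nrow(pairs)) return(0)
  if (max(pairs) > nchar(seq)) {
    rlang::abort("pair index beyond sequence length",
                 class = "mirboost_input_error")
  }
  a <- substring(seq, pairs[, 1], pairs[, 1])
  b <- substring(seq, pairs[, 2], pairs[, 2])
  sum((a == "G" & b == "U") | (a == "U" & b == "G"))
}

#' Extract the 98-dimensional feature vector of one record
#'
#' Concatenates, in frozen schema order, the 64 trinucleotide frequencies,
#' the 32 triplet structure-sequence counts, the folding energy (`MFE`,
#' kcal/mol under the thermodynamic backend, minus the pair count under the
#' fallback) and the G-U wobble pair count. A pure function of
#' `(sequence, structure, energy)`.
#'
#' @param sequence Canonical RNA sequence (length >= 3).
#' @param structure Dot-bracket of the same length.
#' @param energy Folding energy score of `structure`.
#' @return Named numeric vector of length 98 following [feature_schema()].
#' @examples
#' f <- fold_nussinov("GGGCGCAAAAGCGCCC")
#' extract_features("GGGCGCAAAAGCGCCC", f$structure, f$energy)[c("MFE", "GU_pairs")]
#' @export
extract_features <- function(sequence, structure, energy) {
  sequence <- canonicalize_rna(sequence)
  pairs <- pairs_from_dotbracket(structure)
  c(ngram_frequencies(sequence, 3),
    triplet_structure_counts(sequence, structure),
    MFE = as.numeric(energy),
    GU_pairs = as.numeric(gu_pair_count(sequence, pairs)))
}

#' Feature table of folded records
#'
#' Maps [extract_features()] over a folded record table.
#'
#' @param folded A data frame with `id`, `sequence`, `structure`, `energy`
#'   columns, as returned by [fold_rna()].
#' @return A tibble: `id` plus the 98 schema columns, one row per record.
#' @examples
#' recs <- tibble::tibble(id = "hp1", sequence = "GGGCGCAAAAGCGCCC")
#' hairpin_features(fold_rna(recs, backend = "nussinov"))
#' @export
hairpin_features <- function(folded) {
  need <- c("id", "sequence", "structure", "energy")
  if (!is.data.frame(folded) || !all(need %in% names(folded))) {
    rlang::abort("expected a folded record table with id/sequence/structure/energy",
                 class = "mirboost_input_error")
  }
  mat <- t(mapply(extract_features, folded$sequence, folded$structure,
                  folded$energy, USE.NAMES = FALSE))
  colnames(mat) <- feature_schema()
  dplyr::bind_cols(tibble::tibble(id = as.character(folded$id)),
                   tibble::as_tibble(mat))
}

#' Turn a feature tibble into the model's numeric matrix
#'
#' Validates that all 98 schema columns are present and correctly ordered.
#' @param features Tibble from [hairpin_features()] (the `id` column is
#'   dropped if present).
#' @return Numeric matrix, rows named by `id` when available.
#' @export
feature_matrix <- function(features) {
  schema <- feature_schema()
  if (!all(schema %in% names(features))) {
    missing <- setdiff(schema, names(features))
    rlang::abort(sprintf("feature table is missing %d schema columns (first: %s)",
                         length(missing), missing[1]),
                 class = "mirboost_input_error")
  }
  m <- as.matrix(features[, schema])
  if ("id" %in% names(features)) rownames(m) <- features$id
  storage.mode(m) <- "double"
  m
}
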
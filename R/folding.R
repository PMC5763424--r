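RNA_ALPHABET <- c("A", "C", "G", "U")

# base pairs admitted in the fallback folder: Watson-Crick plus G-U wobble
PAIRABLE <- matrix(FALSE, 4, 4, dimnames = list(RNA_ALPHABET, RNA_ALPHABET))
PAIRABLE["A", "U"] <- PAIRABLE["U", "A"] <- TRUE
PAIRABLE["G", "C"] <- PAIRABLE["C", "G"] <- TRUE
PAIRABLE["G", "U"] <- PAIRABLE["U", "G"] <- TRUE

#' Canonicalize RNA sequences
#'
#' Uppercases, maps DNA-style `T` to `U`, and rejects any character outside
#' the `{A, C, G, U, T}` alphabet (case-insensitive), reporting the position
#' of the first offending character.
#'
#' @param x Character vector of raw sequences.
#' @return Character vector of canonical RNA sequences over `{A, C, G, U}`.
#' @examples
#' canonicalize_rna(c("acgt", "GGGaaaCCC"))
#' @export
canonicalize_rna <- function(x) {
  if (!is.character(x) || length(x) == 0 || any(is.na(x)) || any(!nzchar(x))) {
    rlang::abort("sequences must be non-empty, non-missing character strings",
                 class = "mirboost_input_error")
  }
  out <- chartr("T", "U", toupper(x))
  bad <- regexpr("[^ACGU]", out)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    pos <- as.integer(bad[i])
    rlang::abort(
      sprintf("illegal character '%s' at position %d of sequence %d",
              substr(out[i], pos, pos), pos, i),
      class = "mirboost_alphabet_error", position = pos, record = i
    )
  }
  out
}

#' Base-pair table of a dot-bracket string
#'
#' Stack-based matching of `(` with `)`. Pairs are 1-based `(i, j)` with
#' `i < j`; pseudoknots cannot be expressed in plain dot-bracket so no index
#' appears twice.
#'
#' @param dotbracket A string over `(`, `)`, `.`.
#' @return Two-column integer matrix with columns `i` and `j` (zero rows for
#'   an unpaired structure).
#' @examples
#' pairs_from_dotbracket("((...))")
#' @export
pairs_from_dotbracket <- function(dotbracket) {
  stopifnot(is.character(dotbracket), length(dotbracket) == 1)
  chars <- strsplit(dotbracket, "", fixed = TRUE)[[1]]
  if (length(chars) && any(!chars %in% c("(", ")", "."))) {
    rlang::abort(sprintf("invalid structure character at position %d",
                         which(!chars %in% c("(", ")", "."))[1]),
                 class = "mirboost_structure_error")
  }
  stack <- integer(0)
  out <- matrix(0L, nrow = sum(chars == ")"), ncol = 2,
                dimnames = list(NULL, c("i", "j")))
  k <- 0L
  for (p in seq_along(chars)) {
    if (chars[p] == "(") {
      stack <- c(stack, p)
    } else if (chars[p] == ")") {
      if (!length(stack)) {
        rlang::abort(sprintf("unbalanced dot-bracket: unmatched ')' at position %d", p),
                     class = "mirboost_structure_error", position = p)
      }
      k <- k + 1L
      out[k, ] <- c(stack[length(stack)], p)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) {
    rlang::abort(sprintf("unbalanced dot-bracket: unmatched '(' at position %d", stack[1]),
                 class = "mirboost_structure_error", position = stack[1])
  }
  out[order(out[, 1]), , drop = FALSE]
}

dotbracket_from_pairs <- function(pairs, len) {
  chars <- rep(".", len)
  if (nrow(pairs)) {
    chars[pairs[, 1]] <- "("
    chars[pairs[, 2]] <- ")"
  }
  paste(chars, collapse = "")
}

#' Fold one sequence by base-pair maximization
#'
#' Deterministic Nussinov-style dynamic program maximizing the number of
#' admissible base pairs (A-U, G-C and G-U wobble) subject to a minimum
#' hairpin loop of `min_loop` unpaired nucleotides. The traceback is fixed:
#' at each interval the 5' end is paired with the smallest partner index that
#' attains the optimum, and pairing is preferred over leaving it unpaired, so
#' identical input always yields an identical structure. The energy score is
#' minus the pair count (a unitless stability proxy, not kcal/mol).
#'
#' @param seq One canonical RNA sequence.
#' @param min_loop Minimum number of unpaired bases enclosed by a pair.
#' @return A list with `structure` (dot-bracket), `energy`, `pairs`
#'   (1-based matrix) and `backend = "nussinov"`.
#' @examples
#' fold_nussinov("GGGAAACCC")
#' @export
fold_nussinov <- function(seq, min_loop = 3) {
  seq <- canonicalize_rna(seq)
  n <- nchar(seq)
  b <- match(strsplit(seq, "", fixed = TRUE)[[1]], RNA_ALPHABET)
  can <- PAIRABLE[b, b, drop = FALSE]
  M <- matrix(0L, n, n)
  span_min <- min_loop + 1L
  if (n > span_min) {
    for (span in span_min:(n - 1L)) {
      for (i in seq_len(n - span)) {
        j <- i + span
        best <- M[i + 1L, j]
        ks <- (i + span_min):j
        ks <- ks[can[i, ks]]
        if (length(ks)) {
          left <- ifelse(ks - 1L > i, M[cbind(i + 1L, pmax(ks - 1L, i + 1L))], 0L)
          right <- ifelse(ks < j, M[cbind(pmin(ks + 1L, j), j)], 0L)
          best <- max(best, 1L + left + right)
        }
        M[i, j] <- best
      }
    }
  }
  # iterative traceback over an explicit interval stack
  pairs <- matrix(0L, 0, 2, dimnames = list(NULL, c("i", "j")))
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    while (i < j && j - i >= span_min) {
      target <- M[i, j]
      ks <- (i + span_min):j
      ks <- ks[can[i, ks]]
      paired <- FALSE
      for (k in ks) {
        left <- if (k - 1L > i) M[i + 1L, k - 1L] else 0L
        right <- if (k < j) M[k + 1L, j] else 0L
        if (1L + left + right == target) {
          pairs <- rbind(pairs, c(i, k))
          if (k < j) stack[[length(stack) + 1L]] <- c(k + 1L, j)
          j <- k - 1L
          i <- i + 1L
          paired <- TRUE
          break
        }
      }
      if (!paired) i <- i + 1L
    }
  }
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  colnames(pairs) <- c("i", "j")
  list(structure = dotbracket_from_pairs(pairs, n),
       energy = -as.numeric(nrow(pairs)),
       pairs = pairs,
       backend = "nussinov")
}

#' Is the external RNAfold backend available?
#' @return `TRUE` when the `RNAfold` executable is on the PATH.
#' @export
vienna_available <- function() {
  nzchar(Sys.which("RNAfold"))
}

#' Fold sequences with the external RNAfold program
#'
#' Runs ViennaRNA's `RNAfold` once over all sequences and parses the
#' minimum-free-energy structure and its energy (kcal/mol) per record.
#'
#' @param seqs Character vector of canonical RNA sequences.
#' @param ids Optional record identifiers (defaults to `seq_along(seqs)`).
#' @return A tibble with columns `id`, `structure`, `energy`,
#'   `backend = "vienna"`.
#' @export
fold_vienna <- function(seqs, ids = NULL) {
  seqs <- canonicalize_rna(seqs)
  if (is.null(ids)) ids <- as.character(seq_along(seqs))
  if (!vienna_available()) {
    rlang::abort("RNAfold executable not found on PATH",
                 class = "mirboost_backend_unavailable")
  }
  fa <- tempfile(fileext = ".fa")
  on.exit(unlink(fa), add = TRUE)
  writeLines(paste0(">", ids, "\n", seqs), fa)
  out <- suppressWarnings(
    system2("RNAfold", c("--noPS", "--infile", fa), stdout = TRUE, stderr = FALSE)
  )
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    rlang::abort("RNAfold exited with non-zero status",
                 class = "mirboost_backend_unavailable")
  }
  struct_lines <- out[!startsWith(out, ">")]
  struct_lines <- struct_lines[seq(2, length(struct_lines), by = 2)]
  m <- regmatches(struct_lines,
                  regexec("^([().]+)\\s+\\(\\s*(-?[0-9.]+)\\)\\s*$", struct_lines))
  if (length(m) != length(seqs) || any(lengths(m) != 3)) {
    rlang::abort("could not parse RNAfold output",
                 class = "mirboost_backend_unavailable")
  }
  tibble::tibble(
    id = as.character(ids),
    structure = vapply(m, `[`, "", 2),
    energy = as.numeric(vapply(m, `[`, "", 3)),
    backend = "vienna"
  )
}

#' Fold a table of RNA records
#'
#' Adds a secondary structure and energy score to each record, using the
#' thermodynamic RNAfold backend when available (`backend = "auto"`) and the
#' deterministic base-pair-maximization fallback otherwise. The backend that
#' produced each structure is recorded per record.
#'
#' @param records A data frame with columns `id` and `sequence` (extra
#'   columns are carried through).
#' @param backend `"auto"`, `"vienna"` or `"nussinov"`.
#' @param min_loop Minimum hairpin loop size for the fallback folder.
#' @return The input tibble with canonicalized `sequence` plus `structure`,
#'   `energy` and `backend` columns.
#' @examples
#' recs <- tibble::tibble(id = "hp1", sequence = "GGGCGCAAAAGCGCCC")
#' fold_rna(recs, backend = "nussinov")
#' @export
fold_rna <- function(records, backend = c("auto", "vienna", "nussinov"),
                     min_loop = 3) {
  backend <- match.arg(backend)
  records <- validate_records(records)
  if (backend == "auto") {
    backend <- if (vienna_available()) "vienna" else "nussinov"
  }
  if (backend == "vienna") {
    folded <- fold_vienna(records$sequence, records$id)
    dplyr::left_join(records, folded, by = "id")
  } else {
    fb <- purrr::map(records$sequence, fold_nussinov, min_loop = min_loop)
    dplyr::mutate(records,
                  structure = purrr::map_chr(fb, "structure"),
                  energy = purrr::map_dbl(fb, "energy"),
                  backend = "nussinov")
  }
}

validate_records <- function(records) {
  if (!is.data.frame(records) || !all(c("id", "sequence") %in% names(records))) {
    rlang::abort("records must be a data frame with 'id' and 'sequence' columns",
                 class = "mirboost_input_error")
  }
  records <- tibble::as_tibble(records)
  if (anyDuplicated(records$id)) {
    dup <- records$id[duplicated(records$id)][1]
    rlang::abort(sprintf("duplicate record id '%s'", dup),
                 class = "mirboost_input_error")
  }
  records$id <- as.character(records$id)
  records$sequence <- canonicalize_rna(records$sequence)
  records
}
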
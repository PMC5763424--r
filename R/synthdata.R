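COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")

#' Configuration of the synthetic hairpin generator
#'
#' The generator emulates the two classes the classifier must separate:
#' positives are stem-loops — a random 5' arm, a short loop, and the arm's
#' reverse complement with sparse per-position mismatches — while negatives
#' are mononucleotide shuffles of such hairpins, which preserve base
#' composition but destroy the long complementary stem. Species identity is
#' injected through per-species GC content of the 5' arm.
#'
#' @param n_pos,n_neg Numbers of positive (hairpin) and negative (shuffled)
#'   records.
#' @param stem_len Length of each stem arm in nt (default 22, the scale of a
#'   mature-miRNA-bearing arm; total length `2 * stem_len + loop_len`).
#' @param loop_len Loop length in nt.
#' @param mutation_rate Per-stem-position probability that the 3' arm base is
#'   replaced by a random base (mismatch/bulge proxy), default 0.05.
#' @param n_species Number of species labels for the positives.
#' @param species_gc Per-species GC content of the 5' arm, in `[0, 1]`;
#'   defaults to seven values evenly spaced over 0.25-0.75.
#' @param dinucleotide_shuffle Use a dinucleotide-preserving shuffle for the
#'   negatives instead of the default mononucleotide shuffle (harder
#'   negatives).
#' @param seed Integer seed recorded in the manifest.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_pos = 400, n_neg = 400, stem_len = 22,
                         loop_len = 6, mutation_rate = 0.05, n_species = 7,
                         species_gc = NULL, dinucleotide_shuffle = FALSE,
                         seed = 1) {
  if (is.null(species_gc)) {
    species_gc <- seq(0.25, 0.75, length.out = n_species)
  }
  stopifnot(n_pos >= 1, n_neg >= 0, stem_len >= 1, loop_len >= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            n_species >= 1, length(species_gc) == n_species,
            all(species_gc >= 0 & species_gc <= 1))
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 stem_len = as.integer(stem_len),
                 loop_len = as.integer(loop_len),
                 mutation_rate = mutation_rate,
                 n_species = as.integer(n_species),
                 species_gc = species_gc,
                 species = sprintf("sp%02d", seq_len(n_species)),
                 dinucleotide_shuffle = isTRUE(dinucleotide_shuffle),
                 seed = as.integer(seed)),
            class = "synth_config")
}

sample_bases <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  sample(names(p), n, replace = TRUE, prob = p)
}

#' Generate one synthetic hairpin sequence
#'
#' 5' arm sampled at the given GC content, a loop, then the reverse
#' complement of the arm with each position independently replaced by a
#' uniform random base at `mutation_rate`. Uses the current RNG stream.
#'
#' @param config A [synth_config()].
#' @param gc GC content of the 5' arm (defaults to the first species bias).
#' @return A single sequence string of length `2 * stem_len + loop_len`.
#' @export
generate_hairpin <- function(config = synth_config(), gc = config$species_gc[1]) {
  arm <- sample_bases(config$stem_len, gc)
  loop <- sample_bases(config$loop_len, 0.5)
  close <- rev(unname(COMPLEMENT[arm]))
  mut <- stats::runif(config$stem_len) < config$mutation_rate
  if (any(mut)) close[mut] <- sample(names(COMPLEMENT), sum(mut), replace = TRUE)
  paste(c(arm, loop, close), collapse = "")
}

shuffle_mono <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  paste(chars[sample.int(length(chars))], collapse = "")
}

# dinucleotide-preserving shuffle via a random Eulerian-style reordering:
# shuffle, within each source base, the multiset of successor bases
shuffle_dinuc <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 3) return(seq)
  succ <- split(chars[-1], chars[-n])
  succ <- lapply(succ, function(s) s[sample.int(length(s))])
  out <- character(n)
  out[1] <- chars[1]
  ptr <- stats::setNames(rep(1L, length(succ)), names(succ))
  ok <- TRUE
  for (i in 2:n) {
    b <- out[i - 1]
    if (is.null(succ[[b]]) || ptr[[b]] > length(succ[[b]])) { ok <- FALSE; break }
    out[i] <- succ[[b]][ptr[[b]]]
    ptr[[b]] <- ptr[[b]] + 1L
  }
  # a random successor order can strand the walk; fall back to a fresh try
  if (!ok) return(shuffle_dinuc(seq))
  paste(out, collapse = "")
}

#' Generate one pseudo-hairpin (negative) sequence
#'
#' Draws a hairpin and returns its composition-matched shuffle
#' (mononucleotide by default), so the negative shares base composition with
#' the positive class but lacks its long stem.
#'
#' @param config A [synth_config()].
#' @param gc GC content passed to the underlying hairpin draw.
#' @return A single shuffled sequence string.
#' @export
generate_pseudo <- function(config = synth_config(), gc = config$species_gc[1]) {
  hp <- generate_hairpin(config, gc)
  if (config$dinucleotide_shuffle) shuffle_dinuc(hp) else shuffle_mono(hp)
}

#' Generate a labeled synthetic dataset
#'
#' `n_pos` hairpins spread as evenly as possible over the species (each at
#' its species' GC bias) plus `n_neg` shuffled negatives labeled
#' `"pseudo"`, in a reproducible seeded draw. The attached `manifest`
#' attribute records the full configuration, seed and package version.
#'
#' @param config A [synth_config()].
#' @return Tibble with columns `id`, `sequence`, `label` (1 real / 0
#'   pseudo), `species`; attribute `manifest`.
#' @examples
#' d <- generate_dataset(synth_config(n_pos = 6, n_neg = 4, seed = 42))
#' dplyr::count(d, label, species)
#' @export
generate_dataset <- function(config = synth_config()) {
  out <- withr::with_seed(config$seed, {
    sp_idx <- rep_len(seq_len(config$n_species), config$n_pos)
    pos <- tibble::tibble(
      id = sprintf("pos%05d", seq_len(config$n_pos)),
      sequence = vapply(sp_idx, function(i)
        generate_hairpin(config, config$species_gc[i]), ""),
      label = 1L,
      species = config$species[sp_idx]
    )
    if (config$n_neg > 0) {
      neg_idx <- rep_len(seq_len(config$n_species), config$n_neg)
      neg <- tibble::tibble(
        id = sprintf("neg%05d", seq_len(config$n_neg)),
        sequence = vapply(neg_idx, function(i)
          generate_pseudo(config, config$species_gc[i]), ""),
        label = 0L,
        species = "pseudo"
      )
      dplyr::bind_rows(pos, neg)
    } else {
      pos
    }
  })
  attr(out, "manifest") <- c(unclass(config),
                             list(version = as.character(utils::packageVersion("mirboost"))))
  out
}
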
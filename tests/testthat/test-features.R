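test_that("the feature schema is frozen at 98 named columns", {
  schema <- feature_schema()
  expect_length(schema, 98)
  expect_false(anyDuplicated(schema) > 0)
  expect_identical(schema[1], "AAA")
  expect_identical(schema[64], "UUU")
  expect_identical(schema[65], "A(((")
  expect_identical(schema[97:98], c("MFE", "GU_pairs"))
  expect_identical(attr(schema, "version"), "98/1")
})

test_that("trinucleotide frequencies match a brute-force window tally", {
  f <- ngram_frequencies("AAA")
  expect_equal(unname(f["AAA"]), 1)
  expect_equal(sum(f), 1)
  f2 <- ngram_frequencies("ACGU")
  expect_equal(unname(f2[c("ACG", "CGU")]), c(0.5, 0.5))
  expect_equal(sum(f2 != 0), 2)
  withr::with_seed(13, seqs <- c("ACGUACGU", replicate(20, random_rna(sample(3:40, 1)))))
  for (s in seqs) {
    got <- ngram_frequencies(s)
    oracle <- bf_kmer_freq(s, 3)
    expect_equal(got[names(oracle)], oracle, info = s)
    expect_equal(sum(got), 1, tolerance = 1e-9)
  }
  expect_error(ngram_frequencies("AC"), class = "mirboost_input_error")
})

test_that("a sequence and its reverse give k-mer blocks permuted by k-mer reversal", {
  rev_str <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  withr::with_seed(5, s <- random_rna(30))
  f_fwd <- ngram_frequencies(s)
  f_rev <- ngram_frequencies(rev_str(s))
  expect_equal(unname(f_rev[vapply(names(f_fwd), rev_str, "")]),
               unname(f_fwd))
})

test_that("bracket unification is literal and idempotent", {
  expect_identical(unify_brackets("(.)"), "(.(")
  expect_identical(unify_brackets("..."), "...")
  db <- "((..))().."
  expect_identical(unify_brackets(unify_brackets(db)), unify_brackets(db))
  expect_false(grepl(")", unify_brackets(db), fixed = TRUE))
})

test_that("triplet structure-sequence codes count every window once", {
  t1 <- triplet_structure_counts("AAA", "(((")
  expect_equal(unname(t1["A((("]), 1)
  expect_equal(sum(t1), 1)
  # two windows enumerated by hand: (A, "((.") and (C, "(..")
  t2 <- triplet_structure_counts("ACGU", "((..")
  expect_equal(unname(t2[c("A((.", "C(..")]), c(1, 1))
  expect_equal(sum(t2), 2)
  withr::with_seed(17, {
    for (rep in 1:10) {
      L <- sample(3:40, 1)
      s <- random_rna(L)
      db <- fold_nussinov(s)$structure
      counts <- triplet_structure_counts(s, db)
      expect_equal(sum(counts), L - 2)
      expect_true(all(counts >= 0 & counts == round(counts)))
      # invariant under unification of an already-unified structure
      expect_equal(counts, triplet_structure_counts(s, unify_brackets(db)))
    }
  })
  expect_error(triplet_structure_counts("ACGU", "((."),
               class = "mirboost_input_error")
})

test_that("G-U wobble pairs are counted symmetrically", {
  p <- matrix(c(1L, 4L), 1)
  expect_equal(gu_pair_count("GAAU", p), 1)
  expect_equal(gu_pair_count("UAAG", p), 1)
  expect_equal(gu_pair_count("GAAC", p), 0)
  s <- "GUGUGUGUAAAAUGUGUGU"
  pairs <- fold_nussinov(s)$pairs
  chars <- strsplit(s, "")[[1]]
  manual <- 0
  for (r in seq_len(nrow(pairs))) {
    duo <- sort(chars[pairs[r, ]])
    if (identical(duo, c("G", "U"))) manual <- manual + 1
  }
  expect_equal(gu_pair_count(s, pairs), manual)
})

test_that("extract_features concatenates the four blocks in schema order", {
  fv <- extract_features("AAAAAAAAA", strrep(".", 9), 0)
  expect_length(fv, 98)
  expect_identical(names(fv), as.character(feature_schema()))
  trip <- fv[65:96]
  expect_equal(unname(trip["A..."]), 7)
  expect_equal(sum(trip), 7)
  expect_equal(unname(fv["MFE"]), 0)
  expect_equal(unname(fv["GU_pairs"]), 0)
})

test_that("fixed 25-nt hairpin features agree with independent per-block oracles", {
  s <- FIXED_25NT
  fold <- fold_nussinov(s)
  fv <- extract_features(s, fold$structure, fold$energy)
  # block 1: brute-force k-mer tally
  oracle_kmer <- bf_kmer_freq(s, 3)
  expect_equal(fv[names(oracle_kmer)], oracle_kmer)
  expect_equal(sum(fv[1:64]), 1, tolerance = 1e-9)
  # block 2: manual window walk over the unified structure
  uni <- chartr(")", "(", fold$structure)
  manual <- stats::setNames(numeric(32), names(fv)[65:96])
  for (i in 1:(nchar(s) - 2)) {
    code <- paste0(substr(s, i, i), substr(uni, i, i + 2))
    manual[code] <- manual[code] + 1
  }
  expect_equal(fv[65:96], manual)
  # blocks 3-4: energy passthrough and a hand scan of the pair list
  expect_equal(unname(fv["MFE"]), fold$energy)
  chars <- strsplit(s, "")[[1]]
  gu <- sum(apply(fold$pairs, 1, function(p)
    identical(sort(chars[p]), c("G", "U"))))
  expect_equal(unname(fv["GU_pairs"]), gu)
})

test_that("hairpin_features is a pure tabular mapping with id column", {
  recs <- tibble::tibble(id = c("r1", "r2"),
                         sequence = c("GGGCGCAAAAGCGCCC", "ACGUACGUACGU"))
  folded <- fold_rna(recs, backend = "nussinov")
  ft <- hairpin_features(folded)
  expect_identical(dim(ft), c(2L, 99L))
  expect_identical(names(ft), c("id", as.character(feature_schema())))
  expect_identical(ft, hairpin_features(folded))  # pure
  m <- feature_matrix(ft)
  expect_identical(dim(m), c(2L, 98L))
  expect_error(feature_matrix(ft[, 1:50]), class = "mirboost_input_error")
})
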
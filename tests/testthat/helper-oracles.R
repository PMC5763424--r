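# independent oracles used across the suite; deliberately written as plain
# loops/recursion, sharing no code with the package internals

ORACLE_PAIRS <- c("AU", "UA", "GC", "CG", "GU", "UG")

# maximum base-pair count over every legal non-crossing structure, by
# exhaustive recursive enumeration of (pair i with k | leave i unpaired)
bf_max_pairs <- function(seq, min_loop = 3) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (paste0(chars[i], chars[k]) %in% ORACLE_PAIRS) {
        inner <- if (k - 1L >= i + 1L) rec(i + 1L, k - 1L) else 0L
        outer <- if (k + 1L <= j) rec(k + 1L, j) else 0L
        best <- max(best, 1L + inner + outer)
      }
    }
    best
  }
  if (n < 2) 0L else rec(1L, n)
}

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# sliding-window k-mer tally over all 4^k keys, normalized
bf_kmer_freq <- function(seq, k = 3) {
  counts <- new.env()
  L <- nchar(seq)
  for (i in seq_len(L - k + 1)) {
    key <- substr(seq, i, i + k - 1)
    assign(key, get0(key, envir = counts, ifnotfound = 0) + 1, envir = counts)
  }
  out <- numeric(0)
  for (key in sort(ls(counts))) out[key] <- get(key, envir = counts) / (L - k + 1)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a fixed 25-nt hairpin-like sequence reused as a worked example
FIXED_25NT <- "GGCGCAUGCAGAAAACUGCAUGCGC"

small_config <- function(n_inputs, n_hidden = 3, epochs = 30) {
  network_config(n_inputs = n_inputs, n_hidden = n_hidden, epochs = epochs)
}

# two well-separated 2-D Gaussian clouds; returns list(x, y01)
toy_gaussians <- function(n_per = 30, shift = 3, seed = 99) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per * 2), ncol = 2),
               matrix(rnorm(n_per * 2) + shift, ncol = 2))
    list(x = x, y = rep(c(0L, 1L), each = n_per))
  })
}

# hand-built constant weak learner (ignores input, returns `value`)
constant_weak <- function(value, n_inputs = 2) {
  structure(list(w1 = matrix(0, 1, n_inputs), b1 = 0, w2 = 0, b2 = value,
                 center = rep(0, n_inputs), scale = rep(1, n_inputs),
                 config = network_config(n_inputs, n_hidden = 1),
                 diagnostics = list(mse = 0, epochs_run = 0L,
                                    converged = TRUE, note = "constant")),
            class = "bp_weak")
}

# hand-built two-learner ensemble wrapper
manual_ensemble <- function(learners, alphas, class_map = c(negative = "0",
                                                            positive = "1")) {
  structure(list(learners = learners, alphas = alphas,
                 errors = rep(0.25, length(learners)),
                 weight_trace = NULL, n_rounds = length(learners),
                 class_map = class_map, threshold = 0,
                 config = learners[[1]]$config, n_train = NA_integer_,
                 seed = 0L, version = "test"),
            class = "bp_adaboost")
}
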
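# Independent oracles and shared fixtures for the test suite.

# Brute-force Lempel-Ziv exhaustive-history oracle: grows the current
# component one residue at a time and tests reproducibility by direct
# enumeration of every alignment of the candidate inside the sequence up to
# (but excluding) its last position. Independent of the package's scan.
oracle_lz <- function(sequence) {
  L <- nchar(sequence)
  n_components <- 0L
  start <- 1L
  while (start <= L) {
    end <- start
    repeat {
      q <- substr(sequence, start, end)
      space <- substr(sequence, 1L, end - 1L)
      nq <- nchar(q)
      ns <- nchar(space)
      found <- FALSE
      if (ns >= nq) {
        starts <- seq_len(ns - nq + 1L)
        found <- any(substring(space, starts, starts + nq - 1L) == q)
      }
      if (!found) {          # new component closed by insertion
        n_components <- n_components + 1L
        start <- end + 1L
        break
      }
      if (end == L) {        # trailing reproducible component
        n_components <- n_components + 1L
        start <- L + 1L
        break
      }
      end <- end + 1L
    }
  }
  n_components
}

# Direct O(L^2) summation of the discrete Fourier transform, k = 1..n.
oracle_dft <- function(signal, n_components = 10L) {
  L <- length(signal)
  n <- seq_len(L) - 1L
  X <- vapply(seq_len(n_components), function(k) {
    sum(signal * exp(-2i * pi * k * n / L))
  }, complex(1))
  list(amplitudes = Mod(X), phases = Arg(X))
}

random_protein <- function(L) {
  paste(sample(amino_acid_order(), L, replace = TRUE), collapse = "")
}

# Small, well-separated labeled family set reused across classifier and
# evaluation tests (no background class). Cached per session.
small_family_set <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- generate_fixture(fixture_spec(
        n_classes = 4L, per_class = 8L, length_range = c(60L, 70L),
        motif_length = 55L, mutation_rate = 0.001, n_background = 8L,
        seed = 42L))
      cache <<- list(records = fx,
                     x = featurize_records(fx),
                     is_nr = grepl("^NR[0-9]+$", fx$label))
    }
    cache
  }
})
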
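# Sequence-derived descriptor families: amino acid composition, gapped
# dipeptide composition, Lempel-Ziv complexity, and low-frequency Fourier
# spectrum components of physicochemical property signals.

.seq_chars <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  idx <- match(chars, amino_acid_order())
  if (anyNA(idx)) {
    stop("sequence contains non-canonical residues; validate it first")
  }
  idx
}

#' Amino acid composition
#'
#' Normalized occurrence frequencies of the 20 amino acid types: component u
#' is (count of residue u) / L. Components sum to 1.
#'
#' @param sequence Validated residue string.
#' @return Named numeric vector of length 20 in \code{\link{amino_acid_order}}.
#' @export
#' @examples
#' aac("AAC")  # A = 2/3, C = 1/3
aac <- function(sequence) {
  idx <- .seq_chars(sequence)
  if (length(idx) == 0L) stop("empty sequence")
  out <- tabulate(idx, nbins = 20L) / length(idx)
  names(out) <- amino_acid_order()
  out
}

#' Gapped dipeptide composition
#'
#' Frequencies of ordered residue pairs (a, b) separated by \code{g}
#' intervening positions: positions i with R(i) = a and R(i+g+1) = b, divided
#' by the number of such pairs, L - 1 - g, so the 400 components sum to 1.
#' \code{g = 0} is the classical dipeptide composition.
#'
#' @param sequence Validated residue string of length >= g + 2.
#' @param g Non-negative integer gap.
#' @return Named numeric vector of length 400 ordered first-residue-major
#'   (AA, AC, ..., AY, CA, ...).
#' @export
#' @examples
#' gapped_dipeptide("ACAC", g = 0)[c("AC", "CA")]  # 2/3, 1/3
gapped_dipeptide <- function(sequence, g) {
  stopifnot(length(g) == 1L, g >= 0, g == as.integer(g))
  g <- as.integer(g)
  idx <- .seq_chars(sequence)
  L <- length(idx)
  if (L < g + 2L) {
    stop(sprintf("sequence too short for gap %d: length %d < %d",
                 g, L, g + 2L))
  }
  first <- idx[seq_len(L - 1L - g)]
  second <- idx[seq_len(L - 1L - g) + g + 1L]
  pair <- (first - 1L) * 20L + second
  out <- tabulate(pair, nbins = 400L) / (L - 1L - g)
  aa <- amino_acid_order()
  names(out) <- paste0(rep(aa, each = 20L), rep(aa, times = 20L))
  out
}

#' Lempel-Ziv complexity of a residue string
#'
#' Decomposes the sequence by the exhaustive production process: scan left to
#' right, growing the current component Q one symbol at a time; Q is
#' reproducible while it occurs as a substring of the already-synthesized
#' prefix concatenated with Q minus its last character (equivalently, of the
#' sequence up to, but excluding, Q's last position). When Q stops being
#' reproducible it is closed as a component and a new one starts; a trailing
#' reproducible Q closes the final component. The complexity is the number
#' of components.
#'
#' @param sequence Validated residue string.
#' @return List of class \code{lz_synthesis} with \code{components}
#'   (character vector whose concatenation is the input) and
#'   \code{complexity} (integer count of components).
#' @export
#' @examples
#' lz_complexity("ACACA")  # components A, C, ACA -> complexity 3
lz_complexity <- function(sequence) {
  L <- nchar(sequence)
  if (L == 0L) stop("empty sequence")
  components <- character(0)
  start <- 1L
  while (start <= L) {
    end <- start
    closed <- FALSE
    while (end <= L) {
      q <- substr(sequence, start, end)
      space <- substr(sequence, 1L, end - 1L)
      if (!grepl(q, space, fixed = TRUE)) {
        components <- c(components, q)
        start <- end + 1L
        closed <- TRUE
        break
      }
      end <- end + 1L
    }
    if (!closed) {  # ran off the end while still reproducible
      components <- c(components, substr(sequence, start, L))
      start <- L + 1L
    }
  }
  structure(list(components = components,
                 complexity = length(components)),
            class = "lz_synthesis")
}

#' @export
print.lz_synthesis <- function(x, ...) {
  cat("LZ synthesis:", paste(x$components, collapse = " . "),
      sprintf("  (complexity %d)\n", x$complexity))
  invisible(x)
}

#' Convert a sequence to a physicochemical property signal
#'
#' Position n of the signal carries the standardized property value of
#' residue R(n) under one scale.
#'
#' @param sequence Validated residue string.
#' @param scale Named numeric vector over the 20 residues (one element of
#'   \code{\link{property_scales}}).
#' @return Numeric vector of length L.
#' @export
property_signal <- function(sequence, scale) {
  idx <- .seq_chars(sequence)
  if (length(idx) == 0L) stop("empty sequence")
  unname(scale[idx])
}

#' Low-frequency discrete Fourier spectrum of a signal
#'
#' Computes X(k) = sum_n x(n) exp(-2 pi i k n / L) for k = 1..n_components
#' (the constant k = 0 term is excluded: its phase is identically zero for a
#' real signal and its amplitude duplicates composition information) and
#' returns the amplitudes |X(k)| and phases arg(X(k)). A phase is reported as
#' 0 whenever its amplitude is below 1e-12, where arg() is numerically
#' meaningless.
#'
#' @param signal Numeric vector of length L >= 2 * n_components + 1, so all
#'   retained components lie below the conjugate-symmetry fold-over.
#' @param n_components Number of low-frequency components to keep.
#' @return List with \code{amplitudes} and \code{phases}, each of length
#'   \code{n_components}.
#' @export
dft_low_frequency <- function(signal, n_components = 10L) {
  L <- length(signal)
  stopifnot(n_components >= 1L)
  if (L < 2L * n_components + 1L) {
    stop(sprintf("signal too short: length %d < %d", L,
                 2L * n_components + 1L))
  }
  X <- stats::fft(signal)[seq_len(n_components) + 1L]
  amplitudes <- Mod(X)
  phases <- ifelse(amplitudes < 1e-12, 0, Arg(X))
  list(amplitudes = amplitudes, phases = phases)
}

#' Fourier spectrum components of a protein sequence
#'
#' For each property scale in fixed order (hydrophobicity, hydrophilicity,
#' side-chain mass) the sequence is converted to a property signal and the
#' 10 low-frequency amplitudes followed by their 10 phases are retained,
#' giving 60 values in total.
#'
#' @param sequence Validated residue string of length >= 21.
#' @param scales A \code{\link{property_scales}} object.
#' @param n_components Low-frequency components per scale (default 10).
#' @return Named numeric vector of length 6 * n_components.
#' @export
fourier_features <- function(sequence, scales = property_scales(),
                             n_components = 10L) {
  blocks <- lapply(names(scales), function(nm) {
    sig <- property_signal(sequence, scales[[nm]])
    sp <- dft_low_frequency(sig, n_components = n_components)
    out <- c(sp$amplitudes, sp$phases)
    names(out) <- c(paste0(nm, ".A", seq_len(n_components)),
                    paste0(nm, ".P", seq_len(n_components)))
    out
  })
  do.call(c, blocks)
}
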
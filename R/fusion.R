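# Fusion of the four descriptor families into the 881-dimension weighted
# pseudo amino acid composition (PseAAC) vector.
#
# Block layout (0-based offsets in brackets):
#   AAC  [0:20)    20 amino acid composition frequencies
#   DC0  [20:420)  400 classical dipeptide frequencies (gap 0)
#   DC1  [420:820) 400 one-gap dipeptide frequencies
#   CF   [820:821) 1 Lempel-Ziv complexity count
#   FSC  [821:881) 60 Fourier spectrum components

#' Fusion weight factors
#'
#' Weight factors applied to the descriptor blocks when they are fused into
#' the 881-D PseAAC vector: the 800 dipeptide components are multiplied by
#' \code{w_dc} (default 20), the complexity factor by \code{w_cf} and the 60
#' Fourier components by \code{w_fsc} (both default 1); the 20 composition
#' components are never weighted.
#'
#' @param w_dc,w_cf,w_fsc Positive weight factors.
#' @return List of class \code{fusion_weights}.
#' @export
fusion_weights <- function(w_dc = 20, w_cf = 1, w_fsc = 1) {
  stopifnot(w_dc > 0, w_cf > 0, w_fsc > 0)
  structure(list(w_dc = w_dc, w_cf = w_cf, w_fsc = w_fsc),
            class = "fusion_weights")
}

#' PseAAC block layout
#'
#' @return Named list of integer index vectors into the 881-D vector, one per
#'   block (AAC, DC0, DC1, CF, FSC).
#' @export
pseaac_layout <- function() {
  list(AAC = 1:20, DC0 = 21:420, DC1 = 421:820, CF = 821L, FSC = 822:881)
}

#' Fuse descriptor blocks into one PseAAC vector
#'
#' Weighted concatenation in layout order: AAC unweighted, DC blocks scaled
#' by \code{w_dc}, CF by \code{w_cf}, FSC by \code{w_fsc}.
#'
#' @param aac 20 amino acid composition values.
#' @param dc0 400 gap-0 dipeptide values.
#' @param dc1 400 gap-1 dipeptide values.
#' @param cf Scalar complexity factor.
#' @param fsc 60 Fourier spectrum values.
#' @param weights A \code{\link{fusion_weights}} object.
#' @return Named numeric vector of length 881.
#' @export
fuse <- function(aac, dc0, dc1, cf, fsc, weights = fusion_weights()) {
  sizes <- c(AAC = 20L, DC0 = 400L, DC1 = 400L, CF = 1L, FSC = 60L)
  got <- c(AAC = length(aac), DC0 = length(dc0), DC1 = length(dc1),
           CF = length(cf), FSC = length(fsc))
  bad <- names(sizes)[got != sizes]
  if (length(bad) > 0L) {
    stop("wrong block dimension for ", paste(bad, collapse = ", "),
         " (expected ", paste(sizes[bad], collapse = ", "),
         ", got ", paste(got[bad], collapse = ", "), ")")
  }
  v <- c(aac,
         dc0 * weights$w_dc,
         dc1 * weights$w_dc,
         cf * weights$w_cf,
         fsc * weights$w_fsc)
  names(v) <- pseaac_colnames()
  v
}

pseaac_colnames <- function() {
  aa <- amino_acid_order()
  dc <- paste0(rep(aa, each = 20L), rep(aa, times = 20L))
  c(paste0("AAC.", aa), paste0("DC0.", dc), paste0("DC1.", dc), "CF",
    paste0("FSC.", names(fourier_feature_names())))
}

fourier_feature_names <- function(n_components = 10L) {
  nms <- unlist(lapply(c("hydrophobicity", "hydrophilicity",
                         "side_chain_mass"), function(nm) {
    c(paste0(nm, ".A", seq_len(n_components)),
      paste0(nm, ".P", seq_len(n_components)))
  }))
  stats::setNames(seq_along(nms), nms)
}

#' Featurize one validated protein sequence
#'
#' Computes all four descriptor families and fuses them into the 881-D
#' weighted PseAAC vector. Deterministic for a fixed sequence and
#' configuration.
#'
#' @param sequence Validated residue string of length >= 21.
#' @param weights A \code{\link{fusion_weights}} object.
#' @param scales A \code{\link{property_scales}} object.
#' @return Named numeric vector of length 881.
#' @export
#' @examples
#' v <- featurize(strrep("ACDEFGHIKLMNPQRSTVWY", 2))
#' length(v)  # 881
featurize <- function(sequence, weights = fusion_weights(),
                      scales = property_scales()) {
  fuse(aac(sequence),
       gapped_dipeptide(sequence, g = 0L),
       gapped_dipeptide(sequence, g = 1L),
       lz_complexity(sequence)$complexity,
       fourier_features(sequence, scales = scales),
       weights = weights)
}

#' Featurize a set of protein records
#'
#' @param records data.frame with columns id and sequence (validated).
#' @inheritParams featurize
#' @return Numeric matrix, one row per record (rownames = id), 881 columns.
#' @export
featurize_records <- function(records, weights = fusion_weights(),
                              scales = property_scales()) {
  m <- t(vapply(records$sequence, featurize, numeric(881L),
                weights = weights, scales = scales, USE.NAMES = FALSE))
  rownames(m) <- records$id
  m
}

#' Column indices of a feature-ablation mode
#'
#' Modes select descriptor blocks of the fused vector: \code{AAC},
#' \code{AAC+DC(0)}, \code{AAC+DC(1)}, \code{AAC+CF}, \code{AAC+FSC} and
#' \code{ALL}.
#'
#' @param mode Mode name.
#' @return Integer vector of column indices into the 881-D layout.
#' @export
feature_mode_columns <- function(mode) {
  lay <- pseaac_layout()
  modes <- list(
    "AAC" = lay$AAC,
    "AAC+DC(0)" = c(lay$AAC, lay$DC0),
    "AAC+DC(1)" = c(lay$AAC, lay$DC1),
    "AAC+CF" = c(lay$AAC, lay$CF),
    "AAC+FSC" = c(lay$AAC, lay$FSC),
    "ALL" = seq_len(881L)
  )
  if (!mode %in% names(modes)) {
    stop("unknown feature mode '", mode, "'; valid modes: ",
         paste(names(modes), collapse = ", "))
  }
  modes[[mode]]
}

#' Export a feature matrix as TSV
#'
#' @param m Feature matrix from \code{\link{featurize_records}}.
#' @param path Output TSV path (identifier column + one column per feature).
#' @return Invisibly, \code{path}.
#' @export
write_feature_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
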
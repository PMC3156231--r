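#' The canonical amino acid ordering
#'
#' All descriptor blocks index the 20 native amino acid types in this fixed
#' alphabetical one-letter order; every composition vector, property table and
#' feature layout in the package uses it.
#'
#' @return Character vector of the 20 one-letter codes, alphabetical.
#' @export
#' @examples
#' amino_acid_order()
amino_acid_order <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Load amino acid physicochemical property scales
#'
#' Reads a three-column property table (hydrophobicity, hydrophilicity and
#' side-chain mass per residue) and standardizes each scale to zero mean and
#' unit standard deviation over the 20 residues. Standardization uses the
#' population form (divisor 20), the convention of pseudo amino acid
#' composition, so scales with very different units contribute comparably to
#' the property signals.
#'
#' @param path Path to a TSV with columns \code{residue},
#'   \code{hydrophobicity}, \code{hydrophilicity}, \code{side_chain_mass}.
#'   Defaults to the table shipped with the package.
#' @return An object of class \code{property_scales}: a named list of three
#'   numeric vectors (one value per residue, in \code{\link{amino_acid_order}}),
#'   each standardized, with the raw table kept in attribute \code{"raw"}.
#' @export
#' @examples
#' sc <- property_scales()
#' sapply(sc, mean)  # all ~0
property_scales <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "property_scales.tsv", package = "nrpred",
                        mustWork = TRUE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("residue", "hydrophobicity", "hydrophilicity", "side_chain_mass")
  if (!all(need %in% names(tab))) {
    stop("property scale table must have columns: ",
         paste(need, collapse = ", "))
  }
  aa <- amino_acid_order()
  if (!setequal(tab$residue, aa)) {
    stop("property scale table must cover exactly the 20 canonical residues")
  }
  tab <- tab[match(aa, tab$residue), ]
  standardize <- function(v) {
    v <- as.numeric(v)
    mu <- mean(v)
    sdev <- sqrt(mean((v - mu)^2))
    z <- (v - mu) / sdev
    names(z) <- aa
    z
  }
  out <- list(
    hydrophobicity = standardize(tab$hydrophobicity),
    hydrophilicity = standardize(tab$hydrophilicity),
    side_chain_mass = standardize(tab$side_chain_mass)
  )
  attr(out, "raw") <- tab
  class(out) <- "property_scales"
  out
}

#' @export
print.property_scales <- function(x, ...) {
  cat("Amino acid property scales (standardized over 20 residues):\n")
  for (nm in names(x)) {
    cat(sprintf("  %-15s mean=%.2e sd=%.4f\n", nm, mean(x[[nm]]),
                sqrt(mean((x[[nm]] - mean(x[[nm]]))^2))))
  }
  invisible(x)
}
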
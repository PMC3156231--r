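# Sequence input/output and validation.
#
# Protein sets are plain data.frames with columns `id`, `sequence`, and
# `label` (NA when unknown). Class labels follow the nuclear receptor
# convention: NR0..NR6 for the seven subfamilies (or NR1..NRk for synthetic
# families) and NONNR for non-receptor background.

.min_sequence_length <- 21L

.label_pattern <- "^(NR[0-9]+|NONNR)$"

#' Read protein sequences from a FASTA file
#'
#' Accepts multi-record FASTA with arbitrary line wrapping; lines starting
#' with ';' (old-style comments) are ignored. The identifier is the header
#' text up to the first whitespace. A class label may be carried in the final
#' '|'-delimited field of the identifier (e.g. \code{>Q12345|NR1}) or supplied
#' through a two-column sidecar TSV (identifier, label); the sidecar wins
#' when both are present.
#'
#' @param path FASTA file path.
#' @param labels Optional path to a sidecar TSV with columns identifier and
#'   label (no header).
#' @return data.frame with columns \code{id}, \code{sequence}, \code{label}.
#' @export
read_fasta <- function(path, labels = NULL) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  lines <- readLines(path, warn = FALSE)
  has_comments <- any(startsWith(trimws(lines), ";"))
  if (has_comments) {
    lines <- lines[!startsWith(trimws(lines), ";")]
    path <- tempfile(fileext = ".fasta")
    on.exit(unlink(path), add = TRUE)
    writeLines(lines, path)
  }
  aaset <- Biostrings::readAAStringSet(path)
  if (length(aaset) == 0L) stop("FASTA file contains no sequences: ", path)

  header <- names(aaset)
  id <- vapply(strsplit(header, "[ \t]"), `[`, character(1), 1L)
  label <- rep(NA_character_, length(id))

  piped <- grepl("|", id, fixed = TRUE)
  if (any(piped)) {
    parts <- strsplit(id[piped], "|", fixed = TRUE)
    last <- vapply(parts, function(p) p[length(p)], character(1))
    is_lab <- grepl(.label_pattern, last)
    label[piped][is_lab] <- last[is_lab]
    id[piped][is_lab] <- vapply(parts[is_lab], function(p) {
      paste(p[-length(p)], collapse = "|")
    }, character(1))
  }

  dup <- id[duplicated(id)]
  if (length(dup) > 0L) {
    stop("duplicate identifier(s) in FASTA: ",
         paste(unique(dup), collapse = ", "))
  }

  if (!is.null(labels)) {
    lab_tab <- utils::read.delim(labels, header = FALSE,
                                 stringsAsFactors = FALSE,
                                 col.names = c("id", "label"))
    hit <- match(id, lab_tab$id)
    label[!is.na(hit)] <- lab_tab$label[hit[!is.na(hit)]]
  }

  data.frame(id = id, sequence = as.character(aaset), label = label,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write protein records to FASTA
#'
#' Labels, when present, are appended to the header as a final '|' field so
#' that \code{\link{read_fasta}} round-trips them.
#'
#' @param records data.frame with columns id, sequence and optionally label.
#' @param path Output file path.
#' @param width Line-wrap width.
#' @return Invisibly, \code{path}.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  header <- records$id
  if ("label" %in% names(records)) {
    lab <- records$label
    header <- ifelse(is.na(lab), header, paste0(header, "|", lab))
  }
  aaset <- Biostrings::AAStringSet(records$sequence)
  names(aaset) <- header
  Biostrings::writeXStringSet(aaset, filepath = path, width = width)
  invisible(path)
}

#' Validate and clean one protein record
#'
#' Upper-cases the sequence and removes characters outside the 20-letter
#' canonical alphabet (ambiguity codes X/B/Z/J, selenocysteine U, stops,
#' gaps); every descriptor is defined only over the 20 native residue types,
#' and removal keeps composition denominators well defined. Rejects records
#' whose cleaned sequence is shorter than \code{min_length}.
#'
#' @param record One-row data.frame (id, sequence, optional label) or a list
#'   with those fields.
#' @param min_length Minimum cleaned length; the default 21 is required by
#'   the 10-component Fourier block.
#' @return The cleaned record (same shape as input). The number of removed
#'   characters is reported via a warning.
#' @export
validate_record <- function(record, min_length = .min_sequence_length) {
  seq <- toupper(record$sequence)
  chars <- strsplit(seq, "")[[1]]
  keep <- chars %in% amino_acid_order()
  removed <- sum(!keep)
  if (removed > 0L) {
    warning(sprintf("record '%s': removed %d non-canonical character(s)",
                    record$id, removed), call. = FALSE)
  }
  cleaned <- paste(chars[keep], collapse = "")
  if (nchar(cleaned) < min_length) {
    stop(sprintf("record '%s' too short after cleaning: %d < %d",
                 record$id, nchar(cleaned), min_length), call. = FALSE)
  }
  record$sequence <- cleaned
  record
}

#' Validate a batch of protein records
#'
#' Applies \code{\link{validate_record}} to every row; records that fail the
#' length check are dropped with a warning rather than aborting the batch.
#'
#' @inheritParams validate_record
#' @param records data.frame with columns id, sequence, optional label.
#' @return The cleaned data.frame (possibly fewer rows).
#' @export
validate_records <- function(records, min_length = .min_sequence_length) {
  ok <- rep(TRUE, nrow(records))
  for (i in seq_len(nrow(records))) {
    res <- tryCatch(validate_record(records[i, ], min_length = min_length),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning(conditionMessage(res), call. = FALSE)
      ok[i] <- FALSE
    } else {
      records$sequence[i] <- res$sequence
    }
  }
  records[ok, , drop = FALSE]
}

#' Write cascade predictions as a TSV table
#'
#' One row per query, in input order, with columns: identifier, level-1 label
#' (NR or NONNR) and its winning fuzzy membership, then the level-2 subfamily
#' label and membership (empty for queries stopped at level 1).
#'
#' @param results data.frame as returned by \code{\link{predict_cascade}}.
#' @param path Output TSV path.
#' @return Invisibly, \code{path}.
#' @export
write_predictions <- function(results, path) {
  stopifnot(nrow(results) > 0L)
  cols <- c("id", "level1_label", "level1_membership",
            "level2_label", "level2_membership")
  stopifnot(all(cols %in% names(results)))
  out <- results[, cols]
  out$level2_label[is.na(out$level2_label)] <- ""
  out$level1_membership <- formatC(out$level1_membership, digits = 4,
                                   format = "f")
  out$level2_membership <- ifelse(is.na(out$level2_membership), "",
                                  formatC(out$level2_membership, digits = 4,
                                          format = "f"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
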
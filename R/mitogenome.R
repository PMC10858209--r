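# Core domain model: an annotated circular mitogenome.

#' Build a feature table
#'
#' @param name canonical gene tokens.
#' @param start,end 1-based inclusive coordinates on the H-strand frame.
#' @param strand `"H"` or `"L"`; L-strand features keep H-frame coordinates.
#' @param type feature class; inferred from the gene catalog when `NULL`.
#' @param raw_name original spelling; defaults to `name`.
#' @param wraps_origin logical; `TRUE` for a feature spanning the circular
#'   origin, in which case `start > end` and its length is
#'   `(L - start + 1) + end`.
#' @return A `data.frame` with one row per feature, ordered as given, with a
#'   `copy_index` column numbering duplicates of the same token (0-based, by
#'   ascending start).
#' @export
mito_features <- function(name, start, end, strand = "H", type = NULL,
                          raw_name = name, wraps_origin = FALSE) {
  n <- length(name)
  cat_ <- gene_catalog()
  if (is.null(type)) {
    type <- cat_$type[match(name, cat_$name)]
    type[is.na(type)] <- "unknown"
  }
  df <- data.frame(
    name = as.character(name), raw_name = as.character(raw_name),
    type = rep_len(as.character(type), n),
    start = as.integer(start), end = as.integer(end),
    strand = rep_len(as.character(strand), n),
    wraps_origin = rep_len(as.logical(wraps_origin), n),
    stringsAsFactors = FALSE
  )
  df$copy_index <- stats::ave(df$start, df$name,
                              FUN = function(s) rank(s, ties.method = "first") - 1L)
  df$copy_index <- as.integer(df$copy_index)
  df
}

#' Construct an annotated mitogenome
#'
#' @param species species label.
#' @param length genome length in bp; taken from `sequence` when present.
#' @param features a feature table from [mito_features()].
#' @param sequence nucleotide string over `A,C,G,T,N` (upper/lower case), or
#'   `NA` for table-only mode in which only coordinate operations apply.
#' @param accession optional accession string.
#' @return An object of class `mitogenome`.
#' @export
mitogenome <- function(species, length = NA_integer_, features = NULL,
                       sequence = NA_character_, accession = "") {
  if (!is.na(sequence)) {
    sequence <- toupper(sequence)
    if (!is.na(length) && nchar(sequence) != length)
      stop("declared length (", length, ") != sequence length (",
           nchar(sequence), ")")
    length <- nchar(sequence)
  }
  if (is.na(length)) stop("either `length` or `sequence` is required")
  if (is.null(features)) {
    features <- mito_features(character(), integer(), integer())
  }
  g <- structure(
    list(species = species, accession = accession, length = as.integer(length),
         sequence = sequence, features = features, circular = TRUE),
    class = "mitogenome"
  )
  validate_mitogenome(g)
  g
}

#' @export
print.mitogenome <- function(x, ...) {
  cat("<mitogenome> ", x$species,
      if (nzchar(x$accession)) paste0(" [", x$accession, "]"), "\n", sep = "")
  cat("  length  : ", x$length, " bp (circular)",
      if (is.na(x$sequence)) "  [table-only, no sequence]", "\n", sep = "")
  tab <- table(factor(x$features$type,
                      c("PCG", "tRNA", "rRNA", "control", "origin", "unknown")))
  cat("  features: ", nrow(x$features), " (",
      paste(names(tab)[tab > 0], tab[tab > 0], sep = "=", collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Validate a mitogenome's invariants
#'
#' Checks coordinate bounds, strand codes and wrap consistency; errors with
#' the offending feature named.
#'
#' @param g a `mitogenome`.
#' @return `g`, invisibly.
#' @export
validate_mitogenome <- function(g) {
  f <- g$features
  if (!nrow(f)) return(invisible(g))
  bad <- f$start < 1L | f$start > g$length | f$end < 1L | f$end > g$length
  if (any(bad))
    stop("feature(s) outside [1, ", g$length, "]: ",
         paste(f$name[bad], collapse = ", "))
  bad <- !f$wraps_origin & f$start > f$end
  if (any(bad))
    stop("start > end without wraps_origin: ",
         paste(f$name[bad], collapse = ", "))
  bad <- f$wraps_origin & f$start <= f$end
  if (any(bad))
    stop("wraps_origin set but start <= end: ",
         paste(f$name[bad], collapse = ", "))
  if (!all(f$strand %in% c("H", "L")))
    stop("strand must be 'H' or 'L'")
  invisible(g)
}

#' Feature lengths in bp
#'
#' `end - start + 1`, or `(L - start + 1) + end` across the origin.
#'
#' @param g a `mitogenome`.
#' @return integer vector, one element per feature row.
#' @export
feature_lengths <- function(g) {
  f <- g$features
  ifelse(f$wraps_origin,
         (g$length - f$start + 1L) + f$end,
         f$end - f$start + 1L)
}

#' @rdname feature_lengths
#' @param start,end,genome_length scalar coordinates for a single span.
#' @param wraps_origin does the span cross the origin?
#' @export
span_length <- function(start, end, genome_length, wraps_origin = FALSE) {
  if (wraps_origin) (genome_length - start + 1L) + end else end - start + 1L
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Extract a feature's sequence
#'
#' Wrap-aware slice of the genome sequence; L-strand features are
#' reverse-complemented so the result reads 5'->3'.
#'
#' @param g a `mitogenome` carrying a sequence.
#' @param feature a single feature row (or the row index) of `g$features`.
#' @param orient if `FALSE`, return the literal H-strand slice.
#' @return nucleotide string.
#' @export
feature_sequence <- function(g, feature, orient = TRUE) {
  if (is.numeric(feature)) feature <- g$features[feature, ]
  if (is.na(g$sequence)) stop("genome has no sequence (table-only mode)")
  s <- if (feature$wraps_origin) {
    paste0(substr(g$sequence, feature$start, g$length),
           substr(g$sequence, 1L, feature$end))
  } else {
    substr(g$sequence, feature$start, feature$end)
  }
  if (orient && feature$strand == "L") s <- reverse_complement(s)
  s
}

#' Rotate the circular origin
#'
#' Moves the origin so that old position `new_start` becomes position 1;
#' sequence and all feature coordinates are remapped, features that now span
#' the cut get `wraps_origin = TRUE`.  Useful for rotation-invariance checks.
#'
#' @param g a `mitogenome`.
#' @param new_start old coordinate that becomes position 1.
#' @return a rotated `mitogenome`.
#' @export
rotate_mitogenome <- function(g, new_start) {
  L <- g$length
  new_start <- ((new_start - 1L) %% L) + 1L
  shift <- function(p) ((p - new_start) %% L) + 1L
  f <- g$features
  f$start <- shift(f$start)
  f$end <- shift(f$end)
  f$wraps_origin <- f$start > f$end
  seq2 <- g$sequence
  if (!is.na(seq2) && new_start > 1L) {
    seq2 <- paste0(substr(g$sequence, new_start, L),
                   substr(g$sequence, 1L, new_start - 1L))
  }
  g$sequence <- seq2
  f <- f[order(f$start), , drop = FALSE]
  rownames(f) <- NULL
  f$copy_index <- as.integer(
    stats::ave(f$start, f$name, FUN = function(s) rank(s, ties.method = "first") - 1L))
  g$features <- f
  g
}
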
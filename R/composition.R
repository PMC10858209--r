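# Base composition and AT/GC skew per region class.
#
# Skews follow the standard strand-asymmetry statistics
#   AT-skew = (A - T) / (A + T),  GC-skew = (G - C) / (G + C),
# computed on the H-strand reading of each region.

#' Base composition of a nucleotide sequence
#'
#' Case-insensitive counts of A, C, G, T; N and IUPAC ambiguity codes are
#' excluded from the effective total and reported separately.
#'
#' @param sequence nucleotide string.
#' @param region_class label carried through to reports
#'   (`whole`, `PCG`, `rRNA`, `tRNA`, `CR`).
#' @return an object of class `composition_profile`: counts, percentages,
#'   `n_effective`, `n_ambiguous`.
#' @export
base_composition <- function(sequence, region_class = "whole") {
  if (!is.character(sequence) || is.na(sequence) || !nzchar(sequence))
    stop("sequence must be a non-empty string")
  fr <- Biostrings::alphabetFrequency(Biostrings::DNAString(toupper(sequence)))
  counts <- fr[c("A", "C", "G", "T")]
  n_eff <- sum(counts)
  structure(list(
    region_class = region_class,
    counts = counts,
    n_effective = n_eff,
    n_ambiguous = nchar(sequence) - n_eff,
    pct = if (n_eff > 0) 100 * counts / n_eff else counts * NA_real_
  ), class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat("<composition_profile> ", x$region_class, ": n=", x$n_effective,
      if (x$n_ambiguous) paste0(" (+", x$n_ambiguous, " ambiguous)"),
      "\n  ", paste(sprintf("%s=%.2f%%", names(x$pct), x$pct), collapse = "  "),
      "\n", sep = "")
  invisible(x)
}

#' AT- and GC-skew of a composition
#'
#' `AT-skew = (A - T)/(A + T)`, `GC-skew = (G - C)/(G + C)`.  Works
#' identically from counts or percentages (the statistic is scale-free).  A
#' zero denominator yields `NA` with the `undefined` flag set, not an error.
#'
#' @param x a `composition_profile`, or a named numeric vector with elements
#'   `A`, `C`, `G`, `T` (counts or percentages).
#' @return list with `at_skew`, `gc_skew`, `at_percent`, `gc_percent`,
#'   `undefined` (character vector naming any undefined skew).
#' @export
skew <- function(x) {
  v <- if (inherits(x, "composition_profile")) x$counts else x
  if (!all(c("A", "C", "G", "T") %in% names(v)))
    stop("need named elements A, C, G, T")
  v <- as.numeric(v[c("A", "C", "G", "T")])
  names(v) <- c("A", "C", "G", "T")
  tot <- sum(v)
  at <- v["A"] + v["T"]; gc <- v["G"] + v["C"]
  undef <- character()
  at_skew <- if (at > 0) unname((v["A"] - v["T"]) / at) else { undef <- c(undef, "at_skew"); NA_real_ }
  gc_skew <- if (gc > 0) unname((v["G"] - v["C"]) / gc) else { undef <- c(undef, "gc_skew"); NA_real_ }
  # published percentages rarely sum to exactly 100 after rounding; when the
  # input already is a percentage vector, AT% and GC% are the literal sums
  # (not renormalized), matching how such tables print them
  is_pct <- abs(tot - 100) < 0.5
  list(at_skew = at_skew, gc_skew = gc_skew,
       at_percent = if (is_pct) unname(at) else if (tot > 0) unname(100 * at / tot) else NA_real_,
       gc_percent = if (is_pct) unname(gc) else if (tot > 0) unname(100 * gc / tot) else NA_real_,
       undefined = undef)
}

.REGION_CLASS_FOR_TYPE <- c(PCG = "PCG", rRNA = "rRNA", tRNA = "tRNA",
                            control = "CR")

.region_sequence <- function(g, class_) {
  if (class_ == "whole") return(g$sequence)
  f <- g$features
  sel <- which(.REGION_CLASS_FOR_TYPE[f$type] == class_)
  if (!length(sel)) return("")
  sel <- sel[order(f$start[sel])]
  # H-strand reading of each span, concatenated in genomic order: region-level
  # skews are reported on a single reference strand, so L-strand genes are NOT
  # reverse-complemented here (unlike CDS extraction).
  paste(vapply(sel, function(i) feature_sequence(g, i, orient = FALSE), ""),
        collapse = "")
}

#' Per-region composition and skew report
#'
#' One row per region class (`whole`, `PCG`, `rRNA`, `tRNA`, `CR`): region
#' length, base percentages, GC%/AT% and both skews.  Region sequences are
#' genomic-order concatenations of the H-strand spans of same-class features;
#' overlapping same-class features contribute their bases once per feature.
#' A missing class yields a zero-length row with undefined skews.
#'
#' @param g a `mitogenome` with sequence.
#' @param classes region classes to report.
#' @param digits_pct,digits_skew rounding for the report columns.
#' @return data.frame with columns `region`, `length`, `A`, `C`, `G`, `T`
#'   (percent), `GC_pct`, `AT_pct`, `GC_skew`, `AT_skew`.
#' @export
region_composition_report <- function(g,
                                      classes = c("whole", "PCG", "rRNA",
                                                  "tRNA", "CR"),
                                      digits_pct = 2, digits_skew = 3) {
  if (is.na(g$sequence)) stop("genome has no sequence (table-only mode)")
  rows <- lapply(classes, function(cl) {
    s <- .region_sequence(g, cl)
    if (!nzchar(s)) {
      return(data.frame(region = cl, length = 0L, A = NA_real_, C = NA_real_,
                        G = NA_real_, T = NA_real_, GC_pct = NA_real_,
                        AT_pct = NA_real_, GC_skew = NA_real_,
                        AT_skew = NA_real_, stringsAsFactors = FALSE))
    }
    p <- base_composition(s, cl)
    k <- skew(p)
    data.frame(region = cl, length = nchar(s),
               A = round(unname(p$pct["A"]), digits_pct),
               C = round(unname(p$pct["C"]), digits_pct),
               G = round(unname(p$pct["G"]), digits_pct),
               T = round(unname(p$pct["T"]), digits_pct),
               GC_pct = round(k$gc_percent, digits_pct),
               AT_pct = round(k$at_percent, digits_pct),
               GC_skew = round(k$gc_skew, digits_skew),
               AT_skew = round(k$at_skew, digits_skew),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Length census from coordinates alone
#'
#' Per-feature lengths and per-class totals, usable in table-only mode; this
#' is how the published per-gene and per-class sizes (e.g. a 1556 bp total
#' tRNA complement) are recomputed from an annotation.
#'
#' @param g a `mitogenome` (sequence not required).
#' @return list with `features` (name, type, length) and `class_totals`
#'   (named integer vector over feature classes).
#' @export
length_census <- function(g) {
  len <- feature_lengths(g)
  feats <- data.frame(name = g$features$name, type = g$features$type,
                      copy_index = g$features$copy_index, length = len,
                      stringsAsFactors = FALSE)
  totals <- tapply(len, g$features$type, sum)
  list(features = feats,
       class_totals = stats::setNames(as.integer(totals), names(totals)))
}
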
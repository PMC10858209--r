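# Intergenic spacers (IGS) and gene overlaps on the circular genome.
#
# The signed gap between consecutive chain features is
#   start(downstream) - end(upstream) - 1
# (positive = spacer, negative = overlap, 0 = abutting), with one wrap gap
# closing the circle from the last feature back to the first.

#' Build the ordered feature chain used for gap accounting
#'
#' Features are sorted by start.  Under the default `"exclude-container"`
#' policy, a control-class feature wholly containing another annotated
#' feature is dropped from the chain: this removes a D-loop that contains an
#' OH annotation while keeping the OH, which is how published intergenic
#' columns are tallied.  `"keep-all"` keeps every feature.
#'
#' @param g a `mitogenome`.
#' @param policy `"exclude-container"` (default) or `"keep-all"`.
#' @return the chain as a feature data.frame (rows of `g$features`),
#'   ordered by start.
#' @export
build_gap_chain <- function(g, policy = c("exclude-container", "keep-all")) {
  policy <- match.arg(policy)
  f <- g$features
  if (!nrow(f)) stop("genome has no features")
  dup <- duplicated(f[c("start", "end")]) |
    duplicated(f[c("start", "end")], fromLast = TRUE)
  if (any(dup))
    stop("features with identical spans: ",
         paste(unique(f$name[dup]), collapse = ", "))
  if (policy == "exclude-container" && nrow(f) > 1) {
    contains <- vapply(seq_len(nrow(f)), function(i) {
      if (f$type[i] != "control") return(FALSE)
      others <- f[-i, , drop = FALSE]
      any(others$start >= f$start[i] & others$end <= f$end[i] &
            !others$wraps_origin) && !f$wraps_origin[i]
    }, logical(1))
    f <- f[!contains, , drop = FALSE]
  }
  f <- f[order(f$start, f$end), , drop = FALSE]
  rownames(f) <- NULL
  f
}

#' Signed inter-feature gaps along a chain
#'
#' One record per adjacent pair, including the circular wrap pair.  The
#' arithmetic is exact: `signed_length = start(down) - end(up) - 1`, and for
#' the wrap pair `genome_length - end(last) + start(first) - 1` (with a
#' wrap-spanning last feature's end unrolled past the origin).
#'
#' @param chain feature chain from [build_gap_chain()].
#' @param genome_length genome length in bp.
#' @return data.frame `upstream`, `downstream`, `signed_length`,
#'   `wraps_origin`.
#' @export
compute_gaps <- function(chain, genome_length) {
  n <- nrow(chain)
  lab <- function(i) chain$name[i]
  if (n == 1L) {
    len <- if (chain$wraps_origin[1]) {
      (genome_length - chain$start[1] + 1L) + chain$end[1]
    } else chain$end[1] - chain$start[1] + 1L
    return(data.frame(upstream = lab(1), downstream = lab(1),
                      signed_length = genome_length - len,
                      wraps_origin = TRUE, stringsAsFactors = FALSE))
  }
  up <- seq_len(n - 1L); down <- up + 1L
  signed <- chain$start[down] - chain$end[up] - 1L
  last_end <- if (chain$wraps_origin[n]) chain$end[n] + genome_length else chain$end[n]
  wrap_len <- genome_length - last_end + chain$start[1] - 1L
  data.frame(
    upstream = c(lab(up), lab(n)),
    downstream = c(lab(down), lab(1)),
    signed_length = as.integer(c(signed, wrap_len)),
    wraps_origin = c(rep(FALSE, n - 1L), TRUE),
    stringsAsFactors = FALSE
  )
}

#' Summarize spacers and overlaps
#'
#' Counts and total length of positive gaps (IGS), the longest IGS with its
#' flanking pair (ties broken by genomic order and reported), and the
#' overlap census.  Gaps of 0 are neither IGS nor overlap.
#'
#' @param gaps gap table from [compute_gaps()].
#' @return object of class `spacer_summary`.
#' @export
summarize_spacers <- function(gaps) {
  pos <- gaps[gaps$signed_length > 0, , drop = FALSE]
  neg <- gaps[gaps$signed_length < 0, , drop = FALSE]
  longest <- if (nrow(pos)) max(pos$signed_length) else NA_integer_
  at <- which(pos$signed_length == longest)
  structure(list(
    n_igs = nrow(pos),
    total_igs_bp = sum(pos$signed_length),
    longest_igs_bp = longest,
    longest_igs_pair = if (length(at)) paste(pos$upstream[at[1]], pos$downstream[at[1]], sep = "/") else NA_character_,
    longest_igs_tie = length(at) > 1L,
    igs_lengths = pos$signed_length,
    n_overlaps = nrow(neg),
    overlap_lengths = abs(neg$signed_length),
    overlap_range = if (nrow(neg)) range(abs(neg$signed_length)) else c(NA_integer_, NA_integer_),
    total_overlap_bp = sum(abs(neg$signed_length))
  ), class = "spacer_summary")
}

#' @export
print.spacer_summary <- function(x, ...) {
  cat("<spacer_summary> ", x$n_igs, " IGS totaling ", x$total_igs_bp,
      " bp; longest ", x$longest_igs_bp, " bp at ", x$longest_igs_pair,
      if (isTRUE(x$longest_igs_tie)) " (tied)", "; ",
      x$n_overlaps, " overlaps (", x$total_overlap_bp, " bp)\n", sep = "")
  invisible(x)
}

#' Spacer summary for a genome
#'
#' Convenience wrapper: chain, gaps, summary in one call.
#'
#' @inheritParams build_gap_chain
#' @return a `spacer_summary`; the gap table is attached as attribute
#'   `"gaps"`.
#' @export
spacer_summary <- function(g, policy = "exclude-container") {
  chain <- build_gap_chain(g, policy)
  gaps <- compute_gaps(chain, g$length)
  s <- summarize_spacers(gaps)
  attr(s, "gaps") <- gaps
  s
}

#' Compare spacer accounting across genomes
#'
#' One row per genome in the published comparative schema (species, total
#' IGS bp, IGS count, longest IGS and its flanking pair, overlap count and
#' range), plus the number of chain adjacencies shared by every genome
#' (`conserved_boundaries` attribute).
#'
#' @param genomes list of `mitogenome` objects.
#' @param policy chain policy, see [build_gap_chain()].
#' @return data.frame, one row per genome.
#' @export
compare_spacers <- function(genomes, policy = "exclude-container") {
  stopifnot(length(genomes) >= 1)
  per <- lapply(genomes, function(g) {
    s <- spacer_summary(g, policy)
    list(summary = s, gaps = attr(s, "gaps"))
  })
  rows <- do.call(rbind, lapply(seq_along(per), function(i) {
    s <- per[[i]]$summary
    data.frame(
      species = genomes[[i]]$species,
      total_igs_bp = s$total_igs_bp, n_igs = s$n_igs,
      longest_igs_bp = s$longest_igs_bp,
      longest_igs_region = s$longest_igs_pair,
      n_overlaps = s$n_overlaps,
      overlap_range = if (s$n_overlaps) paste0("-", s$overlap_range[1], " to -", s$overlap_range[2]) else "",
      stringsAsFactors = FALSE
    )
  }))
  adj_sets <- lapply(per, function(p) unique(paste(p$gaps$upstream, p$gaps$downstream, sep = ">")))
  rows_attr <- Reduce(intersect, adj_sets)
  attr(rows, "conserved_boundaries") <- length(rows_attr)
  rows
}
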
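# Tandem-repeat detection in the control region.
#
# Self-comparison at each candidate period p: the match vector
# m[i] = (s[i] == s[i+p]) marks tandem arrays as long runs of matches.
# Exact runs seed candidates, which are extended over isolated mismatches
# while the array-wide divergence stays within budget; overlapping
# candidates are resolved by longest span, then smallest period.  Only the
# forward (5'->3') orientation is scanned.

.repeat_seeds <- function(m, min_run) {
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  if (!any(keep)) return(NULL)
  cbind(start = starts[keep], end = ends[keep])
}

# Score-based two-sided extension of a seed run [a,b] in match-vector
# space: each match scores +1, each mismatch -(1-maxdiv)/maxdiv (so an
# array diverged at exactly maxdiv breaks even), and the span is extended
# to the argmax of the cumulative score in each direction.  Inside a true
# array the expected score is positive, so extension never stalls on a
# mismatch cluster; in random flanking sequence it is strongly negative,
# so the argmax sits at the array boundary and copy numbers stay sharp.
.extend_seed <- function(m, a, b, maxdiv) {
  n <- length(m)
  w <- if (maxdiv > 0) (1 - maxdiv) / maxdiv else Inf
  if (b < n) {
    cum <- cumsum(ifelse(m[(b + 1L):n], 1, -w))
    best <- which.max(cum)
    if (cum[best] > 0) b <- b + best
  }
  if (a > 1L) {
    cum <- cumsum(ifelse(m[(a - 1L):1L], 1, -w))
    best <- which.max(cum)
    if (cum[best] > 0) a <- a - best
  }
  c(a, b)
}

#' Find tandem repeats in a sequence
#'
#' Deterministic period-by-period self-match scan reporting each repeat's
#' period, span, fractional copy number (span / period, 1 decimal),
#' majority-vote consensus motif and mean copy-to-copy identity.
#'
#' @param sequence nucleotide string (length >= `2 * min_period`).
#' @param min_period,max_period period search range in bp.
#' @param min_copies minimum fractional copy number (>= 1.5).
#' @param max_divergence maximum tolerated per-copy divergence (mismatch
#'   fraction between adjacent copies).
#' @param min_seed minimum exact self-match run used to seed a candidate
#'   (capped at the period).
#' @return data.frame with columns `span_start`, `span_end`, `period`,
#'   `copy_number`, `consensus_motif`, `mean_copy_identity`,
#'   `strand_direction`; zero rows when nothing is found.
#' @export
find_tandem_repeats <- function(sequence, min_period = 10L, max_period = 400L,
                                min_copies = 1.8, max_divergence = 0.1,
                                min_seed = 12L) {
  if (min_period < 1L) stop("min_period must be >= 1")
  if (min_copies < 1.5) stop("min_copies must be >= 1.5")
  if (max_divergence < 0 || max_divergence >= 1)
    stop("max_divergence must be in [0, 1)")
  s <- strsplit(toupper(sequence), "")[[1]]
  n <- length(s)
  empty <- data.frame(span_start = integer(), span_end = integer(),
                      period = integer(), copy_number = numeric(),
                      consensus_motif = character(),
                      mean_copy_identity = numeric(),
                      strand_direction = character(),
                      stringsAsFactors = FALSE)
  if (n < 2L * min_period) return(empty)
  cand <- list()
  for (p in seq.int(min_period, min(max_period, n %/% 2L))) {
    m <- s[seq_len(n - p)] == s[seq_len(n - p) + p]
    seeds <- .repeat_seeds(m, min(p, min_seed))
    if (is.null(seeds)) next
    seen_hi <- -1L
    for (k in seq_len(nrow(seeds))) {
      if (seeds[k, "start"] <= seen_hi) next  # already absorbed
      ab <- .extend_seed(m, seeds[k, "start"], seeds[k, "end"], max_divergence)
      seen_hi <- ab[2]
      ref <- .refine_span(s, ab[1], ab[2] + p, p, max_divergence)
      span_len <- ref[2] - ref[1] + 1L
      copies <- span_len / p
      if (copies + 1e-9 < min_copies) next
      cand[[length(cand) + 1L]] <- c(ref[1], ref[2], p)
    }
  }
  if (!length(cand)) return(empty)
  cm <- do.call(rbind, cand)
  cm <- cm[order(-(cm[, 2] - cm[, 1]), cm[, 3], cm[, 1]), , drop = FALSE]
  taken <- logical(n)
  rows <- list()
  for (k in seq_len(nrow(cm))) {
    a <- cm[k, 1]; b <- cm[k, 2]; p <- cm[k, 3]
    if (any(taken[a:b])) next
    taken[a:b] <- TRUE
    rec <- .finish_record(s, a, b, p)
    rows[[length(rows) + 1L]] <- rec
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$span_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Consensus-based boundary polish.  The self-match vector double-counts
# point mutations (a mutated base mismatches both neighbours at lag p), so
# argmax extension can trim a genuine array tail by up to w positions.
# Re-extend each boundary against the consensus motif in phase: absorb up to
# p-1 positions while the extension holds at most floor(2*maxdiv*t)
# consensus mismatches over length t and ends on a match (copy-vs-consensus
# noise is about half the copy-vs-copy divergence, hence the factor 2).
# Random flanking sequence (75% mismatch) is absorbed under 1 bp on average.
.refine_span <- function(s, a, b, p, maxdiv) {
  copies <- .split_copies(s, a, b, p)
  full <- copies[lengths(copies) == p]
  if (!length(full)) return(c(a, b))
  mat <- do.call(rbind, full)
  cons <- apply(mat, 2, function(col) names(which.max(table(col))))
  n <- length(s)
  budget_ok <- function(mm, t) mm <= floor(2 * maxdiv * t)
  # a single leading mismatch is tolerated (a mutation right at the array
  # edge); extension stops at the second mismatch that exceeds the budget
  walk <- function(limit, base_at) {
    t_best <- 0L; mm <- 0L
    for (t in seq_len(limit)) {
      hit <- base_at(t)
      if (!hit) mm <- mm + 1L
      if (budget_ok(mm, t) && hit) t_best <- t
      if (!budget_ok(mm, t) && !hit && mm >= 2L) break
    }
    t_best
  }
  b <- b + walk(min(p - 1L, n - b),
                function(t) s[b + t] == cons[((b + t - a) %% p) + 1L])
  a <- a - walk(min(p - 1L, a - 1L),
                function(t) s[a - t] == cons[((a - t - a) %% p) + 1L])
  c(a, b)
}

.split_copies <- function(s, a, b, p) {
  starts <- seq.int(a, b, by = p)
  lapply(starts, function(st) s[st:min(st + p - 1L, b)])
}

.finish_record <- function(s, a, b, p) {
  copies <- .split_copies(s, a, b, p)
  full <- copies[lengths(copies) == p]
  consensus <- if (length(full)) {
    mat <- do.call(rbind, full)
    paste(apply(mat, 2, function(col) names(which.max(table(col)))),
          collapse = "")
  } else paste(copies[[1]], collapse = "")
  idm <- .identity_matrix(copies)
  mid <- if (nrow(idm) > 1) mean(idm[upper.tri(idm)]) else 1
  data.frame(span_start = a, span_end = b, period = p,
             copy_number = round((b - a + 1L) / p, 1),
             consensus_motif = consensus,
             mean_copy_identity = mid,
             strand_direction = "5'->3'",
             stringsAsFactors = FALSE)
}

.identity_matrix <- function(copies) {
  k <- length(copies)
  idm <- matrix(1, k, k)
  if (k > 1) {
    for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k)) {
      len <- min(length(copies[[i]]), length(copies[[j]]))
      idm[i, j] <- idm[j, i] <-
        sum(copies[[i]][seq_len(len)] == copies[[j]][seq_len(len)]) / len
    }
  }
  idm
}

#' Pairwise identity between repeat copies
#'
#' Copies are cut at period boundaries from the span start; the final
#' partial copy is compared over its own length; identity is ungapped
#' matches / compared length.
#'
#' @param record one row of [find_tandem_repeats()] output.
#' @param sequence the scanned sequence.
#' @return square numeric matrix of pairwise identities (diagonal 1).
#' @export
copy_identity_matrix <- function(record, sequence) {
  s <- strsplit(toupper(sequence), "")[[1]]
  copies <- .split_copies(s, record$span_start, record$span_end, record$period)
  idm <- .identity_matrix(copies)
  dimnames(idm) <- list(paste0("copy", seq_along(copies)),
                        paste0("copy", seq_along(copies)))
  idm
}

#' Scan control regions of a genome set
#'
#' Extracts each genome's control-region span (falling back to OH when no CR
#' is annotated) plus an optional flank and scans it.  Reported coordinates
#' are in the genome frame.  Genomes without sequence are skipped with a
#' warning.
#'
#' @param genomes list of `mitogenome` objects.
#' @param flank bp of context added on each side of the CR span.
#' @param ... parameters passed to [find_tandem_repeats()].
#' @return data.frame: `species`, `start`, `end`, `period`, `copy_number`,
#'   `mean_copy_identity`, `consensus_motif`.
#' @export
scan_control_regions <- function(genomes, flank = 0L, ...) {
  rows <- list()
  for (g in genomes) {
    if (is.na(g$sequence)) {
      warning("skipping ", g$species, ": no sequence")
      next
    }
    f <- g$features
    cr <- f[f$type == "control", , drop = FALSE]
    if (!nrow(cr)) cr <- f[f$name == "OH", , drop = FALSE]
    if (!nrow(cr)) next
    for (i in seq_len(nrow(cr))) {
      a <- max(1L, cr$start[i] - flank)
      b <- min(g$length, cr$end[i] + flank)
      hits <- find_tandem_repeats(substr(g$sequence, a, b), ...)
      if (nrow(hits)) {
        rows[[length(rows) + 1L]] <- data.frame(
          species = g$species,
          start = hits$span_start + a - 1L, end = hits$span_end + a - 1L,
          period = hits$period, copy_number = hits$copy_number,
          mean_copy_identity = hits$mean_copy_identity,
          consensus_motif = hits$consensus_motif, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(species = character(), start = integer(),
                      end = integer(), period = integer(),
                      copy_number = numeric(), mean_copy_identity = numeric(),
                      consensus_motif = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
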
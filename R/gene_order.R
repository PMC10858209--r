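# Linearized signed gene orders, duplication census, breakpoint distances.

#' Extract the signed gene order
#'
#' Features are sorted by start and rotated so the anchor (default trnF, the
#' conventional linearization start of vertebrate mitogenomes) comes first;
#' strand is encoded as sign.  The result is invariant to rotation of the
#' circular origin and to annotation order.
#'
#' @param g a `mitogenome`.
#' @param anchor canonical token to start from; if absent the lowest-start
#'   feature is used with a warning.
#' @param include feature classes to keep: `"genes+CR"` (PCG, tRNA, rRNA,
#'   control; the usual published gene-order alphabet), `"all"`, or a
#'   character vector of classes.
#' @return object of class `gene_order`: `species` and `tokens`, a
#'   data.frame (`name`, `strand`, `copy_index`, `signed`).
#' @export
extract_gene_order <- function(g, anchor = "trnF", include = "genes+CR") {
  f <- g$features
  if (identical(include, "genes+CR")) {
    f <- f[f$type %in% c("PCG", "tRNA", "rRNA", "control"), , drop = FALSE]
  } else if (!identical(include, "all")) {
    f <- f[f$type %in% include, , drop = FALSE]
  }
  if (!nrow(f)) stop("no features to order")
  f <- f[order(f$start, f$end), , drop = FALSE]
  i0 <- which(f$name == anchor)
  if (!length(i0)) {
    warning("anchor ", anchor, " absent in ", g$species,
            "; using lowest-start feature")
    i0 <- 1L
  }
  idx <- c(seq(i0[1], nrow(f)), seq_len(i0[1] - 1L))
  f <- f[idx, , drop = FALSE]
  tokens <- data.frame(
    name = f$name, strand = f$strand, copy_index = f$copy_index,
    signed = paste0(ifelse(f$strand == "H", "+", "-"), f$name,
                    ifelse(f$copy_index > 0, paste0(".", f$copy_index), "")),
    stringsAsFactors = FALSE)
  structure(list(species = g$species, tokens = tokens), class = "gene_order")
}

#' @export
print.gene_order <- function(x, ...) {
  cat(x$species, ": ", paste(x$tokens$signed, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
#' @method format gene_order
format.gene_order <- function(x, ...) paste(x$tokens$signed, collapse = " ")

#' Census of duplicated features
#'
#' Groups features by canonical name; every name present more than once is
#' reported with its copy count, spans and feature class.  Split genes
#' annotated as two segments count as duplicates of their token.
#'
#' @param g a `mitogenome`.
#' @return data.frame `name`, `n_copies`, `type`, `spans` (empty when the
#'   genome is single-copy throughout).
#' @export
detect_duplications <- function(g) {
  f <- g$features
  tab <- table(f$name)
  dup <- names(tab)[tab >= 2]
  if (!length(dup))
    return(data.frame(name = character(), n_copies = integer(),
                      type = character(), spans = character(),
                      stringsAsFactors = FALSE))
  rows <- lapply(dup, function(nm) {
    fi <- f[f$name == nm, , drop = FALSE]
    fi <- fi[order(fi$start), ]
    data.frame(name = nm, n_copies = nrow(fi), type = fi$type[1],
               spans = paste(sprintf("%d-%d", fi$start, fi$end), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$name), , drop = FALSE]
}

.adjacency_set <- function(signed) {
  n <- length(signed)
  nxt <- c(seq_len(n)[-1], 1L)
  flip <- function(x) ifelse(startsWith(x, "+"),
                             sub("^\\+", "-", x), sub("^-", "+", x))
  vapply(seq_len(n), function(i) {
    a <- signed[i]; b <- signed[nxt[i]]
    # an adjacency read in the opposite direction flips both signs and order
    alt <- paste(flip(b), flip(a), sep = "|")
    fwd <- paste(a, b, sep = "|")
    min(fwd, alt)
  }, character(1))
}

#' Breakpoint distance between two gene orders
#'
#' Both orders are reduced to the tokens that occur exactly once in each
#' (duplicates are excluded; the duplication census reports those
#' separately), then the number of circular signed adjacencies present in
#' one order but not the other is counted.  Symmetric, zero iff the reduced
#' orders are equivalent up to rotation/reflection of the circle.
#'
#' @param orderA,orderB `gene_order` objects.
#' @return non-negative integer distance.
#' @export
breakpoint_distance <- function(orderA, orderB) {
  ta <- orderA$tokens; tb <- orderB$tokens
  single <- function(t) names(which(table(t$name) == 1))
  shared <- intersect(single(ta), single(tb))
  if (length(shared) < 3)
    stop("fewer than 3 shared single-copy tokens")
  sa <- ta$signed[ta$name %in% shared]
  sb <- tb$signed[tb$name %in% shared]
  A <- .adjacency_set(sa); B <- .adjacency_set(sb)
  length(setdiff(A, B))
}

#' Compare gene orders across genomes
#'
#' Groups genomes sharing an identical token sequence and emits the pairwise
#' breakpoint-distance matrix.
#'
#' @param genomes list of `mitogenome` objects (>= 2).
#' @param anchor,include passed to [extract_gene_order()].
#' @return list: `orders` (per-genome `gene_order`), `groups` (data.frame
#'   `species`, `group`), `distance` (symmetric matrix, zero diagonal).
#' @export
order_comparison_report <- function(genomes, anchor = "trnF",
                                    include = "genes+CR") {
  stopifnot(length(genomes) >= 2)
  orders <- lapply(genomes, extract_gene_order, anchor = anchor,
                   include = include)
  keys <- vapply(orders, format, "")
  sp <- vapply(genomes, function(g) g$species, "")
  groups <- data.frame(species = sp,
                       group = as.integer(factor(keys, levels = unique(keys))),
                       stringsAsFactors = FALSE)
  n <- length(orders)
  D <- matrix(0L, n, n, dimnames = list(sp, sp))
  if (n > 1) for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    D[i, j] <- D[j, i] <- breakpoint_distance(orders[[i]], orders[[j]])
  }
  list(orders = orders, groups = groups, distance = D)
}
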
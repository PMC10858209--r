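# Independent oracles and small fixture builders used across the suite.
# These deliberately take different code paths from the package internals.

# reverse complement without Biostrings
revcomp_oracle <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# random chain-like circular annotation set: each feature overlaps at most
# its neighbours and never by more than a third of either length, so the
# per-position occupancy oracle applies cleanly
rand_annotation_set <- function(n = 8) {
  len <- sample(30:200, n, replace = TRUE)
  gaps <- integer(n)
  for (i in seq_len(n - 1)) {
    if (stats::runif(1) < 0.35) {
      gaps[i] <- -sample.int(max(1L, min(len[i], len[i + 1]) %/% 3L), 1)
    } else {
      gaps[i] <- sample(0:40, 1)
    }
  }
  gaps[n] <- sample(5:60, 1)  # wrap pad kept positive
  start <- integer(n); end <- integer(n)
  pos <- 1L
  for (i in seq_len(n)) {
    start[i] <- pos; end[i] <- pos + len[i] - 1L
    pos <- end[i] + gaps[i] + 1L
  }
  L <- pos - 1L
  # catalog names so table round trips preserve names verbatim
  feats <- mito_features(sample(gene_catalog()$name, n), start, end,
                         strand = sample(c("H", "L"), n, TRUE))
  list(genome = mitogenome("rand", length = L, features = feats),
       gaps = gaps, lengths = len)
}

# per-position occupancy oracle: IGS lengths = maximal uncovered runs on the
# circle; overlap lengths = maximal runs covered >= 2
occupancy_oracle <- function(g) {
  cov <- integer(g$length)
  f <- g$features
  for (i in seq_len(nrow(f))) {
    idx <- if (f$wraps_origin[i]) c(f$start[i]:g$length, 1:f$end[i]) else f$start[i]:f$end[i]
    cov[idx] <- cov[idx] + 1L
  }
  run_lengths <- function(mask) {
    if (!any(mask)) return(integer())
    r <- rle(mask)
    out <- r$lengths[r$values]
    # merge a run crossing the circular origin
    if (mask[1] && mask[length(mask)] && length(out) > 1 &&
        r$values[1] && r$values[length(r$values)]) {
      out <- c(out[1] + out[length(out)], out[-c(1, length(out))])
    }
    out
  }
  list(igs = sort(run_lengths(cov == 0L)),
       overlaps = sort(run_lengths(cov >= 2L)),
       covered_ge2 = sum(cov >= 2L))
}

# independent signed-adjacency distance: for each consecutive pair in A,
# look the two tokens up in B and check they are neighbours with a
# compatible sign pattern in either reading direction
adjacency_oracle <- function(tokA, tokB) {
  # tok*: data.frame(name, sign) with sign in c(1,-1), circular order
  n <- nrow(tokA)
  stopifnot(nrow(tokB) == n)
  posB <- match(tokA$name, tokB$name)
  shared <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    pa <- posB[i]; pb <- posB[j]
    nb <- nrow(tokB)
    nxt <- function(k) if (k == nb) 1L else k + 1L
    if (nxt(pa) == pb) {
      if (tokB$sign[pa] == tokA$sign[i] && tokB$sign[pb] == tokA$sign[j])
        shared <- shared + 1L
    } else if (nxt(pb) == pa) {
      if (-tokB$sign[pa] == tokA$sign[i] && -tokB$sign[pb] == tokA$sign[j])
        shared <- shared + 1L
    }
  }
  n - shared
}

# wrap a token data.frame as a gene_order object
as_gene_order <- function(tok, species = "x") {
  structure(list(species = species, tokens = data.frame(
    name = tok$name, strand = ifelse(tok$sign > 0, "H", "L"),
    copy_index = 0L,
    signed = paste0(ifelse(tok$sign > 0, "+", "-"), tok$name),
    stringsAsFactors = FALSE)), class = "gene_order")
}

rand_signed_order <- function(n) {
  data.frame(name = sample(paste0("g", seq_len(n))),
             sign = sample(c(1, -1), n, TRUE), stringsAsFactors = FALSE)
}

# tiny genome with sequence, built positionally from feature specs:
# list(name=, len=, strand=, gap=) consumed left to right, pad at the end
toy_genome <- function(specs, pad = 20, species = "toy") {
  pos <- 1L; rows <- list(); seqs <- character()
  for (sp in specs) {
    s <- sp$seq %||% random_sequence(sp$len)
    rows[[length(rows) + 1L]] <- data.frame(
      name = sp$name, start = pos, end = pos + nchar(s) - 1L,
      strand = sp$strand %||% "H", stringsAsFactors = FALSE)
    seqs <- c(seqs, s)
    gap <- sp$gap %||% 0L
    if (gap > 0) seqs <- c(seqs, random_sequence(gap))
    pos <- pos + nchar(s) + gap
  }
  if (pad > 0) seqs <- c(seqs, random_sequence(pad))
  df <- do.call(rbind, rows)
  nm <- normalize_gene_name(df$name)
  feats <- mito_features(nm$name, df$start, df$end, strand = df$strand,
                         type = nm$type, raw_name = df$name)
  mitogenome(species, features = feats, sequence = paste(seqs, collapse = ""))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# mutate each position independently to a different base with prob `rate`
mutate_seq_oracle <- function(s, rate) {
  v <- strsplit(s, "")[[1]]
  hit <- which(stats::runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}
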
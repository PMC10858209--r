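# Readers and writers: plain feature tables, GenBank flat files, FASTA.

#' Read a plain feature table
#'
#' Expects TSV (or CSV) with header columns `name`, `from`, `to`, `strand`;
#' `type` is optional and otherwise inferred through name normalization, and
#' an optional logical `wrap` column marks features spanning the circular
#' origin (required whenever `from > to`).
#'
#' @param path file path.
#' @param genome_length genome length in bp.
#' @param species species label.
#' @param sep field separator (default tab; use `","` for CSV).
#' @param accession optional accession.
#' @return a table-only [mitogenome()] (no sequence).
#' @export
read_feature_table <- function(path, genome_length, species = "unknown",
                               sep = "\t", accession = "") {
  tb <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "#",
                          quote = "\"")
  need <- c("name", "from", "to", "strand")
  if (!all(need %in% names(tb)))
    stop("feature table must have columns: ", paste(need, collapse = ", "))
  if (nrow(tb) == 0) {
    return(mitogenome(species, length = genome_length, accession = accession))
  }
  wrap <- if ("wrap" %in% names(tb)) as.logical(tb$wrap) else rep(FALSE, nrow(tb))
  wrap[is.na(wrap)] <- FALSE
  bad <- tb$from > tb$to & !wrap
  if (any(bad))
    stop("from > to without wrap flag: ", paste(tb$name[bad], collapse = ", "))
  dup <- duplicated(tb[c("from", "to")])
  if (any(dup))
    stop("duplicate rows with identical coordinates: ",
         paste(tb$name[dup], collapse = ", "))
  nm <- normalize_gene_name(tb$name)
  type <- if ("type" %in% names(tb) && !all(is.na(tb$type))) tb$type else nm$type
  feats <- mito_features(nm$name, tb$from, tb$to, strand = tb$strand,
                         type = type, raw_name = tb$name, wraps_origin = wrap)
  mitogenome(species, length = genome_length, features = feats,
             accession = accession)
}

#' Write a feature table
#'
#' Emits the `name  from  to  strand  type` TSV schema read back by
#' [read_feature_table()] (plus `wrap` when any feature crosses the origin).
#'
#' @param g a `mitogenome`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(g, path) {
  f <- g$features
  out <- data.frame(name = f$name, from = f$start, to = f$end,
                    strand = f$strand, type = f$type,
                    stringsAsFactors = FALSE)
  if (any(f$wraps_origin)) out$wrap <- f$wraps_origin
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a FASTA file as a plain nucleotide string
#'
#' @param path FASTA path.
#' @return named character vector of sequences (upper case).
#' @export
read_fasta_seq <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta_seq <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

# ---- GenBank flat files ----------------------------------------------------

.GB_KEY_FOR_TYPE <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                      control = "D-loop", origin = "rep_origin",
                      unknown = "misc_feature")

.gb_location <- function(f, L) {
  loc <- if (f$wraps_origin) {
    sprintf("join(%d..%d,1..%d)", f$start, L, f$end)
  } else {
    sprintf("%d..%d", f$start, f$end)
  }
  if (f$strand == "L") loc <- sprintf("complement(%s)", loc)
  loc
}

#' Write a mitogenome as a GenBank flat file
#'
#' Minimal but standard-conforming flat file: LOCUS, FEATURES (one entry per
#' feature, typed `CDS`/`tRNA`/`rRNA`/`D-loop`/`rep_origin`), ORIGIN.  The
#' raw annotation spelling is preserved in `/gene` (or `/note` for
#' replication origins).
#'
#' @param g a `mitogenome` with sequence.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(g, path) {
  if (is.na(g$sequence)) stop("cannot write GenBank without a sequence")
  L <- g$length
  con <- file(path, "w")
  on.exit(close(con))
  locus_name <- gsub("[^A-Za-z0-9_.]", "_", if (nzchar(g$accession)) g$accession else g$species)
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     circular VRT",
                     locus_name, L), con)
  writeLines(sprintf("DEFINITION  %s mitochondrion, complete genome.", g$species), con)
  if (nzchar(g$accession))
    writeLines(sprintf("ACCESSION   %s", g$accession), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", L), con)
  writeLines(sprintf('                     /organism="%s"', g$species), con)
  f <- g$features
  for (i in seq_len(nrow(f))) {
    fi <- f[i, ]
    key <- .GB_KEY_FOR_TYPE[[fi$type]]
    writeLines(sprintf("     %-15s %s", key, .gb_location(fi, L)), con)
    qual <- if (key == "rep_origin") "note" else "gene"
    writeLines(sprintf('                     /%s="%s"', qual, fi$raw_name), con)
  }
  writeLines("ORIGIN", con)
  s <- tolower(g$sequence)
  starts <- seq(1L, L, by = 60L)
  for (st in starts) {
    chunk <- substr(s, st, min(st + 59L, L))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", st, paste(blocks, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

.parse_gb_location <- function(loc, feat_label) {
  strand <- "H"
  x <- gsub("[<>]", "", gsub("\\s", "", loc))
  if (grepl("^complement\\(", x)) {
    strand <- "L"
    x <- sub("^complement\\((.*)\\)$", "\\1", x)
  }
  wraps <- FALSE
  if (grepl("^join\\(", x)) {
    x <- sub("^join\\((.*)\\)$", "\\1", x)
    parts <- strsplit(x, ",")[[1]]
    rng <- lapply(parts, function(p) as.integer(strsplit(p, "\\.\\.")[[1]]))
    if (length(rng) != 2L || any(vapply(rng, length, 1L) != 2L) ||
        rng[[2]][1] != 1L)
      stop("unparseable join location for feature ", feat_label, ": ", loc)
    wraps <- TRUE
    start <- rng[[1]][1]; end <- rng[[2]][2]
  } else {
    rng <- suppressWarnings(as.integer(strsplit(x, "\\.\\.")[[1]]))
    if (length(rng) == 1L) rng <- c(rng, rng)
    if (length(rng) != 2L || any(is.na(rng)))
      stop("unparseable location for feature ", feat_label, ": ", loc)
    start <- rng[1]; end <- rng[2]
  }
  list(start = start, end = end, strand = strand, wraps = wraps)
}

#' Read a GenBank flat file
#'
#' Parses LOCUS length, the FEATURES table (`CDS`, `tRNA`, `rRNA`, `D-loop`,
#' `rep_origin`, `misc_feature`; bare `gene` entries duplicating a typed
#' feature's span are dropped) and the ORIGIN sequence.  Locations may be
#' `a..b`, `complement(...)` and origin-spanning `join(a..L,1..b)`.  Names
#' are normalized through [normalize_gene_name()].
#'
#' @param path GenBank file path.
#' @param species overrides the organism parsed from the file.
#' @return a [mitogenome()].
#' @export
read_genbank <- function(path, species = NULL) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("no LOCUS line in ", path)
  m <- regmatches(locus[1], regexec("\\s(\\d+)\\s+bp", locus[1]))[[1]]
  if (length(m) < 2) stop("LOCUS line lacks a length in bp: ", locus[1])
  L <- as.integer(m[2])
  accession <- ""
  acc_line <- grep("^ACCESSION", lines, value = TRUE)
  if (length(acc_line)) accession <- trimws(sub("^ACCESSION", "", acc_line[1]))
  org <- grep('/organism="', lines, value = TRUE)
  if (is.null(species))
    species <- if (length(org)) sub('.*/organism="([^"]*)".*', "\\1", org[1]) else "unknown"

  fe_start <- grep("^FEATURES", lines)
  or_start <- grep("^ORIGIN", lines)
  if (!length(fe_start)) stop("no FEATURES section in ", path)
  fe_end <- if (length(or_start)) or_start[1] - 1L else length(lines)
  feat_lines <- lines[(fe_start[1] + 1L):fe_end]

  keys <- character(); locs <- character(); names_ <- character()
  cur_key <- NA_character_
  for (ln in feat_lines) {
    if (grepl("^ {5}\\S", ln)) {
      key <- trimws(substr(ln, 1, 20))
      loc <- trimws(substr(ln, 21, nchar(ln)))
      keys <- c(keys, key); locs <- c(locs, loc); names_ <- c(names_, NA)
      cur_key <- key
    } else if (grepl("^ {21}", ln) && length(keys)) {
      q <- trimws(ln)
      if (grepl("^/(gene|product|note|standard_name)=", q) &&
          is.na(names_[length(names_)])) {
        names_[length(names_)] <- gsub('"', "", sub("^/[a-z_]+=", "", q))
      } else if (!grepl("^/", q)) {
        # continuation of a multi-line location
        locs[length(locs)] <- paste0(locs[length(locs)], q)
      }
    }
  }
  keep <- keys %in% c("CDS", "tRNA", "rRNA", "D-loop", "rep_origin",
                      "misc_feature", "gene")
  keys <- keys[keep]; locs <- locs[keep]; names_ <- names_[keep]
  names_[is.na(names_) & keys == "D-loop"] <- "D-loop"
  if (any(is.na(names_)))
    stop("feature without a /gene, /product or /note qualifier: ",
         keys[which(is.na(names_))[1]])

  parsed <- lapply(seq_along(keys),
                   function(i) .parse_gb_location(locs[i], names_[i]))
  df <- data.frame(
    key = keys, raw = names_,
    start = vapply(parsed, `[[`, 1L, "start"),
    end = vapply(parsed, `[[`, 1L, "end"),
    strand = vapply(parsed, `[[`, "", "strand"),
    wraps = vapply(parsed, `[[`, TRUE, "wraps"),
    stringsAsFactors = FALSE
  )
  # drop bare gene entries that duplicate the span of a typed feature
  if (any(df$key == "gene") && any(df$key != "gene")) {
    typed <- df[df$key != "gene", ]
    dupgene <- df$key == "gene" &
      paste(df$start, df$end) %in% paste(typed$start, typed$end)
    df <- df[!dupgene, , drop = FALSE]
  }
  bad <- !df$wraps & (df$start < 1L | df$end > L)
  if (any(bad))
    stop("feature beyond sequence end: ", paste(df$raw[bad], collapse = ", "))

  seq <- NA_character_
  if (length(or_start)) {
    seq_lines <- lines[(or_start[1] + 1L):length(lines)]
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    if (!nchar(seq)) seq <- NA_character_
  }
  nm <- normalize_gene_name(df$raw)
  feats <- mito_features(nm$name, df$start, df$end, strand = df$strand,
                         type = nm$type, raw_name = df$raw,
                         wraps_origin = df$wraps)
  feats <- feats[order(feats$start), , drop = FALSE]
  rownames(feats) <- NULL
  feats$copy_index <- as.integer(
    stats::ave(feats$start, feats$name,
               FUN = function(s) rank(s, ties.method = "first") - 1L))
  mitogenome(species, length = L, features = feats, sequence = seq,
             accession = accession)
}

#' Packaged Boleophthalmus dussumieri annotation fixture
#'
#' The published coordinate table of the B. dussumieri mitogenome (16,685 bp;
#' 13 PCGs + 22 tRNAs + 2 rRNAs + D-loop + OL + OH = 40 rows), shipped as a
#' plain TSV under `extdata` and loaded in table-only mode.
#'
#' @return a table-only [mitogenome()].
#' @export
dussumieri_fixture <- function() {
  path <- system.file("extdata", "boleophthalmus_dussumieri_features.tsv",
                      package = "mitocomp", mustWork = TRUE)
  read_feature_table(path, genome_length = 16685,
                     species = "Boleophthalmus dussumieri")
}

#' Per-feature annotation report
#'
#' One row per feature in genomic order with length, the intergenic column
#' (signed gap to the next chain feature under the given policy; `NA` for
#' features excluded from the chain) and, when a sequence is present,
#' start/stop codon calls for the PCGs.
#'
#' @param g a `mitogenome`.
#' @param policy chain policy for the intergenic column, see
#'   [build_gap_chain()].
#' @param path optional output path; when given the table is written as TSV
#'   (or JSON if the path ends in `.json`).
#' @return data.frame, invisibly when `path` is given.
#' @export
write_feature_report <- function(g, policy = "exclude-container", path = NULL) {
  f <- g$features[order(g$features$start), , drop = FALSE]
  chain <- build_gap_chain(g, policy)
  gaps <- compute_gaps(chain, g$length)
  key <- paste(chain$start, chain$end)
  ig <- rep(NA_integer_, nrow(f))
  m <- match(paste(f$start, f$end), key)
  ig[!is.na(m)] <- gaps$signed_length[m[!is.na(m)]]
  out <- data.frame(name = f$name, raw_name = f$raw_name, type = f$type,
                    start = f$start, end = f$end,
                    length = feature_lengths(structure(list(features = f, length = g$length), class = "mitogenome")),
                    strand = f$strand, intergenic = ig,
                    stringsAsFactors = FALSE)
  out$start_codon <- NA_character_; out$stop_codon <- NA_character_
  if (!is.na(g$sequence)) {
    for (i in which(out$type == "PCG")) {
      cs <- call_start_stop(feature_sequence(g, f[i, ], orient = TRUE))
      out$start_codon[i] <- cs$start_codon
      out$stop_codon[i] <- cs$stop_display
    }
  }
  if (!is.null(path)) {
    if (grepl("\\.json$", path)) {
      jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
    } else {
      utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    return(invisible(out))
  }
  out
}
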
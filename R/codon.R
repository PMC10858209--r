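# Codon usage under the vertebrate mitochondrial code (NCBI table 2):
# CDS extraction, start/stop calling (including the incomplete T-- / TA-
# stops completed by polyadenylation), codon counts, RSCU, degeneracy
# families and amino-acid composition.

.GENETIC_CODE_ID <- "2"  # vertebrate mitochondrial

genetic_code2 <- function() Biostrings::getGeneticCode(.GENETIC_CODE_ID)

stop_codons2 <- function() names(genetic_code2())[genetic_code2() == "*"]

.AA1TO3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
             E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
             M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
             Y = "Tyr", V = "Val")

#' Extract a protein-coding sequence
#'
#' Wrap-aware extraction of a PCG's nucleotides, reverse-complemented for
#' L-strand genes so the result reads 5'->3', with start/stop called from the
#' sequence itself.
#'
#' @param g a `mitogenome` with sequence.
#' @param feature a feature row of `g$features`, its row index, or a
#'   canonical gene token.
#' @return object of class `coding_sequence`: `gene`, `oriented_seq`,
#'   `start_codon`, `stop_codon` (`"TAA"`-like, `"TA-"`, `"T--"`),
#'   `completeness`, `complete_codons`, `trailing_partial`, flags.
#' @export
extract_cds <- function(g, feature) {
  if (is.character(feature)) {
    i <- which(g$features$name == feature)
    if (!length(i)) stop("no feature named ", feature)
    feature <- g$features[i[1], ]
  } else if (is.numeric(feature)) feature <- g$features[feature, ]
  if (feature$type != "PCG")
    stop(feature$name, " is not a protein-coding gene")
  s <- feature_sequence(g, feature, orient = TRUE)
  cs <- call_start_stop(s)
  structure(c(list(gene = feature$name, oriented_seq = s), cs),
            class = "coding_sequence")
}

#' Call start and stop codons, including incomplete stops
#'
#' The trailing length `len mod 3` determines the stop class: 0 = complete
#' 3-mer stop, 2 = `TA-` (one base short), 1 = `T--` (two bases short); the
#' truncated stops are completed to TAA by post-transcriptional
#' polyadenylation.  Non-canonical starts (e.g. GTG) and non-stop terminal
#' 3-mers are reported with flags, never overwritten.
#'
#' @param x nucleotide string (oriented 5'->3') or a `coding_sequence`.
#' @return list: `start_codon`, `stop_codon`, `stop_display` (the
#'   `T(AA)`/`TA(A)` text notation), `completeness` (`complete`,
#'   `TA_incomplete`, `T_incomplete`), `complete_codons`,
#'   `trailing_partial`, `flags` (character vector).
#' @export
call_start_stop <- function(x) {
  s <- if (inherits(x, "coding_sequence")) x$oriented_seq else x
  n <- nchar(s)
  if (n < 4) stop("coding sequence shorter than 4 nt")
  trailing <- n %% 3L
  start_codon <- substr(s, 1, 3)
  flags <- character()
  if (!start_codon %in% c("ATG", "GTG", "ATA", "ATT", "ATC"))
    flags <- c(flags, "non-canonical-start")
  else if (start_codon != "ATG")
    flags <- c(flags, "alternative-start")
  if (trailing == 0L) {
    stop_codon <- substr(s, n - 2, n)
    completeness <- "complete"
    display <- stop_codon
    if (!stop_codon %in% stop_codons2())
      flags <- c(flags, "non-stop-terminal-codon")
  } else if (trailing == 2L) {
    stop_codon <- paste0(substr(s, n - 1, n), "-")
    completeness <- "TA_incomplete"
    display <- paste0(substr(s, n - 1, n), "(A)")
    if (substr(s, n - 1, n) != "TA")
      flags <- c(flags, "unexpected-incomplete-stop")
  } else {
    stop_codon <- paste0(substr(s, n, n), "--")
    completeness <- "T_incomplete"
    display <- paste0(substr(s, n, n), "(AA)")
    if (substr(s, n, n) != "T")
      flags <- c(flags, "unexpected-incomplete-stop")
  }
  list(start_codon = start_codon, stop_codon = stop_codon,
       stop_display = display, completeness = completeness,
       complete_codons = n %/% 3L, trailing_partial = trailing,
       flags = flags)
}

#' The 64 codons in fixed order
#' @return character vector of trinucleotides.
#' @export
all_codons <- function() {
  b <- c("A", "C", "G", "T")
  eg <- expand.grid(p3 = b, p2 = b, p1 = b, stringsAsFactors = FALSE)
  paste0(eg$p1, eg$p2, eg$p3)
}

#' Count codons across coding sequences
#'
#' Counts complete codons only (trailing partial nucleotides ignored); stop
#' codons and codons containing ambiguity characters are excluded from the
#' usable total and tallied separately.
#'
#' @param cds_list list of `coding_sequence` objects (or plain oriented
#'   nucleotide strings).
#' @return object of class `codon_usage_table`: `counts` (named over the 64
#'   codons), `total_codons` (sense codons), `n_stop_codons`,
#'   `n_ambiguous_codons`, `genetic_code_id`.
#' @export
count_codons <- function(cds_list) {
  codons <- all_codons()
  counts <- stats::setNames(integer(64), codons)
  n_amb <- 0L
  for (x in cds_list) {
    s <- if (inherits(x, "coding_sequence")) x$oriented_seq else x
    n3 <- (nchar(s) %/% 3L) * 3L
    if (n3 < 3L) next
    cs <- substring(s, seq(1L, n3, 3L), seq(3L, n3, 3L))
    known <- cs %in% codons
    n_amb <- n_amb + sum(!known)
    t0 <- table(cs[known])
    counts[names(t0)] <- counts[names(t0)] + as.integer(t0)
  }
  stops <- stop_codons2()
  n_stop <- sum(counts[stops])
  structure(list(counts = counts,
                 total_codons = sum(counts) - n_stop,
                 n_stop_codons = n_stop,
                 n_ambiguous_codons = n_amb,
                 genetic_code_id = .GENETIC_CODE_ID),
            class = "codon_usage_table")
}

#' @export
print.codon_usage_table <- function(x, ...) {
  cat("<codon_usage_table> ", x$total_codons, " sense codons (+",
      x$n_stop_codons, " stop, +", x$n_ambiguous_codons,
      " ambiguous), genetic code ", x$genetic_code_id, "\n", sep = "")
  invisible(x)
}

#' Synonymous-family (degeneracy) map under the vertebrate mitochondrial code
#'
#' Families are derived programmatically from the code table, not from a
#' hard-coded list: sense codons are grouped by amino acid, and amino acids
#' encoded from more than one codon-box prefix are split into the
#' conventional subfamilies Leu1 (CTN, 4-fold) / Leu2 (TTR, 2-fold) and
#' Ser1 (AGY, 2-fold) / Ser2 (TCN, 4-fold).  Under this code Trp (TGR) and
#' Met (ATR) are 2-fold.
#'
#' @return data.frame with columns `codon`, `aa` (one-letter), `family`
#'   (e.g. `"Leu1"`), `family_size`.
#' @export
degeneracy_classes <- function() {
  gc2 <- genetic_code2()
  sense <- gc2[gc2 != "*"]
  codon <- names(sense)
  aa <- unname(sense)
  prefix <- substr(codon, 1, 2)
  fam <- character(length(codon))
  for (a in unique(aa)) {
    idx <- which(aa == a)
    prefs <- unique(prefix[idx])
    base <- .AA1TO3[[a]]
    if (length(prefs) == 1L) {
      fam[idx] <- base
    } else {
      # split amino acid: number subfamilies by the field's convention
      # (Leu1 = CTN, Leu2 = TTR; Ser1 = AGY, Ser2 = TCN); any other split
      # would be numbered by codon-box size, largest last.
      conv <- c(CT = "Leu1", TT = "Leu2", AG = "Ser1", TC = "Ser2")
      for (p in prefs) {
        lab <- if (p %in% names(conv) && startsWith(conv[[p]], base)) {
          conv[[p]]
        } else {
          paste0(base, match(p, sort(prefs)))
        }
        fam[idx[prefix[idx] == p]] <- lab
      }
    }
  }
  sz <- table(fam)
  data.frame(codon = codon, aa = aa, family = fam,
             family_size = as.integer(sz[fam]), stringsAsFactors = FALSE)
}

#' Relative synonymous codon usage
#'
#' For codon c in a synonymous family of size k with family total N,
#' `RSCU_c = count_c * k / N`: 1 means uniform use, k means exclusive use.
#' A family with zero observations gets RSCU 0 for all members and is
#' flagged.  Stop codons are not assigned RSCU values.
#'
#' @param table a `codon_usage_table` from [count_codons()].
#' @return data.frame `codon`, `aa`, `family`, `family_size`, `count`,
#'   `RSCU`, with attribute `empty_families` naming unobserved families.
#' @export
rscu <- function(table) {
  stopifnot(inherits(table, "codon_usage_table"))
  fam <- degeneracy_classes()
  fam$count <- as.integer(table$counts[fam$codon])
  totals <- tapply(fam$count, fam$family, sum)
  famtot <- as.integer(totals[fam$family])
  fam$RSCU <- ifelse(famtot > 0, fam$count * fam$family_size / famtot, 0)
  attr(fam, "empty_families") <- names(totals)[totals == 0]
  fam
}

#' Amino-acid composition of a codon usage table
#'
#' Percentages over the sense-codon total, reported both with Leu/Ser merged
#' (the usual published aggregation) and split into Leu1/Leu2, Ser1/Ser2.
#'
#' @param table a `codon_usage_table`.
#' @return list with data.frames `merged` (`aa`, `count`, `percent`) and
#'   `split` (`family`, `count`, `percent`), percentages of the sense total.
#' @export
amino_acid_composition <- function(table) {
  stopifnot(inherits(table, "codon_usage_table"))
  fam <- degeneracy_classes()
  fam$count <- as.integer(table$counts[fam$codon])
  tot <- table$total_codons
  pct <- function(x) if (tot > 0) 100 * x / tot else x * NA_real_
  split_ <- stats::aggregate(count ~ family, fam, sum)
  split_$percent <- pct(split_$count)
  merged <- stats::aggregate(count ~ aa, fam, sum)
  merged$aa <- unname(.AA1TO3[merged$aa])
  merged$percent <- pct(merged$count)
  list(merged = merged[order(-merged$percent), ],
       split = split_[order(-split_$percent), ])
}

#' Codon usage report for a genome
#'
#' Extracts every PCG, counts codons and returns the RSCU table plus
#' amino-acid composition and per-gene start/stop calls.
#'
#' @param g a `mitogenome` with sequence.
#' @return list: `genes` (per-PCG start/stop data.frame), `usage`
#'   (`codon_usage_table`), `rscu`, `aa_composition`.
#' @export
codon_usage_report <- function(g) {
  pcg <- which(g$features$type == "PCG")
  if (!length(pcg)) stop("genome has no protein-coding features")
  cds <- lapply(pcg, function(i) extract_cds(g, i))
  genes <- do.call(rbind, lapply(cds, function(x) data.frame(
    gene = x$gene, start_codon = x$start_codon, stop_codon = x$stop_display,
    completeness = x$completeness, codons = x$complete_codons,
    flags = paste(x$flags, collapse = ";"), stringsAsFactors = FALSE)))
  usage <- count_codons(cds)
  list(genes = genes, usage = usage, rscu = rscu(usage),
       aa_composition = amino_acid_composition(usage))
}
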
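# Canonical gene catalog and annotation-name normalization.
#
# Mitogenome annotations spell the same gene many ways (ND5 / NAD5 / NADH-5,
# COI / COX1, D-loop / control region, ...).  Everything downstream works on
# canonical tokens, so normalization happens once, at the I/O boundary.

#' Canonical gene catalog for the vertebrate mitogenome
#'
#' The 13 protein-coding genes, 22 tRNAs, 2 rRNAs, the control region and the
#' two replication origins, each with its feature class.
#'
#' @return A data.frame with columns `name` and `type`
#'   (`PCG`, `tRNA`, `rRNA`, `control`, `origin`).
#' @export
gene_catalog <- function() {
  pcg  <- c("ND1", "ND2", "ND3", "ND4", "ND4L", "ND5", "ND6",
            "COI", "COII", "COIII", "ATP6", "ATP8", "CYTB")
  trna <- paste0("trn", c("F", "V", "L1", "L2", "I", "Q", "M", "W", "A", "N",
                          "C", "Y", "S1", "S2", "D", "K", "G", "R", "H", "E",
                          "T", "P"))
  data.frame(
    name = c(pcg, trna, "rrnS", "rrnL", "CR", "OL", "OH"),
    type = c(rep("PCG", length(pcg)), rep("tRNA", length(trna)),
             "rRNA", "rRNA", "control", "origin", "origin"),
    stringsAsFactors = FALSE
  )
}

# three-letter -> one-letter amino-acid codes used in tRNA names
.AA3TO1 <- c(PHE = "F", VAL = "V", LEU = "L", ILE = "I", GLN = "Q", MET = "M",
             TRP = "W", ALA = "A", ASN = "N", CYS = "C", TYR = "Y", SER = "S",
             ASP = "D", LYS = "K", GLY = "G", ARG = "R", HIS = "H", GLU = "E",
             THR = "T", PRO = "P")

# anticodons disambiguating the duplicated Leu / Ser tRNA isoacceptors
.ANTICODON_ISO <- c(TAA = "L2", TAG = "L1", TGA = "S2", GCT = "S1", TCT = "S1")

.trna_token <- function(body, anticodon) {
  body <- toupper(body)
  m3 <- regmatches(body, regexec("^([A-Z]{3})\\s?([12]?)$", body))[[1]]
  if (length(m3)) {
    one <- .AA3TO1[m3[2]]
    if (!is.na(one)) body <- paste0(one, m3[3])
  }
  m1 <- regmatches(body, regexec("^([A-Z])([12]?)$", body))[[1]]
  if (!length(m1)) return(NA_character_)
  aa <- m1[2]; idx <- m1[3]
  if (aa %in% c("L", "S") && idx == "") {
    iso <- .ANTICODON_ISO[toupper(anticodon)]
    if (is.na(anticodon) || is.na(iso)) return(NA_character_)
    return(paste0("trn", iso))
  }
  tok <- paste0("trn", aa, idx)
  if (tok %in% gene_catalog()$name) tok else NA_character_
}

.match_canonical <- function(x, anticodon) {
  # x: cleaned, upper-case, no spaces/hyphens/dots
  if (grepl("^TRN", x)) {
    # "TRNA" may be the prefix "tRNA-" or the alanine tRNA "trnA"
    tok <- if (grepl("^TRNA", x)) .trna_token(substring(x, 5), anticodon) else NA
    if (is.na(tok)) tok <- .trna_token(substring(x, 4), anticodon)
    return(tok)
  }
  if (grepl("^(12S|RRNS|SRRNA|SSU)", x)) return("rrnS")
  if (grepl("^(16S|RRNL|LRRNA|LSU)", x)) return("rrnL")
  m <- regmatches(x, regexec("^(?:NADH?|ND)([1-6])(L?)$", x))[[1]]
  if (length(m)) {
    tok <- paste0("ND", m[2], m[3])
    if (tok %in% gene_catalog()$name) return(tok)
    return(NA_character_)
  }
  m <- regmatches(x, regexec("^(?:COX?|CO)(III|II|I|[123])$", x))[[1]]
  if (length(m)) {
    n <- c(I = "I", II = "II", III = "III",
           `1` = "I", `2` = "II", `3` = "III")[m[2]]
    return(paste0("CO", n))
  }
  if (grepl("^(CYTB|CYB|COB)$", x)) return("CYTB")
  m <- regmatches(x, regexec("^ATP(?:ASE)?([68])$", x))[[1]]
  if (length(m)) return(paste0("ATP", m[2]))
  if (grepl("^(DLOOP|CONTROLREGION|CR|PUTATIVECONTROLREGION)$", x)) return("CR")
  if (x == "OL" || grepl("^ORIGIN.*LIGHT", x)) return("OL")
  if (x == "OH" || grepl("^ORIGIN.*HEAVY", x)) return("OH")
  NA_character_
}

#' Normalize a raw gene name to its canonical token
#'
#' Case-insensitive and tolerant of the spelling variants found in published
#' mitogenome annotations (`NAD5`, `NADH-5`, `ND5`; `COX1`/`COI`; `D-loop`;
#' `tRNA-Ser 1(gct)`; duplicate suffixes such as `NADH5_0` or `ATP6 a`).
#' Unknown names pass through flagged, never error.
#'
#' @param raw character vector of names as read from an annotation.
#' @return A data.frame with columns `raw_name`, `name` (canonical token or
#'   `"unmapped:<raw>"`), `type` (catalog class or `"unknown"`), and
#'   `mapped` (logical).
#' @examples
#' normalize_gene_name(c("NAD4L", "tRNA-Leu2(taa)", "D-loop", "mystery"))
#' @export
normalize_gene_name <- function(raw) {
  stopifnot(is.character(raw))
  cat_ <- gene_catalog()
  one <- function(r) {
    anticodon <- NA_character_
    ac <- regmatches(r, regexec("\\(([ACGTUacgtu]{3})\\)", r))[[1]]
    if (length(ac)) anticodon <- toupper(chartr("U", "T", ac[2]))
    x <- toupper(gsub("\\(.*?\\)", "", r))
    x <- gsub("[ .\\-]+", "", x)
    tok <- .match_canonical(x, anticodon)
    if (is.na(tok)) {
      # retry once with a duplicate/copy suffix removed ("NADH5_0", "ATP6A")
      x2 <- sub("([_]?[0-9]|[AB])$", "", x)
      if (x2 != x && nzchar(x2)) tok <- .match_canonical(x2, anticodon)
    }
    tok
  }
  name <- vapply(raw, one, character(1), USE.NAMES = FALSE)
  mapped <- !is.na(name)
  type <- ifelse(mapped, cat_$type[match(name, cat_$name)], "unknown")
  name[!mapped] <- paste0("unmapped:", raw[!mapped])
  data.frame(raw_name = raw, name = name, type = type, mapped = mapped,
             stringsAsFactors = FALSE)
}
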
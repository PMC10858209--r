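# Seeded synthetic mitogenome generator with full ground truth.
#
# A genome is synthesized from a plan: an ordered chain of features with
# lengths, strands, PCG start/stop classes and signed gaps between
# neighbours (negative = planted overlap), plus optionally features
# contained inside another (an OH annotated within the control region).
# PCGs are built codon-by-codon with no in-frame stops while honouring
# bases already fixed by overlapping neighbours; a control-region tandem
# repeat can be planted with substitution-only divergence so the period
# stays exact.  Everything is driven by one seed.

#' Default gene plan: the canonical teleost mitogenome layout
#'
#' 37 genes (13 PCG + 22 tRNA + 2 rRNA) in the canonical vertebrate order
#' plus OL, the control region and an OH contained within it, with lengths,
#' strands, start/stop classes and signed inter-feature gaps mirroring a
#' published mudskipper annotation (genome length 16,685 bp; ND6 and eight
#' tRNAs on the L-strand; incomplete T--/TA- stops where observed).
#'
#' @return data.frame with columns `name`, `length`, `strand`, `type`,
#'   `start_codon`, `stop_codon` (`"TAA"`, `"TAG"`, `"TA"`, `"T"`, or `NA`),
#'   `gap_after` (signed bp to the next chain feature; for the last chain
#'   feature, the pad before the origin), `contained_in`, `offset`.
#' @export
default_gene_plan <- function() {
  p <- function(name, length, strand, start = NA, stop = NA, gap = 0L)
    data.frame(name = name, length = as.integer(length), strand = strand,
               start_codon = start, stop_codon = stop, gap_after = as.integer(gap),
               contained_in = NA_character_, offset = NA_integer_,
               stringsAsFactors = FALSE)
  plan <- rbind(
    p("trnF", 68, "H"),
    p("rrnS", 948, "H"),
    p("trnV", 72, "H", gap = 51),
    p("rrnL", 1640, "H", gap = 8),
    p("trnL2", 75, "H"),
    p("ND1", 975, "H", "ATG", "TAA", gap = 4),
    p("trnI", 70, "H", gap = -1),
    p("trnQ", 71, "L", gap = -1),
    p("trnM", 69, "H"),
    p("ND2", 1047, "H", "ATG", "TAA"),
    p("trnW", 71, "H", gap = 2),
    p("trnA", 69, "L", gap = 1),
    p("trnN", 73, "L", gap = 4),
    p("OL", 31, "H"),
    p("trnC", 65, "L"),
    p("trnY", 71, "L", gap = 1),
    p("COI", 1554, "H", "GTG", "TAA"),
    p("trnS2", 71, "L", gap = 3),
    p("trnD", 72, "H", gap = 4),
    p("COII", 691, "H", "ATG", "T"),
    p("trnK", 76, "H", gap = 1),
    p("ATP8", 165, "H", "ATG", "TAG", gap = -7),
    p("ATP6", 686, "H", "ATG", "TA", gap = 117),
    p("COIII", 653, "H", "ATG", "TA", gap = 14),
    p("trnG", 72, "H"),
    p("ND3", 351, "H", "ATG", "TAG", gap = -2),
    p("trnR", 69, "H"),
    p("ND4L", 297, "H", "ATG", "TAA", gap = -7),
    p("ND4", 1381, "H", "ATG", "T"),
    p("trnH", 69, "H"),
    p("trnS1", 68, "H", gap = 3),
    p("trnL1", 73, "H"),
    p("ND5", 1839, "H", "ATG", "TAA", gap = -4),
    p("ND6", 525, "L", "ATG", "TAG", gap = -3),
    p("trnE", 69, "L", gap = 5),
    p("CYTB", 1141, "H", "ATG", "T"),
    p("trnT", 73, "H", gap = 1),
    p("trnP", 70, "L"),
    p("CR", 1010, "H", gap = 1)
  )
  oh <- p("OH", 331, "H")
  oh$contained_in <- "CR"; oh$offset <- 495L; oh$gap_after <- NA_integer_
  plan <- rbind(plan, oh)
  cat_ <- gene_catalog()
  plan$type <- cat_$type[match(plan$name, cat_$name)]
  plan
}

#' Simulation configuration
#'
#' @param seed integer seed; the same config always yields the same genome.
#' @param gene_plan plan table, see [default_gene_plan()].
#' @param composition named target base frequencies (H-strand frame) used
#'   for sampling; default mirrors a whole-mitogenome composition
#'   (A 0.30, C 0.28, G 0.155, T 0.265).
#' @param class_composition optional named list of per-class overrides,
#'   e.g. `list(control = c(A=.35, C=.22, G=.12, T=.31))`.
#' @param repeat_plan `NULL` (no planted repeat, the default) or
#'   `list(period=, copies=, divergence=, offset=)`: a tandem motif of
#'   `period` bp planted `offset` bp into the control region, repeated
#'   `copies` times (fractional allowed), each copy independently mutated
#'   by substitutions at rate `divergence`.
#' @param duplications `NULL` or a named integer vector, e.g.
#'   `c(CR = 2, OH = 4)`: total copy counts for features to duplicate.
#'   Chain copies are inserted directly after the original (gap 0);
#'   duplicated contained features become chain features after their parent.
#' @param species,accession labels for the emitted genome.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, gene_plan = default_gene_plan(),
                       composition = c(A = 0.30, C = 0.28, G = 0.155, T = 0.265),
                       class_composition = NULL, repeat_plan = NULL,
                       duplications = NULL, species = "Simulatus mitogenomicus",
                       accession = "") {
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (abs(sum(composition) - 1) > 1e-6) stop("composition must sum to 1")
  if (!is.null(repeat_plan)) {
    need <- c("period", "copies", "divergence")
    if (!all(need %in% names(repeat_plan)))
      stop("repeat_plan needs: ", paste(need, collapse = ", "))
    if (is.null(repeat_plan$offset)) repeat_plan$offset <- 50L
  }
  structure(list(seed = as.integer(seed), gene_plan = gene_plan,
                 composition = composition[c("A", "C", "G", "T")],
                 class_composition = class_composition,
                 repeat_plan = repeat_plan, duplications = duplications,
                 species = species, accession = accession),
            class = "sim_config")
}

.apply_duplications <- function(plan, duplications) {
  if (is.null(duplications)) return(plan)
  for (nm in names(duplications)) {
    k <- duplications[[nm]]
    i <- which(plan$name == nm)
    if (!length(i)) stop("duplication of unknown feature: ", nm)
    if (k < 2) next
    row <- plan[i[1], , drop = FALSE]
    extra <- row[rep(1, k - 1L), , drop = FALSE]
    if (!is.na(row$contained_in)) {
      # contained duplicates become chain features right after their parent
      parent <- which(plan$name == row$contained_in)[1]
      extra$contained_in <- NA_character_; extra$offset <- NA_integer_
      extra$gap_after <- 0L
      # parent keeps its gap on the last inserted copy
      extra$gap_after[nrow(extra)] <- plan$gap_after[parent]
      plan$gap_after[parent] <- 0L
      plan <- rbind(plan[seq_len(parent), ], extra,
                    plan[-seq_len(parent), ])
    } else {
      extra$gap_after <- 0L
      # shift the original's trailing gap onto the last copy
      extra$gap_after[nrow(extra)] <- plan$gap_after[i[1]]
      plan$gap_after[i[1]] <- 0L
      plan <- rbind(plan[seq_len(i[1]), ], extra, plan[-seq_len(i[1]), ])
    }
    rownames(plan) <- NULL
  }
  plan
}

.plan_coordinates <- function(plan) {
  chain <- which(is.na(plan$contained_in))
  start <- integer(nrow(plan)); end <- integer(nrow(plan))
  pos <- 1L
  for (i in chain) {
    start[i] <- pos
    end[i] <- pos + plan$length[i] - 1L
    gap <- plan$gap_after[i]
    if (is.na(gap)) gap <- 0L
    pos <- end[i] + gap + 1L
  }
  L <- pos - 1L
  for (i in which(!is.na(plan$contained_in))) {
    parent <- which(plan$name == plan$contained_in[i] & is.na(plan$contained_in))
    if (!length(parent)) stop("contained_in refers to unknown feature: ",
                              plan$contained_in[i])
    start[i] <- start[parent[1]] + plan$offset[i]
    end[i] <- start[i] + plan$length[i] - 1L
    if (end[i] > end[parent[1]])
      stop("contained feature ", plan$name[i], " does not fit in ",
           plan$contained_in[i])
  }
  if (any(start < 1L))
    stop("infeasible plan: negative residual length (feature ",
         plan$name[which(start < 1L)[1]], " starts before position 1)")
  if (L < max(end)) stop("infeasible plan: genome shorter than its features")
  list(start = start, end = end, genome_length = L)
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.class_comp <- function(config, type) {
  cc <- config$class_composition
  if (!is.null(cc) && type %in% names(cc)) {
    v <- cc[[type]][c("A", "C", "G", "T")]
    return(v / sum(v))
  }
  config$composition
}

.sample_bases <- function(n, comp) {
  if (n <= 0) return(character(0))
  sample(names(comp), n, replace = TRUE, prob = comp)
}

# Write a PCG's start/stop bases into H-space before any interior fill, so
# overlapping neighbours (ATP8/ATP6, ND4L/ND4, ND5/ND6) see each other's
# fixed bases as constraints instead of overwriting them.
.place_constraints <- function(chars, start, end, strand, start_codon,
                               stop_codon, name) {
  len <- end - start + 1L
  hpos <- if (strand == "H") seq.int(start, end) else seq.int(end, start)
  put <- function(cds_idx, bases) {
    if (strand == "L") bases <- .COMPLEMENT[bases]
    at <- hpos[cds_idx]
    conflict <- !is.na(chars[at]) & chars[at] != bases
    if (any(conflict))
      stop("infeasible plan: conflicting fixed bases between ", name,
           " and an overlapping feature at position ", at[conflict][1])
    chars[at] <<- bases
  }
  put(1:3, strsplit(start_codon, "")[[1]])
  stop_b <- strsplit(stop_codon, "")[[1]]
  put(seq.int(len - length(stop_b) + 1L, len), stop_b)
  chars
}

# fill one PCG in CDS space, honouring fixed bases, avoiding in-frame stops
.fill_pcg <- function(chars, start, end, strand, start_codon, stop_codon,
                      comp, name) {
  len <- end - start + 1L
  hpos <- if (strand == "H") seq.int(start, end) else seq.int(end, start)
  cds <- chars[hpos]
  if (strand == "L") cds <- ifelse(is.na(cds), NA, .COMPLEMENT[cds])
  put <- function(idx, bases) {
    conflict <- !is.na(cds[idx]) & cds[idx] != bases
    if (any(conflict))
      stop("infeasible plan: base conflict in ", name, " at CDS position ",
           idx[conflict][1])
    cds[idx] <<- bases
  }
  put(1:3, strsplit(start_codon, "")[[1]])
  stop_b <- strsplit(stop_codon, "")[[1]]
  put(seq.int(len - length(stop_b) + 1L, len), stop_b)
  stops <- stop_codons2()
  n_codons <- len %/% 3L
  last_full <- if (len %% 3L == 0L) n_codons - 1L else n_codons  # keep stop intact
  for (ci in seq.int(2L, last_full)) {
    idx <- (ci - 1L) * 3L + 1:3
    free <- which(is.na(cds[idx]))
    if (!length(free)) {
      if (paste(cds[idx], collapse = "") %in% stops)
        stop("infeasible plan: fixed in-frame stop codon in ", name)
      next
    }
    ok <- FALSE
    for (try in 1:50) {
      cand <- cds[idx]
      cand[free] <- .sample_bases(length(free), comp)
      if (!(paste(cand, collapse = "") %in% stops)) {
        cds[idx] <- cand; ok <- TRUE; break
      }
    }
    if (!ok) {
      # exhaustive fallback over the free positions
      grid <- expand.grid(rep(list(c("A", "C", "G", "T")), length(free)),
                          stringsAsFactors = FALSE)
      for (r in seq_len(nrow(grid))) {
        cand <- cds[idx]; cand[free] <- unlist(grid[r, ])
        if (!(paste(cand, collapse = "") %in% stops)) {
          cds[idx] <- cand; ok <- TRUE; break
        }
      }
      if (!ok) stop("infeasible plan: no stop-free codon completion in ", name)
    }
  }
  if (anyNA(cds)) cds[is.na(cds)] <- .sample_bases(sum(is.na(cds)), comp)
  back <- if (strand == "L") .COMPLEMENT[cds] else cds
  chars[hpos] <- back
  chars
}

.mutate_copy <- function(motif, rate) {
  if (rate <= 0) return(motif)
  hit <- stats::runif(length(motif)) < rate
  if (any(hit)) {
    motif[hit] <- vapply(motif[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  }
  motif
}

#' Generate a synthetic annotated mitogenome
#'
#' @param config a [sim_config()].
#' @return list with elements `genome` (a [mitogenome()]) and `truth`
#'   (features, gap plan, planted repeat, duplication table, per-PCG
#'   start/stop classes, composition targets, seed).
#' @export
generate_mitogenome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  plan <- .apply_duplications(config$gene_plan, config$duplications)
  # validate PCG length vs stop class
  pcg <- which(plan$type == "PCG")
  for (i in pcg) {
    want <- c(TAA = 0L, TAG = 0L, TA = 2L, T = 1L)[[plan$stop_codon[i]]]
    if (plan$length[i] %% 3L != want)
      stop("plan error: ", plan$name[i], " length ", plan$length[i],
           " mod 3 inconsistent with stop class ", plan$stop_codon[i])
  }
  co <- .plan_coordinates(plan)
  L <- co$genome_length
  chars <- rep(NA_character_, L)

  # 1a. fix every PCG's start/stop bases first (overlap-aware)
  for (i in pcg) {
    chars <- .place_constraints(chars, co$start[i], co$end[i], plan$strand[i],
                                plan$start_codon[i], plan$stop_codon[i],
                                plan$name[i])
  }
  # 1b. PCG interiors (plan order; previously written bases act as constraints)
  for (i in pcg) {
    comp <- .class_comp(config, "PCG")
    if (plan$strand[i] == "L") {
      comp <- stats::setNames(comp[c("T", "G", "C", "A")], c("A", "C", "G", "T"))
    }
    chars <- .fill_pcg(chars, co$start[i], co$end[i], plan$strand[i],
                       plan$start_codon[i], plan$stop_codon[i], comp,
                       plan$name[i])
  }
  # 2. other features
  for (i in which(plan$type != "PCG")) {
    idx <- seq.int(co$start[i], co$end[i])
    na <- idx[is.na(chars[idx])]
    chars[na] <- .sample_bases(length(na), .class_comp(config, plan$type[i]))
  }
  # 3. planted control-region repeat
  repeat_truth <- NULL
  rp <- config$repeat_plan
  if (!is.null(rp)) {
    if (!all(c("period", "copies", "divergence") %in% names(rp)))
      stop("repeat_plan needs: period, copies, divergence")
    if (is.null(rp$offset)) rp$offset <- 50L
    cri <- which(plan$name == "CR")
    if (!length(cri)) stop("repeat_plan requires a CR feature in the plan")
    cri <- cri[1]
    span_len <- as.integer(round(rp$period * rp$copies))
    a <- co$start[cri] + rp$offset
    b <- a + span_len - 1L
    if (b > co$end[cri])
      stop("infeasible plan: repeat span (", span_len,
           " bp) does not fit in the CR at offset ", rp$offset)
    motif <- .sample_bases(rp$period, .class_comp(config, "control"))
    # `divergence` is the expected copy-to-copy mismatch fraction (what the
    # scanner measures); with every copy mutated independently from the motif
    # at rate r, two copies differ with prob 2r - (4/3)r^2, hence:
    d <- rp$divergence
    rate <- if (d > 0) (2 - sqrt(4 - 16 * d / 3)) / (8 / 3) else 0
    pos <- a
    copy_seqs <- character(0)
    while (pos <= b) {
      take <- min(rp$period, b - pos + 1L)
      cp <- .mutate_copy(motif, rate)[seq_len(take)]
      chars[seq.int(pos, pos + take - 1L)] <- cp
      copy_seqs <- c(copy_seqs, paste(cp, collapse = ""))
      pos <- pos + take
    }
    repeat_truth <- list(span_start = a, span_end = b, period = rp$period,
                         copies = round(span_len / rp$period, 1),
                         divergence = rp$divergence,
                         motif = paste(motif, collapse = ""),
                         copy_seqs = copy_seqs)
  }
  # 4. gap / unannotated positions
  na <- which(is.na(chars))
  chars[na] <- .sample_bases(length(na), config$composition)

  feats <- mito_features(plan$name, co$start, co$end, strand = plan$strand,
                         type = plan$type, raw_name = plan$name)
  ord <- order(feats$start, feats$end)
  feats <- feats[ord, , drop = FALSE]
  rownames(feats) <- NULL
  genome <- mitogenome(config$species, features = feats,
                       sequence = paste(chars, collapse = ""),
                       accession = config$accession)

  chain <- which(is.na(plan$contained_in))
  n <- length(chain)
  gap_plan <- data.frame(
    upstream = plan$name[chain],
    downstream = c(plan$name[chain][-1], plan$name[chain][1]),
    signed_length = c(plan$gap_after[chain][-n],
                      plan$gap_after[chain][n] + co$start[chain][1] - 1L),
    wraps_origin = c(rep(FALSE, n - 1L), TRUE),
    stringsAsFactors = FALSE
  )
  dup_truth <- detect_duplications(genome)
  codon_truth <- data.frame(
    gene = plan$name[pcg], copy_index = feats$copy_index[match(pcg, ord)],
    start_codon = plan$start_codon[pcg],
    stop_class = c(TAA = "complete", TAG = "complete", TA = "TA_incomplete",
                   T = "T_incomplete")[plan$stop_codon[pcg]],
    stop_codon = plan$stop_codon[pcg],
    stringsAsFactors = FALSE
  )
  list(genome = genome,
       truth = list(seed = config$seed, genome_length = L, features = feats,
                    gap_plan = gap_plan, repeat_rec = repeat_truth,
                    duplications = dup_truth, codon = codon_truth,
                    composition = as.list(config$composition)))
}

#' Generate a family of related synthetic genomes
#'
#' Applies per-member overrides (any [sim_config()] field: `duplications`,
#' `repeat_plan`, `species`, `gene_plan`, `seed`, ...) to a base
#' configuration.  Members with no overrides are identical to the base
#' genome.  Optionally writes GenBank + FASTA + feature table + truth JSON
#' per member.
#'
#' @param base_config a [sim_config()].
#' @param variants list of override lists, one per member (may be empty
#'   lists).
#' @param dir if non-`NULL`, output directory for per-member files.
#' @return list of `list(genome, truth)` as from [generate_mitogenome()].
#' @export
make_family <- function(base_config, variants, dir = NULL) {
  stopifnot(inherits(base_config, "sim_config"), is.list(variants))
  out <- vector("list", length(variants))
  for (i in seq_along(variants)) {
    ov <- variants[[i]]
    cfg <- base_config
    for (nm in names(ov)) cfg[[nm]] <- ov[[nm]]
    if (is.null(ov$species))
      cfg$species <- paste0(base_config$species, " member", i)
    res <- generate_mitogenome(cfg)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      stem <- file.path(dir, sprintf("member%02d", i))
      write_genbank(res$genome, paste0(stem, ".gb"))
      write_fasta_seq(stats::setNames(res$genome$sequence, cfg$species),
                      paste0(stem, ".fa"))
      write_feature_table(res$genome, paste0(stem, ".tsv"))
      jsonlite::write_json(res$truth, paste0(stem, ".truth.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
    }
    out[[i]] <- res
  }
  out
}

#' Random nucleotide sequence with a target composition
#'
#' Utility sampler used in tests and null simulations; draws i.i.d. bases
#' from the given frequencies using the current RNG state.
#'
#' @param n length in bp.
#' @param composition named base frequencies (A, C, G, T), normalized
#'   internally.
#' @return nucleotide string.
#' @export
random_sequence <- function(n, composition = c(A = .25, C = .25, G = .25, T = .25)) {
  comp <- composition[c("A", "C", "G", "T")] / sum(composition)
  paste(.sample_bases(n, comp), collapse = "")
}
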
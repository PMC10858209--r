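test_that("CDS extraction is a literal slice on H and revcomp on L", {
  set.seed(5)
  s <- random_sequence(600)
  g <- mitogenome("t", features = mito_features(c("ND1", "ND6"),
                                                c(10, 300), c(129, 407),
                                                strand = c("H", "L")),
                  sequence = s)
  cds_h <- extract_cds(g, "ND1")
  expect_equal(cds_h$oriented_seq, substr(s, 10, 129))
  cds_l <- extract_cds(g, "ND6")
  expect_equal(cds_l$oriented_seq, revcomp_oracle(substr(s, 300, 407)))
  expect_error(extract_cds(g, "trnF"), "no feature")
})

test_that("L-strand extraction equals the revcomp oracle on random features", {
  set.seed(6)
  s <- random_sequence(2000)
  for (i in 1:100) {
    a <- sample(1:1800, 1); b <- a + sample(30:150, 1)
    g <- mitogenome("t", features = mito_features("ND2", a, b, "L"),
                    sequence = s)
    expect_equal(extract_cds(g, 1)$oriented_seq,
                 revcomp_oracle(substr(s, a, b)))
  }
})

test_that("wrap features concatenate across the origin", {
  s <- random_sequence(300)
  g <- mitogenome("t", features = mito_features("ND1", 280, 30, "H",
                                                wraps_origin = TRUE),
                  sequence = s)
  expect_equal(feature_sequence(g, 1),
               paste0(substr(s, 280, 300), substr(s, 1, 30)))
})

test_that("start/stop calling follows length mod 3", {
  # complete TAA
  cs <- call_start_stop("ATGAAACCCTAA")
  expect_equal(cs$completeness, "complete")
  expect_equal(cs$stop_codon, "TAA")
  # one trailing T: incomplete T--
  cs <- call_start_stop("ATGAAACCCT")
  expect_equal(cs$completeness, "T_incomplete")
  expect_equal(cs$stop_codon, "T--")
  expect_equal(cs$stop_display, "T(AA)")
  # two trailing TA: incomplete TA-
  cs <- call_start_stop("ATGAAACCCTA")
  expect_equal(cs$completeness, "TA_incomplete")
  expect_equal(cs$stop_display, "TA(A)")
  # unusual start and non-T trailing flagged, not errored
  cs <- call_start_stop("CCTAAAC")
  expect_true("non-canonical-start" %in% cs$flags)
  expect_true("unexpected-incomplete-stop" %in% cs$flags)
  cs <- call_start_stop("GTGAAATAA")
  expect_true("alternative-start" %in% cs$flags)
})

test_that("generator-planted start/stop classes are recovered exactly", {
  res <- generate_mitogenome(sim_config(seed = 8))
  rep_ <- codon_usage_report(res$genome)
  m <- merge(rep_$genes, res$truth$codon, by = "gene")
  expect_equal(nrow(m), 13L)
  expect_equal(m$start_codon.x, m$start_codon.y)
  expect_equal(m$completeness, m$stop_class)
  expect_setequal(unique(m$completeness),
                  c("complete", "TA_incomplete", "T_incomplete"))
})

test_that("codon counting excludes stops, partials and ambiguity", {
  t1 <- count_codons(list("ATGAAATAA"))
  expect_equal(t1$total_codons, 2L)
  expect_equal(unname(t1$counts[c("ATG", "AAA", "TAA")]), c(1L, 1L, 1L))
  expect_equal(t1$n_stop_codons, 1L)

  t0 <- count_codons(list())
  expect_true(all(t0$counts == 0L))
  expect_equal(t0$total_codons, 0L)

  t2 <- count_codons(list("ATGNNNCCCAT"))  # ambiguous codon + partial "AT"
  expect_equal(t2$total_codons, 2L)
  expect_equal(t2$n_ambiguous_codons, 1L)
})

test_that("codon counts equal the sampling truth for a multinomial stream", {
  set.seed(9)
  sense <- setdiff(all_sense <- names(which(
    Biostrings::getGeneticCode("2") != "*")), character())
  draws <- sample(sense, 400, replace = TRUE)
  t_ <- count_codons(list(paste(draws, collapse = "")))
  truth <- table(draws)
  expect_equal(unname(t_$counts[names(truth)]), unname(as.integer(truth)))
  expect_equal(t_$total_codons, 400L)
})

test_that("degeneracy families derive from the code table", {
  fam <- degeneracy_classes()
  gc2 <- Biostrings::getGeneticCode("2")
  # partition of the 60 sense codons
  expect_equal(sort(fam$codon), sort(names(gc2)[gc2 != "*"]))
  expect_equal(anyDuplicated(fam$codon), 0L)
  # published structure: Gly/Val 4-fold boxes; Leu and Ser split
  expect_setequal(fam$codon[fam$family == "Gly"],
                  c("GGA", "GGC", "GGG", "GGT"))
  expect_equal(unique(fam$family_size[fam$family == "Val"]), 4L)
  expect_setequal(fam$codon[fam$family == "Leu1"], c("CTA", "CTC", "CTG", "CTT"))
  expect_setequal(fam$codon[fam$family == "Leu2"], c("TTA", "TTG"))
  expect_setequal(fam$codon[fam$family == "Ser1"], c("AGC", "AGT"))
  expect_equal(unique(fam$family_size[fam$family == "Ser2"]), 4L)
  # Trp and Met are 2-fold under the vertebrate mitochondrial code
  expect_equal(unique(fam$family_size[fam$family %in% c("Trp", "Met")]), 2L)
  # family sizes always regenerate from the table
  expect_equal(fam$family_size, as.integer(table(fam$family)[fam$family]))
})

test_that("RSCU matches closed-form cases and a brute-force oracle", {
  fam <- degeneracy_classes()
  # uniform family usage -> RSCU 1 everywhere
  t_uni <- structure(list(counts = stats::setNames(rep(3L, 64), all_codons()),
                          total_codons = 180L, n_stop_codons = 12L,
                          n_ambiguous_codons = 0L, genetic_code_id = "2"),
                     class = "codon_usage_table")
  r <- rscu(t_uni)
  expect_true(all(abs(r$RSCU - 1) < 1e-12))
  # sole codon of a 2-fold family -> 2.0
  counts <- stats::setNames(integer(64), all_codons())
  counts["TTA"] <- 7L  # Leu2 family {TTA, TTG}
  t_one <- structure(list(counts = counts, total_codons = 7L,
                          n_stop_codons = 0L, n_ambiguous_codons = 0L,
                          genetic_code_id = "2"),
                     class = "codon_usage_table")
  r <- rscu(t_one)
  expect_equal(r$RSCU[r$codon == "TTA"], 2)
  expect_equal(r$RSCU[r$codon == "TTG"], 0)
  expect_true("Gly" %in% attr(r, "empty_families"))

  # brute-force oracle on 50 random tables: RSCU = count / mean(family)
  set.seed(10)
  for (k in 1:50) {
    counts <- stats::setNames(as.integer(stats::rpois(64, 4)), all_codons())
    tb <- structure(list(counts = counts, total_codons = sum(counts),
                         n_stop_codons = 0L, n_ambiguous_codons = 0L,
                         genetic_code_id = "2"),
                    class = "codon_usage_table")
    r <- rscu(tb)
    for (i in seq_len(nrow(r))) {
      sibs <- r$count[r$family == r$family[i]]
      expected <- if (sum(sibs) > 0) r$count[i] / mean(sibs) else 0
      expect_equal(r$RSCU[i], expected)
    }
    sums <- tapply(r$RSCU, r$family, sum)
    sizes <- tapply(r$family_size, r$family, max)
    nonzero <- tapply(r$count, r$family, sum) > 0
    expect_true(all(abs(sums[nonzero] - sizes[nonzero]) < 1e-9))
  }
})

test_that("amino-acid composition percentages behave", {
  counts <- stats::setNames(integer(64), all_codons())
  counts["GGA"] <- 5L
  tb <- structure(list(counts = counts, total_codons = 5L, n_stop_codons = 0L,
                       n_ambiguous_codons = 0L, genetic_code_id = "2"),
                  class = "codon_usage_table")
  a <- amino_acid_composition(tb)
  expect_equal(a$merged$percent[a$merged$aa == "Gly"], 100)

  # 10-codon toy, hand-computed: 4 Leu (2 CTA + 2 TTA), 3 Gly, 2 Ser, 1 Trp
  counts[] <- 0L
  counts[c("CTA", "TTA", "GGA", "AGC", "TGA")] <- c(2L, 2L, 3L, 2L, 1L)
  tb$counts <- counts; tb$total_codons <- 10L
  a <- amino_acid_composition(tb)
  m <- stats::setNames(a$merged$percent, a$merged$aa)
  expect_equal(unname(m[c("Leu", "Gly", "Ser", "Trp")]), c(40, 30, 20, 10))
  s <- stats::setNames(a$split$percent, a$split$family)
  expect_equal(unname(s[c("Leu1", "Leu2", "Ser1")]), c(20, 20, 20))
  expect_equal(sum(a$merged$percent), 100)
})

test_that("whole-genome codon report is internally consistent", {
  res <- generate_mitogenome(sim_config(seed = 12))
  rep_ <- codon_usage_report(res$genome)
  expect_equal(sum(rep_$aa_composition$merged$percent), 100)
  expect_equal(sum(rep_$rscu$count), rep_$usage$total_codons)
})
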
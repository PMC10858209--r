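test_that("gene-name normalization maps published spelling variants", {
  r <- normalize_gene_name(c("NAD4L", "nd4l", "NADH-4", "ND5", "CYT B",
                             "COX1", "COIII", "12S", "16S rRNA",
                             "tRNA-Ser 1(gct)", "tRNA-Leu2(taa)", "trnA",
                             "D-loop", "OL", "NADH5_0", "NADH5_1", "ATP6 a"))
  expect_true(all(r$mapped))
  expect_equal(r$name[1:2], c("ND4L", "ND4L"))
  expect_equal(r$type[1], "PCG")
  expect_equal(r$name[3:7], c("ND4", "ND5", "CYTB", "COI", "COIII"))
  expect_equal(r$name[8:9], c("rrnS", "rrnL"))
  expect_equal(r$name[10:12], c("trnS1", "trnL2", "trnA"))
  expect_equal(r$type[13:14], c("control", "origin"))
  expect_equal(r$name[15:17], c("ND5", "ND5", "ATP6"))
})

test_that("unknown names pass through flagged, never error", {
  r <- normalize_gene_name(c("mystery", "tRNA-Leu"))  # Leu without index/anticodon
  expect_false(any(r$mapped))
  expect_match(r$name[1], "^unmapped:")
  expect_equal(r$type, c("unknown", "unknown"))
})

test_that("every raw spelling in the packaged fixture maps to the catalog", {
  path <- system.file("extdata", "boleophthalmus_dussumieri_features.tsv",
                      package = "mitocomp")
  raw <- utils::read.table(path, header = TRUE, sep = "\t")$name
  r <- normalize_gene_name(raw)
  expect_true(all(r$mapped))
  expect_true(all(r$name %in% gene_catalog()$name))
  expect_equal(length(unique(r$name)), 40)  # all distinct tokens
})

test_that("the packaged fixture matches the published annotation", {
  g <- dussumieri_fixture()
  expect_equal(g$length, 16685L)
  expect_equal(nrow(g$features), 40L)
  len <- feature_lengths(g)
  expect_equal(len[g$features$name == "ND5"], 1839L)
  expect_equal(len[g$features$name == "trnP"], 70L)
  expect_equal(len[g$features$name == "CR"], 1010L)
  expect_equal(sum(g$features$strand == "L"), 9L)  # ND6 + 8 tRNAs
  expect_equal(g$features$name[g$features$strand == "L" & g$features$type == "PCG"],
               "ND6")
})

test_that("feature tables reject inconsistent rows", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("name\tfrom\tto\tstrand", "ND1\t100\t50\tH"), tf)
  expect_error(read_feature_table(tf, 1000), "wrap")
  writeLines(c("name\tfrom\tto\tstrand", "ND1\t10\t50\tH", "ND2\t10\t50\tH"), tf)
  expect_error(read_feature_table(tf, 1000), "duplicate")
  writeLines("name\tfrom\tto\tstrand", tf)
  g <- read_feature_table(tf, 1000)
  expect_equal(nrow(g$features), 0L)
})

test_that("genome validation catches out-of-range and wrap inconsistencies", {
  f <- mito_features("ND1", 10, 2000, "H")
  expect_error(mitogenome("x", length = 1000, features = f), "outside")
  f <- mito_features("ND1", 900, 100, "H", wraps_origin = TRUE)
  g <- mitogenome("x", length = 1000, features = f)
  expect_equal(feature_lengths(g), 201L)  # (1000-900+1) + 100
})

test_that("GenBank parsing handles strands, wraps and bad input", {
  gb <- c(
    "LOCUS       TEST             1000 bp    DNA     circular VRT",
    "FEATURES             Location/Qualifiers",
    "     source          1..1000",
    '                     /organism="Testus testus"',
    "     CDS             101..400",
    '                     /gene="ND5"',
    "     tRNA            complement(401..470)",
    '                     /gene="tRNA-Gln(ttg)"',
    "     rRNA            join(900..1000,1..100)",
    '                     /gene="12S"',
    "ORIGIN",
    sprintf("%9d %s", seq(1, 1000, 60),
            paste(rep("acgtacgtac", 6), collapse = " "))[1:16],
    sprintf("%9d %s", 961, paste(rep("acgtacgtac", 4), collapse = " ")),
    "//")
  tf <- tempfile(fileext = ".gb")
  writeLines(gb, tf)
  g <- read_genbank(tf)
  expect_equal(g$length, 1000L)
  expect_equal(g$species, "Testus testus")
  f <- g$features
  nd5 <- f[f$name == "ND5", ]
  expect_equal(c(nd5$start, nd5$end), c(101L, 400L))
  expect_equal(f$strand[f$name == "trnQ"], "L")
  expect_true(f$wraps_origin[f$name == "rrnS"])
  expect_equal(feature_lengths(g)[f$name == "rrnS"], 201L)

  writeLines(gb[-1], tf)
  expect_error(read_genbank(tf), "LOCUS")
  gb_bad <- gb; gb_bad[5] <- "     CDS             101..1400"
  writeLines(gb_bad, tf)
  expect_error(read_genbank(tf), "beyond sequence end")
  gb_bad <- gb; gb_bad[5] <- "     CDS             101...x400"
  writeLines(gb_bad, tf)
  expect_error(read_genbank(tf), "unparseable")
})

test_that("a single feature spanning the whole molecule reads back as such", {
  g0 <- mitogenome("one", features = mito_features("CR", 1, 300, "H"),
                   sequence = random_sequence(300))
  tf <- tempfile(fileext = ".gb")
  write_genbank(g0, tf)
  g <- read_genbank(tf)
  expect_equal(nrow(g$features), 1L)
  expect_equal(feature_lengths(g), g$length)
})

test_that("feature-table round trip preserves every field on 100 random sets", {
  set.seed(42)
  cols <- c("name", "start", "end", "strand", "type", "copy_index",
            "wraps_origin")
  for (k in 1:100) {
    rs <- rand_annotation_set(sample(4:12, 1))
    tf <- tempfile(fileext = ".tsv")
    write_feature_table(rs$genome, tf)
    g2 <- read_feature_table(tf, rs$genome$length, species = "rand")
    expect_identical(rs$genome$features[cols], g2$features[cols])
    unlink(tf)
  }
})

test_that("GenBank round trip preserves synthetic genomes bit-for-bit", {
  cols <- c("name", "start", "end", "strand", "type", "copy_index",
            "wraps_origin")
  for (sd in c(11, 12, 13)) {
    res <- generate_mitogenome(sim_config(seed = sd))
    tf <- tempfile(fileext = ".gb")
    write_genbank(res$genome, tf)
    g2 <- read_genbank(tf)
    expect_identical(res$genome$features[cols], g2$features[cols])
    expect_identical(res$genome$sequence, g2$sequence)
    unlink(tf)
  }
})

test_that("the feature report carries the published intergenic column", {
  rep_ <- write_feature_report(dussumieri_fixture())
  trnp <- rep_[rep_$name == "trnP", ]
  expect_equal(trnp$length, 70L)
  expect_equal(trnp$intergenic, 495L)
  expect_true(is.na(rep_$intergenic[rep_$name == "CR"]))  # excluded container

  g1 <- mitogenome("one", length = 500,
                   features = mito_features("ND1", 51, 150, "H"))
  r1 <- write_feature_report(g1)
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$intergenic, 500L - 100L)
})
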
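test_that("the default configuration realizes the canonical plan", {
  res <- generate_mitogenome(sim_config(seed = 1))
  g <- res$genome
  expect_equal(g$length, 16685L)
  expect_equal(nrow(g$features), 40L)
  tab <- table(g$features$type)
  expect_equal(as.integer(tab[c("PCG", "tRNA", "rRNA")]), c(13L, 22L, 2L))
  # planted gap plan reproduces the published spacer accounting
  s <- spacer_summary(g)
  expect_equal(s$n_igs, 17L)
  expect_equal(s$total_igs_bp, 899L)
  expect_equal(s$longest_igs_bp, 495L)
})

test_that("generation is deterministic in the seed", {
  a <- generate_mitogenome(sim_config(seed = 2))
  b <- generate_mitogenome(sim_config(seed = 2))
  c_ <- generate_mitogenome(sim_config(seed = 3))
  expect_identical(a$genome$sequence, b$genome$sequence)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$genome$sequence, c_$genome$sequence))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(generate_mitogenome(sim_config(seed = 9)))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("infeasible plans fail validation before synthesis", {
  plan <- default_gene_plan()
  plan$gap_after[1] <- -10000L
  expect_error(generate_mitogenome(sim_config(seed = 1, gene_plan = plan)),
               "infeasible")
  plan <- default_gene_plan()
  plan$stop_codon[plan$name == "ND1"] <- "TA"  # length 975 %% 3 == 0
  expect_error(generate_mitogenome(sim_config(seed = 1, gene_plan = plan)),
               "stop class")
  expect_error(generate_mitogenome(sim_config(
    seed = 1, repeat_plan = list(period = 400, copies = 3, divergence = 0))),
    "does not fit")
  oh <- default_gene_plan()
  oh$offset[oh$name == "OH"] <- 900L
  expect_error(generate_mitogenome(sim_config(seed = 1, gene_plan = oh)),
               "does not fit")
})

test_that("planted gaps equal the truth plan under keep-all on flat plans", {
  # a plan without containment: drop OH so the chain is the whole annotation
  plan <- default_gene_plan()
  plan <- plan[plan$name != "OH", ]
  set.seed(71)
  for (sd in 71:73) {
    res <- generate_mitogenome(sim_config(seed = sd, gene_plan = plan))
    gaps <- compute_gaps(build_gap_chain(res$genome, "keep-all"),
                         res$genome$length)
    tp <- res$truth$gap_plan
    expect_equal(gaps$upstream, tp$upstream)
    expect_equal(gaps$signed_length, tp$signed_length)
  }
})

test_that("PCGs contain no in-frame stop codons", {
  res <- generate_mitogenome(sim_config(seed = 81))
  stops <- c("TAA", "TAG", "AGA", "AGG")
  for (i in which(res$genome$features$type == "PCG")) {
    cds <- extract_cds(res$genome, i)
    s <- cds$oriented_seq
    n_int <- cds$complete_codons - as.integer(cds$trailing_partial == 0L)
    internal <- substring(s, seq(1L, by = 3L, length.out = n_int),
                          seq(3L, by = 3L, length.out = n_int))
    expect_false(any(internal %in% stops),
                 info = res$genome$features$name[i])
  }
})

test_that("whole-genome composition tracks the configured target", {
  target <- c(A = 0.32, C = 0.26, G = 0.16, T = 0.26)
  res <- generate_mitogenome(sim_config(seed = 91, composition = target))
  p <- base_composition(res$genome$sequence)
  expect_true(all(abs(p$pct / 100 - target) < 0.03))
})

test_that("per-class composition overrides apply to the control region", {
  cc <- list(control = c(A = 0.40, C = 0.17, G = 0.10, T = 0.33))
  res <- generate_mitogenome(sim_config(seed = 92, class_composition = cc))
  f <- res$genome$features
  cr <- f[f$name == "CR", ]
  s <- substr(res$genome$sequence, cr$start, cr$end)
  p <- base_composition(s)
  expect_true(all(abs(p$pct / 100 - cc$control) < 0.05))
})

test_that("families honour overrides and write readable artifacts", {
  base <- sim_config(seed = 101)
  dir <- file.path(tempdir(), "fam_test")
  fam <- make_family(base, list(list(), list(duplications = c(OH = 4))),
                     dir = dir)
  expect_equal(detect_duplications(fam[[1]]$genome)$name, character(0))
  d <- detect_duplications(fam[[2]]$genome)
  expect_equal(d$n_copies[d$name == "OH"], 4L)
  # artifacts round-trip
  g2 <- read_genbank(file.path(dir, "member01.gb"))
  expect_equal(g2$length, fam[[1]]$genome$length)
  fa <- read_fasta_seq(file.path(dir, "member01.fa"))
  expect_equal(unname(fa), fam[[1]]$genome$sequence)
  tr <- jsonlite::read_json(file.path(dir, "member02.truth.json"))
  expect_equal(tr$seed, 101L)
  unlink(dir, recursive = TRUE)
})

test_that("zero-variant families are identical and group together", {
  fam <- make_family(sim_config(seed = 105), list(list(), list()))
  expect_identical(fam[[1]]$genome$sequence, fam[[2]]$genome$sequence)
  oc <- order_comparison_report(lapply(fam, `[[`, "genome"))
  expect_equal(unique(oc$groups$group), 1L)
})

test_that("master integration: every ground-truth field is recovered", {
  cfg <- sim_config(seed = 111,
                    repeat_plan = list(period = 90, copies = 3.5,
                                       divergence = 0.04),
                    duplications = c(OH = 2))
  res <- generate_mitogenome(cfg)
  g <- res$genome

  # features: GenBank round trip equals truth
  tf <- tempfile(fileext = ".gb")
  write_genbank(g, tf)
  g2 <- read_genbank(tf)
  cols <- c("name", "start", "end", "strand", "type", "copy_index")
  expect_identical(g2$features[cols], res$truth$features[cols])
  unlink(tf)

  # codon classes
  rep_ <- codon_usage_report(g2)
  m <- merge(rep_$genes, res$truth$codon, by = "gene")
  expect_equal(m$start_codon.x, m$start_codon.y)
  expect_equal(m$completeness, m$stop_class)

  # repeat
  r <- scan_control_regions(list(g))
  tr <- res$truth$repeat_rec
  expect_equal(nrow(r), 1L)
  expect_lte(abs(r$period - tr$period), 2)
  expect_lte(abs(r$copy_number - tr$copies), 0.2)

  # duplications
  d <- detect_duplications(g)
  expect_equal(d$n_copies[d$name == "OH"],
               res$truth$duplications$n_copies[res$truth$duplications$name == "OH"])

  # composition within binomial tolerance of the target
  p <- base_composition(g$sequence)
  expect_true(all(abs(p$pct / 100 - unlist(res$truth$composition)) < 0.03))
})
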
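test_that("worked CIB component values are reproduced", {
  code <- CODE11
  # one-codon concentration in a 4-fold family: H = 0
  cc <- codon_counts(c(GGG = 4, TGG = 1), code)
  comp <- cib_components(cc, code)
  expect_equal(unname(comp["numerator"]), 0.8 * log(4), tolerance = 1e-12)
  expect_equal(unname(comp["denominator"]), 0.8 * log(4), tolerance = 1e-12)
  expect_equal(cib(cc, code)$cib, 1)

  # equal synonymous usage: numerator 0, CIB 0
  eq <- codon_counts(c(GGT = 1, GGC = 1, GGA = 1, GGG = 1, TGG = 1), code)
  expect_equal(unname(cib_components(eq, code)["numerator"]), 0,
               tolerance = 1e-12)
  expect_equal(cib(eq, code)$cib, 0)

  # hand-evaluated mixed case: p(Gly)=0.8, H = -(0.75 ln 0.75 + 0.25 ln 0.25)
  mix <- codon_counts(c(GGG = 3, GGA = 1, TGG = 1), code)
  h <- -(0.75 * log(0.75) + 0.25 * log(0.25))
  comp <- cib_components(mix, code)
  expect_equal(unname(comp["numerator"]), 0.8 * (log(4) - h),
               tolerance = 1e-12)
  expect_equal(unname(comp["denominator"]), 0.8 * log(4), tolerance = 1e-12)
  expect_equal(cib(mix, code)$cib, 0.8 * (log(4) - h) / (0.8 * log(4)),
               tolerance = 1e-12)

  # only single-codon amino acids: undefined, flagged, not an error
  undef <- cib(codon_counts(c(ATG = 1, TGG = 1), code), code)
  expect_true(is.na(undef$cib))
  expect_true("undefined_cib" %in% undef$flags)

  expect_error(cib_components(codon_counts(c(GGG = 0), code), code),
               "no sense codons")
})

test_that("cib matches the brute-force family enumeration on random counts", {
  code <- CODE11
  set.seed(2024)
  for (i in 1:300) {
    counts <- random_counts(code, n_aa = sample(2:5, 1))
    v <- cib(codon_counts(counts, code), code)$cib
    expect_equal(v, brute_force_cib(counts, code), tolerance = 1e-12)
  }
})

test_that("CIB is bounded, scale-invariant and log-base-invariant", {
  code <- CODE11
  set.seed(31)
  for (i in 1:100) {
    counts <- random_counts(code, n_aa = sample(3:8, 1))
    cc <- codon_counts(counts, code)
    v <- cib(cc, code)
    if (is.na(v$cib)) next
    expect_gte(v$cib, 0)
    expect_lte(v$cib, 1)
    expect_gte(v$numerator, -1e-12)
    expect_lte(v$numerator, v$denominator + 1e-12)
    # multiplying all counts by k changes nothing
    k <- sample(2:7, 1)
    expect_equal(cib(codon_counts(counts * k, code), code)$cib, v$cib,
                 tolerance = 1e-12)
    # ratio of log2-based components equals ratio of ln-based components
    log2_ratio <- (v$numerator / log(2)) / (v$denominator / log(2))
    expect_equal(log2_ratio, v$cib, tolerance = 1e-12)
  }
})

test_that("the zero/one characterizations hold exactly", {
  code <- CODE11
  set.seed(17)
  aas_multi <- names(code$degeneracy)[code$degeneracy > 1L]
  for (i in 1:30) {
    aas <- sample(aas_multi, 3L)
    # uniform within every family -> 0
    uniform <- unlist(lapply(aas, function(a) {
      fam <- code$sense_codons[code$aa_of == a]
      stats::setNames(rep(sample(1:4, 1), length(fam)), fam)
    }))
    expect_equal(cib(codon_counts(uniform, code), code)$cib, 0)
    # one codon per family -> 1
    single <- unlist(lapply(aas, function(a) {
      fam <- code$sense_codons[code$aa_of == a]
      stats::setNames(sample(1:9, 1), sample(fam, 1))
    }))
    expect_equal(cib(codon_counts(single, code), code)$cib, 1)
  }
})

test_that("cib_table keeps input order and flags undefined rows", {
  code <- CODE11
  recs <- c(g1 = "ATGGGTGGAGGGTAA", g2 = "ATGTGG", g3 = "GGTGGCGGAGGG")
  expect_message(tab <- cib_table(recs, code), "undefined")
  expect_equal(tab$gene_id, c("g1", "g2", "g3"))
  expect_true(is.na(tab$cib[2]))
  expect_match(tab$flags[2], "undefined_cib")
  expect_true(all(tab$cib[!is.na(tab$cib)] >= 0 &
                  tab$cib[!is.na(tab$cib)] <= 1))
  expect_equal(tab$length_nt, nchar(unname(recs)))

  empty <- cib_table(stats::setNames(character(0), character(0)), code)
  expect_equal(nrow(empty), 0L)
})

test_that("CIB tables round-trip through TSV with fixed formatting", {
  code <- CODE11
  tab <- cib_table(c(a = "ATGGGGGGGGGGTTATAA", b = "ATGTGG"), code)
  path <- tempfile(fileext = ".tsv")
  write_cib_table(tab, path, header_lines = "seed: 1")
  lines <- readLines(path)
  expect_match(lines[1], "^# seed: 1")
  back <- read_cib_table(path)
  expect_equal(back$gene_id, tab$gene_id)
  expect_equal(back$cib, round(tab$cib, 6), tolerance = 5e-7)
})

test_that("population_cib evaluates models and rejects bad distributions", {
  code <- CODE11
  fam_g <- sort(code$sense_codons[code$aa_of == "G"])
  # uniform conditional usage -> 0
  q_unif <- list(G = stats::setNames(rep(0.25, 4), fam_g))
  expect_equal(population_cib(c(G = 1), q_unif, code), 0)
  # degenerate usage -> 1
  q_one <- list(G = stats::setNames(c(1, 0, 0, 0), fam_g))
  expect_equal(population_cib(c(G = 0.7, W = 0.3),
                              c(q_one, list(W = c(TGG = 1))), code), 1)
  # hand-evaluated: (ln 4 - H) / ln 4 with q = (0.625, 0.125, 0.125, 0.125)
  q_mix <- list(G = stats::setNames(c(0.625, 0.125, 0.125, 0.125), fam_g),
                W = c(TGG = 1))
  h <- -(0.625 * log(0.625) + 3 * 0.125 * log(0.125))
  expect_equal(population_cib(c(G = 0.8, W = 0.2), q_mix, code),
               (log(4) - h) / log(4), tolerance = 1e-12)
  expect_equal(round(population_cib(c(G = 0.8, W = 0.2), q_mix, code), 4),
               0.2256)
  # only single-codon amino acids -> undefined
  expect_true(is.na(population_cib(c(M = 0.5, W = 0.5),
                                   list(M = c(ATG = 1), W = c(TGG = 1)),
                                   code)))
  expect_error(population_cib(c(G = 0.9), q_unif, code), "sum to 1")
  bad_q <- list(G = stats::setNames(c(0.5, 0.1, 0.1, 0.1), fam_g))
  expect_error(population_cib(c(G = 1), bad_q, code), "sum to 1")
})
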
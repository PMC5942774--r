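hit_row <- function(q, s, pident, evalue, cat, qlen = 100, slen = 100) {
  data.frame(qseqid = q, sseqid = s, pident = pident, length = 50,
             mismatch = 0, gapopen = 0, qstart = 1, qend = 50, sstart = 1,
             send = 50, evalue = evalue, bitscore = 200, qlen = qlen,
             slen = slen, category = cat, stringsAsFactors = FALSE)
}

test_that("COG hit filtering applies the published cutoffs", {
  hits <- rbind(
    hit_row("g1", "COG1", 39.0, 1e-10, "P"),   # identity below 40 -> out
    hit_row("g2", "COG2", 80.0, 1e-4, "P"),    # e-value above 1e-5 -> out
    hit_row("g3", "COG3", 80.0, 1e-6, "P"),    # kept
    hit_row("g3", "COG4", 55.0, 1e-9, "O,C"),  # kept, categories union
    hit_row("g4", "COG5", 40.0, 1e-5, "K")     # boundary values kept
  )
  res <- filter_cog_hits(hits)
  expect_equal(res$gene_id, c("g3", "g4"))
  expect_equal(res$categories[res$gene_id == "g3"], "C,O,P")
  expect_equal(res$categories[res$gene_id == "g4"], "K")
})

test_that("metagenome mode additionally requires 90% of the hit length", {
  hits <- rbind(
    hit_row("m1", "COG1", 80, 1e-9, "P", qlen = 89, slen = 100),
    hit_row("m2", "COG1", 80, 1e-9, "P", qlen = 90, slen = 100)
  )
  res <- filter_cog_hits(hits, min_length_fraction = 0.90)
  expect_equal(res$gene_id, "m2")
  no_len <- hits[, setdiff(names(hits), c("qlen", "slen"))]
  expect_error(filter_cog_hits(no_len, min_length_fraction = 0.9),
               "qlen/slen")
})

test_that("tabular hits files parse with 12 or 14 columns and fail loudly", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("g1\tCOG1\t75.0\t50\t2\t0\t1\t50\t1\t50\t1e-20\t180",
               "g2\tCOG2\t55.5\t40\t5\t1\t1\t40\t3\t42\t1e-8\t90"), path)
  hits <- read_blast_hits(path)
  expect_equal(ncol(hits), 12L)
  expect_equal(hits$pident, c(75.0, 55.5))

  writeLines("g1\tCOG1\tseventy\t50\t2\t0\t1\t50\t1\t50\t1e-20\t180", path)
  expect_error(read_blast_hits(path), "row 1")

  writeLines("g1\tCOG1\t75.0", path)
  expect_error(read_blast_hits(path), "12 or 14")
})

test_that("ortholog calls intersect as unordered pairs", {
  t1 <- data.frame(a = c("a1", "a2", "a4"), b = c("b1", "b2", "b4"))
  t2 <- data.frame(a = c("b1", "a3", "b4"), b = c("a1", "b3", "a4"))
  res <- intersect_ortholog_calls(t1, t2)
  expect_equal(nrow(res), 2L)  # (a1,b1) and (a4,b4), despite swapped order
  expect_true(all(c("a1", "a4") %in% res$gene_a))

  disjoint <- intersect_ortholog_calls(t1, data.frame(a = "x", b = "y"))
  expect_equal(nrow(disjoint), 0L)
  expect_equal(nrow(intersect_ortholog_calls(t1, t1)), nrow(t1))
})

test_that("conserved/unique partition covers every gene exactly once", {
  part <- partition_conserved_unique(
    genes_a = c("a1", "a2"), genes_b = "b1",
    pairs = data.frame(gene_a = "a1", gene_b = "b1")
  )
  expect_equal(part$conserved_a, "a1")
  expect_equal(part$unique_a, "a2")
  expect_length(part$unique_b, 0L)

  none <- partition_conserved_unique(c("a1", "a2"), c("b1"),
                                     data.frame(a = character(0),
                                                b = character(0)))
  expect_equal(none$unique_a, c("a1", "a2"))
  expect_equal(none$unique_b, "b1")

  # one-to-one pairings: |conserved| + |unique_a| = |genes_a|
  set.seed(6)
  genes_a <- paste0("a", 1:30)
  genes_b <- paste0("b", 1:25)
  k <- 12
  pairs <- data.frame(gene_a = sample(genes_a, k),
                      gene_b = sample(genes_b, k))
  p <- partition_conserved_unique(genes_a, genes_b, pairs)
  expect_equal(length(p$conserved_a) + length(p$unique_a), length(genes_a))
  expect_equal(length(p$conserved_b) + length(p$unique_b), length(genes_b))
  expect_length(intersect(p$conserved_a, p$unique_a), 0L)

  expect_error(partition_conserved_unique("a1", "b1",
                                          data.frame(a = "zz", b = "b1")),
               "outside")
})

test_that("category means pool genes with multi-category multiplicity", {
  cib_tab <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    cib = c(0.2, 0.4, 0.3, NA),
    numerator = 1, denominator = 2,
    length_nt = c(300L, 600L, 900L, 300L), n_codons = 100L, flags = "",
    stringsAsFactors = FALSE
  )
  assignments <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    categories = c("P", "P", "O,C", "P"),
    stringsAsFactors = FALSE
  )
  groups <- stats::setNames(rep("grp1", 4), cib_tab$gene_id)
  m <- category_means(cib_tab, assignments, groups)
  expect_equal(m["grp1", "P"], 0.3)          # mean of 0.2, 0.4; NA dropped
  expect_equal(m["grp1", "O"], 0.3)          # multi-category contributes to both
  expect_equal(m["grp1", "C"], 0.3)
  n <- attr(m, "n")
  # counts sum to the number of defined (gene, category) assignments
  expect_equal(sum(n), 2L + 2L)
  expect_equal(unname(n["grp1", c("C", "O", "P")]), c(1L, 1L, 2L))
})

test_that("length bins follow the (l-width, l] convention and partition genes", {
  cib_tab <- data.frame(
    gene_id = paste0("g", 1:5),
    cib = c(0.1, 0.3, 0.25, 0.5, NA),
    numerator = 1, denominator = 2,
    length_nt = c(100L, 450L, 700L, 500L, 123L),
    n_codons = 50L, flags = "", stringsAsFactors = FALSE
  )
  bins <- bin_by_length(cib_tab, width = 500L)
  expect_equal(bins$bin_upper, c(500L, 1000L))
  # L = 500 falls in the 500 bin; L = 501 would open the 1000 bin
  expect_equal(bins$n_genes, c(3L, 1L))
  expect_equal(bins$mean_cib, c(mean(c(0.1, 0.3, 0.5)), 0.25))
  expect_equal(sum(bins$n_genes), sum(!is.na(cib_tab$cib)))

  one <- bin_by_length(data.frame(gene_id = "g", cib = 0.25,
                                  numerator = 1, denominator = 2,
                                  length_nt = 700L, n_codons = 1L,
                                  flags = ""), width = 500L)
  expect_equal(one$bin_upper, 1000L)
  expect_equal(one$n_genes, 1L)
})
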
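# Shared fixtures and independent oracles for the suite.

CODE11 <- load_genetic_code(11)

# Independent brute-force CIB: enumerate synonymous families and sum the
# KL terms one by one, using only the raw count vector. Deliberately
# written against the definition, not the package internals.
brute_force_cib <- function(count_vec, code) {
  num <- 0
  den <- 0
  for (a in unique(code$aa_of)) {
    fam <- code$sense_codons[code$aa_of == a]
    fam_counts <- vapply(fam, function(cd) {
      if (cd %in% names(count_vec)) as.numeric(count_vec[[cd]]) else 0
    }, numeric(1))
    tot_a <- sum(fam_counts)
    if (tot_a == 0) next
    n_a <- length(fam)
    p_a <- tot_a / sum(as.numeric(count_vec))
    kl <- 0
    for (cnt in fam_counts) {
      if (cnt > 0) {
        q <- cnt / tot_a
        kl <- kl + q * log(q / (1 / n_a))
      }
    }
    num <- num + p_a * kl
    den <- den + p_a * log(n_a)
  }
  if (den == 0) return(NA_real_)
  num / den
}

# Random codon-count table over a limited set of amino acids.
random_counts <- function(code, n_aa = 5L, max_count = 20L) {
  aas <- sample(unique(code$aa_of), n_aa)
  codons <- code$sense_codons[code$aa_of %in% aas]
  counts <- stats::setNames(sample.int(max_count + 1L, length(codons),
                                       replace = TRUE) - 1L, codons)
  counts[sample.int(length(counts), 1L)] <- counts[[1L]] + 1L  # never all-zero
  counts
}

# Direct double-sum evaluation of the continuous two-sample AD statistic
# on the pooled order (the textbook formula, no shared code with the
# package implementation).
brute_force_ad_continuous <- function(x, y) {
  pooled <- sort(c(x, y))
  N <- length(pooled)
  total <- 0
  for (s in list(x, y)) {
    n_i <- length(s)
    inner <- 0
    for (j in seq_len(N - 1L)) {
      M_ij <- sum(s <= pooled[j])
      inner <- inner + (N * M_ij - j * n_i)^2 / (j * (N - j))
    }
    total <- total + inner / n_i
  }
  total / N
}

# Exhaustive dominance p by explicit split enumeration via combn, computed
# from scratch with a plain ECDF-difference evaluation.
brute_force_dominance_p <- function(x, y) {
  pooled <- c(x, y)
  N <- length(pooled)
  nx <- length(x)
  gap <- function(xs, ys) {
    ts <- sort(unique(pooled))
    max(0, max(vapply(ts, function(t) mean(xs <= t) - mean(ys <= t),
                      numeric(1))))
  }
  d_obs <- gap(x, y)
  splits <- utils::combn(N, nx)
  d_all <- apply(splits, 2L, function(idx) gap(pooled[idx], pooled[-idx]))
  list(d = d_obs, p = mean(d_all >= d_obs - 1e-12))
}

make_tmp_fasta <- function(records) {
  path <- tempfile(fileext = ".fasta")
  con <- file(path, "w")
  for (i in seq_along(records)) {
    writeLines(c(paste0(">", names(records)[i]), records[[i]]), con)
  }
  close(con)
  path
}
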
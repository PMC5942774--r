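#' @title The codon information bias (CIB) statistic
#'
#' @description CIB measures how far a gene's synonymous codon usage departs
#' from the reference scenario in which the codons of each synonymous family
#' are used equally often, weighting each amino acid by how often it occurs.
#' Writing \eqn{p(a)} for the amino-acid relative frequencies of the gene,
#' \eqn{n(a)} for the size of amino acid \eqn{a}'s synonymous family, and
#' \eqn{H_a = -\sum_{c \in a} q(c|a)\log q(c|a)} for the entropy of codon
#' usage within the family, the statistic is the rescaled Kullback--Leibler
#' divergence
#' \deqn{CIB = \frac{\sum_a p(a)\,[\log n(a) - H_a]}{\sum_a p(a) \log n(a)}.}
#' The numerator is the mean KL divergence of the within-family codon
#' distributions from uniform; the denominator is its maximum given the
#' amino-acid composition, so \eqn{CIB \in [0,1]}: 0 if and only if every
#' synonymous family is used uniformly, 1 if and only if each amino acid is
#' represented by exactly one codon (and some family with \eqn{n(a)>1} is
#' present). The logarithm base cancels in the ratio; natural log is used
#' internally.
#'
#' A gene consisting solely of amino acids with a single codon (Met/Trp in
#' the bacterial code) has denominator 0: its CIB is undefined and returned
#' as `NA` with the `"undefined_cib"` flag, never as an error.
#'
#' @param counts A `codon_counts` object.
#' @param code The `genetic_code` the counts were made under.
#'
#' @return `cib_components()`: named numeric vector with elements
#'   `numerator` and `denominator`. `cib()`: an object of class `cib_value`
#'   (list with `gene_id`, `cib`, `numerator`, `denominator`, `length_nt`,
#'   `n_codons`, `flags`).
#'
#' @examples
#' code <- load_genetic_code(11)
#' cc <- codon_counts(c(GGG = 3, GGA = 1, TGG = 1), code)
#' cib(cc, code)$cib  # ~0.594
#' @name cib
NULL

#' @rdname cib
#' @export
cib_components <- function(counts, code) {
  if (!inherits(counts, "codon_counts")) {
    stop("`counts` must be a codon_counts object", call. = FALSE)
  }
  if (counts$n_codons <= 0L) {
    stop("cannot compute CIB components: no sense codons counted",
         call. = FALSE)
  }
  n_tot <- counts$n_codons
  aa_present <- names(counts$aa_counts)[counts$aa_counts > 0L]
  num <- 0
  den <- 0
  for (a in aa_present) {
    n_a <- code$degeneracy[[a]]
    if (n_a == 1L) next  # single-codon families contribute 0 to both sums
    p_a <- counts$aa_counts[[a]] / n_tot
    fam <- counts$counts[code$aa_of == a]
    q <- fam[fam > 0L] / counts$aa_counts[[a]]
    h_a <- -sum(q * log(q))  # 0 log 0 = 0 via the fam > 0 restriction
    num <- num + p_a * (log(n_a) - h_a)
    den <- den + p_a * log(n_a)
  }
  c(numerator = num, denominator = den)
}

#' @rdname cib
#' @export
cib <- function(counts, code) {
  comp <- cib_components(counts, code)
  flags <- counts$warnings
  if (comp[["denominator"]] > 0) {
    value <- comp[["numerator"]] / comp[["denominator"]]
    # clamp away harmless floating-point excursions
    value <- min(max(value, 0), 1)
  } else {
    value <- NA_real_
    flags <- c(flags, "undefined_cib")
  }
  structure(
    list(
      gene_id = counts$gene_id,
      cib = value,
      numerator = comp[["numerator"]],
      denominator = comp[["denominator"]],
      length_nt = counts$length_nt,
      n_codons = counts$n_codons,
      flags = flags
    ),
    class = "cib_value"
  )
}

#' @export
print.cib_value <- function(x, ...) {
  cat("CIB", if (!is.na(x$gene_id)) paste0("[", x$gene_id, "]"), "=",
      if (is.na(x$cib)) "undefined" else format(x$cib, digits = 4),
      "(", x$n_codons, "codons )\n")
  invisible(x)
}

#' Compute CIB for every gene of a sequence collection
#'
#' Applies [cib()] to each coding sequence, in input order. Genes whose CIB
#' is undefined (only single-codon amino acids) are retained with `cib = NA`
#' and flagged, so downstream summaries can count what they drop.
#'
#' @param records Named character vector of DNA sequences (names are gene
#'   ids), as returned by [read_cds_fasta()].
#' @param code A `genetic_code`.
#' @param drop_terminal_stop Passed to [count_codons()].
#'
#' @return A `data.frame` with one row per gene: `gene_id`, `cib`,
#'   `numerator`, `denominator`, `length_nt`, `n_codons`, `flags`
#'   (comma-joined, `""` if clean).
#' @export
cib_table <- function(records, code, drop_terminal_stop = TRUE) {
  if (length(records) == 0L) {
    return(data.frame(
      gene_id = character(0), cib = numeric(0), numerator = numeric(0),
      denominator = numeric(0), length_nt = integer(0), n_codons = integer(0),
      flags = character(0), stringsAsFactors = FALSE
    ))
  }
  ids <- names(records)
  if (is.null(ids)) ids <- paste0("gene", seq_along(records))
  rows <- lapply(seq_along(records), function(i) {
    cc <- count_codons(records[[i]], code, gene_id = ids[[i]],
                       drop_terminal_stop = drop_terminal_stop)
    v <- cib(cc, code)
    data.frame(
      gene_id = v$gene_id, cib = v$cib, numerator = v$numerator,
      denominator = v$denominator, length_nt = v$length_nt,
      n_codons = v$n_codons, flags = paste(v$flags, collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  n_undef <- sum(is.na(out$cib))
  if (n_undef > 0L) {
    message(n_undef, " gene(s) with undefined CIB retained and flagged")
  }
  out
}

#' Population CIB of a codon-usage model
#'
#' Evaluates the same functional as [cib()] on population (not empirical)
#' distributions: an amino-acid distribution `p_aa` and, per amino acid, a
#' conditional codon distribution over its synonymous family. This is the
#' large-sample limit of the empirical CIB of genes drawn from the model and
#' serves as the analytic ground truth for the synthetic-sequence simulator.
#'
#' @param p_aa Named numeric vector over amino acids, summing to 1.
#' @param q_cond Named list: for each amino acid in `p_aa`, a named numeric
#'   vector over that family's codons, summing to 1.
#' @param code A `genetic_code`.
#' @param tol Normalization tolerance.
#'
#' @return A single number in `[0, 1]`, or `NA` if the denominator is 0.
#' @export
population_cib <- function(p_aa, q_cond, code, tol = 1e-9) {
  if (abs(sum(p_aa) - 1) > tol) {
    stop("`p_aa` must sum to 1 (got ", sum(p_aa), ")", call. = FALSE)
  }
  num <- 0
  den <- 0
  for (a in names(p_aa)) {
    if (p_aa[[a]] <= 0) next
    n_a <- code$degeneracy[[a]]
    if (is.null(n_a)) stop("unknown amino acid: ", a, call. = FALSE)
    if (n_a == 1L) next
    q <- q_cond[[a]]
    if (is.null(q) || abs(sum(q) - 1) > tol) {
      stop("conditional codon distribution for ", a, " must sum to 1",
           call. = FALSE)
    }
    fam <- code$sense_codons[code$aa_of == a]
    if (!all(names(q) %in% fam)) {
      stop("q_cond[", a, "] names codons outside the family", call. = FALSE)
    }
    qq <- q[q > 0]
    h_a <- -sum(qq * log(qq))
    num <- num + p_aa[[a]] * (log(n_a) - h_a)
    den <- den + p_aa[[a]] * log(n_a)
  }
  if (den <= 0) return(NA_real_)
  min(max(num / den, 0), 1)
}

#' Write a per-gene CIB table as TSV
#'
#' Fixed 6-decimal formatting and deterministic row order (input order), so
#' outputs are diffable across runs.
#'
#' @param tab Data frame from [cib_table()].
#' @param path Output file path.
#' @param header_lines Optional character vector of `#`-prefixed metadata
#'   lines written before the column header.
#' @return Invisibly, `path`.
#' @export
write_cib_table <- function(tab, path, header_lines = character(0)) {
  fmt <- tab
  for (col in c("cib", "numerator", "denominator")) {
    fmt[[col]] <- ifelse(is.na(tab[[col]]), "NA",
                         formatC(tab[[col]], format = "f", digits = 6))
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) {
    writeLines(paste0("# ", sub("^#\\s*", "", header_lines)), con)
  }
  utils::write.table(fmt, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a per-gene CIB table written by [write_cib_table()]
#' @param path TSV path.
#' @return Data frame in the [cib_table()] layout.
#' @export
read_cib_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE,
                    colClasses = c(gene_id = "character", flags = "character"),
                    na.strings = "NA")
}
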
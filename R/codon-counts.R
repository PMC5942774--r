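#' Count in-frame codons of a coding sequence
#'
#' Tallies every complete in-frame sense codon of a CDS, starting at the
#' first base. The input is taken at face value as a coding sequence: no ORF
#' detection is attempted and the strand is taken as given. Counting is
#' case-insensitive.
#'
#' Irregularities are tolerated and flagged rather than fatal, because draft
#' genomes routinely contain pseudogenes and partial models:
#' \itemize{
#'   \item a trailing partial codon (length not a multiple of 3) is dropped
#'     (`"partial_codon_dropped"`);
#'   \item codons containing non-ACGT characters are skipped, keeping the
#'     counts a true empirical frequency (`"ambiguous_codon_skipped"`);
#'   \item a terminal stop codon is excluded when `drop_terminal_stop` is
#'     `TRUE` (the default), since it codes for no amino acid;
#'   \item internal stop codons are not counted and are flagged
#'     (`"internal_stop"`).
#' }
#'
#' @param sequence A single DNA string (character scalar).
#' @param code A `genetic_code` from [load_genetic_code()].
#' @param gene_id Identifier stored in the result.
#' @param drop_terminal_stop Exclude a final stop codon from consideration.
#'
#' @return An object of class `codon_counts`: list with `gene_id`, `counts`
#'   (named integer vector over the sense codons), `aa_counts` (named integer
#'   vector over amino acids), `n_codons` (total sense codons counted),
#'   `length_nt` (raw input length in bases) and `warnings` (character vector
#'   of flags).
#'
#' @examples
#' code <- load_genetic_code(11)
#' cc <- count_codons("ATGGGTGGATAA", code)
#' cc$n_codons  # 3: ATG GGT GGA, terminal TAA dropped
#' @export
count_codons <- function(sequence, code, gene_id = NA_character_,
                         drop_terminal_stop = TRUE) {
  if (!inherits(code, "genetic_code")) {
    stop("`code` must be a genetic_code object", call. = FALSE)
  }
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence)) {
    stop("`sequence` must be a single non-empty DNA string", call. = FALSE)
  }
  seq_up <- toupper(as.character(sequence))
  len <- nchar(seq_up)
  warnings <- character(0)

  n_full <- len %/% 3L
  if (len %% 3L != 0L) {
    warnings <- c(warnings, "partial_codon_dropped")
  }
  counts <- stats::setNames(integer(length(code$sense_codons)),
                            code$sense_codons)
  if (n_full > 0L) {
    starts <- seq.int(1L, by = 3L, length.out = n_full)
    codons <- substring(seq_up, starts, starts + 2L)
    ok <- !grepl("[^ACGT]", codons)
    if (any(!ok)) warnings <- c(warnings, "ambiguous_codon_skipped")
    codons <- codons[ok]
    is_stop <- codons %in% code$stops
    if (any(is_stop)) {
      last_is_stop <- length(codons) > 0L && is_stop[length(codons)]
      if (drop_terminal_stop && last_is_stop) {
        internal <- is_stop[-length(codons)]
      } else {
        internal <- is_stop
      }
      if (any(internal)) warnings <- c(warnings, "internal_stop")
      codons <- codons[!is_stop]
    }
    if (length(codons)) {
      tab <- table(factor(codons, levels = code$sense_codons))
      counts <- stats::setNames(as.integer(tab), code$sense_codons)
    }
  }
  new_codon_counts(counts, code, gene_id = gene_id, length_nt = len,
                   warnings = unique(warnings))
}

# Construct a codon_counts object from a named count vector (internal, also
# used to build counts directly in tests and simulations).
new_codon_counts <- function(counts, code, gene_id = NA_character_,
                             length_nt = NA_integer_, warnings = character(0)) {
  full <- stats::setNames(integer(length(code$sense_codons)), code$sense_codons)
  if (length(counts)) {
    bad <- setdiff(names(counts), code$sense_codons)
    if (length(bad)) {
      stop("counts contain non-sense codons: ", paste(bad, collapse = ","),
           call. = FALSE)
    }
    full[names(counts)] <- as.integer(counts)
  }
  aa_counts <- tapply_sum(full, code$aa_of)
  structure(
    list(
      gene_id = gene_id,
      counts = full,
      aa_counts = aa_counts,
      n_codons = sum(full),
      length_nt = as.integer(length_nt),
      warnings = warnings
    ),
    class = "codon_counts"
  )
}

# rowsum-based grouped sum returning a plain named integer vector
tapply_sum <- function(v, groups) {
  s <- rowsum(as.integer(v), group = groups)
  stats::setNames(as.integer(s[, 1L]), rownames(s))
}

#' Build a codon_counts object from explicit codon counts
#'
#' Convenience constructor for analyses and simulations that already hold
#' codon tallies (e.g. the worked examples in the package tests). Unnamed
#' codons are taken as zero.
#'
#' @param counts Named integer vector, names are sense codons.
#' @inheritParams count_codons
#' @return A `codon_counts` object.
#' @export
codon_counts <- function(counts, code, gene_id = NA_character_) {
  new_codon_counts(counts, code, gene_id = gene_id,
                   length_nt = 3L * sum(as.integer(counts)))
}

#' @export
print.codon_counts <- function(x, ...) {
  cat("codon_counts", if (!is.na(x$gene_id)) x$gene_id else "",
      ": ", x$n_codons, " sense codons",
      if (length(x$warnings)) paste0(" [", paste(x$warnings, collapse = ","), "]"),
      "\n", sep = "")
  invisible(x)
}

#' Read coding sequences from a FASTA file
#'
#' Reads a (plain or gzip-compressed) FASTA file of coding DNA sequences and
#' returns them in file order. The gene identifier is the first
#' whitespace-delimited token of each header line. An empty file yields an
#' empty result with a warning.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of DNA sequences; names are gene ids.
#' @export
read_cds_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) {
      stop("malformed FASTA in ", path, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (length(set) == 0L) {
    warning("FASTA file ", path, " contains no records")
    return(stats::setNames(character(0), character(0)))
  }
  ids <- sub("\\s.*$", "", names(set))
  stats::setNames(as.character(set), ids)
}
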
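#' Load a genetic code table
#'
#' Builds the codon bookkeeping object every CIB computation needs: the
#' codon-to-amino-acid map, the synonymous-family sizes \eqn{n(a)} (the
#' degeneracy of each amino acid), and the stop-codon set. Tables follow the
#' NCBI translation-table numbering; the bacterial/archaeal table (11) is the
#' default throughout the package. Its sense-codon degeneracy is identical to
#' the standard table (1), so CIB values are the same under either (the tables
#' differ only in permitted start codons, which play no role here).
#'
#' @param table_id Integer NCBI translation-table identifier. Supported: 1
#'   (standard) and 11 (bacterial, archaeal and plant plastid).
#'
#' @return An object of class `genetic_code`: a list with elements
#'   `table_id`, `codon_to_aa` (named character vector over all 64 DNA
#'   triplets; stops are `"*"`), `sense_codons` (character vector, 61 for the
#'   supported tables), `stops` (character vector of stop triplets),
#'   `degeneracy` (named integer vector \eqn{n(a)} over amino acids), and
#'   `aa_of` (amino acid of each sense codon, in `sense_codons` order).
#'
#' @examples
#' code <- load_genetic_code(11)
#' code$degeneracy[["L"]]  # leucine has 6 synonymous codons
#' @export
load_genetic_code <- function(table_id = 11L) {
  if (length(table_id) != 1L || is.na(table_id) ||
      !(as.character(table_id) %in% c("1", "11"))) {
    stop("unsupported genetic code table: ", paste(table_id, collapse = ","),
         " (supported: 1, 11)", call. = FALSE)
  }
  table_id <- as.integer(table_id)
  tab <- Biostrings::getGeneticCode(as.character(table_id))
  codons <- names(tab)
  stopifnot(length(tab) == 64L)
  stops <- codons[tab == "*"]
  sense <- codons[tab != "*"]
  aa_of <- unname(tab[sense])
  degeneracy <- table(aa_of)
  degeneracy <- stats::setNames(as.integer(degeneracy), names(degeneracy))
  structure(
    list(
      table_id = table_id,
      codon_to_aa = tab,
      sense_codons = sense,
      stops = stops,
      degeneracy = degeneracy,
      aa_of = aa_of
    ),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code table", x$table_id, ":",
      length(x$sense_codons), "sense codons,",
      length(x$stops), "stops (", paste(x$stops, collapse = ", "), ")\n")
  invisible(x)
}
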
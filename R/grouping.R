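#' Read tabular protein-alignment hits
#'
#' Parses the standard 12-column tab-separated BLAST output (outfmt 6:
#' qseqid, sseqid, pident, length, mismatch, gapopen, qstart, qend, sstart,
#' send, evalue, bitscore) or the 14-column variant that appends the query
#' and subject lengths (qlen, slen). The length columns are required only
#' for the metagenome-mode length-fraction filter.
#'
#' @param path Path to the tab-separated hits file.
#' @return Data frame with the standard column names; `qlen`/`slen` present
#'   only for 14-column input.
#' @export
read_blast_hits <- function(path) {
  if (!file.exists(path)) stop("hits file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#",
                           colClasses = "character")
  nc <- ncol(raw)
  base_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")
  if (nc == 12L) {
    names(raw) <- base_cols
  } else if (nc == 14L) {
    names(raw) <- c(base_cols, "qlen", "slen")
  } else {
    stop("expected 12 or 14 tab-separated columns, found ", nc,
         " in ", path, call. = FALSE)
  }
  num_cols <- setdiff(names(raw), c("qseqid", "sseqid"))
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    if (anyNA(v)) {
      stop("malformed hits file ", path, ": non-numeric '", col,
           "' at row ", which(is.na(v))[1L], call. = FALSE)
    }
    raw[[col]] <- v
  }
  raw
}

#' Filter alignment hits and assign COG categories
#'
#' Applies the homology-search cutoffs used for functional assignment:
#' keep hits with e-value at or below `max_evalue` and percent identity at
#' or above `min_identity` (defaults 1e-5 and 40). In metagenome mode
#' (`min_length_fraction` set, conventionally 0.90) a hit is additionally
#' required to cover at least that fraction of the subject length
#' (`qlen >= min_length_fraction * slen`), which needs the 14-column input.
#' The COG category letters of all surviving hits of a gene are unioned.
#'
#' @param hits Data frame from [read_blast_hits()], or any data frame with
#'   columns `qseqid`, `pident`, `evalue` and a category source (below).
#' @param cog_categories Either the name of a column of `hits` holding the
#'   hit's category letters, or a named character vector mapping `sseqid`
#'   to letters (multi-letter entries like `"O,C"` allowed).
#' @param max_evalue,min_identity,min_length_fraction Filter cutoffs;
#'   `min_length_fraction = NULL` disables the length filter.
#'
#' @return Data frame with columns `gene_id` and `categories`
#'   (comma-separated sorted unique letters), one row per gene with at
#'   least one surviving, category-bearing hit.
#' @export
filter_cog_hits <- function(hits, cog_categories = "category",
                            max_evalue = 1e-5, min_identity = 40,
                            min_length_fraction = NULL) {
  keep <- hits$evalue <= max_evalue & hits$pident >= min_identity
  if (!is.null(min_length_fraction)) {
    if (!all(c("qlen", "slen") %in% names(hits))) {
      stop("length-fraction filtering needs qlen/slen columns ",
           "(14-column input)", call. = FALSE)
    }
    keep <- keep & hits$qlen >= min_length_fraction * hits$slen
  }
  surv <- hits[keep, , drop = FALSE]
  if (is.character(cog_categories) && length(cog_categories) == 1L &&
      cog_categories %in% names(surv)) {
    cats <- surv[[cog_categories]]
  } else {
    cats <- unname(cog_categories[surv$sseqid])
  }
  ok <- !is.na(cats) & nzchar(cats)
  surv <- surv[ok, , drop = FALSE]
  cats <- cats[ok]
  if (nrow(surv) == 0L) {
    return(data.frame(gene_id = character(0), categories = character(0),
                      stringsAsFactors = FALSE))
  }
  letters_per_hit <- strsplit(cats, ",", fixed = TRUE)
  gene_of_letter <- rep(surv$qseqid, lengths(letters_per_hit))
  letter <- trimws(unlist(letters_per_hit))
  merged <- vapply(split(letter, gene_of_letter), function(v) {
    paste(sort(unique(v)), collapse = ",")
  }, character(1))
  out <- data.frame(gene_id = names(merged), categories = unname(merged),
                    stringsAsFactors = FALSE)
  out[order(out$gene_id), , drop = FALSE]
}

#' Intersect ortholog-pair calls from two tools
#'
#' Keeps only the gene pairs predicted as orthologous by both tools. Pairs
#' are unordered: `(a, b)` and `(b, a)` are the same call; the result is
#' order-normalized (lexicographically smaller member first) and
#' deduplicated.
#'
#' @param pairs_tool1,pairs_tool2 Two-column data frames (or matrices) of
#'   gene-id pairs.
#' @return Two-column data frame `gene_a`, `gene_b` of the intersection.
#' @export
intersect_ortholog_calls <- function(pairs_tool1, pairs_tool2) {
  k1 <- normalize_pairs(pairs_tool1)
  k2 <- normalize_pairs(pairs_tool2)
  common <- intersect(k1$key, k2$key)
  out <- k1[match(common, k1$key), c("gene_a", "gene_b"), drop = FALSE]
  rownames(out) <- NULL
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

normalize_pairs <- function(pairs) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (ncol(pairs) < 2L) stop("pair list needs two columns", call. = FALSE)
  a <- as.character(pairs[[1L]])
  b <- as.character(pairs[[2L]])
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  out <- unique(data.frame(gene_a = lo, gene_b = hi,
                           stringsAsFactors = FALSE))
  out$key <- paste(out$gene_a, out$gene_b, sep = "\t")
  out
}

#' Partition two strains' genes into conserved and unique sets
#'
#' A gene appearing in any surviving ortholog pair is conserved in both
#' strains; the remainder of each strain's gene complement is unique to it.
#'
#' @param genes_a,genes_b Character vectors of gene ids for the two strains.
#' @param pairs Two-column data frame of ortholog pairs `(gene in a, gene
#'   in b)`, e.g. from [intersect_ortholog_calls()].
#' @return List with `conserved_pairs` (two-column data frame),
#'   `conserved_a`, `conserved_b`, `unique_a`, `unique_b` (character
#'   vectors).
#' @export
partition_conserved_unique <- function(genes_a, genes_b, pairs) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (nrow(pairs) > 0L) {
    pa <- as.character(pairs[[1L]])
    pb <- as.character(pairs[[2L]])
    # orient each pair towards (member of a, member of b)
    in_a1 <- pa %in% genes_a
    in_a2 <- pb %in% genes_a
    swap <- !in_a1 & in_a2
    tmp <- pa[swap]; pa[swap] <- pb[swap]; pb[swap] <- tmp
    bad <- !(pa %in% genes_a & pb %in% genes_b)
    if (any(bad)) {
      stop("pair members outside the two gene sets, e.g. (",
           pa[bad][1L], ", ", pb[bad][1L], ")", call. = FALSE)
    }
  } else {
    pa <- character(0)
    pb <- character(0)
  }
  conserved_a <- unique(pa)
  conserved_b <- unique(pb)
  list(
    conserved_pairs = data.frame(gene_a = pa, gene_b = pb,
                                 stringsAsFactors = FALSE),
    conserved_a = conserved_a,
    conserved_b = conserved_b,
    unique_a = sort(setdiff(genes_a, conserved_a)),
    unique_b = sort(setdiff(genes_b, conserved_b))
  )
}

#' Mean CIB per group and functional category
#'
#' Builds the group-by-category matrix of average CIB behind the package's
#' category-profile summaries. Genes carrying several category letters
#' contribute their CIB to every one of them; genes with undefined CIB are
#' dropped. Cells with no genes are `NA` (empty), never 0. By default genes
#' of a group are pooled before averaging; `per_species_mean = TRUE`
#' instead averages per-species means within the group (requires a
#' `species` map).
#'
#' @param cib_tab Data frame from [cib_table()] covering all genes.
#' @param assignments Data frame `gene_id`, `categories` from
#'   [filter_cog_hits()] (or equivalent).
#' @param groups Named character vector mapping gene_id to group label.
#' @param per_species_mean Average per-species means instead of pooling.
#' @param species Named character vector mapping gene_id to species; only
#'   needed when `per_species_mean = TRUE`.
#'
#' @return Numeric matrix (groups x categories) of mean CIB, with a
#'   parallel integer matrix of gene counts in `attr(, "n")`.
#' @export
category_means <- function(cib_tab, assignments, groups,
                           per_species_mean = FALSE, species = NULL) {
  idx <- match(assignments$gene_id, cib_tab$gene_id)
  known <- !is.na(idx)
  if (any(!known)) {
    message(sum(!known), " assigned gene(s) missing from the CIB table; skipped")
  }
  a <- assignments[known, , drop = FALSE]
  cib_v <- cib_tab$cib[idx[known]]
  grp <- unname(groups[a$gene_id])
  cats <- strsplit(a$categories, ",", fixed = TRUE)
  reps <- lengths(cats)
  long <- data.frame(
    gene_id = rep(a$gene_id, reps),
    group = rep(grp, reps),
    cib = rep(cib_v, reps),
    category = trimws(unlist(cats)),
    stringsAsFactors = FALSE
  )
  long <- long[!is.na(long$cib) & !is.na(long$group), , drop = FALSE]
  if (per_species_mean) {
    if (is.null(species)) {
      stop("per_species_mean needs a gene -> species map", call. = FALSE)
    }
    long$species <- unname(species[long$gene_id])
    sp_means <- stats::aggregate(cib ~ group + category + species,
                                 data = long, FUN = mean)
    agg <- stats::aggregate(cib ~ group + category, data = sp_means,
                            FUN = mean)
  } else {
    agg <- stats::aggregate(cib ~ group + category, data = long, FUN = mean)
  }
  cnt <- stats::aggregate(cib ~ group + category, data = long, FUN = length)
  g_lev <- sort(unique(long$group))
  c_lev <- sort(unique(long$category))
  m <- matrix(NA_real_, length(g_lev), length(c_lev),
              dimnames = list(g_lev, c_lev))
  n <- matrix(0L, length(g_lev), length(c_lev),
              dimnames = list(g_lev, c_lev))
  m[cbind(agg$group, agg$category)] <- agg$cib
  n[cbind(cnt$group, cnt$category)] <- cnt$cib
  attr(m, "n") <- n
  m
}

#' Mean CIB in gene-length bins
#'
#' Genes are binned by length in bases into half-open intervals
#' \eqn{(\ell - width, \ell]}: a gene of length L falls in the bin whose
#' upper edge is \eqn{\ell = width \cdot \lceil L / width \rceil}, so with
#' the default width 500 a bin holds genes from \eqn{\ell - 499} to
#' \eqn{\ell} bases. Only bins containing genes (with defined CIB) are
#' emitted.
#'
#' @param cib_tab Data frame from [cib_table()].
#' @param width Bin width in bases.
#' @param group Optional label recorded in the output.
#' @return Data frame `bin_upper`, `mean_cib`, `n_genes`, `group`, ordered
#'   by `bin_upper`.
#' @export
bin_by_length <- function(cib_tab, width = 500L, group = NA_character_) {
  ok <- !is.na(cib_tab$cib)
  L <- cib_tab$length_nt[ok]
  v <- cib_tab$cib[ok]
  if (length(L) == 0L) {
    return(data.frame(bin_upper = integer(0), mean_cib = numeric(0),
                      n_genes = integer(0), group = character(0),
                      stringsAsFactors = FALSE))
  }
  ell <- as.integer(width * ceiling(L / width))
  agg_m <- tapply(v, ell, mean)
  agg_n <- tapply(v, ell, length)
  ord <- order(as.integer(names(agg_m)))
  data.frame(
    bin_upper = as.integer(names(agg_m))[ord],
    mean_cib = unname(agg_m)[ord],
    n_genes = as.integer(unname(agg_n))[ord],
    group = group,
    stringsAsFactors = FALSE
  )
}

#' Read a two-column tab-separated mapping file
#'
#' Utility for gene-to-group, gene-to-species and ortholog-pair files.
#' Lines starting with `#` are ignored.
#'
#' @param path TSV path.
#' @param values_named If `TRUE` (default) return a named character vector
#'   (column 2 named by column 1); otherwise the two-column data frame.
#' @return Named character vector or data frame.
#' @export
read_mapping_tsv <- function(path, values_named = TRUE) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#",
                           colClasses = "character")
  if (ncol(tab) < 2L) {
    stop("expected two tab-separated columns in ", path, call. = FALSE)
  }
  if (values_named) stats::setNames(tab[[2L]], tab[[1L]]) else tab[, 1:2]
}
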
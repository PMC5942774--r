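#' Pipeline configuration
#'
#' Reads (or validates) the run configuration shared by the `run_*` stage
#' functions. A config is a plain named list; [read_run_config()] loads it
#' from YAML (or JSON via yaml's parser) and [validate_run_config()] fills
#' defaults and checks that every referenced input path exists before any
#' computation starts.
#'
#' Recognized keys: `fasta` (named list or vector of FASTA paths, names are
#' group labels), `assignments` (gene -> category TSVs per group),
#' `groups_tsv`, `ortholog_pairs` (two paths), `code` (genetic-code id,
#' default 11), `alpha` (default 0.01), `n_permutations` (default 10000),
#' `seed` (default 1), `bin_width` (default 500), `out_dir` (default
#' `"."`).
#'
#' @param path YAML file path.
#' @param config Named list.
#' @return A validated config list (class `cib_run_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  validate_run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @export
validate_run_config <- function(config) {
  defaults <- list(code = 11L, alpha = 0.01, n_permutations = 10000L,
                   seed = 1L, bin_width = 500L, out_dir = ".")
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  }
  for (k in c("fasta", "assignments", "ortholog_pairs", "groups_tsv",
              "matrix")) {
    paths <- unlist(config[[k]])
    missing <- paths[!vapply(paths, file.exists, logical(1))]
    if (length(missing)) {
      stop("config references missing path(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  class(config) <- "cib_run_config"
  config
}

stage_header <- function(config, extra = character(0)) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  hash <- substr(digest_config(cfg), 1L, 12L)
  c(
    paste0("cibr ", as.character(utils::packageVersion("cibr"))),
    paste0("seed: ", config$seed),
    paste0("config_hash: ", hash),
    extra
  )
}

# Tiny stable config fingerprint (modular rolling hash over the deparsed
# config); enough to tie an output file to the run that produced it.
digest_config <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 5381
  for (b in bytes) {
    h <- (h * 33 + b) %% 2147483647
  }
  format(as.hexmode(as.integer(h)), width = 8)
}

#' Stage 1: per-gene CIB tables
#'
#' Computes a CIB table for every input FASTA and writes one TSV per input
#' to `out_dir`, with a `#` header carrying the package version, seed and
#' config hash so reruns are attributable and byte-identical.
#'
#' @param config A validated config (see [read_run_config()]); must carry
#'   `fasta`.
#' @return Invisibly, a named list of the per-group CIB data frames.
#' @export
run_compute <- function(config) {
  config <- validate_run_config(config)
  if (is.null(config$fasta)) stop("config$fasta is required", call. = FALSE)
  code <- load_genetic_code(config$code)
  fastas <- unlist(config$fasta)
  if (is.null(names(fastas)) || any(!nzchar(names(fastas)))) {
    names(fastas) <- tools::file_path_sans_ext(basename(fastas))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  for (g in names(fastas)) {
    tab <- cib_table(read_cds_fasta(fastas[[g]]), code)
    n_flagged <- sum(nzchar(tab$flags))
    message(g, ": ", nrow(tab), " genes, ", sum(is.na(tab$cib)),
            " undefined CIB, ", n_flagged, " flagged")
    path <- file.path(config$out_dir, paste0("cib_", g, ".tsv"))
    write_cib_table(tab, path,
                    header_lines = stage_header(config,
                                                paste0("genetic_code: ",
                                                       config$code)))
    out[[g]] <- tab
  }
  invisible(out)
}

#' Stage 2: two-stage group comparisons per category
#'
#' Runs [compare_groups()] for a pair of groups, category by category, and
#' writes a comparison TSV (`group_x`, `group_y`, `category`, sample sizes,
#' AD statistic and p, per-direction dominance p-values, verdict).
#'
#' @param cib_x,cib_y Per-gene CIB tables (data frames) for the two groups.
#' @param assignments_x,assignments_y Optional category assignments
#'   (`gene_id`, `categories`); when absent, one overall comparison is run.
#' @param config A validated config (alpha, n_permutations, seed, out_dir).
#' @param group_x,group_y Labels.
#' @return Invisibly, the comparison data frame.
#' @export
run_compare <- function(cib_x, cib_y, config,
                        assignments_x = NULL, assignments_y = NULL,
                        group_x = "x", group_y = "y") {
  config <- validate_run_config(config)
  res <- compare_groups(
    cib_by_category(cib_x, assignments_x),
    cib_by_category(cib_y, assignments_y),
    alpha = config$alpha, n_permutations = config$n_permutations,
    seed = config$seed, group_x = group_x, group_y = group_y
  )
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(config$out_dir,
                    paste0("compare_", group_x, "_vs_", group_y, ".tsv"))
  write_tsv_with_header(res, path, stage_header(config))
  invisible(res)
}

#' Stage 3: summaries and clustering
#'
#' `run_fig1()` builds the group-by-category mean-CIB matrix;
#' `run_bins()` the per-group length-binned mean CIB; `run_cluster()`
#' clusters a strain-by-category matrix and writes the Newick tree plus
#' merge table. Empty (all-`NA`) category columns are excluded from
#' clustering input and output consistently.
#'
#' @param cib_tabs Named list of per-group CIB tables.
#' @param assignments Named list (same names) of category assignments.
#' @param config Validated config.
#' @param profiles Strain-by-category numeric matrix for clustering.
#' @return The matrix / bin table / `cib_dendrogram`, invisibly.
#' @name pipeline_summaries
NULL

#' @rdname pipeline_summaries
#' @export
run_fig1 <- function(cib_tabs, assignments, config) {
  config <- validate_run_config(config)
  all_cib <- do.call(rbind, unname(cib_tabs))
  all_assign <- do.call(rbind, unname(assignments))
  groups <- unlist(lapply(names(cib_tabs), function(g) {
    stats::setNames(rep(g, nrow(cib_tabs[[g]])), cib_tabs[[g]]$gene_id)
  }))
  m <- category_means(all_cib, all_assign, groups)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(config$out_dir, "category_means.tsv")
  write_matrix_tsv(m, path, stage_header(config))
  invisible(m)
}

#' @rdname pipeline_summaries
#' @export
run_bins <- function(cib_tabs, config) {
  config <- validate_run_config(config)
  tabs <- lapply(names(cib_tabs), function(g) {
    bin_by_length(cib_tabs[[g]], width = config$bin_width, group = g)
  })
  out <- do.call(rbind, tabs)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_with_header(out, file.path(config$out_dir, "length_bins.tsv"),
                        stage_header(config))
  invisible(out)
}

#' @rdname pipeline_summaries
#' @export
run_cluster <- function(profiles, config) {
  config <- validate_run_config(config)
  keep <- colSums(!is.na(profiles)) > 0L
  profiles <- profiles[, keep, drop = FALSE]
  dend <- average_linkage_cluster(profiles)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_newick(dend, file.path(config$out_dir, "strain_clustering.nwk"))
  write_tsv_with_header(dend$merges,
                        file.path(config$out_dir, "strain_merges.tsv"),
                        stage_header(config))
  write_matrix_tsv(profiles,
                   file.path(config$out_dir, "clustered_matrix.tsv"),
                   stage_header(config))
  invisible(dend)
}

#' Stage 0: simulate a synthetic study
#'
#' Generates one FASTA plus truth/assignment TSVs per configured group, so
#' the whole pipeline can be exercised with known ground truth. Config keys
#' under `simulate`: list of groups, each with `name`, `beta`, `n_genes`,
#' `length_codons`, optional `categories`.
#'
#' @param config Validated config with a `simulate` block.
#' @return Invisibly, named list of `synthetic_genes` objects.
#' @export
run_simulate <- function(config) {
  config <- validate_run_config(config)
  if (is.null(config$simulate)) {
    stop("config$simulate block is required", call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  for (i in seq_along(config$simulate)) {
    spec <- config$simulate[[i]]
    model <- build_model(
      beta = spec$beta, code = load_genetic_code(config$code),
      length_dist = list(kind = "fixed",
                         codons = spec$length_codons %||% 300L)
    )
    cats <- spec$categories %||% "ALL"
    sim <- simulate_genes(model, spec$n_genes, group = spec$name,
                          categories = unlist(cats),
                          seed = derive_seed(config$seed, i),
                          fasta_out = file.path(config$out_dir,
                                                paste0(spec$name, ".fasta")))
    utils::write.table(
      sim$truth, file.path(config$out_dir, paste0(spec$name, "_truth.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    utils::write.table(
      sim$truth[, c("gene_id", "categories")],
      file.path(config$out_dir, paste0(spec$name, "_categories.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
    )
    out[[spec$name]] <- sim
  }
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv_with_header <- function(df, path, header_lines = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_matrix_tsv <- function(m, path, header_lines = character(0)) {
  df <- data.frame(strain = rownames(m), as.data.frame(m, optional = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_with_header(df, path, header_lines)
}
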
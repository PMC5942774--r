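#' Reported CIB values for copper-resistance and ROS genes
#'
#' Curated published per-gene CIB values for copper-resistance and
#' oxidative-stress (ROS) genes of five consortium biomining strains and
#' homologs from their non-consortium counterpart strains, shipped as a
#' plain-text table under `inst/extdata`. Used in the worked examples: the
#' block means of the consortium column sit visibly below those of the
#' counterpart column in both functional blocks.
#'
#' @return Data frame with columns `block` (`"copper"` or `"ros"`),
#'   `id_consortium`, `cib_consortium`, `id_counterpart`,
#'   `cib_counterpart`, `gene_name`, `annotation`, `cog`.
#' @examples
#' tab <- reported_biomining_cib()
#' block_mean_cib(tab)
#' @export
reported_biomining_cib <- function() {
  path <- system.file("extdata", "biomining_reported_cib.tsv",
                      package = "cibr", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, quote = "")
}

#' Block means of a reported CIB table
#'
#' Averages the consortium and counterpart CIB columns within each
#' functional block, rounded to 3 decimals (the precision of the reported
#' per-gene values).
#'
#' @param tab Data frame as returned by [reported_biomining_cib()].
#' @param digits Rounding applied to the means.
#' @return Data frame `block`, `n`, `mean_consortium`, `mean_counterpart`.
#' @export
block_mean_cib <- function(tab, digits = 3L) {
  blocks <- sort(unique(tab$block))
  out <- lapply(blocks, function(b) {
    sub <- tab[tab$block == b, , drop = FALSE]
    data.frame(
      block = b, n = nrow(sub),
      mean_consortium = round(mean(sub$cib_consortium), digits),
      mean_counterpart = round(mean(sub$cib_counterpart), digits),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Gene-recovery percentage
#'
#' The fraction of a reference gene catalogue whose coding sequences could
#' actually be recovered for codon counting, as a percentage rounded to one
#' decimal. (For the 2014 COG catalogue, 1,737,559 of 1,785,722 listed
#' genes were recoverable: 97.3%.)
#'
#' @param n_recovered,n_total Gene counts.
#' @param digits Decimal places.
#' @return Percentage in `[0, 100]`.
#' @export
gene_recovery_percent <- function(n_recovered, n_total, digits = 1L) {
  if (n_total <= 0 || n_recovered < 0 || n_recovered > n_total) {
    stop("need 0 <= n_recovered <= n_total with n_total > 0", call. = FALSE)
  }
  round(100 * n_recovered / n_total, digits)
}
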
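# Trio parentage verification from a panel of common SNP genotypes.
#
# A SNP is informative for parentage when both parents are homozygous:
# the child's genotype is then fully determined by Mendelian inheritance
# (AA/AA -> AA, BB/BB -> BB, AA/BB -> AB), and any departure is a
# discordance.  SNPs with a heterozygous parent carry no parentage
# information under this rule.

GT_LEVELS <- c("AA", "AB", "BB", "missing")

#' Classify one trio genotype record
#'
#' @param father_gt,mother_gt,child_gt Genotypes, each one of `"AA"`,
#'   `"AB"`, `"BB"` or `"missing"`.
#' @return One of `"informative_concordant"`, `"informative_discordant"`,
#'   `"uninformative"`, `"incomplete"`.
#' @export
classify_informative <- function(father_gt, mother_gt, child_gt) {
  gts <- c(father_gt, mother_gt, child_gt)
  if (!all(gts %in% GT_LEVELS))
    stop("genotypes must be one of ", paste(GT_LEVELS, collapse = ", "))
  if (any(gts == "missing")) return("incomplete")
  if (father_gt == "AB" || mother_gt == "AB") return("uninformative")
  # both parents homozygous: unique Mendelian expectation
  expected <- if (father_gt == mother_gt) father_gt else "AB"
  if (child_gt == expected) "informative_concordant" else "informative_discordant"
}

#' Verify a biological trio from a genotype panel
#'
#' Records with any missing genotype are excluded; X-linked records in
#' male probands are hemizygous and fall outside the biallelic rule, so
#' they are excluded as well (and counted in the summary).  The panel
#' passes when the number of informative discordant SNPs does not exceed
#' `max_discordant`.
#'
#' @param records Data.frame with columns `snp_id`, `chrom_class`
#'   (`"autosomal"` or `"x_linked"`), `father_gt`, `mother_gt`,
#'   `child_gt`.
#' @param max_discordant Maximum tolerated discordant informative SNPs
#'   (default 0; genotyping error tolerance is a policy choice).
#' @param male_proband If `TRUE`, X-linked records are excluded from the
#'   informative set.
#' @return An object of class `trio_verdict`: `verdict` (`"pass"` or
#'   `"fail"`) and `summary`, a named count per class (plus
#'   `excluded_x_linked`).
#' @export
verify_trio <- function(records, max_discordant = 0, male_proband = FALSE) {
  need <- c("snp_id", "chrom_class", "father_gt", "mother_gt", "child_gt")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("genotype table missing column(s): ",
                         paste(miss, collapse = ", "))
  excluded <- male_proband & records$chrom_class == "x_linked"
  use <- records[!excluded, , drop = FALSE]
  cls <- mapply(classify_informative, use$father_gt, use$mother_gt,
                use$child_gt, USE.NAMES = FALSE)
  counts <- table(factor(cls, levels = c("informative_concordant",
                                         "informative_discordant",
                                         "uninformative", "incomplete")))
  n_inf <- counts[["informative_concordant"]] +
    counts[["informative_discordant"]]
  if (n_inf == 0L)
    stop("panel uninformative: no SNP with both parents homozygous and ",
         "complete genotypes")
  verdict <- if (counts[["informative_discordant"]] <= max_discordant)
    "pass" else "fail"
  summary <- c(as.vector(counts), sum(excluded))
  names(summary) <- c(names(counts), "excluded_x_linked")
  structure(list(verdict = verdict, summary = summary,
                 max_discordant = max_discordant),
            class = "trio_verdict")
}

#' @export
print.trio_verdict <- function(x, ...) {
  cat(sprintf("<trio_verdict> %s (discordant %d / informative %d, tolerance %d)\n",
              toupper(x$verdict), x$summary[["informative_discordant"]],
              x$summary[["informative_concordant"]] +
                x$summary[["informative_discordant"]],
              x$max_discordant))
  invisible(x)
}

#' Read / write a trio genotype table
#'
#' Tab-separated with columns `snp_id`, `chrom_class`, `father_gt`,
#' `mother_gt`, `child_gt`.
#'
#' @param path File path.
#' @return `read_genotype_table()` returns the data.frame.
#' @export
read_genotype_table <- function(path) {
  if (!file.exists(path)) stop("genotype table not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_genotype_table
#' @param records Genotype table data.frame.
#' @export
write_genotype_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
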
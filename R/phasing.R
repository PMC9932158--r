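# Parent-of-origin determination for a DNM.
#
# Primary route: phase-set logic on trio phased VCF calls -- SNPs sharing
# the DNM's phase set identify the haplotype carrying the mutation, and
# the parental genotypes at those SNPs identify which parent transmitted
# that haplotype.  Fallback route: read-backed pileup -- a 2x2 table of
# DNM x SNP allele co-occurrence per read, tested with Fisher's exact
# test.  Prior-knowledge shortcuts (X-linked loci in male probands,
# imprinted loci) take precedence over both.
#
# All genomic coordinates are 1-based inclusive (VCF convention).

phasing_result <- function(origin, method, supporting_snp = NA,
                           p_value = NULL, table = NULL, note = NULL) {
  structure(list(origin = origin, method = method,
                 supporting_snp = supporting_snp, p_value = p_value,
                 table = table, note = note),
            class = "phasing_result")
}

#' @export
print.phasing_result <- function(x, ...) {
  cat(sprintf("<phasing_result> %s (method: %s%s%s)\n", x$origin, x$method,
              if (!is.na(x$supporting_snp[1L]))
                paste0(", SNP ", paste(x$supporting_snp, collapse = "+")) else "",
              if (!is.null(x$p_value))
                sprintf(", Fisher p = %.3g", x$p_value) else ""))
  if (!is.null(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

# Split a diploid GT string; returns list(alleles=int vector, phased=flag)
parse_gt <- function(gt) {
  phased <- grepl("|", gt, fixed = TRUE)
  al <- suppressWarnings(as.integer(strsplit(gt, "[|/]")[[1L]]))
  list(alleles = al, phased = phased)
}

#' Resolve parent-of-origin from trio phase sets
#'
#' Takes the phase-set SNPs of the DNM call (same `PS`, depth strictly
#' greater than `min_depth`), determines for each which allele is in
#' phase with the DNM alternate allele, and asks which parent could have
#' transmitted it.  A SNP is informative in the classic configuration:
#' the child is heterozygous and exactly one parent is homozygous for the
#' complement of the in-phase allele while the other parent carries it.
#' The call is made only when all informative phase-set SNPs agree.
#'
#' @param child_calls,father_calls,mother_calls Phased-call data.frames
#'   with columns `pos`, `ref`, `alt`, `gt`, `ps`, `dp` (see
#'   [read_phased_vcf()]).
#' @param dnm_pos 1-based position of the DNM.
#' @param min_depth Phase-set SNPs at depth `<= min_depth` are discarded
#'   (default 10, i.e. the filter keeps depth > 10).
#' @return A `phasing_result` with method `"phase_set"`; origin
#'   `"unresolved"` when the DNM is unphased, no phase-set SNP is
#'   informative, parental calls are missing or identical, or informative
#'   SNPs disagree (flagged in `note`).
#' @export
resolve_from_phase_sets <- function(child_calls, father_calls, mother_calls,
                                    dnm_pos, min_depth = 10) {
  dnm <- child_calls[child_calls$pos == dnm_pos, , drop = FALSE]
  if (nrow(dnm) == 0L)
    return(phasing_result("unresolved", "phase_set",
                          note = "DNM not called in child"))
  if (any(father_calls$pos == dnm_pos) || any(mother_calls$pos == dnm_pos))
    stop("not de novo: the DNM position is called in a parent")
  g <- parse_gt(dnm$gt[1L])
  if (!g$phased || is.na(dnm$ps[1L]) || length(unique(g$alleles)) != 2L)
    return(phasing_result("unresolved", "phase_set",
                          note = "DNM call is unphased"))
  dnm_hap <- which(g$alleles == 1L)   # haplotype index carrying the ALT

  snps <- child_calls[child_calls$pos != dnm_pos &
                        !is.na(child_calls$ps) &
                        child_calls$ps == dnm$ps[1L] &
                        child_calls$dp > min_depth, , drop = FALSE]
  if (nrow(snps) == 0L)
    return(phasing_result("unresolved", "phase_set",
                          note = "no phase-set SNP above the depth filter"))

  origins <- character(0); used <- numeric(0)
  for (i in seq_len(nrow(snps))) {
    s <- snps[i, ]
    sg <- parse_gt(s$gt)
    if (!sg$phased || length(unique(sg$alleles)) != 2L) next
    in_phase <- sg$alleles[dnm_hap]
    comp <- 1L - in_phase
    fa <- parent_alleles(father_calls, s$pos)
    mo <- parent_alleles(mother_calls, s$pos)
    if (is.null(fa) || is.null(mo)) next          # SNP not called in a parent
    if (identical(sort(fa), sort(mo))) next       # identical parental calls
    fa_hom_comp <- all(fa == comp); mo_hom_comp <- all(mo == comp)
    if (fa_hom_comp && in_phase %in% mo) {
      origins <- c(origins, "maternal"); used <- c(used, s$pos)
    } else if (mo_hom_comp && in_phase %in% fa) {
      origins <- c(origins, "paternal"); used <- c(used, s$pos)
    }
  }
  if (length(origins) == 0L)
    return(phasing_result("unresolved", "phase_set",
                          note = "phase set has no informative SNP"))
  if (length(unique(origins)) > 1L)
    return(phasing_result("unresolved", "phase_set", supporting_snp = used,
                          note = "conflict: informative SNPs disagree"))
  phasing_result(origins[1L], "phase_set", supporting_snp = used)
}

# Alleles called for a parent at a position; NULL when the position is
# absent from the parent's call set.  A position with no variant record is
# taken as homozygous reference only if explicitly present as 0/0.
parent_alleles <- function(calls, pos) {
  row <- calls[calls$pos == pos, , drop = FALSE]
  if (nrow(row) == 0L) return(NULL)
  parse_gt(row$gt[1L])$alleles
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact p-value obtained by summing, over all tables with the observed
#' margins, the hypergeometric probabilities not exceeding that of the
#' observed table (with the conventional relative tolerance of 1e-7 for
#' ties).  A table in which only one margin is populated carries no
#' association information and returns p = 1 (documented convention); an
#' all-zero table is an error.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return The two-sided p-value.
#' @export
fisher_exact <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stop("'table' must be 2x2")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("'table' must hold non-negative integer counts")
  if (sum(tab) == 0) stop("all-zero table: association undefined")
  m <- sum(tab[1L, ]); n <- sum(tab[2L, ]); kcol <- sum(tab[, 1L])
  if (m == 0 || n == 0 || kcol == 0 || kcol == sum(tab)) return(1)
  x <- tab[1L, 1L]
  support <- max(0L, kcol - n):min(kcol, m)
  d <- dhyper(support, m, n, kcol)
  sum(d[d <= d[support == x] * (1 + 1e-7)])
}

#' Build a transmissible-allele map for a phasing SNP
#'
#' For each SNP allele (REF/ALT), which parent could have transmitted it
#' to the child.  `"both"` marks alleles carried by both parents (or by
#' neither -- equally uninformative).
#'
#' @param father_gt,mother_gt Parent genotypes at the SNP as GT strings
#'   (e.g. `"0/0"`, `"1/1"`, `"0/1"`).
#' @return Named list `REF`, `ALT` with values `"father"`, `"mother"` or
#'   `"both"`.
#' @export
snp_parent_map <- function(father_gt, mother_gt) {
  fa <- parse_gt(father_gt)$alleles; mo <- parse_gt(mother_gt)$alleles
  who <- function(allele) {
    f <- allele %in% fa; m <- allele %in% mo
    if (f && !m) "father" else if (m && !f) "mother" else "both"
  }
  list(REF = who(0L), ALT = who(1L))
}

#' Resolve parent-of-origin from read-backed pileup observations
#'
#' Builds the 2x2 table (rows: DNM REF/ALT; columns: SNP REF/ALT) from
#' per-read allele observations, tests the association with
#' [fisher_exact()], and -- when significant -- assigns the origin to the
#' parent whose transmissible SNP allele is found in excess on the
#' DNM-ALT reads.
#'
#' @param observations Data.frame `read_id`, `dnm_allele`, `snp_allele`
#'   (values `"REF"`/`"ALT"`).
#' @param parent_map Output of [snp_parent_map()]; must assign at least
#'   one allele uniquely to a parent.
#' @param alpha Significance level for the Fisher test (default 0.01).
#' @return A `phasing_result` with method `"pileup"`, the 2x2 `table`
#'   and Fisher `p_value` attached; `"unresolved"` when the association
#'   is not significant (table kept for manual review).
#' @export
resolve_from_pileup <- function(observations, parent_map, alpha = 0.01) {
  if (nrow(observations) == 0L) stop("no read observations supplied")
  if (parent_map$REF == "both" && parent_map$ALT == "both")
    stop("uninformative SNP: neither allele is parent-specific")
  lev <- c("REF", "ALT")
  tab <- table(factor(observations$dnm_allele, lev),
               factor(observations$snp_allele, lev))
  tab <- unclass(tab)
  dimnames(tab) <- list(dnm = lev, snp = lev)
  p <- fisher_exact(tab)
  if (p >= alpha)
    return(phasing_result("unresolved", "pileup", p_value = p, table = tab,
                          note = "no significant allele co-occurrence"))
  # allele enriched on DNM-ALT reads: compare within-row proportions
  alt_row <- tab["ALT", ]; ref_row <- tab["REF", ]
  in_phase <- if (alt_row[["ALT"]] * ref_row[["REF"]] >
                  alt_row[["REF"]] * ref_row[["ALT"]]) "ALT" else "REF"
  parent <- parent_map[[in_phase]]
  if (parent == "both")
    return(phasing_result("unresolved", "pileup", p_value = p, table = tab,
                          note = "in-phase allele carried by both parents"))
  phasing_result(if (parent == "father") "paternal" else "maternal",
                 "pileup", p_value = p, table = tab)
}

#' Transitive two-SNP pileup phasing
#'
#' When the nearest SNP is itself uninformative with respect to the
#' parents, a second SNP can be phased to the first within the same read
#' set: SNP1 is phased to the DNM, SNP2 to SNP1, and parental
#' informativeness is evaluated at SNP2.
#'
#' @param obs_dnm_snp1 Observations pairing the DNM with SNP1
#'   (`dnm_allele`, `snp_allele`).
#' @param obs_snp1_snp2 Observations pairing SNP1 with SNP2 (columns
#'   `dnm_allele` = SNP1 allele, `snp_allele` = SNP2 allele).
#' @param parent_map2 [snp_parent_map()] for SNP2.
#' @param alpha Significance level applied to each link.
#' @return A `phasing_result` with method `"pileup"` and the two link
#'   p-values in `p_value` (max governs significance).
#' @export
resolve_transitive <- function(obs_dnm_snp1, obs_snp1_snp2, parent_map2,
                               alpha = 0.01) {
  link1 <- resolve_from_pileup(obs_dnm_snp1,
                               list(REF = "mother", ALT = "father"),
                               alpha = alpha)
  if (is.null(link1$table)) return(link1)
  p1 <- link1$p_value
  if (p1 >= alpha)
    return(phasing_result("unresolved", "pileup", p_value = p1,
                          table = link1$table,
                          note = "DNM-SNP1 link not significant"))
  t1 <- link1$table
  snp1_in_phase <- if (t1["ALT", "ALT"] * t1["REF", "REF"] >
                       t1["ALT", "REF"] * t1["REF", "ALT"]) "ALT" else "REF"
  lev <- c("REF", "ALT")
  t2 <- unclass(table(factor(obs_snp1_snp2$dnm_allele, lev),
                      factor(obs_snp1_snp2$snp_allele, lev)))
  dimnames(t2) <- list(snp1 = lev, snp2 = lev)
  p2 <- fisher_exact(t2)
  if (p2 >= alpha)
    return(phasing_result("unresolved", "pileup", p_value = c(p1, p2),
                          table = t2,
                          note = "SNP1-SNP2 link not significant"))
  row2 <- t2[snp1_in_phase, ]; other2 <- t2[setdiff(lev, snp1_in_phase), ]
  snp2_in_phase <- if (row2[["ALT"]] * other2[["REF"]] >
                       row2[["REF"]] * other2[["ALT"]]) "ALT" else "REF"
  parent <- parent_map2[[snp2_in_phase]]
  if (parent == "both")
    return(phasing_result("unresolved", "pileup", p_value = c(p1, p2),
                          table = t2, note = "SNP2 uninformative"))
  phasing_result(if (parent == "father") "paternal" else "maternal",
                 "pileup", p_value = c(p1, p2), table = t2)
}

#' Prior-knowledge origin shortcuts
#'
#' An X-linked locus in a male proband must have come from the maternal X;
#' a locus under imprinting constraints has a configured obligate origin.
#' Either shortcut takes precedence over sequencing-based phasing.
#'
#' @param x_linked_male_proband Locus on chromosome X and proband male?
#' @param imprinted_expected_origin `"paternal"`, `"maternal"`, or `NULL`.
#' @return A `phasing_result` with method `"known_xlinked"` or
#'   `"known_imprinted"`, or `NULL` when no shortcut applies.
#' @export
annotate_known_origin <- function(x_linked_male_proband = FALSE,
                                  imprinted_expected_origin = NULL) {
  if (x_linked_male_proband && !is.null(imprinted_expected_origin) &&
      imprinted_expected_origin != "maternal")
    stop("conflicting locus metadata: X-linked male proband implies a ",
         "maternal origin but the imprinting configuration says ",
         imprinted_expected_origin)
  if (x_linked_male_proband)
    return(phasing_result("maternal", "known_xlinked"))
  if (!is.null(imprinted_expected_origin)) {
    imprinted_expected_origin <- match.arg(imprinted_expected_origin,
                                           c("paternal", "maternal"))
    return(phasing_result(imprinted_expected_origin, "known_imprinted"))
  }
  NULL
}

# ---- minimal VCF I/O (GT:PS:DP) ------------------------------------------

#' Write / read minimal phased VCFs
#'
#' One sample per file, FORMAT `GT:PS:DP`.  `write_phased_vcf()` writes a
#' bgzip-compressed VCF via vcfR; `read_phased_vcf()` reads plain or
#' compressed VCF and returns the phased-call data.frame used by
#' [resolve_from_phase_sets()].
#'
#' @param calls Data.frame with `pos`, `ref`, `alt`, `gt`, `ps`, `dp`.
#' @param path Output path (a `.gz` suffix is added by vcfR if missing).
#' @param sample Sample name recorded in the header.
#' @param chrom Chromosome label used for every record.
#' @return `write_phased_vcf()` the path written; `read_phased_vcf()` the
#'   call data.frame (`chrom`, `pos`, `ref`, `alt`, `gt`, `ps`, `dp`).
#' @export
write_phased_vcf <- function(calls, path, sample = "sample1",
                             chrom = "chr1") {
  n <- nrow(calls)
  fix <- cbind(CHROM = rep(chrom, n), POS = as.character(calls$pos),
               ID = rep(".", n), REF = calls$ref, ALT = calls$alt,
               QUAL = rep(".", n), FILTER = rep("PASS", n),
               INFO = rep(".", n))
  gt_field <- paste(calls$gt,
                    ifelse(is.na(calls$ps), ".", as.character(calls$ps)),
                    as.character(calls$dp), sep = ":")
  gt <- cbind(FORMAT = rep("GT:PS:DP", n), gt_field)
  colnames(gt)[2L] <- sample
  meta <- c("##fileformat=VCFv4.2",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">",
            "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">")
  v <- new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' @rdname write_phased_vcf
#' @export
read_phased_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ps <- suppressWarnings(as.integer(vcfR::extract.gt(v, element = "PS")))
  dp <- suppressWarnings(as.integer(vcfR::extract.gt(v, element = "DP")))
  data.frame(chrom = vcfR::getCHROM(v), pos = vcfR::getPOS(v),
             ref = vcfR::getREF(v), alt = vcfR::getALT(v),
             gt = as.vector(gt[, 1L]), ps = ps, dp = dp,
             stringsAsFactors = FALSE)
}

#' Read / write a read-observation table
#'
#' Tab-separated with columns `read_id`, `dnm_allele`, `snp_allele`.
#'
#' @param path File path.
#' @return `read_observation_table()` returns the data.frame.
#' @export
read_observation_table <- function(path) {
  if (!file.exists(path)) stop("read-observation table not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_observation_table
#' @param observations Observation table data.frame.
#' @export
write_observation_table <- function(observations, path) {
  utils::write.table(observations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
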
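# Synthetic family generator.
#
# Emulates the study design end to end: triplicate deep amplicon
# sequencing of up to 14 tissues across a parent-child trio plus three
# unrelated controls, a common-SNP trio genotype panel, and long-read
# phasing observations spanning the DNM and a nearby SNP.  Each of the
# seven mutational-origin scenarios fixes which individuals and tissues
# carry the variant and at what cell fraction.

TISSUE_CODES <- c(buccal_left = 1, buccal_right = 2, blood = 3, saliva = 4,
                  urine = 5, sperm = 6, diagnostic_gdna = 7)
PARENT_TISSUES <- list(father = 1:6, mother = 1:5)
CHILD_TISSUES <- c(1, 2, 7)

#' Default true cell fractions for a mutational-origin scenario
#'
#' Categories: A paternal one-off, B paternal confined gonadal mosaic,
#' C paternal mixed mosaic, D maternal one-off, E maternal gonadal
#' mosaic, F maternal mixed mosaic, G post-zygotic in the proband.
#' Fractions follow the published magnitudes for each timing class:
#' mixed mosaics ~2-8% with the germline above the soma in the father,
#' confined gonadal ~3% (sperm only), post-zygotic probands with strong
#' inter-tissue variation.  One-off events (A, D) and the inaccessible
#' maternal germline (E) leave every sampled parental tissue at 0.
#'
#' @param category One of `"A"`..`"G"`.
#' @return Data.frame `individual`, `tissue_code`, `vaf`.
#' @export
default_scenario_vafs <- function(category) {
  category <- match.arg(category, LETTERS[1:7])
  base <- rbind(
    data.frame(individual = "father", tissue_code = PARENT_TISSUES$father,
               vaf = 0),
    data.frame(individual = "mother", tissue_code = PARENT_TISSUES$mother,
               vaf = 0),
    data.frame(individual = "child", tissue_code = CHILD_TISSUES,
               vaf = 0.5)
  )
  set_vaf <- function(df, ind, tissues, v) {
    i <- df$individual == ind & df$tissue_code %in% tissues
    df$vaf[i] <- v
    df
  }
  switch(category,
    A = base,
    B = set_vaf(base, "father", 6, 0.03),
    C = set_vaf(set_vaf(base, "father", 1:5, 0.02), "father", 6, 0.08),
    D = base,
    E = base,   # maternal germline is not among the sampled tissues
    F = set_vaf(base, "mother", 1:5, 0.04),
    G = {
      b <- set_vaf(base, "child", c(1, 2), 0)
      b <- set_vaf(b, "child", 1, 0.08)
      b <- set_vaf(b, "child", 2, 0.10)
      set_vaf(b, "child", 7, 0.42)
    })
}

# Parental origin implied by each scenario (used to configure phasing).
scenario_origin <- function(category) {
  switch(category, A = , B = , C = "paternal",
         D = , E = , F = "maternal", G = "post_zygotic")
}

#' Scenario specification for the synthetic generator
#'
#' @param category Mutational-origin category `"A"`..`"G"`.
#' @param true_vaf_by_tissue Data.frame `individual`, `tissue_code`,
#'   `vaf`; defaults to [default_scenario_vafs()].
#' @param seq_error_rate Per-site false-positive rate (default `2e-4`,
#'   middle of the observed 1e-4..1e-3 background range).
#' @param depth_mean Expected reads per replicate (default 6000; the
#'   study targeted >= 5000x per reaction).
#' @param n_replicates Technical replicates per sample (default 3).
#' @param n_controls Unrelated control samples (default 3).
#' @param dropout_prob Probability that a whole sample fails (default 0).
#' @param seed RNG seed for this family.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(category, true_vaf_by_tissue = NULL,
                          seq_error_rate = 2e-4, depth_mean = 6000,
                          n_replicates = 3, n_controls = 3,
                          dropout_prob = 0, seed = NULL) {
  category <- match.arg(category, LETTERS[1:7])
  if (is.null(true_vaf_by_tissue))
    true_vaf_by_tissue <- default_scenario_vafs(category)
  if (any(true_vaf_by_tissue$vaf < 0 | true_vaf_by_tissue$vaf > 1))
    stop("true_vaf_by_tissue: 'vaf' must lie in [0, 1]")
  check_rate(seq_error_rate, "seq_error_rate")
  check_rate(dropout_prob, "dropout_prob")
  if (depth_mean <= 0) stop("'depth_mean' must be > 0")
  if (n_replicates < 1) stop("'n_replicates' must be >= 1")
  if (n_controls < 1) stop("'n_controls' must be >= 1")
  spec <- structure(list(category = category,
                         true_vaf_by_tissue = true_vaf_by_tissue,
                         seq_error_rate = seq_error_rate,
                         depth_mean = depth_mean,
                         n_replicates = n_replicates,
                         n_controls = n_controls,
                         dropout_prob = dropout_prob, seed = seed),
                    class = "scenario_spec")
  validate_scenario(spec)
  spec
}

# Category invariants on the true fractions.
validate_scenario <- function(spec) {
  v <- spec$true_vaf_by_tissue
  get <- function(ind, tissues) v$vaf[v$individual == ind &
                                        v$tissue_code %in% tissues]
  fa_soma <- get("father", 1:5); fa_sperm <- get("father", 6)
  mo_soma <- get("mother", 1:5); ch <- get("child", CHILD_TISSUES)
  ok <- switch(spec$category,
    A = , D = all(c(fa_soma, fa_sperm, mo_soma) == 0) && all(ch == 0.5),
    B = length(fa_sperm) && all(fa_sperm > 0) && all(fa_soma == 0),
    E = all(c(fa_soma, fa_sperm, mo_soma) == 0),
    C = any(fa_soma > 0) && all(fa_sperm > 0),
    F = any(mo_soma > 0),
    G = all(c(fa_soma, fa_sperm, mo_soma) == 0) &&
      any(ch > 0 & ch < 0.5))
  if (!ok) stop("true_vaf_by_tissue violates the category ", spec$category,
                " invariants")
  invisible(spec)
}

#' Simulate the deep-sequencing count table for one family
#'
#' Per replicate the total count is Poisson around `depth_mean`; the alt
#' count is binomial at rate `p + (1-p) q` for case samples and `q` for
#' the unrelated controls.  Output is deterministic given `spec$seed`.
#'
#' @param spec A [scenario_spec()].
#' @param family Family identifier used in the table.
#' @return Count table data.frame (`family`, `individual`, `tissue_code`,
#'   `replicate`, `alt_count`, `total_count`, `is_control`).
#' @export
simulate_counts <- function(spec, family = "SIM1") {
  stopifnot(inherits(spec, "scenario_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  q <- spec$seq_error_rate
  rows <- list()
  for (i in seq_len(nrow(spec$true_vaf_by_tissue))) {
    r <- spec$true_vaf_by_tissue[i, ]
    failed <- runif(1) < spec$dropout_prob
    n <- if (failed) rep(0L, spec$n_replicates) else
      rpois(spec$n_replicates, spec$depth_mean)
    rate <- r$vaf + (1 - r$vaf) * q
    k <- rbinom(spec$n_replicates, n, rate)
    rows[[length(rows) + 1L]] <- data.frame(
      family = family, individual = r$individual,
      tissue_code = r$tissue_code, replicate = seq_len(spec$n_replicates),
      alt_count = k, total_count = n, is_control = FALSE,
      stringsAsFactors = FALSE)
  }
  for (ctl in seq_len(spec$n_controls)) {
    n <- rpois(spec$n_replicates, spec$depth_mean)
    k <- rbinom(spec$n_replicates, n, q)
    rows[[length(rows) + 1L]] <- data.frame(
      family = family, individual = paste0("control", ctl),
      tissue_code = NA_integer_, replicate = seq_len(spec$n_replicates),
      alt_count = k, total_count = n, is_control = TRUE,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Simulate a trio SNP genotype panel
#'
#' Parental genotypes are drawn at Hardy-Weinberg proportions for the
#' given minor-allele frequency; the child genotype is Mendelian (one
#' allele sampled from each parent) under true parentage, otherwise an
#' independent Hardy-Weinberg draw (an unrelated individual).
#'
#' @param n_snps Number of autosomal SNPs (>= 1).
#' @param maf Minor-allele frequency in (0, 0.5].
#' @param true_parentage Simulate a biological trio?
#' @param seed RNG seed.
#' @return Genotype table (`snp_id`, `chrom_class`, `father_gt`,
#'   `mother_gt`, `child_gt`).
#' @export
simulate_trio_genotypes <- function(n_snps = 154, maf = 0.3,
                                    true_parentage = TRUE, seed = NULL) {
  if (n_snps < 1) stop("'n_snps' must be >= 1")
  if (maf <= 0 || maf > 0.5) stop("'maf' must lie in (0, 0.5]")
  if (!is.null(seed)) set.seed(seed)
  draw_alleles <- function(n) matrix(runif(2 * n) < maf, ncol = 2)
  gt_of <- function(al) c("AA", "AB", "BB")[rowSums(al) + 1L]
  fa <- draw_alleles(n_snps); mo <- draw_alleles(n_snps)
  if (true_parentage) {
    pick <- function(al) al[cbind(seq_len(nrow(al)),
                                  sample(c(1L, 2L), nrow(al), replace = TRUE))]
    ch_al <- cbind(pick(fa), pick(mo))
  } else {
    ch_al <- draw_alleles(n_snps)
  }
  data.frame(snp_id = paste0("snp", seq_len(n_snps)),
             chrom_class = "autosomal",
             father_gt = gt_of(fa), mother_gt = gt_of(mo),
             child_gt = gt_of(ch_al), stringsAsFactors = FALSE)
}

#' Simulate long-read phasing data for one DNM
#'
#' Generates (i) a read-observation table with one row per child read
#' spanning both the DNM and a nearby phasing SNP, and (ii) minimal
#' phased-call records for the three trio members.  Half the child reads
#' carry the DNM alternate allele.  In the informative configuration the
#' designated transmitting parent is homozygous ALT at the SNP and the
#' other parent homozygous REF, so DNM-carrying reads show the
#' transmitting parent's SNP allele (flipped with probability
#' `switch_error`).  In the uninformative configuration both parents are
#' identically heterozygous and the origin cannot be resolved.
#'
#' @param origin `"paternal"` or `"maternal"`.
#' @param snp_config `"informative"` or `"uninformative"`.
#' @param depth Number of child reads spanning both sites (>= 1).
#' @param switch_error Per-read probability of a phase switch between the
#'   two sites, in \[0, 0.5).
#' @param seed RNG seed.
#' @param dnm_pos,snp_pos 1-based positions used in the call records.
#' @return List with `observations` (`read_id`, `dnm_allele`,
#'   `snp_allele`), `calls` (list of phased-call data.frames for `child`,
#'   `father`, `mother`), `dnm_pos`, `snp_pos`.
#' @export
simulate_phasing_reads <- function(origin = c("paternal", "maternal"),
                                   snp_config = c("informative",
                                                  "uninformative"),
                                   depth = 200, switch_error = 0.01,
                                   seed = NULL, dnm_pos = 1000L,
                                   snp_pos = 1500L) {
  origin <- match.arg(origin)
  snp_config <- match.arg(snp_config)
  if (depth < 1) stop("'depth' must be >= 1")
  if (switch_error < 0 || switch_error >= 0.5)
    stop("'switch_error' must lie in [0, 0.5)")
  if (!is.null(seed)) set.seed(seed)

  # child haplotypes: hap1 = maternal, hap2 = paternal.  The transmitting
  # parent is ALT/ALT at the SNP when informative, so the haplotype
  # inherited from that parent carries SNP-ALT.
  dnm_hap <- if (origin == "paternal") 2L else 1L
  snp_alt_hap <- if (snp_config == "informative") dnm_hap else 2L

  hap <- sample(c(1L, 2L), depth, replace = TRUE)   # which haplotype each read is
  dnm_allele <- ifelse(hap == dnm_hap, "ALT", "REF")
  snp_on_hap <- ifelse(hap == snp_alt_hap, "ALT", "REF")
  flip <- runif(depth) < switch_error
  snp_allele <- ifelse(flip, ifelse(snp_on_hap == "ALT", "REF", "ALT"),
                       snp_on_hap)
  obs <- data.frame(read_id = sprintf("read%04d", seq_len(depth)),
                    dnm_allele = dnm_allele, snp_allele = snp_allele,
                    stringsAsFactors = FALSE)

  # phased calls: GT uses hap1|hap2 order
  gt_from_haps <- function(h1, h2) paste0(h1, "|", h2)
  child_dnm_gt <- gt_from_haps(as.integer(dnm_hap == 1L),
                               as.integer(dnm_hap == 2L))
  child_snp_gt <- if (snp_config == "informative")
    gt_from_haps(as.integer(snp_alt_hap == 1L), as.integer(snp_alt_hap == 2L))
  else gt_from_haps(as.integer(snp_alt_hap == 1L), as.integer(snp_alt_hap == 2L))
  ps <- dnm_pos
  child <- data.frame(pos = c(dnm_pos, snp_pos), ref = c("A", "C"),
                      alt = c("T", "G"), gt = c(child_dnm_gt, child_snp_gt),
                      ps = c(ps, ps), dp = c(depth, depth),
                      stringsAsFactors = FALSE)
  parent_snp_gt <- function(is_transmitting) {
    if (snp_config == "uninformative") "0/1"
    else if (is_transmitting) "1/1" else "0/0"
  }
  father <- data.frame(pos = snp_pos, ref = "C", alt = "G",
                       gt = parent_snp_gt(origin == "paternal"),
                       ps = NA_integer_, dp = depth,
                       stringsAsFactors = FALSE)
  mother <- data.frame(pos = snp_pos, ref = "C", alt = "G",
                       gt = parent_snp_gt(origin == "maternal"),
                       ps = NA_integer_, dp = depth,
                       stringsAsFactors = FALSE)
  list(observations = obs,
       calls = list(child = child, father = father, mother = mother),
       dnm_pos = dnm_pos, snp_pos = snp_pos)
}

#' Simulate a complete synthetic family
#'
#' Bundles counts, trio genotypes and phasing data for one family under a
#' scenario, using one RNG stream per family seeded from
#' `(master seed, family index)` so families are independently
#' reproducible.
#'
#' @param category Scenario category `"A"`..`"G"`.
#' @param seed Master seed.
#' @param family_index Index of the family under the master seed.
#' @param family Family identifier.
#' @param spec Optional pre-built [scenario_spec()]; its `seed` is
#'   overridden by the derived per-family seed.
#' @param phasing_depth,switch_error Parameters of the phasing simulation.
#' @param snp_config Phasing SNP configuration; post-zygotic scenarios
#'   still get (paternal) phasing data, though the pipeline will not need
#'   it.
#' @return List: `category`, `spec`, `counts`, `genotypes`, `phasing`.
#' @export
simulate_family <- function(category, seed = 1L, family_index = 1L,
                            family = paste0("SIM", family_index),
                            spec = NULL, phasing_depth = 200,
                            switch_error = 0.01,
                            snp_config = "informative") {
  fam_seed <- derive_seed(seed, family_index)
  if (is.null(spec)) {
    spec <- scenario_spec(category, seed = fam_seed)
  } else {
    spec$seed <- fam_seed
  }
  counts <- simulate_counts(spec, family = family)
  genotypes <- simulate_trio_genotypes(seed = derive_seed(fam_seed, 1L))
  origin <- scenario_origin(category)
  phasing <- simulate_phasing_reads(
    origin = if (origin == "maternal") "maternal" else "paternal",
    snp_config = snp_config, depth = phasing_depth,
    switch_error = switch_error, seed = derive_seed(fam_seed, 2L))
  list(category = category, spec = spec, counts = counts,
       genotypes = genotypes, phasing = phasing, family = family)
}

# Deterministic 31-bit seed stream: distinct (seed, index) pairs map to
# distinct child seeds with overwhelming probability.
derive_seed <- function(seed, index) {
  x <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(index) * 16807
  as.integer(x %% 2147483647)
}
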
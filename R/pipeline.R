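# Orchestration of the three-tier workflow over one family:
# parentage QC -> multi-tissue corrected-VAF estimation -> (phasing, only
# when mosaicism has not already resolved the family) -> category
# assignment and recurrence risk.

#' Pipeline configuration
#'
#' All tunable thresholds in one place; every value is recorded in the
#' per-family log so a report is self-describing.
#'
#' @param ci_level Confidence level for VAF estimation.
#' @param mosaic_floor Decision floor on `p_hat` for calling parental
#'   mosaicism (default 0.003).
#' @param constitutional_band Cell-fraction band compatible with
#'   constitutional heterozygosity.
#' @param phasing_alpha Significance level of the pileup Fisher test.
#' @param phasing_min_depth Depth filter for phase-set SNPs (strictly
#'   greater than).
#' @param priors Category priors.
#' @param vaf_model Germline VAF model for composite-category risks.
#' @param conservative Report sperm risks at the CI upper bound.
#' @param force_phase Run phasing even when mosaicism already resolves
#'   the family (concordance checking).
#' @param reporting_floor Cohort reporting floor on quantified risks.
#' @param max_discordant Tolerated discordant SNPs in trio verification.
#' @return A list with class `dnmrisk_config`.
#' @export
pipeline_config <- function(ci_level = 0.95, mosaic_floor = 0.003,
                            constitutional_band = c(0.45, 0.55),
                            phasing_alpha = 0.01, phasing_min_depth = 10,
                            priors = default_priors(),
                            vaf_model = germline_vaf_model(),
                            conservative = TRUE, force_phase = FALSE,
                            reporting_floor = 0.001, max_discordant = 0) {
  structure(list(ci_level = ci_level, mosaic_floor = mosaic_floor,
                 constitutional_band = constitutional_band,
                 phasing_alpha = phasing_alpha,
                 phasing_min_depth = phasing_min_depth, priors = priors,
                 vaf_model = vaf_model, conservative = conservative,
                 force_phase = force_phase,
                 reporting_floor = reporting_floor,
                 max_discordant = max_discordant),
            class = "dnmrisk_config")
}

#' Load a pipeline configuration from YAML
#'
#' Recognized keys mirror the arguments of [pipeline_config()];
#' `vaf_model` may be given as a list with `vafs` (percent or fraction is
#' auto-detected: values > 1 are treated as percent), `mixed_mean`,
#' `n_boot`.
#'
#' @param path YAML file.
#' @return A `dnmrisk_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  args <- list()
  for (key in c("ci_level", "mosaic_floor", "phasing_alpha",
                "phasing_min_depth", "conservative", "force_phase",
                "reporting_floor", "max_discordant"))
    if (!is.null(y[[key]])) args[[key]] <- y[[key]]
  if (!is.null(y$constitutional_band))
    args$constitutional_band <- as.numeric(y$constitutional_band)
  if (!is.null(y$priors)) args$priors <- unlist(y$priors)
  if (!is.null(y$vaf_model)) {
    v <- as.numeric(y$vaf_model$vafs)
    if (any(v > 1)) v <- v / 100
    args$vaf_model <- germline_vaf_model(
      vafs = v,
      mixed_mean = y$vaf_model$mixed_mean %||% 0.08,
      n_boot = y$vaf_model$n_boot %||% 20000L)
  }
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Family manifest
#'
#' Describes one family's inputs.  File paths may be `NULL` when the
#' corresponding in-memory object is supplied to [run_pipeline()] via
#' `data`; the genotype table and phasing inputs are optional (phasing
#' falls back to prior-knowledge shortcuts or stays unresolved).
#'
#' @param family_id Family identifier.
#' @param dnm List describing the DNM: `chrom`, `pos`, `ref`, `alt`,
#'   optional `gene`.
#' @param counts Path to the count table TSV.
#' @param genotypes Path to the trio genotype TSV (optional).
#' @param vcf_child,vcf_father,vcf_mother Paths to minimal phased VCFs
#'   (optional).
#' @param read_obs Path to the read-observation TSV (optional).
#' @param x_linked_male_proband,imprinted_expected_origin Locus metadata
#'   for prior-knowledge phasing shortcuts.
#' @param override Optional externally asserted results (e.g. from an
#'   allele-specific PCR assay): a list with any of `origin`
#'   (`"paternal"`/`"maternal"`), `mosaicism_absent` (logical).
#' @return A list with class `family_manifest`.
#' @export
family_manifest <- function(family_id, dnm, counts = NULL,
                            genotypes = NULL, vcf_child = NULL,
                            vcf_father = NULL, vcf_mother = NULL,
                            read_obs = NULL,
                            x_linked_male_proband = FALSE,
                            imprinted_expected_origin = NULL,
                            override = NULL) {
  if (!is.null(dnm) && identical(dnm$ref, dnm$alt))
    stop("DNM descriptor invalid: REF and ALT alleles are identical")
  for (p in c(counts, genotypes, vcf_child, vcf_father, vcf_mother,
              read_obs))
    if (!is.null(p) && !file.exists(p)) stop("manifest file not found: ", p)
  structure(list(family_id = family_id, dnm = dnm, counts = counts,
                 genotypes = genotypes, vcf_child = vcf_child,
                 vcf_father = vcf_father, vcf_mother = vcf_mother,
                 read_obs = read_obs,
                 x_linked_male_proband = x_linked_male_proband,
                 imprinted_expected_origin = imprinted_expected_origin,
                 override = override),
            class = "family_manifest")
}

#' Run the full workflow for one family
#'
#' Stages: (1) trio verification from the SNP panel (a failure aborts the
#' family with a parentage error); (2) corrected-VAF estimation for every
#' sample against the pooled unrelated controls, and mosaicism calls per
#' individual; (3) parent-of-origin phasing -- skipped, and logged as
#' such, when the mosaicism stage already resolves the family, unless
#' `force_phase`; (4) category assignment and recurrence risk.
#'
#' @param manifest A [family_manifest()].
#' @param config A [pipeline_config()].
#' @param data Optional list of in-memory inputs overriding the manifest
#'   paths: `counts`, `genotypes`, `calls` (list `child`/`father`/
#'   `mother`), `observations`, `dnm_pos`.
#' @param out_dir If non-`NULL`, per-family TSV reports and a YAML
#'   summary are written there.
#' @return A list with class `family_result`: `family_id`, `trio`,
#'   `vaf_table`, `calls`, `phasing`, `assignment`, `category`, `risk`,
#'   `log` (every parameter and stage decision), `status`.
#' @export
run_pipeline <- function(manifest, config = pipeline_config(),
                         data = NULL, out_dir = NULL) {
  log <- list(family_id = manifest$family_id,
              parameters = config_log(config))

  # ---- stage 0: inputs ----
  counts <- data$counts %||%
    (if (!is.null(manifest$counts)) read_count_table(manifest$counts) else
       stop("no count table supplied for family ", manifest$family_id))
  genotypes <- data$genotypes %||%
    (if (!is.null(manifest$genotypes)) read_genotype_table(manifest$genotypes)
     else NULL)

  # ---- stage 1: trio verification ----
  trio <- NULL
  if (!is.null(genotypes)) {
    trio <- verify_trio(genotypes, max_discordant = config$max_discordant)
    log$trio <- as.list(trio$summary)
    if (trio$verdict == "fail")
      stop("parentage error in family ", manifest$family_id,
           ": the SNP panel is discordant with a biological trio (",
           trio$summary[["informative_discordant"]], " discordant SNPs)")
  } else {
    log$trio <- "skipped: no genotype table"
  }

  # ---- stage 2: mosaicism ----
  vaf_table <- estimate_family_vafs(counts, level = config$ci_level)
  ests <- attr(vaf_table, "estimates")
  calls <- list()
  for (ind in c("father", "mother", "child")) {
    keys <- grep(paste0("^", ind, "\\."), names(ests), value = TRUE)
    if (length(keys) == 0L) next
    e <- ests[keys]
    names(e) <- sub(paste0("^", ind, "\\."), "", keys)
    calls[[ind]] <- call_mosaicism(
      e, expected_constitutional = (ind == "child"),
      floor = config$mosaic_floor,
      constitutional_band = config$constitutional_band)
  }
  if (!is.null(manifest$override$mosaicism_absent) &&
      isTRUE(manifest$override$mosaicism_absent)) {
    for (ind in c("father", "mother"))
      if (!is.null(calls[[ind]])) {
        calls[[ind]]$call <- "none"
        calls[[ind]]$mosaic_tissues <- character(0)
      }
    log$override_mosaicism <- "parental mosaicism externally excluded"
  }
  log$mosaic_calls <- lapply(calls, `[[`, "call")

  resolved_by_mosaicism <-
    (!is.null(calls$child) && calls$child$call == "post_zygotic_mosaic") ||
    any(vapply(calls[c("father", "mother")],
               function(x) !is.null(x) && x$call == "mosaic", logical(1)))

  # ---- stage 3: phasing ----
  phasing <- NULL
  known <- annotate_known_origin(manifest$x_linked_male_proband,
                                 manifest$imprinted_expected_origin)
  if (!is.null(manifest$override$origin)) {
    phasing <- phasing_result(manifest$override$origin, "external_assay")
    log$phasing <- paste("external assay:", phasing$origin)
  } else if (!is.null(known)) {
    phasing <- known
    log$phasing <- paste("prior knowledge:", known$method)
  } else if (resolved_by_mosaicism && !config$force_phase) {
    log$phasing <- paste0(
      "skipped: family resolved by overt mosaicism (",
      paste(vapply(names(calls), function(i)
        paste0(i, "=", calls[[i]]$call), character(1)), collapse = ", "),
      ")")
  } else {
    phasing <- phase_family(manifest, config, data)
    log$phasing <- paste0("sequencing-based: ", phasing$origin,
                          " (", phasing$method, ")")
  }

  # ---- stage 4: category and risk ----
  assignment <- assign_category(calls$father, calls$mother, calls$child,
                                origin = phasing)
  sperm_key <- "father.6"
  sperm_est <- if (sperm_key %in% names(ests)) ests[[sperm_key]] else NULL
  risk <- compute_family_risk(assignment, sperm_estimate = sperm_est,
                              priors = config$priors,
                              vaf_model = config$vaf_model,
                              conservative = config$conservative)
  log$category <- assignment$category
  log$risk_basis <- risk$basis

  result <- structure(list(family_id = manifest$family_id, trio = trio,
                           vaf_table = vaf_table, calls = calls,
                           phasing = phasing, assignment = assignment,
                           category = assignment$category, risk = risk,
                           log = log, status = "pass"),
                      class = "family_result")
  if (!is.null(out_dir)) write_family_report(result, out_dir)
  result
}

# Sequencing-based phasing: phase-set logic first, pileup fallback.
phase_family <- function(manifest, config, data = NULL) {
  calls <- data$calls
  if (is.null(calls) && !is.null(manifest$vcf_child) &&
      !is.null(manifest$vcf_father) && !is.null(manifest$vcf_mother)) {
    calls <- list(child = read_phased_vcf(manifest$vcf_child),
                  father = read_phased_vcf(manifest$vcf_father),
                  mother = read_phased_vcf(manifest$vcf_mother))
  }
  dnm_pos <- data$dnm_pos %||% manifest$dnm$pos
  res <- NULL
  if (!is.null(calls)) {
    res <- resolve_from_phase_sets(calls$child, calls$father, calls$mother,
                                   dnm_pos,
                                   min_depth = config$phasing_min_depth)
    if (res$origin != "unresolved") return(res)
  }
  obs <- data$observations %||%
    (if (!is.null(manifest$read_obs)) read_observation_table(manifest$read_obs)
     else NULL)
  if (!is.null(obs) && !is.null(calls)) {
    snp_pos <- phaseable_snp_pos(calls$child, dnm_pos)
    if (!is.na(snp_pos)) {
      fa <- calls$father[calls$father$pos == snp_pos, , drop = FALSE]
      mo <- calls$mother[calls$mother$pos == snp_pos, , drop = FALSE]
      if (nrow(fa) && nrow(mo)) {
        map <- snp_parent_map(fa$gt[1L], mo$gt[1L])
        if (!(map$REF == "both" && map$ALT == "both"))
          return(resolve_from_pileup(obs, map,
                                     alpha = config$phasing_alpha))
      }
    }
  }
  res %||% phasing_result("unresolved", "phase_set",
                          note = "no phasing input available")
}

# Nearest child-heterozygous candidate SNP for the pileup route.
phaseable_snp_pos <- function(child_calls, dnm_pos) {
  het <- vapply(child_calls$gt, function(g)
    length(unique(parse_gt(g)$alleles)) == 2L, logical(1))
  cand <- child_calls[child_calls$pos != dnm_pos & het, , drop = FALSE]
  if (nrow(cand) == 0L) return(NA_integer_)
  cand$pos[which.min(abs(cand$pos - dnm_pos))]
}

config_log <- function(config) {
  list(ci_level = config$ci_level, mosaic_floor = config$mosaic_floor,
       constitutional_band = config$constitutional_band,
       phasing_alpha = config$phasing_alpha,
       phasing_min_depth = config$phasing_min_depth,
       priors = as.list(config$priors),
       germline_vaf_mean = mean(config$vaf_model$vafs),
       n_boot = config$vaf_model$n_boot,
       conservative = config$conservative,
       force_phase = config$force_phase,
       reporting_floor = config$reporting_floor)
}

#' @export
print.family_result <- function(x, ...) {
  cat(sprintf("<family_result> %s: category %s\n", x$family_id, x$category))
  print(x$risk)
  invisible(x)
}

#' Write the per-family report files
#'
#' `\{family\}_vaf.tsv` (per-sample corrected VAFs), `\{family\}_report.tsv`
#' (one-line summary: category, risk, CI, basis) and `\{family\}_log.yaml`
#' (all parameters and stage decisions).
#'
#' @param result A `family_result`.
#' @param out_dir Output directory (created if missing).
#' @return The report paths, invisibly.
#' @export
write_family_report <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(out_dir, result$family_id)
  vaf_path <- paste0(base, "_vaf.tsv")
  utils::write.table(result$vaf_table, vaf_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  r <- result$risk
  report <- data.frame(
    family = result$family_id, category = result$category,
    risk = r$risk, ci_low = r$ci_low, ci_high = r$ci_high,
    basis = r$basis,
    qualitative = ifelse(is.na(r$qualitative), "", r$qualitative),
    origin = if (is.null(result$phasing)) "not_run" else
      result$phasing$origin,
    stringsAsFactors = FALSE)
  report_path <- paste0(base, "_report.tsv")
  utils::write.table(report, report_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  log_path <- paste0(base, "_log.yaml")
  yaml::write_yaml(result$log, log_path)
  invisible(c(vaf = vaf_path, report = report_path, log = log_path))
}

#' Run the workflow over a list of families and summarize
#'
#' @param manifests List of [family_manifest()]s.
#' @param config A [pipeline_config()].
#' @param out_dir Optional report directory.
#' @return List with `families` (per-family results; errors are captured
#'   as entries with `status = "error"`) and `summary` (see
#'   [cohort_summary()]).
#' @export
run_cohort <- function(manifests, config = pipeline_config(),
                       out_dir = NULL) {
  results <- lapply(manifests, function(m) {
    tryCatch(run_pipeline(m, config, out_dir = out_dir),
             error = function(e) list(family_id = m$family_id,
                                      status = "error",
                                      message = conditionMessage(e)))
  })
  ok <- Filter(function(x) identical(x$status, "pass"), results)
  summary <- if (length(ok)) cohort_summary(ok, config$reporting_floor)
             else NULL
  list(families = results, summary = summary)
}

#' Analyze a synthetic family in memory
#'
#' Convenience wrapper wiring the output of [simulate_family()] straight
#' into [run_pipeline()] without touching the file system; used for
#' scenario-recovery studies.
#'
#' @param fam Output of [simulate_family()].
#' @param config A [pipeline_config()].
#' @param use_genotypes Run the trio-verification stage as well.
#' @return A `family_result`.
#' @export
analyze_synthetic_family <- function(fam, config = pipeline_config(),
                                     use_genotypes = FALSE) {
  manifest <- family_manifest(
    family_id = fam$family,
    dnm = list(chrom = "chr1", pos = fam$phasing$dnm_pos, ref = "A",
               alt = "T"))
  data <- list(counts = fam$counts, calls = fam$phasing$calls,
               observations = fam$phasing$observations,
               dnm_pos = fam$phasing$dnm_pos)
  if (use_genotypes) data$genotypes <- fam$genotypes
  run_pipeline(manifest, config, data = data)
}
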
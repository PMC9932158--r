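mk_calls <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(pos = r[[1]], ref = r[[2]], alt = r[[3]], gt = r[[4]],
               ps = r[[5]], dp = r[[6]], stringsAsFactors = FALSE)))
}

test_that("phase-set logic resolves the classic informative configuration", {
  # child carries the DNM on the haplotype with SNP-ALT; mother is 0/0,
  # father 1/1: the in-phase allele can only be paternal
  child <- mk_calls(list(1000, "A", "T", "0|1", 1000, 50),
                    list(1500, "C", "G", "0|1", 1000, 40))
  father <- mk_calls(list(1500, "C", "G", "1/1", NA, 45))
  mother <- mk_calls(list(1500, "C", "G", "0/0", NA, 45))
  res <- resolve_from_phase_sets(child, father, mother, 1000)
  expect_equal(res$origin, "paternal")
  expect_equal(res$method, "phase_set")
  expect_equal(res$supporting_snp, 1500)

  # flip the phase: DNM on the other haplotype -> maternal
  child2 <- child; child2$gt <- c("1|0", "0|1")
  expect_equal(resolve_from_phase_sets(child2, father, mother, 1000)$origin,
               "maternal")
})

test_that("identically heterozygous parents leave the DNM unresolved", {
  child <- mk_calls(list(1000, "A", "T", "0|1", 1000, 50),
                    list(1500, "C", "G", "0|1", 1000, 40))
  both_het <- mk_calls(list(1500, "C", "G", "0/1", NA, 45))
  res <- resolve_from_phase_sets(child, both_het, both_het, 1000)
  expect_equal(res$origin, "unresolved")
})

test_that("disagreeing informative SNPs raise a conflict, not a call", {
  child <- mk_calls(list(1000, "A", "T", "0|1", 1000, 50),
                    list(1500, "C", "G", "0|1", 1000, 40),
                    list(2000, "T", "A", "0|1", 1000, 40))
  # SNP 1500 says paternal, SNP 2000 says maternal
  father <- mk_calls(list(1500, "C", "G", "1/1", NA, 45),
                     list(2000, "T", "A", "0/0", NA, 45))
  mother <- mk_calls(list(1500, "C", "G", "0/0", NA, 45),
                     list(2000, "T", "A", "1/1", NA, 45))
  res <- resolve_from_phase_sets(child, father, mother, 1000)
  expect_equal(res$origin, "unresolved")
  expect_match(res$note, "conflict")
})

test_that("a DNM called in a parent is rejected as not de novo", {
  child <- mk_calls(list(1000, "A", "T", "0|1", 1000, 50))
  father <- mk_calls(list(1000, "A", "T", "0/1", NA, 45))
  mother <- mk_calls(list(1500, "C", "G", "0/0", NA, 45))
  expect_error(resolve_from_phase_sets(child, father, mother, 1000),
               "not de novo")
})

test_that("the phase-set depth filter is strict (> 10)", {
  father <- mk_calls(list(1500, "C", "G", "1/1", NA, 45))
  mother <- mk_calls(list(1500, "C", "G", "0/0", NA, 45))
  at10 <- mk_calls(list(1000, "A", "T", "0|1", 1000, 50),
                   list(1500, "C", "G", "0|1", 1000, 10))
  expect_equal(resolve_from_phase_sets(at10, father, mother, 1000)$origin,
               "unresolved")
  at11 <- mk_calls(list(1000, "A", "T", "0|1", 1000, 50),
                   list(1500, "C", "G", "0|1", 1000, 11))
  expect_equal(resolve_from_phase_sets(at11, father, mother, 1000)$origin,
               "paternal")
})

test_that("an unphased DNM is unresolved, not an error", {
  child <- mk_calls(list(1000, "A", "T", "0/1", NA, 50))
  empty <- mk_calls(list(1500, "C", "G", "0/0", NA, 45))
  res <- resolve_from_phase_sets(child, empty, empty, 1000)
  expect_equal(res$origin, "unresolved")
  expect_match(res$note, "unphased")
})

test_that("Fisher exact p-values match enumeration and handle degenerate margins", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2)), 1.0)
  # independent cross-check against the canonical implementation
  set.seed(501)
  for (i in 1:25) {
    tab <- matrix(rpois(4, sample(c(2, 8, 30), 1)), 2)
    if (sum(tab) == 0) next
    got <- fisher_exact(tab)
    ref <- stats::fisher.test(tab)$p.value
    expect_lt(abs(got - min(ref, 1)), 1e-12)
  }
  # fully separated table
  tab <- matrix(c(8, 0, 0, 7), 2)
  expect_lt(abs(fisher_exact(tab) - stats::fisher.test(tab)$p.value), 1e-12)
  # single populated margin: no association testable
  expect_equal(fisher_exact(matrix(c(1, 0, 0, 0), 2)), 1)
  expect_error(fisher_exact(matrix(0, 2, 2)), "all-zero")
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("pileup phasing calls the enriched parental allele and respects alpha", {
  sim <- simulate_phasing_reads("maternal", "informative", depth = 40,
                                switch_error = 0, seed = 21)
  map <- snp_parent_map(sim$calls$father$gt, sim$calls$mother$gt)
  res <- resolve_from_pileup(sim$observations, map)
  expect_equal(res$origin, "maternal")
  expect_equal(res$method, "pileup")
  expect_lt(res$p_value, 1e-6)
  expect_equal(dim(res$table), c(2L, 2L))

  # a balanced table carries no phase signal
  flat <- data.frame(read_id = sprintf("r%02d", 1:40),
                     dnm_allele = rep(c("REF", "ALT"), each = 20),
                     snp_allele = rep(c("REF", "ALT"), 20),
                     stringsAsFactors = FALSE)
  res_flat <- resolve_from_pileup(flat, list(REF = "mother", ALT = "father"))
  expect_equal(res_flat$origin, "unresolved")
  expect_false(is.null(res_flat$table))
})

test_that("phasing SNP label inversion never flips the origin call", {
  for (seed in 1:10) {
    sim <- simulate_phasing_reads("paternal", "informative", depth = 120,
                                  switch_error = 0.03, seed = seed)
    map <- snp_parent_map(sim$calls$father$gt, sim$calls$mother$gt)
    res1 <- resolve_from_pileup(sim$observations, map)
    flipped <- sim$observations
    flipped$snp_allele <- ifelse(flipped$snp_allele == "ALT", "REF", "ALT")
    res2 <- resolve_from_pileup(flipped, list(REF = map$ALT, ALT = map$REF))
    expect_identical(res1$origin, res2$origin)
    expect_equal(res1$p_value, res2$p_value, tolerance = 1e-12)
  }
})

test_that("maternal pileup calls stay correct under realistic switch error", {
  hits <- 0
  for (seed in 1:60) {
    sim <- simulate_phasing_reads("maternal", "informative", depth = 200,
                                  switch_error = 0.05, seed = seed)
    map <- snp_parent_map(sim$calls$father$gt, sim$calls$mother$gt)
    res <- resolve_from_pileup(sim$observations, map, alpha = 0.01)
    if (res$origin == "maternal") hits <- hits + 1
  }
  expect_gte(hits / 60, 0.95)
})

test_that("transitive two-SNP phasing propagates the in-phase allele", {
  # SNP1 uninformative in the parents; SNP2 informative and in perfect
  # phase with SNP1-ALT, which itself rides with the DNM-ALT
  n <- 60
  hap <- rep(c(1, 2), each = n / 2)
  obs1 <- data.frame(read_id = sprintf("r%03d", 1:n),
                     dnm_allele = ifelse(hap == 2, "ALT", "REF"),
                     snp_allele = ifelse(hap == 2, "ALT", "REF"),
                     stringsAsFactors = FALSE)
  obs2 <- data.frame(read_id = sprintf("r%03d", 1:n),
                     dnm_allele = ifelse(hap == 2, "ALT", "REF"),  # SNP1
                     snp_allele = ifelse(hap == 2, "REF", "ALT"),  # SNP2
                     stringsAsFactors = FALSE)
  # SNP2-REF transmissible only by the mother
  res <- resolve_transitive(obs1, obs2,
                            parent_map2 = list(REF = "mother",
                                               ALT = "father"))
  expect_equal(res$origin, "maternal")
  expect_length(res$p_value, 2)
  expect_true(all(res$p_value < 1e-6))
})

test_that("prior-knowledge shortcuts take precedence and validate conflicts", {
  x <- annotate_known_origin(x_linked_male_proband = TRUE)
  expect_equal(x$origin, "maternal")
  expect_equal(x$method, "known_xlinked")
  im <- annotate_known_origin(imprinted_expected_origin = "paternal")
  expect_equal(im$origin, "paternal")
  expect_equal(im$method, "known_imprinted")
  expect_null(annotate_known_origin())
  expect_error(annotate_known_origin(TRUE, "paternal"), "conflicting")
})

test_that("phase-set and pileup methods agree on noise-free synthetic families", {
  for (seed in 1:50) {
    origin <- if (seed %% 2) "paternal" else "maternal"
    sim <- simulate_phasing_reads(origin, "informative", depth = 60,
                                  switch_error = 0, seed = seed)
    ps <- resolve_from_phase_sets(sim$calls$child, sim$calls$father,
                                  sim$calls$mother, sim$dnm_pos)
    pu <- resolve_from_pileup(sim$observations,
                              snp_parent_map(sim$calls$father$gt,
                                             sim$calls$mother$gt))
    expect_identical(ps$origin, origin)
    expect_identical(pu$origin, origin)
  }
})

test_that("phased calls round-trip through minimal VCF", {
  sim <- simulate_phasing_reads("paternal", "informative", depth = 30,
                                switch_error = 0, seed = 31)
  path <- file.path(withr::local_tempdir(), "child.vcf.gz")
  write_phased_vcf(sim$calls$child, path, sample = "child")
  back <- read_phased_vcf(path)
  expect_equal(back$pos, sim$calls$child$pos)
  expect_equal(back$gt, sim$calls$child$gt)
  expect_equal(back$ps, as.integer(sim$calls$child$ps))
  expect_equal(back$dp, as.integer(sim$calls$child$dp))
  # and the result computed from the round-tripped calls is unchanged
  fa_path <- file.path(withr::local_tempdir(), "father.vcf.gz")
  mo_path <- file.path(withr::local_tempdir(), "mother.vcf.gz")
  write_phased_vcf(sim$calls$father, fa_path, sample = "father")
  write_phased_vcf(sim$calls$mother, mo_path, sample = "mother")
  res <- resolve_from_phase_sets(back, read_phased_vcf(fa_path),
                                 read_phased_vcf(mo_path), sim$dnm_pos)
  expect_equal(res$origin, "paternal")
})
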
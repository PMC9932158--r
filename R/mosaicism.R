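# Corrected variant allele fraction estimation at a DNM site.
#
# The observed alternate-read count in a case sample mixes true variant
# reads with sequencing/calling false positives.  With p the unobserved
# fraction of cells carrying the variant and q the per-site false-positive
# rate, alt reads in the case arise at rate p + (1-p)q while alt reads in
# an unrelated control arise at rate q.  The two samples are tied together
# in a joint binomial likelihood; q is a nuisance parameter.

#' Per-site read counts
#'
#' Container for the quality-filtered alternate and total read counts at
#' the DNM position for one sample (or for pooled technical replicates).
#'
#' @param k Alternate-allele read count.
#' @param n Total read count. `n = 0` marks a failed sample.
#' @param role `"case"` or `"control"`.
#' @return An object of class `site_counts` with fields `k`, `n`, `role`.
#' @export
site_counts <- function(k, n, role = c("case", "control")) {
  role <- match.arg(role)
  if (length(k) != 1L || length(n) != 1L || is.na(k) || is.na(n))
    stop("'k' and 'n' must be single non-missing counts")
  if (k < 0 || n < 0 || k > n)
    stop("invalid counts: need 0 <= k <= n (got k=", k, ", n=", n, ")")
  structure(list(k = as.numeric(k), n = as.numeric(n), role = role),
            class = "site_counts")
}

#' @export
print.site_counts <- function(x, ...) {
  cat(sprintf("<site_counts> %s: %g alt / %g total\n", x$role, x$k, x$n))
  invisible(x)
}

as_site_counts <- function(x, role = "case") {
  if (inherits(x, "site_counts")) return(x)
  if (is.list(x) && !is.null(x$k) && !is.null(x$n))
    return(site_counts(x$k, x$n, role))
  if (is.numeric(x) && length(x) == 2L)
    return(site_counts(x[[1L]], x[[2L]], role))
  stop("cannot interpret object as site_counts")
}

check_rate <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop("'", name, "' must be a single value in [0, 1] (got ",
         format(x), ")")
  invisible(x)
}

#' Joint case/control binomial log-likelihood
#'
#' Log of `B(k1; n1, q) * B(k2; n2, p + (1-p) q)` where `B` is the
#' binomial probability mass function, `(k1, n1)` are the control counts
#' and `(k2, n2)` the case counts.
#'
#' @param p Fraction of case cells carrying the variant, in \[0, 1\].
#' @param q Per-site false-positive rate, in \[0, 1\].
#' @param control,case `site_counts` (or anything coercible via `list(k, n)`).
#' @return The joint log-likelihood (may be `-Inf` at boundary rates).
#' @export
joint_log_likelihood <- function(p, q, control, case) {
  check_rate(p, "p"); check_rate(q, "q")
  control <- as_site_counts(control, "control")
  case <- as_site_counts(case, "case")
  rate <- p + (1 - p) * q
  rate <- min(max(rate, 0), 1)   # guard FP drift outside [0,1]
  dbinom(control$k, control$n, q, log = TRUE) +
    dbinom(case$k, case$n, rate, log = TRUE)
}

# Unnormalized joint log-likelihood on raw numbers (hot path, no validation).
jll <- function(p, q, k1, n1, k2, n2) {
  rate <- p + (1 - p) * q
  rate <- if (rate < 0) 0 else if (rate > 1) 1 else rate
  dbinom(k1, n1, q, log = TRUE) + dbinom(k2, n2, rate, log = TRUE)
}

# Maximizer of the joint log-likelihood over q at fixed p.  The joint
# log-likelihood is log-concave in q, so golden-section search is safe.
# -Inf at boundary rates is clamped to a huge negative finite value so
# optimize() does not warn; marg_ll() treats the clamp as -Inf.
LL_FLOOR <- -.Machine$double.xmax / 2

q_peak <- function(p, k1, n1, k2, n2) {
  optimize(function(q) {
    v <- jll(p, q, k1, n1, k2, n2)
    if (is.finite(v)) v else LL_FLOOR
  }, interval = c(0, 1), maximum = TRUE, tol = 1e-12)
}

#' Marginal log-likelihood of the cell fraction
#'
#' Integrates the joint likelihood over the nuisance false-positive rate
#' `q` on \[0, 1\] by adaptive quadrature and returns the log of the
#' result.  The integrand is stabilized by factoring out its maximum, so
#' depths of 10^5 reads and more do not underflow, and the integration
#' interval is split at the peak so the sharp mode near the control VAF is
#' never stepped over.
#'
#' @inheritParams joint_log_likelihood
#' @return `log integral_0^1 L(p, q) dq`.
#' @export
marginal_log_likelihood <- function(p, control, case) {
  check_rate(p, "p")
  control <- as_site_counts(control, "control")
  case <- as_site_counts(case, "case")
  marg_ll(p, control$k, control$n, case$k, case$n)
}

marg_ll <- function(p, k1, n1, k2, n2) {
  pk <- q_peak(p, k1, n1, k2, n2)
  M <- pk$objective
  if (!is.finite(M) || M <= LL_FLOOR) return(-Inf)
  f <- function(q) exp(jll_vec(p, q, k1, n1, k2, n2) - M)
  val <- tryCatch({
    i1 <- integrate(f, 0, pk$maximum, rel.tol = 1e-9, subdivisions = 500L)
    i2 <- integrate(f, pk$maximum, 1, rel.tol = 1e-9, subdivisions = 500L)
    i1$value + i2$value
  }, error = function(e) {
    stop("quadrature failed at p=", format(p), " (k1=", k1, ", n1=", n1,
         ", k2=", k2, ", n2=", n2, "): ", conditionMessage(e))
  })
  M + log(val)
}

# Vectorized-in-q version of jll for integrate().
jll_vec <- function(p, q, k1, n1, k2, n2) {
  rate <- p + (1 - p) * q
  rate[rate < 0] <- 0
  rate[rate > 1] <- 1
  dbinom(k1, n1, q, log = TRUE) + dbinom(k2, n2, rate, log = TRUE)
}

#' Profile log-likelihood of the cell fraction
#'
#' `max_q log L(p, q)`: the joint log-likelihood maximized (not
#' integrated) over the nuisance false-positive rate. Used for the
#' confidence interval, where the chi-square calibration of the likelihood
#' ratio applies to the profiled, not the integrated, curve.
#'
#' @inheritParams joint_log_likelihood
#' @return The profiled log-likelihood value.
#' @export
profile_log_likelihood <- function(p, control, case) {
  check_rate(p, "p")
  control <- as_site_counts(control, "control")
  case <- as_site_counts(case, "case")
  v <- q_peak(p, control$k, control$n, case$k, case$n)$objective
  if (v <= LL_FLOOR) -Inf else v
}

#' Corrected VAF estimate with profile-likelihood confidence interval
#'
#' Point estimate: the value of p maximizing the marginal likelihood
#' (nuisance q integrated out by adaptive quadrature).  Interval: the set
#' of p whose profile log-likelihood lies within `qchisq(level, 1)/2`
#' (1.9207 log-units at 95%) of the profile maximum, found by bracketed
#' root search on each side and clipped to \[0, 1\] when a boundary lies
#' inside the interval.
#'
#' @param control,case Pooled `site_counts` (see [pool_replicates()]).
#' @param level Confidence level, default 0.95.
#' @return An object of class `vaf_estimate`: `p_hat`, `ci_low`,
#'   `ci_high`, the case counts `k`, `n`, the control counts `control_k`,
#'   `control_n`, `level` and a `status` of `"ok"` or `"sample_failure"`.
#' @export
estimate_corrected_vaf <- function(control, case, level = 0.95) {
  control <- as_site_counts(control, "control")
  case <- as_site_counts(case, "case")
  if (case$n == 0) {
    return(structure(list(p_hat = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, k = NA_real_, n = 0,
                          control_k = control$k, control_n = control$n,
                          level = level, status = "sample_failure"),
                     class = "vaf_estimate"))
  }
  if (control$n == 0)
    stop("control counts are empty; cannot correct for background")
  k1 <- control$k; n1 <- control$n; k2 <- case$k; n2 <- case$n

  ml <- function(p) marg_ll(p, k1, n1, k2, n2)
  opt <- optimize(ml, c(0, 1), maximum = TRUE, tol = 1e-10)
  p_hat <- opt$maximum
  # golden-section never lands exactly on the boundary; check it explicitly
  if (ml(0) > opt$objective) p_hat <- 0
  if (k2 == n2 && ml(1) > max(opt$objective, ml(0))) p_hat <- 1

  pl <- function(p) q_peak(p, k1, n1, k2, n2)$objective
  popt <- optimize(pl, c(0, 1), maximum = TRUE, tol = 1e-10)
  pmax_ll <- max(popt$objective, pl(0), if (k2 == n2) pl(1) else -Inf)
  p_prof <- if (pl(0) >= popt$objective) 0 else popt$maximum
  cut <- pmax_ll - qchisq(level, 1) / 2
  g <- function(p) pl(p) - cut
  ci_low <- if (g(0) >= 0) 0 else
    uniroot(g, c(0, p_prof), tol = 1e-10)$root
  ci_high <- if (g(1) >= 0) 1 else
    uniroot(g, c(max(p_prof, p_hat), 1), tol = 1e-10)$root
  # marginal and profile maximizers differ by O(1/n); keep the invariant
  p_hat <- min(max(p_hat, ci_low), ci_high)

  structure(list(p_hat = p_hat, ci_low = ci_low, ci_high = ci_high,
                 k = k2, n = n2, control_k = k1, control_n = n1,
                 level = level, status = "ok"),
            class = "vaf_estimate")
}

#' @export
print.vaf_estimate <- function(x, ...) {
  if (x$status != "ok") {
    cat("<vaf_estimate> sample failure (n = 0)\n")
  } else {
    cat(sprintf(
      "<vaf_estimate> p_hat = %.4g%% [%.4g%%, %.4g%%] (%d%% profile CI), k/n = %g/%g, control %g/%g\n",
      100 * x$p_hat, 100 * x$ci_low, 100 * x$ci_high,
      round(100 * x$level), x$k, x$n, x$control_k, x$control_n))
  }
  invisible(x)
}

#' Pool technical replicates
#'
#' Sums alternate and total counts over replicates, silently dropping
#' failed replicates (`n = 0`).  Replicates from the unrelated controls
#' are pooled the same way into a single control count.
#'
#' @param replicates A list of `site_counts`, or a data.frame with columns
#'   `alt_count` and `total_count`.
#' @param role Role attached to the pooled counts.
#' @return A pooled `site_counts`; if every replicate failed, a
#'   `site_counts` with `n = 0` (picked up downstream as a sample
#'   failure).
#' @export
pool_replicates <- function(replicates, role = "case") {
  if (is.data.frame(replicates)) {
    ks <- replicates$alt_count; ns <- replicates$total_count
  } else {
    reps <- lapply(replicates, as_site_counts, role = role)
    ks <- vapply(reps, `[[`, numeric(1), "k")
    ns <- vapply(reps, `[[`, numeric(1), "n")
  }
  if (length(ns) == 0L) stop("no replicates supplied")
  keep <- ns > 0
  site_counts(sum(ks[keep]), sum(ns[keep]), role)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided interval obtained by inverting the binomial tail
#' probabilities via the beta quantile function.
#'
#' @param k Number of successes.
#' @param n Number of trials (> 0).
#' @param level Confidence level, default 0.95.
#' @return Named numeric vector `c(low, high)`.
#' @export
binomial_ci <- function(k, n, level = 0.95) {
  if (n <= 0 || k < 0 || k > n) stop("need 0 <= k <= n with n > 0")
  alpha <- 1 - level
  low <- if (k == 0) 0 else qbeta(alpha / 2, k, n - k + 1)
  high <- if (k == n) 1 else qbeta(1 - alpha / 2, k + 1, n - k)
  c(low = low, high = high)
}

#' Call the mosaic status of one individual
#'
#' A parent is called mosaic when any tissue shows unambiguous variant
#' signal above background: the profile-CI lower bound excludes 0 and the
#' point estimate reaches the decision floor.  A child is constitutional
#' when every tissue's CI is compatible with the heterozygous 50% band,
#' and post-zygotic mosaic when the variant is present but at least one
#' tissue's CI upper bound falls below the band (a CI merely excluding
#' 50% is expected in ~2.5% of constitutional tissues by construction,
#' so the band edge -- not 50% itself -- is the decision boundary).
#'
#' @param estimates Named list of `vaf_estimate` objects, one per tissue
#'   (names are tissue codes).
#' @param expected_constitutional `TRUE` for the proband (variant expected
#'   at ~50% in all tissues), `FALSE` for a parent.
#' @param floor Decision floor on `p_hat` for calling mosaicism (default
#'   0.003, i.e. 0.3%).
#' @param constitutional_band Band of cell fractions treated as compatible
#'   with constitutional heterozygosity (default `c(0.45, 0.55)`).
#' @return An object of class `mosaic_call`: `call` (one of `"none"`,
#'   `"mosaic"`, `"constitutional"`, `"post_zygotic_mosaic"`),
#'   `mosaic_tissues`, `floor`, and the per-tissue `evidence`.
#' @export
call_mosaicism <- function(estimates, expected_constitutional = FALSE,
                           floor = 0.003,
                           constitutional_band = c(0.45, 0.55)) {
  ok <- Filter(function(e) e$status == "ok", estimates)
  if (length(ok) == 0L) stop("no successful estimate for this individual")
  lows <- vapply(ok, `[[`, numeric(1), "ci_low")
  highs <- vapply(ok, `[[`, numeric(1), "ci_high")
  phats <- vapply(ok, `[[`, numeric(1), "p_hat")

  if (!expected_constitutional) {
    hit <- lows > 0 & phats >= floor
    call <- if (any(hit)) "mosaic" else "none"
    tissues <- names(ok)[hit]
  } else {
    compatible <- highs >= constitutional_band[1] & lows <= constitutional_band[2]
    below_het <- highs < constitutional_band[1] & phats > floor
    if (any(below_het)) {
      call <- "post_zygotic_mosaic"
      tissues <- names(ok)[below_het]
    } else if (all(compatible)) {
      call <- "constitutional"
      tissues <- character(0)
    } else {
      # present above 50% everywhere measurable, or noisy: not a
      # post-zygotic signature
      call <- "constitutional"
      tissues <- character(0)
    }
  }
  structure(list(call = call, mosaic_tissues = tissues, floor = floor,
                 evidence = estimates),
            class = "mosaic_call")
}

#' @export
print.mosaic_call <- function(x, ...) {
  cat(sprintf("<mosaic_call> %s%s (floor = %g%%)\n", x$call,
              if (length(x$mosaic_tissues))
                paste0(" [tissues: ", paste(x$mosaic_tissues, collapse = ","), "]")
              else "", 100 * x$floor))
  invisible(x)
}

#' Estimate corrected VAFs for every sample of a family count table
#'
#' Replicates are pooled per (individual, tissue); all control rows are
#' pooled into one background count used for every case sample of the
#' family (the three unrelated controls are run on the same amplicon).
#'
#' @param counts Count table with columns `family`, `individual`,
#'   `tissue_code`, `replicate`, `alt_count`, `total_count`, `is_control`
#'   (see [read_count_table()]).
#' @param level Confidence level for the profile CIs.
#' @return A data.frame with one row per (individual, tissue): `family`,
#'   `individual`, `tissue_code`, `p_hat`, `ci_low`, `ci_high`, `k`, `n`,
#'   `control_k`, `control_n`, `status`, plus the `vaf_estimate` objects
#'   in attribute `"estimates"` (a named list `individual.tissue`).
#' @export
estimate_family_vafs <- function(counts, level = 0.95) {
  stopifnot(all(c("individual", "tissue_code", "alt_count", "total_count",
                  "is_control") %in% names(counts)))
  ctl <- counts[as.logical(counts$is_control), , drop = FALSE]
  if (nrow(ctl) == 0L) stop("count table contains no control rows")
  control <- pool_replicates(ctl, role = "control")
  cases <- counts[!as.logical(counts$is_control), , drop = FALSE]
  if (nrow(cases) == 0L) stop("count table contains no case rows")
  key <- interaction(cases$individual, cases$tissue_code, drop = TRUE)
  groups <- split(cases, key)
  ests <- lapply(groups, function(g) {
    pooled <- site_counts(sum(g$alt_count[g$total_count > 0]),
                          sum(g$total_count), "case")
    estimate_corrected_vaf(control, pooled, level = level)
  })
  out <- do.call(rbind, lapply(seq_along(groups), function(i) {
    g <- groups[[i]]; e <- ests[[i]]
    data.frame(family = g$family[1L], individual = g$individual[1L],
               tissue_code = g$tissue_code[1L], p_hat = e$p_hat,
               ci_low = e$ci_low, ci_high = e$ci_high, k = e$k, n = e$n,
               control_k = e$control_k, control_n = e$control_n,
               status = e$status, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "estimates") <- ests
  out
}

#' Read / write the per-family count table
#'
#' Tab-separated with columns `family`, `individual`, `tissue_code`,
#' `replicate`, `alt_count`, `total_count`, `is_control`.
#'
#' @param path File path.
#' @return `read_count_table()` returns the data.frame.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("count table not found: ", path)
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("family", "individual", "tissue_code", "replicate",
            "alt_count", "total_count", "is_control")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("count table missing column(s): ",
                         paste(miss, collapse = ", "))
  x$is_control <- as.logical(x$is_control)
  x
}

#' @rdname read_count_table
#' @param counts Count table data.frame.
#' @export
write_count_table <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
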
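#' Align effect alleles across studies
#'
#' Flips beta signs (and swaps allele labels) in studies whose effect
#' allele is the other allele of the reference study, so effects are
#' counted on a common allele before pooling.
#'
#' @param studies list of one-row-per-study data.frames with `beta`,
#'   `effect_allele`, `other_allele`.
#' @return the list with betas aligned to the first study's effect allele.
#' @export
align_effect_alleles <- function(studies) {
  ref <- studies[[1]]
  lapply(studies, function(s) {
    if (identical(s$effect_allele, ref$effect_allele)) return(s)
    if (identical(s$effect_allele, ref$other_allele) &&
        identical(s$other_allele, ref$effect_allele)) {
      s$beta <- -s$beta
      tmp <- s$effect_allele
      s$effect_allele <- s$other_allele
      s$other_allele <- tmp
      return(s)
    }
    stop("alleles not resolvable across studies")
  })
}

#' Inverse-variance-weighted fixed-effect meta-analysis
#'
#' `w_i = 1/SE_i^2`; combined beta is the weighted mean, combined SE is
#' `1/sqrt(sum w_i)`, and the two-sided P comes from the normal Z. A single
#' study passes through unchanged (tagged `single-study`).
#'
#' @param betas per-study effect sizes (aligned alleles).
#' @param ses per-study standard errors (> 0).
#' @return one-row `data.table`: method, beta, se, z, p, q, q_df, q_p,
#'   n_studies, directions.
#' @export
ivw_meta <- function(betas, ses) {
  k <- length(betas)
  stopifnot(length(ses) == k)
  if (any(ses <= 0)) stop("standard errors must be positive")
  w <- 1 / ses^2
  beta <- sum(w * betas) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- beta / se
  q <- sum(w * (betas - beta)^2)
  data.table::data.table(
    method = if (k == 1) "single-study" else "ivw",
    beta = beta, se = se, z = z,
    p = 2 * stats::pnorm(-abs(z)),
    q = q, q_df = k - 1L,
    q_p = if (k > 1) stats::pchisq(q, k - 1, lower.tail = FALSE) else NA_real_,
    n_studies = k,
    directions = paste(ifelse(betas >= 0, "+", "-"), collapse = ""))
}

#' Sample-size-weighted P-value meta-analysis (the METAL method)
#'
#' Each study contributes a signed Z (`qnorm(P/2)` with the study's effect
#' direction); the combined Z is `sum(z_i sqrt(n_i)) / sqrt(sum n_i)`.
#' More robust than IVW when standard errors are large. Weights use total
#' n by default; effective n `4 / (1/n_cases + 1/n_controls)` is available.
#'
#' @param ps per-study two-sided P values.
#' @param directions per-study effect signs (+1/-1, or "+"/"-").
#' @param n per-study total sample sizes.
#' @param n_cases,n_controls per-study counts, used when
#'   `weights = "effective-n"`.
#' @param weights `"n"` (default) or `"effective-n"`.
#' @return one-row `data.table`: method, z, p, n_studies, directions.
#' @export
stouffer_meta <- function(ps, directions, n, n_cases = NULL, n_controls = NULL,
                          weights = c("n", "effective-n")) {
  weights <- match.arg(weights)
  k <- length(ps)
  if (is.character(directions)) directions <- ifelse(directions == "-", -1, 1)
  directions <- sign(directions)
  if (any(ps == 0)) {
    message("P value of 0 clamped to the smallest representable positive")
    ps[ps == 0] <- .Machine$double.xmin
  }
  z <- directions * stats::qnorm(ps / 2, lower.tail = FALSE)
  wn <- if (weights == "n") n else 4 / (1 / n_cases + 1 / n_controls)
  zc <- sum(z * sqrt(wn)) / sqrt(sum(wn))
  data.table::data.table(
    method = if (k == 1) "single-study" else "pvalue",
    z = zc, p = 2 * stats::pnorm(-abs(zc)), n_studies = k,
    directions = paste(ifelse(directions >= 0, "+", "-"), collapse = ""))
}

#' Cochran's Q heterogeneity test
#'
#' `Q = sum(w_i (beta_i - beta_ivw)^2)` with IVW weights; P from a
#' chi-square with k - 1 degrees of freedom.
#'
#' @inheritParams ivw_meta
#' @return list `(q, df, p)`.
#' @export
cochran_q <- function(betas, ses) {
  stopifnot(length(betas) >= 2)
  r <- ivw_meta(betas, ses)
  list(q = r$q, df = r$q_df, p = r$q_p)
}

#' Dual-threshold significance call for meta-analysed variants
#'
#' A variant is significant iff both the IVW and the P-value-method P lie
#' below the stage threshold (5e-8 for genome-wide scans, 1e-8 for
#' exome-wide).
#'
#' @param p_ivw,p_pvalue the two meta P values.
#' @param threshold stage threshold (default 5e-8).
#' @return list `(significant, reason)`; reason names the failing
#'   method(s), or `"both-pass"`.
#' @export
flag_significant <- function(p_ivw, p_pvalue, threshold = 5e-8) {
  fail <- c(if (!(p_ivw < threshold)) "ivw",
            if (!(p_pvalue < threshold)) "pvalue-method")
  list(significant = length(fail) == 0,
       reason = if (length(fail) == 0) "both-pass"
                else paste(fail, collapse = "+"))
}

#' Meta-analyse two or more per-study summary-statistic tables
#'
#' Joins per-study association tables on `variant_id`, aligns effect
#' alleles to the first study, and computes IVW, the sample-size-weighted
#' P-value method, Cochran's Q and the dual-threshold significance flag.
#' Variants present in a single study pass through tagged `single-study`.
#'
#' @param studies named list of `data.table`s with `variant_id`, `beta`,
#'   `se`, `p`, `n`, and optionally `effect_allele`/`other_allele`.
#' @param threshold stage significance threshold (default 5e-8).
#' @param weights see [stouffer_meta()].
#' @return `data.table`, one row per variant.
#' @export
meta_analyse <- function(studies, threshold = 5e-8, weights = "n") {
  stopifnot(length(studies) >= 1)
  all_ids <- unique(unlist(lapply(studies, `[[`, "variant_id")))
  rows <- lapply(all_ids, function(v) {
    per <- lapply(studies, function(s) s[s$variant_id == v, ])
    per <- per[vapply(per, nrow, 0L) > 0]
    if (all(c("effect_allele", "other_allele") %in% names(per[[1]])))
      per <- align_effect_alleles(per)
    betas <- vapply(per, `[[`, 0, "beta")
    ses <- vapply(per, `[[`, 0, "se")
    ns <- vapply(per, `[[`, 0, "n")
    iv <- ivw_meta(betas, ses)
    st <- stouffer_meta(vapply(per, `[[`, 0, "p"), sign(betas), ns,
                        weights = weights)
    fl <- flag_significant(iv$p, st$p, threshold)
    data.table::data.table(
      variant_id = v, n_studies = length(per),
      beta_meta = iv$beta, se_meta = iv$se, p_ivw = iv$p,
      z_meta = st$z, p_pvalue = st$p,
      q = iv$q, q_df = iv$q_df, q_p = iv$q_p,
      directions = iv$directions,
      significant = fl$significant, reason = fl$reason)
  })
  data.table::rbindlist(rows)
}
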
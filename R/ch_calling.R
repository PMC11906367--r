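#' Load a CH driver-qualification rule set
#'
#' Rules are stored as editable JSON. Each gene has exactly one rule class:
#' `whole_gene_ptv_plus_hotspot` (any protein-truncating variant along the
#' gene body, or a catalogued hotspot), `exon_restricted_ptv` (PTVs only
#' within listed exons) or `hotspot_only` (catalogued hotspots only).
#' Hotspots are keyed on amino-acid change when the call carries one, else
#' on `chrom:pos:ref:alt`.
#'
#' @param panel `"panel15"`, `"panel58"`, or `"custom"` (requires `path`).
#' @param path path to a JSON file in the shipped schema; overrides `panel`.
#' @return an object of class `ch_ruleset`: list with `panel` and `genes`.
#' @export
ch_rules <- function(panel = c("panel15", "panel58", "custom"), path = NULL) {
  panel <- match.arg(panel)
  if (is.null(path)) {
    if (panel == "custom") stop("custom panel requires `path`")
    path <- system.file("extdata", paste0("ch_rules_", panel, ".json"),
                        package = "chancestry", mustWork = TRUE)
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  genes <- lapply(raw$genes, function(g) {
    rc <- g$rule_class
    if (!rc %in% c("whole_gene_ptv_plus_hotspot", "exon_restricted_ptv",
                   "hotspot_only")) {
      stop("unknown rule_class: ", rc)
    }
    list(rule_class = rc,
         allowed_exons = as.integer(g$allowed_exons %||% integer()),
         hotspots = as.character(g$hotspots %||% character()))
  })
  for (nm in names(genes)) {
    g <- genes[[nm]]
    if (g$rule_class == "exon_restricted_ptv" && length(g$allowed_exons) == 0L)
      stop(nm, ": exon_restricted_ptv requires allowed_exons")
    if (g$rule_class == "hotspot_only" && length(g$hotspots) == 0L)
      stop(nm, ": hotspot_only requires hotspots")
  }
  structure(list(panel = raw$panel %||% panel, genes = genes),
            class = "ch_ruleset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

PTV_CLASSES <- c("nonsense", "frameshift", "splice_site")

#' Classify one somatic variant call against a rule set
#'
#' Gates are evaluated in a fixed order — panel membership, alternate-read
#' support (>= 3 reads), variant allele fraction (0.03 <= VAF <= 0.40,
#' inclusive), then consequence against the gene's rule class — and the
#' reason code reports the first failed gate, so verdicts are deterministic.
#'
#' @param call a list or one-row data.frame with fields `gene`,
#'   `consequence`, `alt_reads`, `depth`, and optionally `vaf`,
#'   `exon_number`, `protein_change`, `chrom`, `pos`, `ref`, `alt`.
#' @param rules a [ch_rules()] object.
#' @return list `(qualified, reason)`; reason is `"ok"`, `"panel"`,
#'   `"reads"`, `"vaf"` or `"consequence"`.
#' @export
classify_variant <- function(call, rules) {
  if (is.data.frame(call)) call <- as.list(call[1, ])
  if (is.null(call$depth) || is.na(call$depth) || call$depth == 0)
    stop("malformed somatic record: depth is zero or missing")
  vaf <- call$vaf %||% (call$alt_reads / call$depth)
  if (is.na(vaf)) vaf <- call$alt_reads / call$depth
  g <- rules$genes[[call$gene]]
  if (is.null(g)) return(list(qualified = FALSE, reason = "panel"))
  if (call$alt_reads < 3) return(list(qualified = FALSE, reason = "reads"))
  if (vaf < 0.03 || vaf > 0.40) return(list(qualified = FALSE, reason = "vaf"))
  ok <- consequence_qualifies(call, g)
  list(qualified = ok, reason = if (ok) "ok" else "consequence")
}

consequence_qualifies <- function(call, g) {
  is_ptv <- call$consequence %in% PTV_CLASSES
  hot <- is_hotspot(call, g$hotspots)
  switch(g$rule_class,
    whole_gene_ptv_plus_hotspot = is_ptv || hot,
    exon_restricted_ptv = is_ptv && !is.null(call$exon_number) &&
      !is.na(call$exon_number) && call$exon_number %in% g$allowed_exons,
    hotspot_only = hot)
}

is_hotspot <- function(call, hotspots) {
  if (length(hotspots) == 0L) return(FALSE)
  pc <- call$protein_change
  if (!is.null(pc) && !is.na(pc) && nzchar(pc)) return(pc %in% hotspots)
  key <- paste(call$chrom, call$pos, call$ref, call$alt, sep = ":")
  key %in% hotspots
}

# Vectorized verdicts over a somatic call table; returns character reasons.
classify_calls <- function(calls, rules) {
  calls <- data.table::as.data.table(calls)
  n <- nrow(calls)
  if (n == 0L) return(character())
  if (any(is.na(calls$depth) | calls$depth == 0))
    stop("malformed somatic record: depth is zero or missing")
  vaf <- if ("vaf" %in% names(calls)) calls$vaf else calls$alt_reads / calls$depth
  vaf[is.na(vaf)] <- (calls$alt_reads / calls$depth)[is.na(vaf)]
  reason <- rep("ok", n)
  in_panel <- calls$gene %in% names(rules$genes)
  conseq_ok <- logical(n)
  for (i in which(in_panel)) {
    conseq_ok[i] <- consequence_qualifies(as.list(calls[i]), rules$genes[[calls$gene[i]]])
  }
  reason[!conseq_ok] <- "consequence"
  reason[vaf < 0.03 | vaf > 0.40] <- "vaf"
  reason[calls$alt_reads < 3] <- "reads"
  reason[!in_panel] <- "panel"
  reason
}

#' Call per-individual CH status from somatic variant records
#'
#' Applies [classify_variant()] to every record and aggregates to one row
#' per cohort individual: an overall CH flag (the OR over gene flags) and
#' one logical column per panel gene. Individuals with no qualifying call
#' get an all-false row. Duplicate records (same sample, chrom, pos, alt)
#' are collapsed with a warning.
#'
#' @param calls data.frame of somatic calls (see [classify_variant()] for
#'   fields; `sample_id` required).
#' @param rules a [ch_rules()] object.
#' @param cohort_ids character/integer vector of all cohort individuals.
#' @return `data.table` with `sample_id`, `overall_ch`, and one column per
#'   gene; attribute `"audit"` holds the per-call verdict table.
#' @export
call_ch <- function(calls, rules, cohort_ids) {
  calls <- data.table::as.data.table(calls)
  if (nrow(calls) > 0 && !all(calls$sample_id %in% cohort_ids))
    stop("somatic calls reference sample ids absent from the cohort")
  if (nrow(calls) > 0) {
    key_cols <- intersect(c("sample_id", "chrom", "pos", "alt"), names(calls))
    dup <- duplicated(calls, by = key_cols)
    if (any(dup)) {
      warning(sum(dup), " duplicate somatic record(s) removed")
      calls <- calls[!dup]
    }
  }
  genes <- names(rules$genes)
  status <- data.table::data.table(sample_id = cohort_ids)
  for (g in genes) data.table::set(status, j = g, value = FALSE)
  audit <- data.table::copy(calls)
  if (nrow(calls) > 0) {
    audit$reason <- classify_calls(calls, rules)
    audit$qualified <- audit$reason == "ok"
    qual <- audit[audit$qualified]
    if (nrow(qual) > 0) {
      hit <- unique(qual[, c("sample_id", "gene")])
      for (g in unique(hit$gene)) {
        idx <- match(hit$sample_id[hit$gene == g], status$sample_id)
        data.table::set(status, i = idx, j = g, value = TRUE)
      }
    }
  } else {
    audit$reason <- character(); audit$qualified <- logical()
  }
  data.table::set(status, j = "overall_ch",
                  value = Reduce(`|`, as.list(status[, genes, with = FALSE])))
  data.table::setcolorder(status, c("sample_id", "overall_ch", genes))
  data.table::setattr(status, "audit", audit)
  status[]
}

#' Per-gene screen for association between driver mutations and age
#'
#' Fits, for each gene with at least `min_cases` mutated individuals, a
#' logistic regression of gene-specific CH on age (optionally sex) and
#' flags genes with OR > 1 per year at the configured significance level.
#'
#' @param status output of [call_ch()].
#' @param covariates data.frame with `sample_id`, `age`, optionally `sex`.
#' @param genes genes to test (default: all gene columns in `status`).
#' @param use_sex include sex as a covariate.
#' @param alpha significance threshold for the flag (default 0.05).
#' @param min_cases genes with fewer mutated individuals are skipped with a
#'   message (default 2).
#' @return `data.table`: gene, n_cases, or_per_year, ci_low, ci_high, p,
#'   age_associated.
#' @export
age_association_screen <- function(status, covariates, genes = NULL,
                                   use_sex = FALSE, alpha = 0.05,
                                   min_cases = 2L) {
  covariates <- data.table::as.data.table(covariates)
  dat <- merge(status, covariates, by = "sample_id")
  if (is.null(genes))
    genes <- setdiff(names(status), c("sample_id", "overall_ch"))
  out <- lapply(genes, function(g) {
    y <- dat[[g]]
    if (sum(y) < min_cases) {
      message("gene ", g, " skipped: ", sum(y), " case(s)")
      return(NULL)
    }
    fm <- if (use_sex) y ~ age + sex else y ~ age
    env <- list2env(list(y = y, age = dat$age, sex = dat$sex))
    fit <- stats::glm(fm, family = stats::binomial(), data = env)
    sm <- summary(fit)$coefficients
    b <- sm["age", "Estimate"]; se <- sm["age", "Std. Error"]
    data.table::data.table(
      gene = g, n_cases = sum(y), or_per_year = exp(b),
      ci_low = exp(b - 1.96 * se), ci_high = exp(b + 1.96 * se),
      p = sm["age", "Pr(>|z|)"],
      age_associated = exp(b) > 1 & sm["age", "Pr(>|z|)"] < alpha)
  })
  data.table::rbindlist(out)
}

#' CH frequency by group with Wilson confidence intervals
#'
#' @param status output of [call_ch()], or any data.frame with a logical
#'   `overall_ch` column (pass `outcome` to use a different flag).
#' @param covariates optional data.frame merged on `sample_id` to supply
#'   grouping columns.
#' @param by character vector of grouping columns (default: none — one
#'   overall row).
#' @param outcome name of the logical outcome column (default
#'   `"overall_ch"`).
#' @param compare optional length-2 list of values of the single `by`
#'   column; a chi-square test between those two groups is attached as
#'   attribute `"chisq"`.
#' @return `data.table`: group columns, n, cases, freq_pct, ci_low_pct,
#'   ci_high_pct. Empty groups carry `NA` frequency and `flagged = TRUE`.
#' @export
ch_frequency <- function(status, covariates = NULL, by = character(),
                         outcome = "overall_ch", compare = NULL) {
  dat <- data.table::as.data.table(status)
  if (!is.null(covariates))
    dat <- merge(dat, data.table::as.data.table(covariates), by = "sample_id")
  if (length(by) == 0L) {
    res <- dat[, freq_row(get(outcome))]
  } else {
    res <- dat[, freq_row(get(outcome)), by = by]
  }
  if (!is.null(compare)) {
    stopifnot(length(by) == 1L, length(compare) == 2L)
    tab <- sapply(compare, function(v) {
      y <- dat[get(by) == v][[outcome]]
      c(sum(y), sum(!y))
    })
    data.table::setattr(res, "chisq", stats::chisq.test(t(tab)))
  }
  res[]
}

freq_row <- function(y) {
  n <- length(y); cases <- sum(y)
  if (n == 0L) {
    return(data.table::data.table(n = 0L, cases = 0L, freq_pct = NA_real_,
                                  ci_low_pct = NA_real_, ci_high_pct = NA_real_,
                                  flagged = TRUE))
  }
  ci <- wilson_ci(cases, n)
  data.table::data.table(n = n, cases = cases, freq_pct = 100 * cases / n,
                         ci_low_pct = 100 * ci[1], ci_high_pct = 100 * ci[2],
                         flagged = FALSE)
}

#' Wilson score interval for a binomial proportion
#'
#' @param cases number of successes.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @return numeric length-2 vector (lower, upper) on the proportion scale.
#' @export
wilson_ci <- function(cases, n, conf = 0.95) {
  if (n == 0L) return(c(NA_real_, NA_real_))
  if (cases == 0L || cases == n) {
    # prop.test is undefined at the boundary only through its chi-square;
    # the Wilson formula itself is fine there
    z <- stats::qnorm(1 - (1 - conf) / 2)
    p <- cases / n
    ctr <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    return(c(max(0, ctr - hw), min(1, ctr + hw)))
  }
  as.numeric(stats::prop.test(cases, n, conf.level = conf,
                              correct = FALSE)$conf.int)
}
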
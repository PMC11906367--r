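#' Load the qualifying-variant model registry
#'
#' The 11 models select rare germline variants for gene-level collapsing by
#' consequence class, global and per-ancestry MAF tiers, REVEL score and
#' Missense Tolerance Ratio. They ship as editable JSON so thresholds are
#' auditable. All models are dominant except `rec`, which is recessive.
#'
#' @param path optional path to a registry JSON (defaults to the shipped
#'   one).
#' @return named list of model specs (class `qv_registry`).
#' @export
qv_models <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "qv_models.json", package = "chancestry",
                        mustWork = TRUE)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  models <- stats::setNames(raw$models,
                            vapply(raw$models, `[[`, "", "name"))
  for (m in models) {
    if ((m$genetic_model == "recessive") != (m$name == "rec"))
      stop("only the rec model may be recessive")
  }
  structure(models, class = "qv_registry")
}

NONSYN_CLASSES <- c("missense", "inframe_indel", PTV_CLASSES)

#' Select qualifying variants for one model
#'
#' A variant qualifies iff every gate of the model passes: consequence
#' class, global MAF, per-ancestry MAF (the maximum over the `maf_anc`
#' columns), REVEL minimum and the MTR gate (MTR < 0.78 or MTR centile
#' < 50). Missing REVEL/MTR fails the corresponding gate. Composite models
#' qualify a variant iff it qualifies under either component. Variants
#' with an unknown consequence class are excluded with a warning.
#'
#' @param meta annotation `data.table`: `variant_id`, `gene`,
#'   `consequence`, `maf_global`, per-ancestry `maf_*` columns, `revel`,
#'   `mtr`, `mtr_centile`.
#' @param model one element of [qv_models()], or a model name.
#' @param registry the registry to resolve names/components against.
#' @return character vector of qualifying `variant_id`s.
#' @export
qualify_variants <- function(meta, model, registry = qv_models()) {
  if (is.character(model)) model <- registry[[model]]
  if (is.null(model)) stop("unknown qualifying-variant model")
  meta <- data.table::as.data.table(meta)
  known <- c("synonymous", "other", NONSYN_CLASSES)
  bad <- !meta$consequence %in% known
  if (any(bad)) {
    warning(sum(bad), " variant(s) with unknown consequence class excluded")
    meta <- meta[!bad]
  }
  if (model$consequence == "composite") {
    ids <- unique(unlist(lapply(model$components, function(cn)
      qualify_variants(meta, registry[[cn]], registry))))
    return(ids)
  }
  ok <- switch(model$consequence,
    synonymous = meta$consequence == "synonymous",
    missense = meta$consequence == "missense",
    nonsynonymous = meta$consequence %in% NONSYN_CLASSES,
    ptv = meta$consequence %in% PTV_CLASSES)
  if (!is.null(model$maf_global_max))
    ok <- ok & !is.na(meta$maf_global) & meta$maf_global <= model$maf_global_max
  if (!is.null(model$maf_ancestry_max)) {
    anc_cols <- grep("^maf_(?!global)", names(meta), value = TRUE, perl = TRUE)
    if (length(anc_cols) > 0) {
      anc_max <- do.call(pmax, c(meta[, anc_cols, with = FALSE], na.rm = TRUE))
      ok <- ok & !is.na(anc_max) & anc_max <= model$maf_ancestry_max
    }
  }
  if (!is.null(model$revel_min))
    ok <- ok & !is.na(meta$revel) & meta$revel >= model$revel_min
  if (isTRUE(model$mtr_gate)) {
    mtr_ok <- (!is.na(meta$mtr) & meta$mtr < 0.78) |
      (!is.na(meta$mtr_centile) & meta$mtr_centile < 50)
    ok <- ok & mtr_ok
  }
  meta$variant_id[ok]
}

#' Per-gene carrier status under a genetic model
#'
#' Dominant: carrier iff the summed qualifying-allele dosage in the gene is
#' >= 1. Recessive: >= 2 (a homozygote, or two heterozygous qualifying
#' variants in the same gene — phase is not used). Missing genotypes count
#' as 0.
#'
#' @param geno hard-call dosage matrix (individuals x variants, named
#'   columns).
#' @param meta annotation table mapping `variant_id` to `gene`.
#' @param qualifying character vector of qualifying variant ids.
#' @param genetic_model `"dominant"` or `"recessive"`.
#' @return logical matrix individuals x genes.
#' @export
carrier_status <- function(geno, meta, qualifying,
                           genetic_model = c("dominant", "recessive")) {
  genetic_model <- match.arg(genetic_model)
  meta <- data.table::as.data.table(meta)
  qual <- meta[meta$variant_id %in% qualifying]
  genes <- sort(unique(qual$gene))
  out <- matrix(FALSE, nrow = nrow(geno), ncol = length(genes),
                dimnames = list(rownames(geno), genes))
  thr <- if (genetic_model == "dominant") 1 else 2
  for (g in genes) {
    vs <- intersect(qual$variant_id[qual$gene == g], colnames(geno))
    if (length(vs) == 0) next
    dose <- rowSums(geno[, vs, drop = FALSE], na.rm = TRUE)
    out[, g] <- dose >= thr
  }
  out
}

#' Gene-level collapsing test
#'
#' Fisher's exact two-sided test on the 2x2 carrier-by-case table for each
#' gene; OR is the cross-product ratio with a Haldane–Anscombe 0.5
#' correction on zero cells.
#'
#' @param carriers logical matrix individuals x genes (see
#'   [carrier_status()]).
#' @param pheno binary phenotype aligned with rows.
#' @param threshold study-wide significance threshold (default 1e-8).
#' @return `data.table`: gene, carriers_cases, carriers_controls, n_cases,
#'   n_controls, or, ci_low, ci_high, p, significant, untestable.
#' @export
collapsing_test <- function(carriers, pheno, threshold = 1e-8) {
  y <- as.numeric(pheno)
  out <- lapply(colnames(carriers), function(g) {
    cc <- carriers[, g]
    a <- sum(cc & y == 1); b <- sum(!cc & y == 1)
    c_ <- sum(cc & y == 0); d <- sum(!cc & y == 0)
    if (a + c_ == 0) {
      return(data.table::data.table(
        gene = g, carriers_cases = a, carriers_controls = c_,
        n_cases = a + b, n_controls = c_ + d, or = NA_real_,
        ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
        significant = FALSE, untestable = TRUE))
    }
    tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
    p <- stats::fisher.test(tab)$p.value
    hc <- if (any(tab == 0)) 0.5 else 0
    or <- ((a + hc) * (d + hc)) / ((b + hc) * (c_ + hc))
    se <- sqrt(sum(1 / (tab + hc)))
    data.table::data.table(
      gene = g, carriers_cases = a, carriers_controls = c_,
      n_cases = a + b, n_controls = c_ + d, or = or,
      ci_low = exp(log(or) - 1.96 * se), ci_high = exp(log(or) + 1.96 * se),
      p = p, significant = p < threshold, untestable = FALSE)
  })
  data.table::rbindlist(out)
}

#' Cochran–Mantel–Haenszel meta-analysis of stratified 2x2 tables
#'
#' Combines per-study carrier-by-case tables for one gene. The common OR
#' is the Mantel–Haenszel estimator `sum(a_i d_i / n_i) / sum(b_i c_i /
#' n_i)` with a Robins–Breslow–Greenland confidence interval; the
#' chi-square statistic is
#' `(|sum(a_i) - sum(E_i)| - cc)^2 / sum(V_i)` with the hypergeometric
#' mean and variance per stratum, continuity correction `cc` off by
#' default (matching `stats::mantelhaen.test(correct = FALSE)`). Strata
#' with a zero margin contribute nothing.
#'
#' @param tables list of 2x2 matrices `rbind(c(a, b), c(c, d))` with rows =
#'   carrier/non-carrier and columns = case/control (one per study), or a
#'   `2 x 2 x k` array.
#' @param correct continuity correction (default FALSE).
#' @return one-row `data.table`: or_mh, ci_low, ci_high, chisq, p,
#'   n_strata, untestable.
#' @export
cmh_meta <- function(tables, correct = FALSE) {
  if (is.array(tables) && length(dim(tables)) == 3) {
    tables <- lapply(seq_len(dim(tables)[3]), function(i) tables[, , i])
  }
  ok <- vapply(tables, function(t)
    all(dim(t) == c(2, 2)) &&
      all(rowSums(t) > 0) && all(colSums(t) > 0), logical(1))
  tabs <- tables[ok]
  if (length(tabs) == 0) {
    return(data.table::data.table(
      or_mh = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
      chisq = NA_real_, p = NA_real_, n_strata = 0L, untestable = TRUE))
  }
  st <- vapply(tabs, function(t) {
    n <- sum(t)
    c(a = t[1, 1],
      e = rowSums(t)[1] * colSums(t)[1] / n,
      v = prod(rowSums(t)) * prod(colSums(t)) / (n^2 * (n - 1)),
      r = t[1, 1] * t[2, 2] / n,
      s = t[1, 2] * t[2, 1] / n,
      pr = (t[1, 1] + t[2, 2]) / n * t[1, 1] * t[2, 2] / n,
      ps = (t[1, 1] + t[2, 2]) / n * t[1, 2] * t[2, 1] / n,
      qr = (t[1, 2] + t[2, 1]) / n * t[1, 1] * t[2, 2] / n,
      qs = (t[1, 2] + t[2, 1]) / n * t[1, 2] * t[2, 1] / n)
  }, numeric(9))
  sums <- rowSums(st)
  or_mh <- if (sums[["s"]] == 0) Inf else sums[["r"]] / sums[["s"]]
  cc <- if (correct) 0.5 else 0
  chisq <- (abs(sums[["a"]] - sums[["e"]]) - cc)^2 / sums[["v"]]
  # Robins-Breslow-Greenland variance of log OR_MH
  ci <- c(NA_real_, NA_real_)
  if (is.finite(or_mh) && or_mh > 0 && sums[["r"]] > 0 && sums[["s"]] > 0) {
    var_log <- sums[["pr"]] / (2 * sums[["r"]]^2) +
      (sums[["ps"]] + sums[["qr"]]) / (2 * sums[["r"]] * sums[["s"]]) +
      sums[["qs"]] / (2 * sums[["s"]]^2)
    ci <- exp(log(or_mh) + c(-1.96, 1.96) * sqrt(var_log))
  }
  data.table::data.table(
    or_mh = or_mh, ci_low = ci[1], ci_high = ci[2],
    chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE),
    n_strata = length(tabs), untestable = FALSE)
}

#' Run the full collapsing analysis for a set of models
#'
#' @param geno hard-call dosage matrix.
#' @param meta annotation table (see [qualify_variants()]).
#' @param pheno binary phenotype.
#' @param models model names (default: all in the registry).
#' @param registry a [qv_models()] registry.
#' @param threshold study-wide significance threshold (default 1e-8).
#' @return `data.table` stacking [collapsing_test()] output per model.
#' @export
collapse_genes <- function(geno, meta, pheno, models = NULL,
                           registry = qv_models(), threshold = 1e-8) {
  if (is.null(models)) models <- names(registry)
  out <- lapply(models, function(mn) {
    m <- registry[[mn]]
    q <- qualify_variants(meta, m, registry)
    if (length(q) == 0) return(NULL)
    carr <- carrier_status(geno, meta, q, m$genetic_model)
    res <- collapsing_test(carr, pheno, threshold)
    res$model <- mn
    res
  })
  data.table::rbindlist(out, use.names = TRUE)
}
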
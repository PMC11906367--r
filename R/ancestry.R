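#' Local-ancestry mosaics
#'
#' A `la_mosaic` holds, for each individual and haplotype, an ancestry code
#' per genomic window: `windows` is a `data.table` (chrom, spos, epos;
#' 0-based half-open), `hap` is an integer matrix `[n_windows x 2n]` with
#' haplotype columns paired per individual, `labels` maps codes to ancestry
#' names, and `ids` names the individuals. The constructor checks that the
#' windows tile the span without gaps or overlaps.
#'
#' @param windows data.frame with `chrom`, `spos`, `epos`.
#' @param hap integer code matrix, `n_windows` rows, `2 * length(ids)`
#'   columns.
#' @param labels character vector mapping codes 1..k to ancestry labels.
#' @param ids individual identifiers.
#' @return object of class `la_mosaic`.
#' @export
la_mosaic <- function(windows, hap, labels = c("AMR", "EUR", "AFR"), ids) {
  windows <- data.table::as.data.table(windows)
  hap <- as.matrix(hap)
  if (nrow(windows) != nrow(hap))
    stop("hap must have one row per window")
  if (ncol(hap) != 2L * length(ids))
    stop("hap must have two columns per individual")
  for (cr in unique(windows$chrom)) {
    w <- windows[windows$chrom == cr][order(spos)]
    if (nrow(w) > 1 && any(w$spos[-1] != w$epos[-nrow(w)])) {
      i <- which(w$spos[-1] != w$epos[-nrow(w)])[1]
      stop(sprintf("gap or overlap in mosaic windows on %s at position %d",
                   cr, w$epos[i]))
    }
  }
  structure(list(windows = windows, hap = hap, labels = labels, ids = ids),
            class = "la_mosaic")
}

#' Global ancestry fractions from a local-ancestry mosaic
#'
#' The fraction for ancestry A is the total base-pairs labelled A across
#' both haplotypes divided by twice the span length (base-pair-weighted,
#' not window-count-weighted, since windows may differ in length).
#'
#' @param mosaic a `la_mosaic`.
#' @return `data.table`: sample_id plus one fraction column per ancestry
#'   label; rows sum to 1.
#' @export
global_ancestry_fractions <- function(mosaic) {
  stopifnot(inherits(mosaic, "la_mosaic"))
  len <- as.numeric(mosaic$windows$epos - mosaic$windows$spos)
  span2 <- 2 * sum(len)
  n <- length(mosaic$ids)
  out <- data.table::data.table(sample_id = mosaic$ids)
  for (k in seq_along(mosaic$labels)) {
    bp <- crossprod(len, mosaic$hap == k)          # 1 x 2n
    out[[paste0("frac_", mosaic$labels[k])]] <-
      as.numeric(bp[seq(1, 2 * n, 2)] + bp[seq(2, 2 * n, 2)]) / span2
  }
  out[]
}

#' Ancestry fraction over a query interval, per haplotype
#'
#' Overlap-weighted fraction of the query interval assigned to `ancestry`
#' on each haplotype, using the mosaic windows intersecting the query.
#'
#' @param mosaic a `la_mosaic`.
#' @param chrom,start,end query interval (0-based half-open).
#' @param ancestry ancestry label (default `"EUR"`).
#' @return numeric matrix `[n x 2]` of fractions, rows named by individual.
#' @export
interval_ancestry <- function(mosaic, chrom, start, end, ancestry = "EUR") {
  stopifnot(inherits(mosaic, "la_mosaic"))
  if (end <= start) stop("query interval is empty")
  w <- mosaic$windows
  ov <- pmin(w$epos, end) - pmax(w$spos, start)
  ov[w$chrom != chrom] <- 0
  ov <- pmax(ov, 0)
  if (sum(ov) == 0) stop("query interval does not overlap the mosaic span")
  k <- match(ancestry, mosaic$labels)
  if (is.na(k)) stop("unknown ancestry label: ", ancestry)
  bp <- as.numeric(crossprod(ov, mosaic$hap == k)) / sum(ov)
  n <- length(mosaic$ids)
  matrix(bp, nrow = n, ncol = 2, byrow = TRUE,
         dimnames = list(mosaic$ids, c("hap0", "hap1")))
}

#' Categorize a diplotype by mean European ancestry
#'
#' The two allele fractions are averaged and binned: European homozygous
#' (mean >= 0.95, additive code 2), European heterozygous (0.45–0.55,
#' code 1), non-European homozygous (<= 0.05, code 0, the reference group);
#' anything else is unassigned (code `NA`) and excluded from the additive
#' model.
#'
#' @param frac0,frac1 European ancestry fractions of the two alleles
#'   (vectors of equal length).
#' @return `data.table`: mean_eur, category, code.
#' @export
categorize_diplotype <- function(frac0, frac1) {
  stopifnot(length(frac0) == length(frac1),
            all(frac0 >= 0 & frac0 <= 1), all(frac1 >= 0 & frac1 <= 1))
  m <- (frac0 + frac1) / 2
  cat <- rep("unassigned", length(m))
  cat[m >= 0.95] <- "eur_hom"
  cat[m >= 0.45 & m <= 0.55] <- "eur_het"
  cat[m <= 0.05] <- "noneur_hom"
  code <- c(eur_hom = 2L, eur_het = 1L, noneur_hom = 0L,
            unassigned = NA_integer_)[cat]
  data.table::data.table(mean_eur = m, category = cat, code = unname(code))
}

#' Exact covariate matching between two cohorts
#'
#' Exact matching within strata (age in 1-year bins crossed with the other
#' keys). Within each stratum min(nA, ratio * nB-capacity) pairs are drawn
#' without replacement under a fixed seed; strata present in only one
#' cohort are dropped. Stratum labels are preserved for stratified tests.
#'
#' @param cov_a,cov_b covariate data.frames with `sample_id` and the key
#'   columns.
#' @param keys matching keys (default `c("age", "sex")`; `"smoking"` may be
#'   added).
#' @param ratio controls-per-case matching ratio (default 1).
#' @param seed RNG seed for within-stratum sampling.
#' @return `data.table`: stratum, id_a, id_b (ratio > 1 yields multiple
#'   rows per id_a).
#' @export
match_cohorts <- function(cov_a, cov_b, keys = c("age", "sex"), ratio = 1L,
                          seed = 1L) {
  stopifnot(ratio >= 1)
  a <- data.table::as.data.table(cov_a)
  b <- data.table::as.data.table(cov_b)
  stratum_of <- function(d) {
    parts <- lapply(keys, function(k) {
      if (k == "age") as.character(floor(d$age)) else as.character(d[[k]])
    })
    do.call(paste, c(parts, sep = "|"))
  }
  a$stratum <- stratum_of(a)
  b$stratum <- stratum_of(b)
  shared <- intersect(unique(a$stratum), unique(b$stratum))
  if (length(shared) == 0) stop("no overlapping matching strata")
  set.seed(seed)
  out <- lapply(shared, function(s) {
    ia <- a$sample_id[a$stratum == s]
    ib <- b$sample_id[b$stratum == s]
    n_pairs <- min(length(ia), floor(length(ib) / ratio))
    if (n_pairs == 0) return(NULL)
    ia <- sample(ia, n_pairs)
    ib <- sample(ib, n_pairs * ratio)
    data.table::data.table(stratum = s,
                           id_a = rep(ia, each = ratio), id_b = ib)
  })
  data.table::rbindlist(out)
}

#' Logistic CH risk model over cohort, ancestry or PRS predictors
#'
#' Fits a logistic regression of a binary outcome on one main predictor —
#' a cohort label, a continuous European fraction, a binned European
#' fraction (left-closed bins of width `bin_width`, lowest bin as
#' reference), a diplotype additive code, or a polygenic score — adjusted
#' for any covariate subset. Ordinary maximum likelihood by default; Firth
#' penalization on request, or automatically when separation is detected
#' (the refit is flagged).
#'
#' @param data data.frame holding outcome, predictor and covariates.
#' @param outcome name of the binary outcome column.
#' @param predictor name of the main predictor column.
#' @param covariates names of adjustment columns (character vector).
#' @param firth use Firth penalized fit.
#' @param binned bin the predictor into left-closed bins of `bin_width`
#'   with the lowest bin as reference.
#' @param bin_width bin width on the predictor scale (default 0.10).
#' @return `data.table`: term, estimate (log-odds), se, or, ci_low,
#'   ci_high, p, n, n_cases, method.
#' @export
cohort_risk_model <- function(data, outcome, predictor, covariates = character(),
                              firth = FALSE, binned = FALSE, bin_width = 0.10) {
  d <- data.table::as.data.table(data)
  y <- d[[outcome]]
  if (is.logical(y)) y <- as.numeric(y)
  if (is.factor(y) || is.character(y)) y <- as.numeric(factor(y)) - 1
  if (length(unique(y)) < 2) stop("outcome is constant")
  xp <- d[[predictor]]
  if (binned) {
    br <- seq(0, 1 + bin_width, by = bin_width)
    xp <- droplevels(cut(xp, breaks = br, right = FALSE, include.lowest = TRUE))
    xp <- stats::relevel(xp, ref = levels(xp)[1])
  } else if (is.character(xp)) {
    xp <- factor(xp)
  }
  mm_terms <- c(predictor, covariates)
  mf <- data.frame(.y = y, .p = xp, check.names = FALSE)
  for (cv in covariates) mf[[cv]] <- d[[cv]]
  X <- stats::model.matrix(
    stats::reformulate(c(".p", covariates)), data = mf)[, -1, drop = FALSE]
  method <- if (firth) "firth" else "logistic"
  flagged <- FALSE
  if (!firth) {
    fit <- withCallingHandlers(
      stats::glm(y ~ X, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          flagged <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (flagged || !fit$converged || any(abs(stats::coef(fit)[-1]) > 15,
                                         na.rm = TRUE)) {
      method <- "firth_refit"
      ff <- firth_logistic_fit(y, X, p_method = "wald")
      est <- ff$coef[-1]; se <- ff$se[-1]; pv <- ff$p[-1]
    } else {
      sm <- summary(fit)$coefficients[-1, , drop = FALSE]
      est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]; pv <- sm[, "Pr(>|z|)"]
      names(est) <- names(se) <- names(pv) <- colnames(X)
    }
  } else {
    ff <- firth_logistic_fit(y, X, p_method = "lrt")
    est <- ff$coef[-1]; se <- ff$se[-1]; pv <- ff$p[-1]
  }
  terms <- sub("^X", "", names(est))
  terms <- sub("^\\.p", predictor, terms)
  data.table::data.table(
    term = terms, estimate = unname(est), se = unname(se),
    or = exp(unname(est)),
    ci_low = exp(unname(est) - 1.96 * unname(se)),
    ci_high = exp(unname(est) + 1.96 * unname(se)),
    p = unname(pv), n = length(y), n_cases = sum(y == 1), method = method)
}

#' Read an RFMix MSP-like local-ancestry file
#'
#' Expects a first comment line `#Subpopulation order/codes: AMR=0 EUR=1
#' AFR=2`, a header line, and columns chrom, spos, epos followed by two
#' haplotype code columns per individual (`<id>.0`, `<id>.1`).
#'
#' @param path file path.
#' @return a `la_mosaic`.
#' @export
read_msp <- function(path) {
  first <- readLines(path, n = 1)
  labmap <- regmatches(first, gregexpr("([A-Za-z]+)=([0-9]+)", first))[[1]]
  codes <- as.integer(sub(".*=", "", labmap))
  labels <- sub("=.*", "", labmap)
  labels <- labels[order(codes)]
  dt <- data.table::fread(path, skip = 1)
  hapcols <- names(dt)[-(1:3)]
  ids <- unique(sub("\\.[01]$", "", hapcols))
  hap <- as.matrix(dt[, -(1:3)]) + 1L      # file codes 0-based
  la_mosaic(windows = dt[, 1:3][, stats::setNames(.SD, c("chrom", "spos", "epos"))],
            hap = hap, labels = labels, ids = ids)
}

#' Write a `la_mosaic` as an RFMix MSP-like TSV
#'
#' @param mosaic a `la_mosaic`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msp <- function(mosaic, path) {
  hdr <- paste0("#Subpopulation order/codes: ",
                paste0(mosaic$labels, "=", seq_along(mosaic$labels) - 1L,
                       collapse = " "))
  cols <- as.vector(t(outer(mosaic$ids, c(".0", ".1"), paste0)))
  dt <- data.table::data.table(mosaic$windows)
  body <- data.table::as.data.table(mosaic$hap - 1L)
  data.table::setnames(body, cols)
  writeLines(hdr, path)
  data.table::fwrite(cbind(dt, body), path, sep = "\t", append = TRUE,
                     col.names = TRUE)
  invisible(path)
}
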
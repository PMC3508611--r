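# Normalized expression (reads per million clean reads), fold changes,
# Audic-Claverie count significance, differential calls, and the Livak
# delta-delta-CT qPCR contract.

#' Normalized expression level (reads per million clean reads)
#'
#' @param count read count(s) assigned to a feature.
#' @param total_clean_reads library sequencing depth (clean reads).
#' @return `count / total_clean_reads * 1e6`. Summed over all tags of a
#'   library this is exactly 1e6.
#' @export
normalize_nel <- function(count, total_clean_reads) {
  if (any(total_clean_reads <= 0)) stop("total_clean_reads must be > 0")
  count / total_clean_reads * 1e6
}

#' Fold change between two normalized expression levels
#'
#' @param nel_a,nel_b normalized expression in libraries a and b (vectors
#'   recycle).
#' @param names_ab names reported in `direction` (default `c("a", "b")`).
#' @return data frame with `fc` (= max/min, so always >= 1) and `direction`
#'   (side with the larger NEL). Both zero gives `fc = NA`.
#' @export
fold_change <- function(nel_a, nel_b, names_ab = c("a", "b")) {
  hi <- pmax(nel_a, nel_b)
  lo <- pmin(nel_a, nel_b)
  fc <- ifelse(hi == 0, NA_real_, hi / lo)
  direction <- ifelse(hi == 0, NA_character_,
                      ifelse(nel_a >= nel_b, names_ab[1L], names_ab[2L]))
  data.frame(fc = fc, direction = direction, stringsAsFactors = FALSE)
}

#' Audic-Claverie significance of a two-library count difference
#'
#' Under equal relative abundance the posterior distribution of the second
#' library's count y given the first library's count x is negative binomial
#' with size x + 1 and success probability n1 / (n1 + n2). The two-sided
#' p-value is 2 x min(lower tail, upper tail), capped at 1.
#'
#' @param count_a,count_b feature counts in the two libraries (vectorized).
#' @param total_a,total_b library depths.
#' @return two-sided p-value(s) in (0, 1].
#' @export
count_significance <- function(count_a, total_a, count_b, total_b) {
  if (any(total_a <= 0) || any(total_b <= 0)) stop("totals must be > 0")
  prob <- total_a / (total_a + total_b)
  lower <- pnbinom(count_b, size = count_a + 1, prob = prob)
  upper <- 1 - pnbinom(count_b - 1, size = count_a + 1, prob = prob)
  pmin(1, 2 * pmin(lower, upper))
}

#' Score and call differentially expressed miRNAs between two libraries
#'
#' Computes per-feature NEL in both libraries, the fold change (max/min with
#' its direction), the Audic-Claverie p-value and its Benjamini-Hochberg FDR,
#' and flags features passing `fc >= min_fc` and `p <= alpha`. Features with a
#' zero count in one library get their fold change from a half-minimum
#' pseudo-NEL (reporting only; the significance test always uses the raw
#' counts). Features with zero counts in both libraries are dropped.
#'
#' @param counts count table: `feature_id` plus exactly two library columns.
#' @param totals named numeric of clean-read depths for the two libraries
#'   (defaults to the column sums of `counts`).
#' @param min_fc fold-change gate (default 2).
#' @param alpha p-value gate (default 0.01).
#' @param method `"audic-claverie"` (default) or `"proportion"` (two-sided
#'   two-proportion z-test).
#' @return data frame with one row per retained feature: `mirna_id`, per
#'   library `nel_*`, `fc`, `direction`, `p_value`, `fdr`, `significant`.
#'   Row order follows sorted `feature_id`, so output is independent of input
#'   record order.
#' @export
differential_expression <- function(counts, totals = NULL, min_fc = 2,
                                    alpha = 0.01,
                                    method = c("audic-claverie",
                                               "proportion")) {
  method <- match.arg(method)
  libs <- setdiff(names(counts), "feature_id")
  if (length(libs) != 2L) stop("counts must have exactly two library columns")
  if (is.null(totals)) {
    totals <- setNames(colSums(counts[, libs, drop = FALSE]), libs)
  }
  stopifnot(all(libs %in% names(totals)))
  counts <- counts[order(counts$feature_id, method = "radix"), , drop = FALSE]
  a <- counts[[libs[1L]]]
  b <- counts[[libs[2L]]]
  keep <- a + b > 0
  counts <- counts[keep, , drop = FALSE]
  a <- a[keep]
  b <- b[keep]
  nel_a <- normalize_nel(a, totals[[libs[1L]]])
  nel_b <- normalize_nel(b, totals[[libs[2L]]])
  # half-minimum pseudo-NEL for reporting fold changes with one zero side
  pos <- c(nel_a[nel_a > 0], nel_b[nel_b > 0])
  pseudo <- if (length(pos)) min(pos) / 2 else NA_real_
  fc <- fold_change(pmax(nel_a, pseudo * (nel_a == 0)),
                    pmax(nel_b, pseudo * (nel_b == 0)),
                    names_ab = libs)
  p <- switch(method,
    "audic-claverie" = count_significance(a, totals[[libs[1L]]],
                                          b, totals[[libs[2L]]]),
    "proportion" = {
      vapply(seq_along(a), function(i) {
        suppressWarnings(stats::prop.test(
          c(a[i], b[i]), c(totals[[libs[1L]]], totals[[libs[2L]]])))$p.value
      }, numeric(1))
    })
  out <- data.frame(mirna_id = counts$feature_id,
                    nel_a = nel_a, nel_b = nel_b,
                    fc = fc$fc, direction = fc$direction,
                    p_value = p, fdr = p.adjust(p, "BH"),
                    stringsAsFactors = FALSE)
  names(out)[names(out) == "nel_a"] <- paste0("nel_", libs[1L])
  names(out)[names(out) == "nel_b"] <- paste0("nel_", libs[2L])
  out$significant <- out$fc >= min_fc & out$p_value <= alpha
  rownames(out) <- NULL
  out
}

#' Filter scored records to differential calls
#'
#' @param records data frame from [differential_expression()].
#' @param min_fc,alpha gates (defaults 2 and 0.01).
#' @return `records` rows with `fc >= min_fc` and `p_value <= alpha`.
#' @export
call_differential <- function(records, min_fc = 2, alpha = 0.01) {
  records[!is.na(records$fc) & records$fc >= min_fc &
            records$p_value <= alpha, , drop = FALSE]
}

#' Livak comparative-CT relative quantity
#'
#' RQ = 2^-((ct_target - ct_reference) - (ct_target_calibrator -
#' ct_reference_calibrator)).
#'
#' @param ct_target,ct_reference CT of the target and reference assays in the
#'   sample of interest.
#' @param ct_target_calibrator,ct_reference_calibrator CT of the same assays
#'   in the calibrator sample.
#' @return relative quantity (1 when delta-delta-CT is 0).
#' @export
ddct_relative_quantity <- function(ct_target, ct_reference,
                                   ct_target_calibrator,
                                   ct_reference_calibrator) {
  ddct <- (ct_target - ct_reference) -
    (ct_target_calibrator - ct_reference_calibrator)
  2^(-ddct)
}

#' Relative quantities for a CT table
#'
#' @param ct data frame with columns `sample`, `condition`, `assay`, `ct`.
#' @param reference_assay normalizer assay id (e.g. `"U6"`).
#' @param calibrator_condition condition whose mean delta-CT per assay is the
#'   calibrator (default: first condition in the table).
#' @return data frame with per-sample `rq` per assay plus per-condition mean
#'   RQ; the reference assay's RQ is 1 in every sample by construction.
#' @export
qpcr_relative_quantity <- function(ct, reference_assay = "U6",
                                   calibrator_condition = NULL) {
  stopifnot(all(c("sample", "condition", "assay", "ct") %in% names(ct)))
  if (!reference_assay %in% ct$assay) {
    stop("reference assay not in table: ", reference_assay)
  }
  if (is.null(calibrator_condition)) {
    calibrator_condition <- ct$condition[1L]
  }
  ref <- ct[ct$assay == reference_assay, c("sample", "ct")]
  names(ref)[2L] <- "ct_ref"
  m <- merge(ct, ref, by = "sample")
  m$dct <- m$ct - m$ct_ref
  cal <- m[m$condition == calibrator_condition, ]
  cal_dct <- tapply(cal$dct, cal$assay, mean)
  m$rq <- 2^(-(m$dct - cal_dct[m$assay]))
  m <- m[order(m$assay, m$condition, m$sample), ]
  rownames(m) <- NULL
  m[, c("sample", "condition", "assay", "ct", "dct", "rq")]
}
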
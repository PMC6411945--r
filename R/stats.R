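#' Mean, standard error and count
#'
#' @param values numeric vector (non-empty; SEM needs n >= 2 and is `NA`
#'   for a single value)
#' @return list with `mean`, `sem` (sample sd / sqrt(n)) and `n`
#' @export
summarize <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("empty input")
  n <- length(values)
  list(mean = mean(values),
       sem = if (n >= 2) stats::sd(values) / sqrt(n) else NA_real_,
       n = n)
}

#' Two-sided two-sample test
#'
#' Default is Welch's unequal-variance t-test (Welch-Satterthwaite degrees
#' of freedom); `method = "wilcoxon"` gives a Mann-Whitney U test instead.
#' Two samples with zero variance and equal values give `t = 0, p = 1` by
#' convention.
#'
#' @param a,b numeric samples (each n >= 2)
#' @param method `"welch"` (default) or `"wilcoxon"`
#' @return list with `statistic`, `p_value`, `method`
#' @export
ttest_two_tailed <- function(a, b, method = c("welch", "wilcoxon")) {
  method <- match.arg(method)
  if (length(a) < 2 || length(b) < 2) stop("each sample needs n >= 2")
  if (method == "wilcoxon") {
    w <- stats::wilcox.test(a, b, alternative = "two.sided", exact = FALSE,
                            correct = TRUE)
    return(list(statistic = unname(w$statistic), p_value = w$p.value,
                method = "wilcoxon"))
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(list(statistic = 0, p_value = 1, method = "welch"))
    return(list(statistic = sign(mean(a) - mean(b)) * Inf, p_value = 0,
                method = "welch"))
  }
  tt <- stats::t.test(a, b, alternative = "two.sided", var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       method = "welch")
}

#' Build a Ct table for fold-change computation
#'
#' @param gene,condition,replicate,ct,is_reference equal-length vectors;
#'   `condition` must use the labels `"control"` and `"treated"`; exactly
#'   one gene is flagged as the reference
#' @return validated data.frame of class `CtTable`
#' @export
ct_table <- function(gene, condition, replicate, ct, is_reference) {
  tab <- data.frame(gene = as.character(gene),
                    condition = as.character(condition),
                    replicate = as.integer(replicate),
                    ct = as.numeric(ct),
                    is_reference = as.logical(is_reference),
                    stringsAsFactors = FALSE)
  if (!all(tab$condition %in% c("control", "treated")))
    stop("condition labels must be 'control' or 'treated'")
  refs <- unique(tab$gene[tab$is_reference])
  if (length(refs) != 1)
    stop("exactly one reference gene must be flagged")
  for (g in unique(tab$gene))
    for (cond in c("control", "treated"))
      if (!any(tab$gene == g & tab$condition == cond))
        stop(sprintf("gene '%s' missing in condition '%s'", g, cond))
  class(tab) <- c("CtTable", "data.frame")
  tab
}

#' qPCR fold change by the 2^-ddCt method
#'
#' For each gene of interest g: `dCt(condition) = mean Ct_g - mean Ct_ref`
#' within the condition, `ddCt = dCt(treated) - dCt(control)`, and
#' `fold = 2^-ddCt`, i.e. expression of the treated condition relative to
#' control after normalization to the reference gene.  Adding any constant
#' to every Ct (a machine offset) leaves the folds unchanged.
#'
#' With `per_replicate = TRUE`, replicates are paired by index across genes
#' within each condition and a per-replicate fold distribution is derived
#' (treated replicate dCt against the control-condition mean dCt), giving
#' the SEM over replicates.
#'
#' @param table a [ct_table()]
#' @param per_replicate also emit per-replicate folds (default TRUE)
#' @return data.frame, one row per gene of interest: `gene`, `ddct`,
#'   `fold`, and with `per_replicate` also `fold_sem`, `n_replicates`
#' @export
ddct_fold_change <- function(table, per_replicate = TRUE) {
  stopifnot(inherits(table, "CtTable"))
  ref <- unique(table$gene[table$is_reference])
  goi <- setdiff(unique(table$gene), ref)
  ref_mean <- function(cond)
    mean(table$ct[table$gene == ref & table$condition == cond])
  rows <- lapply(goi, function(g) {
    dct <- function(cond)
      mean(table$ct[table$gene == g & table$condition == cond]) -
        ref_mean(cond)
    ddct <- dct("treated") - dct("control")
    out <- data.frame(gene = g, ddct = ddct, fold = 2^(-ddct),
                      stringsAsFactors = FALSE)
    if (per_replicate) {
      tr <- table[table$gene == g & table$condition == "treated", ]
      rf <- table[table$gene == ref & table$condition == "treated", ]
      common <- intersect(tr$replicate, rf$replicate)
      if (length(common) >= 2) {
        dct_rep <- tr$ct[match(common, tr$replicate)] -
          rf$ct[match(common, rf$replicate)]
        folds <- 2^(-(dct_rep - dct("control")))
        out$fold_sem <- stats::sd(folds) / sqrt(length(folds))
        out$n_replicates <- length(folds)
      } else {
        out$fold_sem <- NA_real_
        out$n_replicates <- length(common)
      }
    }
    out
  })
  do.call(rbind, rows)
}
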
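#' Volume-normalized abundance table
#'
#' Technical replicates of a sample are pooled before normalization:
#' counts are summed and imaged seawater volumes summed, then
#' concentration = pooled count / pooled volume (counts per liter).
#' Samples with zero count are retained at concentration 0; a replicate
#' without a known volume excludes its sample with a warning.
#'
#' @param counts data.frame with columns `sample`, `taxon`, `count`
#'   (`sample` may name a technical replicate).
#' @param volumes data.frame with columns `sample`, `volume_l`
#'   (liters, > 0), one row per replicate.
#' @param replicates optional data.frame `sample`, `pooled` mapping
#'   replicates to the sample they belong to; default identity.
#' @return an `abundance_table` data.frame: `sample` (pooled), `taxon`,
#'   `count`, `volume_l`, `concentration_per_l`.
#' @export
normalize_counts <- function(counts, volumes, replicates = NULL) {
  stopifnot(all(c("sample", "taxon", "count") %in% names(counts)),
            all(c("sample", "volume_l") %in% names(volumes)))
  pool_of <- function(s) {
    if (is.null(replicates)) return(s)
    m <- match(s, replicates$sample)
    ifelse(is.na(m), s, replicates$pooled[m])
  }
  vol_idx <- match(counts$sample, volumes$sample)
  missing <- unique(counts$sample[is.na(vol_idx)])
  if (length(missing)) {
    warning("no imaged volume for sample(s) ",
            paste(missing, collapse = ", "), "; excluded")
    counts <- counts[!is.na(vol_idx), , drop = FALSE]
  }
  if (any(volumes$volume_l <= 0)) stop("volumes must be > 0")
  counts$pooled <- pool_of(counts$sample)
  volumes$pooled <- pool_of(volumes$sample)
  pooled_vol <- tapply(volumes$volume_l[!duplicated(volumes$sample)],
                       volumes$pooled[!duplicated(volumes$sample)], sum)
  agg <- stats::aggregate(count ~ pooled + taxon, data = counts, FUN = sum)
  out <- data.frame(sample = agg$pooled, taxon = agg$taxon,
                    count = agg$count,
                    volume_l = as.numeric(pooled_vol[agg$pooled]),
                    stringsAsFactors = FALSE)
  out$concentration_per_l <- out$count / out$volume_l
  class(out) <- c("abundance_table", "data.frame")
  out
}

#' Spearman correlation of a taxon's concentration with a covariate
#'
#' Samples that do not contain the taxon (count 0) are excluded; the
#' Spearman rank correlation is computed over the remaining samples,
#' with average ranks on ties. The p-value is exact for n <= 9 without
#' ties and uses the large-sample approximation otherwise. A
#' least-squares line of concentration on the covariate is reported for
#' display.
#'
#' @param abundance an [abundance_table][normalize_counts()].
#' @param covariate data.frame with columns `sample`, `value` (e.g.
#'   phosphate concentration).
#' @param taxon taxon to analyse.
#' @return a `correlation_result` list: `taxon`, `rho`, `n`, `p_value`,
#'   `fit` (intercept, slope).
#' @export
correlate_with_covariate <- function(abundance, covariate, taxon) {
  sub <- abundance[abundance$taxon == taxon & abundance$count > 0, ,
                   drop = FALSE]
  m <- match(sub$sample, covariate$sample)
  sub <- sub[!is.na(m), , drop = FALSE]
  x <- covariate$value[m[!is.na(m)]]
  y <- sub$concentration_per_l
  n <- length(y)
  if (n < 3) stop("fewer than 3 usable samples for taxon '", taxon, "'")
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = n <= 9 && !ties))
  fit <- stats::coef(stats::lm(y ~ x))
  structure(list(taxon = taxon, rho = unname(ct$estimate), n = n,
                 p_value = ct$p.value,
                 fit = c(intercept = unname(fit[1]), slope = unname(fit[2]))),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("correlation_result: %s rho = %.3f (n = %d, p = %.3g)\n",
              x$taxon, x$rho, x$n, x$p_value))
  invisible(x)
}

#' Live-cell predicate
#'
#' Operationalizes "cells with preserved organellar content" on the
#' feature catalog: at least one DNA sub-object (a nucleus survived
#' fixation) and non-zero membrane biovolume.
#'
#' @param features catalog feature matrix (rows = objects).
#' @return logical vector.
#' @export
is_live_cell <- function(features) {
  features[, "dna_subobj_count"] >= 1 &
    features[, "membranes_biovolume_um3"] > 0
}
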
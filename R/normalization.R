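#' Compute per-sample size factors from reference genes
#'
#' Size factors rescale samples so that designated reference genes — spike-in
#' RNA of fixed input amount, mitochondrial transcripts, or the k most stable
#' endogenous transcripts — have equal normalized abundance across samples.
#' The factor for sample s is its total reference count divided by the
#' across-sample mean of those totals, so factors average to exactly 1 and
#' normalized counts stay on the raw count scale.
#'
#' For `method = "top_k_stable"` the expression filter (`min_reads`, applied
#' to every sample) is applied first and the k retained genes with the lowest
#' coefficient of variation of raw counts are used as the reference set; for
#' `"spike_in"` and `"mito"` the reference class is exempt from any filter
#' (spikes are controls, not biology).
#'
#' @param matrix A [timecourse_counts()] object.
#' @param method One of `"spike_in"`, `"mito"`, `"top_k_stable"`.
#' @param k Number of stable genes used when `method = "top_k_stable"`.
#' @param min_reads Expression filter threshold used to pre-filter candidates
#'   for `"top_k_stable"`.
#' @return An object of class `size_factors`: list with `factors` (named
#'   numeric, mean 1), `method` and `reference_gene_ids`.
#' @export
compute_size_factors <- function(matrix,
                                 method = c("spike_in", "mito", "top_k_stable"),
                                 k = 70, min_reads = 25) {
  stopifnot(inherits(matrix, "timecourse_counts"))
  method <- match.arg(method)
  if (method %in% c("spike_in", "mito")) {
    cls <- if (method == "spike_in") "spike" else "mito"
    ref_ids <- matrix$genes$gene_id[matrix$genes$gene_class == cls]
    if (!length(ref_ids)) stop("no reference genes of class '", cls, "'")
  } else {
    filt <- apply_expression_filter(matrix, min_reads = min_reads)
    keep <- filt$genes$gene_class != "spike"
    cand <- filt$counts[keep, , drop = FALSE]
    if (nrow(cand) < k) {
      stop("top_k_stable needs >= ", k, " genes passing the expression ",
           "filter, found ", nrow(cand))
    }
    cv <- apply(cand, 1, function(x) sd(x) / mean(x))
    ref_ids <- rownames(cand)[order(cv, rownames(cand))[seq_len(k)]]
  }
  totals <- colSums(matrix$counts[matrix$genes$gene_id %in% ref_ids, ,
                                  drop = FALSE])
  if (any(totals == 0)) {
    stop("sample with zero reference counts: ",
         paste(names(totals)[totals == 0], collapse = ", "))
  }
  factors <- totals / mean(totals)
  message("compute_size_factors: method=", method, ", ", length(ref_ids),
          " reference genes")
  structure(
    list(factors = factors, method = method, reference_gene_ids = ref_ids),
    class = "size_factors"
  )
}

#' @export
print.size_factors <- function(x, ...) {
  cat("size_factors (", x$method, "): ", length(x$factors), " samples, ",
      length(x$reference_gene_ids), " reference genes\n", sep = "")
  print(round(x$factors, 4))
  invisible(x)
}

#' Filter genes by a per-sample read cutoff
#'
#' Keeps genes with at least `min_reads` counts in every sample (gene order
#' preserved). This is the read cutoff applied before half-life estimation;
#' the operation is idempotent and an empty result is permitted.
#'
#' @param matrix A [timecourse_counts()] object.
#' @param min_reads Minimum count required in each sample (default 25).
#' @return A filtered [timecourse_counts()] object.
#' @export
apply_expression_filter <- function(matrix, min_reads = 25) {
  stopifnot(inherits(matrix, "timecourse_counts"))
  keep <- apply(matrix$counts >= min_reads, 1, all)
  if (!nrow(matrix$counts)) keep <- logical(0)
  message("apply_expression_filter: ", sum(keep), "/", length(keep),
          " genes retained at >=", min_reads, " reads in each sample")
  out <- matrix
  out$genes <- matrix$genes[keep, , drop = FALSE]
  rownames(out$genes) <- NULL
  out$counts <- matrix$counts[keep, , drop = FALSE]
  out
}

#' Normalize counts by size factors and average replicates
#'
#' Divides each sample's counts by its size factor and averages samples that
#' share a (condition, time_h) pair, i.e. biological replicates, yielding one
#' abundance column per timepoint.
#'
#' @param matrix A [timecourse_counts()] object.
#' @param factors A `size_factors` object covering every sample.
#' @return A `normalized_abundance` object; `timepoints` records the number
#'   of replicates behind each column and `n_replicates_averaged` the
#'   maximum across columns.
#' @export
normalize_and_average <- function(matrix, factors) {
  stopifnot(inherits(matrix, "timecourse_counts"),
            inherits(factors, "size_factors"))
  miss <- setdiff(matrix$samples$sample_id, names(factors$factors))
  if (length(miss)) {
    stop("no size factor for sample(s): ", paste(miss, collapse = ", "))
  }
  f <- factors$factors[matrix$samples$sample_id]
  norm <- sweep(matrix$counts, 2, f, "/")
  key <- paste(matrix$samples$condition, matrix$samples$time_h, sep = "\r")
  groups <- unique(key)
  ord <- order(matrix$samples$condition[match(groups, key)],
               matrix$samples$time_h[match(groups, key)])
  groups <- groups[ord]
  ab <- vapply(groups, function(g) {
    rowMeans(norm[, key == g, drop = FALSE])
  }, numeric(nrow(norm)))
  if (nrow(norm) == 1) ab <- matrix(ab, nrow = 1)
  if (length(groups) == 1) ab <- matrix(ab, ncol = 1)
  idx <- match(groups, key)
  timepoints <- data.frame(
    condition = matrix$samples$condition[idx],
    time_h = matrix$samples$time_h[idx],
    n_replicates = as.integer(table(key)[groups]),
    stringsAsFactors = FALSE
  )
  rownames(timepoints) <- NULL
  new_normalized_abundance(
    genes = matrix$genes, timepoints = timepoints, abundance = ab,
    method = factors$method,
    n_replicates_averaged = max(timepoints$n_replicates)
  )
}

#' Extract one timepoint from a normalized abundance table
#'
#' @param table A `normalized_abundance` object.
#' @param time_h Timepoint (hours) to keep.
#' @param condition Optional condition filter.
#' @return A `normalized_abundance` restricted to the matching columns.
#' @export
subset_timepoint <- function(table, time_h, condition = NULL) {
  keep <- table$timepoints$time_h == time_h
  if (!is.null(condition)) keep <- keep & table$timepoints$condition %in% condition
  if (!any(keep)) stop("no timepoint at t=", time_h, " h",
                       if (!is.null(condition)) paste0(" for condition ",
                                                       condition))
  new_normalized_abundance(
    genes = table$genes,
    timepoints = table$timepoints[keep, , drop = FALSE],
    abundance = table$abundance[, keep, drop = FALSE],
    method = table$method,
    n_replicates_averaged = table$n_replicates_averaged
  )
}
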
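#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef cor lm median optim rexp rgamma rlnorm rnorm
#'   rnbinom rpois runif sd setNames quantile var
#' @importFrom utils read.delim write.table head
NULL

GENE_CLASSES <- c("coding", "lncRNA", "spike", "mito", "other")

#' Construct a timecourse count matrix
#'
#' Bundles a gene x sample matrix of raw counts with gene annotation
#' (`gene_id`, `gene_class`) and sample metadata (`sample_id`, `condition`,
#' `time_h`, `replicate`), validating all structural invariants: unique gene
#' ids, unique (condition, time_h, replicate) triples, non-negative integral
#' counts, and matching dimensions.
#'
#' @param counts Integer matrix, genes in rows, samples in columns.
#' @param genes Data frame with columns `gene_id` and `gene_class`
#'   (one of `"coding"`, `"lncRNA"`, `"spike"`, `"mito"`, `"other"`).
#' @param samples Data frame with columns `sample_id`, `condition`,
#'   `time_h` (hours, finite, >= 0) and `replicate` (positive integer).
#' @return An object of class `timecourse_counts`: a list with elements
#'   `genes`, `samples` and `counts` (dimnames set from the ids).
#' @export
timecourse_counts <- function(counts, genes, samples) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  stopifnot(
    all(c("gene_id", "gene_class") %in% names(genes)),
    all(c("sample_id", "condition", "time_h", "replicate") %in% names(samples))
  )
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(genes) || ncol(counts) != nrow(samples)) {
    stop("count matrix dimensions (", nrow(counts), " x ", ncol(counts),
         ") do not match gene/sample tables (", nrow(genes), " x ",
         nrow(samples), ")")
  }
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  }
  bad_class <- setdiff(unique(genes$gene_class), GENE_CLASSES)
  if (length(bad_class)) {
    stop("unknown gene_class: ", paste(bad_class, collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id")
  key <- paste(samples$condition, samples$time_h, samples$replicate)
  if (anyDuplicated(key)) {
    stop("duplicate (condition, time_h, replicate) triple: ",
         key[duplicated(key)][1])
  }
  if (!all(is.finite(samples$time_h)) || any(samples$time_h < 0)) {
    stop("time_h must be finite and >= 0")
  }
  if (any(samples$replicate < 1) || any(samples$replicate != round(samples$replicate))) {
    stop("replicate must be a positive integer")
  }
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(genes$gene_id, samples$sample_id)
  structure(
    list(genes = genes, samples = samples, counts = counts),
    class = "timecourse_counts"
  )
}

#' @export
print.timecourse_counts <- function(x, ...) {
  cat("timecourse_counts:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples\n")
  cat("  conditions:", paste(unique(x$samples$condition), collapse = ", "), "\n")
  cat("  times (h):", paste(sort(unique(x$samples$time_h)), collapse = ", "), "\n")
  cat("  gene classes:",
      paste(names(table(x$genes$gene_class)), table(x$genes$gene_class),
            collapse = ", "), "\n")
  invisible(x)
}

#' Construct a poly(A) tail-length sample
#'
#' A set of per-read (or per-molecule) poly(A) tail-length measurements for
#' one condition/timepoint, with optional positive weights (e.g. read counts).
#'
#' @param condition Condition label.
#' @param time_h Timepoint in hours.
#' @param records Data frame with columns `gene_id`, `tail_nt`
#'   (non-negative integers) and `weight` (finite, > 0; defaults to 1 if the
#'   column is absent).
#' @return An object of class `tail_sample`.
#' @export
tail_sample <- function(condition, time_h, records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "tail_nt") %in% names(records))) {
    stop("records must have columns gene_id and tail_nt")
  }
  if (is.null(records$weight)) records$weight <- 1
  if (nrow(records)) {
    if (any(!is.finite(records$tail_nt)) || any(records$tail_nt < 0) ||
        any(records$tail_nt != round(records$tail_nt))) {
      stop("tail_nt must be a non-negative integer")
    }
    if (any(!is.finite(records$weight)) || any(records$weight <= 0)) {
      stop("weight must be finite and > 0")
    }
  }
  if (!is.finite(time_h)) stop("time_h must be finite")
  structure(
    list(condition = as.character(condition), time_h = as.numeric(time_h),
         records = records[, c("gene_id", "tail_nt", "weight")]),
    class = "tail_sample"
  )
}

#' @export
print.tail_sample <- function(x, ...) {
  cat("tail_sample:", nrow(x$records), "records |", x$condition, "@",
      x$time_h, "h\n")
  if (nrow(x$records)) {
    cat("  median tail:", median_tail(x), "nt\n")
  }
  invisible(x)
}

# internal constructor for replicate-averaged normalized abundances
new_normalized_abundance <- function(genes, timepoints, abundance, method,
                                     n_replicates_averaged) {
  stopifnot(nrow(abundance) == nrow(genes), ncol(abundance) == nrow(timepoints))
  if (any(!is.finite(abundance)) || any(abundance < 0)) {
    stop("abundance must be finite and >= 0")
  }
  dimnames(abundance) <- list(
    genes$gene_id, paste0(timepoints$condition, "_t", timepoints$time_h)
  )
  structure(
    list(genes = genes, timepoints = timepoints, abundance = abundance,
         method = method, n_replicates_averaged = n_replicates_averaged),
    class = "normalized_abundance"
  )
}

#' @export
print.normalized_abundance <- function(x, ...) {
  cat("normalized_abundance:", nrow(x$abundance), "genes x",
      ncol(x$abundance), "timepoints | method:", x$method,
      "| replicates averaged:", x$n_replicates_averaged, "\n")
  invisible(x)
}
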
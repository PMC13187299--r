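#' Summarize per-gene stabilization ratios by gene class
#'
#' The stabilization ratio of a gene is its alternative-condition (mitotic)
#' half-life divided by its reference-condition (interphase) half-life,
#' computed from capped half-lives. Genes with both half-lives sitting at
#' the same cap carry no information about the ratio; they are flagged
#' `uninformative` and retained (flagged, logged, never silently dropped).
#'
#' @param comparisons Data frame from [join_and_filter()].
#' @param classes Named character vector mapping gene_id to gene_class
#'   (optional; genes without a class are labelled `"other"`).
#' @return List with `per_gene` (gene_id, gene_class, ratio, uninformative)
#'   and `per_class` (gene_class, n, median_ratio).
#' @export
stabilization_summary <- function(comparisons, classes = NULL) {
  if (!nrow(comparisons)) stop("no comparisons to summarize")
  cls <- if (is.null(classes)) rep("other", nrow(comparisons)) else {
    out <- unname(classes[comparisons$gene_id])
    out[is.na(out)] <- "other"
    out
  }
  at_cap <- function(h) h == 200 | h == 0.25
  uninformative <- at_cap(comparisons$half_life_ref_h) &
    comparisons$half_life_ref_h == comparisons$half_life_alt_h
  if (any(uninformative)) {
    message("stabilization_summary: ", sum(uninformative),
            " gene(s) with both half-lives at the same cap (flagged ",
            "uninformative, retained)")
  }
  per_gene <- data.frame(
    gene_id = comparisons$gene_id, gene_class = cls,
    ratio = comparisons$ratio, uninformative = uninformative,
    stringsAsFactors = FALSE
  )
  med <- tapply(per_gene$ratio, per_gene$gene_class, median)
  per_class <- data.frame(
    gene_class = names(med),
    n = as.integer(table(per_gene$gene_class)[names(med)]),
    median_ratio = as.numeric(med),
    stringsAsFactors = FALSE
  )
  rownames(per_class) <- NULL
  list(per_gene = per_gene, per_class = per_class)
}

#' Spearman rank correlation between two per-gene covariates
#'
#' Inner-joins two named vectors on gene id and computes the Spearman rank
#' correlation with average ranks for ties. An optional log10 transform with
#' a pseudo-count (default c = 0.9, used for count covariates such as ARE
#' counts) is available; being strictly monotone it cannot change the
#' statistic — a property the test suite verifies rather than assumes.
#'
#' @param x,y Named numeric vectors (names are gene ids).
#' @param log_transform Apply `log10(y + pseudo_count)` before ranking.
#' @param pseudo_count Pseudo-count added under `log_transform` (default
#'   0.9).
#' @return Spearman correlation in \[-1, 1\].
#' @export
rank_correlation <- function(x, y, log_transform = FALSE, pseudo_count = 0.9) {
  common <- intersect(names(x), names(y))
  xv <- x[common]
  yv <- y[common]
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]
  yv <- yv[ok]
  if (length(xv) < 3) stop("need >= 3 paired finite values, have ", length(xv))
  if (log_transform) yv <- log10(yv + pseudo_count)
  unname(cor(xv, yv, method = "spearman"))
}

#' Assign genes to P-body enrichment groups
#'
#' Strict inequalities exactly as printed: a transcript is P-body-enriched
#' iff FDR < `fdr_max` AND log2 enrichment > `log2_min`.
#'
#' @param covariates Data frame with columns `gene_id`, `pbody_fdr`,
#'   `pbody_log2_enrichment`.
#' @param fdr_max FDR threshold (default 0.01, strict `<`).
#' @param log2_min log2 enrichment threshold (default 2, strict `>`).
#' @return Named character vector gene_id -> `"enriched"`/`"not_enriched"`.
#' @export
pbody_membership <- function(covariates, fdr_max = 0.01, log2_min = 2) {
  stopifnot(all(c("gene_id", "pbody_fdr", "pbody_log2_enrichment") %in%
                  names(covariates)))
  enriched <- covariates$pbody_fdr < fdr_max &
    covariates$pbody_log2_enrichment > log2_min
  setNames(ifelse(enriched, "enriched", "not_enriched"), covariates$gene_id)
}

#' Assign genes to ARE-containing groups
#'
#' @param covariates Data frame with columns `gene_id` and `are_count`
#'   (number of AU-rich elements in the 3' UTR).
#' @return Named character vector gene_id -> `"ARE"`/`"no_ARE"`.
#' @export
are_membership <- function(covariates) {
  stopifnot(all(c("gene_id", "are_count") %in% names(covariates)))
  setNames(ifelse(covariates$are_count > 0, "ARE", "no_ARE"),
           covariates$gene_id)
}

#' Compare a per-gene statistic between covariate-defined groups
#'
#' @param values Named numeric vector (e.g. stabilization ratios).
#' @param membership Named character vector gene_id -> group label, e.g.
#'   from [pbody_membership()] or [are_membership()]. Every joined gene must
#'   resolve to exactly one group.
#' @param groups Optional group levels to report (groups absent from the
#'   data are reported with n = 0 and median NA).
#' @return Data frame with columns `group`, `n`, `median`.
#' @export
group_comparison <- function(values, membership, groups = NULL) {
  common <- intersect(names(values), names(membership))
  v <- values[common]
  g <- unname(membership[common])
  if (is.null(groups)) groups <- sort(unique(g))
  out <- do.call(rbind, lapply(groups, function(grp) {
    sel <- g == grp
    data.frame(group = grp, n = sum(sel),
               median = if (any(sel)) median(v[sel]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-gene abundance fold changes between two timepoints
#'
#' Computes abundance(t = delta) / abundance(t = 0) per gene for every
#' condition present in both tables, with the per-condition median. The two
#' tables must cover the same genes and be normalized by the same method;
#' genes with zero baseline abundance are excluded and logged.
#'
#' @param table0 `normalized_abundance` at the baseline timepoint (one
#'   column per condition).
#' @param table1 `normalized_abundance` at the later timepoint.
#' @param by_condition Conditions to report (default: all shared).
#' @return List with `per_gene` (gene_id, condition, fold_change) and
#'   `per_condition` (condition, n, median_fold_change).
#' @export
foldchange_summary <- function(table0, table1, by_condition = NULL) {
  stopifnot(inherits(table0, "normalized_abundance"),
            inherits(table1, "normalized_abundance"))
  if (!identical(table0$genes$gene_id, table1$genes$gene_id)) {
    diff <- union(setdiff(table0$genes$gene_id, table1$genes$gene_id),
                  setdiff(table1$genes$gene_id, table0$genes$gene_id))
    stop("gene sets differ between tables: ",
         paste(head(diff, 5), collapse = ", "),
         if (length(diff) > 5) " ...")
  }
  if (!identical(table0$method, table1$method)) {
    stop("tables normalized by different methods: ", table0$method, " vs ",
         table1$method)
  }
  conds <- intersect(table0$timepoints$condition, table1$timepoints$condition)
  if (!is.null(by_condition)) conds <- intersect(conds, by_condition)
  if (!length(conds)) stop("no shared condition between tables")
  per_gene <- do.call(rbind, lapply(conds, function(cond) {
    i0 <- which(table0$timepoints$condition == cond)
    i1 <- which(table1$timepoints$condition == cond)
    if (length(i0) != 1 || length(i1) != 1) {
      stop("condition '", cond, "' must have exactly one timepoint per table")
    }
    base <- table0$abundance[, i0]
    later <- table1$abundance[, i1]
    nz <- base > 0
    if (any(!nz)) {
      message("foldchange_summary(", cond, "): excluding ", sum(!nz),
              " gene(s) with zero baseline")
    }
    data.frame(gene_id = table0$genes$gene_id[nz], condition = cond,
               fold_change = later[nz] / base[nz], stringsAsFactors = FALSE)
  }))
  rownames(per_gene) <- NULL
  per_condition <- do.call(rbind, lapply(conds, function(cond) {
    fc <- per_gene$fold_change[per_gene$condition == cond]
    data.frame(condition = cond, n = length(fc),
               median_fold_change = median(fc), stringsAsFactors = FALSE)
  }))
  rownames(per_condition) <- NULL
  list(per_gene = per_gene, per_condition = per_condition)
}
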
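# TSV dialect: tab-separated, UTF-8, "." decimal, no quoting, "#" comments.

fmt_num <- function(x) {
  ifelse(is.na(x), "NA",
         ifelse(x == round(x) & abs(x) < 1e15,
                sprintf("%.0f", x), sprintf("%.10g", x)))
}

write_tsv_body <- function(df, path, comments = character()) {
  con <- file(path, open = "wb")  # binary mode: byte-identical across platforms
  on.exit(close(con))
  lines <- character()
  if (length(comments)) lines <- comments
  lines <- c(lines, paste(names(df), collapse = "\t"))
  if (nrow(df)) {
    cols <- lapply(df, function(col) {
      if (is.numeric(col)) fmt_num(col)
      else if (is.logical(col)) ifelse(col, "TRUE", "FALSE")
      else as.character(col)
    })
    lines <- c(lines, do.call(paste, c(cols, sep = "\t")))
  }
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  readLines(path, encoding = "UTF-8")
}

split_fields <- function(line) strsplit(line, "\t", fixed = TRUE)[[1]]

#' Read a timecourse count table and its sample metadata
#'
#' The count file must have the header
#' `gene_id<TAB>gene_class<TAB><sample_id>...` followed by one row per gene
#' with integral counts; the metadata file must have the header
#' `sample_id<TAB>condition<TAB>time_h<TAB>replicate`. Every sample column in
#' the count file must have a metadata row. Violations raise a parse error
#' naming the offending line.
#'
#' @param path Path to the count TSV.
#' @param metadata_path Path to the sample-metadata TSV.
#' @return A validated [timecourse_counts()] object.
#' @export
read_count_table <- function(path, metadata_path) {
  lines <- read_tsv_lines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) stop("empty count file: ", path)
  header <- split_fields(lines[1])
  if (length(header) < 3 || header[1] != "gene_id" || header[2] != "gene_class") {
    stop("count file ", path,
         ": header must be gene_id<TAB>gene_class<TAB><sample_id>...")
  }
  sample_ids <- header[-(1:2)]

  mlines <- read_tsv_lines(metadata_path)
  mlines <- mlines[!startsWith(mlines, "#")]
  mhead <- split_fields(mlines[1])
  if (!identical(mhead, c("sample_id", "condition", "time_h", "replicate"))) {
    stop("metadata file ", metadata_path,
         ": header must be sample_id<TAB>condition<TAB>time_h<TAB>replicate")
  }
  meta <- do.call(rbind, lapply(seq_along(mlines)[-1], function(i) {
    f <- split_fields(mlines[i])
    if (length(f) != 4) {
      stop("metadata file ", metadata_path, " line ", i, ": expected 4 fields")
    }
    data.frame(sample_id = f[1], condition = f[2],
               time_h = as.numeric(f[3]), replicate = as.integer(f[4]),
               stringsAsFactors = FALSE)
  }))
  missing_meta <- setdiff(sample_ids, meta$sample_id)
  if (length(missing_meta)) {
    stop("sample(s) without metadata: ", paste(missing_meta, collapse = ", "))
  }
  meta <- meta[match(sample_ids, meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL

  n_col <- length(header)
  body <- lines[-1]
  genes <- data.frame(gene_id = character(length(body)),
                      gene_class = character(length(body)),
                      stringsAsFactors = FALSE)
  counts <- matrix(0, nrow = length(body), ncol = length(sample_ids))
  for (i in seq_along(body)) {
    f <- split_fields(body[i])
    if (length(f) != n_col) {
      stop("count file ", path, " line ", i + 1, ": expected ", n_col,
           " fields, found ", length(f))
    }
    genes$gene_id[i] <- f[1]
    genes$gene_class[i] <- f[2]
    vals <- f[-(1:2)]
    bad <- which(!grepl("^[0-9]+$", vals))
    if (length(bad)) {
      stop("count file ", path, " line ", i + 1, ", column ",
           sample_ids[bad[1]], ": non-integer count '", vals[bad[1]], "'")
    }
    counts[i, ] <- as.numeric(vals)
  }
  if (anyDuplicated(genes$gene_id)) {
    dup <- genes$gene_id[duplicated(genes$gene_id)][1]
    stop("count file ", path, " line ",
         which(genes$gene_id == dup)[2] + 1, ": duplicate gene_id '", dup, "'")
  }
  timecourse_counts(counts, genes, meta)
}

#' Write a timecourse count table and its sample metadata
#'
#' Inverse of [read_count_table()]; emits the fixed column order and header
#' of the package's TSV dialect.
#'
#' @param x A [timecourse_counts()] object.
#' @param path,metadata_path Output paths for counts and sample metadata.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path, metadata_path) {
  stopifnot(inherits(x, "timecourse_counts"))
  df <- data.frame(gene_id = x$genes$gene_id, gene_class = x$genes$gene_class,
                   stringsAsFactors = FALSE)
  cnt <- as.data.frame(x$counts)
  names(cnt) <- x$samples$sample_id
  write_tsv_body(cbind(df, cnt), path)
  write_tsv_body(x$samples[, c("sample_id", "condition", "time_h", "replicate")],
                 metadata_path)
  invisible(path)
}

#' Read a per-read poly(A) tail-length table
#'
#' Expects a comment line `#condition=<c>\t#time_h=<t>` followed by the
#' header `gene_id<TAB>tail_nt<TAB>weight`.
#'
#' @param path Path to the tail TSV.
#' @return A validated [tail_sample()] object.
#' @export
read_tail_table <- function(path) {
  lines <- read_tsv_lines(path)
  if (!length(lines) || !startsWith(lines[1], "#condition=")) {
    stop("tail file ", path,
         ": first line must be a comment '#condition=<c>\t#time_h=<t>'")
  }
  cf <- split_fields(lines[1])
  condition <- sub("^#condition=", "", cf[1])
  th <- grep("^#time_h=", cf, value = TRUE)
  if (!length(th)) stop("tail file ", path, ": missing #time_h= in comment header")
  time_h <- as.numeric(sub("^#time_h=", "", th[1]))
  body <- lines[-1]
  body <- body[!startsWith(body, "#")]
  header <- split_fields(body[1])
  if (!identical(header, c("gene_id", "tail_nt", "weight"))) {
    missing <- setdiff(c("gene_id", "tail_nt", "weight"), header)
    stop("tail file ", path, ": header must be gene_id<TAB>tail_nt<TAB>weight",
         if (length(missing)) paste0(" (missing column: ",
                                     paste(missing, collapse = ", "), ")"))
  }
  rows <- body[-1]
  if (length(rows)) {
    parts <- strsplit(rows, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf != 3)) {
      stop("tail file ", path, " line ", which(nf != 3)[1] + 2,
           ": expected 3 fields")
    }
    m <- matrix(unlist(parts), ncol = 3, byrow = TRUE)
    records <- data.frame(gene_id = m[, 1],
                          tail_nt = as.numeric(m[, 2]),
                          weight = as.numeric(m[, 3]),
                          stringsAsFactors = FALSE)
  } else {
    records <- data.frame(gene_id = character(), tail_nt = numeric(),
                          weight = numeric(), stringsAsFactors = FALSE)
  }
  tail_sample(condition, time_h, records)
}

#' Write a poly(A) tail-length table
#'
#' @param x A [tail_sample()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tail_table <- function(x, path) {
  stopifnot(inherits(x, "tail_sample"))
  write_tsv_body(
    x$records,
    path,
    comments = sprintf("#condition=%s\t#time_h=%s", x$condition,
                       fmt_num(x$time_h))
  )
  invisible(path)
}

#' Write / read a decay-fit table
#'
#' Fixed column order: gene_id, gene_class, a0, kd_per_h, half_life_h,
#' capped_flag, r2, n_timepoints.
#'
#' @param fits Data frame as returned by [fit_table()].
#' @param path Output path.
#' @return `path` (writer) or the fit data frame (reader).
#' @export
write_fit_table <- function(fits, path) {
  out <- data.frame(
    gene_id = fits$gene_id, gene_class = fits$gene_class, a0 = fits$a0,
    kd_per_h = fits$kd_per_h, half_life_h = fits$half_life_h,
    capped_flag = fits$capped, r2 = fits$r2, n_timepoints = fits$n_timepoints,
    stringsAsFactors = FALSE
  )
  write_tsv_body(out, path)
  invisible(path)
}

#' @rdname write_fit_table
#' @export
read_fit_table <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("gene_id", "gene_class", "a0", "kd_per_h", "half_life_h",
            "capped_flag", "r2", "n_timepoints")
  if (!all(need %in% names(df))) {
    stop("fit table ", path, ": missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  names(df)[names(df) == "capped_flag"] <- "capped"
  df
}

#' Write a half-life comparison table
#'
#' Columns: gene_id, half_life_ref_h, half_life_alt_h, ratio, passed_filter.
#'
#' @param cmp Data frame as returned by [join_and_filter()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison_table <- function(cmp, path) {
  write_tsv_body(
    cmp[, c("gene_id", "half_life_ref_h", "half_life_alt_h", "ratio",
            "passed_filter")],
    path
  )
  invisible(path)
}
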
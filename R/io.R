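# Readers/writers for the cohort, panel and score files. All files are
# UTF-8, tab-separated, '.' decimal. Readers validate and reject malformed
# input rather than coercing silently.

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) stop("empty file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol0 <- length(fields[[1L]])
  widths <- lengths(fields)
  if (any(widths != ncol0)) {
    bad <- which(widths != ncol0)[1L]
    stop(sprintf("ragged row at line %d of %s (%d fields, expected %d)",
                 bad, path, widths[bad], ncol0), call. = FALSE)
  }
  fields
}

parse_numeric_cells <- function(cells, path, line_offset) {
  lapply(seq_along(cells), function(i) {
    num <- suppressWarnings(as.numeric(cells[[i]]))
    bad <- which(is.na(num) & cells[[i]] != "NA")
    if (length(bad))
      stop(sprintf("non-numeric cell '%s' at line %d, column %d of %s",
                   cells[[i]][bad[1L]], i + line_offset, bad[1L] + 1L, path),
           call. = FALSE)
    num
  })
}

#' Read / write an expression matrix
#'
#' Expression TSV layout: first column gene symbol, header row of sample
#' ids; a second header line `#group:` tab-separated tumor/normal labels is
#' written by [write_expression()] and required by [read_expression()]
#' unless `sample_group` is supplied.
#'
#' @param path File path.
#' @param sample_group Optional tumor/normal labels overriding the `#group:`
#'   line.
#' @return [read_expression()] returns an `mps_expression`.
#' @export
read_expression <- function(path, sample_group = NULL) {
  fields <- read_tsv_checked(path)
  header <- fields[[1L]]
  sample_ids <- header[-1L]
  body <- fields[-1L]
  group_line <- NULL
  if (length(body) && body[[1L]][1L] == "#group") {
    group_line <- body[[1L]][-1L]
    body <- body[-1L]
  }
  if (is.null(sample_group)) {
    if (is.null(group_line))
      stop("no '#group' line and no `sample_group` supplied: ", path,
           call. = FALSE)
    sample_group <- group_line
  }
  if (length(body) == 0L)
    stop("expression file has no gene rows: ", path, call. = FALSE)
  genes <- vapply(body, `[[`, "", 1L)
  if (anyDuplicated(genes))
    stop("duplicate gene symbol(s) in ", path, ": ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  cells <- lapply(body, `[`, -1L)
  offset <- if (is.null(group_line)) 1L else 2L
  vals <- parse_numeric_cells(cells, path, offset)
  m <- do.call(rbind, vals)
  rownames(m) <- genes
  colnames(m) <- sample_ids
  expression_matrix(m, sample_group)
}

#' @rdname read_expression
#' @param expr An `mps_expression`.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "mps_expression"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("symbol", colnames(expr$values)), collapse = "\t"), con)
  writeLines(paste(c("#group", as.character(expr$sample_group)), collapse = "\t"), con)
  body <- apply(expr$values, 1L, function(r)
    paste(format(r, digits = 15, trim = TRUE, scientific = FALSE), collapse = "\t"))
  writeLines(paste(rownames(expr$values), body, sep = "\t"), con)
  invisible(path)
}

#' Read / write a clinical table
#'
#' Clinical TSV: one row per sample with columns `sample_id`, `os_time`,
#' `os_event` and the optional categorical covariates.
#'
#' @param path File path.
#' @param time_unit `"days"` (default) or `"months"` for the `os_time`
#'   column of the file.
#' @return [read_clinical()] returns an `mps_clinical` (times in days).
#' @export
read_clinical <- function(path, time_unit = c("days", "months")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character")
  clinical_table(df, time_unit = match.arg(time_unit))
}

#' @rdname read_clinical
#' @param clinical An `mps_clinical`.
#' @export
write_clinical <- function(clinical, path) {
  stopifnot(inherits(clinical, "mps_clinical"))
  write.table(clinical, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a gene panel
#'
#' Panel file: TSV with columns `symbol`, `score_high`, `score_low`,
#' `weight` (extra columns are carried along but ignored), or a JSON file
#' with the same fields.
#'
#' @param path File path (`.json` files parsed as JSON, anything else as TSV).
#' @return [read_panel()] returns an `mps_panel`.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  need <- c("symbol", "score_high", "score_low", "weight")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("panel file missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  gene_panel(df$symbol, df$score_high, df$score_low, df$weight,
             provenance = paste("read from", path))
}

#' @rdname read_panel
#' @param panel An `mps_panel`.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "mps_panel"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.data.frame(panel), path, auto_unbox = TRUE,
                         digits = NA)
  } else {
    write.table(as.data.frame(panel), path, sep = "\t", quote = FALSE,
                row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Write per-sample mPS results
#'
#' @param results Data frame with columns `sample_id`, `mps`, `stratum`
#'   (an `mps_result`).
#' @param path Output TSV path.
#' @export
write_scores <- function(results, path) {
  need <- c("sample_id", "mps", "stratum")
  missing_cols <- setdiff(need, names(results))
  if (length(missing_cols))
    stop("results missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  write.table(results[, need], path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Align expression and clinical samples by sample id
#'
#' Joins on `sample_id`. In `"strict"` mode any tumor sample present in one
#' input but not the other is an error; in `"permissive"` mode the
#' intersection is used and the unmatched ids are reported via a message.
#'
#' @param expr An `mps_expression`.
#' @param clinical An `mps_clinical`.
#' @param mode `"strict"` or `"permissive"`.
#' @return List with `expr` (tumor columns restricted to matched ids, in
#'   clinical order) and `clinical` (matched rows).
#' @export
align_samples <- function(expr, clinical, mode = c("strict", "permissive")) {
  mode <- match.arg(mode)
  tumor_ids <- samples_in_group(expr, "tumor")
  only_expr <- setdiff(tumor_ids, clinical$sample_id)
  only_clin <- setdiff(clinical$sample_id, tumor_ids)
  if (length(only_expr) || length(only_clin)) {
    msg <- sprintf("unmatched sample ids: %d expression-only, %d clinical-only",
                   length(only_expr), length(only_clin))
    if (mode == "strict") stop(msg, call. = FALSE)
    message(msg, " (intersecting)")
  }
  keep <- intersect(clinical$sample_id, tumor_ids)
  if (length(keep) == 0L) stop("no overlapping tumor samples", call. = FALSE)
  clin <- clinical[match(keep, clinical$sample_id), , drop = FALSE]
  ex <- expr$values[, keep, drop = FALSE]
  list(expr = expression_matrix(ex, rep("tumor", length(keep))),
       clinical = clin)
}
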
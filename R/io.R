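#' Read a right-censored time-to-event table
#'
#' Reads a delimited file (comma- or tab-separated, chosen from the file
#' extension unless `sep` is given) into a validated data frame with the
#' canonical columns `time`, `status`, `covariate` and optionally `genotype`.
#' Rows violating the data model — non-positive or non-finite times, status
#' values outside `{0, 1}` after mapping, genotypes outside `{0, 1, 2}` — are
#' reported with their row numbers.
#'
#' @param path file to read.
#' @param time_col,status_col,covariate_col,genotype_col column names in the
#'   file; `genotype_col = NULL` omits genotypes.
#' @param status_map optional named vector mapping status codes to 0/1, e.g.
#'   `c(censored = 0, event = 1)`; by default the column must already be 0/1.
#' @param sep field separator; inferred from the extension when `NULL`.
#' @return Data frame with columns `id`, `time`, `status`, `covariate` and,
#'   if requested, `genotype`.
#' @export
read_survival_data <- function(path, time_col = "time", status_col = "status",
                               covariate_col = "covariate",
                               genotype_col = NULL, status_map = NULL,
                               sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(time_col, status_col, covariate_col, genotype_col)
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))

  time <- suppressWarnings(as.numeric(raw[[time_col]]))
  bad <- which(!is.finite(time) | time <= 0)
  if (length(bad))
    stop("invalid time (must be a positive number) in row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  status <- raw[[status_col]]
  if (!is.null(status_map)) {
    mapped <- status_map[as.character(status)]
    bad <- which(is.na(mapped))
    if (length(bad))
      stop("status value not covered by status_map in row(s): ",
           paste(utils::head(bad, 10), collapse = ", "))
    status <- as.numeric(mapped)
  }
  status <- suppressWarnings(as.numeric(status))
  bad <- which(!(status %in% c(0, 1)))
  if (length(bad))
    stop("invalid status (must be 0 or 1 after mapping) in row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))

  out <- data.frame(id = if ("id" %in% names(raw)) raw$id else seq_len(nrow(raw)),
                    time = time, status = status,
                    covariate = raw[[covariate_col]],
                    stringsAsFactors = FALSE)
  if (!is.null(genotype_col)) {
    g <- suppressWarnings(as.integer(raw[[genotype_col]]))
    bad <- which(!(g %in% 0:2))
    if (length(bad))
      stop("invalid genotype (must be 0, 1 or 2) in row(s): ",
           paste(utils::head(bad, 10), collapse = ", "))
    out$genotype <- g
  }
  out
}

#' Write a residual table with provenance
#'
#' Writes a residual (or any) table as CSV with numeric columns at 10
#' significant digits — lossless to well below 1e-9 on this data's scale — and
#' a leading provenance comment line recording the package version and an MD5
#' hash of the run configuration, so downstream association runs can be tied
#' back to the exact settings that produced their phenotype file.
#'
#' @param table non-empty data frame (e.g. from [residuals.ote_fit()]).
#' @param path output file.
#' @param config optional list of run settings hashed into the provenance
#'   line.
#' @return Invisibly, the provenance line written.
#' @export
write_residuals <- function(table, path, config = NULL) {
  stopifnot(is.data.frame(table))
  if (nrow(table) == 0L) stop("refusing to write an empty residual table")
  out <- table
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) signif(x, 10))
  prov <- sprintf("# otesurv %s config_md5=%s",
                  as.character(utils::packageVersion("otesurv")),
                  config_hash(config))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(prov, con)
  utils::write.csv(out, con, row.names = FALSE)
  invisible(prov)
}

#' MD5 hash of a run configuration
#'
#' Canonicalises a configuration list as JSON (sorted keys, unboxed scalars)
#' and hashes it, giving a stable fingerprint for provenance lines.
#'
#' @param config list of settings (may be `NULL`).
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                           null = "null", force = TRUE)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(json), tf)
  unname(tools::md5sum(tf))
}
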
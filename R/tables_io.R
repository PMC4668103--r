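#' Read a replicate-level spot-intensity table
#'
#' Reads a long-format densitometry table with one row per
#' (spot, genotype, stage, replicate) observation. The long format is
#' canonical throughout the package; wide matrices are derived views.
#' Field separator is sniffed from the extension (`.csv` comma, anything
#' else tab); decimal separator is `.` and encoding UTF-8.
#'
#' Validation is strict: malformed or invariant-violating rows are reported
#' with their line numbers rather than silently dropped, duplicated
#' (spot, genotype, stage, replicate) records are an error, and when
#' `expected_replicates` is given every (spot, genotype, stage) cell must
#' carry exactly that many replicates.
#'
#' @param path file path to a CSV/TSV with header columns `spot_id`,
#'   `genotype`, `stage`, `replicate`, `intensity`.
#' @param expected_replicates required replicate count per
#'   (spot, genotype, stage) cell, default 3; `NULL` skips the completeness
#'   check.
#' @return A `spot_table`: a data frame with the five columns above,
#'   `replicate` integer and `intensity` non-negative numeric.
#' @seealso [validate_spot_table()] for in-memory tables,
#'   [normalize_total_ppm()].
#' @export
read_spot_table <- function(path, expected_replicates = 3L) {
  stopifnot(file.exists(path))
  df <- .read_table_file(path)
  need <- c("spot_id", "genotype", "stage", "replicate", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  validate_spot_table(df[need], expected_replicates = expected_replicates)
}

#' Validate a spot-intensity table held in memory
#'
#' Applies the same invariant checks as [read_spot_table()]: column types,
#' non-negative intensities, replicate indices >= 1, no duplicate
#' (spot, genotype, stage, replicate) records, and (optionally) a uniform
#' replicate count per cell. Validation never mutates the data beyond type
#' coercion of the key columns.
#'
#' @param df data frame with columns `spot_id`, `genotype`, `stage`,
#'   `replicate`, `intensity`.
#' @inheritParams read_spot_table
#' @return The validated table, classed `spot_table`.
#' @export
validate_spot_table <- function(df, expected_replicates = 3L) {
  stopifnot(is.data.frame(df))
  need <- c("spot_id", "genotype", "stage", "replicate", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  df$spot_id <- as.character(df$spot_id)
  df$genotype <- as.character(df$genotype)
  df$stage <- as.character(df$stage)

  rep_num <- suppressWarnings(as.numeric(df$replicate))
  bad <- which(is.na(rep_num) | rep_num < 1 | rep_num != round(rep_num))
  if (length(bad))
    stop("invalid replicate index at data row(s): ",
         .row_list(bad), " (must be a positive integer)")
  df$replicate <- as.integer(rep_num)

  inten <- suppressWarnings(as.numeric(df$intensity))
  bad <- which(is.na(inten) | inten < 0)
  if (length(bad))
    stop("invalid intensity at data row(s): ", .row_list(bad),
         " (must be a non-negative number)")
  df$intensity <- inten

  key <- paste(df$spot_id, df$genotype, df$stage, df$replicate, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    first <- df[dup[1L], ]
    stop("duplicate (spot, genotype, stage, replicate) record(s) at data row(s): ",
         .row_list(dup), "; first duplicate: (",
         paste(first$spot_id, first$genotype, first$stage, first$replicate,
               sep = ", "), ")")
  }

  if (!is.null(expected_replicates)) {
    expected_replicates <- as.integer(expected_replicates)
    stopifnot(length(expected_replicates) == 1L, expected_replicates >= 1L)
    cell <- paste(df$spot_id, df$genotype, df$stage, sep = "\r")
    counts <- table(cell)
    short <- counts[counts != expected_replicates]
    if (length(short)) {
      labs <- gsub("\r", ", ", names(short), fixed = TRUE)
      stop("incomplete replication (expected ", expected_replicates,
           " replicates) in cell(s): ",
           paste(utils::head(sprintf("(%s): %d", labs, short), 5L),
                 collapse = "; "),
           if (length(short) > 5L) sprintf(" ... and %d more", length(short) - 5L))
    }
  }

  rownames(df) <- NULL
  class(df) <- c("spot_table", "data.frame")
  df
}

#' Read a replicate-level seed-setting table
#'
#' One row per (genotype, stage, replicate) with the number of filled seeds
#' and the total spikelet count scored in that replicate. The seed setting
#' rate downstream is `filled_seeds / total_spikelets`.
#'
#' @param path file path to a CSV/TSV with header columns `genotype`,
#'   `stage`, `replicate`, `filled_seeds`, `total_spikelets`.
#' @return A `seedset_table` data frame.
#' @export
read_seedset_table <- function(path) {
  stopifnot(file.exists(path))
  df <- .read_table_file(path)
  need <- c("genotype", "stage", "replicate", "filled_seeds",
            "total_spikelets")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  validate_seedset_table(df[need])
}

#' @rdname read_seedset_table
#' @param df in-memory data frame with the same columns.
#' @export
validate_seedset_table <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("genotype", "stage", "replicate", "filled_seeds",
            "total_spikelets")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  df$genotype <- as.character(df$genotype)
  df$stage <- as.character(df$stage)
  for (col in c("replicate", "filled_seeds", "total_spikelets")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | v != round(v) | v < 0)
    if (length(bad))
      stop("invalid ", col, " at data row(s): ", .row_list(bad))
    df[[col]] <- as.integer(v)
  }
  if (any(df$replicate < 1L))
    stop("replicate indices must be >= 1")
  bad <- which(df$total_spikelets < 1L)
  if (length(bad))
    stop("total_spikelets must be positive at data row(s): ", .row_list(bad))
  bad <- which(df$filled_seeds > df$total_spikelets)
  if (length(bad))
    stop("filled_seeds exceeds total_spikelets at data row(s): ",
         .row_list(bad))
  key <- paste(df$genotype, df$stage, df$replicate, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate (genotype, stage, replicate) record(s) at data row(s): ",
         .row_list(dup))
  rownames(df) <- NULL
  class(df) <- c("seedset_table", "data.frame")
  df
}

#' Write a result table as TSV
#'
#' Writes any result data frame (calls, tallies, normalized tables, ...)
#' with a stable column order (as given), tab separator, no quoting and no
#' row names. Double-precision columns are written with 17 significant
#' digits so a write/read/write cycle is byte-identical; columns already
#' rounded for reporting (e.g. percentages) pass through unchanged. An
#' empty table yields a header-only file.
#'
#' @param results a data frame; must be non-null.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  if (is.null(results)) stop("results must be non-null")
  stopifnot(is.data.frame(results))
  out <- as.data.frame(results)
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- "NA"
      out[[j]] <- v
    }
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Extension-based dialect sniffing: .csv is comma-separated, everything
# else tab-separated; always UTF-8, "." decimal.
.read_table_file <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = TRUE, fileEncoding = "UTF-8",
                    colClasses = "character")
}

.row_list <- function(idx, n = 5L) {
  # +1 converts data-row index to file line number (header is line 1)
  shown <- utils::head(idx + 1L, n)
  paste0(paste(shown, collapse = ", "),
         if (length(idx) > n) sprintf(" ... and %d more", length(idx) - n))
}
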
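#' Read a tab-separated table
#'
#' Thin wrapper around [utils::read.delim()] with the conventions used by
#' every table in this package: tab-separated, header line, no quoting
#' surprises, strings kept as character. Lines starting with `#` are treated
#' as provenance headers and skipped.
#'
#' @param path Path to a TSV file.
#' @param required_cols Character vector of column names that must be
#'   present; an informative error is thrown otherwise.
#' @return A `data.frame`.
#' @export
read_tsv_table <- function(path, required_cols = NULL) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!is.null(required_cols)) {
    missing <- setdiff(required_cols, names(df))
    if (length(missing) > 0) {
      stop("file ", path, " is missing required column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  df
}

#' Write a tab-separated table
#'
#' @param df A data.frame.
#' @param path Output path.
#' @param header_comment Optional character vector written as `#`-prefixed
#'   provenance lines before the column header.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(df, path, header_comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", header_comment), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' GMT is the tab-separated gene-set format: one set per line, fields are
#' set name, description, then one gene per remaining field.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors (gene symbols); the
#'   `description` attribute on each element carries the second field.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("malformed GMT line ", i, ": fewer than 3 tab-separated fields",
           call. = FALSE)
    }
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    attr(genes, "description") <- fields[[2]]
    sets[[fields[[1]]]] <- genes
  }
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions
#'   (defaults to the set name).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(descriptions)) descriptions <- names(sets)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[[i]], descriptions[[i]], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a STRING-dialect protein interaction edge table
#'
#' Expects tab-separated columns `node1`, `node2`, `combined_score`
#' (scores on STRING's 0-1000 scale). Malformed rows are reported with
#' their line number.
#'
#' @param path Path to the edge TSV.
#' @return A data.frame with columns `node1`, `node2`, `combined_score`.
#' @export
read_string_edges <- function(path) {
  df <- read_tsv_table(path, required_cols = c("node1", "node2",
                                               "combined_score"))
  score <- suppressWarnings(as.numeric(df$combined_score))
  bad <- which(is.na(score) | score < 0 | score > 1000 |
                 !nzchar(df$node1) | !nzchar(df$node2))
  if (length(bad) > 0) {
    stop("malformed edge row(s) at data line(s): ",
         paste(utils::head(bad, 10), collapse = ", "),
         " in ", path, call. = FALSE)
  }
  df$combined_score <- score
  df
}
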
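# Shared helpers: TSV writers with commented headers, small validators.

#' Write a table as TSV with a commented header line
#'
#' All tabular outputs of the pipeline share one dialect: tab-separated
#' values, no quoting, with a single leading line of the form
#' `# col1<TAB>col2...` naming the columns. List-columns are collapsed to
#' comma-separated strings before writing.
#'
#' @param x A data frame.
#' @param path Output file path.
#' @return `x`, invisibly (so writers can sit inside a pipe).
#' @export
write_spectrum_tsv <- function(x, path) {
  stopifnot(is.data.frame(x))
  flat <- as_tibble(x)
  is_list <- vapply(flat, is.list, logical(1))
  for (nm in names(flat)[is_list]) {
    flat[[nm]] <- vapply(
      flat[[nm]],
      function(v) paste(as.character(v), collapse = ","),
      character(1)
    )
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# ", paste(names(flat), collapse = "\t")), con)
  if (nrow(flat) > 0) {
    utils::write.table(flat, con,
      sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE
    )
  }
  invisible(x)
}

#' Read a TSV written by [write_spectrum_tsv()]
#'
#' @param path File path.
#' @param list_cols Character vector of columns to split back into
#'   character-vector list-columns (comma-separated on disk).
#' @return A tibble.
#' @export
read_spectrum_tsv <- function(path, list_cols = character()) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "# ")) {
    abort(paste0("not a spectrum TSV (missing '# ' header): ", path))
  }
  cols <- strsplit(sub("^# ", "", header), "\t", fixed = TRUE)[[1]]
  body <- readr::read_tsv(path,
    skip = 1L, col_names = cols,
    col_types = readr::cols(.default = readr::col_guess()),
    progress = FALSE, show_col_types = FALSE,
    na = c("NA", "")
  )
  for (nm in intersect(list_cols, names(body))) {
    body[[nm]] <- strsplit(as.character(body[[nm]]), ",", fixed = TRUE)
    body[[nm]] <- lapply(body[[nm]], function(v) v[!is.na(v) & nzchar(v)])
  }
  strip_readr_attrs(body)
}

# drop readr bookkeeping attributes (they hold environments, which breaks
# identical() comparisons between reruns)
strip_readr_attrs <- function(x) {
  attr(x, "spec") <- NULL
  attr(x, "problems") <- NULL
  x
}

# condition label -> filesystem-safe token ("2i/L" -> "2iL")
sanitize_label <- function(x) gsub("[^A-Za-z0-9]+", "", x)

# stopifnot-with-message
check_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

# deterministic RNG scope: run `expr` under `seed` and restore RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
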
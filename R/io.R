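# Readers for set inputs. Three plain-text formats, all UTF-8:
#   * per-file:  one item per line, one file per set (set name = file stem)
#   * membership TSV: two columns (set_name, item), no header required
#   * JSON: an object mapping set name -> array of items
# Items are opaque strings (gene IDs, compounds, species, ...).

#' Read item sets into a Venn collection
#'
#' Exactly one of `paths`, `tsv` or `json` must be given. Blank lines are
#' skipped; duplicated items are removed with a logged count; an empty
#' input yields an empty set with a warning. The resulting collection must
#' have 2..7 sets.
#'
#' @param paths Character vector of per-set list files (one item per line).
#' @param tsv Path to a two-column TSV (`set_name`, `item`). A header row
#'   named `set_name`/`item` (or `set`/`item`) is detected and skipped.
#' @param json Path to a JSON object mapping set names to item arrays.
#' @param set_names Optional names overriding the default (file stems for
#'   `paths`; ignored for TSV/JSON, which carry their own names).
#' @param quiet Suppress de-duplication messages?
#' @return A `venn` collection.
#' @export
read_sets <- function(paths = NULL, tsv = NULL, json = NULL,
                      set_names = NULL, quiet = FALSE) {
  given <- c(!is.null(paths), !is.null(tsv), !is.null(json))
  if (sum(given) != 1L) {
    stop("give exactly one of `paths`, `tsv` or `json`", call. = FALSE)
  }
  sets <- if (!is.null(paths)) {
    check_readable(paths)
    nm <- if (!is.null(set_names)) set_names
          else tools::file_path_sans_ext(basename(paths))
    if (length(nm) != length(paths)) {
      stop("`set_names` must match the number of files", call. = FALSE)
    }
    stats::setNames(lapply(paths, function(p) {
      x <- readLines(p, encoding = "UTF-8", warn = FALSE)
      x[nzchar(trimws(x))]
    }), nm)
  } else if (!is.null(tsv)) {
    check_readable(tsv)
    df <- utils::read.delim(tsv, header = FALSE, colClasses = "character",
                            fileEncoding = "UTF-8")
    if (ncol(df) < 2L) {
      stop("membership TSV needs two columns (set_name, item)", call. = FALSE)
    }
    if (nrow(df) && tolower(df[1L, 1L]) %in% c("set_name", "set") &&
        tolower(df[1L, 2L]) == "item") {
      df <- df[-1L, , drop = FALSE]
    }
    split(df[[2L]], factor(df[[1L]], levels = unique(df[[1L]])))
  } else {
    check_readable(json)
    x <- jsonlite::read_json(json, simplifyVector = TRUE)
    if (is.null(names(x))) {
      stop("JSON input must be an object mapping set names to item arrays",
           call. = FALSE)
    }
    lapply(x, as.character)
  }
  empty <- lengths(sets) == 0L | vapply(sets, function(s)
    all(!nzchar(trimws(s))), logical(1))
  if (any(empty)) {
    warning("empty input set(s): ", paste(names(sets)[empty], collapse = ", "),
            call. = FALSE)
  }
  make_venn(sets, quiet = quiet)
}

check_readable <- function(paths) {
  bad <- paths[!file.exists(paths)]
  if (length(bad)) {
    stop("cannot read input file(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(paths)
}
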
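## Enzyme catalog: built-in protease definitions shipped as grammar-format
## text files under inst/enzymes/, compiled lazily at first access, plus a
## registry for user-defined enzymes loaded from files at run time.

.catalog <- new.env(parent = emptyenv())

catalog_dir <- function() {
  system.file("enzymes", package = "protcleave")
}

ensure_builtins <- function() {
  if (!is.null(.catalog$builtin)) {
    return(invisible())
  }
  .catalog$builtin <- list()
  dir <- catalog_dir()
  files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  for (f in files) {
    for (enz in read_enzyme_file(f)) {
      if (!is.null(.catalog$builtin[[enz$name]])) {
        pc_stop_data(sprintf(
          "catalog error: duplicate built-in enzyme name '%s' (%s)",
          enz$name, basename(f)
        ))
      }
      .catalog$builtin[[enz$name]] <- enz
    }
  }
  invisible()
}

if (is.null(.catalog$user)) .catalog$user <- list()

#' Parse an enzyme-definition file
#'
#' Reads a plain-text file of protease definitions. Lines starting with `#`
#' are comments; an enzyme block starts with `NAME: <name>` followed by
#' `RULE: <expr>` and `EXCEPTION: <expr>` lines in declaration order (rules
#' must precede the exceptions that modify them). A file may hold several
#' blocks.
#'
#' @param path File path.
#' @return List of compiled `protease` objects (possibly empty, with a
#'   warning for a file that defines nothing).
#' @export
read_enzyme_file <- function(path) {
  if (!file.exists(path)) {
    pc_stop_usage(sprintf("enzyme file '%s' does not exist", path))
  }
  lines <- readLines(path, warn = FALSE)
  enzymes <- list()
  cur_name <- NULL
  cur_lines <- list()
  flush <- function() {
    if (is.null(cur_name)) {
      return()
    }
    enz <- tryCatch(
      compile_enzyme_lines(cur_name, cur_lines),
      protcleave_error = function(e) {
        pc_stop_parse(sprintf("%s: %s", basename(path), conditionMessage(e)))
      }
    )
    enzymes[[length(enzymes) + 1L]] <<- enz
  }
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    m <- regmatches(ln, regexec("^(NAME|RULE|EXCEPTION)\\s*:\\s*(.*)$", ln))[[1L]]
    if (length(m) != 3L) {
      pc_stop_parse(sprintf(
        "%s line %d: expected 'NAME:', 'RULE:' or 'EXCEPTION:'",
        basename(path), i
      ))
    }
    tag <- m[2L]
    rest <- trimws(m[3L])
    if (tag == "NAME") {
      flush()
      cur_name <- tolower(rest)
      cur_lines <- list()
      if (!nzchar(cur_name)) {
        pc_stop_parse(sprintf("%s line %d: empty enzyme name",
                              basename(path), i))
      }
    } else {
      if (is.null(cur_name)) {
        pc_stop_parse(sprintf(
          "%s line %d: %s line before any NAME", basename(path), i, tag
        ))
      }
      cur_lines[[length(cur_lines) + 1L]] <-
        list(text = rest, is_exception = tag == "EXCEPTION")
    }
  }
  flush()
  if (!length(enzymes)) {
    warning(sprintf("enzyme file '%s' defines no enzymes", path))
  }
  enzymes
}

#' Load an enzyme from the catalog
#'
#' Looks the name up among user-registered enzymes first, then among the
#' built-in definitions shipped with the package.
#'
#' @param name Enzyme name (case-insensitive).
#' @return A `protease` object.
#' @examples
#' load_enzyme("trypsin")
#' @export
load_enzyme <- function(name) {
  ensure_builtins()
  key <- tolower(name)
  enz <- .catalog$user[[key]]
  if (is.null(enz)) enz <- .catalog$builtin[[key]]
  if (is.null(enz)) {
    pc_stop_usage(sprintf(
      "unknown enzyme '%s'; available: %s",
      name, paste(available_enzymes(), collapse = ", ")
    ))
  }
  enz
}

#' Names of all available enzymes
#'
#' @return Sorted character vector of built-in and user-registered enzyme
#'   names.
#' @export
available_enzymes <- function() {
  ensure_builtins()
  sort(unique(c(names(.catalog$builtin), names(.catalog$user))))
}

#' Register user-defined enzymes from a definition file
#'
#' Compiles every enzyme block in the file and adds it to the session
#' catalog, where it is usable exactly like a built-in. Re-registering an
#' existing name (built-in or user) is an error.
#'
#' @param path Enzyme-definition file, see [read_enzyme_file()].
#' @return Character vector of the names added (invisibly empty for a file
#'   that defines nothing).
#' @export
register_user_file <- function(path) {
  ensure_builtins()
  enzymes <- read_enzyme_file(path)
  added <- character(0)
  for (enz in enzymes) {
    if (enz$name %in% names(.catalog$builtin) ||
        enz$name %in% names(.catalog$user)) {
      pc_stop_usage(sprintf(
        "enzyme '%s' is already defined; user enzymes cannot shadow the catalog",
        enz$name
      ))
    }
    .catalog$user[[enz$name]] <- enz
    added <- c(added, enz$name)
  }
  invisible(added)
}

## Test/CLI helper: forget user registrations.
clear_user_enzymes <- function() {
  .catalog$user <- list()
  invisible()
}

#' Print the catalog in grammar form
#'
#' @param names Enzymes to print; default all.
#' @return Invisibly, the printed lines.
#' @export
list_enzymes <- function(names = available_enzymes()) {
  out <- unlist(lapply(names, function(nm) {
    c(format_enzyme(load_enzyme(nm)), "")
  }))
  cat(out, sep = "\n")
  invisible(out)
}
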
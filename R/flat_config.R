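# Flat "key = value" text files used for game, player and protocol
# configuration. One key per line, "#" starts a comment, values are numbers,
# logicals or bare strings. Parsers reject unknown keys instead of guessing.

format_flat <- function(x) {
  vals <- vapply(x, function(v) {
    if (is.logical(v)) {
      if (v) "true" else "false"
    } else if (is.numeric(v)) {
      format(v, digits = 17, scientific = FALSE, trim = TRUE)
    } else {
      as.character(v)
    }
  }, character(1))
  paste(names(x), "=", vals)
}

write_flat <- function(x, path) {
  writeLines(format_flat(x), path)
  invisible(path)
}

read_flat <- function(path) {
  if (!file.exists(path)) {
    stop_domain("config file not found: %s", path)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "=", fixed = TRUE)[[1]]
    if (length(parts) != 2) {
      stop_domain("malformed config line %d in %s: '%s'", i, path, lines[[i]])
    }
    key <- trimws(parts[[1]])
    val <- trimws(parts[[2]])
    out[[key]] <- parse_flat_value(val)
  }
  out
}

parse_flat_value <- function(val) {
  if (tolower(val) %in% c("true", "false")) {
    return(tolower(val) == "true")
  }
  num <- suppressWarnings(as.numeric(val))
  if (!is.na(num)) {
    return(num)
  }
  val
}

# Restrict a parsed flat file to the formal arguments of a constructor,
# rejecting anything it does not understand.
check_known_keys <- function(x, allowed, path) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    stop_domain("unknown key(s) in %s: %s", path,
                paste(unknown, collapse = ", "))
  }
  invisible(x)
}

#' Read and write game configuration files
#'
#' Game configurations are stored as flat `key = value` text; every field of
#' [game_config()] is a key. Unknown keys are rejected.
#'
#' @param path File path.
#' @param config A [game_config()].
#' @return `read_game_config()` returns a validated [game_config()];
#'   `write_game_config()` returns `path` invisibly.
#' @export
read_game_config <- function(path) {
  vals <- read_flat(path)
  check_known_keys(vals, names(formals(game_config)), path)
  do.call(game_config, vals)
}

#' @rdname read_game_config
#' @export
write_game_config <- function(config, path) {
  stopifnot(inherits(config, "game_config"))
  write_flat(unclass(config), path)
}

# Stable md5 fingerprint of a configuration, recorded in session metadata so
# analysis can verify which constants produced a log.
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".cfg")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(format_flat(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}
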
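# Flat-file persistence for player parameters and study protocols (same
# "key = value" dialect as the game configuration).

#' Read and write player parameter files
#'
#' Flat `key = value` text covering every field of [player_params()];
#' unknown keys are rejected.
#'
#' @param path File path.
#' @param params A [player_params()].
#' @return `read_player_params()` returns a validated [player_params()].
#' @export
read_player_params <- function(path) {
  vals <- read_flat(path)
  check_known_keys(vals, names(formals(player_params)), path)
  do.call(player_params, vals)
}

#' @rdname read_player_params
#' @export
write_player_params <- function(params, path) {
  stopifnot(inherits(params, "player_params"))
  write_flat(unclass(params), path)
}

#' Read and write study protocol files
#'
#' Flat `key = value` text covering every field of [study_protocol()]; the
#' adherence pattern is written as a string over `F`/`H`/`N`, one character
#' per calendar day.
#'
#' @param path File path.
#' @param protocol A [study_protocol()].
#' @return `read_study_protocol()` returns a validated [study_protocol()].
#' @export
read_study_protocol <- function(path) {
  vals <- read_flat(path)
  check_known_keys(vals, names(formals(study_protocol)), path)
  do.call(study_protocol, vals)
}

#' @rdname read_study_protocol
#' @export
write_study_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "study_protocol"))
  out <- unclass(protocol)
  out$adherence_pattern <- paste(out$adherence_pattern, collapse = "")
  out$start_date <- as.character(out$start_date)
  write_flat(out, path)
}
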
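## Text serialization: response tables, parameter key-value files, run
## metadata sidecars.

#' Write a response set as delimited text
#'
#' Columns: `trial,condition,choice,rt,timed_out` (plus `true_choice` when
#' known).
#'
#' @param responses A [response_set()].
#' @param path Output file path.
#' @export
write_responses <- function(responses, path) {
  stopifnot(inherits(responses, "response_set"))
  df <- as.data.frame(responses)
  if (all(is.na(df$true_choice))) df$true_choice <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a response set written by [write_responses()]
#'
#' @param path File path.
#' @return A [response_set()].
#' @export
read_responses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("choice", "rt", "timed_out")
  if (!all(need %in% names(df)))
    stop("response file must have columns choice, rt, timed_out",
         call. = FALSE)
  response_set(choice = df$choice, rt = df$rt,
               timed_out = as.logical(df$timed_out),
               condition = if ("condition" %in% names(df)) df$condition
                           else "default",
               true_choice = if ("true_choice" %in% names(df))
                 df$true_choice else NA_integer_)
}

#' Write a flat key-value parameter/metadata file
#'
#' One `key = value` pair per line; vectors are comma-joined. Used for run
#' metadata sidecars (seed, parameters) and CLI parameter exchange.
#'
#' @param x Named list of scalars or short vectors.
#' @param path Output file path.
#' @export
write_keyvalue <- function(x, path) {
  stopifnot(!is.null(names(x)), all(nzchar(names(x))))
  lines <- vapply(names(x), function(k)
    paste0(k, " = ", paste(format(x[[k]], digits = 15, scientific = FALSE,
                                  trim = TRUE), collapse = ",")),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a key-value file written by [write_keyvalue()]
#'
#' Values that parse as numeric are returned numeric.
#'
#' @param path File path.
#' @return Named list.
#' @export
read_keyvalue <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) next
    key <- trimws(kv[1])
    vals <- trimws(strsplit(kv[2], ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(vals))
    out[[key]] <- if (anyNA(num)) vals else num
  }
  out
}
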
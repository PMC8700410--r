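# Bundled lifetime datasets and plain-text sample input.

#' Bundled lifetime datasets
#'
#' Three classical uncensored lifetime datasets shipped as plain-text
#' fixtures:
#' \describe{
#'   \item{`guinea_pigs`}{survival times (days/100) of 72 guinea pigs
#'     infected with virulent tubercle bacilli (Bjerkedal, 1960).}
#'   \item{`fluid_group1`, `fluid_group2`}{two groups of 10 breakdown times
#'     (minutes) of an insulating fluid under high voltage stress (Nelson,
#'     1982); group 1 is conventionally the strength sample and group 2 the
#'     stress sample in stress-strength analyses.}
#' }
#'
#' @param name one of `"guinea_pigs"`, `"fluid_group1"`, `"fluid_group2"`.
#' @return numeric vector of positive lifetimes, in source order.
#' @examples
#' length(neitl_data("guinea_pigs"))  # 72
#' @export
neitl_data <- function(name = c("guinea_pigs", "fluid_group1",
                                "fluid_group2")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".txt"), package = "neitl",
                      mustWork = TRUE)
  read_lifetimes(path)
}

#' Read a one-column lifetime sample
#'
#' Reads a plain-text (or single-column CSV) file of strictly positive
#' numbers, one per line; `#` starts a comment and blank lines are skipped.
#' Non-numeric or non-positive rows abort with the offending line number.
#' Input order is preserved.
#'
#' @param path path to the file.
#' @return numeric vector of positive values.
#' @export
read_lifetimes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- which(trimws(lines) != "")
  if (!length(keep)) stop("no data in file: ", path, call. = FALSE)
  vals <- suppressWarnings(as.numeric(trimws(lines[keep])))
  if (anyNA(vals)) {
    stop("non-numeric value at line ", keep[which(is.na(vals))[1]], " of ",
         path, call. = FALSE)
  }
  if (any(vals <= 0)) {
    stop("non-positive value at line ", keep[which(vals <= 0)[1]], " of ",
         path, call. = FALSE)
  }
  vals
}
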
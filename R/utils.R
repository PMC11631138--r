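#' @importFrom stats quantile sd pnorm qnorm rbinom rpois rnbinom rnorm runif
#' @importFrom utils head read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a free-text condition term
#'
#' Lowercases, strips punctuation, and collapses whitespace so that condition
#' terms from trial records and phecode descriptions can be compared by exact
#' string equality.
#'
#' @param x Character vector of terms.
#' @return Character vector of normalized terms.
#' @export
#' @examples
#' normalize_term("  Type 2  Diabetes! ")
normalize_term <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("[[:punct:]]+", " ", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

is_valid_zip3 <- function(zip3) {
  is.character(zip3) & grepl("^[0-9]{3}$", zip3)
}

assert_zip3 <- function(zip3, what = "zip3") {
  bad <- !is_valid_zip3(zip3)
  if (any(bad)) {
    stop(sprintf("malformed %s: %s (expected three digits)", what,
                 paste(utils::head(unique(zip3[bad]), 5L), collapse = ", ")),
         call. = FALSE)
  }
  invisible(zip3)
}

# scalar date coercion used for reference dates
as_ref_date <- function(x) {
  d <- tryCatch(as.Date(x), error = function(e) NA)
  if (length(d) != 1L || is.na(d)) stop("invalid reference date: ", x, call. = FALSE)
  d
}
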
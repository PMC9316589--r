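#' Gini index of a nonnegative count vector
#'
#' Inequality of guide representation: 0 for a perfectly uniform library,
#' approaching 1 when reads concentrate on few guides. Computed from the
#' sorted vector as `sum((2i - n - 1) x_(i)) / (n sum x)`.
#'
#' @param x Nonnegative numeric vector.
#' @return A single number in \[0, 1); 0 for an all-zero vector.
#' @export
#' @examples
#' gini_index(rep(5, 10))       # 0
#' gini_index(c(0, 0, 0, 100))  # 0.75
gini_index <- function(x) {
  stopifnot(is.numeric(x), all(x >= 0), !anyNA(x))
  n <- length(x)
  s <- sum(x)
  if (n == 0L || s == 0) {
    return(0)
  }
  xs <- sort(x)
  sum((2 * seq_len(n) - n - 1) * xs) / (n * s)
}

## Gate membership is decided on quotients of decimal-rounded values so that
## guides sitting exactly on a threshold land on the same side on every
## platform.
round_stable <- function(x, digits = 12L) {
  round(x, digits)
}

## sample columns of a screen counts/normalized tibble (everything that is
## not an annotation column)
sample_cols <- function(x) {
  setdiff(names(x), c("guide_id", "gene"))
}

assert_file <- function(path, what = "file") {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    abort(sprintf("%s not found: %s", what, paste(path, collapse = ", ")))
  }
  invisible(path)
}

## random DNA strings of fixed width, vectorised
random_dna <- function(n, width) {
  if (n == 0L) {
    return(character(0))
  }
  m <- matrix(sample(c("A", "C", "G", "T"), n * width, replace = TRUE),
              nrow = n)
  apply(m, 1L, paste0, collapse = "")
}
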
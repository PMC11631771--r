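# internal helpers

stopf <- function(fmt, ..., class = "spotnet_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ..., class = "spotnet_error") {
  if (!isTRUE(cond)) stopf(fmt, ..., class = class)
  invisible(TRUE)
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) && x == floor(x)

# lexicographically-smallest mode of a character vector
lex_mode <- function(x) {
  tab <- table(x)
  names(tab)[order(-tab, names(tab))][1L]
}

# pairwise Euclidean distances between rows of a 2-column coordinate matrix
pair_dist <- function(xy) as.matrix(stats::dist(xy))
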
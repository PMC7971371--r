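# internal validation helpers

as_named_numeric <- function(x, what) {
  if (is.null(x) || length(x) == 0L) return(stats::setNames(numeric(), character()))
  x <- unlist(x)
  if (!is.numeric(x)) stop(what, " must be numeric", call. = FALSE)
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop(what, " must have non-empty names", call. = FALSE)
  }
  if (anyDuplicated(names(x))) {
    stop(what, " has duplicate keys: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "),
         call. = FALSE)
  }
  x
}

check_fraction <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(what, " must be a single number in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

check_nonneg <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    stop(what, " must be a single non-negative number", call. = FALSE)
  }
  invisible(x)
}

# stable sort: primary key decreasing, ties broken by name increasing
order_desc_by_name <- function(values, nms) {
  order(-values, nms, method = "radix")
}
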
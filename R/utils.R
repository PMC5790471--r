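# internal helpers

stop2 <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn2 <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# first few offenders, for error messages
.preview <- function(x, n = 5L) {
  x <- unique(x)
  extra <- if (length(x) > n) ", ..." else ""
  paste0(paste(utils::head(x, n), collapse = ", "), extra)
}
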
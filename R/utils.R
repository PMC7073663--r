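`%||%` <- function(a, b) if (is.null(a)) b else a

stat_mode <- function(x) {
  x <- x[!is.na(x)]
  tab <- sort(table(x), decreasing = TRUE)
  names(tab)[1L]
}

# sub-seeds for pipeline stages, all derived from one master seed so a single
# integer reproduces every stochastic stage
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

is_count_kind <- function(kind) kind %in% c("continuous", "count")

write_json_stable <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
}
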
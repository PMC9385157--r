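# Internal helpers: classed errors, seeded evaluation, deterministic CSV I/O.

sm_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(paste0("shellmea_", class), "shellmea_error")))
}

assert_scalar_number <- function(x, name, positive = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    sm_stop(sprintf("`%s` must be a single finite number", name), "invalid_parameter")
  if (positive && x <= 0)
    sm_stop(sprintf("`%s` must be > 0", name), "invalid_parameter")
  if (integerish && abs(x - round(x)) > 1e-8)
    sm_stop(sprintf("`%s` must be a whole number", name), "invalid_parameter")
  invisible(x)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream. seed = NULL leaves the global stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  assert_scalar_number(seed, "seed", integerish = TRUE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Fixed-format numeric columns so identical inputs always yield
# byte-identical CSV artifacts (locale- and precision-independent).
fmt_num <- function(x, digits) {
  out <- sprintf(paste0("%.", digits, "f"), x)
  out[is.na(x)] <- "NA"
  out
}

write_csv_deterministic <- function(df, path, digits = NULL) {
  stopifnot(is.data.frame(df))
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) {
      d <- if (!is.null(digits) && nm %in% names(digits)) digits[[nm]] else 6L
      out[[nm]] <- fmt_num(out[[nm]], d)
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(out, con, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n",
                     na = "NA")
  invisible(path)
}

read_csv_plain <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
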
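# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_dm <- function(..., call. = FALSE) stop(..., call. = call.)

check_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min ||
      x != as.integer(x)) {
    stop_dm(sprintf("'%s' must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1) {
    stop_dm(sprintf("'%s' must be a single number in [0, 1]", name))
  }
  as.numeric(x)
}

check_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_dm(sprintf("%s is missing required column(s): %s", what,
                    paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# sex-specific rubric entries may be a scalar or a list keyed by sex level;
# resolve to a per-row vector
resolve_by_sex <- function(entry, sex, what) {
  if (is.list(entry) && !is.null(names(entry))) {
    if (is.null(sex)) {
      stop_dm(sprintf("'%s' is sex-specific but no sex was supplied", what))
    }
    sex <- as.character(sex)
    bad <- setdiff(unique(sex), names(entry))
    if (length(bad)) {
      stop_dm(sprintf("sex level(s) %s not found in rubric entry '%s'",
                      paste(bad, collapse = ", "), what))
    }
    vapply(sex, function(s) as.numeric(entry[[s]]), numeric(1L),
           USE.NAMES = FALSE)
  } else {
    rep(as.numeric(entry), length(sex %||% 1L))
  }
}

# derive a reproducible child seed from a master seed and a stage label;
# kept below 2^31 so it is always a valid R integer seed
spawn_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}
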
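# Internal helpers shared across modules.

abort_validation <- function(message, ...) {
  rlang::abort(message, class = "bpthia_validation_error", ...)
}

# Check that `df` carries exactly one row per combination of the values in
# `grid` (a named list of key vectors). Returns invisibly; aborts naming the
# first few offending keys otherwise.
check_complete_grid <- function(df, grid, what) {
  full <- tidyr::expand_grid(!!!grid)
  missing <- dplyr::anti_join(full, df, by = names(grid))
  if (nrow(missing) > 0) {
    keys <- utils::head(apply(missing, 1, paste, collapse = ", "), 5)
    abort_validation(c(
      sprintf("%s is missing %d cell(s) of its index grid.", what, nrow(missing)),
      stats::setNames(sprintf("(%s)", keys), rep("x", length(keys)))
    ))
  }
  dup <- df[duplicated(df[names(grid)]), names(grid), drop = FALSE]
  if (nrow(dup) > 0) {
    abort_validation(sprintf("%s has duplicated key(s), e.g. (%s).",
                             what, paste(dup[1, ], collapse = ", ")))
  }
  invisible(df)
}

assert_cols <- function(df, cols, what) {
  if (!is.data.frame(df)) {
    abort_validation(sprintf("%s must be a data frame.", what))
  }
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    abort_validation(sprintf("%s lacks column(s): %s.", what,
                             paste(miss, collapse = ", ")))
  }
  invisible(df)
}

assert_scalar_number <- function(x, what, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    abort_validation(sprintf("%s must be a single non-missing number.", what))
  }
  if (x < min || x > max) {
    abort_validation(sprintf("%s must lie in [%s, %s], got %s.",
                             what, format(min), format(max), format(x)))
  }
  invisible(x)
}

# Evaluate `expr`, re-raising any error with the pipeline stage name attached.
with_stage <- function(stage, expr) {
  withCallingHandlers(expr, error = function(e) {
    rlang::abort(sprintf("[stage %s] %s", stage, conditionMessage(e)),
                 class = "bpthia_stage_error", parent = e)
  })
}

# Exact CSV reader: base R's numeric parser is correctly rounded, so a
# write_csv()/read_table_csv() cycle preserves doubles bit-for-bit. Key
# columns are kept as character.
read_table_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (nm in names(df)) {
    if (nm %in% c("id", "age_group", "region", "period", "path")) {
      df[[nm]] <- as.character(df[[nm]])
    } else if (is.integer(df[[nm]])) {
      df[[nm]] <- as.numeric(df[[nm]])
    }
  }
  tibble::as_tibble(df)
}

# Run `expr` with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
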
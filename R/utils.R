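# Internal helpers shared across modules.

abort <- function(msg, class) {
  stop(structure(
    class = c(class, "equicover_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

assert_that <- function(cond, msg, class = "equicover_invalid") {
  if (!isTRUE(cond)) abort(msg, class)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_prob <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x <= 1)

# Proportions may arrive on the percentage scale (e.g. values copied from a
# published table); anything above 1 is taken to be a percentage.
as_proportion <- function(x) {
  if (any(x > 1, na.rm = TRUE)) x / 100 else x
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards so library code never clobbers it.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

# Quartile-style labels QI, QII, ... for k ordered groups.
quantile_labels <- function(k) paste0("Q", as.character(utils::as.roman(seq_len(k))))

# Stable short hash of an R object (base R only; used for provenance).
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}
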
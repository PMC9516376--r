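## Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so seeded operations do not perturb
# the session RNG stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Escape regex metacharacters so keyword terms match literally.
regex_escape <- function(x) {
  gsub("([.\\\\|()\\[\\]{}^$*+?])", "\\\\\\1", x, perl = TRUE)
}

# Largest-remainder apportionment of `total` among groups with weights
# proportional to `sizes`; used for stratified test allocation.
largest_remainder <- function(sizes, fraction) {
  quota <- sizes * fraction
  base <- floor(quota)
  want <- round(sum(quota))
  rem <- quota - base
  extra <- want - sum(base)
  if (extra > 0) {
    ord <- order(rem, decreasing = TRUE)
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1L
  }
  as.integer(base)
}

# Round half away from zero (the tables report integer means, 1.5 -> 2).
round_half_up <- function(x) {
  floor(x + 0.5)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
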
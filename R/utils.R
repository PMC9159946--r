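# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, restoring the caller's
#' RNG state afterwards so library functions never perturb user randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
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
  set.seed(seed)
  code
}

# Deterministic substream seeds derived from one master seed.
# Kept below 2^31 so they are valid R integer seeds.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_invalid <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("clonescar_invalid_config", "error")))
}

stop_validation <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("clonescar_validation_error", "error")))
}

assert_count <- function(x, name, min = 1) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < min || x != round(x)) {
    stop_invalid("'%s' must be a single integer >= %d (got %s)",
                 name, min, paste(format(x), collapse = ","))
  }
  invisible(as.integer(x))
}

assert_fraction <- function(x, name) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < 0 || x > 1) {
    stop_invalid("'%s' must be a single value in [0, 1]", name)
  }
  invisible(as.numeric(x))
}

assert_number <- function(x, name, min = -Inf) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < min) {
    stop_invalid("'%s' must be a single number >= %s", name, format(min))
  }
  invisible(as.numeric(x))
}

# Reverse complement of plain character vectors of DNA.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Random DNA of given widths (uses current RNG stream).
random_dna <- function(widths) {
  vapply(widths, function(w) {
    paste(sample(c("A", "C", "G", "T"), w, replace = TRUE), collapse = "")
  }, character(1))
}

# Per-base substitution errors at rate `rate` (uses current RNG stream).
mutate_reads <- function(reads, rate) {
  if (rate <= 0) {
    return(reads)
  }
  vapply(reads, function(s) {
    n <- nchar(s)
    hit <- which(stats::runif(n) < rate)
    if (!length(hit)) {
      return(s)
    }
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    for (i in hit) {
      ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
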
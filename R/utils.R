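# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. `seed = NULL` uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Coerce a genome argument to a named uppercase character vector of sequences.
as_genome_chr <- function(genome, arg = "genome") {
  if (is(genome, "DNAStringSet")) {
    out <- toupper(as.character(genome))
  } else if (is.character(genome)) {
    out <- toupper(genome)
  } else {
    abort(sprintf("`%s` must be a DNAStringSet or a named character vector", arg))
  }
  if (is.null(names(out)) || anyNA(names(out)) || any(names(out) == "")) {
    abort(sprintf("`%s` must have (non-empty) chromosome names", arg))
  }
  if (anyDuplicated(names(out))) {
    abort(sprintf("`%s` has duplicated chromosome names", arg))
  }
  out
}

as_genome <- function(x) {
  if (is(x, "DNAStringSet")) return(x)
  Biostrings::DNAStringSet(as_genome_chr(x))
}

genome_lengths <- function(genome) {
  g <- as_genome_chr(genome)
  setNames(nchar(g), names(g))
}

check_fraction <- function(x, name, allow_one = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 ||
      (allow_one && x > 1) || (!allow_one && x >= 1)) {
    abort(sprintf("`%s` must be a single value in [0, %s]", name,
                  if (allow_one) "1" else "1)"))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  invisible(as.integer(x))
}

revcomp_chr <- function(x) {
  vapply(x, cpp_revcomp, character(1), USE.NAMES = FALSE)
}

# longest run of TRUE in a logical vector
longest_true_run <- function(x) {
  if (!length(x) || !any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}
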